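#' Map event coordinates onto reference exon ranks
#'
#' Attaches "gene and exon number" identifiers to IR and ES events by
#' matching their flanking (and, for ES, skipped) exon coordinates against
#' the gene's reference exons. Flanks are matched through their
#' junction-side boundary (the coordinate shared with the variable
#' element), so a flank whose outer boundary differs between isoforms still
#' maps to the correct reference exon; the skipped exon of an ES event must
#' match a reference exon exactly. Unmatched positions yield `NA` ranks.
#'
#' @param events Event table (IR and ES rows are annotated; other types are
#'   passed through with `NA` ranks).
#' @param ref_exons Reference exon table from [reference_exons()].
#' @return `events` with `rank_up`, `rank_down` (transcription-order
#'   flanks) and `rank_var` (skipped exon; `NA` for IR) columns.
#' @export
map_event_exon_ranks <- function(events, ref_exons) {
  key_start <- split(seq_len(nrow(ref_exons)),
                     paste(ref_exons$gene_id, ref_exons$start))
  key_end <- split(seq_len(nrow(ref_exons)),
                   paste(ref_exons$gene_id, ref_exons$end))
  key_both <- split(seq_len(nrow(ref_exons)),
                    paste(ref_exons$gene_id, ref_exons$start, ref_exons$end))
  rank_at <- function(keys, map) {
    vapply(keys, function(k) {
      idx <- map[[k]]
      if (is.null(idx)) NA_integer_ else ref_exons$rank[idx[1L]]
    }, integer(1L))
  }
  n <- nrow(events)
  rank_up <- rep(NA_integer_, n)
  rank_down <- rep(NA_integer_, n)
  rank_var <- rep(NA_integer_, n)
  sel <- events$event_type %in% c("IR", "ES")
  if (any(sel)) {
    ev <- events[sel, , drop = FALSE]
    plus <- ev$strand == "+"
    # junction-side boundary of each transcription-order flank:
    # upstream flank abuts the variable element at its 5' side
    up_key <- ifelse(plus, paste(ev$gene_id, ev$var_start),
                     paste(ev$gene_id, ev$var_end))
    down_key <- ifelse(plus, paste(ev$gene_id, ev$var_end),
                       paste(ev$gene_id, ev$var_start))
    rank_up[sel] <- ifelse(plus, rank_at(up_key, key_end),
                           rank_at(up_key, key_start))
    rank_down[sel] <- ifelse(plus, rank_at(down_key, key_start),
                             rank_at(down_key, key_end))
    is_es <- ev$event_type == "ES"
    if (any(is_es)) {
      var_key <- paste(ev$gene_id, ev$var_start, ev$var_end)[is_es]
      rv <- rank_at(var_key, key_both)
      rank_var[sel][is_es] <- rv
      # the skipped exon itself separates the flanks: for ES the flank
      # boundaries are the junction partners, one exon beyond the skipped
      # exon, so rematch them through the recorded flank intervals
      ev_es <- ev[is_es, , drop = FALSE]
      fu_key <- paste(ev_es$gene_id, ev_es$flank_up_start, ev_es$flank_up_end)
      fd_key <- paste(ev_es$gene_id, ev_es$flank_down_start,
                      ev_es$flank_down_end)
      exact_up <- rank_at(fu_key, key_both)
      exact_down <- rank_at(fd_key, key_both)
      plus_es <- ev_es$strand == "+"
      bnd_up <- ifelse(plus_es, paste(ev_es$gene_id, ev_es$flank_up_end),
                       paste(ev_es$gene_id, ev_es$flank_up_start))
      bnd_down <- ifelse(plus_es, paste(ev_es$gene_id, ev_es$flank_down_start),
                         paste(ev_es$gene_id, ev_es$flank_down_end))
      fb_up <- ifelse(plus_es, rank_at(bnd_up, key_end),
                      rank_at(bnd_up, key_start))
      fb_down <- ifelse(plus_es, rank_at(bnd_down, key_start),
                        rank_at(bnd_down, key_end))
      rank_up[sel][is_es] <- ifelse(is.na(exact_up), fb_up, exact_up)
      rank_down[sel][is_es] <- ifelse(is.na(exact_down), fb_down, exact_down)
    }
  }
  events$rank_up <- rank_up
  events$rank_down <- rank_down
  events$rank_var <- rank_var
  events
}

# fast membership test for RBH pairs, symmetric in the two sides
rbh_pair_set <- function(rbh_map) {
  fwd <- paste(rbh_map$unit_a, rbh_map$gene_a, rbh_map$rank_a,
               rbh_map$unit_b, rbh_map$gene_b, rbh_map$rank_b)
  rev <- paste(rbh_map$unit_b, rbh_map$gene_b, rbh_map$rank_b,
               rbh_map$unit_a, rbh_map$gene_a, rbh_map$rank_a)
  unique(c(fwd, rev))
}

is_rbh <- function(set, unit_a, gene_a, rank_a, unit_b, gene_b, rank_b) {
  !is.na(rank_a) & !is.na(rank_b) &
    paste(unit_a, gene_a, rank_a, unit_b, gene_b, rank_b) %in% set
}

conservation_call <- function(status, reason) {
  list(status = status, reason = reason)
}

#' Pairwise conservation call for two exon-skipping events
#'
#' The two ES events (one per species/genome unit) are conserved when (i)
#' they lie in the same orthogroup, (ii) the skipped exons form an RBH pair
#' between the two units, and (iii) the transcription-order upstream and
#' downstream flanking exons each form RBH pairs with their counterparts.
#' When a flank is unavailable in both events (terminal skipped exon), the
#' RBH requirement applies only to the single available flank. The first
#' failing criterion, in order (i), (ii), (iii), becomes the reason.
#'
#' @param event_a,event_b Single event rows (lists or one-row tibbles) with
#'   `event_type`, `gene_id`, `unit`, `orthogroup_id`, and the `rank_*`
#'   columns from [map_event_exon_ranks()].
#' @param rbh_set Pair set from `rbh_pair_set()` applied to a
#'   [build_rbh_map()] result (a tibble is also accepted).
#' @return A list with `status` (`"conserved"`/`"non_conserved"`) and
#'   `reason` (`"ok"`, `"not_same_orthogroup"`, `"skipped_exon_not_rbh"`,
#'   `"flank_not_rbh"`).
#' @export
call_conserved_es <- function(event_a, event_b, rbh_set) {
  if (event_a$event_type != "ES" || event_b$event_type != "ES") {
    stopf("call_conserved_es() requires two ES events")
  }
  if (is.data.frame(rbh_set)) rbh_set <- rbh_pair_set(rbh_set)
  if (is.na(event_a$orthogroup_id) || is.na(event_b$orthogroup_id) ||
      event_a$orthogroup_id != event_b$orthogroup_id) {
    return(conservation_call("non_conserved", "not_same_orthogroup"))
  }
  if (!is_rbh(rbh_set, event_a$unit, event_a$gene_id, event_a$rank_var,
              event_b$unit, event_b$gene_id, event_b$rank_var)) {
    return(conservation_call("non_conserved", "skipped_exon_not_rbh"))
  }
  for (side in c("rank_up", "rank_down")) {
    ra <- event_a[[side]]; rb <- event_b[[side]]
    if (is.na(ra) && is.na(rb)) next  # terminal: flank absent in both
    if (is.na(ra) || is.na(rb) ||
        !is_rbh(rbh_set, event_a$unit, event_a$gene_id, ra,
                event_b$unit, event_b$gene_id, rb)) {
      return(conservation_call("non_conserved", "flank_not_rbh"))
    }
  }
  conservation_call("conserved", "ok")
}

#' Pairwise conservation call for two intron-retention events
#'
#' Conserved when both events lie in the same orthogroup and the retained
#' intron sits between the same pair of flanking exons, enforced by
#' requiring each transcription-order flank (upstream with upstream,
#' downstream with downstream) to form an RBH pair with its counterpart.
#'
#' @inheritParams call_conserved_es
#' @return As [call_conserved_es()].
#' @export
call_conserved_ir <- function(event_a, event_b, rbh_set) {
  if (event_a$event_type != "IR" || event_b$event_type != "IR") {
    stopf("call_conserved_ir() requires two IR events")
  }
  if (is.data.frame(rbh_set)) rbh_set <- rbh_pair_set(rbh_set)
  if (is.na(event_a$orthogroup_id) || is.na(event_b$orthogroup_id) ||
      event_a$orthogroup_id != event_b$orthogroup_id) {
    return(conservation_call("non_conserved", "not_same_orthogroup"))
  }
  for (side in c("rank_up", "rank_down")) {
    ra <- event_a[[side]]; rb <- event_b[[side]]
    if (is.na(ra) || is.na(rb) ||
        !is_rbh(rbh_set, event_a$unit, event_a$gene_id, ra,
                event_b$unit, event_b$gene_id, rb)) {
      return(conservation_call("non_conserved", "flank_not_rbh"))
    }
  }
  conservation_call("conserved", "ok")
}

#' Pairwise conservation calls across a cohort
#'
#' Compares every pair of same-type IR/ES events from different genome
#' units of different species within each single-copy orthogroup.
#' An event with no conserved partner in some other species is implicitly
#' non-conserved there (reason `missing_in_other` at the summary level);
#' only explicit event-pair comparisons are returned.
#'
#' @param events Event table restricted to one tissue, annotated with
#'   `unit`, `species_id`, `orthogroup_id` and exon ranks
#'   ([map_event_exon_ranks()]).
#' @param rbh_map RBH table from [build_rbh_map()].
#' @return A tibble of pairwise calls with member identifiers, `status` and
#'   `reason`.
#' @export
pairwise_conservation <- function(events, rbh_map) {
  rbh_set <- rbh_pair_set(rbh_map)
  ev <- events[events$event_type %in% c("IR", "ES") &
                 !is.na(events$orthogroup_id), , drop = FALSE]
  rows <- list()
  for (og in unique(ev$orthogroup_id)) {
    sub <- ev[ev$orthogroup_id == og, , drop = FALSE]
    for (tp in unique(sub$event_type)) {
      ss <- sub[sub$event_type == tp, , drop = FALSE]
      n <- nrow(ss)
      if (n < 2L) next
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (ss$unit[i] == ss$unit[j]) next
        if (ss$species_id[i] == ss$species_id[j]) next
        a <- as.list(ss[i, ]); b <- as.list(ss[j, ])
        call <- if (tp == "IR") call_conserved_ir(a, b, rbh_set)
                else call_conserved_es(a, b, rbh_set)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          orthogroup_id = og, event_type = tp,
          unit_a = a$unit, species_a = a$species_id, gene_a = a$gene_id,
          event_a = a$event_id,
          unit_b = b$unit, species_b = b$species_id, gene_b = b$gene_id,
          event_b = b$event_id,
          status = call$status, reason = call$reason
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(orthogroup_id = character(), event_type = character(),
                          unit_a = character(), species_a = character(),
                          gene_a = character(), event_a = character(),
                          unit_b = character(), species_b = character(),
                          gene_b = character(), event_b = character(),
                          status = character(), reason = character()))
  }
  dplyr::bind_rows(rows)
}

#' Merge pairwise conservation calls into multi-species clusters
#'
#' Events are nodes and conserved pairwise calls are edges; clusters are
#' the connected components spanning at least two species (transitive
#' merging across the orthogroup, matching organization by orthologous
#' family and exon-number identifiers). A strict-clique mode restricts
#' clusters to maximal sets in which every cross-species pair was called
#' conserved.
#'
#' @param calls Pairwise call table from [pairwise_conservation()] (one
#'   tissue, or pre-annotated with a `tissue` column constant).
#' @param clique Require complete pairwise conservation within a cluster.
#' @return A tibble with one row per cluster member: `cluster_id`,
#'   `event_type`, `orthogroup_id`, `unit`, `species_id`, `gene_id`,
#'   `event_id`, plus per-cluster `species_level` (number of distinct
#'   species) and `n_events`.
#' @export
build_clusters <- function(calls, clique = FALSE) {
  cons <- calls[calls$status == "conserved", , drop = FALSE]
  empty <- tibble::tibble(cluster_id = character(), event_type = character(),
                          orthogroup_id = character(), unit = character(),
                          species_id = character(), gene_id = character(),
                          event_id = character(), species_level = integer(),
                          n_events = integer())
  if (nrow(cons) == 0L) return(empty)
  node_a <- paste(cons$unit_a, cons$event_a, sep = "|")
  node_b <- paste(cons$unit_b, cons$event_b, sep = "|")
  g <- igraph::graph_from_edgelist(cbind(node_a, node_b), directed = FALSE)
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  membership <- comp$membership
  node_info <- unique(rbind(
    data.frame(node = node_a, event_type = cons$event_type,
               orthogroup_id = cons$orthogroup_id, unit = cons$unit_a,
               species_id = cons$species_a, gene_id = cons$gene_a,
               event_id = cons$event_a, stringsAsFactors = FALSE),
    data.frame(node = node_b, event_type = cons$event_type,
               orthogroup_id = cons$orthogroup_id, unit = cons$unit_b,
               species_id = cons$species_b, gene_id = cons$gene_b,
               event_id = cons$event_b, stringsAsFactors = FALSE)
  ))
  node_info$component <- membership[node_info$node]
  if (clique) {
    edge_set <- unique(c(paste(node_a, node_b), paste(node_b, node_a)))
    keep <- vapply(split(node_info$node, node_info$component), function(nodes) {
      if (length(nodes) < 2L) return(TRUE)
      prs <- utils::combn(nodes, 2L)
      all(paste(prs[1L, ], prs[2L, ]) %in% edge_set)
    }, logical(1L))
    node_info <- node_info[keep[as.character(node_info$component)], ,
                           drop = FALSE]
  }
  per <- dplyr::summarise(
    dplyr::group_by(node_info, .data$component),
    species_level = dplyr::n_distinct(.data$species_id),
    n_events = dplyr::n(), .groups = "drop"
  )
  node_info <- dplyr::inner_join(node_info, per, by = "component")
  node_info <- node_info[node_info$species_level >= 2L, , drop = FALSE]
  node_info <- dplyr::arrange(tibble::as_tibble(node_info),
                              .data$orthogroup_id, .data$event_type,
                              .data$unit, .data$event_id)
  ids <- match(node_info$component, unique(node_info$component))
  node_info$cluster_id <- sprintf("CL%04d", ids)
  dplyr::select(node_info, "cluster_id", "event_type", "orthogroup_id",
                "unit", "species_id", "gene_id", "event_id",
                "species_level", "n_events")
}

#' Shared conserved clusters per subgenome unit combination
#'
#' Tabulates, for the allotetraploid subgenome units only, how many
#' conserved clusters have members in exactly each pair or triple of units,
#' mirroring subgenome-resolved sharing matrices.
#'
#' @param clusters Cluster member table from [build_clusters()].
#' @param tetraploid_units Character vector of the subgenome unit ids
#'   (e.g. `"Pgi_A"`); members outside this set are ignored.
#' @return A tibble with `unit_set` (sorted, `+`-joined), `n_units` and
#'   `n_clusters`.
#' @export
subgenome_summary <- function(clusters, tetraploid_units) {
  sub <- clusters[clusters$unit %in% tetraploid_units, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(tibble::tibble(unit_set = character(), n_units = integer(),
                          n_clusters = integer()))
  }
  sets <- vapply(split(sub$unit, sub$cluster_id),
                 function(u) paste(sort(unique(u)), collapse = "+"),
                 character(1L))
  sizes <- lengths(lapply(strsplit(sets, "+", fixed = TRUE), unique))
  keep <- sizes %in% c(2L, 3L)
  tb <- table(sets[keep])
  tibble::tibble(unit_set = names(tb),
                 n_units = lengths(strsplit(names(tb), "+", fixed = TRUE)),
                 n_clusters = as.integer(tb))
}

#' Summary of conserved clusters
#'
#' @param clusters Cluster member table from [build_clusters()] (one
#'   tissue).
#' @return A list with `by_type` (cluster/event/gene counts and cluster
#'   share per event type, share reported to 0.1%), `by_level` (cluster
#'   counts by type and species level), and scalar totals.
#' @export
conservation_summary <- function(clusters) {
  cl <- dplyr::distinct(clusters, .data$cluster_id, .data$event_type,
                        .data$species_level)
  total <- nrow(cl)
  by_type <- dplyr::summarise(
    dplyr::group_by(clusters, .data$event_type),
    n_clusters = dplyr::n_distinct(.data$cluster_id),
    n_events = dplyr::n(),
    n_genes = dplyr::n_distinct(.data$gene_id),
    .groups = "drop"
  )
  by_type$share_pct <- percent_share(by_type$n_clusters, total, digits = 1)
  by_level <- dplyr::count(cl, .data$event_type, .data$species_level,
                           name = "n_clusters")
  list(by_type = by_type, by_level = by_level,
       n_clusters = total,
       n_events = nrow(clusters),
       n_genes = dplyr::n_distinct(clusters$gene_id))
}

#' Conserved clusters at or above each species-sharing level
#'
#' @param clusters Cluster member table from [build_clusters()].
#' @return A tibble with `species_level` N and `n_clusters_at_least`, the
#'   number of clusters shared by N or more species (non-increasing in N).
#' @export
clusters_by_min_level <- function(clusters) {
  cl <- dplyr::distinct(clusters, .data$cluster_id, .data$species_level)
  levels <- seq(2L, max(cl$species_level, 2L))
  tibble::tibble(
    species_level = levels,
    n_clusters_at_least = vapply(levels, function(N)
      sum(cl$species_level >= N), integer(1L))
  )
}
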