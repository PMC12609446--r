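#' Configuration for the synthetic multi-species cohort
#'
#' Defines the study conditions emulated by the generator: five species of
#' which two are diploid and three are allotetraploid (each contributing
#' subgenome units A and B), sharing single-copy orthogroups of multi-exon
#' genes; per-unit sequence divergence through point substitutions; planted
#' AS events of the four types with known cross-species conservation
#' levels; and per-tissue PSI values realized as binomially sampled
#' replicate read counts.
#'
#' Generator knobs mirror the directions expected of real splicing
#' landscapes: retained-intron candidates are GC-richer and shorter than
#' background introns, and skipped-exon candidates are GC-poorer than
#' background exons.
#'
#' @param species Tibble with `species_id` and `ploidy`
#'   (`"diploid"`/`"tetraploid"`).
#' @param n_orthogroups Number of single-copy orthogroups.
#' @param exons_per_gene Inclusive range of exon counts per gene.
#' @param exon_length,intron_length Length ranges (bp) of background exons
#'   and introns.
#' @param ir_intron_length Length range of introns at planted IR positions.
#' @param gc_background,gc_ir_intron,gc_skipped_exon GC fractions used when
#'   sampling ancestral sequence.
#' @param divergence Per-site substitution probability on each unit's
#'   branch from the ancestor (two units then differ at up to twice this
#'   rate).
#' @param events_per_orthogroup Planted AS events per orthogroup.
#' @param type_rates Named sampling weights over `IR`, `A3`, `A5`, `ES`.
#' @param level_probs Probabilities that a planted event is shared by
#'   1..5 species.
#' @param dse_rates_specific,dse_rates_conserved Class weights
#'   (`none`/`DAS`/`gain`/`loss`) for species-specific and for conserved
#'   events; conserved events are kept at intermediate PSI in both tissues.
#' @param depth Binomial read depth per replicate and event.
#' @param replicates Biological replicates per sample.
#' @param tissues Tissue labels (condition 1 first).
#' @param seed Integer seed fixing all randomness of the cohort.
#' @return A named list of class `cohort_config`.
#' @export
cohort_config <- function(species = tibble::tibble(
                            species_id = c("Pst", "Pno", "Pgi", "Pqu", "Pja"),
                            ploidy = c("diploid", "diploid", "tetraploid",
                                       "tetraploid", "tetraploid")),
                          n_orthogroups = 200L,
                          exons_per_gene = c(4L, 8L),
                          exon_length = c(80L, 300L),
                          intron_length = c(80L, 200L),
                          ir_intron_length = c(60L, 120L),
                          gc_background = 0.40,
                          gc_ir_intron = 0.55,
                          gc_skipped_exon = 0.32,
                          divergence = 0.05,
                          events_per_orthogroup = 2L,
                          type_rates = c(IR = 0.5, A3 = 0.2, A5 = 0.2, ES = 0.1),
                          level_probs = c(0.30, 0.25, 0.20, 0.15, 0.10),
                          dse_rates_specific = c(none = 0.4, DAS = 0.2,
                                                 gain = 0.2, loss = 0.2),
                          dse_rates_conserved = c(none = 0.6, DAS = 0.4),
                          depth = 100L,
                          replicates = 3L,
                          tissues = c("leaf", "root"),
                          seed = 1L) {
  cfg <- list(species = species, n_orthogroups = n_orthogroups,
              exons_per_gene = exons_per_gene, exon_length = exon_length,
              intron_length = intron_length,
              ir_intron_length = ir_intron_length,
              gc_background = gc_background, gc_ir_intron = gc_ir_intron,
              gc_skipped_exon = gc_skipped_exon, divergence = divergence,
              events_per_orthogroup = events_per_orthogroup,
              type_rates = type_rates, level_probs = level_probs,
              dse_rates_specific = dse_rates_specific,
              dse_rates_conserved = dse_rates_conserved,
              depth = depth, replicates = replicates, tissues = tissues,
              seed = seed)
  probs <- c(type_rates, level_probs, dse_rates_specific, dse_rates_conserved,
             divergence, gc_background, gc_ir_intron, gc_skipped_exon)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (min(exon_length) < 40L) stopf("exons must be at least 40 bp")
  if (min(intron_length) < 40L || min(ir_intron_length) < 40L) {
    stopf("introns must be at least 40 bp (planted boundary shifts need room)")
  }
  structure(cfg, class = "cohort_config")
}

rand_bases <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

mutate_bases <- function(bases, rate) {
  hit <- which(stats::runif(length(bases)) < rate)
  if (length(hit) > 0L) {
    repl <- sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
    same <- repl == bases[hit]
    while (any(same)) {
      repl[same] <- sample(c("A", "C", "G", "T"), sum(same), replace = TRUE)
      same <- repl == bases[hit]
    }
    bases[hit] <- repl
  }
  bases
}

sample_range <- function(rng, n = 1L) {
  if (rng[1L] == rng[2L]) rep(rng[1L], n) else
    sample(seq(rng[1L], rng[2L]), n, replace = TRUE)
}

# Plant event positions so that no two events interact: each planted event
# claims a window of intron indices (the intron itself for IR/A5/A3, the
# two introns around the skipped exon for ES) and windows are disjoint.
plan_orthogroup_events <- function(n_ex, n_events, type_rates) {
  free <- rep(TRUE, n_ex - 1L)
  plans <- list()
  for (k in seq_len(n_events)) {
    type <- sample(names(type_rates), 1L, prob = type_rates)
    if (type == "ES") {
      cand <- (2:(n_ex - 1L))[free[seq(1L, n_ex - 2L)] & free[seq(2L, n_ex - 1L)]]
      if (length(cand) == 0L) {
        type <- sample(c("IR", "A3", "A5"), 1L)
      } else {
        j <- if (length(cand) == 1L) cand else sample(cand, 1L)
        free[c(j - 1L, j)] <- FALSE
        plans[[length(plans) + 1L]] <- list(type = "ES", exon = j)
        next
      }
    }
    cand <- which(free)
    if (length(cand) == 0L) break
    i <- if (length(cand) == 1L) cand else sample(cand, 1L)
    free[i] <- FALSE
    plans[[length(plans) + 1L]] <- list(type = type, intron = i)
  }
  plans
}

draw_psi_pair <- function(class) {
  switch(class,
    none = { p <- stats::runif(1, 0.25, 0.75); c(p, p) },
    DAS = {
      p <- stats::runif(1, 0.15, 0.45)
      if (stats::runif(1) < 0.5) c(p, p + 0.3) else c(p + 0.3, p)
    },
    gain = c(sample(c(0.98, 0.02), 1L), stats::runif(1, 0.3, 0.7)),
    loss = c(stats::runif(1, 0.3, 0.7), sample(c(0.98, 0.02), 1L))
  )
}

#' Generate a synthetic multi-species cohort with ground truth
#'
#' Synthesizes ancestral multi-exon genes, derives one diverged copy per
#' genome unit (a diploid genome, or subgenome A/B of an allotetraploid),
#' plants AS events as additional transcript isoforms at homologous
#' positions in the designated species sets, and simulates replicate
#' inclusion/exclusion read counts from the planted per-tissue PSI values.
#' Substitutions only (no indels), so exon coordinates remain homologous by
#' construction and the truth tables are exact; canonical GT..AG
#' dinucleotides are written at intron boundaries for realism.
#'
#' @param config A [cohort_config()].
#' @return A list with `models` (exon table), `genome`
#'   ([Biostrings::DNAStringSet], one chromosome per unit), `orthogroups`,
#'   `counts`, `units`, and `truth` — a list with `events` (one row per
#'   planted event instance: type, conservation level, true PSI per tissue,
#'   true differential-splicing class, and the identifiers the detector
#'   will assign) and `clusters` (planted conserved IR/ES clusters).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  sp <- config$species
  units <- dplyr::bind_rows(lapply(seq_len(nrow(sp)), function(i) {
    if (sp$ploidy[i] == "tetraploid") {
      tibble::tibble(species_id = sp$species_id[i], subgenome = c("A", "B"))
    } else {
      tibble::tibble(species_id = sp$species_id[i], subgenome = "none")
    }
  }))
  units$unit <- unit_id(units$species_id, units$subgenome)
  nu <- nrow(units)
  spacer <- 100L

  chrom_parts <- stats::setNames(vector("list", nu), units$unit)
  offsets <- stats::setNames(rep(0L, nu), units$unit)
  model_rows <- list()
  og_rows <- list()
  truth_rows <- list()

  for (g in seq_len(config$n_orthogroups)) {
    og_id <- sprintf("OG%04d", g)
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample_range(config$exons_per_gene)
    plans <- plan_orthogroup_events(n_ex, config$events_per_orthogroup,
                                    config$type_rates)
    ir_pos <- vapply(plans, function(p)
      if (p$type == "IR") p$intron else NA_integer_, integer(1L))
    es_pos <- vapply(plans, function(p)
      if (p$type == "ES") p$exon else NA_integer_, integer(1L))

    il <- sample_range(config$intron_length, n_ex - 1L)
    il[stats::na.omit(ir_pos)] <- sample_range(config$ir_intron_length,
                                               length(stats::na.omit(ir_pos)))
    el <- sample_range(config$exon_length, n_ex)

    # per-event metadata: members, class, PSI, boundary shift
    for (k in seq_along(plans)) {
      p <- plans[[k]]
      n_lvl <- min(length(config$level_probs), nrow(sp))
      lvl <- sample(seq_len(n_lvl), 1L,
                    prob = config$level_probs[seq_len(n_lvl)])
      members <- sample(sp$species_id, lvl)
      p$units <- vapply(members, function(s) {
        u <- units$unit[units$species_id == s]
        if (length(u) > 1L) sample(u, 1L) else u
      }, character(1L))
      rates <- if (lvl >= 2L) config$dse_rates_conserved
               else config$dse_rates_specific
      p$class <- sample(names(rates), 1L, prob = rates)
      p$psi <- draw_psi_pair(p$class)
      p$level <- lvl
      if (p$type %in% c("A3", "A5")) {
        p$delta <- sample_range(c(8L, min(30L, il[p$intron] - 15L)))
        p$shift_right <- (p$type == "A3" && strand == "+") ||
          (p$type == "A5" && strand == "-")
      }
      plans[[k]] <- p
    }

    # ancestral sequence parts (exons and introns interleaved)
    gc_ex <- rep(config$gc_background, n_ex)
    gc_ex[stats::na.omit(es_pos)] <- config$gc_skipped_exon
    gc_in <- rep(config$gc_background, n_ex - 1L)
    gc_in[stats::na.omit(ir_pos)] <- config$gc_ir_intron
    parts <- vector("list", 2L * n_ex - 1L)
    for (i in seq_len(n_ex)) parts[[2L * i - 1L]] <- rand_bases(el[i], gc_ex[i])
    for (i in seq_len(n_ex - 1L)) {
      intr <- rand_bases(il[i], gc_in[i])
      if (strand == "+") {
        intr[1:2] <- c("G", "T"); intr[(il[i] - 1L):il[i]] <- c("A", "G")
      } else {
        intr[1:2] <- c("C", "T"); intr[(il[i] - 1L):il[i]] <- c("A", "C")
      }
      parts[[2L * i]] <- intr
    }
    anc <- unlist(parts)

    # local exon coordinates (0-based half-open, gene-local)
    s_loc <- integer(n_ex); e_loc <- integer(n_ex)
    pos <- 0L
    for (i in seq_len(n_ex)) {
      s_loc[i] <- pos; e_loc[i] <- pos + el[i]
      pos <- e_loc[i] + if (i < n_ex) il[i] else 0L
    }
    gene_len <- pos

    for (u in seq_len(nu)) {
      un <- units$unit[u]
      gene_id <- sprintf("%s_g%04d", un, g)
      chrom <- paste0(un, "_chr1")
      o <- offsets[[un]]
      seq_u <- mutate_bases(anc, config$divergence)
      chrom_parts[[un]] <- c(chrom_parts[[un]], list(seq_u),
                             list(rand_bases(spacer, config$gc_background)))
      offsets[[un]] <- o + gene_len + spacer
      s <- o + s_loc; e <- o + e_loc

      tx_list <- list(cbind(s, e))
      tx_ids <- sprintf("%s.t1", gene_id)
      for (k in seq_along(plans)) {
        p <- plans[[k]]
        if (!un %in% p$units) next
        iso <- switch(p$type,
          IR = {
            i <- p$intron
            ss <- s[-(i + 1L)]; ee <- e[-(i + 1L)]; ee[i] <- e[i + 1L]
            cbind(ss, ee)
          },
          ES = {
            j <- p$exon
            cbind(s[-j], e[-j])
          },
          {
            i <- p$intron
            ss <- s; ee <- e
            if (p$shift_right) ss[i + 1L] <- s[i + 1L] - p$delta
            else ee[i] <- e[i] + p$delta
            cbind(ss, ee)
          })
        tx_list[[length(tx_list) + 1L]] <- iso
        tx_ids <- c(tx_ids, sprintf("%s.t%d", gene_id, length(tx_list)))

        # truth identifiers exactly as the detector derives them
        truth_rows[[length(truth_rows) + 1L]] <- truth_event_row(
          p, k, og_id, gene_id, chrom, strand, s, e, un,
          units$species_id[u], units$subgenome[u]
        )
      }
      for (t in seq_along(tx_list)) {
        m <- tx_list[[t]]
        k2 <- nrow(m)
        rk <- if (strand == "+") seq_len(k2) else rev(seq_len(k2))
        model_rows[[length(model_rows) + 1L]] <- list(
          gene_id = rep(gene_id, k2), transcript_id = rep(tx_ids[t], k2),
          chrom = rep(chrom, k2), start = m[, 1L], end = m[, 2L],
          strand = rep(strand, k2), rank = rk,
          class_code = rep(NA_character_, k2),
          species_id = rep(units$species_id[u], k2),
          subgenome = rep(units$subgenome[u], k2), unit = rep(un, k2)
        )
      }
      og_rows[[length(og_rows) + 1L]] <- list(
        orthogroup_id = og_id, species_id = units$species_id[u],
        subgenome = units$subgenome[u], gene_id = gene_id
      )
    }
  }

  models <- tibble::as_tibble(data.table::rbindlist(model_rows))
  models <- dplyr::arrange(models, .data$chrom, .data$start, .data$gene_id,
                           .data$transcript_id, .data$rank)
  genome <- Biostrings::DNAStringSet(vapply(chrom_parts, function(p)
    paste0(unlist(p), collapse = ""), character(1L)))
  names(genome) <- paste0(units$unit, "_chr1")
  orthogroups <- read_orthogroups(tibble::as_tibble(data.table::rbindlist(og_rows)))
  truth_events <- tibble::as_tibble(data.table::rbindlist(truth_rows))

  counts <- simulate_read_counts(
    tibble::tibble(
      sample_id = rep(paste(truth_events$species_id,
                            rep(config$tissues, each = nrow(truth_events)),
                            sep = "_"), 1L),
      inclusion_form = rep(truth_events$inclusion_form, length(config$tissues)),
      exclusion_form = rep(truth_events$exclusion_form, length(config$tissues)),
      psi = c(truth_events$psi_leaf, truth_events$psi_root)
    ),
    depth = config$depth, replicates = config$replicates
  )

  truth_clusters <- truth_events[truth_events$species_level >= 2L &
                                   truth_events$event_type %in% c("IR", "ES"), ,
                                 drop = FALSE]
  list(models = models, genome = genome, orthogroups = orthogroups,
       counts = counts, units = units,
       truth = list(events = truth_events, clusters = truth_clusters,
                    config = config))
}

truth_event_row <- function(p, k, og_id, gene_id, chrom, strand, s, e,
                            un, species_id, subgenome) {
  if (p$type == "IR") {
    i <- p$intron
    id <- make_event_id(gene_id, "IR", chrom, strand,
                        c(s[i], e[i], s[i + 1L], e[i + 1L]))
    incl <- body_key(chrom, e[i], s[i + 1L])
    excl <- junc_key(chrom, e[i], s[i + 1L])
  } else if (p$type == "ES") {
    j <- p$exon
    id <- make_event_id(gene_id, "ES", chrom, strand,
                        c(e[j - 1L], s[j], e[j], s[j + 1L]))
    incl <- body_key(chrom, s[j], e[j])
    excl <- junc_key(chrom, e[j - 1L], s[j + 1L])
  } else {
    i <- p$intron; b <- e[i]; cc <- s[i + 1L]
    if (p$shift_right) {
      id <- make_event_id(gene_id, p$type, chrom, strand,
                          c("R", b, cc - p$delta, cc))
      incl <- body_key(chrom, cc - p$delta, cc)
    } else {
      id <- make_event_id(gene_id, p$type, chrom, strand,
                          c("L", cc, b, b + p$delta))
      incl <- body_key(chrom, b, b + p$delta)
    }
    excl <- junc_key(chrom, b, cc)
  }
  list(
    orthogroup_id = og_id, planted_key = sprintf("%s_ev%d", og_id, k),
    event_type = p$type, species_level = p$level, dse_class = p$class,
    psi_leaf = p$psi[1L], psi_root = p$psi[2L],
    unit = un, species_id = species_id, subgenome = subgenome,
    gene_id = gene_id, event_id = id,
    inclusion_form = incl, exclusion_form = excl, chrom = chrom
  )
}

#' Simulate replicate junction/element read counts from planted PSI
#'
#' For each event, sample and replicate, the inclusion count is drawn as
#' `Binomial(depth, psi)` and the exclusion count is `depth - inclusion`,
#' written under the event's inclusion and exclusion feature keys.
#'
#' @param truth_psi Tibble with columns `sample_id`, `inclusion_form`,
#'   `exclusion_form`, `psi`.
#' @param depth Reads per replicate and event (at least 1).
#' @param replicates Number of replicates per sample.
#' @param seed Optional seed; by default the current RNG stream is used.
#' @return A count table ([read_count_table()] layout).
#' @export
simulate_read_counts <- function(truth_psi, depth, replicates = 3L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (depth < 1L) stopf("depth must be at least 1")
  if (any(truth_psi$psi < 0 | truth_psi$psi > 1)) {
    stopf("planted PSI outside [0, 1]")
  }
  n <- nrow(truth_psi)
  rows <- lapply(seq_len(replicates), function(r) {
    inc <- stats::rbinom(n, depth, truth_psi$psi)
    tibble::tibble(
      sample_id = rep(truth_psi$sample_id, 2L),
      replicate = r,
      feature_key = c(truth_psi$inclusion_form, truth_psi$exclusion_form),
      count = c(inc, depth - inc)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$replicate <- as.integer(out$replicate)
  out$count <- as.integer(out$count)
  dplyr::arrange(out, .data$sample_id, .data$replicate, .data$feature_key)
}

#' Write a synthetic cohort to standard files
#'
#' Emits the cohort as one GTF (all units), one genome FASTA, and TSVs for
#' orthogroups, counts and truth events.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    gtf = file.path(dir, "annotation.gtf"),
    fasta = file.path(dir, "genome.fa"),
    orthogroups = file.path(dir, "orthogroups.tsv"),
    counts = file.path(dir, "counts.tsv"),
    truth_events = file.path(dir, "truth_events.tsv")
  )
  write_gene_models(cohort$models, paths[["gtf"]])
  Biostrings::writeXStringSet(cohort$genome, paths[["fasta"]])
  readr::write_tsv(cohort$orthogroups[, c("orthogroup_id", "species_id",
                                          "subgenome", "gene_id")],
                   paths[["orthogroups"]])
  readr::write_tsv(cohort$counts, paths[["counts"]])
  readr::write_tsv(cohort$truth$events, paths[["truth_events"]])
  invisible(paths)
}
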