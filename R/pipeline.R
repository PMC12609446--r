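#' Run the full splicing-conservation pipeline
#'
#' Orchestrates the stages on a cohort (a generated synthetic cohort, or
#' objects ingested from files): event detection, read-support filtering,
#' PSI quantification and presence filtering, per-species differential
#' splicing between the two tissues, sequence-feature contrasts, the exon
#' RBH homology reference set, per-tissue conservation calling and
#' clustering, and the reporting summaries. When `out_dir` is given, each
#' stage writes its TSV interface there along with a JSON run manifest
#' (configuration snapshot, seed, per-stage row counts, file checksums).
#'
#' @param cohort A cohort list as returned by [generate_cohort()], or
#'   `NULL` to generate one from `config`.
#' @param config A [cohort_config()] used when `cohort` is `NULL`.
#' @param out_dir Optional output directory for stage TSVs and manifest.
#' @param min_reads Read-support threshold (strict `>`).
#' @param dpsi,alpha,hi,lo Differential-splicing thresholds
#'   ([classify_dse()]).
#' @param evalue_max,min_cov RBH filters ([build_rbh_map()]).
#' @param clique Use strict-clique clusters ([build_clusters()]).
#' @return A list with the stage tables: `events`, `support`,
#'   `events_supported`, `psi`, `present`, `dse`, `features`,
#'   `feature_tests`, `rbh`, `calls`, `clusters` (per tissue),
#'   `summaries`, and `manifest`.
#' @export
run_pipeline <- function(cohort = NULL, config = cohort_config(),
                         out_dir = NULL, min_reads = 3L,
                         dpsi = 0.2, alpha = 0.05, hi = 0.95, lo = 0.05,
                         evalue_max = 1e-5, min_cov = 0.6, clique = FALSE) {
  if (is.null(cohort)) cohort <- generate_cohort(config)
  models <- filter_by_class_code(cohort$models)
  tissues <- cohort$truth$config$tissues %||% c("leaf", "root")

  events <- detect_events(models)
  events$unit <- unit_id(events$species_id, events$subgenome)
  og <- cohort$orthogroups
  events <- dplyr::left_join(
    events,
    dplyr::select(og, "gene_id", "orthogroup_id", og_single_copy = "single_copy"),
    by = "gene_id"
  )

  # read-support filter, applied per (species, tissue) sample
  support <- event_support_from_counts(events, cohort$counts)
  supported <- dplyr::bind_rows(lapply(
    split(events, events$species_id),
    function(ev_sp) {
      sp_samples <- paste(ev_sp$species_id[1L], tissues, sep = "_")
      sup_sp <- support[support$sample_id %in% sp_samples &
                          support$event_id %in% ev_sp$event_id, , drop = FALSE]
      if (nrow(sup_sp) == 0L) return(NULL)
      filter_by_read_support(ev_sp, sup_sp, min_reads = min_reads)
    }
  ))
  supported$tissue <- sub(".*_", "", supported$sample_id)

  psi <- psi_from_counts(events, cohort$counts)
  psi$tissue <- sub(".*_", "", psi$sample_id)
  present <- enumerate_as_present(psi)

  # per-species differential splicing, condition 1 = first tissue (leaf)
  dse <- list()
  for (spid in unique(events$species_id)) {
    ev_sp <- events$event_id[events$species_id == spid]
    p1 <- psi[psi$event_id %in% ev_sp &
                psi$sample_id == paste(spid, tissues[1L], sep = "_"), ]
    p2 <- psi[psi$event_id %in% ev_sp &
                psi$sample_id == paste(spid, tissues[2L], sep = "_"), ]
    d <- differential_splicing(p1, p2, dpsi = dpsi, alpha = alpha,
                               hi = hi, lo = lo)
    if (nrow(d) > 0L) d$species_id <- spid
    dse[[spid]] <- d
  }
  dse <- dplyr::bind_rows(dse)
  dse <- dplyr::left_join(dse, events[, c("event_id", "event_type")],
                          by = "event_id")

  # eligibility for downstream stages: supported and present, per sample
  eligible_key <- intersect(
    paste(supported$event_id, supported$sample_id),
    paste(present$event_id, present$sample_id)
  )
  eligible <- tibble::tibble(event_id = sub(" .*$", "", eligible_key),
                             sample_id = sub("^.* ", "", eligible_key))

  features <- list(); feature_tests <- list()
  for (ts in tissues) {
    samp <- paste(unique(events$species_id), ts, sep = "_")
    keep <- events$event_id %in%
      eligible$event_id[eligible$sample_id %in% samp]
    ft <- build_feature_table(events[keep, , drop = FALSE], models,
                              cohort$genome)
    features[[ts]] <- ft
    feature_tests[[ts]] <- feature_summary(ft)
  }

  rbh <- build_rbh_map(models, cohort$orthogroups, cohort$genome,
                       evalue_max = evalue_max, min_cov = min_cov)

  ref <- reference_exons(models)
  ev_ranked <- map_event_exon_ranks(events, ref)
  calls <- list(); clusters <- list()
  for (ts in tissues) {
    samp_keys <- eligible_key[sub("^.*_", "", eligible_key) == ts]
    ev_ts <- ev_ranked[paste(ev_ranked$event_id,
                             paste(ev_ranked$species_id, ts, sep = "_")) %in%
                         eligible_key, , drop = FALSE]
    ev_ts <- ev_ts[!is.na(ev_ts$og_single_copy) & ev_ts$og_single_copy, ,
                   drop = FALSE]
    cl_calls <- pairwise_conservation(ev_ts, rbh)
    cl <- build_clusters(cl_calls, clique = clique)
    if (nrow(cl_calls) > 0L) cl_calls$tissue <- ts
    if (nrow(cl) > 0L) cl$tissue <- ts
    calls[[ts]] <- cl_calls
    clusters[[ts]] <- cl
  }

  tet_units <- cohort$units$unit[cohort$units$subgenome %in% c("A", "B")]
  ev_eligible <- dplyr::inner_join(events, eligible, by = "event_id",
                                   relationship = "many-to-many")
  ev_eligible$tissue <- sub(".*_", "", ev_eligible$sample_id)
  ev_eligible <- ev_eligible[ev_eligible$sample_id ==
                               paste(ev_eligible$species_id,
                                     ev_eligible$tissue, sep = "_"), ,
                             drop = FALSE]
  summaries <- list(
    events = summarize_events(ev_eligible),
    dse_composition = dse_composition(dse),
    ks = lapply(stats::setNames(tissues, tissues), function(ts) {
      pt <- present[present$tissue == ts, , drop = FALSE]
      pt <- dplyr::inner_join(pt, events[, c("event_id", "species_id")],
                              by = "event_id")
      pt <- pt[pt$sample_id == paste(pt$species_id, ts, sep = "_"), ]
      if (dplyr::n_distinct(pt$species_id) < 2L) return(NULL)
      ks_matrix(tibble::tibble(group = pt$species_id, psi = pt$psi))
    }),
    conservation = lapply(clusters, conservation_summary),
    subgenome = lapply(clusters, subgenome_summary,
                       tetraploid_units = tet_units),
    decline = lapply(clusters, function(cl)
      if (nrow(cl) > 0L) clusters_by_min_level(cl) else NULL)
  )

  result <- list(events = events, support = support,
                 events_supported = supported, psi = psi, present = present,
                 dse = dse, features = features,
                 feature_tests = feature_tests, rbh = rbh, calls = calls,
                 clusters = clusters, summaries = summaries)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- function(x, name) {
      p <- file.path(out_dir, paste0(name, ".tsv"))
      readr::write_tsv(x, p)
      p
    }
    paths <- c(
      tsv(events, "events"), tsv(support, "support"), tsv(psi, "psi"),
      tsv(dse, "dse"), tsv(rbh, "rbh"),
      unlist(lapply(tissues, function(ts) {
        c(tsv(feature_tests[[ts]], paste0("feature_tests_", ts)),
          tsv(clusters[[ts]], paste0("clusters_", ts)))
      }))
    )
    manifest <- list(
      tool = "asconserve",
      version = as.character(utils::packageVersion("asconserve")),
      seed = cohort$truth$config$seed,
      config = cohort$truth$config[setdiff(names(cohort$truth$config),
                                           "species")],
      row_counts = lapply(result[c("events", "support", "psi", "dse", "rbh")],
                          nrow),
      checksums = as.list(tools::md5sum(paths))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    result$manifest <- manifest
  }
  result
}
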