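#' Percent spliced in (PSI) from inclusion and exclusion read counts
#'
#' PSI is the read-based inclusion fraction
#' `inclusion / (inclusion + exclusion)` on pooled replicate counts, and is
#' undefined (`NA`) when both counts are zero.
#'
#' @param inclusion,exclusion Non-negative integer count vectors.
#' @return Numeric vector of PSI values in `[0, 1]`, `NA` where undefined.
#' @export
compute_psi <- function(inclusion, exclusion) {
  if (any(inclusion < 0, na.rm = TRUE) || any(exclusion < 0, na.rm = TRUE)) {
    stopf("negative read counts in PSI computation")
  }
  tot <- inclusion + exclusion
  ifelse(tot == 0, NA_real_, inclusion / tot)
}

#' Build per-sample PSI records for events
#'
#' Pools replicate counts per sample and looks up each event's inclusion
#' and exclusion feature keys.
#'
#' @param events Event table from [detect_events()].
#' @param counts Count table from [read_count_table()].
#' @return A tibble with `event_id`, `sample_id`, `inclusion_reads`,
#'   `exclusion_reads`, `psi`. Events with no counted feature in a sample
#'   are omitted.
#' @export
psi_from_counts <- function(events, counts) {
  pooled <- dplyr::summarise(
    dplyr::group_by(counts, .data$sample_id, .data$feature_key),
    reads = sum(.data$count), .groups = "drop"
  )
  inc <- dplyr::inner_join(events[, c("event_id", "inclusion_form")], pooled,
                           by = c(inclusion_form = "feature_key"),
                           relationship = "many-to-many")
  exc <- dplyr::inner_join(events[, c("event_id", "exclusion_form")], pooled,
                           by = c(exclusion_form = "feature_key"),
                           relationship = "many-to-many")
  rec <- dplyr::full_join(
    tibble::tibble(event_id = inc$event_id, sample_id = inc$sample_id,
                   inclusion_reads = inc$reads),
    tibble::tibble(event_id = exc$event_id, sample_id = exc$sample_id,
                   exclusion_reads = exc$reads),
    by = c("event_id", "sample_id")
  )
  rec$inclusion_reads[is.na(rec$inclusion_reads)] <- 0L
  rec$exclusion_reads[is.na(rec$exclusion_reads)] <- 0L
  rec$psi <- compute_psi(rec$inclusion_reads, rec$exclusion_reads)
  dplyr::arrange(rec, .data$event_id, .data$sample_id)
}

#' Events present in a sample (0 < PSI < 1)
#'
#' An event counts as present only when both isoforms are observed, i.e.
#' the PSI lies strictly between 0 and 1; constitutive (PSI exactly 0 or 1)
#' and undefined records are excluded.
#'
#' @param psirecords Tibble with a `psi` column.
#' @return The subset of rows with `0 < psi < 1`.
#' @export
enumerate_as_present <- function(psirecords) {
  keep <- !is.na(psirecords$psi) & psirecords$psi > 0 & psirecords$psi < 1
  psirecords[keep, , drop = FALSE]
}

#' Exact binomial test for differential splicing
#'
#' Two-sided exact binomial test of the condition-2 inclusion count among
#' the condition-2 total reads, under the null that the inclusion
#' probability equals the condition-1 PSI (clipped to `[1e-6, 1 - 1e-6]` so
#' a degenerate reference PSI never yields a zero-likelihood null).
#'
#' @param inclusion_2,exclusion_2 Condition-2 read counts (vectorized).
#' @param psi_1 Condition-1 PSI values (vectorized).
#' @return Numeric vector of two-sided p-values; `NA` where condition 2 has
#'   zero total reads.
#' @export
binomial_dse_test <- function(inclusion_2, exclusion_2, psi_1) {
  if (any(inclusion_2 < 0, na.rm = TRUE) || any(exclusion_2 < 0, na.rm = TRUE)) {
    stopf("negative read counts in binomial test")
  }
  p0 <- pmin(pmax(psi_1, 1e-6), 1 - 1e-6)
  n <- inclusion_2 + exclusion_2
  mapply(function(x, nn, p) {
    if (is.na(nn) || nn == 0 || is.na(p)) return(NA_real_)
    stats::binom.test(x, nn, p = p, alternative = "two.sided")$p.value
  }, inclusion_2, n, p0)
}

#' Classify significant differential splicing events
#'
#' A record is significant only when `delta_psi > 0.2` and
#' `p_value < 0.05` (strict inequalities); everything else is `"none"`.
#' Among significant events, a **gain** has near-constitutive splicing in
#' condition 1 (`psi_1 > hi` or `psi_1 < lo`) with intermediate PSI in
#' condition 2, a **loss** is the mirror image, and the remainder are
#' **DAS** (differential alternative splicing). With the tissue convention
#' used throughout (condition 1 = leaf, condition 2 = root) this matches
#' the gain/loss orientation of tissue-resolved splicing comparisons.
#'
#' @param psi_1,psi_2 PSI in condition 1 (leaf) and condition 2 (root).
#' @param delta_psi Absolute PSI difference.
#' @param p_value Binomial test p-value.
#' @param dpsi,alpha Significance thresholds on `delta_psi` and `p_value`.
#' @param hi,lo Near-constitutive PSI thresholds.
#' @return Character vector in `{"gain", "loss", "DAS", "none"}`.
#' @export
classify_dse <- function(psi_1, psi_2, delta_psi, p_value,
                         dpsi = 0.2, alpha = 0.05, hi = 0.95, lo = 0.05) {
  if (hi <= 0 || hi >= 1 || lo <= 0 || lo >= 1 || lo >= hi) {
    stopf("gain/loss PSI thresholds must satisfy 0 < lo < hi < 1")
  }
  sig <- !is.na(delta_psi) & !is.na(p_value) &
    delta_psi > dpsi & p_value < alpha
  extreme_1 <- psi_1 > hi | psi_1 < lo
  extreme_2 <- psi_2 > hi | psi_2 < lo
  mid_1 <- psi_1 > lo & psi_1 < hi
  mid_2 <- psi_2 > lo & psi_2 < hi
  out <- rep("none", length(psi_1))
  out[sig & extreme_1 & mid_2] <- "gain"
  out[sig & extreme_2 & mid_1] <- "loss"
  out[sig & out == "none"] <- "DAS"
  out
}

#' Differential splicing between two conditions of one species
#'
#' Joins per-sample PSI records for the two conditions, computes
#' `delta_psi`, runs the exact binomial test of condition-2 counts against
#' the condition-1 PSI, and classifies each event.
#'
#' @param psi_1,psi_2 PSI record tibbles ([psi_from_counts()] rows) for
#'   condition 1 (leaf) and condition 2 (root); one row per event each.
#' @param dpsi,alpha,hi,lo Thresholds passed to [classify_dse()].
#' @return A tibble with `event_id`, `psi_leaf`, `psi_root`, `delta_psi`,
#'   `p_value` and `class`. Events with undefined PSI in either condition
#'   are unclassifiable and omitted.
#' @export
differential_splicing <- function(psi_1, psi_2, dpsi = 0.2, alpha = 0.05,
                                  hi = 0.95, lo = 0.05) {
  d <- dplyr::inner_join(
    dplyr::select(psi_1, "event_id", psi_leaf = "psi"),
    dplyr::select(psi_2, "event_id", psi_root = "psi",
                  inc_root = "inclusion_reads", exc_root = "exclusion_reads"),
    by = "event_id"
  )
  d <- d[!is.na(d$psi_leaf) & !is.na(d$psi_root), , drop = FALSE]
  d$delta_psi <- abs(d$psi_root - d$psi_leaf)
  d$p_value <- binomial_dse_test(d$inc_root, d$exc_root, d$psi_leaf)
  d$class <- classify_dse(d$psi_leaf, d$psi_root, d$delta_psi, d$p_value,
                          dpsi = dpsi, alpha = alpha, hi = hi, lo = lo)
  dplyr::select(d, "event_id", "psi_leaf", "psi_root", "delta_psi",
                "p_value", "class")
}

#' Two-sample Kolmogorov-Smirnov comparison of PSI distributions
#'
#' @param psis_a,psis_b Non-empty numeric vectors of PSI values (typically
#'   the events present, `0 < PSI < 1`, in two species or tissues).
#' @return A list with `statistic` (the KS `D`) and `p_value`.
#' @export
compare_psi_distributions <- function(psis_a, psis_b) {
  if (length(psis_a) == 0L || length(psis_b) == 0L) {
    stopf("cannot compare empty PSI samples")
  }
  kt <- suppressWarnings(stats::ks.test(psis_a, psis_b,
                                        alternative = "two.sided"))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Pairwise KS test matrix of PSI distributions
#'
#' Runs [compare_psi_distributions()] for every unordered pair of groups,
#' mirroring the per-tissue pairwise distribution-comparison tables of
#' cross-species splicing surveys.
#'
#' @param psi_table Tibble with columns `group` and `psi`.
#' @return A tibble with `group_a`, `group_b`, `statistic`, `p_value`.
#' @export
ks_matrix <- function(psi_table) {
  groups <- sort(unique(psi_table$group))
  pairs <- utils::combn(groups, 2L)
  res <- apply(pairs, 2L, function(pr) {
    cmp <- compare_psi_distributions(psi_table$psi[psi_table$group == pr[1L]],
                                     psi_table$psi[psi_table$group == pr[2L]])
    tibble::tibble(group_a = pr[1L], group_b = pr[2L],
                   statistic = cmp$statistic, p_value = cmp$p_value)
  })
  dplyr::bind_rows(res)
}
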