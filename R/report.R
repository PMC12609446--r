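#' Percentage share of a count within a total
#'
#' `round(100 * n / total, digits)` — the formatting used throughout the
#' reporting stage (e.g. the share of intron-retention clusters among all
#' conserved clusters, reported to 0.1%).
#'
#' @param n,total Counts.
#' @param digits Decimal places of the printed percentage.
#' @return Numeric percentage(s).
#' @export
percent_share <- function(n, total, digits = 1) {
  round(100 * n / total, digits)
}

#' Fold change between two counts
#'
#' @param n,reference Counts (e.g. event totals of two species).
#' @param digits Decimal places.
#' @return `round(n / reference, digits)`.
#' @export
fold_change <- function(n, reference, digits = 1) {
  round(n / reference, digits)
}

#' Composition of differential splicing events by type
#'
#' Summarizes a classified differential-splicing table into, per event
#' type, the number of differential events (class other than `"none"`) and
#' the counts and percentage shares of gains, losses and DAS among them —
#' the composition reported for tissue-resolved splicing comparisons.
#' Percentages are reported to 0.01%.
#'
#' @param dse Tibble with columns `event_type` and `class`.
#' @param digits Decimal places of the percentage columns.
#' @return A tibble per event type with `n_differential`, `n_gain`,
#'   `n_loss`, `n_das` and `pct_gain`, `pct_loss`, `pct_das`.
#' @export
dse_composition <- function(dse, digits = 2) {
  sig <- dse[dse$class != "none", , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(sig, .data$event_type),
    n_differential = dplyr::n(),
    n_gain = sum(.data$class == "gain"),
    n_loss = sum(.data$class == "loss"),
    n_das = sum(.data$class == "DAS"),
    .groups = "drop"
  )
  out$pct_gain <- percent_share(out$n_gain, out$n_differential, digits)
  out$pct_loss <- percent_share(out$n_loss, out$n_differential, digits)
  out$pct_das <- percent_share(out$n_das, out$n_differential, digits)
  out
}

#' Event-count expansion relative to an outgroup
#'
#' @param event_counts Tibble with `species_id` and `n_events` (one tissue).
#' @param outgroup Species id used as the reference.
#' @param digits Decimal places of the fold change.
#' @return The table with a `fold_vs_outgroup` column.
#' @export
event_expansion <- function(event_counts, outgroup, digits = 1) {
  ref <- sum(event_counts$n_events[event_counts$species_id == outgroup])
  if (ref == 0) stopf("outgroup %s has no events", outgroup)
  totals <- dplyr::summarise(
    dplyr::group_by(event_counts, .data$species_id),
    n_events = sum(.data$n_events), .groups = "drop"
  )
  totals$fold_vs_outgroup <- fold_change(totals$n_events, ref, digits)
  totals
}
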