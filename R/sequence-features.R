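#' GC content of a nucleotide sequence
#'
#' Fraction `(G + C) / (A + C + G + T)` counted case-insensitively;
#' ambiguous bases (N and other IUPAC codes) are excluded from both
#' numerator and denominator. A sequence with no unambiguous base has
#' undefined GC content (`NA`, with a warning).
#'
#' @param sequence Character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @return Numeric vector of GC fractions.
#' @export
gc_content <- function(sequence) {
  if (is.character(sequence)) {
    if (any(!nzchar(sequence))) stopf("empty sequence in gc_content()")
    sequence <- Biostrings::DNAStringSet(toupper(sequence))
  }
  cnt <- Biostrings::letterFrequency(sequence, letters = c("A", "C", "G", "T"))
  denom <- rowSums(cnt)
  if (any(denom == 0)) {
    warnf("%d sequence(s) contain only ambiguous bases; GC content undefined",
          sum(denom == 0))
  }
  ifelse(denom == 0, NA_real_, (cnt[, "G"] + cnt[, "C"]) / denom)
}

# Unique annotated introns (gaps between consecutive exons of each
# transcript), deduplicated across transcripts.
annotated_introns <- function(exons) {
  o <- order(exons$transcript_id, exons$start)
  tx <- exons$transcript_id[o]
  n <- length(tx)
  if (n < 2L) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  ii <- which(tx[-n] == tx[-1L])
  unique(data.frame(chrom = exons$chrom[o][ii],
                    start = exons$end[o][ii],
                    end = exons$start[o][ii + 1L],
                    stringsAsFactors = FALSE))
}

#' Build the AS-versus-background feature table
#'
#' Classifies unique genomic intervals into four feature classes and
#' annotates each with its GC content and length:
#'
#' * `ES_exon`: exons skipped in at least one detected ES event;
#' * `background_exon`: annotated exons never skipped in any ES event;
#' * `IR_intron`: introns retained in at least one detected IR event;
#' * `background_intron`: annotated introns never retained.
#'
#' Background status is genome-wide (an exon skipped anywhere is excluded
#' from the background), and each unique interval contributes exactly one
#' observation regardless of how many transcripts or events reuse it.
#'
#' @param events Event table from [detect_events()] (post-filtering).
#' @param exons Exon table from [read_gene_models()].
#' @param genome [Biostrings::DNAStringSet] covering all chromosomes.
#' @return A tibble with `feature_id`, `feature_class`, `chrom`, `start`,
#'   `end`, `gc_fraction`, `length_bp`.
#' @export
build_feature_table <- function(events, exons, genome) {
  uex <- unique(exons[, c("chrom", "start", "end")])
  introns <- annotated_introns(exons)
  es <- events[events$event_type == "ES", , drop = FALSE]
  ir <- events[events$event_type == "IR", , drop = FALSE]
  skipped <- unique(paste(es$chrom, es$var_start, es$var_end))
  retained <- unique(paste(ir$chrom, ir$var_start, ir$var_end))
  ex_key <- paste(uex$chrom, uex$start, uex$end)
  in_key <- paste(introns$chrom, introns$start, introns$end)
  feat <- rbind(
    data.frame(uex, feature_class = ifelse(ex_key %in% skipped,
                                           "ES_exon", "background_exon")),
    data.frame(introns, feature_class = ifelse(in_key %in% retained,
                                               "IR_intron", "background_intron"))
  )
  miss <- setdiff(unique(feat$chrom), names(genome))
  if (length(miss) > 0L) {
    stopf("chromosome(s) absent from genome: %s", paste(miss, collapse = ", "))
  }
  if (any(feat$end > Biostrings::width(genome)[match(feat$chrom, names(genome))]) ||
      any(feat$start < 0L)) {
    stopf("feature coordinates outside chromosome bounds")
  }
  seqs <- Biostrings::DNAStringSet(genome[feat$chrom],
                                   start = feat$start + 1L, end = feat$end)
  tibble::tibble(
    feature_id = sprintf("%s:%d-%d", feat$chrom, feat$start, feat$end),
    feature_class = feat$feature_class,
    chrom = feat$chrom, start = feat$start, end = feat$end,
    gc_fraction = gc_content(seqs),
    length_bp = feat$end - feat$start
  )
}

#' Wilcoxon rank-sum comparison of two feature groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test; the exact null
#' distribution is used for small tie-free samples (combined n of 20 or
#' fewer), otherwise the normal approximation with tie correction.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return A list with `statistic` (the rank-sum `W` of the first group)
#'   and `p_value`.
#' @export
wilcoxon_compare <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stopf("cannot compare empty groups")
  }
  no_ties <- !anyDuplicated(c(group_a, group_b))
  exact <- (length(group_a) + length(group_b)) <= 20L && no_ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = exact, correct = !exact)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Summary of GC and length contrasts between AS and background features
#'
#' Tests `ES_exon` against `background_exon` and `IR_intron` against
#' `background_intron`, for GC content and length.
#'
#' @param feature_table Output of [build_feature_table()].
#' @return A tibble with one row per (contrast, measure): group medians,
#'   Wilcoxon statistic and p-value.
#' @export
feature_summary <- function(feature_table) {
  contrasts <- list(c("ES_exon", "background_exon"),
                    c("IR_intron", "background_intron"))
  measures <- c("gc_fraction", "length_bp")
  rows <- list()
  for (ct in contrasts) for (m in measures) {
    a <- feature_table[[m]][feature_table$feature_class == ct[1L]]
    b <- feature_table[[m]][feature_table$feature_class == ct[2L]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) == 0L || length(b) == 0L) next
    wc <- wilcoxon_compare(a, b)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      as_class = ct[1L], background_class = ct[2L], measure = m,
      median_as = stats::median(a), median_background = stats::median(b),
      statistic = wc$statistic, p_value = wc$p_value
    )
  }
  dplyr::bind_rows(rows)
}
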