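#' Read gene models from a GTF file
#'
#' Parses exon features from an Ensembl-style GTF file into the flat exon
#' table used throughout the package. GTF 1-based inclusive coordinates are
#' converted at this boundary to 0-based half-open coordinates; all interval
#' arithmetic downstream is free of off-by-one adjustments. Exons are grouped
#' by transcript and ranked in transcription order (reverse of genomic order
#' on the minus strand).
#'
#' @param gtf_path Path to a GTF file with `exon` features carrying
#'   `gene_id` and `transcript_id` attributes. A `class_code` attribute
#'   (assembled-transcript comparison code) is kept when present.
#' @param species_id Optional species label attached to every exon row.
#' @return A tibble with one row per exon and columns `gene_id`,
#'   `transcript_id`, `chrom`, `start`, `end` (0-based half-open), `strand`,
#'   `rank`, `class_code`, and `species_id`, ordered deterministically by
#'   (chrom, start, gene_id, transcript_id, rank).
#' @export
read_gene_models <- function(gtf_path, species_id = NA_character_) {
  if (!file.exists(gtf_path)) stopf("GTF file not found: %s", gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stopf("no exon features in %s", gtf_path)
  bad <- is.na(gr$gene_id) | is.na(gr$transcript_id)
  if (any(bad)) {
    lines <- grep("\texon\t", readLines(gtf_path), fixed = TRUE)
    miss <- lines[!grepl("gene_id", readLines(gtf_path)[lines]) |
                    !grepl("transcript_id", readLines(gtf_path)[lines])]
    stopf("exon feature missing gene_id/transcript_id attribute (line %s)",
          paste(utils::head(miss, 5L), collapse = ", "))
  }
  cc <- if ("class_code" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$class_code)
  } else {
    rep(NA_character_, length(gr))
  }
  ex <- tibble::tibble(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    class_code = cc,
    species_id = species_id
  )
  if (any(ex$start >= ex$end)) {
    stopf("exon with start >= end in %s", gtf_path)
  }
  if (any(!ex$strand %in% c("+", "-"))) {
    stopf("exon without +/- strand in %s", gtf_path)
  }
  rank_gene_models(ex)
}

#' Assign transcription-order exon ranks and canonical row order
#'
#' Ranks exons 1..n in 5'-to-3' transcription order within each transcript
#' (descending genomic coordinate on the minus strand) and sorts the table
#' into the package's deterministic (chrom, start, gene, transcript) order.
#'
#' @param exons Exon table with at least `gene_id`, `transcript_id`,
#'   `chrom`, `start`, `end`, `strand`.
#' @return The exon table with a `rank` column, canonically ordered.
#' @export
rank_gene_models <- function(exons) {
  exons <- dplyr::arrange(exons, .data$chrom, .data$gene_id,
                          .data$transcript_id, .data$start)
  exons <- dplyr::group_by(exons, .data$gene_id, .data$transcript_id)
  exons <- dplyr::mutate(
    exons,
    rank = if (.data$strand[1L] == "+") seq_len(dplyr::n()) else rev(seq_len(dplyr::n()))
  )
  exons <- dplyr::ungroup(exons)
  validate_gene_models(exons)
  dplyr::arrange(exons, .data$chrom, .data$start, .data$gene_id,
                 .data$transcript_id, .data$rank)
}

validate_gene_models <- function(exons) {
  stopifnot(all(exons$start < exons$end))
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in by_tx) {
    if (length(unique(exons$chrom[idx])) != 1L ||
        length(unique(exons$strand[idx])) != 1L) {
      stopf("transcript %s spans multiple chromosomes or strands",
            exons$transcript_id[idx[1L]])
    }
    o <- order(exons$start[idx])
    s <- exons$start[idx][o]; e <- exons$end[idx][o]
    if (length(idx) > 1L && any(s[-1L] < e[-length(e)])) {
      stopf("overlapping exons in transcript %s", exons$transcript_id[idx[1L]])
    }
  }
  invisible(exons)
}

#' Write gene models to a GTF file
#'
#' Inverse of [read_gene_models()]: converts the internal 0-based half-open
#' coordinates back to GTF 1-based inclusive coordinates. Rows are written
#' in canonical (chrom, start, gene, transcript) order so that a
#' read-write round trip is byte-stable.
#'
#' @param exons Exon table as returned by [read_gene_models()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(exons, path) {
  exons <- dplyr::arrange(exons, .data$chrom, .data$start, .data$gene_id,
                          .data$transcript_id, .data$rank)
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; exon_number "%d";',
                   exons$gene_id, exons$transcript_id, exons$rank)
  has_cc <- !is.na(exons$class_code %||% rep(NA_character_, nrow(exons)))
  attrs[has_cc] <- paste0(attrs[has_cc],
                          sprintf(' class_code "%s";', exons$class_code[has_cc]))
  lines <- sprintf("%s\tasconserve\texon\t%d\t%d\t.\t%s\t.\t%s",
                   exons$chrom, exons$start + 1L, exons$end, exons$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Filter transcripts by assembly comparison class code
#'
#' Keeps transcripts whose class code (the tag assigned when assembled
#' transcripts are compared against a reference annotation) belongs to the
#' retained set; the default set keeps complete or contained matches and
#' novel-junction variants of known genes. Transcripts without a class code
#' (reference annotations, synthetic data) are retained by default, since
#' codes only exist for assembled transcripts.
#'
#' @param exons Exon table (one row per exon, `class_code` per transcript).
#' @param allowed Character vector of retained class codes.
#' @param keep_unlabeled Keep transcripts whose class code is `NA`.
#' @return Exon table restricted to retained transcripts.
#' @export
filter_by_class_code <- function(exons,
                                 allowed = c("=", "j", "c", "k", "m", "n"),
                                 keep_unlabeled = TRUE) {
  keep <- exons$class_code %in% allowed |
    (keep_unlabeled & is.na(exons$class_code))
  exons[keep, , drop = FALSE]
}

#' Read an orthogroup membership table
#'
#' Reads a TSV with columns `orthogroup_id`, `species_id`, `subgenome`,
#' `gene_id` and flags single-copy orthogroups. Copy number is evaluated
#' per genome unit: a diploid genome is one unit, while each subgenome (A/B)
#' of an allotetraploid is its own unit, so a tetraploid may contribute one
#' gene in A and one in B and the group is still single copy.
#'
#' @param tsv_path Path to the TSV file, or a data frame with the same
#'   columns (used directly).
#' @return A tibble with the input columns plus `unit` and a logical
#'   `single_copy` flag per row.
#' @export
read_orthogroups <- function(tsv_path) {
  og <- if (is.data.frame(tsv_path)) {
    tibble::as_tibble(tsv_path)
  } else {
    readr::read_tsv(tsv_path, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  }
  need <- c("orthogroup_id", "species_id", "subgenome", "gene_id")
  if (!all(need %in% names(og))) {
    stopf("orthogroup table must have columns: %s", paste(need, collapse = ", "))
  }
  dup <- og$gene_id[duplicated(og$gene_id)]
  if (length(dup) > 0L) {
    stopf("gene_id present in more than one orthogroup: %s",
          paste(unique(dup)[1:min(5, length(unique(dup)))], collapse = ", "))
  }
  og$unit <- unit_id(og$species_id, og$subgenome)
  sc <- dplyr::summarise(
    dplyr::group_by(og, .data$orthogroup_id),
    single_copy = !anyDuplicated(.data$unit),
    .groups = "drop"
  )
  dplyr::left_join(og, sc, by = "orthogroup_id")
}

#' Read a junction/element read-count table
#'
#' Reads a TSV with columns `sample_id`, `replicate`, `feature_key`,
#' `count`. Feature keys name either the body of a variable element
#' (retained intron, skipped exon, extended segment) or a splice junction.
#'
#' @param tsv_path Path to the TSV file, or a data frame with the same
#'   columns.
#' @return A tibble with the validated count rows.
#' @export
read_count_table <- function(tsv_path) {
  ct <- if (is.data.frame(tsv_path)) {
    tibble::as_tibble(tsv_path)
  } else {
    readr::read_tsv(tsv_path, show_col_types = FALSE,
                    col_types = readr::cols(
                      sample_id = readr::col_character(),
                      replicate = readr::col_integer(),
                      feature_key = readr::col_character(),
                      count = readr::col_integer()
                    ))
  }
  need <- c("sample_id", "replicate", "feature_key", "count")
  if (!all(need %in% names(ct))) {
    stopf("count table must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(ct$count < 0)) stopf("negative read count in count table")
  if (anyDuplicated(ct[c("sample_id", "replicate", "feature_key")])) {
    stopf("duplicate (sample_id, replicate, feature_key) rows in count table")
  }
  ct
}

#' Read genome sequences from a FASTA file
#'
#' @param fasta_path Path to a (multi-)FASTA file.
#' @return A [Biostrings::DNAStringSet] named by the first whitespace-free
#'   token of each header.
#' @export
read_genome <- function(fasta_path) {
  g <- Biostrings::readDNAStringSet(fasta_path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
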