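#' Alignment parameters for exon homology search
#'
#' BLASTN-like nucleotide scoring (match +2, mismatch -3, gap open 5, gap
#' extend 2, so a gap of length L costs 5 + 2L) with Karlin-Altschul
#' expectation values. `lambda` is solved from the scoring scheme under
#' uniform base composition; `k` is the standard order-of-magnitude
#' constant for ungapped nucleotide statistics. The pairwise conservation
#' logic downstream depends only on pass/fail against the e-value and
#' coverage thresholds, which is robust to the exact calibration.
#'
#' @param match,mismatch Match reward and mismatch penalty.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param k Karlin-Altschul K constant.
#' @return A named list of parameters, including the solved `lambda` and
#'   the substitution matrix.
#' @export
alignment_params <- function(match = 2, mismatch = -3, gap_open = 5,
                             gap_extend = 2, k = 0.35) {
  lambda <- stats::uniroot(
    function(l) 0.25 * exp(match * l) + 0.75 * exp(mismatch * l) - 1,
    lower = 1e-6, upper = 5, tol = 1e-12
  )$root
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, k = k, lambda = lambda,
       submat = Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                         mismatch = mismatch))
}

ka_evalue <- function(score, m, n, params) {
  params$k * as.numeric(m) * as.numeric(n) * exp(-params$lambda * score)
}

# Vectorized elementwise Smith-Waterman scores only (no traceback).
score_pairs <- function(seq_a, seq_b, params, chunk_size = 20000L) {
  n <- length(seq_a)
  out <- numeric(n)
  for (ch in seq_len(ceiling(n / chunk_size))) {
    idx <- seq((ch - 1L) * chunk_size + 1L, min(ch * chunk_size, n))
    out[idx] <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(seq_a[idx]),
      Biostrings::DNAStringSet(seq_b[idx]),
      type = "local", substitutionMatrix = params$submat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend,
      scoreOnly = TRUE
    )
  }
  out
}

# Vectorized elementwise Smith-Waterman over paired sequence vectors,
# chunked to bound memory. Returns score/identity/span columns.
align_pairs <- function(seq_a, seq_b, params, chunk_size = 20000L) {
  n <- length(seq_a)
  out <- vector("list", ceiling(n / chunk_size))
  for (ch in seq_along(out)) {
    idx <- seq((ch - 1L) * chunk_size + 1L, min(ch * chunk_size, n))
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(seq_a[idx]),
      Biostrings::DNAStringSet(seq_b[idx]),
      type = "local", substitutionMatrix = params$submat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend
    )
    pa <- Biostrings::pattern(aln); sa <- Biostrings::subject(aln)
    ncols <- Biostrings::nchar(aln)
    out[[ch]] <- tibble::tibble(
      score = Biostrings::score(aln),
      identity = ifelse(ncols > 0, Biostrings::nmatch(aln) / ncols, 0),
      span_a = Biostrings::end(pa) - Biostrings::start(pa) + 1L,
      span_b = Biostrings::end(sa) - Biostrings::start(sa) + 1L
    )
  }
  dplyr::bind_rows(out)
}

#' Local alignment of two exon sequences
#'
#' Optimal (Smith-Waterman) local alignment under the configured scores,
#' via [Biostrings::pairwiseAlignment()]. Coverage is the aligned span on
#' each sequence divided by its length; the e-value uses the
#' Karlin-Altschul formula with effective search space
#' `length(query) * search_space_n` (defaulting to the subject length; RBH
#' search passes the total subject exon length of the gene pair).
#'
#' @param query_seq,subject_seq Nucleotide sequences (character or
#'   [Biostrings::DNAString]).
#' @param params Scoring parameters from [alignment_params()].
#' @param search_space_n Effective subject-side search space in bp.
#' @return A list with `score`, `identity`, `coverage_query`,
#'   `coverage_subject`, `evalue`, or `NULL` when no positive-scoring local
#'   alignment exists.
#' @export
align_exons <- function(query_seq, subject_seq, params = alignment_params(),
                        search_space_n = NULL) {
  q <- as.character(query_seq); s <- as.character(subject_seq)
  h <- align_pairs(q, s, params)
  if (h$score[1L] <= 0) return(NULL)
  nspace <- if (is.null(search_space_n)) nchar(s) else search_space_n
  list(score = h$score[1L], identity = h$identity[1L],
       coverage_query = h$span_a[1L] / nchar(q),
       coverage_subject = h$span_b[1L] / nchar(s),
       evalue = ka_evalue(h$score[1L], nchar(q), nspace, params))
}

# Reciprocal-best-hit selection on a precomputed all-vs-all hit table.
# `hits` must carry: group (one gene pair), ia/ib (exon row ids), rank_a,
# rank_b, score, identity, evalue, cov_a, cov_b. Best hits are chosen per
# side by (score, identity, lower opposite rank); a pair is kept when it is
# best in both directions and passes the filters.
rbh_select <- function(hits, evalue_max, min_cov) {
  ord <- order(hits$group, hits$ia, -hits$score, -hits$identity, hits$rank_b)
  best_a <- hits[ord, ][!duplicated(hits[ord, c("group", "ia")]), ]
  ord <- order(hits$group, hits$ib, -hits$score, -hits$identity, hits$rank_a)
  best_b <- hits[ord, ][!duplicated(hits[ord, c("group", "ib")]), ]
  key <- function(h) paste(h$group, h$ia, h$ib)
  rbh <- best_a[key(best_a) %in% key(best_b), , drop = FALSE]
  rbh[rbh$score > 0 & rbh$evalue <= evalue_max &
        rbh$cov_a >= min_cov & rbh$cov_b >= min_cov, , drop = FALSE]
}

#' Reciprocal best hits between the exon sets of two orthologous genes
#'
#' All-versus-all local alignment of the exon sequences of one gene against
#' those of its ortholog, restricted to a single orthogroup and species
#' pair. An exon pair (x, y) is reported when y is x's best hit, x is y's
#' best hit, the e-value (the larger of the two directional e-values) is at
#' most `evalue_max`, and the aligned coverage reaches `min_cov` on
#' **both** sequences. Best-hit ties are broken deterministically by higher
#' identity, then lower opposite exon rank.
#'
#' @param exons_a,exons_b Tibbles with columns `exon_id`, `gene_id`,
#'   `rank`, `seq` (one row per exon of the gene in species A / B).
#' @param orthogroup_id Orthogroup label carried into the output.
#' @param params Scoring parameters from [alignment_params()].
#' @param evalue_max,min_cov Filter thresholds.
#' @return A tibble of RBH pairs: `orthogroup_id`, exon/gene/rank columns
#'   for both sides, `score`, `evalue`, `cov_q`, `cov_s`, `identity`.
#' @export
reciprocal_best_hits <- function(exons_a, exons_b, orthogroup_id = NA_character_,
                                 params = alignment_params(),
                                 evalue_max = 1e-5, min_cov = 0.6) {
  na <- nrow(exons_a); nb <- nrow(exons_b)
  if (na == 0L || nb == 0L) return(empty_rbh_table())
  grid <- expand.grid(ia = seq_len(na), ib = seq_len(nb))
  res <- align_pairs(exons_a$seq[grid$ia], exons_b$seq[grid$ib], params)
  len_a <- nchar(exons_a$seq)[grid$ia]
  len_b <- nchar(exons_b$seq)[grid$ib]
  space_a <- sum(nchar(exons_a$seq)); space_b <- sum(nchar(exons_b$seq))
  hits <- tibble::tibble(
    group = 1L, ia = grid$ia, ib = grid$ib,
    rank_a = exons_a$rank[grid$ia], rank_b = exons_b$rank[grid$ib],
    score = res$score, identity = res$identity,
    evalue = pmax(ka_evalue(res$score, len_a, space_b, params),
                  ka_evalue(res$score, len_b, space_a, params)),
    cov_a = res$span_a / len_a, cov_b = res$span_b / len_b
  )
  rbh <- rbh_select(hits, evalue_max, min_cov)
  if (nrow(rbh) == 0L) return(empty_rbh_table())
  tibble::tibble(
    orthogroup_id = orthogroup_id,
    exon_a = exons_a$exon_id[rbh$ia], gene_a = exons_a$gene_id[rbh$ia],
    rank_a = rbh$rank_a,
    exon_b = exons_b$exon_id[rbh$ib], gene_b = exons_b$gene_id[rbh$ib],
    rank_b = rbh$rank_b,
    score = rbh$score, evalue = rbh$evalue,
    cov_q = rbh$cov_a, cov_s = rbh$cov_b, identity = rbh$identity
  )
}

empty_rbh_table <- function() {
  tibble::tibble(orthogroup_id = character(), exon_a = character(),
                 gene_a = character(), rank_a = integer(),
                 exon_b = character(), gene_b = character(),
                 rank_b = integer(), score = numeric(), evalue = numeric(),
                 cov_q = numeric(), cov_s = numeric(), identity = numeric())
}

#' Reference exons of each gene
#'
#' The exon set used for homology search and for the "gene and exon
#' number" identifiers: the exons of the gene's primary transcript (the
#' transcript with the most exons; ties broken by transcript id), ranked in
#' transcription order.
#'
#' @param exons Exon table from [read_gene_models()].
#' @param genome [Biostrings::DNAStringSet] with the gene's chromosome (or
#'   `NULL` to skip sequence extraction).
#' @return A tibble with `gene_id`, `exon_id` (`gene@rank`), `rank`,
#'   `chrom`, `start`, `end`, `strand`, and `seq` (transcription-strand
#'   sequence) when `genome` is given.
#' @export
reference_exons <- function(exons, genome = NULL) {
  cnt <- dplyr::count(exons, .data$gene_id, .data$transcript_id)
  cnt <- dplyr::arrange(cnt, .data$gene_id, dplyr::desc(.data$n),
                        .data$transcript_id)
  primary <- cnt[!duplicated(cnt$gene_id), c("gene_id", "transcript_id")]
  ref <- dplyr::inner_join(exons, primary, by = c("gene_id", "transcript_id"))
  ref <- dplyr::select(ref, "gene_id", "chrom", "start", "end", "strand",
                       "rank")
  ref$exon_id <- sprintf("%s@%d", ref$gene_id, ref$rank)
  if (!is.null(genome)) {
    seqs <- Biostrings::DNAStringSet(genome[ref$chrom],
                                     start = ref$start + 1L, end = ref$end)
    minus <- ref$strand == "-"
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
    ref$seq <- unname(as.character(seqs))
  }
  dplyr::arrange(tibble::as_tibble(ref), .data$gene_id, .data$rank)
}

#' Cross-species exon homology reference set
#'
#' For every single-copy orthogroup and every pair of genome units (a
#' diploid genome, or one subgenome of an allotetraploid), aligns the
#' reference exons of the two member genes all-versus-all and records the
#' reciprocal best hits passing the e-value and coverage filters. All exon
#' pairs of the cohort are aligned in a small number of vectorized
#' alignment calls.
#'
#' @param exons Exon table covering all species, with `species_id` and
#'   `subgenome` columns.
#' @param orthogroups Orthogroup table from [read_orthogroups()].
#' @param genome [Biostrings::DNAStringSet] covering all chromosomes of all
#'   units.
#' @param params Scoring parameters from [alignment_params()].
#' @param evalue_max,min_cov Filter thresholds.
#' @return A tibble of RBH pairs with `unit_a`/`unit_b` columns added; the
#'   pair set is stored with `unit_a < unit_b` and is symmetric by
#'   construction.
#' @export
build_rbh_map <- function(exons, orthogroups, genome,
                          params = alignment_params(),
                          evalue_max = 1e-5, min_cov = 0.6) {
  og <- orthogroups[orthogroups$single_copy, , drop = FALSE]
  refs <- reference_exons(exons, genome)
  refs$row <- seq_len(nrow(refs))
  exon_rows <- split(refs$row, refs$gene_id)
  gene_space <- vapply(split(nchar(refs$seq), refs$gene_id), sum, numeric(1L))

  # enumerate gene pairs (one per orthogroup and unordered unit pair)
  gp <- list()
  for (og_id in unique(og$orthogroup_id)) {
    members <- og[og$orthogroup_id == og_id, , drop = FALSE]
    members <- members[order(members$unit), , drop = FALSE]
    nu <- nrow(members)
    if (nu < 2L) next
    prs <- utils::combn(nu, 2L)
    gp[[og_id]] <- tibble::tibble(
      orthogroup_id = og_id,
      unit_a = members$unit[prs[1L, ]], gene_a = members$gene_id[prs[1L, ]],
      unit_b = members$unit[prs[2L, ]], gene_b = members$gene_id[prs[2L, ]]
    )
  }
  if (length(gp) == 0L) {
    res <- empty_rbh_table()
    res$unit_a <- character(); res$unit_b <- character()
    return(res)
  }
  gp <- dplyr::bind_rows(gp)
  gp$group <- seq_len(nrow(gp))

  # expand to the all-vs-all exon pair table
  rows_a <- exon_rows[gp$gene_a]
  rows_b <- exon_rows[gp$gene_b]
  n_a <- lengths(rows_a); n_b <- lengths(rows_b)
  grp <- rep.int(gp$group, n_a * n_b)
  ia <- unlist(lapply(seq_len(nrow(gp)), function(g)
    rep(rows_a[[g]], times = n_b[g])))
  ib <- unlist(lapply(seq_len(nrow(gp)), function(g)
    rep(rows_b[[g]], each = n_a[g])))

  # two-pass alignment: scores everywhere, full alignments only for the
  # rows that can be a best hit in either direction
  sc <- score_pairs(refs$seq[ia], refs$seq[ib], params)
  dt <- data.table::data.table(grp = grp, ia = ia, ib = ib, sc = sc)
  dt[, `:=`(mxa = max(sc)), by = c("grp", "ia")]
  dt[, `:=`(mxb = max(sc)), by = c("grp", "ib")]
  cand <- which(dt$sc == dt$mxa | dt$sc == dt$mxb)
  res_c <- align_pairs(refs$seq[ia[cand]], refs$seq[ib[cand]], params)
  identity <- numeric(length(ia)); span_a <- numeric(length(ia))
  span_b <- numeric(length(ia))
  identity[cand] <- res_c$identity
  span_a[cand] <- res_c$span_a; span_b[cand] <- res_c$span_b
  len_a <- nchar(refs$seq)[ia]; len_b <- nchar(refs$seq)[ib]
  space_a <- gene_space[gp$gene_a][grp]; space_b <- gene_space[gp$gene_b][grp]
  hits <- tibble::tibble(
    group = grp, ia = ia, ib = ib,
    rank_a = refs$rank[ia], rank_b = refs$rank[ib],
    score = sc, identity = identity,
    evalue = pmax(ka_evalue(sc, len_a, space_b, params),
                  ka_evalue(sc, len_b, space_a, params)),
    cov_a = span_a / len_a, cov_b = span_b / len_b
  )
  rbh <- rbh_select(hits, evalue_max, min_cov)
  if (nrow(rbh) == 0L) {
    res <- empty_rbh_table()
    res$unit_a <- character(); res$unit_b <- character()
    return(res)
  }
  g <- rbh$group
  tibble::tibble(
    orthogroup_id = gp$orthogroup_id[g],
    exon_a = refs$exon_id[rbh$ia], gene_a = refs$gene_id[rbh$ia],
    rank_a = rbh$rank_a,
    exon_b = refs$exon_id[rbh$ib], gene_b = refs$gene_id[rbh$ib],
    rank_b = rbh$rank_b,
    score = rbh$score, evalue = rbh$evalue,
    cov_q = rbh$cov_a, cov_s = rbh$cov_b, identity = rbh$identity,
    unit_a = gp$unit_a[g], unit_b = gp$unit_b[g]
  )
}
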