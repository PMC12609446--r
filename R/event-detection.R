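#' Detect alternative splicing events from transcript structures
#'
#' Enumerates the four primary event types by pairwise comparison of the
#' transcript structures annotated for each gene, in the style of
#' annotation-based event generators:
#'
#' * **IR** (intron retention): one transcript splices an intron between two
#'   exons while another transcript carries a single exon spanning exactly
#'   the same outer boundaries (exon1-intron-exon2 read as one exon).
#' * **ES** (exon skipping): an internal exon of one transcript is absent
#'   from another transcript whose splice junction joins the two neighbours
#'   directly (exon1-exon3 junction).
#' * **A5 / A3** (alternative donor / acceptor): two transcripts use introns
#'   that share one boundary and differ at the other; the variable segment
#'   between the alternative boundaries is exonic in the short-intron
#'   transcript. The donor is the 5' splice site in transcription
#'   orientation, so the genomic side of an A5/A3 label depends on strand.
#'
#' Events found from several transcript pairs are deduplicated through their
#' coordinate-defined identifiers (first occurrence wins for the auxiliary
#' flank fields). Detection is purely annotation-based; read support is
#' applied afterwards by [filter_by_read_support()].
#'
#' @param exons Exon table as returned by [read_gene_models()] (columns
#'   `gene_id`, `transcript_id`, `chrom`, `start`, `end`, `strand`; optional
#'   `species_id`, `subgenome`).
#' @return A tibble of events with defining coordinates: `var_start`/
#'   `var_end` delimit the variable element (retained intron, skipped exon,
#'   or extended segment), `flank_up_*`/`flank_down_*` the flanking exons in
#'   transcription order (IR/ES), `anchor_*` the shared anchor exon (A5/A3),
#'   and `inclusion_form`/`exclusion_form` the count-table feature keys
#'   evidencing each isoform.
#' @export
detect_events <- function(exons) {
  stopifnot(all(c("gene_id", "transcript_id", "chrom", "start", "end",
                  "strand") %in% names(exons)))
  meta_cols <- intersect(c("species_id", "subgenome"), names(exons))
  gidx <- split(seq_len(nrow(exons)), exons$gene_id)
  out <- vector("list", length(gidx))
  for (i in seq_along(gidx)) {
    idx <- gidx[[i]]
    out[[i]] <- detect_gene_events(
      gene_id = exons$gene_id[idx[1L]],
      chrom = exons$chrom[idx[1L]],
      strand = exons$strand[idx[1L]],
      tx = exons$transcript_id[idx],
      s = exons$start[idx],
      e = exons$end[idx]
    )
  }
  out <- unlist(out[!vapply(out, is.null, logical(1L))], recursive = FALSE)
  if (length(out) == 0L) {
    return(empty_event_table(meta_cols))
  }
  res <- tibble::as_tibble(data.table::rbindlist(out))
  res <- res[!duplicated(res$event_id), , drop = FALSE]
  if (length(meta_cols) > 0L) {
    meta <- unique(exons[c("gene_id", meta_cols)])
    res <- dplyr::left_join(res, meta, by = "gene_id")
  }
  dplyr::arrange(res, .data$chrom, .data$var_start, .data$event_id)
}

empty_event_table <- function(meta_cols = character()) {
  tb <- tibble::tibble(
    event_id = character(), event_type = character(), gene_id = character(),
    chrom = character(), strand = character(),
    var_start = integer(), var_end = integer(),
    flank_up_start = integer(), flank_up_end = integer(),
    flank_down_start = integer(), flank_down_end = integer(),
    anchor_start = integer(), anchor_end = integer(),
    inclusion_form = character(), exclusion_form = character()
  )
  for (mc in meta_cols) tb[[mc]] <- character()
  tb
}

# Event detection for a single gene; inputs are parallel vectors of exon
# rows. Returns a data.frame of events or NULL.
detect_gene_events <- function(gene_id, chrom, strand, tx, s, e) {
  txi <- split(seq_along(s), tx)
  txi <- lapply(txi, function(ii) ii[order(s[ii])])

  # unique exons and introns across transcripts
  ex_s <- integer(0); ex_e <- integer(0)
  in_b <- integer(0); in_c <- integer(0)   # intron (b, c)
  in_a <- integer(0); in_d <- integer(0)   # flank outer coords (a,b) (c,d)
  for (ii in txi) {
    ex_s <- c(ex_s, s[ii]); ex_e <- c(ex_e, e[ii])
    k <- length(ii)
    if (k >= 2L) {
      in_b <- c(in_b, e[ii][-k]); in_c <- c(in_c, s[ii][-1L])
      in_a <- c(in_a, s[ii][-k]); in_d <- c(in_d, e[ii][-1L])
    }
  }
  exon_key <- unique(paste(ex_s, ex_e))
  if (length(in_b) > 0L) {
    junc_key_set <- unique(paste(in_b, in_c))
  } else {
    junc_key_set <- character(0)
  }
  uex <- !duplicated(paste(ex_s, ex_e))
  ex_s <- ex_s[uex]; ex_e <- ex_e[uex]

  rows <- list()
  add <- function(type, var1, var2, fu = c(NA_integer_, NA_integer_),
                  fd = c(NA_integer_, NA_integer_),
                  an = c(NA_integer_, NA_integer_), id_coords, incl, excl) {
    rows[[length(rows) + 1L]] <<- list(
      event_id = make_event_id(gene_id, type, chrom, strand, id_coords),
      event_type = type, gene_id = gene_id, chrom = chrom, strand = strand,
      var_start = var1, var_end = var2,
      flank_up_start = fu[1L], flank_up_end = fu[2L],
      flank_down_start = fd[1L], flank_down_end = fd[2L],
      anchor_start = an[1L], anchor_end = an[2L],
      inclusion_form = incl, exclusion_form = excl
    )
  }

  # IR: intron (b,c) with flanks (a,b),(c,d) in one transcript; exon (a,d)
  # in another.
  if (length(in_b) > 0L) {
    ir_hit <- paste(in_a, in_d) %in% exon_key
    seen <- character(0)
    for (r in which(ir_hit)) {
      a <- in_a[r]; b <- in_b[r]; cc <- in_c[r]; d <- in_d[r]
      key <- paste(a, b, cc, d)
      if (key %in% seen) next
      seen <- c(seen, key)
      left <- c(a, b); right <- c(cc, d)
      if (strand == "+") { fu <- left; fd <- right } else { fu <- right; fd <- left }
      add("IR", b, cc, fu = fu, fd = fd, id_coords = c(a, b, cc, d),
          incl = body_key(chrom, b, cc), excl = junc_key(chrom, b, cc))
    }
  }

  # ES: internal exon (c,d) with junctions (b,c) and (d,ee) in one
  # transcript; junction (b,ee) in another.
  for (ii in txi) {
    k <- length(ii)
    if (k < 3L) next
    ss <- s[ii]; ee_ <- e[ii]
    for (j in 2:(k - 1L)) {
      b <- ee_[j - 1L]; cc <- ss[j]; d <- ee_[j]; e2 <- ss[j + 1L]
      if (paste(b, e2) %in% junc_key_set) {
        left <- c(ss[j - 1L], ee_[j - 1L]); right <- c(ss[j + 1L], ee_[j + 1L])
        if (strand == "+") { fu <- left; fd <- right } else { fu <- right; fd <- left }
        add("ES", cc, d, fu = fu, fd = fd, id_coords = c(b, cc, d, e2),
            incl = body_key(chrom, cc, d), excl = junc_key(chrom, b, e2))
      }
    }
  }

  # A5/A3: unique introns sharing one boundary, differing at the other,
  # with overlapping variant-side exons.
  if (length(in_b) > 0L) {
    ui <- !duplicated(paste(in_b, in_c))
    ub <- in_b[ui]; uc <- in_c[ui]
    # shared left boundary (b): alternative at genomic-right coordinate
    for (b in unique(ub[duplicated(ub)])) {
      cs <- sort(unique(uc[ub == b]))
      if (length(cs) < 2L) next
      anchor <- which(ex_e == b)
      an <- if (length(anchor) > 0L) {
        ai <- anchor[which.min(ex_s[anchor])]
        c(ex_s[ai], ex_e[ai])
      } else c(NA_integer_, NA_integer_)
      for (p in seq_len(length(cs) - 1L)) for (q in (p + 1L):length(cs)) {
        c1 <- cs[p]; c2 <- cs[q]
        # variant exons (starting at c1 / c2) must overlap
        if (!any(ex_s == c1 & ex_e > c2)) next
        type <- if (strand == "+") "A3" else "A5"
        add(type, c1, c2, an = an, id_coords = c("R", b, c1, c2),
            incl = body_key(chrom, c1, c2), excl = junc_key(chrom, b, c2))
      }
    }
    # shared right boundary (c): alternative at genomic-left coordinate
    for (cc in unique(uc[duplicated(uc)])) {
      bs <- sort(unique(ub[uc == cc]))
      if (length(bs) < 2L) next
      anchor <- which(ex_s == cc)
      an <- if (length(anchor) > 0L) {
        ai <- anchor[which.max(ex_e[anchor])]
        c(ex_s[ai], ex_e[ai])
      } else c(NA_integer_, NA_integer_)
      for (p in seq_len(length(bs) - 1L)) for (q in (p + 1L):length(bs)) {
        b1 <- bs[p]; b2 <- bs[q]
        if (!any(ex_e == b2 & ex_s < b1)) next
        type <- if (strand == "+") "A5" else "A3"
        add(type, b1, b2, an = an, id_coords = c("L", cc, b1, b2),
            incl = body_key(chrom, b1, b2), excl = junc_key(chrom, b1, cc))
      }
    }
  }

  if (length(rows) == 0L) return(NULL)
  rows
}

#' Pool replicate counts into per-sample event support
#'
#' Supporting reads for an event are the reads assigned to its variable
#' element (retained-intron body for IR, skipped exon for ES, extended
#' segment for A5/A3), i.e. the `inclusion_form` feature key; biological
#' replicates are pooled by summation before filtering.
#'
#' @param events Event table from [detect_events()].
#' @param counts Count table from [read_count_table()].
#' @return A tibble with `event_id`, `sample_id`, `supporting_reads`.
#' @export
event_support_from_counts <- function(events, counts) {
  pooled <- dplyr::summarise(
    dplyr::group_by(counts, .data$sample_id, .data$feature_key),
    supporting_reads = sum(.data$count), .groups = "drop"
  )
  sup <- dplyr::inner_join(
    events[, c("event_id", "inclusion_form")], pooled,
    by = c(inclusion_form = "feature_key"),
    relationship = "many-to-many"
  )
  tibble::tibble(event_id = sup$event_id, sample_id = sup$sample_id,
                 supporting_reads = sup$supporting_reads)
}

#' Filter events by read support
#'
#' Retains an event in a sample only when its variable element is supported
#' by strictly more than `min_reads` pooled reads (with the default of 3,
#' four reads pass and three fail). Events absent from the support table
#' are treated as having zero reads and dropped, with a warning giving the
#' number of such event-sample pairs.
#'
#' @param events Event table from [detect_events()].
#' @param support Support table from [event_support_from_counts()].
#' @param min_reads Strict lower bound on supporting reads.
#' @return The event table expanded per sample (`sample_id`,
#'   `supporting_reads` columns added), restricted to supported rows.
#' @export
filter_by_read_support <- function(events, support, min_reads = 3L) {
  samples <- unique(support$sample_id)
  grid <- tidyr::expand_grid(event_id = events$event_id, sample_id = samples)
  grid <- dplyr::left_join(grid, support, by = c("event_id", "sample_id"))
  n_missing <- sum(is.na(grid$supporting_reads))
  if (n_missing > 0L) {
    warnf("%d event-sample pairs missing from support table; treated as 0 reads",
          n_missing)
    grid$supporting_reads[is.na(grid$supporting_reads)] <- 0L
  }
  grid <- grid[grid$supporting_reads > min_reads, , drop = FALSE]
  dplyr::inner_join(events, grid, by = "event_id")
}

#' Summarize detected events per species and tissue
#'
#' @param events Event table carrying `species_id` and `tissue` columns.
#' @return A list with `event_counts` (events by type), `gene_counts`
#'   (genes with at least one event of a type; a gene with several types is
#'   counted once per type), and `events_per_gene` (genes binned by their
#'   per-type event count into 1, 2, 3, 4, 5, >5).
#' @export
summarize_events <- function(events) {
  stopifnot(all(c("species_id", "tissue") %in% names(events)))
  ev <- dplyr::distinct(events, .data$species_id, .data$tissue,
                        .data$event_type, .data$gene_id, .data$event_id)
  event_counts <- dplyr::count(ev, .data$species_id, .data$tissue,
                               .data$event_type, name = "n_events")
  gene_counts <- dplyr::summarise(
    dplyr::group_by(ev, .data$species_id, .data$tissue, .data$event_type),
    n_genes = dplyr::n_distinct(.data$gene_id), .groups = "drop"
  )
  per_gene <- dplyr::count(ev, .data$species_id, .data$tissue,
                           .data$event_type, .data$gene_id, name = "n")
  per_gene$bin <- ifelse(per_gene$n > 5L, ">5", as.character(per_gene$n))
  hist <- dplyr::count(per_gene, .data$species_id, .data$tissue,
                       .data$event_type, .data$bin, name = "n_genes")
  hist$bin <- factor(hist$bin, levels = c("1", "2", "3", "4", "5", ">5"))
  list(event_counts = event_counts, gene_counts = gene_counts,
       events_per_gene = dplyr::arrange(hist, .data$species_id, .data$tissue,
                                        .data$event_type, .data$bin))
}
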