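make_tx <- function(gene, tx, starts, ends, strand = "+") {
  tibble::tibble(gene_id = gene, transcript_id = tx, chrom = "chr1",
                 start = as.integer(starts), end = as.integer(ends),
                 strand = strand)
}

test_that("exon skipping is detected from a direct neighbour junction", {
  g <- rbind(
    make_tx("g1", "t1", c(0, 200, 400), c(100, 300, 500)),
    make_tx("g1", "t2", c(0, 400), c(100, 500))
  )
  ev <- detect_events(g)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "ES")
  expect_equal(ev$var_start, 200L)
  expect_equal(ev$var_end, 300L)
  expect_equal(ev$flank_up_end, 100L)
  expect_equal(ev$flank_down_start, 400L)
})

test_that("intron retention requires the exact merged exon", {
  g <- rbind(
    make_tx("g1", "t1", c(0, 200), c(100, 300)),
    make_tx("g1", "t2", 0, 300)
  )
  ev <- detect_events(g)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "IR")
  expect_equal(c(ev$var_start, ev$var_end), c(100L, 200L))
  # a spanning exon with different outer bounds is not retention
  g2 <- rbind(
    make_tx("g2", "t1", c(0, 200), c(100, 300)),
    make_tx("g2", "t2", 10, 300)
  )
  expect_equal(nrow(detect_events(g2)), 0L)
})

test_that("alternative donor/acceptor labels follow the strand", {
  # introns (100,200) and (100,170): alternative genomic-right boundary
  plus <- rbind(
    make_tx("gp", "t1", c(0, 200), c(100, 300)),
    make_tx("gp", "t2", c(0, 170), c(100, 300))
  )
  ev <- detect_events(plus)
  expect_equal(ev$event_type, "A3")
  expect_equal(c(ev$var_start, ev$var_end), c(170L, 200L))
  minus <- plus
  minus$strand <- "-"
  expect_equal(detect_events(minus)$event_type, "A5")
})

test_that("single-transcript genes yield no events", {
  g <- make_tx("g1", "t1", c(0, 200, 400), c(100, 300, 500))
  expect_equal(nrow(detect_events(g)), 0L)
})

test_that("detection is invariant to transcript and row order", {
  set.seed(42)
  for (rep in 1:20) {
    g <- random_gene(sprintf("g%d", rep))
    ev1 <- detect_events(g)
    g2 <- g[sample.int(nrow(g)), , drop = FALSE]
    g2$transcript_id <- factor(g2$transcript_id,
                               levels = sample(unique(g2$transcript_id)))
    g2$transcript_id <- as.character(g2$transcript_id)
    ev2 <- detect_events(g2)
    expect_identical(ev1$event_id, ev2$event_id)
  }
})

test_that("detected events match the exhaustive pairwise oracle", {
  set.seed(99)
  genes <- lapply(1:500, function(i) random_gene(sprintf("g%04d", i)))
  ev <- detect_events(dplyr::bind_rows(genes))
  impl <- split(ev$event_id, ev$gene_id)
  n_bad <- 0L
  for (g in genes) {
    want <- oracle_gene_events(g$gene_id[1L], "chr1", g$strand[1L],
                               g$transcript_id, g$start, g$end)
    got <- sort(impl[[g$gene_id[1L]]] %||% character(0))
    if (!identical(got, want)) n_bad <- n_bad + 1L
  }
  expect_equal(n_bad, 0L)
})

test_that("every reported isoform form is evidenced by a transcript", {
  set.seed(7)
  for (rep in 1:40) {
    g <- random_gene(sprintf("g%d", rep))
    ev <- detect_events(g)
    if (nrow(ev) == 0L) next
    txl <- split(g[order(g$start), ], g$transcript_id[order(g$start)])
    exon_keys <- unlist(lapply(txl, function(d) paste(d$start, d$end)))
    junc_keys <- unlist(lapply(txl, function(d) {
      k <- nrow(d)
      if (k < 2L) return(character(0))
      paste(d$end[-k], d$start[-1L])
    }))
    # exclusion form is always a junction present in some transcript
    exc <- sub("junc:chr1:", "", ev$exclusion_form)
    exc <- sub("-", " ", exc, fixed = TRUE)
    expect_true(all(exc %in% junc_keys))
    # the variable element of IR/ES events is exonic/intronic in a transcript
    ir <- ev[ev$event_type == "IR", ]
    if (nrow(ir) > 0L) {
      expect_true(all(paste(ir$var_start, ir$var_end) %in% junc_keys))
    }
    es <- ev[ev$event_type == "ES", ]
    if (nrow(es) > 0L) {
      expect_true(all(paste(es$var_start, es$var_end) %in% exon_keys))
    }
  }
})

test_that("read-support filter keeps events with strictly more than min reads", {
  ev <- detect_events(rbind(
    make_tx("g1", "t1", c(0, 200), c(100, 300)),
    make_tx("g1", "t2", 0, 300),
    make_tx("g2", "t1", c(1000, 1200), c(1100, 1300)),
    make_tx("g2", "t2", 1000, 1300)
  ))
  sup <- tibble::tibble(
    event_id = rep(ev$event_id, each = 2L),
    sample_id = rep(c("s_leaf", "s_root"), 2L),
    supporting_reads = c(4L, 3L, 2L, 10L)
  )
  kept <- filter_by_read_support(ev, sup, min_reads = 3L)
  expect_equal(nrow(kept), 2L)
  expect_setequal(paste(kept$event_id, kept$sample_id),
                  paste(ev$event_id[c(1L, 2L)], c("s_leaf", "s_root")))
  # min_reads = 0 keeps everything with at least one read
  expect_equal(nrow(filter_by_read_support(ev, sup, min_reads = 0L)), 4L)
  # missing event-sample pairs are zero-read and dropped, with a warning
  expect_warning(
    kept2 <- filter_by_read_support(ev, sup[-1L, ], min_reads = 3L),
    "missing"
  )
  expect_equal(nrow(kept2), 1L)
  # threshold oracle on random support values
  set.seed(3)
  supr <- tibble::tibble(event_id = rep(ev$event_id, 25L),
                         sample_id = rep(sprintf("r%02d_leaf", 1:25), each = 2L),
                         supporting_reads = sample(0:8, 50L, replace = TRUE))
  for (mr in c(0L, 3L, 5L)) {
    got <- filter_by_read_support(ev, supr, min_reads = mr)
    expect_equal(nrow(got), sum(supr$supporting_reads > mr))
  }
})

test_that("event summaries bin genes by their per-type event count", {
  ev <- tibble::tibble(
    species_id = "sp", tissue = "leaf",
    event_type = c(rep("IR", 6L), "IR", "ES"),
    gene_id = c(rep("g1", 6L), "g2", "g2"),
    event_id = paste0("e", 1:8)
  )
  s <- summarize_events(ev)
  hist <- s$events_per_gene
  expect_equal(hist$n_genes[hist$event_type == "IR" & hist$bin == ">5"], 1L)
  expect_equal(hist$n_genes[hist$event_type == "IR" & hist$bin == "1"], 1L)
  # a gene with several types appears once per type
  expect_equal(s$gene_counts$n_genes[s$gene_counts$event_type == "ES"], 1L)
  expect_equal(s$gene_counts$n_genes[s$gene_counts$event_type == "IR"], 2L)
  # bins partition genes: per-type totals equal gene counts
  tot <- dplyr::summarise(dplyr::group_by(hist, .data$event_type),
                          n = sum(.data$n_genes), .groups = "drop")
  expect_equal(tot$n[match(s$gene_counts$event_type, tot$event_type)],
               s$gene_counts$n_genes)
  # groupby oracle on a random event table
  set.seed(12)
  evr <- tibble::tibble(
    species_id = "sp", tissue = "leaf",
    event_type = sample(c("IR", "ES", "A3", "A5"), 300L, replace = TRUE),
    gene_id = sample(sprintf("g%02d", 1:40), 300L, replace = TRUE),
    event_id = paste0("e", 1:300)
  )
  sr <- summarize_events(evr)
  brute <- table(tapply(evr$event_id, paste(evr$gene_id, evr$event_type),
                        length))
  got <- tapply(sr$events_per_gene$n_genes,
                as.character(sr$events_per_gene$bin), sum)
  for (b in c("1", "2", "3", "4", "5")) {
    expect_equal(unname(got[b]), unname(brute[b]) %||% NULL)
  }
})
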