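# Small constructed world for the pairwise call logic: one orthogroup, two
# genome units with rank-matched RBH exons.
mk_event <- function(unit, gene, type, rank_up, rank_down, rank_var = NA,
                     og = "OG1", species = sub("_.*", "", unit)) {
  list(event_id = paste0(gene, ":", type, ":", rank_up), event_type = type,
       gene_id = gene, unit = unit, species_id = species,
       orthogroup_id = og, rank_up = rank_up, rank_down = rank_down,
       rank_var = rank_var)
}

mk_rbh <- function(unit_a, gene_a, unit_b, gene_b, ranks_a,
                   ranks_b = ranks_a) {
  tibble::tibble(orthogroup_id = "OG1",
                 exon_a = sprintf("%s@%d", gene_a, ranks_a), gene_a = gene_a,
                 rank_a = ranks_a,
                 exon_b = sprintf("%s@%d", gene_b, ranks_b), gene_b = gene_b,
                 rank_b = ranks_b,
                 score = 100, evalue = 1e-20, cov_q = 1, cov_s = 1,
                 identity = 1, unit_a = unit_a, unit_b = unit_b)
}

test_that("ES conservation needs orthogroup, skipped-exon and flank RBH", {
  rbh <- mk_rbh("s1", "gA", "s2", "gB", 1:5)
  a <- mk_event("s1", "gA", "ES", 2, 4, rank_var = 3)
  b <- mk_event("s2", "gB", "ES", 2, 4, rank_var = 3)
  expect_equal(call_conserved_es(a, b, rbh)$status, "conserved")
  # downstream flank lacking RBH support
  rbh_part <- mk_rbh("s1", "gA", "s2", "gB", c(1:3, 5))
  cal <- call_conserved_es(a, b, rbh_part)
  expect_equal(cal$status, "non_conserved")
  expect_equal(cal$reason, "flank_not_rbh")
  # skipped exon itself not an RBH pair
  rbh_noskip <- mk_rbh("s1", "gA", "s2", "gB", c(1, 2, 4, 5))
  expect_equal(call_conserved_es(a, b, rbh_noskip)$reason,
               "skipped_exon_not_rbh")
  # different orthogroups fail criterion (i) first
  b2 <- mk_event("s2", "gB", "ES", 2, 4, rank_var = 3, og = "OG2")
  expect_equal(call_conserved_es(a, b2, rbh)$reason, "not_same_orthogroup")
  expect_error(call_conserved_es(a, mk_event("s2", "gB", "IR", 2, 3), rbh),
               "ES")
})

test_that("terminal skipped exons need only the available flank", {
  rbh <- mk_rbh("s1", "gA", "s2", "gB", 1:5)
  a <- mk_event("s1", "gA", "ES", 4, NA, rank_var = 5)
  b <- mk_event("s2", "gB", "ES", 4, NA, rank_var = 5)
  expect_equal(call_conserved_es(a, b, rbh)$status, "conserved")
  # a flank present in one event but absent in the other is a mismatch
  b2 <- mk_event("s2", "gB", "ES", 4, 6, rank_var = 5)
  expect_equal(call_conserved_es(a, b2, rbh)$reason, "flank_not_rbh")
})

test_that("IR conservation requires both flanks RBH in matching orientation", {
  rbh <- mk_rbh("s1", "gA", "s2", "gB", 1:5)
  a <- mk_event("s1", "gA", "IR", 2, 3)
  b <- mk_event("s2", "gB", "IR", 2, 3)
  expect_equal(call_conserved_ir(a, b, rbh)$status, "conserved")
  # counterpart intron sits between a different exon pair
  b_shift <- mk_event("s2", "gB", "IR", 3, 4)
  expect_equal(call_conserved_ir(a, b_shift, rbh)$reason, "flank_not_rbh")
  # exon-shuffle: rank 3 of gA pairs with rank 4 of gB
  rbh_shuf <- mk_rbh("s1", "gA", "s2", "gB", c(1, 2, 3), c(1, 2, 4))
  expect_equal(call_conserved_ir(a, b, rbh_shuf)$reason, "flank_not_rbh")
  b3 <- mk_event("s2", "gB", "IR", 2, 3, og = "OG9")
  expect_equal(call_conserved_ir(a, b3, rbh)$reason, "not_same_orthogroup")
})

test_that("conservation calls are symmetric in the species pair", {
  rbh <- mk_rbh("s1", "gA", "s2", "gB", 1:5)
  a <- mk_event("s1", "gA", "IR", 2, 3)
  b <- mk_event("s2", "gB", "IR", 2, 3)
  expect_equal(call_conserved_ir(a, b, rbh)$status,
               call_conserved_ir(b, a, rbh)$status)
  a2 <- mk_event("s1", "gA", "ES", 2, 4, rank_var = 3)
  b2 <- mk_event("s2", "gB", "ES", 2, 4, rank_var = 3)
  expect_equal(call_conserved_es(a2, b2, rbh)$status,
               call_conserved_es(b2, a2, rbh)$status)
})

mk_call <- function(ua, ea, ub, eb, og = "OG1", type = "IR",
                    status = "conserved") {
  tibble::tibble(orthogroup_id = og, event_type = type,
                 unit_a = ua, species_a = sub("_.*", "", ua),
                 gene_a = paste0("g_", ua), event_a = ea,
                 unit_b = ub, species_b = sub("_.*", "", ub),
                 gene_b = paste0("g_", ub), event_b = eb,
                 status = status, reason = ifelse(status == "conserved",
                                                  "ok", "flank_not_rbh"))
}

test_that("clusters are connected components spanning at least two species", {
  calls <- rbind(mk_call("s1", "e1", "s2", "e2"),
                 mk_call("s2", "e2", "s3", "e3"))
  cl <- build_clusters(calls)
  expect_equal(dplyr::n_distinct(cl$cluster_id), 1L)
  expect_equal(unique(cl$species_level), 3L)
  expect_equal(nrow(cl), 3L)
  # two disjoint pairs in different orthogroups give two level-2 clusters
  calls2 <- rbind(mk_call("s1", "a1", "s2", "a2", og = "OG1"),
                  mk_call("s3", "b1", "s4", "b2", og = "OG2"))
  cl2 <- build_clusters(calls2)
  expect_equal(dplyr::n_distinct(cl2$cluster_id), 2L)
  expect_equal(unique(cl2$species_level), 2L)
  # all five species pairwise conserved collapse into one level-5 cluster
  prs <- utils::combn(paste0("s", 1:5), 2L)
  calls5 <- dplyr::bind_rows(lapply(seq_len(ncol(prs)), function(i)
    mk_call(prs[1L, i], paste0("e", substr(prs[1L, i], 2, 2)),
            prs[2L, i], paste0("e", substr(prs[2L, i], 2, 2)))))
  cl5 <- build_clusters(calls5)
  expect_equal(dplyr::n_distinct(cl5$cluster_id), 1L)
  expect_equal(unique(cl5$species_level), 5L)
  # non-conserved calls contribute no edges
  expect_equal(nrow(build_clusters(mk_call("s1", "x", "s2", "y",
                                           status = "non_conserved"))), 0L)
})

test_that("clique mode drops non-complete components", {
  # path s1-s2-s3 without the closing s1-s3 edge
  calls <- rbind(mk_call("s1", "e1", "s2", "e2"),
                 mk_call("s2", "e2", "s3", "e3"))
  expect_equal(nrow(build_clusters(calls, clique = TRUE)), 0L)
  calls_tri <- rbind(calls, mk_call("s1", "e1", "s3", "e3"))
  expect_equal(dplyr::n_distinct(build_clusters(calls_tri,
                                                clique = TRUE)$cluster_id), 1L)
})

test_that("subgenome summary tabulates exact unit combinations", {
  cl <- tibble::tibble(
    cluster_id = c("c1", "c1", "c2", "c2", "c2", "c3", "c3"),
    event_type = "IR",
    orthogroup_id = "OG1",
    unit = c("Pg_A", "Pq_A", "Pg_A", "Pq_A", "Pj_A", "d1", "d2"),
    species_id = c("Pg", "Pq", "Pg", "Pq", "Pj", "d1", "d2"),
    gene_id = paste0("g", 1:7), event_id = paste0("e", 1:7),
    species_level = c(2L, 2L, 3L, 3L, 3L, 2L, 2L), n_events = 2L
  )
  tet <- c("Pg_A", "Pg_B", "Pq_A", "Pq_B", "Pj_A", "Pj_B")
  s <- subgenome_summary(cl, tet)
  expect_equal(s$n_clusters[s$unit_set == "Pg_A+Pq_A"], 1L)
  expect_equal(s$n_clusters[s$unit_set == "Pg_A+Pj_A+Pq_A"], 1L)
  # the diploid-only cluster increments nothing
  expect_equal(sum(s$n_clusters), 2L)
})

test_that("conservation summaries tally types, genes and sharing levels", {
  cl <- tibble::tibble(
    cluster_id = rep(c("c1", "c2", "c3", "c4"), times = c(2L, 2L, 3L, 2L)),
    event_type = rep(c("IR", "IR", "IR", "ES"), times = c(2L, 2L, 3L, 2L)),
    orthogroup_id = "OG", unit = paste0("u", 1:9),
    species_id = c("s1", "s2", "s1", "s3", "s1", "s2", "s3", "s4", "s5"),
    gene_id = c("g1", "g2", "g1", "g3", "g4", "g5", "g6", "g7", "g8"),
    event_id = paste0("e", 1:9),
    species_level = rep(c(2L, 2L, 3L, 2L), times = c(2L, 2L, 3L, 2L)),
    n_events = rep(c(2L, 2L, 3L, 2L), times = c(2L, 2L, 3L, 2L))
  )
  s <- conservation_summary(cl)
  expect_equal(s$n_clusters, 4L)
  expect_equal(s$by_type$n_clusters[s$by_type$event_type == "IR"], 3L)
  expect_equal(s$by_type$share_pct[s$by_type$event_type == "IR"], 75)
  # genes in several clusters are deduplicated (g1 appears in c1 and c2)
  expect_equal(s$by_type$n_genes[s$by_type$event_type == "IR"], 6L)
  lv <- s$by_level
  expect_equal(lv$n_clusters[lv$event_type == "IR" & lv$species_level == 2L],
               2L)
  decline <- clusters_by_min_level(cl)
  expect_equal(decline$n_clusters_at_least, c(4L, 1L))
  expect_true(all(diff(decline$n_clusters_at_least) <= 0L))
})

test_that("cohort-level calls recover planted conservation structure", {
  co <- fixture_cohort()
  res <- fixture_pipeline()
  truth <- co$truth$clusters
  for (ts in c("leaf", "root")) {
    det <- res$clusters[[ts]]
    det_sets <- cluster_member_sets(det, "cluster_id")
    tr_sets <- cluster_member_sets(truth, "planted_key")
    expect_gt(length(det_sets), 0L)
    tp <- sum(det_sets %in% tr_sets)
    expect_gte(tp / length(det_sets), 0.95)
    expect_gte(tp / length(tr_sets), 0.95)
    # every cluster member passed the support and presence filters
    elig <- paste(res$events_supported$event_id,
                  res$events_supported$sample_id)
    mem_key <- paste(det$event_id,
                     paste(det$species_id, ts, sep = "_"))
    expect_true(all(mem_key %in% elig))
    pres <- paste(res$present$event_id, res$present$sample_id)
    expect_true(all(mem_key %in% pres))
  }
})
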