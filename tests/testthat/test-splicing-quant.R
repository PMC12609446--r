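test_that("PSI is the inclusion fraction, undefined at zero depth", {
  expect_equal(compute_psi(10L, 0L), 1.0)
  expect_equal(compute_psi(5L, 5L), 0.5)
  expect_equal(compute_psi(3L, 7L), 0.3)
  expect_true(is.na(compute_psi(0L, 0L)))
  expect_equal(compute_psi(c(1L, 0L), c(3L, 0L)), c(0.25, NA))
  expect_error(compute_psi(-1L, 5L), "negative")
})

test_that("presence requires PSI strictly between 0 and 1", {
  rec <- tibble::tibble(event_id = paste0("e", 1:5),
                        psi = c(0, 1, 0.999, 0.5, NA))
  kept <- enumerate_as_present(rec)
  expect_setequal(kept$event_id, c("e3", "e4"))
  # brute-force filter oracle on random records
  set.seed(8)
  r <- tibble::tibble(event_id = paste0("r", 1:200),
                      psi = sample(c(0, 1, runif(40)), 200L, replace = TRUE))
  expect_identical(enumerate_as_present(r)$event_id,
                   r$event_id[!is.na(r$psi) & r$psi > 0 & r$psi < 1])
})

test_that("binomial test matches closed forms and the pmf-summation oracle", {
  expect_equal(binomial_dse_test(5L, 5L, 0.5), 1.0)
  expect_equal(binomial_dse_test(10L, 0L, 0.5), 2 * 0.5^10)
  expect_true(is.na(binomial_dse_test(0L, 0L, 0.5)))
  expect_error(binomial_dse_test(-1L, 2L, 0.5), "negative")
  set.seed(21)
  for (i in 1:100) {
    n <- sample(1:20, 1L)
    x <- sample(0:n, 1L)
    p0 <- runif(1, 0.05, 0.95)
    expect_equal(binomial_dse_test(x, n - x, p0),
                 oracle_binom_p(x, n, p0), tolerance = 1e-12)
  }
  # degenerate reference PSI is clipped, not fatal
  expect_true(binomial_dse_test(0L, 10L, 0) >= 0)
  expect_true(binomial_dse_test(10L, 0L, 1) >= 0)
})

test_that("binomial p-value decreases as the observation departs the null", {
  # along each side of the null, for fixed total reads
  for (p0 in c(0.5, 0.3)) {
    n <- 30L
    xs <- 0:n
    p <- binomial_dse_test(xs, n - xs, rep(p0, n + 1L))
    mode <- round(n * p0)
    expect_true(all(diff(p[xs >= mode]) <= 1e-12))
    expect_true(all(diff(p[xs <= mode]) >= -1e-12))
  }
})

test_that("gain/loss/DAS classification follows the PSI thresholds", {
  expect_equal(classify_dse(0.97, 0.50, 0.47, 0.001), "gain")
  expect_equal(classify_dse(0.50, 0.02, 0.48, 0.001), "loss")
  expect_equal(classify_dse(0.30, 0.60, 0.30, 0.001), "DAS")
  expect_equal(classify_dse(0.40, 0.55, 0.15, 0.001), "none")
  expect_equal(classify_dse(0.97, 0.50, 0.47, 0.2), "none")
  # boundary strictness: delta exactly 0.2 / p exactly 0.05 are not enough
  expect_equal(classify_dse(0.5, 0.7, 0.2, 0.001), "none")
  expect_equal(classify_dse(0.5, 0.8, 0.3, 0.05), "none")
  expect_error(classify_dse(0.5, 0.5, 0.3, 0.01, hi = 1.2), "thresholds")
})

test_that("significant events partition into gain/loss/DAS and swap symmetrically", {
  set.seed(31)
  n <- 500L
  psi1 <- runif(n); psi2 <- runif(n)
  d <- abs(psi2 - psi1); p <- runif(n)^2
  cl <- classify_dse(psi1, psi2, d, p)
  n_sig <- sum(d > 0.2 & p < 0.05)
  expect_equal(sum(cl != "none"), n_sig)
  expect_equal(sum(cl %in% c("gain", "loss", "DAS")), n_sig)
  # swapping the two conditions maps gain <-> loss and fixes DAS
  cl_sw <- classify_dse(psi2, psi1, d, p)
  expect_identical(cl_sw[cl == "gain"], rep("loss", sum(cl == "gain")))
  expect_identical(cl_sw[cl == "loss"], rep("gain", sum(cl == "loss")))
  expect_identical(cl_sw[cl == "DAS"], rep("DAS", sum(cl == "DAS")))
  expect_identical(cl_sw[cl == "none"], rep("none", sum(cl == "none")))
})

test_that("KS comparison matches the empirical-CDF scan oracle", {
  same <- c(0.1, 0.4, 0.8)
  expect_equal(compare_psi_distributions(same, same)$statistic, 0)
  expect_equal(compare_psi_distributions(c(0.1, 0.2, 0.3),
                                         c(0.7, 0.8, 0.9))$statistic, 1)
  expect_error(compare_psi_distributions(numeric(0), same), "empty")
  set.seed(14)
  for (i in 1:100) {
    a <- runif(sample(2:8, 1L)); b <- runif(sample(2:8, 1L))
    expect_equal(compare_psi_distributions(a, b)$statistic,
                 oracle_ks_D(a, b), tolerance = 1e-12)
  }
})

test_that("the pairwise KS matrix covers every unordered group pair", {
  set.seed(2)
  pt <- tibble::tibble(group = rep(c("a", "b", "c"), each = 30L),
                       psi = runif(90))
  m <- ks_matrix(pt)
  expect_equal(nrow(m), 3L)
  expect_setequal(paste(m$group_a, m$group_b), c("a b", "a c", "b c"))
  direct <- compare_psi_distributions(pt$psi[pt$group == "a"],
                                      pt$psi[pt$group == "b"])
  expect_equal(m$statistic[m$group_a == "a" & m$group_b == "b"],
               direct$statistic)
})

test_that("differential splicing joins conditions and classifies events", {
  p1 <- tibble::tibble(event_id = c("e1", "e2", "e3"),
                       inclusion_reads = c(98L, 50L, 0L),
                       exclusion_reads = c(2L, 50L, 0L))
  p1$psi <- compute_psi(p1$inclusion_reads, p1$exclusion_reads)
  p2 <- tibble::tibble(event_id = c("e1", "e2", "e3"),
                       inclusion_reads = c(50L, 52L, 10L),
                       exclusion_reads = c(50L, 48L, 0L))
  p2$psi <- compute_psi(p2$inclusion_reads, p2$exclusion_reads)
  d <- differential_splicing(p1, p2)
  expect_equal(d$class[d$event_id == "e1"], "gain")
  expect_equal(d$class[d$event_id == "e2"], "none")
  expect_false("e3" %in% d$event_id)  # undefined PSI in condition 1
  expect_equal(d$delta_psi[d$event_id == "e1"], abs(0.5 - 0.98))
})
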