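# Independent brute-force oracles used to validate the fast implementations.

# Exhaustive pairwise-definition event oracle: explicit loops over every
# ordered transcript pair and every exon/intron position, testing each
# event definition literally.
oracle_gene_events <- function(gene_id, chrom, strand, tx, s, e) {
  txl <- lapply(split(data.frame(s = s, e = e), tx),
                function(d) d[order(d$s), , drop = FALSE])
  all_ex <- unique(do.call(rbind, txl))
  ids <- character(0)
  for (t1 in txl) for (t2 in txl) {
    k1 <- nrow(t1); k2 <- nrow(t2)
    # IR: intron i of t1 spanned by an exon of t2 with the same outer bounds
    if (k1 >= 2L) for (i in 1:(k1 - 1L)) {
      a <- t1$s[i]; b <- t1$e[i]; cc <- t1$s[i + 1L]; d <- t1$e[i + 1L]
      if (any(t2$s == a & t2$e == d)) {
        ids <- c(ids, make_event_id(gene_id, "IR", chrom, strand, c(a, b, cc, d)))
      }
    }
    # ES: internal exon j of t1 skipped by a direct junction in t2
    if (k1 >= 3L && k2 >= 2L) for (j in 2:(k1 - 1L)) {
      b <- t1$e[j - 1L]; cc <- t1$s[j]; d <- t1$e[j]; e2 <- t1$s[j + 1L]
      for (i2 in 1:(k2 - 1L)) {
        if (t2$e[i2] == b && t2$s[i2 + 1L] == e2) {
          ids <- c(ids, make_event_id(gene_id, "ES", chrom, strand,
                                      c(b, cc, d, e2)))
        }
      }
    }
    # A5/A3: introns sharing one boundary with overlapping variant exons
    if (k1 >= 2L && k2 >= 2L) for (i in 1:(k1 - 1L)) for (i2 in 1:(k2 - 1L)) {
      b1 <- t1$e[i]; c1 <- t1$s[i + 1L]
      b2 <- t2$e[i2]; c2 <- t2$s[i2 + 1L]
      if (b1 == b2 && c1 != c2) {
        cs <- sort(c(c1, c2))
        if (any(all_ex$s == cs[1L] & all_ex$e > cs[2L])) {
          type <- if (strand == "+") "A3" else "A5"
          ids <- c(ids, make_event_id(gene_id, type, chrom, strand,
                                      c("R", b1, cs[1L], cs[2L])))
        }
      }
      if (c1 == c2 && b1 != b2) {
        bs <- sort(c(b1, b2))
        if (any(all_ex$e == bs[2L] & all_ex$s < bs[1L])) {
          type <- if (strand == "+") "A5" else "A3"
          ids <- c(ids, make_event_id(gene_id, type, chrom, strand,
                                      c("L", c1, bs[1L], bs[2L])))
        }
      }
    }
  }
  sort(unique(ids))
}

# Random multi-isoform gene for detector fuzzing: a reference structure of
# up to `max_exons` exons and up to `max_tx` isoforms derived by exon
# subsetting, adjacent-exon merging (retention) and boundary shifts.
random_gene <- function(gene_id, max_exons = 6L, max_tx = 4L) {
  n_ex <- sample.int(max_exons, 1L)
  el <- sample(20:80, n_ex, replace = TRUE)
  il <- if (n_ex > 1L) sample(30:100, n_ex - 1L, replace = TRUE) else integer(0)
  s <- integer(n_ex); e <- integer(n_ex)
  pos <- 10L
  for (i in seq_len(n_ex)) {
    s[i] <- pos; e[i] <- pos + el[i]
    pos <- e[i] + if (i < n_ex) il[i] else 0L
  }
  strand <- sample(c("+", "-"), 1L)
  n_tx <- sample.int(max_tx, 1L)
  rows <- list()
  for (t in seq_len(n_tx)) {
    keep <- sort(sample.int(n_ex, sample.int(n_ex, 1L)))
    ss <- s[keep]; ee <- e[keep]
    k <- length(ss)
    if (k >= 2L && stats::runif(1) < 0.35) {
      i <- sample.int(k - 1L, 1L)
      ee[i] <- ee[i + 1L]
      ss <- ss[-(i + 1L)]; ee <- ee[-(i + 1L)]
      k <- k - 1L
    }
    if (k >= 2L && stats::runif(1) < 0.45) {
      i <- sample.int(k - 1L, 1L)           # intron between kept exons i,i+1
      gap <- ss[i + 1L] - ee[i]
      if (gap > 12L) {
        delta <- sample.int(min(10L, gap - 2L), 1L)
        if (stats::runif(1) < 0.5) ee[i] <- ee[i] + delta
        else ss[i + 1L] <- ss[i + 1L] - delta
      }
    }
    rows[[t]] <- data.frame(
      gene_id = gene_id, transcript_id = paste0(gene_id, ".t", t),
      chrom = "chr1", start = ss, end = ee, strand = strand,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# Two-sided exact binomial p by direct pmf summation (minimum-likelihood
# rule with the standard relative tolerance).
oracle_binom_p <- function(x, n, p) {
  d <- stats::dbinom(0:n, n, p)
  sum(d[d <= d[x + 1L] * (1 + 1e-7)])
}

# Two-sample KS statistic by scanning empirical CDF differences at every
# data point.
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1L))))
}

# Two-sided exact Wilcoxon rank-sum p by complete enumeration of the
# assignments of the pooled ranks to group A (tie-free samples only).
oracle_wilcoxon_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  w_all <- apply(combos, 2L, function(idx) sum(seq_len(na + nb)[idx])) -
    na * (na + 1) / 2
  if (w_obs > na * nb / 2) {
    min(1, 2 * mean(w_all >= w_obs))
  } else {
    min(1, 2 * mean(w_all <= w_obs))
  }
}

# Smith-Waterman with affine gaps (gap of length L costs open + L * extend)
# by direct dynamic programming; used on short sequences only.
oracle_sw_score <- function(qa, qb, match = 2, mismatch = -3,
                            gap_open = 5, gap_extend = 2) {
  a <- strsplit(qa, "")[[1L]]; b <- strsplit(qb, "")[[1L]]
  m <- length(a); n <- length(b)
  M <- matrix(0, m + 1L, n + 1L)
  Ix <- matrix(-Inf, m + 1L, n + 1L)
  Iy <- matrix(-Inf, m + 1L, n + 1L)
  best <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    sub <- if (a[i] == b[j]) match else mismatch
    M[i + 1L, j + 1L] <- max(0,
                             M[i, j] + sub, Ix[i, j] + sub, Iy[i, j] + sub)
    Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open - gap_extend,
                              Ix[i, j + 1L] - gap_extend)
    Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open - gap_extend,
                              Iy[i + 1L, j] - gap_extend)
    best <- max(best, M[i + 1L, j + 1L])
  }
  best
}

# independent point-substitution helper for homology tests
mutate_bases_for_test <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  chars
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}
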