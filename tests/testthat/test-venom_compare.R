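hit_rows <- function(q, s, ev, bs) {
  data.frame(qseqid = q, sseqid = s, pident = 50, length = 100,
             mismatch = 10, gapopen = 1, qstart = 1, qend = 100,
             sstart = 1, send = 100, evalue = ev, bitscore = bs,
             stringsAsFactors = FALSE)
}

test_that("best_hits keeps minimum e-value with bit-score and id tie rules", {
  rows <- rbind(hit_rows("q1", "s1", 1e-10, 60), hit_rows("q1", "s2", 1e-3, 90),
                hit_rows("q2", "s3", 1e-5, 60), hit_rows("q2", "s4", 1e-5, 80),
                hit_rows("q3", "sB", 1e-5, 70), hit_rows("q3", "sA", 1e-5, 70))
  bh <- best_hits(rows)
  expect_equal(bh$sseqid[bh$qseqid == "q1"], "s1")
  expect_equal(bh$sseqid[bh$qseqid == "q2"], "s4")
  expect_equal(bh$sseqid[bh$qseqid == "q3"], "sA")
  expect_equal(nrow(best_hits(rows[0, ])), 0L)
})

test_that("homology_call is inclusive on both printed cutoffs", {
  expect_true(homology_call(1e-5, 50))
  expect_false(homology_call(1e-4, 200))
  expect_false(homology_call(1e-20, 49))
  expect_false(homology_call(NA, NA))
})

test_that("venn_partition labels by the dual-cutoff calls", {
  paired <- data.frame(
    protein_id = c("u", "a", "b", "ab"),
    ev_a = c(NA, 1e-8, 1e-3, 1e-9), bs_a = c(NA, 80, 30, 120),
    ev_b = c(NA, 1e-2, 1e-7, 1e-6), bs_b = c(NA, 20, 75, 55))
  vp <- venn_partition(paired)
  expect_equal(unname(vp$counts), c(1L, 1L, 1L, 1L))
  expect_equal(vp$assignments$label, c("unique", "a_only", "b_only", "both"))
  # all scores absent -> all unique
  none <- data.frame(protein_id = letters[1:3], ev_a = NA, bs_a = NA,
                     ev_b = NA, bs_b = NA)
  expect_equal(unname(venn_partition(none)$counts), c(3L, 0L, 0L, 0L))
  expect_equal(sum(vp$counts), nrow(paired))
})

test_that("paired_better_fraction applies strictness and the absence rule", {
  paired <- data.frame(
    protein_id = c("p1", "p2", "p3", "p4"),
    ev_a = c(1e-10, 1e-5, NA, 1e-5), bs_a = c(90, 50, NA, 50),
    ev_b = c(1e-5, 1e-10, 1e-5, NA), bs_b = c(50, 90, 50, NA))
  out <- paired_better_fraction(paired)
  expect_equal(out$n_better_ev, 2L)  # p1 smaller-better, p4 absence rule
  expect_equal(out$n_better_bs, 2L)
  expect_equal(out$frac_better_ev, 0.5)
  # all pairs equal -> zero counts
  ties <- data.frame(protein_id = "t", ev_a = 1e-5, bs_a = 50,
                     ev_b = 1e-5, bs_b = 50)
  out <- paired_better_fraction(ties)
  expect_equal(out$n_better_ev + out$n_better_bs, 0L)
  # better + worse + ties partitions n
  set.seed(41)
  rnd <- data.frame(protein_id = paste0("p", 1:50),
                    ev_a = 10^-sample(0:20, 50, TRUE),
                    bs_a = sample(20:100, 50, TRUE),
                    ev_b = 10^-sample(0:20, 50, TRUE),
                    bs_b = sample(20:100, 50, TRUE))
  out <- paired_better_fraction(rnd)
  swapped <- rnd
  names(swapped) <- c("protein_id", "ev_b", "bs_b", "ev_a", "bs_a")
  out_sw <- paired_better_fraction(swapped)
  ties_ev <- sum(rnd$ev_a == rnd$ev_b)
  expect_equal(out$n_better_ev + out_sw$n_better_ev + ties_ev, 50L)
})

test_that("the printed better-score fraction arithmetic holds", {
  expect_equal(round(100 * 48 / 70, 1), 68.6)
  expect_equal(round(100 * 46 / 70, 1), 65.7)
})

test_that("wilcoxon_signed_rank reproduces closed-form extreme cases", {
  w <- wilcoxon_signed_rank(6:10, 1:5, alternative = "greater")
  expect_equal(w$p_value, 1 / 32)
  expect_equal(w$statistic, 15)
  w <- wilcoxon_signed_rank(6:10, 1:5)
  expect_equal(w$p_value, 0.0625)
  w <- wilcoxon_signed_rank(c(1, 2), c(1, 2))
  expect_equal(w$p_value, 1)
  expect_equal(w$n_used, 0L)
})

test_that("exact signed-rank equals the 2^n enumeration oracle", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(1:12, 1)
    # rounding forces ties and zero differences
    x <- round(rnorm(n, 0.3, 1), sample(0:1, 1))
    y <- round(rnorm(n), sample(0:1, 1))
    for (alt in c("two.sided", "greater", "less")) {
      got <- wilcoxon_signed_rank(x, y, alternative = alt)
      want <- oracle_signed_rank(x, y, alternative = alt)
      expect_equal(got$p_value, want$p_value,
                   info = sprintf("case %d alt %s", i, alt))
    }
  }
})

test_that("exact signed-rank agrees with the reference implementation when
          ties are absent", {
  set.seed(43)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- wilcoxon_signed_rank(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = TRUE))
    expect_equal(got$p_value, ref$p.value)
  }
})

test_that("normal-approximation branch tracks the exact branch near the
          switch point", {
  set.seed(44)
  x <- rnorm(24, 0.4); y <- rnorm(24)
  p_ex <- wilcoxon_signed_rank(x, y, exact_n = 25)$p_value
  p_no <- wilcoxon_signed_rank(x, y, exact_n = 5)$p_value
  expect_lt(abs(p_ex - p_no) / p_ex, 0.25)
})

test_that("fisher_exact_2x2 reproduces the printed enrichment p-value", {
  f <- fisher_exact_2x2(13, 57, 3, 76)
  expect_equal(round(f$p_value, 3), 0.006)
  expect_equal(f$statistic, 13 * 76 / (57 * 3))
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_value, 1)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "empty")
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("fisher_exact_2x2 equals enumeration, reference code and is
          transposition-invariant", {
  set.seed(45)
  for (i in 1:60) {
    cells <- sample(0:15, 4, replace = TRUE)
    if (sum(cells) == 0) cells[1] <- 1
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    p <- fisher_exact_2x2(a, b, c, d)$p_value
    expect_equal(p, oracle_fisher(a, b, c, d), info = paste(cells, collapse = ","))
    expect_equal(p, fisher_exact_2x2(a, c, b, d)$p_value)
    expect_equal(p, fisher.test(matrix(c(a, c, b, d), 2))$p.value)
    expect_equal(fisher_exact_2x2(a, b, c, d, "greater")$p_value,
                 fisher.test(matrix(c(a, c, b, d), 2),
                             alternative = "greater")$p.value)
  }
})

test_that("cutoff_sensitivity sweeps consistently and monotonically", {
  set.seed(46)
  paired <- data.frame(protein_id = paste0("p", 1:40),
                       ev_a = 10^-runif(40, 0, 30),
                       bs_a = runif(40, 20, 300),
                       ev_b = 10^-runif(40, 0, 30),
                       bs_b = runif(40, 20, 300))
  paired$ev_a[1:5] <- NA; paired$bs_a[1:5] <- NA
  grid <- c(0, 50, 100, 200, 400)
  sweep <- cutoff_sensitivity(paired, grid)
  expect_equal(sweep[sweep$bs_min == 50, -1],
               data.frame(t(venn_partition(paired)$counts)),
               ignore_attr = TRUE)
  expect_true(all(diff(sweep$unique) >= 0))
  expect_true(all(rowSums(sweep[, -1]) == 40))
  # bs = 0: unique means no hit rows at all (e-value cutoff still applies
  # to present scores sampled above 1e-5 here only when small)
  none <- data.frame(protein_id = c("h", "n"), ev_a = c(1e-9, NA),
                     bs_a = c(30, NA), ev_b = c(1e-9, NA), bs_b = c(30, NA))
  expect_equal(cutoff_sensitivity(none, 0)$unique, 1)
  expect_error(cutoff_sensitivity(paired, numeric(0)), "non-empty")
})

test_that("paired_score_tests compares on log10 e-values over complete
          pairs", {
  paired <- data.frame(protein_id = paste0("p", 1:12),
                       ev_a = 10^-(21:32), bs_a = 101:112,
                       ev_b = 10^-(1:12), bs_b = 51:62)
  paired$ev_b[1] <- NA; paired$bs_b[1] <- NA
  out <- paired_score_tests(paired)
  expect_equal(out$evalue$n_used, 11L)
  expect_lt(out$evalue$p_value, 0.01)
  expect_lt(out$bitscore$p_value, 0.01)
  # e-values of zero are floored, not dropped
  paired$ev_a[2] <- 0
  expect_silent(paired_score_tests(paired))
})
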