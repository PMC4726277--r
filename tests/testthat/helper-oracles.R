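# Independent oracles used to freeze expected values. Each is a brute-force
# or closed-form computation kept deliberately separate from the package's
# implementation path.

# Wilcoxon signed-rank p by literal enumeration of all 2^n sign assignments.
oracle_signed_rank <- function(x, y,
                               alternative = c("two.sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(statistic = 0, p_value = 1))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  eps <- 1e-9
  p_ge <- mean(w_all >= w_obs - eps)
  p_le <- mean(w_all <= w_obs + eps)
  p <- switch(alternative, greater = p_ge, less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  list(statistic = w_obs, p_value = p)
}

# Fisher two-sided p by explicit enumeration of all tables with the observed
# margins, probabilities from binomial coefficients in log space.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  lp <- vapply(lo:hi, function(k) {
    lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  }, numeric(1))
  p <- exp(lp)
  obs <- p[(lo:hi) == a]
  sum(p[p <= obs * (1 + 1e-7)])
}

# Conditional binomial two-sided p by explicit outcome enumeration.
oracle_binom_de <- function(k, t, p0) {
  if (t == 0) return(1)
  lp <- vapply(0:t, function(i) {
    lchoose(t, i) + i * log(p0) + (t - i) * log1p(-p0)
  }, numeric(1))
  p <- exp(lp)
  min(1, sum(p[p <= p[k + 1] * (1 + 1e-7)]))
}

# Longest ORF over all six frames by brute force (each stop-free segment
# trimmed to its first Met when one exists, longest trimmed candidate wins),
# independent of predict_orf's segment bookkeeping.
oracle_six_frame_orf <- function(sequence, min_aa = 10L) {
  best <- ""
  for (fr in c(1, 2, 3, -1, -2, -3)) {
    prot <- venomics::translate_frame(sequence, fr)
    for (seg in strsplit(prot, "*", fixed = TRUE)[[1]]) {
      m <- regexpr("M", seg, fixed = TRUE)
      if (m > 0) seg <- substring(seg, m)
      if (nchar(seg) > nchar(best)) best <- seg
    }
  }
  if (nchar(best) < min_aa) NA_character_ else best
}

# Deterministic random nucleotide sequence helper for property loops.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# md5 digest of a character vector (via a temp file, for byte-level checks)
digest_strings <- function(x) {
  f <- tempfile()
  writeLines(x, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}
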