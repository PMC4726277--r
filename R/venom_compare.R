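# Comparative analysis of three venom-protein sets: best-hit extraction from
# 12-column similarity tables, dual-criterion homology calls, three-set Venn
# partitioning, paired better-score fractions, exact Wilcoxon matched-pairs
# signed-rank test, Fisher exact 2x2 test, and a bit-score cutoff sweep.

.outfmt6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Read a 12-column tabular similarity table
#'
#' Standard 12-column tab-separated hit format (query, subject, percent
#' identity, alignment length, mismatches, gap opens, query/subject
#' coordinates, e-value, bit score), no header.
#'
#' @param path Path to the table.
#' @return data.frame with the 12 standard column names; zero rows allowed.
#' @export
read_outfmt6 <- function(path) {
  x <- tryCatch(
    utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(x) || nrow(x) == 0L) {
    x <- as.data.frame(setNames(
      c(list(character(), character()), rep(list(numeric()), 10)),
      .outfmt6_cols), stringsAsFactors = FALSE)
    return(x)
  }
  if (ncol(x) != 12L) stop("expected 12 tab-separated columns in ", path)
  names(x) <- .outfmt6_cols
  x$qseqid <- as.character(x$qseqid)
  x$sseqid <- as.character(x$sseqid)
  x
}

#' Best hit per query
#'
#' Keeps, per query, the row with minimum e-value; ties broken by maximum
#' bit score, then lexicographically smallest subject id.
#'
#' @param rows data.frame in 12-column format (one query set vs one
#'   reference set).
#' @return data.frame with one row per query present in `rows`.
#' @export
best_hits <- function(rows) {
  if (nrow(rows) == 0L) return(rows)
  o <- order(rows$qseqid, rows$evalue, -rows$bitscore, rows$sseqid)
  rows <- rows[o, , drop = FALSE]
  rows[!duplicated(rows$qseqid), , drop = FALSE]
}

#' Dual-criterion homology call
#'
#' `TRUE` iff `evalue <= ev_max` and `bitscore >= bs_min`, both inclusive.
#' Missing scores (`NA`) give `FALSE`.
#'
#' @param evalue,bitscore Best-hit scores (vectorized).
#' @param ev_max,bs_min Cutoffs (defaults 1e-5 and 50).
#' @return Logical vector.
#' @export
homology_call <- function(evalue, bitscore, ev_max = 1e-5, bs_min = 50) {
  out <- !is.na(evalue) & !is.na(bitscore) &
    evalue <= ev_max & bitscore >= bs_min
  out
}

#' Paired best-hit scores of one query set against two reference sets
#'
#' @param query_ids Character vector: the full query set (queries with no
#'   hits are retained with absent scores).
#' @param rows_a,rows_b 12-column hit tables of the queries vs reference
#'   sets A and B.
#' @return data.frame with columns `protein_id`, `ev_a`, `bs_a`, `ev_b`,
#'   `bs_b` (`NA` = no hit).
#' @export
paired_scores <- function(query_ids, rows_a, rows_b) {
  ba <- best_hits(rows_a); bb <- best_hits(rows_b)
  ia <- match(query_ids, ba$qseqid); ib <- match(query_ids, bb$qseqid)
  data.frame(protein_id = as.character(query_ids),
             ev_a = ba$evalue[ia], bs_a = ba$bitscore[ia],
             ev_b = bb$evalue[ib], bs_b = bb$bitscore[ib],
             stringsAsFactors = FALSE)
}

#' Three-set Venn partition by dual homology cutoffs
#'
#' Each query is labelled `both` when its calls against both reference sets
#' pass, `a_only` / `b_only` when exactly one passes, and `unique` when
#' neither does.
#'
#' @param paired Output of [paired_scores()].
#' @param ev_max,bs_min Cutoffs passed to [homology_call()].
#' @return List with `assignments` (data.frame `protein_id`, `label`) and
#'   `counts` (named integer vector in order unique, a_only, b_only, both).
#' @export
venn_partition <- function(paired, ev_max = 1e-5, bs_min = 50) {
  in_a <- homology_call(paired$ev_a, paired$bs_a, ev_max, bs_min)
  in_b <- homology_call(paired$ev_b, paired$bs_b, ev_max, bs_min)
  label <- ifelse(in_a & in_b, "both",
                  ifelse(in_a, "a_only",
                         ifelse(in_b, "b_only", "unique")))
  counts <- c(unique = sum(label == "unique"),
              a_only = sum(label == "a_only"),
              b_only = sum(label == "b_only"),
              both = sum(label == "both"))
  list(assignments = data.frame(protein_id = paired$protein_id,
                                label = label, stringsAsFactors = FALSE),
       counts = counts)
}

#' Paired better-score counts
#'
#' Counts queries whose best hit against set A beats set B: smaller e-value
#' is better, larger bit score is better (strict comparisons). A present
#' score beats an absent one; two absent scores are a tie. Fractions are
#' over all queries.
#'
#' @param paired Output of [paired_scores()].
#' @return List: `n`, `n_better_ev`, `n_better_bs`, `frac_better_ev`,
#'   `frac_better_bs`.
#' @export
paired_better_fraction <- function(paired) {
  better <- function(a, b, smaller_better) {
    ifelse(is.na(a), FALSE,
           ifelse(is.na(b), TRUE,
                  if (smaller_better) a < b else a > b))
  }
  n <- nrow(paired)
  nev <- sum(better(paired$ev_a, paired$ev_b, TRUE))
  nbs <- sum(better(paired$bs_a, paired$bs_b, FALSE))
  list(n = n, n_better_ev = nev, n_better_bs = nbs,
       frac_better_ev = nev / n, frac_better_bs = nbs / n)
}

# exact null distribution of the positive-rank sum W+ given |d| ranks
# (average ranks for ties), as a generating-function dynamic program over
# doubled ranks; identical to enumerating all 2^n sign assignments.
.signed_rank_distribution <- function(ranks2) {
  probs <- 1
  offset <- 0L  # support is 0..sum(ranks2) in steps of 1 (doubled scale)
  total <- sum(ranks2)
  dist <- numeric(total + 1L); dist[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), dist[seq_len(total + 1L - r)])
    dist <- (dist + shifted) / 2
  }
  dist  # dist[w+1] = P(2*W+ = w)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Differences `d = x - y`; zero differences are dropped; ranks of `|d|` use
#' average ranks for ties; the statistic is the sum of positive ranks. For
#' `n <= exact_n` the p-value is exact over the 2^n equiprobable sign
#' assignments (computed by an equivalent dynamic program); the two-sided
#' p doubles the smaller tail (capped at 1). Beyond `exact_n` a normal
#' approximation with continuity correction and tie-variance adjustment is
#' used.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param alternative `"two.sided"` (default), `"greater"` (x > y), or
#'   `"less"`.
#' @param exact_n Maximum n for the exact distribution (default 25).
#' @return List of class `venomics_test`: `statistic` (W+), `p_value`,
#'   `n_used`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 exact_n = 25L) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y) || length(x) < 1L) {
    stop("x and y must be paired vectors of equal length >= 1")
  }
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(statistic = 0, p_value = 1, n_used = 0L,
                          method = "wilcoxon_signed_rank/degenerate"),
                     class = "venomics_test"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_n) {
    ranks2 <- as.integer(round(2 * r))
    dist <- .signed_rank_distribution(ranks2)
    w2 <- as.integer(round(2 * w))
    p_ge <- sum(dist[(w2 + 1L):length(dist)])
    p_le <- sum(dist[1L:(w2 + 1L)])
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "wilcoxon_signed_rank/exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    zstat <- function(num) num / sqrt(sigma2)
    p_ge <- stats::pnorm(zstat(w - mu - 0.5), lower.tail = FALSE)
    p_le <- stats::pnorm(zstat(w - mu + 0.5))
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "wilcoxon_signed_rank/normal"
  }
  structure(list(statistic = w, p_value = p, n_used = n, method = method),
            class = "venomics_test")
}

#' Compare paired e-values and bit scores by signed-rank tests
#'
#' E-values are compared on the log10 scale (zeros floored at 1e-180);
#' queries lacking a hit in either set are excluded (no defined pair).
#'
#' @param paired Output of [paired_scores()].
#' @return List with elements `evalue` and `bitscore`, each a
#'   `venomics_test` (signed so that "greater" means set A scores better).
#' @export
paired_score_tests <- function(paired) {
  keep <- !is.na(paired$ev_a) & !is.na(paired$ev_b)
  ev_a <- pmax(paired$ev_a[keep], 1e-180)
  ev_b <- pmax(paired$ev_b[keep], 1e-180)
  list(
    evalue = wilcoxon_signed_rank(-log10(ev_a), -log10(ev_b)),
    bitscore = wilcoxon_signed_rank(paired$bs_a[keep], paired$bs_b[keep]))
}

#' Fisher exact test on a 2x2 table
#'
#' Conditions on both margins (hypergeometric model). The two-sided p-value
#' sums the probabilities of all tables with the same margins whose point
#' probability does not exceed the observed one (minimum-likelihood method,
#' with 1e-7 relative slack). The odds ratio reported is the sample odds
#' ratio `(a*d)/(b*c)`.
#'
#' @param a,b,c,d Cell counts (a,b = row 1; c,d = row 2).
#' @param alternative `"two.sided"` (default), `"greater"` (odds ratio > 1),
#'   or `"less"`.
#' @return List of class `venomics_test`: `statistic` (odds ratio),
#'   `p_value`, `n_used`, `method`.
#' @export
#' @examples
#' fisher_exact_2x2(13, 57, 3, 76)$p_value  # ~0.006
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("two.sided", "greater",
                                             "less")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  n <- sum(cells)
  if (n == 0) stop("empty table")
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  support <- lo:hi
  probs <- stats::dhyper(support, m1, m2, k)
  obs <- probs[support == a]
  p <- switch(alternative,
              two.sided = sum(probs[probs <= obs * (1 + 1e-7)]),
              greater = sum(probs[support >= a]),
              less = sum(probs[support <= a]))
  or <- (a * d) / (b * c)
  structure(list(statistic = or, p_value = min(1, p), n_used = n,
                 method = paste0("fisher_exact/", alternative)),
            class = "venomics_test")
}

#' Venn counts across a grid of bit-score cutoffs
#'
#' Recomputes [venn_partition()] at e-value cutoff 1e-5 and each bit-score
#' cutoff in `bs_grid`.
#'
#' @param paired Output of [paired_scores()].
#' @param bs_grid Numeric vector of bit-score cutoffs.
#' @param ev_max E-value cutoff held fixed (default 1e-5).
#' @return data.frame: `bs_min`, `unique`, `a_only`, `b_only`, `both`.
#' @export
cutoff_sensitivity <- function(paired, bs_grid, ev_max = 1e-5) {
  if (length(bs_grid) == 0L) stop("bs_grid must be non-empty")
  do.call(rbind, lapply(bs_grid, function(bs) {
    cnt <- venn_partition(paired, ev_max = ev_max, bs_min = bs)$counts
    data.frame(bs_min = bs, unique = cnt[["unique"]],
               a_only = cnt[["a_only"]], b_only = cnt[["b_only"]],
               both = cnt[["both"]])
  }))
}

#' @export
print.venomics_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic),
      ", p = ", format(x$p_value), ", n = ", x$n_used, "\n", sep = "")
  invisible(x)
}
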