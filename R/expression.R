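# FPKM computation, two-library differential expression (conditional exact
# binomial test), Benjamini-Hochberg correction, the DE filter, and qPCR
# relative expression by the 2^-ddCt method.

#' Compute FPKM
#'
#' FPKM = 1e9 * count / (library_size * effective_length): fragments per
#' kilobase of transcript per million mapped reads.
#'
#' @param count Read count(s) for the transcript.
#' @param library_size Total mapped reads in the library.
#' @param effective_length Effective transcript length in bp.
#' @return FPKM value(s); vectorized over all arguments.
#' @export
#' @examples
#' compute_fpkm(100, 1e6, 1000)  # 100
compute_fpkm <- function(count, library_size, effective_length) {
  if (any(library_size <= 0)) stop("library_size must be > 0")
  if (any(effective_length <= 0)) stop("effective_length must be > 0")
  1e9 * count / (library_size * effective_length)
}

#' Log2 expression ratio with explicit infinity handling
#'
#' `log2(fpkm_vg / fpkm_carcass)`. A zero denominator with a positive
#' numerator yields `+Inf` (and symmetrically `-Inf`); both zero yields the
#' undefined marker `NaN`, distinct from the infinities and excluded from DE
#' flagging downstream.
#'
#' @param fpkm_vg,fpkm_carcass Non-negative FPKM values (vectorized).
#' @return Numeric vector: finite ratio, `Inf`, `-Inf`, or `NaN`.
#' @export
log2_ratio <- function(fpkm_vg, fpkm_carcass) {
  if (any(fpkm_vg < 0) || any(fpkm_carcass < 0)) {
    stop("FPKM values must be non-negative")
  }
  out <- suppressWarnings(log2(fpkm_vg / fpkm_carcass))
  out[fpkm_vg == 0 & fpkm_carcass == 0] <- NaN
  out[fpkm_vg > 0 & fpkm_carcass == 0] <- Inf
  out[fpkm_vg == 0 & fpkm_carcass > 0] <- -Inf
  out
}

#' Two-library differential expression p-value
#'
#' Conditional exact binomial test for a two-library design without
#' replicates. Conditioning on the total `t = count_vg + count_carcass`,
#' under the null `count_vg ~ Binomial(t, libsize_vg / (libsize_vg +
#' libsize_carcass))`. The two-sided p-value sums the probabilities of all
#' outcomes no more likely than the observed one (minimum-likelihood
#' ordering, with a small relative slack against floating-point ties).
#' `method = "normal"` instead uses the normal approximation with continuity
#' correction.
#'
#' @param count_vg,count_carcass Observed read counts.
#' @param libsize_vg,libsize_carcass Library sizes (> 0).
#' @param method `"exact"` (default) or `"normal"`.
#' @return Two-sided p-value in (0, 1]; `t = 0` gives 1.
#' @export
de_test <- function(count_vg, count_carcass, libsize_vg, libsize_carcass,
                    method = c("exact", "normal")) {
  method <- match.arg(method)
  if (libsize_vg <= 0 || libsize_carcass <= 0) {
    stop("library sizes must be > 0")
  }
  t <- count_vg + count_carcass
  if (t == 0) return(1)
  p0 <- libsize_vg / (libsize_vg + libsize_carcass)
  if (method == "normal") {
    mu <- t * p0
    sd <- sqrt(t * p0 * (1 - p0))
    z <- (abs(count_vg - mu) - 0.5) / sd
    return(min(1, 2 * stats::pnorm(max(z, 0), lower.tail = FALSE)))
  }
  d <- stats::dbinom(0:t, t, p0)
  min(1, sum(d[d <= d[count_vg + 1L] * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up: on ascending-sorted p-values, `q_(i) = min_{j >= i} p_(j) * m / j`
#' capped at 1 and mapped back to the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values)
  q_sorted <- pmin(1, rev(cummin(rev(p_values[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Build an expression table from counts
#'
#' Computes FPKM for both tissues, the log2 ratio, exact binomial DE
#' p-values, BH q-values, and applies [de_filter()].
#'
#' @param counts data.frame with columns `id`, `count_vg`, `count_carcass`,
#'   `effective_length`.
#' @param libsize_vg,libsize_carcass Library sizes; default to the column sums.
#' @param ... Passed to [de_filter()] (thresholds).
#' @return data.frame of expression records with a logical `de_flag` column.
#' @export
expression_table <- function(counts, libsize_vg = sum(counts$count_vg),
                             libsize_carcass = sum(counts$count_carcass),
                             ...) {
  stopifnot(all(c("id", "count_vg", "count_carcass", "effective_length")
                %in% names(counts)))
  rec <- data.frame(
    id = as.character(counts$id),
    count_vg = counts$count_vg,
    count_carcass = counts$count_carcass,
    effective_length = counts$effective_length,
    fpkm_vg = compute_fpkm(counts$count_vg, libsize_vg,
                           counts$effective_length),
    fpkm_carcass = compute_fpkm(counts$count_carcass, libsize_carcass,
                                counts$effective_length),
    stringsAsFactors = FALSE)
  rec$log2_ratio <- log2_ratio(rec$fpkm_vg, rec$fpkm_carcass)
  rec$p_value <- mapply(de_test, rec$count_vg, rec$count_carcass,
                        MoreArgs = list(libsize_vg = libsize_vg,
                                        libsize_carcass = libsize_carcass))
  rec$q_value <- bh_adjust(rec$p_value)
  de_filter(rec, ...)
}

#' Flag differentially expressed records
#'
#' A record is flagged iff `fpkm_vg > fpkm_min` AND `log2_ratio > log2_min`
#' AND `q_value < q_max`; all comparisons strict. `+Inf` ratios pass
#' `log2_min`; the undefined (both-zero) marker never passes.
#'
#' @param records data.frame with columns `fpkm_vg`, `log2_ratio`, `q_value`.
#' @param fpkm_min,log2_min,q_max Thresholds (defaults 10, 1, 0.001).
#' @return `records` with a logical `de_flag` column set.
#' @export
de_filter <- function(records, fpkm_min = 10, log2_min = 1, q_max = 0.001) {
  ratio_ok <- !is.nan(records$log2_ratio) & records$log2_ratio > log2_min
  records$de_flag <- records$fpkm_vg > fpkm_min & ratio_ok &
    records$q_value < q_max
  records
}

#' qPCR relative expression by 2^-ddCt
#'
#' Per tissue, `dCt = mean(Ct_target) - mean(Ct_reference)`;
#' `ddCt = dCt_vg - dCt_carcass`; fold change = `2^-ddCt`. The p-value is a
#' two-sample equal-variance Student's t test on per-replicate dCt values
#' (target Ct minus the tissue's mean reference Ct), or `NA` when either
#' tissue has fewer than two replicates.
#'
#' @param ct_target_vg,ct_ref_vg Ct replicates in the venom gland.
#' @param ct_target_carcass,ct_ref_carcass Ct replicates in the carcass.
#' @return List with `fold_change`, `p_value`, `ddct`.
#' @export
ddct_fold_change <- function(ct_target_vg, ct_ref_vg,
                             ct_target_carcass, ct_ref_carcass) {
  lens <- lengths(list(ct_target_vg, ct_ref_vg,
                       ct_target_carcass, ct_ref_carcass))
  if (any(lens < 1L)) stop("each Ct field needs at least one replicate")
  dct_vg <- mean(ct_target_vg) - mean(ct_ref_vg)
  dct_ca <- mean(ct_target_carcass) - mean(ct_ref_carcass)
  ddct <- dct_vg - dct_ca
  fold <- 2^(-ddct)
  x <- ct_target_vg - mean(ct_ref_vg)
  y <- ct_target_carcass - mean(ct_ref_carcass)
  p <- NA_real_
  if (length(x) >= 2L && length(y) >= 2L) {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
      (nx + ny - 2)
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    p <- 2 * stats::pt(abs(tstat), df = nx + ny - 2, lower.tail = FALSE)
  }
  list(fold_change = fold, p_value = p, ddct = ddct)
}
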