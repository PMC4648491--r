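# Method-agreement statistics: Lin's concordance correlation coefficient,
# Bland-Altman limits, and Sanger peak-height proportions.

#' Pair two measurement vectors
#'
#' @param x,y equal-length numeric vectors (length >= 2, no missing
#'   values) from two methods measuring the same samples.
#' @param sample_ids optional identifiers.
#' @return A list of class `"paired_measurements"`.
#' @export
paired_measurements <- function(x, y, sample_ids = NULL) {
  if (length(x) != length(y))
    abort_validation("x and y must have equal length")
  if (length(x) < 2L)
    abort_validation("need >= 2 paired measurements")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    abort_validation("paired measurements must be finite and complete")
  structure(list(
    sample_ids = sample_ids %||% sprintf("S%d", seq_along(x)),
    x = as.numeric(x), y = as.numeric(y)
  ), class = "paired_measurements")
}

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' population moments (n denominators), per Lin's original definition.
#' The CCC penalises both imprecision (scatter) and inaccuracy (location
#' or scale shift from the identity line), so `|ccc| <= |r|` always. The
#' 95% CI uses the Fisher z-transformation with Lin's (1989) standard
#' error; it is degenerate (and returned as the point value) when the data
#' are perfectly concordant.
#'
#' @param p a [paired_measurements()] object, or `x` when `y` is given.
#' @param y optional second vector (with `p` as the first).
#' @return A list of class `"concordance_result"`: `ccc`, `ci_low`,
#'   `ci_high`, `pearson_r`, `r_squared`, `n`.
#' @examples
#' lins_ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7
#' @export
lins_ccc <- function(p, y = NULL) {
  if (!inherits(p, "paired_measurements")) p <- paired_measurements(p, y)
  x <- p$x; yv <- p$y; n <- length(x)
  mx <- mean(x); my <- mean(yv)
  sx2 <- mean((x - mx)^2); sy2 <- mean((yv - my)^2)
  sxy <- mean((x - mx) * (yv - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0)
    abort_validation("ccc undefined: both vectors are constant and equal")
  ccc <- 2 * sxy / denom
  r <- if (sx2 > 0 && sy2 > 0) sxy / sqrt(sx2 * sy2) else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (n >= 3 && !is.na(r) && abs(ccc) < 1 && r != 0) {
    u <- (mx - my) / sqrt(sqrt(sx2) * sqrt(sy2))  # location shift, Lin 1989
    z <- atanh(ccc)
    se2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
              2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
              ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    if (is.finite(se2) && se2 >= 0) {
      half <- stats::qnorm(0.975) * sqrt(se2)
      ci <- tanh(c(z - half, z + half))
    }
  } else if (abs(ccc) == 1) {
    ci <- c(ccc, ccc)
  }
  structure(list(
    ccc = ccc, ci_low = ci[1], ci_high = ci[2],
    pearson_r = r, r_squared = if (is.na(r)) NA_real_ else r^2, n = n
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Lin's CCC = %.4f (95%% CI %.4f-%.4f); Pearson r = %.4f, R^2 = %.4f, n = %d\n",
              x$ccc, x$ci_low, x$ci_high, x$pearson_r, x$r_squared, x$n))
  invisible(x)
}

#' Bland-Altman agreement limits
#'
#' Differences `d = x - y`; bias is `mean(d)` and the limits of agreement
#' are `bias +/- 1.96 * sd(d)` (sample SD).
#'
#' @inheritParams lins_ccc
#' @return A list of class `"bland_altman_result"`: `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `n`, and the per-sample `differences` and
#'   `means` (for plotting).
#' @examples
#' bland_altman(c(1, 2, 3), c(1.1, 1.9, 3.05))
#' @export
bland_altman <- function(p, y = NULL) {
  if (!inherits(p, "paired_measurements")) p <- paired_measurements(p, y)
  d <- p$x - p$y
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(
    bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    sd_diff = s, n = length(d),
    differences = d, means = (p$x + p$y) / 2
  ), class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4f, limits of agreement %.4f to %.4f (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Risk-allele proportion from Sanger chromatogram peak heights
#'
#' Per strand, `peak_risk / (peak_risk + peak_prot)`; the reported value
#' is the mean of the forward and reverse strand proportions. A strand
#' with zero total peak height is dropped with a warning; if both strands
#' are empty the proportion is undefined.
#'
#' @param fwd,rev numeric length-2 vectors `c(peak_risk, peak_prot)` for
#'   the forward and reverse reads.
#' @return The mean risk-allele proportion across usable strands.
#' @examples
#' sanger_proportion(c(60, 40), c(58, 42))  # 0.59
#' @export
sanger_proportion <- function(fwd, rev) {
  if (length(fwd) != 2L || length(rev) != 2L)
    abort_validation("fwd and rev must each be c(peak_risk, peak_prot)")
  if (any(c(fwd, rev) < 0))
    abort_validation("peak heights must be >= 0")
  props <- c()
  for (strand in list(fwd = fwd, rev = rev)) {
    tot <- sum(strand)
    if (tot > 0) props <- c(props, strand[1] / tot)
  }
  if (length(props) == 0L)
    abort_validation("zero total peak height on both strands: proportion undefined")
  if (length(props) == 1L)
    warning("one strand had zero total peak height and was dropped",
            call. = FALSE)
  mean(props)
}
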