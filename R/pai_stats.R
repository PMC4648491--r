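# Exact binomial test for preferential allelic imbalance and
# cohort-level summaries.

#' Exact binomial test for preferential allelic imbalance
#'
#' Among heterozygote tumors with AI, tests whether the split between AI
#' favoring the risk allele (`k_risk`) and AI favoring the protective
#' allele (`k_prot`) departs from the null of an even coin
#' (`p = q = 0.5`). The one-sided tail is taken from the *majority*
#' direction: `p = P(X >= max(k_risk, k_prot))` for
#' `X ~ Binomial(k_risk + k_prot, 0.5)`, computed by exact summation of
#' binomial coefficients. With `direction = "risk"` the tail is instead
#' always taken from the risk count (strict a-priori one-sided test).
#' Ties (`k_risk == k_prot`) report `P(X >= k)` with a tie flag;
#' the majority label defaults to `"risk"` by convention.
#'
#' @param k_risk,k_prot counts of AI samples favoring each allele
#'   (`k_risk + k_prot >= 1`).
#' @param direction `"majority"` (default) or `"risk"`.
#' @return A list of class `"pai_result"`: `k_risk`, `k_prot`, `n_ai`,
#'   `p_value`, `direction_tested`, `tie`.
#' @examples
#' binomial_pai_test(11, 6)   # p ~ 0.166, prints as 0.17
#' binomial_pai_test(14, 3)   # p ~ 0.0064
#' @export
binomial_pai_test <- function(k_risk, k_prot,
                              direction = c("majority", "risk")) {
  direction <- match.arg(direction)
  if (k_risk < 0 || k_prot < 0)
    abort_validation("counts must be non-negative")
  n <- k_risk + k_prot
  if (n < 1)
    abort_validation("undefined test: no AI samples (k_risk + k_prot = 0)")
  k <- if (direction == "risk") k_risk else max(k_risk, k_prot)
  # exact upper tail by direct summation of binomial coefficients
  p <- sum(choose(n, k:n)) * 0.5^n
  tested <- if (direction == "risk") "risk"
            else if (k_risk >= k_prot) "risk" else "protective"
  structure(list(
    k_risk = k_risk, k_prot = k_prot, n_ai = n,
    p_value = min(p, 1), direction_tested = tested,
    tie = (k_risk == k_prot)
  ), class = "pai_result")
}

#' @export
print.pai_result <- function(x, ...) {
  cat(sprintf(
    "PAI binomial test: %d risk vs %d protective (n = %d), one-sided p = %.4g (%s tail%s)\n",
    x$k_risk, x$k_prot, x$n_ai, x$p_value, x$direction_tested,
    if (x$tie) ", tie" else ""))
  invisible(x)
}

#' Summarize AI calls for one SNP cohort
#'
#' Tabulates AI calls (excluded samples do not count as AI), reports the
#' percentage of heterozygotes with AI to one decimal, and attaches the
#' majority-tail binomial PAI test. With zero AI calls the p-value is `NA`
#' and flagged as undefined.
#'
#' @param calls an AI-call `data.frame` from [call_ai()].
#' @param n_heterozygotes number of heterozygote samples assayed
#'   (>= number of non-excluded calls).
#' @param snp_id SNP label for the summary row.
#' @return A one-row `data.frame` of class `"cohort_summary"`: `snp_id`,
#'   `n_heterozygotes`, `n_ai`, `pct_ai`, `k_risk`, `k_prot`, `p_value`.
#' @examples
#' th <- calibrate_thresholds(c(0.49, 0.5, 0.51))
#' calls <- call_ai(c(0.6, 0.5, 0.42), th)
#' summarize_cohort(calls, n_heterozygotes = 3, snp_id = "rs0000001")
#' @export
summarize_cohort <- function(calls, n_heterozygotes, snp_id = "snp") {
  check_columns(calls, c("sample_id", "status"), file = "calls")
  k_risk <- sum(calls$status == "AI_risk")
  k_prot <- sum(calls$status == "AI_protective")
  n_called <- sum(calls$status != "excluded")
  if (n_heterozygotes < n_called)
    abort_validation("n_heterozygotes is smaller than the number of non-excluded calls")
  n_ai <- k_risk + k_prot
  p <- if (n_ai >= 1) binomial_pai_test(k_risk, k_prot)$p_value else NA_real_
  if (n_ai == 0)
    warning(sprintf("cohort '%s': no AI calls; PAI p-value undefined", snp_id),
            call. = FALSE)
  out <- data.frame(
    snp_id = snp_id, n_heterozygotes = n_heterozygotes, n_ai = n_ai,
    pct_ai = round(100 * n_ai / n_heterozygotes, 1),
    k_risk = k_risk, k_prot = k_prot, p_value = p,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort_summary", class(out))
  out
}
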