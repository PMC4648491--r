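# Replicate merging, risk-allele proportions, three-sigma AI thresholds
# and per-sample AI status.

#' Merge replicate well concentrations into one sample measurement
#'
#' Heterozygote samples are typically run in duplicate. Allele
#' concentrations are averaged across replicates; the spread is summarised
#' as the standard error of the per-replicate risk-allele proportions
#' (0 for a single replicate, NA when no replicate has any signal).
#'
#' @param conc_risk,conc_prot numeric vectors of per-replicate allele
#'   concentrations (copies/uL), equal length >= 1.
#' @param sample_id sample identifier.
#' @param tissue `"constitutional"` or `"tumor"`.
#' @return A list of class `"sample_measurement"` with `sample_id`,
#'   `tissue`, `mean_conc_risk`, `mean_conc_prot`, `sem_proportion`,
#'   `n_replicates`.
#' @examples
#' merge_replicates(c(400, 420), c(400, 380))
#' @export
merge_replicates <- function(conc_risk, conc_prot, sample_id = "S1",
                             tissue = c("tumor", "constitutional")) {
  tissue <- match.arg(tissue)
  n <- length(conc_risk)
  if (n == 0L || length(conc_prot) != n)
    abort_validation("need >= 1 replicate with paired risk/protective concentrations")
  if (any(conc_risk < 0) || any(conc_prot < 0))
    abort_validation("concentrations must be >= 0")
  tot <- conc_risk + conc_prot
  props <- ifelse(tot > 0, conc_risk / tot, NA_real_)
  props <- props[!is.na(props)]
  sem <- if (length(props) >= 2) stats::sd(props) / sqrt(length(props))
         else if (length(props) == 1) 0
         else NA_real_
  structure(list(
    sample_id = sample_id, tissue = tissue,
    mean_conc_risk = mean(conc_risk), mean_conc_prot = mean(conc_prot),
    sem_proportion = sem, n_replicates = n
  ), class = "sample_measurement")
}

#' Risk-allele proportion
#'
#' `conc_risk / (conc_risk + conc_prot)`. A heterozygote without somatic
#' alteration is expected at 0.50; departures beyond the calibrated
#' thresholds are called allelic imbalance. The proportion is invariant to
#' rescaling both concentrations (so it does not depend on the droplet
#' volume convention).
#'
#' @param conc_risk,conc_prot allele concentrations (copies/uL), or a
#'   single `sample_measurement` as the first argument.
#' @return Proportion in `[0, 1]`, vectorized over inputs.
#' @examples
#' risk_allele_proportion(300, 100)  # 0.75
#' @export
risk_allele_proportion <- function(conc_risk, conc_prot = NULL) {
  if (inherits(conc_risk, "sample_measurement")) {
    m <- conc_risk
    conc_risk <- m$mean_conc_risk
    conc_prot <- m$mean_conc_prot
  }
  if (any(conc_risk < 0) || any(conc_prot < 0))
    abort_validation("concentrations must be >= 0")
  tot <- conc_risk + conc_prot
  if (any(tot == 0))
    abort_validation("risk-allele proportion undefined: both allele concentrations are zero")
  conc_risk / tot
}

#' Calibrate three-sigma AI thresholds from constitutional heterozygotes
#'
#' Constitutional (germline) DNA from heterozygotes has no somatic copy
#' alteration, so repeat measurements of its risk-allele proportion
#' estimate the assay's measurement distribution around 0.5. The AI bounds
#' are `mean +/- sigma_multiplier * SD` (sample SD, n-1 denominator;
#' default three-sigma).
#'
#' @param constitutional_proportions numeric vector of proportions in
#'   `[0, 1]`, length >= 2.
#' @param sigma_multiplier number of SDs (default 3).
#' @return A list of class `"ai_thresholds"`: `mean_constitutional`,
#'   `sd_constitutional`, `upper`, `lower`,
#'   `n_constitutional_measurements`, `sigma_multiplier`.
#' @examples
#' calibrate_thresholds(c(0.49, 0.50, 0.51))
#' @export
calibrate_thresholds <- function(constitutional_proportions,
                                 sigma_multiplier = 3) {
  p <- constitutional_proportions
  if (length(p) < 2L)
    abort_validation("threshold calibration needs >= 2 constitutional measurements")
  if (any(p < 0 | p > 1))
    abort_validation("proportions must lie in [0, 1]")
  m <- mean(p)
  s <- stats::sd(p)
  if (s == 0)
    warning("degenerate thresholds: constitutional proportions have zero spread",
            call. = FALSE)
  structure(list(
    mean_constitutional = m, sd_constitutional = s,
    upper = m + sigma_multiplier * s, lower = m - sigma_multiplier * s,
    n_constitutional_measurements = length(p),
    sigma_multiplier = sigma_multiplier
  ), class = "ai_thresholds")
}

#' @export
print.ai_thresholds <- function(x, ...) {
  cat(sprintf(
    "AI thresholds: mean %.4f, SD %.4f (n = %d) -> lower %.4f / upper %.4f (%g-sigma)\n",
    x$mean_constitutional, x$sd_constitutional,
    x$n_constitutional_measurements, x$lower, x$upper, x$sigma_multiplier))
  invisible(x)
}

#' Flag samples with too little template in both channels
#'
#' Wells with very low total allele concentration give unstable
#' proportions and are excluded before AI calling.
#'
#' @param conc_risk,conc_prot mean allele concentrations (copies/uL), or a
#'   `sample_measurement` as the first argument.
#' @param min_total_conc exclusion cutoff on the summed concentration
#'   (copies/uL; default 5).
#' @return Logical: `TRUE` when the sample should be excluded.
#' @export
qc_exclude_low_concentration <- function(conc_risk, conc_prot = NULL,
                                         min_total_conc = 5) {
  if (inherits(conc_risk, "sample_measurement")) {
    m <- conc_risk
    conc_risk <- m$mean_conc_risk
    conc_prot <- m$mean_conc_prot
  }
  (conc_risk + conc_prot) < min_total_conc
}

#' Call AI status for tumor proportions against calibrated thresholds
#'
#' Strict inequalities: a proportion above `upper` is `AI_risk`, below
#' `lower` is `AI_protective`, exactly at a threshold is `no_AI`.
#' QC exclusion takes precedence over any status.
#'
#' @param proportion numeric vector of risk-allele proportions.
#' @param thresholds an [calibrate_thresholds()] result.
#' @param qc_excluded logical (recycled) exclusion flags.
#' @param sample_id optional identifiers (recycled).
#' @return A `data.frame` of class `"ai_call"`: `sample_id`, `proportion`,
#'   `status` in `{AI_risk, AI_protective, no_AI, excluded}`.
#' @examples
#' th <- calibrate_thresholds(c(0.49, 0.50, 0.51))
#' call_ai(c(0.60, 0.50, 0.40), th)
#' @export
call_ai <- function(proportion, thresholds, qc_excluded = FALSE,
                    sample_id = NULL) {
  stopifnot(inherits(thresholds, "ai_thresholds"))
  n <- length(proportion)
  qc_excluded <- rep_len(qc_excluded, n)
  sample_id <- if (is.null(sample_id)) sprintf("S%d", seq_len(n))
               else rep_len(sample_id, n)
  status <- ifelse(qc_excluded, "excluded",
            ifelse(proportion > thresholds$upper, "AI_risk",
            ifelse(proportion < thresholds$lower, "AI_protective", "no_AI")))
  out <- data.frame(sample_id = sample_id, proportion = proportion,
                    status = status, stringsAsFactors = FALSE)
  class(out) <- c("ai_call", class(out))
  out
}

#' Run the AI-calling pipeline on a table of wells
#'
#' Convenience wrapper chaining quantitation, replicate merging, QC
#' exclusion, per-assay threshold calibration from pooled constitutional
#' samples, and AI calling of tumor samples.
#'
#' @param wells droplet-well table for one SNP assay.
#' @param samples annotation `data.frame` with columns `sample_id` and
#'   `tissue` (`"constitutional"` / `"tumor"`).
#' @param min_total_conc QC cutoff, see [qc_exclude_low_concentration()].
#' @param sigma_multiplier see [calibrate_thresholds()].
#' @return A list with `thresholds`, `measurements` (per-sample
#'   `data.frame`), and `calls` (tumor AI calls including per-sample
#'   `sem`, `upper`, `lower` columns).
#' @export
ai_pipeline <- function(wells, samples, min_total_conc = 5,
                        sigma_multiplier = 3) {
  validate_wells(wells)
  check_columns(samples, c("sample_id", "tissue"), file = "samples")
  quant <- quantify_wells(wells)
  ids <- unique(quant$sample_id)
  meas <- do.call(rbind, lapply(ids, function(sid) {
    q <- quant[quant$sample_id == sid, , drop = FALSE]
    tissue <- samples$tissue[match(sid, samples$sample_id)]
    if (is.na(tissue))
      abort_validation(sprintf("sample '%s' present in wells but not in sample annotation", sid))
    m <- merge_replicates(q$conc_fam, q$conc_vic, sample_id = sid,
                          tissue = tissue)
    total <- m$mean_conc_risk + m$mean_conc_prot
    data.frame(sample_id = sid, tissue = tissue,
               mean_conc_risk = m$mean_conc_risk,
               mean_conc_prot = m$mean_conc_prot,
               sem_proportion = m$sem_proportion,
               n_replicates = m$n_replicates,
               proportion = if (total > 0) m$mean_conc_risk / total else NA_real_,
               qc_excluded = qc_exclude_low_concentration(
                 m$mean_conc_risk, m$mean_conc_prot, min_total_conc),
               stringsAsFactors = FALSE)
  }))
  const <- meas[meas$tissue == "constitutional" & !meas$qc_excluded &
                  !is.na(meas$proportion), , drop = FALSE]
  thr <- calibrate_thresholds(const$proportion, sigma_multiplier)
  tum <- meas[meas$tissue == "tumor", , drop = FALSE]
  calls <- call_ai(ifelse(is.na(tum$proportion), 0.5, tum$proportion), thr,
                   qc_excluded = tum$qc_excluded | is.na(tum$proportion),
                   sample_id = tum$sample_id)
  calls$sem <- tum$sem_proportion
  calls$upper <- thr$upper
  calls$lower <- thr$lower
  list(thresholds = thr, measurements = meas, calls = calls)
}
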