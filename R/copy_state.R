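# Somatic copy-state classification at a heterozygous SNP locus.
#
# A tumor sample is modelled as a mixture of normal diploid heterozygous
# cells (1 risk + 1 protective copy, 2 control copies) and one altered
# clone at fraction f. Each candidate state implies a curve in the
# (risk-allele proportion, control-normalized copy number) plane as f runs
# over [0, 1]; classification projects an observed point onto every curve
# and keeps the closest state.

#' Candidate somatic copy-state models
#'
#' Ordered from simplest (fewest somatic events) to most complex; the
#' order is the tie-break when two models fit an observation equally well.
#' @export
ALTERATION_MODELS <- c(
  "diploid", "hom_del",
  "hemi_del_prot_lost", "hemi_del_risk_lost",
  "cnloh_risk", "cnloh_prot",
  "gain_risk", "gain_prot",
  "tetraploid_3to1_risk", "tetraploid_3to1_prot"
)

#' Control-normalized total copy number
#'
#' Summed allele concentration divided by the genomic-control
#' concentration (a locus not somatically altered, e.g. an SLC24A3-style
#' assay). 1.0 corresponds to an unaltered diploid locus.
#'
#' @param conc_risk,conc_prot mean allele concentrations (copies/uL), or a
#'   `sample_measurement` as the first argument.
#' @param control_conc genomic-control concentration (copies/uL, > 0), or
#'   a `channel_concentration`.
#' @return Normalized copy number (ratio, >= 0), vectorized.
#' @examples
#' normalized_copy_number(400, 400, 800)  # 1.0
#' @export
normalized_copy_number <- function(conc_risk, conc_prot = NULL,
                                   control_conc = NULL) {
  if (inherits(conc_risk, "sample_measurement")) {
    m <- conc_risk
    control_conc <- conc_prot %||% control_conc
    conc_risk <- m$mean_conc_risk
    conc_prot <- m$mean_conc_prot
  }
  if (inherits(control_conc, "channel_concentration"))
    control_conc <- control_conc$concentration_copies_per_ul
  if (is.null(control_conc) || any(control_conc <= 0))
    abort_validation("control concentration must be > 0; check the genomic-control assay")
  (conc_risk + conc_prot) / control_conc
}

#' Forward model: expected (proportion, copy number) for a state
#'
#' Closed forms from copy-count arithmetic over a mixture of normal cells
#' (fraction `1 - f`) and an altered clone (fraction `f`):
#' \describe{
#'   \item{diploid}{(0.5, 1) for all f.}
#'   \item{hom_del}{clone loses both alleles: cn = 1 - f, proportion 0.5.}
#'   \item{hemi_del_prot_lost}{clone loses the protective copy:
#'     cn = 1 - f/2, proportion 1/(2 - f); mirrored for risk loss.}
#'   \item{cnloh_risk}{protective copy replaced by risk: cn = 1,
#'     proportion (1 + f)/2; mirrored.}
#'   \item{gain_risk}{trisomy with an extra risk copy: cn = (2 + f)/2,
#'     proportion (1 + f)/(2 + f); mirrored.}
#'   \item{tetraploid_3to1_risk}{tetrasomy at 3:1 risk:protective:
#'     cn = 1 + f, proportion (1 + 2f)/(2 + 2f); mirrored.}
#' }
#' At f = 0 every model coincides with the diploid point (0.5, 1).
#'
#' @param model one of [ALTERATION_MODELS].
#' @param f clonal fraction(s) in `[0, 1]`.
#' @return `data.frame` with columns `proportion` and `normalized_cn`.
#' @examples
#' forward_state("gain_risk", 1)            # (2/3, 1.5)
#' forward_state("tetraploid_3to1_risk", 1) # (0.75, 2)
#' @export
forward_state <- function(model, f) {
  if (length(model) != 1L || !model %in% ALTERATION_MODELS)
    abort_validation(sprintf("unknown model '%s'; see ALTERATION_MODELS",
                             paste(model, collapse = ",")))
  if (any(f < 0 | f > 1))
    abort_validation("clonal fraction f must lie in [0, 1]")
  res <- switch(model,
    diploid = list(p = rep(0.5, length(f)), cn = rep(1, length(f))),
    hom_del = list(p = rep(0.5, length(f)), cn = 1 - f),
    hemi_del_prot_lost = list(p = 1 / (2 - f), cn = 1 - f / 2),
    hemi_del_risk_lost = list(p = (1 - f) / (2 - f), cn = 1 - f / 2),
    cnloh_risk = list(p = (1 + f) / 2, cn = rep(1, length(f))),
    cnloh_prot = list(p = (1 - f) / 2, cn = rep(1, length(f))),
    gain_risk = list(p = (1 + f) / (2 + f), cn = (2 + f) / 2),
    gain_prot = list(p = 1 / (2 + f), cn = (2 + f) / 2),
    tetraploid_3to1_risk = list(p = (1 + 2 * f) / (2 + 2 * f), cn = 1 + f),
    tetraploid_3to1_prot = list(p = 1 / (2 + 2 * f), cn = 1 + f)
  )
  data.frame(proportion = res$p, normalized_cn = res$cn)
}

# Closed-form projection onto the reciprocal curve family
# (a - 1/u)^2 + (b - u/2)^2 over u in [lo, hi]: stationary points are real
# roots of u^4 - 2 b u^3 + 4 a u - 4 = 0 (checked against endpoints).
#' @keywords internal
#' @noRd
fit_reciprocal_curve <- function(a, b, lo, hi) {
  roots <- polyroot(c(-4, 4 * a, 0, -2 * b, 1))
  cand <- Re(roots[abs(Im(roots)) < 1e-8])
  cand <- cand[cand >= lo & cand <= hi]
  cand <- c(cand, lo, hi)
  obj <- (a - 1 / cand)^2 + (b - cand / 2)^2
  i <- which.min(obj)
  list(u = cand[i], sq = obj[i])
}

# Best-fit clonal fraction and squared residual for one model.
#' @keywords internal
#' @noRd
fit_state <- function(model, p, cn) {
  clamp <- function(x) min(max(x, 0), 1)
  sq_to <- function(f) {
    fw <- forward_state(model, f)
    (p - fw$proportion)^2 + (cn - fw$normalized_cn)^2
  }
  switch(model,
    diploid = list(f = 0, sq = (p - 0.5)^2 + (cn - 1)^2),
    hom_del = { f <- clamp(1 - cn); list(f = f, sq = sq_to(f)) },
    cnloh_risk = { f <- clamp(2 * p - 1); list(f = f, sq = sq_to(f)) },
    cnloh_prot = { f <- clamp(1 - 2 * p); list(f = f, sq = sq_to(f)) },
    hemi_del_prot_lost = {
      r <- fit_reciprocal_curve(p, cn, 1, 2)
      list(f = 2 - r$u, sq = r$sq)
    },
    hemi_del_risk_lost = {
      r <- fit_reciprocal_curve(1 - p, cn, 1, 2)
      list(f = 2 - r$u, sq = r$sq)
    },
    gain_risk = {
      r <- fit_reciprocal_curve(1 - p, cn, 2, 3)
      list(f = r$u - 2, sq = r$sq)
    },
    gain_prot = {
      r <- fit_reciprocal_curve(p, cn, 2, 3)
      list(f = r$u - 2, sq = r$sq)
    },
    tetraploid_3to1_risk = {
      r <- fit_reciprocal_curve(1 - p, cn, 2, 4)
      list(f = (r$u - 2) / 2, sq = r$sq)
    },
    tetraploid_3to1_prot = {
      r <- fit_reciprocal_curve(p, cn, 2, 4)
      list(f = (r$u - 2) / 2, sq = r$sq)
    }
  )
}

#' Classify the somatic copy state of one observation
#'
#' Fits every candidate model's clonal fraction by minimising the
#' Euclidean distance between the observed
#' `(proportion, normalized_cn)` point and the model's forward curve
#' (closed-form projections), and returns the model with the smallest
#' residual. When several models achieve the same minimum because their
#' curves coincide at the fitted point (every model passes through the
#' diploid point at f = 0, and the trisomy curve is the cn <= 1.5 segment
#' of the 3:1 tetrasomy curve), the simplest model in [ALTERATION_MODELS]
#' order wins. The call is flagged ambiguous when a model predicting a
#' genuinely different point fits within `ambiguity_margin` of the best
#' residual.
#'
#' @param proportion observed risk-allele proportion in `[0, 1]`.
#' @param normalized_cn observed control-normalized copy number (>= 0).
#' @param ambiguity_margin residual margin for the ambiguity flag
#'   (default 0.02).
#' @return A list of class `"alteration_call"`: `model`,
#'   `clonal_fraction`, `residual`, `ambiguous`, `runner_up_model`,
#'   `runner_up_residual`.
#' @examples
#' classify_alteration(0.5, 0.6)   # subclonal homozygous deletion, f = 0.4
#' classify_alteration(0.75, 1.0)  # copy-neutral LOH toward risk, f = 0.5
#' @export
classify_alteration <- function(proportion, normalized_cn,
                                ambiguity_margin = 0.02) {
  if (proportion < 0 || proportion > 1)
    abort_validation("proportion must lie in [0, 1]")
  if (normalized_cn < 0)
    abort_validation("normalized copy number must be >= 0")
  fits <- lapply(ALTERATION_MODELS, fit_state,
                 p = proportion, cn = normalized_cn)
  res <- sqrt(vapply(fits, `[[`, numeric(1), "sq"))
  best_res <- min(res)
  # coincident-curve ties resolve to the simplest model (list order)
  best_i <- which(res <= best_res + 1e-9)[1]
  pred_best <- forward_state(ALTERATION_MODELS[best_i], fits[[best_i]]$f)
  distinct <- vapply(seq_along(fits), function(i) {
    pr <- forward_state(ALTERATION_MODELS[i], fits[[i]]$f)
    max(abs(pr$proportion - pred_best$proportion),
        abs(pr$normalized_cn - pred_best$normalized_cn)) > 1e-9
  }, logical(1))
  runner_i <- if (any(distinct)) which(distinct)[which.min(res[distinct])]
              else NA_integer_
  ambiguous <- !is.na(runner_i) &&
    (res[runner_i] - res[best_i]) <= ambiguity_margin
  structure(list(
    model = ALTERATION_MODELS[best_i],
    clonal_fraction = fits[[best_i]]$f,
    residual = res[best_i],
    ambiguous = ambiguous,
    runner_up_model = if (is.na(runner_i)) NA_character_
                      else ALTERATION_MODELS[runner_i],
    runner_up_residual = if (is.na(runner_i)) NA_real_ else res[runner_i]
  ), class = "alteration_call")
}

#' @export
print.alteration_call <- function(x, ...) {
  cat(sprintf("copy state: %s at clonal fraction %.3f (residual %.4g%s)\n",
              x$model, x$clonal_fraction, x$residual,
              if (x$ambiguous) sprintf(", AMBIGUOUS vs %s at %.4g",
                                       x$runner_up_model,
                                       x$runner_up_residual) else ""))
  invisible(x)
}

#' Classify a cohort of (proportion, copy number) observations
#'
#' @param proportion,normalized_cn equal-length numeric vectors.
#' @param sample_id optional identifiers.
#' @inheritParams classify_alteration
#' @return `data.frame`: `sample_id`, `proportion`, `normalized_cn`,
#'   `model`, `clonal_fraction`, `residual`, `ambiguous`.
#' @export
classify_cohort <- function(proportion, normalized_cn, sample_id = NULL,
                            ambiguity_margin = 0.02) {
  n <- length(proportion)
  if (length(normalized_cn) != n)
    abort_validation("proportion and normalized_cn must have equal length")
  sample_id <- if (is.null(sample_id)) sprintf("S%d", seq_len(n))
               else rep_len(sample_id, n)
  rows <- lapply(seq_len(n), function(i) {
    cl <- classify_alteration(proportion[i], normalized_cn[i],
                              ambiguity_margin)
    data.frame(sample_id = sample_id[i], proportion = proportion[i],
               normalized_cn = normalized_cn[i], model = cl$model,
               clonal_fraction = cl$clonal_fraction,
               residual = cl$residual, ambiguous = cl$ambiguous,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
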