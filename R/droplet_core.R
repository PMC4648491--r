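# Droplet partitioning model and Poisson quantitation.
#
# A duplexed ddPCR well partitions a reaction into 10-20,000 droplets; each
# droplet is scored positive/negative per fluorescence channel (FAM = risk
# allele, VIC = protective allele by convention here). Absolute target
# concentration follows from the fraction of negative droplets via the
# Poisson occupancy model: lambda = -ln(n_neg / n_total) molecules/droplet.

#' Default droplet volume in microlitres
#'
#' The QX100-era droplet volume convention (0.85 nL). Instruments report
#' copies/uL using a fixed nominal droplet volume; proportions of two
#' channels are invariant to this choice.
#' @export
DEFAULT_DROPLET_VOLUME_UL <- 0.00085

#' Construct a droplet-well record
#'
#' One row per well of a duplexed assay: total accepted droplets and the
#' number positive in each fluorescence channel.
#'
#' @param well_id,sample_id,assay_id identifiers (character scalars).
#' @param n_total accepted droplets (> 0).
#' @param n_fam_pos,n_vic_pos droplets positive in the FAM / VIC channel.
#' @param droplet_volume_ul volume per droplet in microlitres (> 0).
#' @return A one-row `data.frame` with class `"droplet_well"` prepended.
#' @examples
#' droplet_well("A01", "S1", "snp", 15000, 4000, 4100)
#' @export
droplet_well <- function(well_id, sample_id, assay_id, n_total,
                         n_fam_pos, n_vic_pos,
                         droplet_volume_ul = DEFAULT_DROPLET_VOLUME_UL) {
  df <- data.frame(
    well_id = as.character(well_id), sample_id = as.character(sample_id),
    assay_id = as.character(assay_id), n_total = as.integer(n_total),
    n_fam_pos = as.integer(n_fam_pos), n_vic_pos = as.integer(n_vic_pos),
    droplet_volume_ul = as.numeric(droplet_volume_ul),
    stringsAsFactors = FALSE
  )
  validate_wells(df)
  class(df) <- c("droplet_well", class(df))
  df
}

#' Validate a table of droplet wells
#'
#' Checks the droplet-well invariants (counts within `[0, n_total]`,
#' positive droplet volume, positive droplet total) and raises a
#' validation error naming the first offending well.
#'
#' @param wells a `data.frame` of wells (see [droplet_well()] for columns).
#' @param file label used in error messages.
#' @return `wells`, invisibly.
#' @export
validate_wells <- function(wells, file = "wells") {
  check_columns(wells, c("well_id", "sample_id", "assay_id", "n_total",
                         "n_fam_pos", "n_vic_pos", "droplet_volume_ul"),
                file = file)
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i)) {
      abort_validation(sprintf("%s: well '%s' %s", file,
                               wells$well_id[i[1]], what))
    }
  }
  bad(wells$n_total <= 0, "has n_total <= 0")
  bad(wells$n_fam_pos < 0 | wells$n_vic_pos < 0, "has a negative count")
  bad(wells$n_fam_pos > wells$n_total, "has n_fam_pos > n_total")
  bad(wells$n_vic_pos > wells$n_total, "has n_vic_pos > n_total")
  bad(wells$droplet_volume_ul <= 0, "has non-positive droplet volume")
  invisible(wells)
}

#' Estimate absolute concentration from droplet counts
#'
#' Poisson occupancy estimator: with a fraction `q` of negative droplets,
#' the mean molecules per droplet is `lambda = -ln(q)` and concentration is
#' `lambda / droplet_volume_ul` copies/uL. The 95% confidence interval is a
#' Wilson score interval on the negative-droplet fraction propagated through
#' the same transform (stable at both low and high occupancy).
#'
#' @param n_pos droplets positive in the channel.
#' @param n_total accepted droplets (> 0).
#' @param droplet_volume_ul droplet volume in microlitres.
#' @param conf_level confidence level for the interval.
#' @return A list of class `"channel_concentration"` with elements
#'   `concentration_copies_per_ul`, `ci_low`, `ci_high`, `lambda_hat`,
#'   `n_pos`, `n_total`, `droplet_volume_ul`.
#' @examples
#' estimate_channel_concentration(5000, 10000, 0.00085)
#' @export
estimate_channel_concentration <- function(n_pos, n_total,
                                           droplet_volume_ul = DEFAULT_DROPLET_VOLUME_UL,
                                           conf_level = 0.95) {
  if (length(n_pos) != 1L || length(n_total) != 1L)
    abort_validation("estimate_channel_concentration is per-channel scalar; see quantify_wells() for tables")
  if (is.na(n_pos) || is.na(n_total) || n_pos < 0 || n_total <= 0)
    abort_validation("counts must satisfy 0 <= n_pos <= n_total, n_total > 0")
  if (n_pos > n_total)
    abort_validation("n_pos exceeds n_total")
  if (droplet_volume_ul <= 0)
    abort_validation("droplet_volume_ul must be > 0")
  if (n_pos == n_total)
    abort_saturation(sprintf(
      "all %d droplets positive: concentration unbounded (saturated well); dilute or reduce input", n_total))

  q_hat <- (n_total - n_pos) / n_total   # negative-droplet fraction
  lambda <- -log(q_hat)
  conc <- lambda / droplet_volume_ul

  # Wilson score bounds for q; high q bound -> low concentration bound.
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  n <- n_total
  denom <- 1 + z^2 / n
  centre <- (q_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(q_hat * (1 - q_hat) / n + z^2 / (4 * n^2)) / denom
  q_lo <- max(centre - half, .Machine$double.xmin)
  q_hi <- min(centre + half, 1)
  structure(list(
    concentration_copies_per_ul = conc,
    ci_low = -log(q_hi) / droplet_volume_ul,
    ci_high = -log(q_lo) / droplet_volume_ul,
    lambda_hat = lambda,
    n_pos = n_pos, n_total = n_total,
    droplet_volume_ul = droplet_volume_ul
  ), class = "channel_concentration")
}

#' @export
print.channel_concentration <- function(x, ...) {
  cat(sprintf("channel concentration: %.3f copies/uL (95%% CI %.3f-%.3f), lambda = %.5f\n",
              x$concentration_copies_per_ul, x$ci_low, x$ci_high, x$lambda_hat))
  invisible(x)
}

#' Quantify both channels of a table of wells
#'
#' Applies [estimate_channel_concentration()] to the FAM and VIC counts of
#' every well.
#'
#' @param wells a validated droplet-well table.
#' @inheritParams estimate_channel_concentration
#' @return A `data.frame` with one row per well: identifiers plus
#'   `conc_fam`, `conc_fam_lo`, `conc_fam_hi`, `conc_vic`, `conc_vic_lo`,
#'   `conc_vic_hi`.
#' @export
quantify_wells <- function(wells, conf_level = 0.95) {
  validate_wells(wells)
  one <- function(n_pos, n_total, v) {
    est <- estimate_channel_concentration(n_pos, n_total, v, conf_level)
    c(est$concentration_copies_per_ul, est$ci_low, est$ci_high)
  }
  fam <- t(mapply(one, wells$n_fam_pos, wells$n_total, wells$droplet_volume_ul))
  vic <- t(mapply(one, wells$n_vic_pos, wells$n_total, wells$droplet_volume_ul))
  data.frame(
    well_id = wells$well_id, sample_id = wells$sample_id,
    assay_id = wells$assay_id,
    conc_fam = fam[, 1], conc_fam_lo = fam[, 2], conc_fam_hi = fam[, 3],
    conc_vic = vic[, 1], conc_vic_lo = vic[, 2], conc_vic_hi = vic[, 3],
    stringsAsFactors = FALSE
  )
}

#' Simulate one duplexed droplet well
#'
#' Each droplet receives molecule counts of the two targets independently
#' with Poisson mean `concentration x droplet_volume_ul`; a droplet is
#' channel-positive iff it holds at least one molecule of that channel's
#' target. Equivalently, channel-positive counts are Binomial with success
#' probability `1 - exp(-lambda)`, which is how they are drawn. Counts are
#' bit-reproducible for a fixed seed.
#'
#' An optional probe cross-reactivity rate `cross_reactivity` (default 0)
#' lets a molecule of the other target also light up the channel with that
#' probability, i.e. the channel rate becomes
#' `1 - exp(-(lambda_own + cross_reactivity * lambda_other))`.
#'
#' @param conc_risk,conc_prot concentrations of the two alleles (copies/uL;
#'   FAM carries the risk allele).
#' @param n_droplets droplets to generate (> 0).
#' @param droplet_volume_ul droplet volume in microlitres.
#' @param seed integer seed for this well.
#' @param cross_reactivity probability in `[0, 1]`, default 0.
#' @param well_id,sample_id,assay_id identifiers for the returned record.
#' @return A one-row droplet-well `data.frame` (see [droplet_well()]).
#' @examples
#' simulate_well(800, 800, 20000, seed = 1)
#' @export
simulate_well <- function(conc_risk, conc_prot, n_droplets,
                          droplet_volume_ul = DEFAULT_DROPLET_VOLUME_UL,
                          seed = 1L, cross_reactivity = 0,
                          well_id = "W1", sample_id = "S1",
                          assay_id = "snp") {
  if (conc_risk < 0 || conc_prot < 0)
    abort_validation("concentrations must be >= 0")
  if (n_droplets <= 0)
    abort_validation("n_droplets must be > 0")
  if (cross_reactivity < 0 || cross_reactivity > 1)
    abort_validation("cross_reactivity must lie in [0, 1]")
  lam_f <- (conc_risk + cross_reactivity * conc_prot) * droplet_volume_ul
  lam_v <- (conc_prot + cross_reactivity * conc_risk) * droplet_volume_ul
  counts <- with_seed(seed, {
    c(stats::rbinom(1L, n_droplets, 1 - exp(-lam_f)),
      stats::rbinom(1L, n_droplets, 1 - exp(-lam_v)))
  })
  droplet_well(well_id, sample_id, assay_id, n_droplets,
               counts[1], counts[2], droplet_volume_ul)
}

#' Define a mixture of tumor clones at one SNP locus
#'
#' The forward model behind the simulator: a sample is a mixture of cell
#' populations ("clones"), each carrying integer copy numbers of the risk
#' allele, the protective allele, and a genomic-control locus assumed not
#' to vary somatically (two copies per cell in every clone, normally).
#'
#' @param clones a `data.frame` with columns `fraction` (in `[0,1]`, summing
#'   to 1), `copies_risk`, `copies_prot` (non-negative integers) and
#'   `copies_control` (positive integers).
#' @param total_control_conc measured control-locus concentration of the
#'   sample in copies/uL (> 0).
#' @return A list of class `"clone_population"`.
#' @examples
#' # clonal hemizygous deletion of the protective allele at fraction 0.5
#' clone_population(data.frame(
#'   fraction = c(0.5, 0.5), copies_risk = c(1, 1),
#'   copies_prot = c(0, 1), copies_control = c(2, 2)
#' ), total_control_conc = 800)
#' @export
clone_population <- function(clones, total_control_conc) {
  check_columns(clones, c("fraction", "copies_risk", "copies_prot",
                          "copies_control"), file = "clones")
  if (nrow(clones) < 1L)
    abort_validation("at least one clone is required")
  if (abs(sum(clones$fraction) - 1) > 1e-9)
    abort_validation("clone fractions must sum to 1 (within 1e-9)")
  if (any(clones$fraction < 0))
    abort_validation("clone fractions must be non-negative")
  if (any(clones$copies_risk < 0 | clones$copies_prot < 0))
    abort_validation("allele copy numbers must be non-negative")
  if (any(clones$copies_control <= 0))
    abort_validation("control copy number must be positive in every clone")
  if (total_control_conc <= 0)
    abort_validation("total_control_conc must be > 0")
  structure(list(clones = clones,
                 total_control_conc = total_control_conc),
            class = "clone_population")
}

#' Expected allele and control concentrations of a clone mixture
#'
#' Copy-weighted expectations: each allele's concentration is the control
#' concentration scaled by the ratio of its mixture-averaged copy number to
#' the mixture-averaged control copy number.
#'
#' @param pop a [clone_population()].
#' @return A list with `conc_risk`, `conc_prot`, `conc_control`,
#'   `expected_proportion`, `expected_normalized_cn`.
#' @export
expected_concentrations <- function(pop) {
  stopifnot(inherits(pop, "clone_population"))
  cl <- pop$clones
  w_risk <- sum(cl$fraction * cl$copies_risk)
  w_prot <- sum(cl$fraction * cl$copies_prot)
  w_ctrl <- sum(cl$fraction * cl$copies_control)
  conc_risk <- pop$total_control_conc * w_risk / w_ctrl
  conc_prot <- pop$total_control_conc * w_prot / w_ctrl
  total <- w_risk + w_prot
  list(
    conc_risk = conc_risk, conc_prot = conc_prot,
    conc_control = pop$total_control_conc,
    expected_proportion = if (total > 0) w_risk / total else NA_real_,
    expected_normalized_cn = total / w_ctrl
  )
}

#' Simulate replicate SNP and control wells for one sample
#'
#' Draws `n_replicates` duplexed SNP-assay wells at the clone mixture's
#' expected allele concentrations and `n_replicates` genomic-control wells
#' at the control concentration, each well on its own deterministic seed
#' substream derived from `seed`.
#'
#' @param pop a [clone_population()].
#' @param n_droplets droplets per well.
#' @param droplet_volume_ul droplet volume in microlitres.
#' @param n_replicates replicate wells per assay (>= 1).
#' @param seed top-level integer seed.
#' @param sample_id sample identifier.
#' @param snp_assay,control_assay assay identifiers.
#' @return A list with `snp_wells` and `control_wells` droplet-well tables.
#' @examples
#' pop <- clone_population(data.frame(fraction = 1, copies_risk = 1,
#'                                    copies_prot = 1, copies_control = 2),
#'                         total_control_conc = 800)
#' simulate_sample(pop, n_droplets = 15000, seed = 42)
#' @export
simulate_sample <- function(pop, n_droplets = 15000,
                            droplet_volume_ul = DEFAULT_DROPLET_VOLUME_UL,
                            n_replicates = 2, seed = 1L,
                            sample_id = "S1", snp_assay = "snp",
                            control_assay = "control") {
  stopifnot(inherits(pop, "clone_population"))
  if (n_replicates < 1L)
    abort_validation("n_replicates must be >= 1")
  exp_conc <- expected_concentrations(pop)
  seeds <- spawn_seeds(seed, 2L * n_replicates)
  snp <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    simulate_well(exp_conc$conc_risk, exp_conc$conc_prot, n_droplets,
                  droplet_volume_ul, seed = seeds[r],
                  well_id = sprintf("%s_%s_r%d", sample_id, snp_assay, r),
                  sample_id = sample_id, assay_id = snp_assay)
  }))
  ctrl <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    simulate_well(exp_conc$conc_control, 0, n_droplets,
                  droplet_volume_ul, seed = seeds[n_replicates + r],
                  well_id = sprintf("%s_%s_r%d", sample_id, control_assay, r),
                  sample_id = sample_id, assay_id = control_assay)
  }))
  list(snp_wells = snp, control_wells = ctrl)
}
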