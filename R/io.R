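# Readers/writers for the documented CSV/TSV dialects, packaged fixtures,
# configuration, and the cohort simulator used by the demo.

#' Read a droplet-well CSV
#'
#' Documented dialect: headered CSV with columns `well_id`, `sample_id`,
#' `assay_id`, `n_total`, `n_fam_pos`, `n_vic_pos`, `droplet_volume_ul`.
#' Unknown extra columns are preserved. An empty-but-headered file yields
#' an empty table; invariant violations raise validation errors naming
#' the well.
#'
#' @param path CSV path.
#' @return A validated droplet-well `data.frame`.
#' @export
read_wells_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("well_id", "sample_id", "assay_id", "n_total",
                      "n_fam_pos", "n_vic_pos", "droplet_volume_ul"),
                file = path)
  if (nrow(df)) validate_wells(df, file = path)
  df
}

#' Write a droplet-well CSV
#' @param wells droplet-well table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_wells_csv <- function(wells, path) {
  validate_wells(wells)
  utils::write.csv(as.data.frame(wells), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read/write AI-call tables (TSV)
#'
#' Columns: `sample_id`, `proportion`, `sem`, `status`, `upper`, `lower`.
#' @param path TSV path.
#' @return `read_calls_tsv`: the calls `data.frame`.
#' @export
read_calls_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample_id", "proportion", "status"), file = path)
  df
}

#' @rdname read_calls_tsv
#' @param calls calls `data.frame`.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an MLPA probe-ratio CSV
#'
#' Dialect: `sample_id`, `probe_id`, `ratio` (normalized peak-height
#' ratio, as exported after intra/inter-sample normalization).
#'
#' @param path CSV path.
#' @return `data.frame` of per-probe ratios.
#' @export
read_mlpa_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample_id", "probe_id", "ratio"), file = path)
  if (any(df$ratio < 0)) abort_validation(sprintf("%s: negative MLPA ratio", path))
  df
}

#' Mean MLPA probe ratio per sample
#'
#' Averages locus-probe ratios within each sample, the per-sample summary
#' compared against ddPCR normalized copy number.
#'
#' @param mlpa a [read_mlpa_csv()] table.
#' @return `data.frame` with `sample_id`, `mean_ratio`, `n_probes`.
#' @export
mlpa_mean_ratio <- function(mlpa) {
  check_columns(mlpa, c("sample_id", "ratio"), file = "mlpa")
  agg <- stats::aggregate(ratio ~ sample_id, data = mlpa,
                          FUN = function(r) c(mean(r), length(r)))
  data.frame(sample_id = agg$sample_id,
             mean_ratio = agg$ratio[, 1], n_probes = agg$ratio[, 2],
             stringsAsFactors = FALSE)
}

#' Read a Sanger peak-height CSV
#'
#' Dialect: `sample_id`, `strand` (`fwd`/`rev`), `peak_risk`, `peak_prot`.
#'
#' @param path CSV path.
#' @return `data.frame` of peak heights.
#' @export
read_sanger_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample_id", "strand", "peak_risk", "peak_prot"),
                file = path)
  df
}

#' Run configuration
#'
#' Bundles the knobs shared across subcommands, with the three-sigma rule
#' as the default threshold multiplier.
#'
#' @param droplet_volume_ul droplet volume (uL).
#' @param n_droplets droplets per simulated well.
#' @param n_replicates replicate wells per sample.
#' @param min_total_conc QC exclusion cutoff (copies/uL).
#' @param sigma_multiplier threshold multiplier (default 3).
#' @param seed integer seed.
#' @param ambiguity_margin residual margin for ambiguous copy-state calls.
#' @param n_constitutional constitutional samples in simulated cohorts.
#' @param control_conc control-locus concentration for simulation.
#' @param tumor_states simulated tumor composition, as
#'   `"model:f:count"` triples joined by `;`.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(droplet_volume_ul = DEFAULT_DROPLET_VOLUME_UL,
                       n_droplets = 15000, n_replicates = 2,
                       min_total_conc = 5, sigma_multiplier = 3,
                       seed = 1L, ambiguity_margin = 0.02,
                       n_constitutional = 20, control_conc = 800,
                       tumor_states = paste(
                         "diploid:0:6", "hemi_del_prot_lost:1:3",
                         "hemi_del_prot_lost:0.5:2", "hemi_del_risk_lost:1:2",
                         "hom_del:0.5:2", "cnloh_risk:0.8:2",
                         "gain_risk:1:2", "tetraploid_3to1_risk:1:1",
                         sep = ";")) {
  cfg <- list(droplet_volume_ul = droplet_volume_ul,
              n_droplets = n_droplets, n_replicates = n_replicates,
              min_total_conc = min_total_conc,
              sigma_multiplier = sigma_multiplier, seed = as.integer(seed),
              ambiguity_margin = ambiguity_margin,
              n_constitutional = n_constitutional,
              control_conc = control_conc, tumor_states = tumor_states)
  num <- cfg[c("droplet_volume_ul", "n_droplets", "n_replicates",
               "min_total_conc", "sigma_multiplier", "ambiguity_margin",
               "n_constitutional", "control_conc")]
  if (any(unlist(num) <= 0))
    abort_validation("all run_config numeric fields must be positive")
  class(cfg) <- "run_config"
  cfg
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Unknown keys
#' raise a validation error. Values override [run_config()] defaults.
#'
#' @param path config file path.
#' @return A `"run_config"` list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), character(1))
  defaults <- run_config()
  unknown <- setdiff(keys, names(unclass(defaults)))
  if (length(unknown))
    abort_validation(sprintf("%s: unknown config key(s): %s", path,
                             paste(unknown, collapse = ", ")))
  args <- stats::setNames(as.list(vals), keys)
  numeric_keys <- setdiff(names(args), "tumor_states")
  args[numeric_keys] <- lapply(args[numeric_keys], as.numeric)
  do.call(run_config, args)
}

# clone table realizing one copy-state model at clonal fraction f
#' @keywords internal
#' @noRd
state_clones <- function(model, f) {
  alt <- switch(model,
    diploid = c(1, 1),
    hom_del = c(0, 0),
    hemi_del_prot_lost = c(1, 0),
    hemi_del_risk_lost = c(0, 1),
    cnloh_risk = c(2, 0),
    cnloh_prot = c(0, 2),
    gain_risk = c(2, 1),
    gain_prot = c(1, 2),
    tetraploid_3to1_risk = c(3, 1),
    tetraploid_3to1_prot = c(1, 3),
    abort_validation(sprintf("unknown model '%s'", model))
  )
  if (f >= 1) {
    data.frame(fraction = 1, copies_risk = alt[1], copies_prot = alt[2],
               copies_control = 2)
  } else if (f <= 0) {
    data.frame(fraction = 1, copies_risk = 1, copies_prot = 1,
               copies_control = 2)
  } else {
    data.frame(fraction = c(f, 1 - f),
               copies_risk = c(alt[1], 1), copies_prot = c(alt[2], 1),
               copies_control = c(2, 2))
  }
}

#' Simulate a constitutional + tumor cohort
#'
#' Generates `n_constitutional` unaltered diploid heterozygote samples and
#' a tumor arm whose composition is given by `tumor_states`
#' (`"model:f:count"` triples). Every sample gets replicate duplexed SNP
#' wells and genomic-control wells via [simulate_sample()], all driven by
#' deterministic substreams of `config$seed`.
#'
#' @param config a [run_config()].
#' @return A list with `wells` (all wells, SNP assay id `"snp"`, control
#'   assay id `"control"`) and `samples` (annotation with `sample_id`,
#'   `tissue`, `true_model`, `true_f`).
#' @export
simulate_cohort <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  states <- strsplit(split_list_field(config$tumor_states, sep = ";"), ":")
  plan <- data.frame(
    model = rep("diploid", config$n_constitutional),
    f = 0, tissue = "constitutional", stringsAsFactors = FALSE)
  for (s in states) {
    if (length(s) != 3L)
      abort_validation("tumor_states entries must be model:f:count")
    plan <- rbind(plan, data.frame(
      model = rep(s[1], as.integer(s[3])), f = as.numeric(s[2]),
      tissue = "tumor", stringsAsFactors = FALSE))
  }
  seeds <- spawn_seeds(config$seed, nrow(plan))
  wells <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    sid <- sprintf("%s%03d", ifelse(plan$tissue[i] == "tumor", "T", "C"), i)
    pop <- clone_population(state_clones(plan$model[i], plan$f[i]),
                            total_control_conc = config$control_conc)
    sim <- simulate_sample(pop, n_droplets = config$n_droplets,
                           droplet_volume_ul = config$droplet_volume_ul,
                           n_replicates = config$n_replicates,
                           seed = seeds[i], sample_id = sid)
    wells[[i]] <- rbind(sim$snp_wells, sim$control_wells)
    plan$sample_id[i] <- sid
  }
  list(
    wells = do.call(rbind, wells),
    samples = data.frame(sample_id = plan$sample_id, tissue = plan$tissue,
                         true_model = plan$model, true_f = plan$f,
                         stringsAsFactors = FALSE)
  )
}

#' Load a packaged fixture
#'
#' Available fixtures:
#' \describe{
#'   \item{table1_counts}{Per-SNP heterozygote/AI counts of the published
#'     childhood-ALL cohort (one row per SNP; the `cohort = "prior"` row
#'     is the earlier missense-SNP result).}
#'   \item{table2_loci}{The 16 recurrent SCNA peaks whose overlapping
#'     GWAS SNPs matched the SCNA tumor type, with per-locus association
#'     cancer lists (hg19, 1-based inclusive).}
#'   \item{demo_cohort}{A deterministic simulated ddPCR cohort
#'     (see [simulate_cohort()]; seed 1).}
#' }
#'
#' @param name fixture name.
#' @return A `data.frame` (counts, loci) or list (demo cohort).
#' @export
load_fixture <- function(name) {
  known <- c("table1_counts", "table2_loci", "demo_cohort")
  if (!name %in% known)
    abort_validation(sprintf("unknown fixture '%s'; available: %s", name,
                             paste(known, collapse = ", ")))
  if (name == "demo_cohort")
    return(simulate_cohort(run_config(seed = 1L)))
  path <- system.file("extdata", paste0(name, ".tsv"),
                      package = "smartddpcr")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (name == "table2_loci") df <- scna_regions(df)
  df
}
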