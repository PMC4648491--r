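# Shared helpers: small simulation wrappers and independent oracles.

# Simulate one sample for a planted copy state and return the derived
# (proportion, normalized_cn) observation from quantified replicate wells.
observe_state <- function(model, f, seed, n_droplets = 15000,
                          control_conc = 800, n_replicates = 2) {
  clones <- smartddpcr:::state_clones(model, f)
  pop <- clone_population(clones, total_control_conc = control_conc)
  sim <- simulate_sample(pop, n_droplets = n_droplets,
                         n_replicates = n_replicates, seed = seed)
  qs <- quantify_wells(sim$snp_wells)
  qc <- quantify_wells(sim$control_wells)
  risk <- mean(qs$conc_fam); prot <- mean(qs$conc_vic)
  ctrl <- mean(qc$conc_fam)
  # complete loss (e.g. clonal homozygous deletion) leaves no allelic
  # signal; use the balanced convention 0.5 for copy-state purposes
  prop <- if (risk + prot > 0) risk / (risk + prot) else 0.5
  list(proportion = prop, normalized_cn = (risk + prot) / ctrl)
}

# Brute-force majority-tail binomial p by full 2^n enumeration.
brute_force_majority_p <- function(k_risk, k_prot) {
  n <- k_risk + k_prot
  k <- max(k_risk, k_prot)
  outcomes <- 0:(2^n - 1)
  # popcount of each equally likely risk/protective assignment
  successes <- vapply(outcomes, function(o) sum(bitwAnd(o, 2^(0:(n - 1))) > 0),
                      numeric(1))
  mean(successes >= k)
}

# ai_call data.frame with given status counts, for cohort summaries.
make_calls <- function(k_risk, k_prot, n_no_ai = 0, n_excluded = 0) {
  status <- c(rep("AI_risk", k_risk), rep("AI_protective", k_prot),
              rep("no_AI", n_no_ai), rep("excluded", n_excluded))
  data.frame(sample_id = sprintf("S%d", seq_along(status)),
             proportion = 0.5, status = status, stringsAsFactors = FALSE)
}
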