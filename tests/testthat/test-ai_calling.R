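test_that("replicate merging averages concentrations and spreads", {
  m1 <- merge_replicates(400, 400)
  expect_equal(m1$mean_conc_risk, 400)
  expect_equal(m1$sem_proportion, 0)

  m2 <- merge_replicates(c(400, 420), c(400, 380))
  expect_equal(m2$mean_conc_risk, 410)
  expect_equal(m2$mean_conc_prot, 390)
  expect_equal(m2$sem_proportion, sd(c(0.5, 0.525)) / sqrt(2))
  expect_equal(m2$sem_proportion, 0.0125, tolerance = 1e-10)

  m0 <- merge_replicates(c(0, 0), c(0, 0))
  expect_equal(m0$mean_conc_risk, 0)
  expect_true(is.na(m0$sem_proportion))
  expect_true(qc_exclude_low_concentration(m0$mean_conc_risk,
                                           m0$mean_conc_prot, 5))
  expect_error(merge_replicates(numeric(0), numeric(0)),
               class = "smartddpcr_validation_error")
})

test_that("risk-allele proportion is correct and scale-invariant", {
  expect_equal(risk_allele_proportion(400, 400), 0.5)
  expect_equal(risk_allele_proportion(300, 100), 0.75)
  expect_equal(risk_allele_proportion(0, 250), 0)
  expect_error(risk_allele_proportion(0, 0),
               class = "smartddpcr_validation_error")
  set.seed(1)
  for (i in 1:25) {
    r <- runif(1, 0, 1000); p <- runif(1, 0, 1000); c0 <- runif(1, 0.01, 100)
    expect_equal(risk_allele_proportion(r, p),
                 risk_allele_proportion(c0 * r, c0 * p), tolerance = 1e-12)
  }
})

test_that("three-sigma thresholds use the sample SD", {
  th <- calibrate_thresholds(c(0.49, 0.50, 0.51))
  expect_equal(th$mean_constitutional, 0.5)
  expect_equal(th$sd_constitutional, 0.01)
  expect_equal(th$upper, 0.53)
  expect_equal(th$lower, 0.47)
  expect_equal(th$n_constitutional_measurements, 3L)

  expect_warning(thd <- calibrate_thresholds(rep(0.5, 5)), "degenerate")
  expect_equal(thd$upper, thd$lower)
  expect_error(calibrate_thresholds(0.5),
               class = "smartddpcr_validation_error")
  expect_error(calibrate_thresholds(c(0.4, 1.2)),
               class = "smartddpcr_validation_error")
})

test_that("AI status uses strict inequalities with QC precedence", {
  th <- calibrate_thresholds(c(0.49, 0.50, 0.51))  # 0.47 / 0.53
  calls <- call_ai(c(0.60, 0.50, 0.40, 0.53, 0.47), th)
  expect_equal(calls$status, c("AI_risk", "no_AI", "AI_protective",
                               "no_AI", "no_AI"))  # boundaries are no_AI
  exc <- call_ai(0.40, th, qc_excluded = TRUE)
  expect_equal(exc$status, "excluded")

  # published mean thresholds force the classification of 0.60
  th2 <- structure(list(mean_constitutional = 0.5, sd_constitutional = NA,
                        upper = 0.548, lower = 0.453,
                        n_constitutional_measurements = NA,
                        sigma_multiplier = 3), class = "ai_thresholds")
  expect_equal(call_ai(0.60, th2)$status, "AI_risk")
})

test_that("low-concentration QC rule is a strict total cutoff", {
  expect_true(qc_exclude_low_concentration(0.5, 0.4, 5))
  expect_false(qc_exclude_low_concentration(400, 400, 5))
  expect_true(qc_exclude_low_concentration(0, 0, 5))
  expect_false(qc_exclude_low_concentration(3, 2, 5))  # exactly at cutoff
})

test_that("diploid cohorts stay under 1% false-positive AI at three sigma", {
  # constitutional calibration arm
  const <- vapply(seq_len(30), function(s) {
    o <- observe_state("diploid", 0, seed = 10000 + s)
    o$proportion
  }, numeric(1))
  th <- calibrate_thresholds(const)
  # 500 independent diploid tumor samples, 15000 droplets, duplicates
  props <- vapply(seq_len(500), function(s) {
    observe_state("diploid", 0, seed = 20000 + s)$proportion
  }, numeric(1))
  calls <- call_ai(props, th)
  fp <- mean(calls$status != "no_AI")
  expect_lte(fp, 0.01)
})

test_that("clonal hemizygous deletions are called AI essentially always", {
  const <- vapply(seq_len(30), function(s) {
    observe_state("diploid", 0, seed = 30000 + s)$proportion
  }, numeric(1))
  th <- calibrate_thresholds(const)
  props <- vapply(seq_len(100), function(s) {
    observe_state("hemi_del_prot_lost", 1, seed = 40000 + s)$proportion
  }, numeric(1))
  calls <- call_ai(props, th)
  expect_gte(mean(calls$status == "AI_risk"), 0.99)
})

test_that("ai_pipeline chains quantitation, QC, calibration and calling", {
  cohort <- simulate_cohort(run_config(seed = 5L, n_constitutional = 12))
  snp_wells <- cohort$wells[cohort$wells$assay_id == "snp", ]
  res <- ai_pipeline(snp_wells, cohort$samples)
  expect_s3_class(res$thresholds, "ai_thresholds")
  truth <- cohort$samples[cohort$samples$tissue == "tumor", ]
  merged <- merge(res$calls, truth, by = "sample_id")
  # clonal one-allele losses must be AI in the matching direction
  expect_true(all(merged$status[merged$true_model == "hemi_del_prot_lost" &
                                  merged$true_f == 1] == "AI_risk"))
  expect_true(all(merged$status[merged$true_model == "hemi_del_risk_lost" &
                                  merged$true_f == 1] == "AI_protective"))
  # balanced losses keep proportion 0.5
  expect_true(all(merged$status[merged$true_model %in%
                                  c("diploid", "hom_del")] == "no_AI"))
})
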