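test_that("Poisson quantitation matches closed forms and flags edge cases", {
  est0 <- estimate_channel_concentration(0, 10000, 0.00085)
  expect_equal(est0$concentration_copies_per_ul, 0)
  expect_equal(est0$lambda_hat, 0)
  expect_equal(est0$ci_low, 0)

  est <- estimate_channel_concentration(5000, 10000, 0.00085)
  expect_equal(est$lambda_hat, log(2))
  expect_equal(est$concentration_copies_per_ul, -log(0.5) / 0.00085,
               tolerance = 1e-12)
  expect_lte(est$ci_low, est$concentration_copies_per_ul)
  expect_gte(est$ci_high, est$concentration_copies_per_ul)

  expect_error(estimate_channel_concentration(10000, 10000, 0.00085),
               class = "smartddpcr_saturation_error")
  expect_error(estimate_channel_concentration(-1, 100, 0.00085),
               class = "smartddpcr_validation_error")
  expect_error(estimate_channel_concentration(5, 100, 0),
               class = "smartddpcr_validation_error")
})

test_that("estimator is strictly increasing in n_pos", {
  conc <- vapply(c(0, 1, 10, 500, 5000, 14999), function(k) {
    estimate_channel_concentration(k, 15000)$concentration_copies_per_ul
  }, numeric(1))
  expect_true(all(diff(conc) > 0))
})

test_that("simulated wells are bit-reproducible and respect trivial limits", {
  w1 <- simulate_well(800, 400, 20000, seed = 11)
  w2 <- simulate_well(800, 400, 20000, seed = 11)
  expect_identical(w1$n_fam_pos, w2$n_fam_pos)
  expect_identical(w1$n_vic_pos, w2$n_vic_pos)
  expect_false(identical(
    w1$n_fam_pos, simulate_well(800, 400, 20000, seed = 12)$n_fam_pos))

  w0 <- simulate_well(0, 0, 10000, seed = 3)
  expect_equal(w0$n_fam_pos, 0L)
  expect_equal(w0$n_vic_pos, 0L)

  sat <- simulate_well(1e7, 0, 1000, seed = 4)
  expect_equal(sat$n_fam_pos, 1000L)
  expect_error(estimate_channel_concentration(sat$n_fam_pos, sat$n_total),
               class = "smartddpcr_saturation_error")
})

test_that("round-trip: estimator is unbiased with valid CI coverage", {
  v <- DEFAULT_DROPLET_VOLUME_UL
  n_droplets <- 20000
  n_seeds <- 400
  for (lambda in c(0.05, 0.2, 0.5, 1.0)) {
    truth <- lambda / v
    # seed base depends on lambda so the four conditions use independent
    # RNG substreams (reusing one stream correlates their coverage)
    est <- t(vapply(seq_len(n_seeds), function(s) {
      w <- simulate_well(truth, 0, n_droplets, v,
                         seed = round(lambda * 1e6) + s)
      e <- estimate_channel_concentration(w$n_fam_pos, w$n_total, v)
      c(e$concentration_copies_per_ul, e$ci_low, e$ci_high)
    }, numeric(3)))
    expect_lt(abs(mean(est[, 1]) - truth) / truth, 0.02)
    coverage <- mean(est[, 2] <= truth & truth <= est[, 3])
    expect_gte(coverage, 0.93)
  }
})

test_that("FAM and VIC channels are drawn independently", {
  counts <- t(vapply(seq_len(300), function(s) {
    w <- simulate_well(600, 600, 15000, seed = 4000 + s)
    c(w$n_fam_pos, w$n_vic_pos)
  }, numeric(2)))
  expect_lt(abs(cor(counts[, 1], counts[, 2])), 0.15)
})

test_that("clone populations validate and give copy-weighted expectations", {
  expect_error(clone_population(
    data.frame(fraction = c(0.6, 0.6), copies_risk = 1, copies_prot = 1,
               copies_control = 2), 800),
    class = "smartddpcr_validation_error")
  expect_error(clone_population(
    data.frame(fraction = 1, copies_risk = 1, copies_prot = 1,
               copies_control = 0), 800),
    class = "smartddpcr_validation_error")

  # diploid heterozygote
  p1 <- clone_population(data.frame(fraction = 1, copies_risk = 1,
                                    copies_prot = 1, copies_control = 2), 800)
  e1 <- expected_concentrations(p1)
  expect_equal(e1$expected_proportion, 0.5)
  expect_equal(e1$expected_normalized_cn, 1.0)

  # subclonal hemizygous loss of the protective allele at f = 0.5
  p2 <- clone_population(data.frame(
    fraction = c(0.5, 0.5), copies_risk = c(1, 1), copies_prot = c(0, 1),
    copies_control = c(2, 2)), 800)
  e2 <- expected_concentrations(p2)
  expect_equal(e2$expected_proportion, 1 / 1.5, tolerance = 1e-12)
  expect_equal(e2$expected_normalized_cn, 0.75)

  # clonal trisomy with a risk-allele gain
  p3 <- clone_population(data.frame(fraction = 1, copies_risk = 2,
                                    copies_prot = 1, copies_control = 2), 800)
  e3 <- expected_concentrations(p3)
  expect_equal(e3$expected_proportion, 2 / 3, tolerance = 1e-12)
  expect_equal(e3$expected_normalized_cn, 1.5)
})

test_that("simulate_sample recovers the planted expectations", {
  pop <- clone_population(data.frame(
    fraction = c(0.5, 0.5), copies_risk = c(1, 1), copies_prot = c(0, 1),
    copies_control = c(2, 2)), 800)
  sim <- simulate_sample(pop, n_droplets = 20000, n_replicates = 4, seed = 99)
  expect_equal(nrow(sim$snp_wells), 4L)
  expect_equal(nrow(sim$control_wells), 4L)
  qs <- quantify_wells(sim$snp_wells)
  prop <- mean(qs$conc_fam) / (mean(qs$conc_fam) + mean(qs$conc_vic))
  expect_equal(prop, 2 / 3, tolerance = 0.02)
  # deterministic for a fixed top-level seed
  sim2 <- simulate_sample(pop, n_droplets = 20000, n_replicates = 4, seed = 99)
  expect_identical(sim$snp_wells$n_fam_pos, sim2$snp_wells$n_fam_pos)
})
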