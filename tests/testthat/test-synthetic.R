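test_that("noiseless logistic datasets repeat the mean curve exactly", {
  d <- generate_logistic_dataset(noise_sd = 0, seed = 1)
  # 2 conditions x 3 bio x 6 tech x 43 time points
  expect_equal(nrow(d), 2 * 3 * 6 * 43)
  expect_equal(length(unique(d$time_h)), 43)
  one <- d[d$condition == "R1881" & d$bio_rep == 1 & d$tech_rep == 1, ]
  for (b in 1:3) for (tr in 1:6) {
    cur <- d[d$condition == "R1881" & d$bio_rep == b & d$tech_rep == tr, ]
    expect_equal(cur$relative_count, one$relative_count)
  }
  # every series is 1 at the 24-h normalization point
  expect_true(all(d$relative_count[d$time_h == 24] == 1))
})

test_that("logistic generation is seeded and rejects bad initial values", {
  a <- generate_logistic_dataset(noise_sd = 0.08, seed = 7)
  b <- generate_logistic_dataset(noise_sd = 0.08, seed = 7)
  expect_identical(a, b)
  c <- generate_logistic_dataset(noise_sd = 0.08, seed = 8)
  expect_false(identical(a, c))
  expect_error(generate_logistic_dataset(n0 = 0), "0 < n0 < K")
  expect_error(generate_logistic_dataset(n0 = 20, K = 10), "0 < n0 < K")
})

test_that("simulator-backed datasets carry the scenario condition and are normalized", {
  cfg <- small_scenario(c(tumor = 40), ticks = 10)
  d <- generate_simulated_dataset(preset_params("R1881"), cfg,
                                  n_bio = 2, n_tech = 2, seed = 3)
  expect_equal(unique(d$condition), "R1881")
  expect_equal(unique(d$population), "tumor")
  expect_true(all(d$relative_count[d$time_h == 24] == 1))
  expect_equal(nrow(d), 2 * 2 * 11)
  # deterministic in the master seed
  expect_identical(
    d, generate_simulated_dataset(preset_params("R1881"), cfg,
                                  n_bio = 2, n_tech = 2, seed = 3))
})

test_that("hormone-proficient runs grow faster than deprived ones", {
  mk <- function(cond) {
    cfg <- small_scenario(c(tumor = 60), condition = cond, ticks = 30,
                          width = 40, height = 40)
    d <- generate_simulated_dataset(preset_params(cond), cfg,
                                    n_bio = 3, n_tech = 3, seed = 9)
    mean(d$relative_count[d$time_h == max(d$time_h)])
  }
  expect_gt(mk("R1881"), mk("DMSO"))
})

test_that("replicate means agree with fresh direct simulations", {
  cfg <- small_scenario(c(tumor = 50), ticks = 12, width = 40, height = 40)
  p <- preset_params("R1881")
  d <- generate_simulated_dataset(p, cfg, n_bio = 3, n_tech = 6, seed = 31)
  final_ds <- d$relative_count[d$time_h == max(d$time_h)]
  fresh <- vapply(1:18, function(i) {
    traj <- run_simulation(cfg, p, seed = 5000 + i)
    g <- relative_growth(traj)
    g$value[length(g$value)]
  }, numeric(1))
  se <- sqrt(stats::var(final_ds) / 18 + stats::var(fresh) / 18)
  expect_lt(abs(mean(final_ds) - mean(fresh)), 3 * se)
})
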