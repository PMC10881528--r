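test_that("mse cost matches hand arithmetic", {
  expect_equal(mse_cost(c(1, 2), c(1, 4)), 2)
  expect_equal(mse_cost(c(1, 2, 3), c(1, 2, 3)), 0)
  # constant offset c over n points costs c^2
  expect_equal(mse_cost(rep(0.3, 7) + 1.5, rep(0.3, 7)), 1.5^2)
  expect_error(mse_cost(numeric(0), numeric(0)), "non-empty")
})

test_that("mse cost matches data times to the nearest tick within tolerance", {
  model <- data.frame(time_h = seq(0, 40, 4), value = seq(0, 40, 4) / 10)
  data <- data.frame(time_h = c(0, 7, 25), value = c(0, 0.8, 2.4))
  # 7 -> tick 8 (value .8), 25 -> tick 24 (value 2.4): exact match, cost 0
  expect_equal(mse_cost(model, data), 0)
  # beyond the simulated range there is no tick within half a tick's time
  bad <- data.frame(time_h = c(0, 50), value = c(0, 1))
  expect_error(mse_cost(model, bad), "half a tick")
})

test_that("PSO recovers a known 2-D optimum and bookkeeping is sound", {
  target <- c(x1 = 0.312, x2 = 0.777)
  fn <- function(x) sum((x - target)^2)
  fit <- pso_optimize(fn, c(x1 = 0, x2 = 0), c(x1 = 1, x2 = 1),
                      pso_config(swarm_size = 20, iterations = 60,
                                 restarts = 40, seed = 11))
  err <- apply(fit$per_restart[, c("x1", "x2")], 1,
               function(x) max(abs(x - target)))
  expect_gte(mean(err < 1e-3), 0.95)
  # best-so-far trace is non-increasing within every restart
  for (tr in fit$traces) expect_true(all(diff(tr) <= 1e-15))
  # with one restart the median is that restart's optimum
  fit1 <- pso_optimize(fn, c(0, 0), c(1, 1),
                       pso_config(swarm_size = 10, iterations = 30,
                                  restarts = 1, seed = 2))
  expect_equal(unname(fit1$median), unname(fit1$best))
})

test_that("PSO respects box bounds", {
  fn <- function(x) -sum(x)            # pushes to the upper bound
  fit <- pso_optimize(fn, c(0, 0), c(1, 2),
                      pso_config(swarm_size = 10, iterations = 30,
                                 restarts = 5, seed = 3))
  pr <- as.matrix(fit$per_restart[, c("x1", "x2")])
  expect_true(all(pr >= 0 - 1e-12))
  expect_true(all(pr[, 1] <= 1 + 1e-12 & pr[, 2] <= 2 + 1e-12))
  # a boundary optimum is approached but reflection keeps iterates interior
  expect_equal(unname(fit$best), c(1, 2), tolerance = 1e-2)
})

test_that("candidate evaluation is deterministic and penalizes wrong parameters", {
  p <- preset_params("R1881")
  cfg <- small_scenario(c(tumor = 60), ticks = 20, width = 40, height = 40)
  ds <- generate_simulated_dataset(p, cfg, n_bio = 1, n_tech = 4, seed = 13)
  spec <- fit_spec(list(TUpprol = c(0, 0.5)), p, cfg, n_sim_rep = 3)
  truth <- c(TUpprol = p$TUpprol)
  c1 <- evaluate_candidate(truth, spec, ds, seed = 4)
  expect_identical(c1, evaluate_candidate(truth, spec, ds, seed = 4))
  expect_gte(c1, 0)
  # the generating value beats a +/-50% perturbation in most seeds
  hits <- vapply(1:10, function(s) {
    ct <- evaluate_candidate(truth, spec, ds, seed = s)
    chi <- evaluate_candidate(truth * 1.5, spec, ds, seed = s)
    clo <- evaluate_candidate(truth * 0.5, spec, ds, seed = s)
    ct < chi && ct < clo
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(evaluate_candidate(c(TUpprol = 0.9), spec, ds), "bounds")
})

test_that("averaging more simulations per evaluation reduces cost variance", {
  p <- preset_params("R1881")
  cfg <- small_scenario(c(tumor = 50), ticks = 12, width = 40, height = 40)
  ds <- generate_simulated_dataset(p, cfg, n_bio = 1, n_tech = 4, seed = 17)
  costs <- function(nrep) {
    spec <- fit_spec(list(TUpprol = c(0, 0.5)), p, cfg, n_sim_rep = nrep)
    vapply(1:12, function(s)
      evaluate_candidate(c(TUpprol = 0.2), spec, ds, seed = 100 + s),
      numeric(1))
  }
  expect_lt(stats::var(costs(8)), stats::var(costs(1)))
})

test_that("parameters outside free_params are never touched by fitting", {
  p <- preset_params("R1881")
  cfg <- small_scenario(c(tumor = 40), ticks = 10, width = 30, height = 30)
  ds <- generate_simulated_dataset(p, cfg, n_bio = 1, n_tech = 2, seed = 19)
  spec <- fit_spec(list(TUpprol = c(0, 0.5)), p, cfg, n_sim_rep = 1)
  fit <- run_pso(spec, ds, pso_config(swarm_size = 5, iterations = 5,
                                      restarts = 2, seed = 23))
  expect_named(fit$median, "TUpprol")
  refit_params <- pcabm:::.apply_candidate(fit$median, spec)
  frozen <- setdiff(names(p), "TUpprol")
  expect_identical(unclass(refit_params)[frozen], unclass(p)[frozen])
  expect_gte(fit$cost_at_median, 0)
})

test_that("staged fitting errors name the missing stage", {
  expect_error(staged_fit(list(), stages = "tumor_mono"),
               "tumor_mono")
  # stage 1 needs hormone-proficient rows before anything is fitted
  d <- generate_logistic_dataset(noise_sd = 0, seed = 1, n_bio = 1,
                                 n_tech = 1, conditions = "DMSO")
  expect_error(staged_fit(list(tumor_mono = d), stages = "tumor_mono"),
               "R1881")
  expect_error(staged_fit(list(tumor_mono = d), stages = "nonsense"),
               "unknown stage")
})
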