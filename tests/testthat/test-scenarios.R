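test_that("catalog scenarios encode the documented compositions", {
  s <- build_scenario("LNCaP_F_M1_411_R1881")
  expect_equal(unname(s$counts[c("tumor", "fibroblast", "M1")]),
               c(1000L, 250L, 250L))
  expect_equal(s$condition, "R1881")
  expect_equal(s$ticks, 42L)

  s <- build_scenario("M1_TU_F_111_R1881")
  expect_equal(unname(s$counts[c("tumor", "fibroblast", "M1")]),
               c(1000L, 1000L, 1000L))

  s <- build_scenario("CRPC_DMSO")
  expect_equal(s$resistant_fraction, 1 / 101)
  expect_equal(s$condition, "DMSO")

  s <- build_scenario("LNCaPabl_mono_DMSO")
  expect_equal(s$resistant_fraction, 1)

  expect_error(build_scenario("no_such_thing_DMSO"), "catalog")
  expect_error(build_scenario("LNCaP_mono"), "catalog")  # missing condition
})

test_that("every catalog scenario round-trips through serialization", {
  path <- withr::local_tempfile(fileext = ".json")
  for (name in scenario_catalog()) {
    cfg <- build_scenario(name)
    write_scenario(cfg, path)
    expect_equal(read_scenario(path), cfg, info = name)
  }
})

test_that("relative growth normalizes at the 24-h tick", {
  cfg <- small_scenario(c(tumor = 25), ticks = 10)
  traj <- run_simulation(cfg, null_params(), seed = 1)
  g <- relative_growth(traj)      # default t0 = 24 h
  expect_true(all(g$value == 1))
  expect_equal(g$time_h, seq(0, 40, by = 4))
  expect_equal(g$value[g$time_h == 24], 1)
})

test_that("relative growth is scale invariant and errors on zero baseline", {
  cfg <- small_scenario(c(tumor = 40, fibroblast = 20), ticks = 10)
  p <- pcabm_params(TUpprol = 0.2, TUpmax = 6, Fpprol = 0.1)
  traj <- run_simulation(cfg, p, seed = 3)
  g1 <- relative_growth(traj, "tumor_total")
  # doubling all counts leaves the relative curve unchanged
  traj2 <- traj
  traj2$counts$tumor <- traj$counts$tumor * 7L
  traj2$counts$tumor_resistant <- traj$counts$tumor_resistant * 7L
  expect_equal(relative_growth(traj2, "tumor_total")$value, g1$value)
  # no M2 seeded -> zero baseline is an explicit error
  expect_error(relative_growth(traj, "M2"), "zero")
  expect_error(relative_growth(traj, "tumor_total", t0_hours = 23),
               "does not correspond")
})

test_that("growth doubling shows up as a final relative value of 2", {
  traj <- structure(list(
    counts = data.frame(tick = 0:6, time_h = seq(0, 24, 4),
                        tumor = c(100L, 100L, 100L, 100L, 100L, 150L, 200L),
                        tumor_resistant = 0L, fibroblast = 0L,
                        M1 = 0L, M2 = 0L),
    config = list(name = "manual", condition = "R1881")),
    class = "pcabm_trajectory")
  g <- relative_growth(traj, t0_hours = 0)
  expect_equal(g$value[length(g$value)], 2)
})

test_that("fold changes divide correctly and report integer folds", {
  expect_equal(fold_change(0.1116, 0.005), 22.32)
  expect_equal(round(fold_change(0.1116, 0.005)), 22)
  expect_equal(fold_change(0.1144, 0.0389), 2.940874, tolerance = 1e-6)
  expect_equal(round(fold_change(0.1144, 0.0389)), 3)
  expect_equal(fold_change(0.37, 0.37), 1)
  expect_error(fold_change(1, 0), "positive")
  expect_error(fold_change(1, -2), "positive")
})

test_that("clustering index flags a contiguous blob against the uniform null", {
  snap <- matrix(0L, 40, 40)
  snap[15:20, 15:20] <- 2L       # 36 resistant cells in one blob
  set.seed(21)
  cl <- nearest_neighbor_clustering(snap, "tumor_resistant", n_null = 999)
  expect_lt(cl$index, 1)
  expect_lte(cl$p_value, 0.05)   # below the 5th percentile of the null
})

test_that("uniformly scattered agents give index near 1 on average", {
  set.seed(22)
  idx <- replicate(40, {
    snap <- matrix(0L, 30, 30)
    snap[sample.int(900, 25)] <- 1L
    nearest_neighbor_clustering(snap, "tumor", n_null = 59)$index
  })
  expect_equal(mean(idx), 1, tolerance = 0.05)
})

test_that("fewer than two agents is an explicit undefined", {
  snap <- matrix(0L, 10, 10)
  snap[5, 5] <- 2L
  expect_error(nearest_neighbor_clustering(snap, "tumor_resistant"),
               "undefined")
  expect_error(nearest_neighbor_clustering(snap, "tumor"), "undefined")
})
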