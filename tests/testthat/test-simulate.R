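test_that("effective tumor proliferation combines preset and M2 bonus", {
  r <- preset_params("R1881")
  d <- preset_params("DMSO")
  with_m2 <- make_state(c("tumor", "M2"), row = c(0, 5), col = c(0, 5))
  no_m2 <- make_state("tumor", row = 0, col = 0)
  expect_equal(effective_tumor_pprol(r, with_m2), 0.1144 + 0.0995)
  expect_equal(effective_tumor_pprol(r, no_m2), 0.1144)
  expect_equal(effective_tumor_pprol(d, with_m2), 0.0389)  # M2TUadd = 0
  expect_equal(effective_tumor_pprol(d, with_m2, is_resistant = TRUE),
               d$TUpprolres)
  # clamped to 1
  big <- pcabm_params(TUpprol = 0.95, M2TUadd = 0.05)
  expect_equal(effective_tumor_pprol(big, with_m2), 1)
})

test_that("forced tumor branches: death, division, capacity exhaustion", {
  set.seed(1)
  # forced death vacates the position
  st <- make_state("tumor", row = 4, col = 4)
  out <- resolve_agent_action(st, 1, pcabm_params(TUpdeath = 1))
  expect_false(out$state$alive[1])
  expect_equal(sum(as_snapshot_matrix(out$state)), 0)
  expect_equal(out$events$event, "death")

  # forced division: daughter adjacent, both capacities decremented
  st <- make_state("tumor", row = 4, col = 4, divs = 4)
  out <- resolve_agent_action(st, 1, pcabm_params(TUpprol = 1))
  expect_equal(sum(out$state$alive), 2)
  expect_equal(out$state$divs, c(3L, 3L))
  d <- max(abs(out$state$row[2] - 4), abs(out$state$col[2] - 4))
  expect_equal(d, 1)
  expect_equal(out$events$event, "birth")

  # exhausted capacity: proliferation intent degrades to idle
  st <- make_state("tumor", row = 4, col = 4, divs = 0)
  out <- resolve_agent_action(st, 1, pcabm_params(TUpprol = 1))
  expect_equal(sum(out$state$alive), 1)
  expect_equal(nrow(out$events), 0)
})

test_that("resistant daughters arise with TUpres and full resistant capacity", {
  set.seed(2)
  p <- pcabm_params(TUpprol = 1, TUpres = 1, TUpmaxres = 50)
  st <- make_state("tumor", row = 4, col = 4, divs = 4)
  out <- resolve_agent_action(st, 1, p)
  expect_equal(out$state$kind[2], 2L)
  expect_equal(out$state$divs[2], 50L)
  expect_equal(out$state$divs[1], 3L)   # parent still decremented
})

test_that("forced fibroblast branches: death, division, directed migration", {
  set.seed(3)
  st <- make_state("fibroblast", row = 4, col = 4)
  out <- resolve_agent_action(st, 1, pcabm_params(Fpdeath = 1))
  expect_false(out$state$alive[1])

  st <- make_state("fibroblast", row = 4, col = 4, divs = -1)
  out <- resolve_agent_action(st, 1, pcabm_params(Fpprol = 1))
  expect_equal(sum(out$state$alive), 2)
  expect_equal(out$state$kind[2], 3L)
  expect_equal(out$state$divs[2], -1L)  # unlimited capacity inherited

  # directed migration moves to the free neighbor nearest the tumor cell
  st <- make_state(c("fibroblast", "tumor"), row = c(4, 4), col = c(4, 7))
  out <- resolve_agent_action(st, 1, pcabm_params(Fpmig = 1, Frwalk = 0))
  expect_equal(c(out$state$row[1], out$state$col[1]), c(4L, 5L))
})

test_that("tumor directed migration approaches the nearest fibroblast", {
  set.seed(4)
  st <- make_state(c("tumor", "fibroblast"), row = c(4, 4), col = c(4, 0))
  out <- resolve_agent_action(st, 1,
                              pcabm_params(TUpmig = 1, TUrwalk = 0))
  expect_equal(c(out$state$row[1], out$state$col[1]), c(4L, 3L))
})

test_that("macrophage kill is local, decrements capacity, sets engagement", {
  set.seed(5)
  p <- pcabm_params(M1pkill = 1)
  st <- make_state(c("M1", "tumor"), row = c(4, 4), col = c(4, 5),
                   kills = c(11, 0))
  out <- resolve_agent_action(st, 1, p)
  expect_false(out$state$alive[2])
  expect_equal(out$state$kills[1], 10L)
  expect_equal(out$state$engage[1], 60L)
  ev <- out$events
  expect_equal(ev$event, "kill")
  expect_equal(ev$killer_id, 1L)
  expect_lte(max(abs(ev$row - ev$killer_row), abs(ev$col - ev$killer_col)), 1)
})

test_that("exhausted macrophages never kill", {
  set.seed(6)
  p <- pcabm_params(M1pkill = 1)
  st <- make_state(c("M1", "tumor"), row = c(4, 4), col = c(4, 5),
                   kills = c(0, 0))
  out <- resolve_agent_action(st, 1, p)
  expect_true(out$state$alive[2])
  expect_equal(nrow(out$events), 0)
})

test_that("engagement paralyzes a macrophage for ceiling(duration/speed) ticks", {
  p <- pcabm_params(M1pkill = 1, M1speed = 40, M1engagementDuration = 60)
  st <- make_state(c("M1", "tumor"), row = c(4, 4), col = c(4, 5),
                   kills = c(11, 0), engage = c(60, 0))
  set.seed(7)
  out1 <- resolve_agent_action(st, 1, p)
  expect_equal(out1$state$engage[1], 20L)
  expect_true(out1$state$alive[2])          # no action while engaged
  out2 <- resolve_agent_action(out1$state, 1, p)
  expect_equal(out2$state$engage[1], 0L)
  expect_true(out2$state$alive[2])
  out3 <- resolve_agent_action(out2$state, 1, p)  # free again: kills
  expect_false(out3$state$alive[2])
})

test_that("macrophage migration stops when a tumor cell becomes adjacent", {
  set.seed(8)
  p <- pcabm_params(M1pmig = 1, M1rwalk = 0, M1speed = 40)
  st <- make_state(c("M1", "tumor"), row = c(0, 0), col = c(0, 8),
                   width = 12, height = 12)
  out <- resolve_agent_action(st, 1, p)
  cheb <- max(abs(out$state$row[1] - 0), abs(out$state$col[1] - 8))
  expect_equal(cheb, 1)
})

test_that("null dynamics leave counts unchanged and advance the tick", {
  cfg <- small_scenario(c(tumor = 20, fibroblast = 10, M1 = 5, M2 = 5))
  st <- initialize_state(cfg, null_params(), seed = 9)
  st2 <- advance_one_tick(st, null_params())
  expect_equal(st2$tick, 1L)
  expect_equal(live_counts(st2), live_counts(st))
  expect_equal(as_snapshot_matrix(st2), as_snapshot_matrix(st))
})

test_that("newborn agents idle on their birth tick", {
  p <- pcabm_params(TUpprol = 1, TUpmax = 10)
  st <- make_state("tumor", row = 4, col = 4, divs = 10,
                   width = 21, height = 21)
  set.seed(10)
  st <- advance_one_tick(st, p)
  expect_equal(sum(st$alive), 2)     # doubling, not a same-tick chain
  st <- advance_one_tick(st, p)
  expect_equal(sum(st$alive), 4)
})

test_that("per-tick count changes equal births minus deaths minus kills", {
  set.seed(11)
  cfg <- small_scenario(c(tumor = 60, fibroblast = 30, M1 = 20, M2 = 10),
                        ticks = 20)
  p <- pcabm_params(TUpprol = 0.25, TUpdeath = 0.03, TUpmig = 0.2,
                    TUpres = 0.05, TUpprolres = 0.2, TUpmaxres = 8,
                    Fpprol = 0.15, Fpdeath = 0.02, Fpmig = 0.3,
                    M1pkill = 0.4, M1pmig = 0.3, M2pkill = 0.2,
                    M2pmig = 0.3, Mpdeath = 0.02)
  traj <- run_simulation(cfg, p, seed = 12, record_events = TRUE)
  ev <- traj$events
  cts <- traj$counts
  kinds <- c("tumor", "tumor_resistant", "fibroblast", "M1", "M2")
  for (t in seq_len(nrow(cts) - 1)) {
    et <- ev[ev$tick == t, ]
    for (k in kinds) {
      delta <- cts[[k]][t + 1] - cts[[k]][t]
      expected <- sum(et$event == "birth" & et$kind == k) -
        sum(et$event == "death" & et$kind == k) -
        sum(et$event == "kill" & et$kind == k)
      expect_equal(delta, expected,
                   info = sprintf("tick %d kind %s", t, k))
    }
  }
  # kills only ever remove tumor kinds
  expect_true(all(ev$kind[ev$event == "kill"] %in%
                    c("tumor", "tumor_resistant")))
})

test_that("identical seeds reproduce whole trajectories exactly", {
  cfg <- small_scenario(c(tumor = 40, fibroblast = 15, M1 = 10), ticks = 12)
  p <- preset_params("R1881")
  a <- run_simulation(cfg, p, seed = 99, snapshot_ticks = c(0, 6, 12))
  b <- run_simulation(cfg, p, seed = 99, snapshot_ticks = c(0, 6, 12))
  expect_identical(a$counts, b$counts)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$final_state, b$final_state)
  c <- run_simulation(cfg, p, seed = 100)
  expect_false(identical(a$counts, c$counts))
})

test_that("constant-count run under frozen dynamics, snapshots on request", {
  cfg <- small_scenario(c(tumor = 25), ticks = 8)
  traj <- run_simulation(cfg, null_params(), seed = 5,
                         snapshot_ticks = c(0, 8))
  expect_true(all(traj$counts$tumor == 25))
  expect_equal(names(traj$snapshots), c("0", "8"))
  expect_equal(traj$snapshots[["0"]], traj$snapshots[["8"]])
  expect_error(scenario_config("bad", c(tumor = 10), ticks = 0), "ticks")
})

test_that("low-density growth follows the branching-process mean", {
  # sparse monoculture: crowding negligible, so E[N_t] = N0 (1 + p - d)^t
  p <- preset_params("R1881")
  cfg <- small_scenario(c(tumor = 25), ticks = 8, width = 50, height = 50)
  runs <- vapply(1:60, function(s)
    run_simulation(cfg, p, seed = s)$counts$tumor, integer(9))
  m <- rowMeans(runs)
  se <- apply(runs, 1, stats::sd) / sqrt(ncol(runs))
  expected <- 25 * (1 + p$TUpprol - p$TUpdeath)^(0:8)
  z <- (m[-1] - expected[-1]) / se[-1]
  expect_true(all(abs(z) < 3))
})
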