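test_that("valve flow is a regularized ideal diode", {
  expect_equal(valve_flow(0, 0.01), 0)
  expect_equal(valve_flow(10, 0.01), 1000, tolerance = 1e-6)
  expect_lt(abs(valve_flow(-10, 0.01)), 1e-6 * (10 / 0.01))
  # continuity across zero
  dp <- seq(-0.2, 0.2, by = 1e-3)
  q <- valve_flow(dp, 0.01)
  expect_true(all(abs(diff(q)) < 5))
  expect_error(valve_flow(1, 0), "positive")
})

test_that("assembled system has the declared state dimension", {
  sys <- assemble_system(cv_config("idealized_male", default_shared_params()))
  expect_equal(sys$n_state, 19L)   # 14 compartment volumes + 5 inertial flows
  expect_length(sys$y0, 19L)
  expect_named(sys$y0)
})

test_that("removing an arterial segment is a configuration error", {
  cfg <- cv_config("idealized_male", default_shared_params())
  cfg$vessels <- cfg$vessels[cfg$vessels$name != "carotid_artery", ]
  expect_error(assemble_system(cfg), "carotid")
})

test_that("the continuous formulation conserves volume exactly", {
  sys <- assemble_system(cv_config("idealized_male", default_shared_params()))
  set.seed(1)
  for (i in 1:10) {
    y <- sys$y0 * runif(19, 0.6, 1.4)
    d <- sys$rhs(runif(1, 0, 0.8), y, NULL)[[1]]
    expect_lt(abs(sum(d[1:14])), 1e-10 * max(abs(d[1:14])))
  }
})

test_that("simulation conserves volume and reaches a periodic regime", {
  sim <- sim_version("idealized_male")
  expect_lt(sim$volume_drift, 0.001)
  expect_lt(sim$periodicity, 0.005)
  expect_true(sim$periodic)
})

test_that("last-cycle LV volume has one global maximum and one minimum", {
  sim <- sim_version("idealized_male")
  V <- sim$V[sim$last_cycle, "lv"]
  # smooth single-beat morphology: the volume crosses its mid-range
  # level exactly twice over the cycle
  mid <- (max(V) + min(V)) / 2
  crossings <- sum(abs(diff(sign(V - mid))) > 0)
  expect_equal(crossings, 2)
  expect_true(all(V > 0))
})

test_that("repeated simulation is bitwise identical (no hidden randomness)", {
  cfg <- cv_config("idealized_male", shared_cal())
  s1 <- simulate_circuit(cfg, n_cycles = 2)
  s2 <- simulate_circuit(cfg, n_cycles = 2)
  expect_identical(s1$V, s2$V)
  expect_identical(s1$P, s2$P)
})

test_that("valve flows are forward on average over the last cycle", {
  sim <- sim_version("idealized_male")
  for (v in colnames(sim$Qv))
    expect_gt(mean(sim$Qv[sim$last_cycle, v]), 0)
})

test_that("without activation the system relaxes toward a flow-free state", {
  sh <- default_shared_params()
  sh$U_L <- 1e-9; sh$U_R <- 1e-9
  cfg <- cv_config("idealized_male", sh)
  cfg$ventricles$left$E_S <- 1e-9
  cfg$ventricles$right$E_S <- 1e-9
  sim <- suppressWarnings(simulate_circuit(cfg, n_cycles = 30))
  q_late <- sim$Qv[sim$t > 29 * sim$Tc, ]
  q_early <- sim$Qv[sim$t < sim$Tc, ]
  expect_lt(max(abs(q_late)), 0.05 * max(abs(q_early)))
})

test_that("ventricular pressure never falls below its passive component", {
  sim <- sim_version("idealized_male")
  cfg <- sim$config
  passive <- cfg$ventricles$left$E_D *
    (sim$V[, "lv"] - cfg$ventricles$left$V0)
  expect_true(all(sim$P[, "lv"] - passive > -1e-6))
})

test_that("tidy waveform export has the declared columns", {
  sim <- sim_version("idealized_male")
  td <- waveforms_tidy(sim)
  expect_named(td, c("time_s", "compartment", "pressure_mmHg", "volume_mL",
                     "flow_mL_s"))
  expect_setequal(unique(td$compartment), colnames(sim$V))
})
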