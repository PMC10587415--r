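test_that("EDV/ESV are the waveform extrema", {
  Tc <- 0.8
  t <- seq(0, Tc, by = 1e-3)
  V <- 100 + 20 * sin(2 * pi * t / Tc)
  vv <- ventricular_volumes(V)
  expect_equal(unname(vv), c(120, 80), tolerance = 1e-5)
  expect_error(ventricular_volumes(V[1:5]), "10")
})

test_that("stroke metrics follow their defining formulas", {
  sm <- stroke_metrics(120, 80, 60)
  expect_equal(unname(sm), c(40, 2.4, 1 / 3))
  # female-preset arithmetic: SV and EF from the tabulated volumes
  smf <- stroke_metrics(137.2, 54.9, 78.75)
  expect_equal(smf[["SV"]], 82.3)
  expect_equal(100 * smf[["EF"]], 60.0, tolerance = 0.05)
  expect_error(stroke_metrics(80, 90, 60), "EDV")
})

test_that("EF is invariant under joint scaling of EDV and ESV", {
  for (k in c(0.3, 1, 2.7)) {
    expect_equal(stroke_metrics(137.2 * k, 54.9 * k, 70)[["EF"]],
                 stroke_metrics(137.2, 54.9, 70)[["EF"]])
  }
})

test_that("ESP is the pressure maximum", {
  expect_equal(esp_from_pressure(rep(100, 50)), 100)
  t <- seq(0, 1, by = 1e-3)
  expect_equal(esp_from_pressure(90 + 47.4 * sin(pi * t)), 137.4)
})

test_that("coupling identities hold on random positive inputs", {
  set.seed(42)
  for (i in 1:25) {
    ESP <- runif(1, 20, 200); SV <- runif(1, 30, 120); ESV <- runif(1, 20, 110)
    left <- elastance_indexes(ESP, SV, ESV, "left")
    right <- elastance_indexes(ESP, SV, ESV, "right")
    # VAC = Ea/Ees = ESV/SV regardless of ESP; PAC is its reciprocal
    expect_equal(left[["coupling"]], ESV / SV)
    expect_equal(right[["coupling"]], SV / ESV)
    expect_equal(left[["coupling"]] * right[["coupling"]], 1)
  }
  # tabulated female LV / male RV combinations
  expect_equal(elastance_indexes(139.6, 82.3, 54.9, "left")[["coupling"]],
               0.67, tolerance = 0.005)
  expect_equal(elastance_indexes(39.6, 97.1, 70.6, "right")[["coupling"]],
               1.38, tolerance = 0.005)
  expect_error(elastance_indexes(100, 0, 50, "left"), "positive")
})

test_that("percent difference uses the (male - female)/male convention", {
  expect_equal(percent_difference(155.4, 137.2), 11.7, tolerance = 0.01)
  expect_equal(percent_difference(89.3, 82.3), 7.8, tolerance = 0.05)
  expect_equal(percent_difference(3.2, 3.2), 0)
  expect_equal(percent_difference(100, 110), -10)
  expect_error(percent_difference(0, 1), "non-zero")
})

test_that("metrics are invariant to a phase rotation of the cycle", {
  sim <- sim_version("idealized_male")
  lc <- which(sim$last_cycle)
  V <- sim$V[lc, "lv"]; P <- sim$P[lc, "lv"]
  rot <- function(x, k) c(x[-seq_len(k)], x[seq_len(k)])
  for (k in c(17, 301)) {
    expect_equal(ventricular_volumes(rot(V, k)), ventricular_volumes(V))
    expect_equal(esp_from_pressure(rot(P, k)), esp_from_pressure(P))
  }
})
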