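test_that("potassium Nernst potential matches closed form and is monotone", {
  expect_equal(nernst_potassium(5.4, 5.4), 0)
  # independently computed (arbitrary-precision) with TP06 constants at 310 K
  expect_equal(nernst_potassium(5.4, 138), -86.57541763245666, tolerance = 1e-12)
  expect_equal(nernst_potassium(10, 138), -70.11476858206696, tolerance = 1e-12)
  expect_gt(nernst_potassium(10, 138), nernst_potassium(5.4, 138))
  expect_error(nernst_potassium(0, 138), "positive")
  expect_error(nernst_potassium(5.4, -1), "positive")
})

test_that("I_KATP vanishes at zero open fraction and is linear in f and g0", {
  V <- seq(-90, 40, by = 10)
  expect_equal(i_katp(V, 10, 140, f_atp = 0), rep(0, length(V)))
  base <- i_katp(V, 5.4, 138, f_atp = 0.02, g0 = 100)
  expect_equal(i_katp(V, 5.4, 138, f_atp = 0.04, g0 = 100), 2 * base)
  expect_equal(i_katp(V, 5.4, 138, f_atp = 0.02, g0 = 200), 2 * base)
  expect_error(i_katp(-40, 5.4, 138, f_atp = -0.1), "non-negative")
})

test_that("I_KATP matches an independent transcription of its formula", {
  # frozen from a symbol-by-symbol arbitrary-precision evaluation
  expect_equal(i_katp(-40, 5.4, 138, f_atp = 0.05, g0 = 1),
               0.056403668898559, tolerance = 1e-12)
  # outward above E_K, zero at E_K, inward below
  EK <- nernst_potassium(5.4, 138)
  expect_equal(i_katp(EK, 5.4, 138, 0.05), 0)
  expect_gt(i_katp(EK + 10, 5.4, 138, 0.05), 0)
  expect_lt(i_katp(EK - 10, 5.4, 138, 0.05), 0)
  # conductance rises with Ko at fixed driving force
  dr <- 30
  g_low <- i_katp(nernst_potassium(4, 138) + dr, 4, 138, 0.05) / dr
  g_high <- i_katp(nernst_potassium(10, 138) + dr, 10, 138, 0.05) / dr
  expect_gt(g_high, g_low)
})

test_that("applying ischemia scales GNa/GCaL and preserves everything else", {
  base <- tp06_params(1.8)
  same <- apply_ischemia(base, ischemia(Ko = 5.4, acidosis = 1, f_atp = 0))
  expect_equal(same$GNa, base$GNa)
  expect_equal(same$GCaL, base$GCaL)
  expect_equal(same$GKr, base$GKr)
  acid <- apply_ischemia(base, ischemia(acidosis = 0.2))
  expect_equal(acid$GNa, 0.2 * base$GNa)
  expect_equal(acid$GCaL, 0.2 * base$GCaL)
  expect_equal(acid$GK1, base$GK1)
  expect_warning(i13 <- ischemia(Ko = 13), "outside")
  expect_equal(i13$Ko, 13)  # warned but retained
  expect_warning(ischemia(acidosis = 0.1), "outside")
})

test_that("total ionic current is near zero at rest and I_KATP adds outward", {
  # settle to the resting steady state first
  s <- step_cell(cell_state(), 0, dt = 0.02, nsteps = 50000L)  # 1 s quiet
  expect_lt(abs(total_ionic_current(s)), 0.01)
  itot0 <- total_ionic_current(s, isch = ischemia())
  itot1 <- total_ionic_current(s, isch = ischemia(f_atp = 0.05))
  expect_gt(itot1, itot0)  # V > E_K at rest, so the added term is outward
  bad <- unclass(cell_state()); bad[1] <- NaN
  expect_error(total_ionic_current(bad), "NaN")
})

test_that("current breakdown sums to the total", {
  cur <- total_ionic_current(cell_state(), breakdown = TRUE)
  parts <- unlist(cur[setdiff(names(cur), c("total", "EK"))])
  expect_equal(sum(parts), cur$total, tolerance = 1e-12)
})

test_that("quiescent cell stays at rest and step errors are O(dt^2) locally", {
  s0 <- cell_state()
  s1 <- step_cell(s0, 0, dt = 0.02, nsteps = 50000L)  # 1000 ms
  expect_lt(abs(s1["V"] - s0["V"]), 0.5)
  # Richardson: bring the cell mid-upstroke, then compare one dt step with
  # two dt/2 steps; halving dt again shrinks the difference ~4x
  sm <- cell_state()
  sm <- step_cell(sm, -52, dt = 0.02, nsteps = 40L)   # 0.8 ms of stimulus
  d_of <- function(dt) {
    a <- step_cell(sm, 0, dt = dt, nsteps = 1L)
    b <- step_cell(sm, 0, dt = dt / 2, nsteps = 2L)
    abs(a["V"] - b["V"])
  }
  d1 <- d_of(0.02); d2 <- d_of(0.01)
  expect_gt(d1 / d2, 2.5)
  expect_lt(d1 / d2, 6)
})

test_that("a -52 pA/pF 1 ms stimulus elicits an action potential; a weak one does not", {
  tr <- run_paced_cell(n_beats = 1, bcl = 600, tail_ms = 500)
  expect_gt(max(tr$V), 0)
  expect_false(tr$no_ap)
  expect_warning(tr2 <- run_paced_cell(n_beats = 1, bcl = 600, stim_amp = -5,
                                       tail_ms = 500), "no action potential")
  expect_lt(max(tr2$V), -20)
  expect_true(tr2$no_ap)
})

test_that("pacing yields one AP per stimulus and ischemia shortens APD", {
  tr <- run_paced_cell(n_beats = 10)
  expect_length(measure_apd(tr), 10)
  apd0 <- steady_state_apd(n_beats = 8)
  expect_lt(steady_state_apd(isch = ischemia(Ko = 9), n_beats = 8), apd0)
  expect_lt(steady_state_apd(isch = ischemia(f_atp = 0.02), n_beats = 8),
            apd0)
})

test_that("APD measurement recovers synthetic ground truths", {
  # square pulse of 300 ms
  t <- seq(0, 600, by = 0.5)
  V <- ifelse(t >= 100 & t < 400, 20, -86)
  expect_equal(measure_apd(list(t = t, V = V)), 300, tolerance = 0.6)
  # exponential repolarization: V = -86 + 106 * exp(-(t - t0)/tau) after an
  # instantaneous upstroke; APD90 has the closed form tau * log(10.6/1.06)
  # ... crossing V_rest + 0.1*(V_peak - V_rest) = -86 + 10.6
  tau <- 120
  V2 <- ifelse(t < 100, -86, -86 + 106 * exp(-(t - 100) / tau))
  expect_equal(measure_apd(list(t = t, V = V2)), tau * log(106 / 10.6),
               tolerance = 1)
  # two identical APs give two equal APDs
  V3 <- ifelse((t >= 50 & t < 250) | (t >= 350 & t < 550), 20, -86)
  a <- measure_apd(list(t = t, V = V3))
  expect_length(a, 2)
  expect_equal(a[1], a[2], tolerance = 0.51)
  # no AP -> empty
  expect_length(measure_apd(list(t = t, V = rep(-86, length(t)))), 0)
})

test_that("g0 calibration halves the APD and behaves monotonically", {
  p <- tp06_params(1.8)
  apd0 <- steady_state_apd(p, n_beats = 8)
  # g0 = 0 leaves the APD unchanged (ratio 1)
  p0 <- p; p0$g0katp <- 0
  expect_equal(steady_state_apd(p0, ischemia(f_atp = 0.05), n_beats = 8),
               apd0, tolerance = 0.01 * apd0)
  # the shipped default g0 achieves the halving within 1%
  ratio <- steady_state_apd(p, ischemia(f_atp = 0.05), n_beats = 8) / apd0
  expect_equal(ratio, 0.5, tolerance = 0.01)
  # doubling g0 overshoots (ratio below 0.5)
  p2 <- p; p2$g0katp <- 2 * p$g0katp
  expect_lt(steady_state_apd(p2, ischemia(f_atp = 0.05), n_beats = 8) / apd0,
            0.5)
})

test_that("look-up tables reproduce direct evaluation", {
  expect_lt(lut_discrepancy(cell_state()), 1e-6)
  # also from a depolarized state
  s <- step_cell(cell_state(), -52, dt = 0.02, nsteps = 60L)
  expect_lt(lut_discrepancy(s), 1e-6)
})
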