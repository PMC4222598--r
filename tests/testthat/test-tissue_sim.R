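test_that("diffusion term: nullity, conservation, and stencil weights", {
  # constant field -> exactly zero
  expect_equal(diffusion_term(matrix(-85, 30, 20)), matrix(0, 30, 20))
  # discrete conservation under no-flux: sum of the term is zero
  set.seed(42)
  V <- matrix(rnorm(30 * 20, -60, 25), 30, 20)
  expect_equal(sum(diffusion_term(V)), 0, tolerance = 1e-9)
  V1 <- rnorm(50, -60, 25)
  expect_equal(sum(diffusion_term(V1)), 0, tolerance = 1e-10)
  # single-node delta reproduces hand-computed 5-point weights
  D <- 1.54; dx <- 0.025
  Vd <- matrix(0, 11, 11); Vd[6, 6] <- 1
  lap <- diffusion_term(Vd, D, dx)
  w <- (D / 1000) / dx^2
  expect_equal(lap[6, 6], -4 * w)
  expect_equal(lap[5, 6], w); expect_equal(lap[7, 6], w)
  expect_equal(lap[6, 5], w); expect_equal(lap[6, 7], w)
  expect_equal(lap[5, 5], 0)
  # 1D: 3-point weights
  V1d <- rep(0, 11); V1d[6] <- 1
  lap1 <- diffusion_term(V1d, D, dx)
  expect_equal(lap1[6], -2 * w)
  expect_equal(lap1[5], w)
})

test_that("D = 0 decouples tissue nodes to the single-cell trajectory", {
  g <- tissue_grid(5, 1, D = 0)
  rec <- run_protocol(g, stimulus(50, x = c(0, Inf)), duration = 400,
                      probes = c(0.05), probe_dt = 0.2)
  tr <- run_paced_cell(n_beats = 1, bcl = 400, tail_ms = 350,
                       record_dt = 0.2)
  n <- min(length(rec$t), length(tr$t))
  expect_equal(rec$V[seq_len(n), 1], tr$V[seq_len(n)], tolerance = 1e-12)
})

test_that("uniform unstimulated sheet stays uniform and quiescent", {
  g <- tissue_grid(30, 30)
  rec <- run_protocol(g, list(), duration = 200, snapshot_dt = 100)
  expect_lt(diff(range(rec$snaps[, ncol(rec$snaps)])), 1e-9)
  expect_lt(max(rec$snaps), -80)
})

test_that("identical configurations reproduce recordings bit-identically", {
  run1 <- run_protocol(tissue_grid(60, 1), stimulus(5, x = c(0, 0.1)),
                       duration = 150, probes = c(0.5, 1.0), probe_dt = 1)
  run2 <- run_protocol(tissue_grid(60, 1), stimulus(5, x = c(0, 0.1)),
                       duration = 150, probes = c(0.5, 1.0), probe_dt = 1)
  expect_identical(run1$V, run2$V)
})

test_that("a plane wave on a sheet has straight isochrones", {
  g <- tissue_grid(80, 20)
  rec <- run_protocol(g, stimulus(5, x = c(0, 0.1)), duration = 40,
                      snapshot_dt = 40)
  V <- matrix(rec$snaps[, ncol(rec$snaps)], 80, 20)
  # transverse spread at mid-propagation is tiny at every x
  expect_lt(max(apply(V, 1, function(row) diff(range(row)))), 1)
})

test_that("baseline plane-wave conduction velocity is in the expected range", {
  cv <- measure_cv(cached_cv_recording(), 2, 4)
  expect_gt(cv, 65); expect_lt(cv, 77)
  # pseudo-1D strip gives the same plane-wave CV as the cable
  g3 <- tissue_grid(200, 3)
  stims <- lapply(5 + 1000 * (0:1), function(on) stimulus(on, x = c(0, 0.1)))
  rec3 <- run_protocol(g3, stims, duration = 1400, probes = c(2, 4),
                       probe_dt = 0.25)
  expect_equal(measure_cv(rec3, 2, 4), cv, tolerance = 0.01 * cv)
})

test_that("CV scales as the square root of the diffusion coefficient", {
  # measured at the finer space step where discretization slowing is small
  cvf <- function(D) {
    g <- tissue_grid(400, 1, dx = 0.0125, D = D)
    stims <- lapply(5 + 1000 * (0:1), function(on) stimulus(on, x = c(0, 0.1)))
    rec <- run_protocol(g, stims, duration = 1400, probes = c(2, 4),
                        probe_dt = 0.25)
    measure_cv(rec, 2, 4)
  }
  expect_equal(cvf(3.08) / cvf(1.54), sqrt(2), tolerance = 0.03)
})

test_that("severe hyperkalemia slows conduction; inexcitable tissue signals block", {
  cv10 <- measure_cv(cached_cv_recording(ischemia(Ko = 10)), 2, 4)
  cv0 <- measure_cv(cached_cv_recording(), 2, 4)
  expect_lt(cv10, cv0)
  # far outside the excitable range the wave never reaches the probes
  g <- tissue_grid(120, 1,
                   isch = suppressWarnings(ischemia(Ko = 13,
                                                    acidosis = 0.2)))
  rec <- suppressWarnings(
    run_protocol(g, stimulus(5, x = c(0, 0.1)), duration = 300,
                 probes = c(1, 2.5), probe_dt = 0.5))
  cv <- measure_cv(rec, 1, 2.5)
  expect_true(is.na(cv))
  expect_true(isTRUE(attr(cv, "conduction_block")))
})

test_that("cross-field S1S2 initiates a single spiral; premature S2 does not", {
  rec <- cached_spiral()
  ph <- phase_map(rec)
  ps <- detect_phase_singularities(ph, snapshot = 1)
  expect_equal(nrow(ps), 1L)
  # S2 inside the S1 refractory period leaves no re-entry
  g <- tissue_grid(120, 120, D = 0.25, params = tp06_params(1.1))
  rec0 <- init_spiral_crossfield(g, s2_delay = 80, settle_ms = 200,
                                 snapshot_dt = 10)
  expect_equal(nrow(detect_phase_singularities(phase_map(rec0))), 0L)
})

test_that("stability guard names the offending node", {
  g <- tissue_grid(30, 1)
  expect_error(run_protocol(g, stimulus(5, x = c(0, Inf), amplitude = -5000),
                            duration = 50), "instability")
})

test_that("diffusion stability precondition is enforced", {
  g <- tissue_grid(30, 30, D = 1.54)
  expect_error(run_protocol(g, list(), duration = 10, dt = 0.02 * 12),
               "stability")
})
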