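test_that("dominant period recovers pure and mixed sinusoids", {
  t <- seq(0, 4000, by = 2)  # ms
  v4 <- 40 * sin(2 * pi * 4 * t / 1000) - 40
  rec <- matrix(v4, ncol = 1)
  expect_equal(dominant_period(rec, dt = 2), 250, tolerance = 5)
  # the larger of two peaks wins
  v47 <- 2 * sin(2 * pi * 4 * t / 1000) + sin(2 * pi * 7 * t / 1000)
  expect_equal(dominant_period(matrix(40 * v47, ncol = 1), dt = 2), 250,
               tolerance = 5)
  # quiescence signalled, not guessed
  q <- dominant_period(matrix(rep(-85, 2001), ncol = 1), dt = 2)
  expect_true(is.na(q))
  expect_true(isTRUE(attr(q, "quiescent")))
})

test_that("phase embedding rejects too-coarse movies and passes vortices through", {
  vf <- gen_vortex_field(1, positions = matrix(c(30, 30), 1), charges = 1L)
  # a synthetic voltage movie rotating with the planted phase
  nt <- 12
  snaps <- sapply(seq_len(nt), function(k)
    -40 + 30 * cos(vf$phase[, , 1] + 0.5 * (k - 1)))
  movie <- list(snaps = snaps, snap_t = 5 * seq_len(nt), nx = vf$nx,
                ny = vf$ny, dx = 1)
  expect_error(phase_map(movie, tau = 2), "stride")
  ph <- phase_map(movie, tau = 10)
  ps <- detect_phase_singularities(ph)
  expect_equal(nrow(ps), 1L)
  expect_lt(abs(ps$x - 30) + abs(ps$y - 30), 3)
})

test_that("PS detector resolves planted analytic vortices exactly", {
  # single vortex: position and charge
  v1 <- gen_vortex_field(1, positions = matrix(c(20.2, 35.7), 1),
                         charges = 1L)
  ps <- detect_phase_singularities(v1$phase[, , 1])
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$charge, 1L)
  expect_lt(abs(ps$x - 20.2), 1.5); expect_lt(abs(ps$y - 35.7), 1.5)
  # opposite pair: two singularities, net charge zero
  v2 <- gen_vortex_field(2, positions = rbind(c(15, 15), c(45, 45)),
                         charges = c(1L, -1L))
  ps2 <- detect_phase_singularities(v2$phase[, , 1])
  expect_equal(nrow(ps2), 2L)
  expect_equal(sum(ps2$charge), 0L)
})

test_that("detector recovers random planted vortex sets (generator truth)", {
  for (seed in 1:10) {
    n <- 1 + seed %% 8
    vf <- gen_vortex_field(n, grid = list(nx = 80, ny = 80), seed = seed)
    tr <- attr(vf, "truth")
    ps <- detect_phase_singularities(vf$phase[, , 1])
    expect_true(ps_match(ps, tr$positions, tr$charges),
                label = sprintf("seed %d (n = %d)", seed, nrow(tr$positions)))
  }
})

test_that("PS detector agrees with the brute-force contour-integral oracle", {
  ok <- TRUE
  for (seed in 1:50) {
    vf <- gen_vortex_field(1 + seed %% 6, grid = list(nx = 50, ny = 50),
                           seed = 1000 + seed)
    ph <- vf$phase[, , 1]
    det <- detect_phase_singularities(ph, merge_dist = 0)
    bf <- brute_force_ps(ph)
    same <- nrow(det) == nrow(bf) &&
      isTRUE(all.equal(det[order(det$x, det$y), ],
                       bf[order(bf$x, bf$y), ], check.attributes = FALSE))
    if (!same) ok <- FALSE
  }
  expect_true(ok)
})

test_that("wavefront counting handles plane waves, collisions, quiescence", {
  mk <- function(cols, nx = 40, ny = 30) {
    V <- matrix(-85, nx, ny)
    V[cols, ] <- 10
    V
  }
  prev <- matrix(-85, 40, 30)
  expect_equal(count_wavefronts(mk(10:12), prev), 1L)
  expect_equal(count_wavefronts(mk(c(5:7, 25:27)), prev), 2L)
  expect_equal(count_wavefronts(prev, prev), 0L)
  # depolarized but repolarizing tissue is not a front
  expect_equal(count_wavefronts(mk(10:12), mk(10:12) + 5), 0L)
  # diagonal contact joins fronts under 8-connectivity
  V <- matrix(-85, 20, 20); V[cbind(5:10, 5:10)] <- 10
  expect_equal(count_wavefronts(V, matrix(-85, 20, 20)), 1L)
})

test_that("ps_count_series tracks planted time-varying vortex scenarios", {
  # positions off the grid nodes so each singularity sits inside a plaquette
  v2 <- gen_vortex_field(2, positions = rbind(c(15.3, 15.3), c(45.6, 45.6)),
                         charges = c(1L, -1L), n_frames = 2)
  v1 <- gen_vortex_field(1, positions = matrix(c(15.3, 15.3), 1),
                         charges = 1L, n_frames = 2)
  ph <- v2
  ph$phase <- array(c(v2$phase[, , 1], v2$phase[, , 2], v1$phase[, , 1]),
                    dim = c(60, 60, 3))
  ph$t <- 1:3
  out <- ps_count_series(ph)
  expect_equal(out$count, c(2L, 2L, 1L))
  expect_equal(out$mean, mean(c(2, 2, 1)))
  expect_equal(out$rms_dev, sqrt(mean((c(2, 2, 1) - 5 / 3)^2)))
})

test_that("period surface enforces the monotone interpolation contract", {
  Ko <- seq(6, 9, by = 1); f <- seq(0, 0.1, by = 0.05)
  P <- outer(Ko, f, function(K, ff) 180 + 20 * (K - 6) - 100 * ff)
  P[2, 2] <- P[3, 2] + 15  # plant a violation in the Ko direction
  expect_message(ps <- period_surface(Ko, f, P, tol = 1), "smoothing")
  expect_true(all(apply(ps$period, 2, function(col) all(diff(col) >= -1e-9))))
  expect_true(all(apply(ps$period, 1, function(row) all(diff(row) <= 1e-9))))
  expect_gt(attr(ps, "monotone_adjustment"), 1)
})

test_that("surface interpolation reproduces grid values with signed partials", {
  surf <- reference_period_surface()
  itp <- surface_interpolant(surf)
  # node reproduction
  for (i in c(1, 5, 12)) for (j in c(1, 6, 11))
    expect_equal(itp$T(surf$Ko[i], surf$f_atp[j]), surf$period[i, j],
                 tolerance = 1e-8)
  # partial derivatives carry the direction of the physiology
  expect_gt(itp$dT_dKo(7, 0.05), 0)
  expect_lt(itp$dT_df(7, 0.05), 0)
  # clamped outside the fitted domain
  expect_equal(itp$T(20, 0), itp$T(max(surf$Ko), 0))
})

test_that("stable spiral: PS count stays 1 and spectral period matches rotations", {
  rec <- cached_spiral()
  ps <- ps_count_series(rec)
  expect_true(all(ps$count >= 1))
  expect_lte(stats::median(ps$count), 2)
  Tdom <- dominant_period(rec, window_s = 1)
  # time-domain oracle: successive upstrokes at one probe
  v <- rec$V[, 6]
  up <- which(diff(v > -20) == 1)
  expect_gte(length(up), 3)
  Trot <- mean(diff(rec$t[up]))
  expect_equal(Tdom, Trot, tolerance = 0.03 * Trot)
})

test_that("a simulated period-surface point shows the hyperkalemia direction", {
  fix <- cached_vf_fixture()
  surf <- build_period_surface(7.5, 0, fix, run_ms = 900, ramp_ms = 300,
                               analyze_ms = 500)
  expect_s3_class(surf, "period_surface")
  expect_true(is.finite(surf$period[1, 1]))
  # hyperkalemia lengthens the period relative to the fixture's own
  # normal-conditions activity
  Tn <- dominant_period(attr(fix, "develop_recording"), window_s = 1.2,
                        end_at_quiescence = TRUE)
  expect_gt(surf$period[1, 1], Tn)
})
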