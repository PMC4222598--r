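test_that("max_slope matches closed forms on synthetic curves", {
  di <- seq(20, 400, by = 20)
  lin <- data.frame(DI = di, APD = 0.5 * di + 100)
  expect_equal(max_slope(lin), 0.5)
  # saturating exponential APD = A(1 - exp(-DI/tau)): steepest at smallest DI
  A <- 250; tau <- 80
  ex <- data.frame(DI = di, APD = A * (1 - exp(-di / tau)))
  # centered-difference estimate at the second point, computed independently
  expected <- (ex$APD[3] - ex$APD[1]) / (ex$DI[3] - ex$DI[1])
  expect_equal(max_slope(ex), expected)
  expect_equal(max_slope(ex), A / tau * exp(-ex$DI[2] / tau),
               tolerance = 0.05)
  expect_error(max_slope(lin[1:2, ]), "3 points")
})

test_that("apd_min returns the left-most captured point", {
  cur <- data.frame(DI = c(300, 50, 120), APD = c(250, 150, 200))
  expect_equal(apd_min(cur), 150)
  expect_error(apd_min(cur[0, ]), "empty")
})

test_that("S1S2 restitution curves are monotone and continuous with the S1 train", {
  cur <- cached_restitution(1.8)
  pts <- cur$points
  expect_gte(nrow(pts), 15)
  # APD increases with DI overall
  expect_gt(pts$APD[which.max(pts$DI)], pts$APD[which.min(pts$DI)] + 20)
  expect_gt(cor(pts$DI, pts$APD, method = "spearman"), 0.95)
  # S2 at the S1 interval reproduces the steady-state APD within 2 ms
  expect_equal(pts$APD[which.max(pts$S2)], cur$meta$s1_apd, tolerance = 2)
})

test_that("restitution slope presets are ordered and near their labels", {
  s <- vapply(c(1.1, 1.4, 1.8), function(sl)
    max_slope(cached_restitution(sl)), numeric(1))
  expect_true(s[1] < s[2] && s[2] < s[3])
  expect_equal(s[3], 1.8, tolerance = 0.2 / 1.8)
})

test_that("hyperkalemia shifts the restitution curve down and APD_min up", {
  nrm <- cached_restitution_isch("normal", ischemia())
  hyp <- cached_restitution_isch("ko10", ischemia(Ko = 10))
  # severe hyperkalemia blocks premature beats until very long recovery
  # (post-repolarization refractoriness), so its curve only exists at long
  # DI.  Where the DI ranges overlap, every hyperkalemic APD undercuts the
  # normal curve at the matched DI; if they do not overlap, the
  # hyperkalemic points lie beyond every normal DI, where the (increasing)
  # normal curve is at least its largest observed APD.
  lo <- max(min(nrm$points$DI), min(hyp$points$DI))
  hi <- min(max(nrm$points$DI), max(hyp$points$DI))
  if (hi > lo) {
    di <- seq(lo, hi, length.out = 8)
    expect_true(all(approx(hyp$points$DI, hyp$points$APD, di)$y <
                      approx(nrm$points$DI, nrm$points$APD, di)$y))
  } else {
    expect_gt(min(hyp$points$DI), max(nrm$points$DI))
    expect_true(all(hyp$points$APD < max(nrm$points$APD)))
  }
  # the paced (S1) APD is also shorter
  expect_lt(hyp$meta$s1_apd, nrm$meta$s1_apd)
  expect_gt(apd_min(hyp), apd_min(nrm))
})

test_that("hypoxia shortens APD_min; moderate acidosis barely moves it", {
  nrm <- cached_restitution_isch("normal", ischemia())
  hyp <- cached_restitution_isch("hypox", ischemia(f_atp = 0.05))
  expect_lt(apd_min(hyp), apd_min(nrm))
  acid5 <- cached_restitution_isch("acid05", ischemia(acidosis = 0.5))
  expect_lt(abs(apd_min(acid5) - apd_min(nrm)) / apd_min(nrm), 0.1)
})

test_that("CV dispersion: hypoxia leaves CV unchanged, acidosis slows it", {
  nrm <- cached_restitution_isch("normal", ischemia())
  hyp <- cached_restitution_isch("hypox", ischemia(f_atp = 0.05))
  acid <- cached_restitution_isch("acid02", ischemia(acidosis = 0.2))
  # S2 CV at the longest coupling reproduces the S1 plane-wave CV
  long_cv <- nrm$points$CV[which.max(nrm$points$S2)]
  expect_equal(long_cv, nrm$meta$s1_cv, tolerance = 0.02 * nrm$meta$s1_cv)
  # hypoxia does not touch sodium-channel recovery: CV at matched diastolic
  # interval is within 2% of normal
  di <- seq(max(min(nrm$points$DI), min(hyp$points$DI)) + 5,
            min(max(nrm$points$DI), max(hyp$points$DI)) - 5, length.out = 8)
  cn <- approx(nrm$points$DI, nrm$points$CV, di)$y
  ch <- approx(hyp$points$DI, hyp$points$CV, di)$y
  expect_lt(max(abs(ch - cn) / cn), 0.02)
  # acidosis: CV reduced at all matched diastolic intervals
  di2 <- seq(max(min(nrm$points$DI), min(acid$points$DI)) + 5,
             min(max(nrm$points$DI), max(acid$points$DI)) - 5,
             length.out = 8)
  ca <- approx(acid$points$DI, acid$points$CV, di2)$y
  cn2 <- approx(nrm$points$DI, nrm$points$CV, di2)$y
  expect_true(all(ca < cn2))
})
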