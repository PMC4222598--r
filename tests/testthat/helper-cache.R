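# Session-level cache for expensive simulation artifacts shared across
# test files (test_dir runs all files in one session).
.sim_cache <- new.env(parent = emptyenv())

cache_get <- function(name, expr) {
  if (!exists(name, envir = .sim_cache, inherits = FALSE))
    assign(name, force(expr), envir = .sim_cache)
  get(name, envir = .sim_cache, inherits = FALSE)
}

# ---- shared simulation artifacts -------------------------------------------

# plane-wave recording on a 5 cm cable, 1 Hz x 3 beats, probes at 2 and 4 cm
cached_cv_recording <- function(isch = ischemia(), D = 1.54, dx = 0.025,
                                nx = 200) {
  key <- sprintf("cv_%g_%g_%g_%d", isch$Ko, isch$acidosis, D, nx)
  cache_get(key, {
    g <- tissue_grid(nx, 1, dx = dx, D = D, isch = isch)
    stims <- lapply(5 + 1000 * (0:2), function(on) stimulus(on, x = c(0, 0.1)))
    run_protocol(g, stims, duration = 2400, probes = c(2, 4),
                 probe_dt = 0.25)
  })
}

# full-protocol S1S2 restitution curves for the three presets (acceptance)
cached_restitution <- function(slope) {
  cache_get(sprintf("resti_%g", slope),
            s1s2_apd_restitution(tp06_params(slope), length_cm = 5))
}

# reduced-harness curves for ischemia-component comparisons (S2 from 700 ms:
# severe hyperkalemia blocks premature beats up to ~500 ms coupling)
cached_restitution_isch <- function(tag, isch) {
  cache_get(sprintf("resti_isch_%s", tag),
            s1s2_apd_restitution(tp06_params(1.8), isch, length_cm = 5,
                                 n_s1 = 3, s2_max = 700, s2_coarse = 25))
}

# single stable-ish spiral (flat preset) with snapshots + probes, desk scale
cached_spiral <- function() {
  cache_get("spiral", {
    g <- tissue_grid(180, 180, D = 0.25, params = tp06_params(1.1))
    rec <- init_spiral_crossfield(g, s2_delay = 310, settle_ms = 300,
                                  snapshot_dt = 10)
    probes <- ischvf:::.sublattice_probes(rec$grid, 16)
    run_protocol(rec$grid, duration = 1000, probes = probes, probe_dt = 2,
                 snapshot_dt = 10)
  })
}

# developed multi-wave fibrillation fixture (steep preset, desk scale),
# with the development-phase probe recording attached (the fixture's own
# normal-conditions reference activity)
cached_vf_fixture <- function() {
  cache_get("vf_fixture", {
    probes <- as.matrix(expand.grid(x = seq(0.2, 4.3, length.out = 10),
                                    y = seq(0.2, 4.3, length.out = 10)))
    gen_vf_fixture(probes = probes)
  })
}

# continuation run from the fixture (acidosis arm of the period comparison)
cached_vf_run <- function(tag, ramp_to = NULL, duration = 1200) {
  cache_get(sprintf("vf_run_%s", tag), {
    fix <- cached_vf_fixture()
    probes <- attr(fix, "develop_recording")$probes
    run_protocol(fix, duration = duration, probes = probes, probe_dt = 2,
                 snapshot_dt = 10, ramp_to = ramp_to,
                 ramp_window = c(0, 500))
  })
}

# ---- independent oracles ----------------------------------------------------

# brute-force phase-singularity detector: explicit contour integration of
# wrapped phase differences around each 2x2 loop, plain R loops; kept
# deliberately independent of detect_phase_singularities()
brute_force_ps <- function(ph) {
  wrap <- function(x) {
    while (x > pi) x <- x - 2 * pi
    while (x <= -pi) x <- x + 2 * pi
    x
  }
  out <- list()
  for (i in seq_len(nrow(ph) - 1)) {
    for (j in seq_len(ncol(ph) - 1)) {
      loop <- c(ph[i, j], ph[i + 1, j], ph[i + 1, j + 1], ph[i, j + 1],
                ph[i, j])
      s <- 0
      for (k in 1:4) s <- s + wrap(loop[k + 1] - loop[k])
      q <- round(s / (2 * pi))
      if (q != 0)
        out[[length(out) + 1]] <- data.frame(x = i + 0.5, y = j + 0.5,
                                             charge = q)
    }
  }
  if (length(out) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), charge = integer(0)))
  do.call(rbind, out)
}

# match detected and true vortex positions within a tolerance (grid units)
ps_match <- function(detected, truth_pos, truth_charge, tol = 1.5) {
  if (nrow(detected) != nrow(truth_pos)) return(FALSE)
  used <- rep(FALSE, nrow(detected))
  for (i in seq_len(nrow(truth_pos))) {
    d <- sqrt((detected$x - truth_pos[i, 1])^2 +
                (detected$y - truth_pos[i, 2])^2)
    j <- which(!used & d <= tol & detected$charge == truth_charge[i])
    if (length(j) == 0) return(FALSE)
    used[j[1]] <- TRUE
  }
  all(used)
}
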