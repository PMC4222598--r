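# Deterministic generators for every input the pipeline needs: patient-like
# DF recordings with known ground truth, planted-vortex phase movies, and
# developed-fibrillation tissue states.

# seed handling that does not clobber the caller's RNG stream
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Synthetic patient specification
#'
#' Ground-truth parameters of a simulated clinical recording: 30 s
#' perfused fibrillation, 150 s global ischemia with monotone rises of
#' extracellular potassium and ATP-channel activation to (`K_B`, `f_B`),
#' then 30 s reperfusion in which potassium washes out quickly while the
#' ATP channels recover only partially (slowly).
#'
#' @param K_B_true potassium at the end of ischemia, mM.
#' @param f_B_true open ATP-channel fraction at end of ischemia, percent.
#' @param baseline_Ko baseline potassium, mM.
#' @param f_A open fraction already present at ischemia onset (perfused
#'   phase drift toward it; nonzero models energy depletion before
#'   ischemia, the alternative-fit scenario), percent.
#' @param tau_K_rise,tau_f_rise saturating-exponential rise constants of
#'   the ischemia-phase trajectories, s.
#' @param tau_K_wash potassium washout constant during reperfusion, s
#'   (fast).
#' @param recovery_fraction fraction of ATP channels recovered by the end
#'   of the 30 s reperfusion window (sets the slow f washout constant;
#'   0 = no recovery).
#' @param noise_sd per-sample Gaussian DF noise, Hz (electrode spread).
#' @param seed RNG seed for the noise.
#' @return an object of class `synthetic_patient_spec`.
#' @export
synthetic_patient_spec <- function(K_B_true = 7.2, f_B_true = 0.05,
                                   baseline_Ko = 5.4, f_A = 0,
                                   tau_K_rise = 60, tau_f_rise = 60,
                                   tau_K_wash = 8, recovery_fraction = 0,
                                   noise_sd = 0.1, seed = 1L) {
  stopifnot(K_B_true >= baseline_Ko, f_B_true >= 0, tau_K_rise > 0,
            tau_f_rise > 0, tau_K_wash > 0, recovery_fraction >= 0,
            recovery_fraction < 1, noise_sd >= 0, f_A >= 0,
            f_A <= f_B_true)
  structure(as.list(environment()), class = "synthetic_patient_spec")
}

#' Ground-truth ischemia trajectories
#'
#' Deterministic (Ko(t), f(t)) over the 210 s protocol: flat (Ko) and a
#' linear drift to `f_A` (f) while perfused; saturating-exponential rises
#' normalized to hit (`K_B_true`, `f_B_true`) exactly at 180 s; exponential
#' washouts during reperfusion with the two time constants carried by the
#' `spec` argument (fast for potassium, slow for the ATP channels).
#'
#' @param spec a `synthetic_patient_spec`.
#' @param t sample times, s (default 0..210 at 1 Hz).
#' @return data.frame with `t`, `Ko`, `f_atp`, `phase`.
#' @export
gen_trajectories <- function(spec, t = 0:210) {
  stopifnot(inherits(spec, "synthetic_patient_spec"))
  tA <- 30; tB <- 180; tC <- 210
  rise <- function(x, tau) (1 - exp(-x / tau)) / (1 - exp(-(tB - tA) / tau))
  Ko <- numeric(length(t)); f <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- t[i]
    if (ti <= tA) {
      Ko[i] <- spec$baseline_Ko
      f[i] <- spec$f_A * ti / tA
    } else if (ti <= tB) {
      Ko[i] <- spec$baseline_Ko +
        (spec$K_B_true - spec$baseline_Ko) * rise(ti - tA, spec$tau_K_rise)
      f[i] <- spec$f_A +
        (spec$f_B_true - spec$f_A) * rise(ti - tA, spec$tau_f_rise)
    } else {
      Ko[i] <- spec$baseline_Ko +
        (spec$K_B_true - spec$baseline_Ko) * exp(-(ti - tB) / spec$tau_K_wash)
      tau_f <- if (spec$recovery_fraction > 0)
        -(tC - tB) / log(1 - spec$recovery_fraction) else Inf
      f[i] <- if (is.finite(tau_f))
        spec$f_B_true * exp(-(ti - tB) / tau_f) else spec$f_B_true
    }
  }
  phase <- cut(t, c(-Inf, tA, tB, Inf),
               labels = c("perfused", "ischemia", "reperfusion"))
  data.frame(t = t, Ko = Ko, f_atp = f, phase = as.character(phase))
}

#' Synthetic dominant-frequency recording
#'
#' Samples DF(t) = 1000 / T_surface(Ko(t), f(t)) at 1 Hz along the
#' ground-truth trajectories, adds seeded Gaussian noise, labels the
#' perfusion phases, and attaches the ground truth.  Reproduces the
#' clinical morphology: DF declines through ischemia and, when the ATP
#' channels wash out more slowly than potassium, rebounds after reperfusion
#' to above its initial level.
#'
#' @param spec a `synthetic_patient_spec`.
#' @param surface a `period_surface` covering the trajectory range.
#' @param t sample times, s.
#' @return a `df_recording` with attributes `truth` (the trajectory
#'   data.frame plus `K_B_true`, `f_B_true`) and `spec`.
#' @importFrom stats rnorm
#' @export
gen_df_recording <- function(spec, surface, t = 0:210) {
  traj <- gen_trajectories(spec, t)
  itp <- surface_interpolant(surface)
  if (max(traj$Ko) > itp$range_Ko[2] + 1e-9 ||
      max(traj$f_atp) > itp$range_f[2] + 1e-9) {
    bad <- traj$t[which.max(pmax(traj$Ko - itp$range_Ko[2],
                                 traj$f_atp - itp$range_f[2]))]
    stop("trajectory exits the surface domain (first at t = ", bad, " s)")
  }
  Tms <- itp$T(traj$Ko, traj$f_atp)
  df <- 1000 / Tms
  noise <- .with_seed(spec$seed, stats::rnorm(length(df), 0, spec$noise_sd))
  rec <- df_recording(t, pmax(df + noise, 0.5),
                      df_sd = rep(spec$noise_sd, length(df)),
                      phase = traj$phase)
  attr(rec, "truth") <- list(trajectories = traj, K_B_true = spec$K_B_true,
                             f_B_true = spec$f_B_true, df_clean = df)
  attr(rec, "spec") <- spec
  rec
}

#' Synthetic reference period surface
#'
#' A parametric stand-in for a simulated fibrillation period surface:
#' period rising with extracellular potassium, falling with ATP-channel
#' activation, with a saturating interaction (hypoxia matters less at high
#' potassium).  Magnitudes emulate human fibrillation (baseline period
#' about 185 ms, dominant frequencies 4-7 Hz).  Monotone by construction;
#' used as the invertible forward model in inverse-fit studies and tests.
#'
#' @param Ko,f_atp grid vectors (mM; percent).
#' @param T0 baseline period at (5.4 mM, 0%), ms.
#' @return a `period_surface` flagged `synthetic` in its metadata.
#' @export
reference_period_surface <- function(Ko = seq(5.4, 10, by = 0.4),
                                     f_atp = seq(0, 0.25, by = 0.025),
                                     T0 = 185) {
  P <- outer(Ko, f_atp, function(K, f)
    T0 + 95 * ((K - 5.4) / 4.6)^1.1 -
      35 * (1 - exp(-f / 0.06)) * exp(-(K - 5.4) / 5))
  period_surface(Ko, f_atp, P, smooth = FALSE,
                 meta = list(synthetic = TRUE, T0 = T0))
}

#' Planted-vortex phase movie
#'
#' Analytic phase field \eqn{\theta(x, y, t) = \sum_i q_i\,
#' \mathrm{atan2}(y - y_i, x - x_i) + \omega t} (wrapped to (-pi, pi]) with
#' known singularity positions and charges; the ground truth for the
#' phase-singularity detector.
#'
#' @param n number of vortices; ignored when `positions` is given.
#' @param positions `n x 2` matrix of (x, y) in grid units; default: seeded
#'   random placement with minimum pairwise separation `min_sep`.
#' @param charges vector of +1/-1 (default: alternating).
#' @param grid list with `nx`, `ny` (default 60 x 60).
#' @param omega rotation rate, rad per frame.
#' @param n_frames number of frames.
#' @param min_sep minimum pairwise separation, grid units (default 10).
#' @param seed RNG seed for random placement.
#' @return a `phase_field` with attribute `truth` (positions, charges).
#' @export
gen_vortex_field <- function(n, positions = NULL, charges = NULL,
                             grid = list(nx = 60, ny = 60), omega = 0.3,
                             n_frames = 3, min_sep = 10, seed = 1L) {
  nx <- grid$nx; ny <- grid$ny
  if (is.null(positions)) {
    positions <- .with_seed(seed, {
      pos <- matrix(NA_real_, 0, 2)
      tries <- 0L
      while (nrow(pos) < n && tries < 5000L) {
        cand <- c(stats::runif(1, 6, nx - 5), stats::runif(1, 6, ny - 5))
        if (nrow(pos) == 0L ||
            min(sqrt(colSums((t(pos) - cand)^2))) >= min_sep)
          pos <- rbind(pos, cand)
        tries <- tries + 1L
      }
      pos
    })
    if (nrow(positions) < n)
      stop("could not place ", n, " vortices with separation ", min_sep)
  }
  positions <- matrix(positions, ncol = 2)
  n <- nrow(positions)
  if (is.null(charges)) charges <- rep_len(c(1L, -1L), n)
  if (n > 1 && min(stats::dist(positions)) < min_sep)
    stop("vortex separation below ", min_sep, " grid units")
  if (n > 0 && any(abs(charges) != 1)) stop("charges must be +1 or -1")
  xs <- seq_len(nx); ys <- seq_len(ny)
  base <- matrix(0, nx, ny)
  for (i in seq_len(n))
    base <- base + charges[i] *
      outer(xs - positions[i, 1], ys - positions[i, 2],
            function(a, b) atan2(b, a))
  arr <- array(0, dim = c(nx, ny, n_frames))
  for (k in seq_len(n_frames))
    arr[, , k] <- .wrap_pi(base + omega * (k - 1))
  structure(list(phase = arr, t = seq_len(n_frames), nx = nx, ny = ny,
                 dx = 1),
            class = "phase_field",
            truth = list(positions = positions, charges = charges))
}

#' Generate a developed-fibrillation tissue state
#'
#' Initiates a spiral by the cross-field S1S2 protocol on a
#' breakup-capable preset (slope 1.8) and lets it degenerate into a
#' multi-wave pattern, verifying that at least `min_ps` phase
#' singularities are present at the end.  The returned `tissue_grid` is
#' the reusable initial condition for fibrillation studies.
#'
#' @param size_cm sheet edge length, cm.
#' @param develop_ms time allowed for breakup after S2, ms.
#' @param params ionic preset (default slope 1.8, the breakup-capable set).
#' @param isch environment (default normal).
#' @param D diffusion coefficient, cm^2/s.  The desk-scale default (0.25)
#'   compresses the re-entrant wavelength so that multi-wave activity fits
#'   and survives on a few-centimetre sheet; at the full tissue value
#'   (1.54) the human-scale wavelength needs a sheet far beyond desk scale.
#' @param s2_delay S2 delay, ms; NULL triggers a scan.
#' @param min_ps minimum phase singularities required (default 3).
#' @param probes optional probe positions (as in [run_protocol()]): voltage
#'   at these nodes is recorded through the development phase and attached
#'   as attribute `develop_recording` — the normal-conditions reference
#'   activity of the fixture, usable for dominant-period baselines without
#'   an extra continuation run.
#' @param dx,dt solver settings.
#' @param path optional file path: the fixture is also serialized with
#'   [write_fixture()].
#' @return a `tissue_grid` with attribute `ps_count` (singularities at the
#'   end of initialization) and optionally `develop_recording`.
#' @export
gen_vf_fixture <- function(size_cm = 4.5, develop_ms = 2300,
                           params = tp06_params(slope = 1.8),
                           isch = ischemia(), D = 0.25, s2_delay = 360,
                           min_ps = 3, probes = NULL, dx = 0.025,
                           dt = 0.02, path = NULL) {
  n <- round(size_cm / dx)
  grid <- tissue_grid(n, n, dx = dx, D = D, params = params, isch = isch)
  if (is.null(s2_delay)) {
    s2_delay <- scan_s2_delay(grid)
  }
  rec <- init_spiral_crossfield(grid, s2_delay = s2_delay, settle_ms = 300,
                                snapshot_dt = 0, dt = dt)
  # develop breakup, then advance in short hops until a state with the
  # required number of phase singularities is current (the instantaneous
  # count fluctuates as wavelets break and merge)
  pdt <- if (is.null(probes)) 0 else 2
  dev <- run_protocol(rec$grid, duration = max(develop_ms - 300, 500) - 200,
                      probes = probes, probe_dt = pdt, snapshot_dt = 0,
                      dt = dt)
  g <- dev$grid
  tt <- dev$t; vv <- dev$V
  nps <- 0L
  for (hop in 1:14) {
    r <- run_protocol(g, duration = 100, probes = probes, probe_dt = pdt,
                      snapshot_dt = 5, dt = dt)
    g <- r$grid
    if (!is.null(probes)) {  # drop the duplicated boundary sample
      tt <- c(tt, r$t[-1]); vv <- rbind(vv, r$V[-1, , drop = FALSE])
    }
    nps <- nrow(detect_phase_singularities(phase_map(r)))
    if (hop >= 2L && nps >= min_ps) break
  }
  if (nps < min_ps)
    stop("fibrillation did not develop (", nps, " phase singularities",
         " < ", min_ps, "); try other S2 delays (scan_s2_delay) or a ",
         "larger sheet")
  out <- g
  attr(out, "ps_count") <- nps
  if (!is.null(probes)) {
    drec <- structure(list(t = tt, V = vv, probes = probes, nx = n, ny = n,
                           dx = dx), class = "field_recording")
    attr(out, "develop_recording") <- drec
  }
  if (!is.null(path)) write_fixture(out, path)
  out
}
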