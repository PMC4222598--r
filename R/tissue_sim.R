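#' Create a tissue grid
#'
#' A 1D cable (`ny = 1`) or 2D sheet of TP06 cells for the monodomain
#' reaction-diffusion model, with isotropic diffusion and no-flux
#' boundaries.
#'
#' @param nx,ny node counts; `ny = 1` gives a cable.
#' @param dx space step, cm (default 0.025 cm = 0.25 mm).
#' @param D diffusion coefficient, cm^2/s (default 1.54; converted to
#'   cm^2/ms internally).
#' @param params `ionic_params` shared by all nodes.
#' @param isch `ischemia_params` of the environment.
#' @param state0 initial per-node state; a single `cell_state` (replicated)
#'   or a `(nx*ny) x 19` matrix.
#' @return an object of class `tissue_grid`.
#' @export
tissue_grid <- function(nx, ny = 1, dx = 0.025, D = 1.54,
                        params = tp06_params(), isch = ischemia(),
                        state0 = cell_state()) {
  stopifnot(nx >= 3, ny >= 1, dx > 0, D >= 0)
  n <- nx * ny
  if (is.matrix(state0)) {
    stopifnot(nrow(state0) == n, ncol(state0) == 19L)
    states <- state0
  } else {
    states <- matrix(rep(.as_state(state0), each = n), nrow = n)
  }
  colnames(states) <- .state_names
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx,
                 D = D, params = params, isch = isch, states = states,
                 t = 0),
            class = "tissue_grid")
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat(sprintf("tissue grid %d x %d (%.2f x %.2f cm), D = %g cm^2/s, t = %g ms\n",
              x$nx, x$ny, x$nx * x$dx, x$ny * x$dx, x$D, x$t))
  invisible(x)
}

#' Stimulus event
#'
#' A rectangular stimulated region, specified in cm from the grid origin.
#'
#' @param onset onset time, ms.
#' @param duration duration, ms.
#' @param amplitude current density, pA/pF (negative depolarizes).
#' @param x,y length-2 numeric ranges in cm (defaults: whole extent).
#' @return an object of class `stimulus`.
#' @export
stimulus <- function(onset, duration = 1, amplitude = -52,
                     x = c(0, Inf), y = c(0, Inf)) {
  stopifnot(duration > 0)
  structure(list(onset = onset, duration = duration, amplitude = amplitude,
                 x = x, y = y), class = "stimulus")
}

.stim_df <- function(stimuli, grid) {
  if (inherits(stimuli, "stimulus")) stimuli <- list(stimuli)
  if (length(stimuli) == 0L)
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      amplitude = numeric(0), ix0 = integer(0),
                      ix1 = integer(0), iy0 = integer(0), iy1 = integer(0)))
  rows <- lapply(stimuli, function(s) {
    ix0 <- max(1L, 1L + floor(s$x[1] / grid$dx))
    ix1 <- min(grid$nx, ceiling(pmin(s$x[2], grid$nx * grid$dx) / grid$dx))
    iy0 <- max(1L, 1L + floor(s$y[1] / grid$dx))
    iy1 <- min(grid$ny, ceiling(pmin(s$y[2], grid$ny * grid$dx) / grid$dx))
    if (ix1 < ix0 || iy1 < iy0) stop("stimulus region is empty")
    data.frame(onset = s$onset, duration = s$duration,
               amplitude = s$amplitude, ix0 = ix0, ix1 = ix1,
               iy0 = iy0, iy1 = iy1)
  })
  do.call(rbind, rows)
}

#' Discrete diffusion term
#'
#' 3-point (1D) or 5-point (2D) Laplacian scaled by `D / dx^2`, with
#' no-flux boundaries realized by cell-centred mirror ghost nodes.  The sum
#' of the term over all nodes is zero to machine precision (discrete
#' conservation).
#'
#' @param Vfield numeric vector (1D) or matrix (`nx x ny`) of voltages, mV.
#' @param D diffusion coefficient, cm^2/s.
#' @param dx space step, cm.
#' @return field of the same shape, in mV/ms.
#' @export
diffusion_term <- function(Vfield, D = 1.54, dx = 0.025) {
  if (is.matrix(Vfield)) {
    nx <- nrow(Vfield); ny <- ncol(Vfield)
    out <- diffusion_term_cpp(as.numeric(Vfield), nx, ny, D / 1000, dx)
    matrix(out, nx, ny)
  } else {
    diffusion_term_cpp(as.numeric(Vfield), length(Vfield), 1L, D / 1000, dx)
  }
}

#' Convert probe positions (cm) to node indices
#' @noRd
.probe_idx <- function(grid, probes) {
  if (is.null(probes)) return(integer(0))
  if (is.matrix(probes)) {
    ix <- pmin(grid$nx, pmax(1L, round(probes[, 1] / grid$dx)))
    iy <- pmin(grid$ny, pmax(1L, round(probes[, 2] / grid$dx)))
    as.integer((iy - 1L) * grid$nx + ix)
  } else {
    ix <- pmin(grid$nx, pmax(1L, round(probes / grid$dx)))
    iy <- max(1L, (grid$ny + 1L) %/% 2L)
    as.integer((iy - 1L) * grid$nx + ix)
  }
}

#' Run a stimulation protocol on a tissue grid
#'
#' Advances the monodomain model with explicit Euler time stepping,
#' applying the given stimuli, recording voltage at probe locations and
#' optionally full-field snapshots.  Ischemia parameters can be ramped
#' linearly over a time window (gradual onset of ischemia).
#'
#' @param grid a `tissue_grid`.
#' @param stimuli a `stimulus` or list of stimuli.
#' @param duration model time to simulate, ms.
#' @param probes probe positions: numeric vector of x-positions (cm,
#'   mid-row) or a 2-column matrix of (x, y) cm; NULL for none.
#' @param probe_dt probe sampling interval, ms.
#' @param snapshot_dt full-field snapshot interval, ms (NULL/0 = none).
#' @param dt time step, ms.
#' @param ramp_to optional `ischemia_params`: ramp the environment from
#'   `grid$isch` to this over `ramp_window`.
#' @param ramp_window length-2 numeric, ms (relative to the start of this
#'   run) over which the ramp is applied; default `c(0, 500)`.
#' @return a `field_recording`: probe times/voltages, snapshots (nodes x
#'   times), grid geometry, and the advanced `tissue_grid` in `$grid`.
#' @export
run_protocol <- function(grid, stimuli = list(), duration, probes = NULL,
                         probe_dt = 1, snapshot_dt = NULL, dt = 0.02,
                         ramp_to = NULL, ramp_window = c(0, 500)) {
  stopifnot(inherits(grid, "tissue_grid"), duration > 0)
  pidx <- .probe_idx(grid, probes)
  sdf <- .stim_df(stimuli, grid)
  isch_to <- if (is.null(ramp_to)) grid$isch else ramp_to
  rt0 <- if (is.null(ramp_to)) 0 else grid$t + ramp_window[1]
  rt1 <- if (is.null(ramp_to)) -1 else grid$t + ramp_window[2]
  res <- run_tissue_cpp(grid$states, grid$nx, grid$ny, grid$params,
                        grid$isch, isch_to, rt0, rt1,
                        grid$D / 1000, grid$dx, dt, grid$t, duration, sdf,
                        pidx, if (length(pidx)) probe_dt else 0,
                        if (is.null(snapshot_dt)) 0 else snapshot_dt)
  grid$states <- res$states
  colnames(grid$states) <- .state_names
  grid$t <- res$t_end
  if (!is.null(ramp_to)) grid$isch <- ramp_to
  np <- as.integer(res$n_probe_rec)
  ns <- as.integer(res$n_snap_rec)
  rec <- list(
    t = if (np > 0) res$probe_t else numeric(0),
    V = if (np > 0) res$probe_V[seq_len(np), , drop = FALSE] else NULL,
    probes = probes, probe_idx = pidx,
    snap_t = if (ns > 0) res$snap_t else numeric(0),
    snaps = if (ns > 0) res$snaps[, seq_len(ns), drop = FALSE] else NULL,
    nx = grid$nx, ny = grid$ny, dx = grid$dx,
    grid = grid)
  class(rec) <- "field_recording"
  rec
}

#' @export
print.field_recording <- function(x, ...) {
  cat(sprintf("field recording: %d probes x %d samples, %d snapshots (%d x %d grid)\n",
              if (is.null(x$V)) 0L else ncol(x$V), length(x$t),
              length(x$snap_t), x$nx, x$ny))
  invisible(x)
}

#' Upstroke time at a probe
#'
#' Time of maximum dV/dt for the `beat`-th (default last) suprathreshold
#' depolarization, refined by parabolic interpolation of the discrete
#' derivative peak.
#' @noRd
.upstroke_time <- function(t, V, beat = Inf, thresh = -20) {
  above <- V > thresh
  starts <- which(diff(c(FALSE, above)) == 1L)
  if (length(starts) == 0L) return(NA_real_)
  k <- if (is.finite(beat)) beat else length(starts)
  if (k > length(starts)) return(NA_real_)
  i0 <- max(2L, starts[k] - 60L)
  i1 <- min(length(V), starts[k] + 10L)
  dv <- diff(V[i0:i1]) / diff(t[i0:i1])
  m <- which.max(dv)
  tm <- (t[i0 + m - 1L] + t[i0 + m]) / 2
  # parabolic refinement on the derivative samples
  if (m > 1L && m < length(dv)) {
    y1 <- dv[m - 1L]; y2 <- dv[m]; y3 <- dv[m + 1L]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 1e-12) {
      delta <- 0.5 * (y1 - y3) / den
      tm <- tm + delta * (t[i0 + m] - t[i0 + m - 1L])
    }
  }
  tm
}

#' Measure conduction velocity between two probes
#'
#' CV = distance / upstroke-transit-time for the chosen beat (default the
#' last), with upstroke time defined as the instant of fastest dV/dt.
#'
#' @param rec a `field_recording` with probes at known x-positions.
#' @param x1,x2 probe x-positions, cm (must match recorded probes).
#' @param beat which beat to use (default last).
#' @return velocity in cm/s, or `NA` with attribute `conduction_block =
#'   TRUE` if either probe shows no upstroke.
#' @export
measure_cv <- function(rec, x1, x2, beat = Inf) {
  pos <- if (is.matrix(rec$probes)) rec$probes[, 1] else rec$probes
  i1 <- which.min(abs(pos - x1)); i2 <- which.min(abs(pos - x2))
  if (abs(pos[i1] - x1) > rec$dx || abs(pos[i2] - x2) > rec$dx)
    stop("no probe recorded near the requested positions")
  t1 <- .upstroke_time(rec$t, rec$V[, i1], beat)
  t2 <- .upstroke_time(rec$t, rec$V[, i2], beat)
  if (is.na(t1) || is.na(t2) || t2 <= t1) {
    out <- NA_real_
    attr(out, "conduction_block") <- TRUE
    return(out)
  }
  # cm / ms -> cm/s
  (x2 - x1) / (t2 - t1) * 1000
}

#' Initiate a spiral wave by a cross-field S1S2 protocol
#'
#' Delivers an S1 plane-wave stimulus along the left edge and, after
#' `s2_delay`, an S2 stimulus covering the quarter of the sheet behind the
#' S1 wavefront and below the midline, producing a single spiral whose
#' chirality follows the stimulated half.
#'
#' @param grid a 2D `tissue_grid`.
#' @param s2_delay S2 onset relative to S1 onset, ms (must lie in the
#'   vulnerable window; see [scan_s2_delay()]).
#' @param s2_xfrac fraction of the x-extent covered by S2 (default 0.5).
#' @param mirror stimulate the upper instead of the lower half (flips
#'   chirality).
#' @param settle_ms additional time simulated after S2, ms.
#' @param snapshot_dt snapshot interval for the returned recording, ms.
#' @param dt time step, ms.
#' @return a `field_recording` (with the advanced grid in `$grid`).
#' @export
init_spiral_crossfield <- function(grid, s2_delay, s2_xfrac = 0.5,
                                   mirror = FALSE, settle_ms = 200,
                                   snapshot_dt = 5, dt = 0.02) {
  stopifnot(grid$ny > 1)
  Lx <- grid$nx * grid$dx; Ly <- grid$ny * grid$dx
  s1 <- stimulus(onset = 5, x = c(0, 0.1))
  yr <- if (mirror) c(Ly / 2, Ly) else c(0, Ly / 2)
  s2 <- stimulus(onset = 5 + s2_delay, x = c(0, s2_xfrac * Lx), y = yr)
  run_protocol(grid, list(s1, s2), duration = 5 + s2_delay + settle_ms,
               snapshot_dt = snapshot_dt, dt = dt)
}

#' Scan S2 delays for successful spiral initiation
#'
#' Tries S2 delays in `delays` until the cross-field protocol leaves
#' exactly one phase singularity `check_ms` after S2.
#'
#' @param grid a 2D `tissue_grid` (copied for each trial).
#' @param delays candidate S2 delays, ms.
#' @param check_ms verification time after S2, ms.
#' @param ... passed to [init_spiral_crossfield()].
#' @return the first successful delay (with the recording as attribute
#'   `recording`), or an error if none succeed.
#' @export
scan_s2_delay <- function(grid, delays = seq(250, 400, by = 25),
                          check_ms = 200, ...) {
  for (d in delays) {
    rec <- init_spiral_crossfield(grid, s2_delay = d, settle_ms = check_ms,
                                  ...)
    ph <- phase_map(rec)
    ps <- detect_phase_singularities(ph, snapshot = dim(ph$phase)[3])
    if (nrow(ps) == 1L) {
      out <- d
      attr(out, "recording") <- rec
      return(out)
    }
  }
  stop("no S2 delay in the scanned range initiated a single spiral; ",
       "widen the scan (vulnerable window not found)")
}
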