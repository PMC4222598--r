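#' Dominant period of fibrillatory activity
#'
#' Per-probe periodogram (linear detrend, split-cosine taper, zero padding)
#' of the last `window_s` seconds; the dominant frequency is the location
#' of the largest peak of the across-probe median spectrum within `band`,
#' and the dominant period its reciprocal.
#'
#' @param x a `field_recording` (probe voltages), a `voltage_trace`, or a
#'   numeric matrix of probe series (rows = time).
#' @param window_s analysis window, s (taken from the end; NULL = all).
#' @param band frequency band searched, Hz.
#' @param dt sample interval in ms (required only for a bare matrix).
#' @param min_amplitude probes whose peak-to-peak voltage is below this (mV)
#'   are considered quiescent and dropped.
#' @param end_at_quiescence if TRUE, the analysis window ends at the last
#'   time any probe was still active (all-probe peak-to-peak amplitude above
#'   `min_amplitude` in 100 ms blocks), so that activity which terminates
#'   spontaneously is measured while it existed; the attribute
#'   `active_until` reports that time.
#' @return dominant period, ms; `NA` with attribute `quiescent = TRUE` if
#'   no probe shows activity.
#' @importFrom stats spec.pgram ts median
#' @export
dominant_period <- function(x, window_s = NULL, band = c(0.5, 15),
                            dt = NULL, min_amplitude = 10,
                            end_at_quiescence = FALSE) {
  if (inherits(x, "field_recording")) {
    V <- x$V; tt <- x$t
  } else if (inherits(x, "voltage_trace")) {
    V <- matrix(x$V, ncol = 1); tt <- x$t
  } else {
    V <- as.matrix(x)
    if (is.null(dt)) stop("dt (ms) required for a bare matrix")
    tt <- seq_len(nrow(V)) * dt
  }
  if (is.null(V) || nrow(V) < 8L) stop("recording too short for a spectrum")
  dtm <- diff(tt[1:2])
  active_until <- tt[length(tt)]
  if (end_at_quiescence) {
    block <- (tt - tt[1]) %/% 100
    # a block counts as active only if some probe both swings by the
    # amplitude floor and reaches depolarized potentials (slow
    # repolarization drift of dying tissue does neither)
    amp <- vapply(split(seq_along(tt), block), function(ix) {
      Vb <- V[ix, , drop = FALSE]
      swing <- apply(Vb, 2, function(v) diff(range(v)))
      peak <- apply(Vb, 2, max)
      max(swing * (peak > -30))
    }, numeric(1))
    alive <- which(amp >= min_amplitude)
    if (length(alive) == 0L) {
      out <- NA_real_
      attr(out, "quiescent") <- TRUE
      return(out)
    }
    keep <- block <= as.numeric(names(amp)[max(alive)])
    V <- V[keep, , drop = FALSE]
    tt <- tt[keep]
    active_until <- tt[length(tt)]
    if (tt[length(tt)] - tt[1] < 500) {  # too little activity for a spectrum
      out <- NA_real_
      attr(out, "quiescent") <- TRUE
      attr(out, "active_until") <- active_until
      return(out)
    }
  }
  if (!is.null(window_s)) {
    nkeep <- min(nrow(V), ceiling(window_s * 1000 / dtm))
    if (nkeep < 8L) stop("window shorter than a few samples")
    V <- V[(nrow(V) - nkeep + 1L):nrow(V), , drop = FALSE]
  }
  fs <- 1000 / dtm  # Hz
  amp <- apply(V, 2, function(v) diff(range(v)))
  keep <- amp >= min_amplitude
  if (!any(keep)) {
    out <- NA_real_
    attr(out, "quiescent") <- TRUE
    return(out)
  }
  V <- V[, keep, drop = FALSE]
  specs <- apply(V, 2, function(v) {
    sp <- stats::spec.pgram(stats::ts(v, frequency = fs), taper = 0.5,
                            pad = 7, detrend = TRUE, plot = FALSE)
    sp$spec
  })
  sp1 <- stats::spec.pgram(stats::ts(V[, 1], frequency = fs), taper = 0.5,
                           pad = 7, detrend = TRUE, plot = FALSE)
  freq <- sp1$freq
  med <- if (is.matrix(specs)) apply(specs, 1, stats::median) else specs
  inband <- freq >= band[1] & freq <= band[2]
  if (!any(inband)) stop("no spectral estimate inside the search band")
  fpk <- freq[inband][which.max(med[inband])]
  out <- 1000 / fpk
  if (end_at_quiescence) attr(out, "active_until") <- active_until
  out
}

#' Phase map of a voltage movie by delay embedding
#'
#' Per-node activation phase \eqn{\theta = \mathrm{atan2}(V(t-\tau) - V^*,
#' V(t) - V^*)} computed from full-field snapshots.
#'
#' @param movie a `field_recording` with snapshots, or a list with `snaps`
#'   (nodes x times matrix), `snap_t`, `nx`, `ny`, `dx`.
#' @param tau embedding delay, ms (default 10; must be a multiple of the
#'   snapshot stride).
#' @param V_star embedding origin, mV (default -40).
#' @return a `phase_field`: list with `phase` (nx x ny x ntime array in
#'   (-pi, pi]), `t`, `nx`, `ny`, `dx`.
#' @export
phase_map <- function(movie, tau = 10, V_star = -40) {
  snaps <- movie$snaps
  if (is.null(snaps)) stop("movie carries no snapshots")
  st <- movie$snap_t
  stride <- diff(st[1:2])
  if (stride > tau + 1e-9)
    stop("snapshot stride (", stride, " ms) exceeds the embedding delay tau (",
         tau, " ms)")
  lag <- round(tau / stride)
  if (abs(lag * stride - tau) > 1e-6 * tau)
    tau <- lag * stride  # snap to the grid
  nt <- ncol(snaps)
  if (nt <= lag) stop("movie shorter than the embedding delay")
  idx <- (lag + 1L):nt
  ph <- atan2(snaps[, idx - lag, drop = FALSE] - V_star,
              snaps[, idx, drop = FALSE] - V_star)
  arr <- array(ph, dim = c(movie$nx, movie$ny, length(idx)))
  structure(list(phase = arr, t = st[idx], nx = movie$nx, ny = movie$ny,
                 dx = movie$dx), class = "phase_field")
}

.wrap_pi <- function(x) (x + pi) %% (2 * pi) - pi

#' Detect phase singularities by plaquette winding
#'
#' For every 2x2 plaquette the wrapped phase differences around the loop
#' are summed; a total of +/- 2*pi marks a phase singularity of that
#' topological charge, located at the plaquette centre.  Singularities
#' closer than `merge_dist` plaquettes are merged (same charge).
#'
#' @param phase a `phase_field`, or a numeric matrix of phases.
#' @param snapshot which time slice of a `phase_field` to analyse
#'   (default: the last).
#' @param merge_dist merge radius in grid units (default 2).
#' @return data.frame with columns `x`, `y` (grid units, plaquette-centre
#'   convention: node index + 0.5) and `charge` (+1/-1).
#' @export
detect_phase_singularities <- function(phase, snapshot = NULL,
                                       merge_dist = 2) {
  ph <- if (inherits(phase, "phase_field")) {
    if (is.null(snapshot)) snapshot <- dim(phase$phase)[3]
    phase$phase[, , snapshot]
  } else as.matrix(phase)
  nx <- nrow(ph); ny <- ncol(ph)
  a <- ph[-nx, -ny]; b <- ph[-1, -ny]; c <- ph[-1, -1]; d <- ph[-nx, -1]
  w <- .wrap_pi(b - a) + .wrap_pi(c - b) + .wrap_pi(d - c) + .wrap_pi(a - d)
  q <- round(w / (2 * pi))
  hits <- which(q != 0, arr.ind = TRUE)
  if (nrow(hits) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), charge = integer(0)))
  out <- data.frame(x = hits[, 1] + 0.5, y = hits[, 2] + 0.5,
                    charge = q[hits])
  # merge clusters of plaquettes closer than merge_dist (same singularity)
  if (nrow(out) > 1L) {
    dmat <- as.matrix(stats::dist(out[, c("x", "y")]))
    grp <- seq_len(nrow(out))
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(out))) {
        nb <- which(dmat[i, ] <= merge_dist & grp != grp[i] &
                      out$charge == out$charge[i])
        if (length(nb)) {
          grp[grp %in% grp[nb]] <- grp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    out <- do.call(rbind, lapply(split(out, grp), function(g)
      data.frame(x = mean(g$x), y = mean(g$y), charge = g$charge[1])))
    rownames(out) <- NULL
  }
  out
}

#' Phase-singularity count over time
#'
#' Runs the PS detector on every snapshot of a movie and summarizes the
#' count series (mean and RMS deviation).
#'
#' @param movie a `field_recording` with snapshots, or a `phase_field`.
#' @param ... passed to [phase_map()] when `movie` is a recording.
#' @return list with `t`, `count`, `mean`, `rms_dev`, and `ps` (list of
#'   per-snapshot data frames).
#' @export
ps_count_series <- function(movie, ...) {
  ph <- if (inherits(movie, "phase_field")) movie else phase_map(movie, ...)
  nt <- dim(ph$phase)[3]
  ps <- lapply(seq_len(nt), function(k)
    detect_phase_singularities(ph, snapshot = k))
  cnt <- vapply(ps, nrow, integer(1))
  list(t = ph$t, count = cnt, mean = mean(cnt),
       rms_dev = sqrt(mean((cnt - mean(cnt))^2)), ps = ps)
}

#' Count propagating wavefronts in a snapshot
#'
#' Wavefronts are connected components (8-connectivity) of the set of
#' nodes that are above `threshold` and depolarizing (V rising since the
#' previous snapshot).
#'
#' @param V voltage snapshot, `nx x ny` matrix, mV.
#' @param V_prev previous snapshot (same shape) used for the dV/dt > 0
#'   condition.
#' @param threshold wavefront threshold, mV (default -40).
#' @return number of wavefronts (integer).
#' @export
count_wavefronts <- function(V, V_prev, threshold = -40) {
  stopifnot(is.matrix(V), all(dim(V) == dim(V_prev)))
  mask <- (V > threshold) & (V - V_prev > 0)
  if (!any(mask)) return(0L)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  # bwlabel is 4-connected; merge labels touching diagonally (8-connectivity)
  nl <- max(lab)
  if (nl > 1L) {
    parent <- seq_len(nl)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    nx <- nrow(lab); ny <- ncol(lab)
    for (dd in list(c(1, 1), c(1, -1))) {
      a <- lab[seq_len(nx - 1), if (dd[2] > 0) seq_len(ny - 1) else 2:ny]
      b <- lab[2:nx, if (dd[2] > 0) 2:ny else seq_len(ny - 1)]
      touch <- which(a > 0 & b > 0 & a != b)
      for (k in touch) {
        ra <- find(a[k]); rb <- find(b[k])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
    nl <- length(unique(vapply(seq_len(nl), find, integer(1))))
  }
  as.integer(nl)
}

#' Period-surface container with monotone smoothing
#'
#' Gridded mapping (Ko, f_atp) -> VF period.  The stored surface is made
#' monotone (non-decreasing in Ko, non-increasing in f_atp) by alternating
#' isotonic regression along the two axes; the maximum adjustment applied
#' is recorded in attribute `monotone_adjustment` and violations beyond
#' `tol` are reported via message.
#'
#' @param Ko grid of extracellular potassium values, mM (increasing).
#' @param f_atp grid of open fractions, percent (increasing).
#' @param period matrix `length(Ko) x length(f_atp)` of periods, ms (NA =
#'   terminated run).
#' @param smooth apply the monotone projection (default TRUE).
#' @param tol adjustment size (ms) above which a message is emitted.
#' @param meta optional provenance metadata list.
#' @return an object of class `period_surface`.
#' @importFrom stats isoreg
#' @export
period_surface <- function(Ko, f_atp, period, smooth = TRUE, tol = 1,
                           meta = list()) {
  period <- as.matrix(period)
  stopifnot(nrow(period) == length(Ko), ncol(period) == length(f_atp),
            !is.unsorted(Ko), !is.unsorted(f_atp))
  if (any(period[!is.na(period)] <= 0)) stop("periods must be positive")
  adj <- 0
  if (smooth) {
    p0 <- period
    for (pass in 1:2) {
      for (j in seq_along(f_atp)) {   # non-decreasing in Ko
        ok <- !is.na(period[, j])
        if (sum(ok) > 1)
          period[ok, j] <- stats::isoreg(Ko[ok], period[ok, j])$yf
      }
      for (i in seq_along(Ko)) {      # non-increasing in f_atp
        ok <- !is.na(period[i, ])
        if (sum(ok) > 1)
          period[i, ok] <- -stats::isoreg(f_atp[ok], -period[i, ok])$yf
      }
    }
    adj <- max(abs(period - p0), na.rm = TRUE)
    if (adj > tol)
      message("period_surface: monotone smoothing moved values by up to ",
              signif(adj, 3), " ms")
  }
  structure(list(Ko = Ko, f_atp = f_atp, period = period, meta = meta),
            class = "period_surface", monotone_adjustment = adj)
}

#' @export
print.period_surface <- function(x, ...) {
  cat(sprintf("period surface: Ko %g-%g mM (%d) x f_atp %g-%g%% (%d), periods %.0f-%.0f ms\n",
              min(x$Ko), max(x$Ko), length(x$Ko), min(x$f_atp),
              max(x$f_atp), length(x$f_atp),
              min(x$period, na.rm = TRUE), max(x$period, na.rm = TRUE)))
  invisible(x)
}

#' Interpolant of a period surface
#'
#' Monotonicity-preserving piecewise-cubic interpolation (Fritsch-Carlson)
#' along each axis, tensored in two stages; partial derivatives are central
#' differences of the interpolant.
#'
#' @param surface a `period_surface` (must be NA-free; see
#'   [period_surface()]).
#' @return list of functions `T(Ko, f)`, `dT_dKo(Ko, f)`, `dT_df(Ko, f)`;
#'   arguments are clamped to the fitted domain.
#' @importFrom stats splinefun
#' @export
surface_interpolant <- function(surface) {
  stopifnot(inherits(surface, "period_surface"))
  if (any(is.na(surface$period)))
    stop("interpolation requires a complete (NA-free) surface")
  Ko <- surface$Ko; f <- surface$f_atp; P <- surface$period
  # stage 1: splines along Ko for each grid f
  along_Ko <- lapply(seq_along(f), function(j)
    stats::splinefun(Ko, P[, j], method = "monoH.FC"))
  Tfun <- function(K, ff) {
    n <- max(length(K), length(ff))
    K <- rep_len(pmin(max(Ko), pmax(min(Ko), K)), n)
    ff <- rep_len(pmin(max(f), pmax(min(f), ff)), n)
    vapply(seq_len(n), function(i) {
      vals <- vapply(along_Ko, function(s) s(K[i]), numeric(1))
      if (length(f) == 1L) vals[1]
      else stats::splinefun(f, vals, method = "monoH.FC")(ff[i])
    }, numeric(1))
  }
  hK <- 1e-4 * diff(range(Ko))
  hf <- 1e-4 * max(diff(range(f)), 1e-6)
  list(
    T = Tfun,
    dT_dKo = function(K, ff)
      (Tfun(pmin(max(Ko), K + hK), ff) - Tfun(pmax(min(Ko), K - hK), ff)) /
        (pmin(max(Ko), K + hK) - pmax(min(Ko), K - hK)),
    dT_df = function(K, ff)
      (Tfun(K, pmin(max(f), ff + hf)) - Tfun(K, pmax(min(f), ff - hf))) /
        (pmin(max(f), ff + hf) - pmax(min(f), ff - hf)),
    range_Ko = range(Ko), range_f = range(f))
}

#' Build a VF period surface by simulation
#'
#' For every grid point (Ko, f_atp): start from a saved multi-wave
#' fibrillation state, ramp the ischemia parameters over `ramp_ms`,
#' simulate `run_ms`, and measure the dominant period over the last
#' `analyze_ms` at a sublattice of probe nodes.  Runs in which activity
#' terminated are recorded as NA.
#'
#' @param grid_Ko,grid_f parameter grids.
#' @param fixture a `tissue_grid` holding the developed VF state (see
#'   [gen_vf_fixture()]).
#' @param run_ms simulated time per grid point, ms.
#' @param ramp_ms ischemia onset ramp, ms.
#' @param analyze_ms analysis window, ms.
#' @param n_probes approximate number of probe nodes (regular sublattice).
#' @param probe_dt probe sampling, ms.
#' @param dt time step, ms.
#' @return a `period_surface` (isotonic-smoothed) with provenance metadata.
#' @export
build_period_surface <- function(grid_Ko, grid_f, fixture, run_ms = 3000,
                                 ramp_ms = 500, analyze_ms = 2000,
                                 n_probes = 100, probe_dt = 2, dt = 0.02) {
  stopifnot(inherits(fixture, "tissue_grid"))
  probes <- .sublattice_probes(fixture, n_probes)
  P <- matrix(NA_real_, length(grid_Ko), length(grid_f))
  for (i in seq_along(grid_Ko)) for (j in seq_along(grid_f)) {
    g <- fixture
    rec <- run_protocol(g, duration = run_ms, probes = probes,
                        probe_dt = probe_dt, dt = dt,
                        ramp_to = ischemia(Ko = grid_Ko[i],
                                           f_atp = grid_f[j]),
                        ramp_window = c(0, ramp_ms))
    per <- dominant_period(rec, window_s = analyze_ms / 1000,
                           end_at_quiescence = TRUE)
    terminated <- isTRUE(attr(per, "quiescent")) ||
      attr(per, "active_until") < max(rec$t) - 200
    P[i, j] <- if (terminated) NA_real_ else per
  }
  if (mean(is.na(P)) > 0.5)
    stop("more than half of the grid points terminated; surface unusable")
  period_surface(grid_Ko, grid_f, P,
                 meta = list(nx = fixture$nx, ny = fixture$ny,
                             dx = fixture$dx, run_ms = run_ms,
                             ramp_ms = ramp_ms, analyze_ms = analyze_ms))
}

# regular sublattice of about n probe positions, as (x, y) cm matrix
.sublattice_probes <- function(grid, n) {
  k <- max(1L, round(sqrt(n)))
  xs <- seq(grid$dx * 2, (grid$nx - 2) * grid$dx, length.out = k)
  ys <- seq(grid$dx * 2, (grid$ny - 2) * grid$dx,
            length.out = max(1L, min(k, grid$ny - 4L)))
  as.matrix(expand.grid(x = xs, y = ys))
}
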