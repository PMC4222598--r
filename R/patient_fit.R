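#' Dominant-frequency recording container
#'
#' Clinical-style DF time series: time from fibrillation onset, the
#' across-electrode mean and standard deviation of the dominant frequency,
#' and the perfusion phase of each sample.  The protocol landmarks are
#' point A (ischemia onset, 30 s), point B (ischemia end, 180 s) and point
#' C (end of the reperfusion recording, 210 s).
#'
#' @param t time, s (strictly increasing).
#' @param df_mean mean DF, Hz (> 0).
#' @param df_sd electrode spread, Hz (default 0).
#' @param phase character/factor in `perfused`, `ischemia`, `reperfusion`;
#'   must be contiguous in that order.
#' @param landmarks list with `t_A`, `t_B`, `t_C` (s).
#' @return an object of class `df_recording` (a data.frame with metadata).
#' @export
df_recording <- function(t, df_mean, df_sd = 0, phase = NULL,
                         landmarks = list(t_A = 30, t_B = 180, t_C = 210)) {
  stopifnot(length(t) == length(df_mean))
  if (is.unsorted(t, strictly = TRUE)) stop("time must be strictly increasing")
  if (any(df_mean <= 0)) stop("df_mean must be positive")
  if (is.null(phase))
    phase <- cut(t, c(-Inf, landmarks$t_A, landmarks$t_B, Inf),
                 labels = c("perfused", "ischemia", "reperfusion"))
  phase <- as.character(phase)
  lev <- c("perfused", "ischemia", "reperfusion")
  if (!all(phase %in% lev)) stop("unknown phase label")
  r <- rle(phase)$values
  if (!identical(r, lev[lev %in% r]))
    stop("phases must be contiguous in the order perfused -> ischemia -> ",
         "reperfusion")
  out <- data.frame(t = t, df_mean = df_mean,
                    df_sd = rep_len(df_sd, length(t)), phase = phase)
  attr(out, "landmarks") <- landmarks
  class(out) <- c("df_recording", "data.frame")
  out
}

#' Moving-average smoothing of a DF recording
#'
#' Centred moving average of the mean DF over a `window_s` window (edges
#' use shrinking windows); the other columns are passed through.
#'
#' @param rec a `df_recording`.
#' @param window_s window length, s (default 1).
#' @return a `df_recording` with smoothed `df_mean`.
#' @export
smooth_df <- function(rec, window_s = 1) {
  stopifnot(inherits(rec, "df_recording"))
  if (nrow(rec) == 0L) stop("empty recording")
  dt <- if (nrow(rec) > 1L) min(diff(rec$t)) else window_s
  if (window_s < dt) stop("window shorter than the sample spacing")
  half <- window_s / 2
  sm <- vapply(seq_len(nrow(rec)), function(i) {
    w <- abs(rec$t - rec$t[i]) <= half + 1e-9
    mean(rec$df_mean[w])
  }, numeric(1))
  out <- rec
  out$df_mean <- sm
  out
}

# DF at a landmark time, averaged over +/- avg_s (protocol decision);
# restricted to a perfusion phase where the landmark is a phase boundary,
# so e.g. the point-B average never mixes in reperfusion samples
.df_at <- function(rec, t0, avg_s = 2, phase = NULL) {
  w <- abs(rec$t - t0) <= avg_s + 1e-9
  if (!is.null(phase)) w <- w & rec$phase == phase
  if (!any(w)) stop("landmark t = ", t0, " s outside the recording")
  mean(rec$df_mean[w])
}

#' Scale a period surface to a patient recording
#'
#' Multiplies all periods by `s = T_patient(anchor) / T_surface(baseline)`,
#' where the anchor is the recording's DF at point A (`"point_A"`, the
#' regular fit) or at the start of the recording (`"recording_start"`, the
#' alternative fit), and the surface baseline is (Ko = `baseline_Ko`,
#' f_atp = 0).
#'
#' @param surface a `period_surface`.
#' @param rec a `df_recording`.
#' @param anchor `"point_A"` or `"recording_start"`.
#' @param baseline_Ko baseline extracellular potassium, mM (default 5.4).
#' @return the scaled `period_surface`, with attribute `scale_factor`.
#' @export
scale_surface <- function(surface, rec, anchor = c("point_A",
                                                   "recording_start"),
                          baseline_Ko = 5.4) {
  anchor <- match.arg(anchor)
  lm <- attr(rec, "landmarks")
  t_anchor <- if (anchor == "point_A") lm$t_A else rec$t[1]
  T_pat <- 1000 / .df_at(rec, t_anchor)
  itp <- surface_interpolant(surface)
  T_base <- itp$T(baseline_Ko, 0)
  s <- T_pat / T_base
  out <- period_surface(surface$Ko, surface$f_atp, surface$period * s,
                        smooth = FALSE, meta = surface$meta)
  attr(out, "scale_factor") <- s
  attr(out, "anchor") <- anchor
  out
}

# monotone bisection for T(K, f fixed) = target (increasing in K) or
# T(K fixed, f) = target (decreasing in f); returns value + clamped flag
.solve_Ko <- function(itp, f, target, tol = 1e-4) {
  lo <- itp$range_Ko[1]; hi <- itp$range_Ko[2]
  Tlo <- itp$T(lo, f); Thi <- itp$T(hi, f)
  if (Thi < Tlo) stop("surface slice not increasing in Ko")
  if (target <= Tlo) return(structure(lo, clamped = target < Tlo * (1 - tol)))
  if (target >= Thi) return(structure(hi, clamped = target > Thi * (1 + tol)))
  r <- stats::uniroot(function(K) itp$T(K, f) - target, c(lo, hi),
                      tol = tol * (hi - lo))
  structure(r$root, clamped = FALSE)
}
.solve_f <- function(itp, K, target, tol = 1e-4) {
  lo <- itp$range_f[1]; hi <- itp$range_f[2]
  Tlo <- itp$T(K, lo); Thi <- itp$T(K, hi)
  if (Thi > Tlo) stop("surface slice not decreasing in f_atp")
  if (target >= Tlo) return(structure(lo, clamped = target > Tlo * (1 + tol)))
  if (target <= Thi) return(structure(hi, clamped = target < Thi * (1 - tol)))
  r <- stats::uniroot(function(f) itp$T(K, f) - target, c(lo, hi),
                      tol = tol * max(hi - lo, 1e-9))
  structure(r$root, clamped = FALSE)
}

#' Three-point estimate of hyperkalemia and hypoxia
#'
#' Estimates the extracellular potassium `K_B` and open ATP-channel
#' fraction `f_B` at the end of ischemia (point B) from the DF at points
#' A, B and C, under the reperfusion assumption that potassium has
#' returned to baseline by point C while the ATP channels have recovered
#' only by `recovery_fraction`:
#' solve `T(K_baseline, f_C) = 1/DF_C` for `f_C`, set
#' `f_B = f_C / (1 - recovery_fraction)`, then solve
#' `T(K_B, f_B) = 1/DF_B` for `K_B` (monotone bisection on the scaled
#' surface).
#'
#' @param rec a `df_recording`.
#' @param surface an *unscaled* `period_surface` (scaling is applied
#'   according to `anchor`).
#' @param recovery_fraction fraction of ATP channels recovered by point C
#'   (0, 0.25 or 0.5).
#' @param anchor scaling anchor, see [scale_surface()].
#' @param baseline_Ko baseline potassium, mM.
#' @param avg_s half-width of the landmark averaging window, s.
#' @return a `fit_result` list: `K_B`, `f_B`, `f_C`, `f_A`, scale factor,
#'   clamp flags, and the inputs used.
#' @export
three_point_fit <- function(rec, surface, recovery_fraction = 0,
                            anchor = c("point_A", "recording_start"),
                            baseline_Ko = 5.4, avg_s = 2) {
  anchor <- match.arg(anchor)
  stopifnot(recovery_fraction >= 0, recovery_fraction < 1)
  lm <- attr(rec, "landmarks")
  ssc <- scale_surface(surface, rec, anchor, baseline_Ko)
  itp <- surface_interpolant(ssc)
  DF_A <- .df_at(rec, lm$t_A, avg_s)
  DF_B <- .df_at(rec, lm$t_B, avg_s, phase = "ischemia")
  DF_C <- .df_at(rec, lm$t_C, avg_s, phase = "reperfusion")
  # alternative anchor: channels may already be open at point A
  f_A <- if (anchor == "recording_start") {
    fa <- .solve_f(itp, baseline_Ko, 1000 / DF_A)
    as.numeric(fa)
  } else 0
  f_C <- .solve_f(itp, baseline_Ko, 1000 / DF_C)
  f_B <- as.numeric(f_C) / (1 - recovery_fraction)
  K_B <- .solve_Ko(itp, f_B, 1000 / DF_B)
  clamped <- isTRUE(attr(f_C, "clamped")) || isTRUE(attr(K_B, "clamped"))
  if (clamped)
    warning("target period outside the scaled surface range; ",
            "estimate clamped to the surface boundary")
  structure(list(K_B = as.numeric(K_B), f_B = f_B, f_C = as.numeric(f_C),
                 f_A = f_A, recovery_fraction = recovery_fraction,
                 anchor = anchor, scale_factor = attr(ssc, "scale_factor"),
                 baseline_Ko = baseline_Ko, clamped = clamped,
                 DF = c(A = DF_A, B = DF_B, C = DF_C),
                 surface_scaled = ssc),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit (%s anchor, %.0f%% recovery): K_B = %.2f mM, f_B = %.3f%%%s\n",
              x$anchor, 100 * x$recovery_fraction, x$K_B, x$f_B,
              if (x$clamped) " [clamped]" else ""))
  invisible(x)
}

#' Constrained trajectory fit of hyperkalemia and hypoxia during ischemia
#'
#' Recovers monotone trajectories K(t), f(t) on the ischemia interval from
#' the smoothed patient period T(t) = 1/DF(t), the scaled period surface,
#' and the point-B targets from [three_point_fit()].  The chain rule
#' \deqn{dT/dt = (\partial T/\partial K) dK/dt + (\partial T/\partial f) df/dt}
#' is closed with the equal-relative-approach constraint
#' \deqn{\frac{dK/dt}{K_B - K + \epsilon} = \frac{df/dt}{f_B - f + \epsilon}}
#' which drives both components toward their point-B values.  Rates are
#' clamped at zero to enforce monotonicity; steps where the closure
#' denominator crosses zero are clamped and counted.
#'
#' @param rec a `df_recording`.
#' @param fit a `fit_result` from [three_point_fit()] (carries the scaled
#'   surface, anchor and baseline).
#' @param smooth_window_s smoothing window for the DF series, s.
#' @param eps closure regularizer (default 1e-3).
#' @return a `fit_result` extended with `trajectories` (data.frame `t`,
#'   `Ko`, `f_atp`, `T_fit`), `clamp_fraction`, and a `quality_warning`
#'   flag when more than 10% of steps were clamped.
#' @export
fit_trajectories <- function(rec, fit, smooth_window_s = 1, eps = 1e-3) {
  stopifnot(inherits(fit, "fit_result"))
  lm <- attr(rec, "landmarks")
  sm <- smooth_df(rec, smooth_window_s)
  isc <- sm[sm$t >= lm$t_A & sm$t <= lm$t_B, ]
  if (nrow(isc) < 3L) stop("too few ischemia-phase samples")
  itp <- surface_interpolant(fit$surface_scaled)
  Tpat <- 1000 / isc$df_mean
  tt <- isc$t
  n <- length(tt)
  K <- numeric(n); f <- numeric(n)
  K[1] <- fit$baseline_Ko
  f[1] <- fit$f_A
  clamp_n <- 0L
  for (i in seq_len(n - 1L)) {
    dTdt <- (Tpat[i + 1L] - Tpat[i]) / (tt[i + 1L] - tt[i])
    gK <- itp$dT_dKo(K[i], f[i])
    gf <- itp$dT_df(K[i], f[i])
    wK <- fit$K_B - K[i] + eps
    wf <- fit$f_B - f[i] + eps
    den <- gK * wK + gf * wf
    lam <- if (abs(den) < 1e-12) { clamp_n <- clamp_n + 1L; 0 }
           else dTdt / den
    if (lam < 0) { clamp_n <- clamp_n + 1L; lam <- 0 }
    dtl <- tt[i + 1L] - tt[i]
    K[i + 1L] <- min(max(K[i] + lam * wK * dtl, K[i]), itp$range_Ko[2])
    f[i + 1L] <- min(max(f[i] + lam * wf * dtl, f[i]), itp$range_f[2])
  }
  out <- fit
  out$trajectories <- data.frame(t = tt, Ko = K, f_atp = f,
                                 T_fit = itp$T(K, f),
                                 T_patient = Tpat)
  out$clamp_fraction <- clamp_n / (n - 1L)
  out$quality_warning <- out$clamp_fraction > 0.1
  if (out$quality_warning)
    warning(sprintf("%.0f%% of trajectory steps were clamped",
                    100 * out$clamp_fraction))
  out
}

#' Fit a cohort of DF recordings
#'
#' Runs the three-point fit for every recovery fraction under the regular
#' anchor, plus the alternative anchor at zero recovery, and the trajectory
#' fit for the regular zero-recovery case, for each recording.  Failures
#' are isolated per recording.
#'
#' @param recordings named list of `df_recording`s.
#' @param surface an unscaled `period_surface`.
#' @param recovery_fractions recovery variants for the regular fit.
#' @param trajectories also run [fit_trajectories()] (regular, 0 recovery).
#' @param ... passed to [three_point_fit()].
#' @return list with `table` (one row per recording: K_B/f_B per variant)
#'   and `fits` (per-recording list of `fit_result`s; failed recordings
#'   carry the error condition).
#' @export
fit_cohort <- function(recordings, surface,
                       recovery_fractions = c(0, 0.25, 0.5),
                       trajectories = FALSE, ...) {
  if (is.null(names(recordings)))
    names(recordings) <- sprintf("P%03d", seq_along(recordings))
  fits <- list(); rows <- list()
  for (nm in names(recordings)) {
    rec <- recordings[[nm]]
    res <- tryCatch({
      per <- lapply(recovery_fractions, function(r)
        three_point_fit(rec, surface, recovery_fraction = r,
                        anchor = "point_A", ...))
      alt <- three_point_fit(rec, surface, recovery_fraction = 0,
                             anchor = "recording_start", ...)
      traj <- if (trajectories) fit_trajectories(rec, per[[1]]) else NULL
      list(regular = per, alternative = alt, trajectories = traj)
    }, error = function(e) e)
    fits[[nm]] <- res
    if (inherits(res, "error")) {
      rows[[nm]] <- NULL
      next
    }
    vals <- unlist(lapply(res$regular, function(f) c(f$K_B, f$f_B)))
    row <- data.frame(patient = nm, t(vals),
                      alt_K_B = res$alternative$K_B,
                      alt_f_B = res$alternative$f_B)
    names(row)[2:(1 + 2 * length(recovery_fractions))] <-
      as.vector(rbind(sprintf("K_B_%g", recovery_fractions),
                      sprintf("f_B_%g", recovery_fractions)))
    rows[[nm]] <- row
  }
  tab <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(tab)) rownames(tab) <- NULL
  failed <- names(Filter(function(x) inherits(x, "error"), fits))
  if (length(failed))
    warning("fit failed for: ", paste(failed, collapse = ", "))
  list(table = tab, fits = fits)
}
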