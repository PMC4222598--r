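#' S1S2 APD restitution on a thin tissue strip
#'
#' Classic S1S2 protocol: `n_s1` conditioning stimuli at `bcl` delivered
#' along one short edge of a pseudo-1D strip, followed by a single S2 whose
#' coupling interval is decremented (coarse step, refined near conduction
#' block).  For every captured S2 the diastolic interval (DI) and APD are
#' measured at a site `measure_x` from the stimulated edge: DI is the
#' interval from the APD90 end of the last S1 response to the S2 upstroke
#' at that site.
#'
#' The strip is simulated once up to the last S1; each S2 restarts from the
#' saved post-S1 state, so the cost is linear in the number of S2 values.
#'
#' @param params `ionic_params`.
#' @param isch `ischemia_params`.
#' @param length_cm strip length, cm (>= 5).
#' @param width_nodes strip thickness in nodes (3 behaves as pseudo-1D; 1
#'   gives a true cable).
#' @param measure_x measurement site, cm from the stimulated edge.
#' @param bcl S1 cycle length, ms.
#' @param n_s1 number of S1 stimuli.
#' @param s2_max,s2_coarse,s2_fine S2 coupling schedule, ms: decremented
#'   from `s2_max` by `s2_coarse` until block, then refined by `s2_fine`.
#' @param level repolarization fraction for APD (default 0.9).
#' @param dx,D,dt grid and solver settings.
#' @param cv_probes if TRUE also measure the S2 conduction velocity
#'   between probes bracketing the measurement site (for [cv_dispersion()]).
#' @return a `restitution_curve`: data.frame `points` with columns `DI`,
#'   `APD` (and `CV`, `CL = DI + APD` when `cv_probes`), plus protocol
#'   metadata.
#' @export
s1s2_apd_restitution <- function(params = tp06_params(), isch = ischemia(),
                                 length_cm = 6, width_nodes = 1,
                                 measure_x = 2.5, bcl = 1000, n_s1 = 10,
                                 s2_max = 1000, s2_coarse = 20, s2_fine = 5,
                                 level = 0.9, dx = 0.025, D = 1.54,
                                 dt = 0.02, cv_probes = TRUE) {
  stopifnot(length_cm >= 5)
  nx <- round(length_cm / dx)
  grid <- tissue_grid(nx, width_nodes, dx = dx, D = D, params = params,
                      isch = isch)
  probes <- c(measure_x - 0.25, measure_x, measure_x + 0.25)
  s1_onsets <- 5 + bcl * (seq_len(n_s1) - 1)
  t_last_s1 <- s1_onsets[n_s1]
  stims <- lapply(s1_onsets, function(on) stimulus(on, x = c(0, 0.1)))

  # conditioning train: checkpoint right after the last S1 stimulus ends,
  # so every S2 coupling interval can be replayed from the same state
  cond <- run_protocol(grid, stims, duration = t_last_s1 + 2, probe_dt = 0,
                       dt = dt)
  base <- cond$grid  # t = t_last_s1 + 2; last S1 wave under way

  # reference continuation: the last S1 response at the measurement site
  mcol <- 2L
  ref <- run_protocol(base, list(), duration = 700, probes = probes,
                      probe_dt = 0.25, dt = dt)
  s1_apd_all <- measure_apd(list(t = ref$t, V = ref$V[, mcol]),
                            level = level)
  if (length(s1_apd_all) == 0L)
    stop("S1 train failed to propagate to the measurement site")
  s1_up <- .upstroke_time(ref$t, ref$V[, mcol], beat = 1)
  s1_apd <- s1_apd_all[1]
  s1_end <- s1_up + s1_apd
  s1_cv <- measure_cv(ref, probes[1], probes[3], beat = 1)

  # checkpoint the quiescent wait between the last S1 and each S2 once, so
  # a replay at coupling ci costs only the post-S2 segment
  wait_states <- new.env(parent = emptyenv())
  assign("g0", base, envir = wait_states)
  wait_upto <- function(ci) {
    key <- sprintf("g%d", ci)
    if (!exists(key, envir = wait_states, inherits = FALSE)) {
      done <- sort(as.integer(sub("^g", "", ls(wait_states))))
      from <- max(done[done <= ci])
      g <- get(sprintf("g%d", from), envir = wait_states)
      if (ci > from)
        g <- run_protocol(g, list(),
                          duration = (t_last_s1 + ci) - g$t,
                          probe_dt = 0, dt = dt)$grid
      assign(key, g, envir = wait_states)
    }
    get(key, envir = wait_states, inherits = FALSE)
  }

  run_s2 <- function(ci) {
    s2_on <- t_last_s1 + ci
    rec <- run_protocol(wait_upto(ci), stimulus(s2_on, x = c(0, 0.1)),
                        duration = 700, probes = probes, probe_dt = 0.25,
                        dt = dt)
    v <- rec$V[, mcol]
    apds <- measure_apd(list(t = rec$t, V = v), level = level)
    if (length(apds) == 0L) return(NULL)   # S2 blocked before the site
    # the S2 response is the last depolarization of the replay, and must
    # postdate the S2 stimulus (a leading segment of the still-repolarizing
    # S1 response can otherwise be counted)
    up <- .upstroke_time(rec$t, v, beat = Inf)
    if (is.na(up) || up <= s2_on + 1) return(NULL)
    di <- up - s1_end
    if (di < 0) return(NULL)  # S2 arrived before local repolarization
    cv <- if (cv_probes) {
      r2 <- list(t = rec$t, V = rec$V[, c(1L, 3L), drop = FALSE],
                 probes = probes[c(1L, 3L)], dx = dx)
      class(r2) <- "field_recording"
      measure_cv(r2, probes[1], probes[3], beat = Inf)
    } else NA_real_
    data.frame(DI = di, APD = apds[length(apds)], CV = cv, S2 = ci)
  }

  # one ascending pass fills the coarse-coupling checkpoints (~1 s of
  # quiescent tissue simulated once instead of per replay)
  invisible(lapply(sort(seq(s2_max, 50, by = -s2_coarse)), wait_upto))

  pts <- list()
  ci <- s2_max
  last_captured <- NA_real_
  while (ci >= 50) {
    row <- run_s2(ci)
    if (is.null(row)) break
    pts[[length(pts) + 1L]] <- row
    last_captured <- ci
    ci <- ci - s2_coarse
  }
  if (!is.na(last_captured)) {
    # refine on both sides of the block: below the last captured coarse
    # coupling (to locate block) and through the steep segment just above it
    fine <- c(seq(last_captured - s2_fine,
                  max(50, last_captured - s2_coarse + s2_fine),
                  by = -s2_fine),
              seq(last_captured + s2_fine,
                  min(s2_max, last_captured + s2_coarse - s2_fine),
                  by = s2_fine))
    for (cf in fine) {
      row <- run_s2(cf)
      if (is.null(row)) next
      pts[[length(pts) + 1L]] <- row
    }
  }
  if (length(pts) == 0L) stop("no S2 was captured at the measurement site")
  curve <- do.call(rbind, pts)
  # keep the functional branch: near block, decrementally conducting S2
  # waves can arrive so much later that the site DI stops decreasing with
  # the coupling interval; those reversed points are not part of the
  # APD(DI) relation and are dropped (recorded in the metadata)
  curve <- curve[order(curve$S2, decreasing = TRUE), ]
  keep <- rep(TRUE, nrow(curve))
  di_min <- Inf
  for (k in seq_len(nrow(curve))) {
    if (curve$DI[k] < di_min) di_min <- curve$DI[k] else keep[k] <- FALSE
  }
  n_reversed <- sum(!keep)
  curve <- curve[keep, ]
  curve$CL <- curve$DI + curve$APD
  curve <- curve[order(curve$DI), ]
  rownames(curve) <- NULL
  structure(list(points = curve,
                 meta = list(bcl = bcl, n_s1 = n_s1, measure_x = measure_x,
                             level = level, isch = unclass(isch),
                             slope_variant = params$slope_variant,
                             s1_apd = s1_apd[length(s1_apd)],
                             s1_cv = s1_cv, dx = dx, D = D,
                             n_reversed = n_reversed)),
            class = "restitution_curve")
}

#' Conduction-velocity dispersion relation
#'
#' Same S1S2 harness as [s1s2_apd_restitution()]; returns the S2 wave's
#' conduction velocity against the preceding cycle length `CL = DI + APD`
#' at the measurement site.  Points where the S2 blocked are omitted (the
#' attempted coupling intervals are in the metadata).
#'
#' @inheritParams s1s2_apd_restitution
#' @return a `restitution_curve` whose `points` carry `CL` and `CV`.
#' @export
cv_dispersion <- function(params = tp06_params(), isch = ischemia(), ...) {
  out <- s1s2_apd_restitution(params, isch, cv_probes = TRUE, ...)
  out$points <- out$points[!is.na(out$points$CV), ]
  out
}

#' @export
print.restitution_curve <- function(x, ...) {
  cat(sprintf("restitution curve: %d points, DI %.0f-%.0f ms, APD %.0f-%.0f ms\n",
              nrow(x$points), min(x$points$DI), max(x$points$DI),
              min(x$points$APD), max(x$points$APD)))
  invisible(x)
}

#' Maximal slope of a restitution curve
#'
#' Maximum centred finite difference d(APD)/d(DI) over the curve (one-sided
#' at the ends).
#'
#' @param curve a `restitution_curve`, or a data.frame with `DI` and `APD`.
#' @return dimensionless slope (scalar).
#' @export
max_slope <- function(curve) {
  pts <- if (inherits(curve, "restitution_curve")) curve$points else curve
  pts <- pts[order(pts$DI), ]
  n <- nrow(pts)
  if (n < 3L) stop("slope estimation needs at least 3 points")
  di <- pts$DI; apd <- pts$APD
  sl <- (apd[3:n] - apd[1:(n - 2)]) / (di[3:n] - di[1:(n - 2)])
  max(sl)
}

#' Minimal APD of a restitution curve
#'
#' APD of the smallest-DI captured point (the left-most point of the
#' curve), a key determinant of the period of fibrillation.
#'
#' @param curve a `restitution_curve` or data.frame with `DI`, `APD`.
#' @return APD_min, ms.
#' @export
apd_min <- function(curve) {
  pts <- if (inherits(curve, "restitution_curve")) curve$points else curve
  if (nrow(pts) == 0L) stop("empty restitution curve")
  pts$APD[which.min(pts$DI)]
}
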