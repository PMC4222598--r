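#' @useDynLib ischvf, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats uniroot
NULL

# state vector layout used by the C++ core
.state_names <- c("V", "m", "h", "j", "d", "f", "f2", "fCass", "r", "s",
                  "xr1", "xr2", "xs", "Nai", "Ki", "Cai", "CaSS", "CaSR",
                  "Rbar")

#' TP06 ionic parameter set (epicardial) with restitution-slope presets
#'
#' Returns the maximal conductances and pump/exchanger parameters of the
#' ten Tusscher-Panfilov 2006 human ventricular epicardial cell model,
#' with the five-parameter quintet (`GKr`, `GKs`, `GpCa`, `GpK` and the
#' plateau `tau_f` factor) set to one of the base model's restitution-slope
#' presets.  The `slope` label names the maximal S1S2 APD-restitution slope
#' the preset produces under normal conditions.
#'
#' @param slope one of 1.1, 1.4, 1.8 (numeric); preset selecting the quintet.
#' @param g0_katp scaling coefficient of the ATP-sensitive potassium current
#'   per percent of open channels (pA/pF per mV driving force, folded);
#'   the default is the package calibration at which 0.05% open channels
#'   halve the steady-state APD90 at 1 Hz (see [calibrate_g0()]).
#' @return an object of class `ionic_params` (named list of parameters).
#' @examples
#' p <- tp06_params(slope = 1.1)
#' p$GKr
#' @export
tp06_params <- function(slope = 1.1, g0_katp = NULL) {
  slope <- as.numeric(slope)
  if (!slope %in% c(1.1, 1.4, 1.8))
    stop("slope must be one of 1.1, 1.4, 1.8")
  # base-model defaults are the steep set (slope 1.8); the flatter presets
  # raise the sarcolemmal calcium pump and lower the plateau potassium pump
  p <- list(
    GNa = 14.838, GK1 = 5.405, Gto = 0.294, GKr = 0.153, GKs = 0.392,
    GCaL = 3.98e-5, GbNa = 0.00029, GbCa = 0.000592, GpK = 0.0146,
    GpCa = 0.1238, PNaK = 2.724, kNaCa = 1000, taufmult = 1.0,
    g0katp = if (is.null(g0_katp)) .g0_katp_default else g0_katp,
    slope_variant = slope, cell_type = "epicardial")
  if (slope == 1.4) {
    p$GKr <- 0.172; p$GKs <- 0.441; p$GpCa <- 0.3714; p$GpK <- 0.00730
  } else if (slope == 1.1) {
    p$GKr <- 0.172; p$GKs <- 0.441; p$GpCa <- 0.8666; p$GpK <- 0.00219
    p$taufmult <- 0.5
  }
  structure(p, class = "ionic_params")
}

# default I_KATP scaling; value produced by calibrate_g0(tp06_params(1.1))
# at the 0.05% calibration fraction (APD90 halving at 1 Hz); frozen here so
# ordinary use does not re-run the calibration.
.g0_katp_default <- 16.713

#' Ischemia parameterization (hyperkalemia, acidosis, hypoxia)
#'
#' The three ischemia components applied to the cell model: extracellular
#' potassium `Ko` (hyperkalemia, 5-12 mM), a dimensionless `acidosis` factor
#' scaling the fast sodium and L-type calcium maximal conductances
#' (0.2-1.0), and the percentage `f_atp` of open ATP-sensitive potassium
#' channels (hypoxia).  Values outside the modeled ranges are retained with
#' a warning.
#'
#' @param Ko extracellular potassium, mM.
#' @param acidosis scaling of `GNa` and `GCaL`, dimensionless in (0, 1].
#' @param f_atp fraction of open ATP-sensitive channels, percent.
#' @return an object of class `ischemia_params`.
#' @examples
#' ischemia()                      # normal conditions
#' ischemia(Ko = 9, f_atp = 0.03)
#' @export
ischemia <- function(Ko = 5.4, acidosis = 1.0, f_atp = 0.0) {
  stopifnot(is.finite(Ko), is.finite(acidosis), is.finite(f_atp))
  if (Ko <= 0) stop("Ko must be positive")
  if (f_atp < 0) stop("f_atp must be non-negative")
  if (acidosis <= 0) stop("acidosis factor must be positive")
  if (Ko < 5 || Ko > 12)
    warning("Ko = ", Ko, " mM is outside the modeled hyperkalemia range ",
            "(5-12 mM); value retained")
  if (acidosis < 0.2 || acidosis > 1)
    warning("acidosis factor ", acidosis, " is outside the modeled range ",
            "(0.2-1.0); value retained")
  if (f_atp > 0.3)
    warning("f_atp = ", f_atp, "% is far above the fractions the model was ",
            "exercised at (< 0.3%); value retained")
  structure(list(Ko = Ko, acidosis = acidosis, f_atp = f_atp),
            class = "ischemia_params")
}

#' Nernst potential for potassium
#'
#' @param Ko extracellular potassium, mM.
#' @param Ki intracellular potassium, mM.
#' @return equilibrium potential, mV, at 310 K.
#' @examples
#' nernst_potassium(5.4, 138)  # about -86.6 mV
#' @export
nernst_potassium <- function(Ko, Ki) {
  if (any(Ko <= 0) || any(Ki <= 0))
    stop("concentrations must be positive")
  26.713760659695648 * log(Ko / Ki)
}

#' ATP-sensitive potassium current density
#'
#' Outward potassium current carried by ATP-sensitive channels, activated by
#' hypoxia.  The current scales linearly with the open fraction `f_atp` and
#' the coefficient `g0`, has a power dependence on extracellular potassium,
#' an exponential voltage factor, and a driving term referenced to the
#' potassium Nernst potential:
#' \deqn{I_{KATP} = g_0 f (K_o/5.4)^{0.3} (V - E_K) / (40 + 3.5 e^{0.025 V})}
#'
#' @param V membrane potential, mV.
#' @param Ko extracellular potassium, mM.
#' @param Ki intracellular potassium, mM.
#' @param f_atp open-channel fraction, percent.
#' @param g0 scaling coefficient (default: package calibration).
#' @return current density, pA/pF (positive = outward).
#' @export
i_katp <- function(V, Ko, Ki, f_atp, g0 = .g0_katp_default) {
  if (any(Ko <= 0) || any(Ki <= 0)) stop("concentrations must be positive")
  if (any(f_atp < 0)) stop("f_atp must be non-negative")
  EK <- nernst_potassium(Ko, Ki)
  g0 * f_atp * (Ko / 5.4)^0.3 * (V - EK) / (40 + 3.5 * exp(0.025 * V))
}

#' Apply an ischemia parameterization to an ionic parameter set
#'
#' Returns the parameter set with `GNa` and `GCaL` scaled by the acidosis
#' factor, and the extracellular environment (`Ko`, `f_atp`) attached.  All
#' other parameters are untouched.  The simulation drivers take the
#' components separately; this helper materializes the combined effective
#' set for inspection.
#'
#' @param base an `ionic_params` object.
#' @param isch an `ischemia_params` object.
#' @return an `ionic_params` object with fields `GNa`, `GCaL` scaled and
#'   `Ko`, `f_atp` recorded.
#' @export
apply_ischemia <- function(base, isch) {
  stopifnot(inherits(base, "ionic_params"), inherits(isch, "ischemia_params"))
  out <- base
  out$GNa <- base$GNa * isch$acidosis
  out$GCaL <- base$GCaL * isch$acidosis
  out$Ko <- isch$Ko
  out$f_atp <- isch$f_atp
  out
}

#' Initial (resting) cell state
#'
#' TP06 initial conditions for an epicardial cell at normal extracellular
#' potassium; a close approximation of the resting steady state.
#'
#' @return a named numeric vector of length 19 (class `cell_state`).
#' @export
cell_state <- function() {
  s <- c(V = -86.2, m = 0.0, h = 0.75, j = 0.75, d = 0.0, f = 1.0, f2 = 1.0,
         fCass = 1.0, r = 0.0, s = 1.0, xr1 = 0.0, xr2 = 1.0, xs = 0.0,
         Nai = 7.67, Ki = 138.3, Cai = 7e-5, CaSS = 7e-5, CaSR = 1.3,
         Rbar = 1.0)
  class(s) <- "cell_state"
  s
}

.as_state <- function(s) {
  s <- unclass(s)
  if (length(s) != 19L) stop("a cell state has 19 components")
  storage.mode(s) <- "double"
  s
}

#' Validate cell-state invariants
#'
#' Gates in \[0, 1\], concentrations positive, V within \[-120, 80\] mV.
#' @param s a cell state vector.
#' @return TRUE invisibly; stops on violation.
#' @export
check_cell_state <- function(s) {
  s <- .as_state(s)
  gates <- s[2:13]
  if (any(!is.finite(s))) stop("non-finite component in cell state")
  if (any(gates < -1e-12) || any(gates > 1 + 1e-12))
    stop("gating variable outside [0, 1]")
  if (any(s[14:18] <= 0)) stop("non-positive concentration")
  if (s[1] < -120 || s[1] > 80) stop("membrane potential outside [-120, 80] mV")
  invisible(TRUE)
}

#' Total ionic current at a state
#'
#' Sum of all TP06 currents plus the ATP-sensitive potassium current,
#' evaluated at the given state.  Positive is outward (repolarizing).
#'
#' @param state cell state vector.
#' @param params `ionic_params`.
#' @param isch `ischemia_params`.
#' @param breakdown if TRUE return the full named list of currents.
#' @return total current density in pA/pF, or a named list.
#' @export
total_ionic_current <- function(state, params = tp06_params(),
                                isch = ischemia(), breakdown = FALSE) {
  state <- .as_state(state)
  if (any(!is.finite(state)))
    stop("NaN/Inf in cell state: ", paste(signif(state, 4), collapse = " "))
  cur <- ionic_currents_cpp(state, params, isch)
  if (breakdown) cur else cur$total
}

#' Advance a cell one (or more) explicit time steps
#'
#' Gates are updated with the Rush-Larsen exponential scheme; voltage and
#' concentrations with forward Euler.
#'
#' @param state cell state vector.
#' @param I_stim stimulus current density, pA/pF (negative depolarizes).
#' @param dt time step, ms (must be <= 0.02).
#' @param params,isch model parameters.
#' @param nsteps number of steps to take.
#' @return the advanced cell state.
#' @export
step_cell <- function(state, I_stim = 0, dt = 0.02, params = tp06_params(),
                      isch = ischemia(), nsteps = 1L) {
  if (dt > 0.02 + 1e-12) stop("dt must be <= 0.02 ms")
  out <- step_cell_cpp(.as_state(state), I_stim, dt, params, isch,
                       as.integer(nsteps))
  names(out) <- .state_names
  class(out) <- "cell_state"
  check_cell_state(out)
  out
}

#' Run a paced single cell and record the voltage trace
#'
#' Applies `n_beats` stimuli of the configured amplitude/duration at cycle
#' length `bcl` and records the membrane potential.
#'
#' @param params `ionic_params`.
#' @param isch `ischemia_params`.
#' @param bcl basic cycle length, ms.
#' @param n_beats number of stimuli.
#' @param dt integration step, ms.
#' @param stim_amp stimulus amplitude, pA/pF (default -52, about twice
#'   threshold).
#' @param stim_dur stimulus duration, ms.
#' @param record_dt sampling interval of the returned trace, ms.
#' @param tail_ms extra time simulated after the last beat, ms.
#' @param state0 starting state (default [cell_state()]).
#' @param use_lut serve voltage-dependent rates from look-up tables.
#' @return a `voltage_trace`: list with `t` (ms), `V` (mV), `stim_times`,
#'   the final `state`, and a `no_ap` flag if a stimulus failed to elicit an
#'   action potential.
#' @export
run_paced_cell <- function(params = tp06_params(), isch = ischemia(),
                           bcl = 1000, n_beats = 10, dt = 0.02,
                           stim_amp = -52, stim_dur = 1, record_dt = 0.2,
                           tail_ms = NULL, state0 = cell_state(),
                           use_lut = TRUE) {
  stopifnot(bcl > 0, n_beats >= 1)
  if (is.null(tail_ms)) tail_ms <- bcl
  onsets <- 50 + bcl * (seq_len(n_beats) - 1)
  duration <- max(onsets) + tail_ms
  res <- run_cell_cpp(.as_state(state0), params, isch, dt, duration,
                      onsets, stim_dur, stim_amp, record_dt,
                      use_lut = use_lut)
  st <- res$state
  names(st) <- .state_names
  class(st) <- "cell_state"
  tr <- list(t = res$t, V = res$V, stim_times = onsets, state = st)
  # flag stimuli that elicited no action potential (V never crosses -20 mV
  # within one cycle of the stimulus)
  no_ap <- vapply(onsets, function(on) {
    w <- tr$t >= on & tr$t < on + min(bcl, 600)
    !any(tr$V[w] > -20)
  }, logical(1))
  tr$no_ap <- any(no_ap)
  if (tr$no_ap)
    warning("at least one stimulus elicited no action potential")
  class(tr) <- "voltage_trace"
  tr
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat("voltage trace:", length(x$t), "samples,",
      round(max(x$t) - min(x$t)), "ms,",
      length(x$stim_times), "stimuli\n")
  invisible(x)
}

#' Measure action potential durations from a voltage trace
#'
#' For each action potential the APD is the time from the fastest upstroke
#' to the crossing of `V_rest + (1 - level) * (V_peak - V_rest)` during
#' repolarization, where `V_rest` is the potential just before the upstroke
#' and `V_peak` the maximum of that action potential.  The default
#' `level = 0.9` gives APD90.
#'
#' @param trace a `voltage_trace`, or a list with numeric `t` and `V`.
#' @param level repolarization fraction in (0, 1); default 0.9.
#' @param thresh detection threshold, mV: an AP is an excursion above this.
#' @return numeric vector of APDs, ms (empty if no AP).
#' @export
measure_apd <- function(trace, level = 0.9, thresh = -20) {
  stopifnot(level > 0, level < 1)
  t <- trace$t; V <- trace$V
  n <- length(t)
  if (n < 3L || !any(V > thresh)) return(numeric(0))
  above <- V > thresh
  starts <- which(diff(c(FALSE, above)) == 1L)
  ends <- which(diff(c(above, FALSE)) == -1L)
  apds <- numeric(0)
  prev_end <- 1L
  for (k in seq_along(starts)) {
    i0 <- starts[k]; i1 <- ends[k]
    # upstroke: fastest dV/dt in a window straddling the threshold crossing
    lo <- max(prev_end, i0 - 80L)
    seg <- lo:min(i1 + 2L, n)
    dv <- diff(V[seg]) / diff(t[seg])
    iup <- seg[which.max(dv)]
    t_up <- t[iup]
    v_rest <- V[max(lo, iup - 5L)]
    # repolarization target
    hi <- if (k < length(starts)) starts[k + 1L] - 1L else n
    v_peak <- max(V[i0:min(i1, hi)])
    v_target <- v_rest + (1 - level) * (v_peak - v_rest)
    ipk <- (i0:hi)[which.max(V[i0:hi])]
    below <- which(V[ipk:hi] <= v_target)
    if (length(below) == 0L) { prev_end <- i1; next }  # not yet repolarized
    ic <- ipk + below[1L] - 1L
    # linear interpolation of the crossing time
    t_cross <- if (ic > ipk && V[ic - 1L] > v_target) {
      t[ic - 1L] + (t[ic] - t[ic - 1L]) *
        (V[ic - 1L] - v_target) / (V[ic - 1L] - V[ic])
    } else t[ic]
    apds <- c(apds, t_cross - t_up)
    prev_end <- i1
  }
  apds
}

#' Steady-state APD90 under pacing
#'
#' Convenience wrapper: paces the cell and returns the APD of the last beat.
#'
#' @inheritParams run_paced_cell
#' @param level repolarization fraction.
#' @return steady-state APD, ms (NA if no AP).
#' @export
steady_state_apd <- function(params = tp06_params(), isch = ischemia(),
                             bcl = 1000, n_beats = 15, level = 0.9,
                             dt = 0.02, ...) {
  tr <- run_paced_cell(params, isch, bcl = bcl, n_beats = n_beats, dt = dt,
                       ...)
  a <- measure_apd(tr, level = level)
  if (length(a) == 0L) return(NA_real_)
  a[length(a)]
}

#' Calibrate the I_KATP scaling coefficient
#'
#' Finds `g0` such that the steady-state APD90 at 1 Hz pacing with
#' `f_ref` percent of ATP-sensitive channels open equals half the APD90
#' with none open, by bracketed root finding on the APD ratio.
#'
#' @param params `ionic_params` (the `g0katp` field is ignored).
#' @param f_ref calibration open fraction, percent (default 0.05).
#' @param bracket search interval for `g0`.
#' @param tol relative tolerance on `g0`.
#' @param n_beats pre-pacing beats used for the steady-state APD.
#' @return the calibrated `g0` (numeric scalar) with attribute
#'   `apd_ratio` giving the achieved APD ratio.
#' @export
calibrate_g0 <- function(params = tp06_params(), f_ref = 0.05,
                         bracket = c(1, 2000), tol = 1e-3, n_beats = 12) {
  stopifnot(f_ref > 0)
  apd0 <- steady_state_apd(params, ischemia(), n_beats = n_beats)
  if (!is.finite(apd0)) stop("baseline pacing produced no action potential")
  objective <- function(g0) {
    p <- params; p$g0katp <- g0
    a <- steady_state_apd(p, ischemia(f_atp = f_ref), n_beats = n_beats)
    if (!is.finite(a)) return(-0.5)  # AP lost: far past the halving point
    a / apd0 - 0.5
  }
  flo <- objective(bracket[1]); fhi <- objective(bracket[2])
  if (flo * fhi > 0)
    stop("no sign change in bracket [", bracket[1], ", ", bracket[2],
         "]: ratio-0.5 at ends = ", signif(flo, 3), ", ", signif(fhi, 3))
  r <- uniroot(objective, bracket, tol = tol * mean(bracket),
               f.lower = flo, f.upper = fhi)
  g0 <- r$root
  attr(g0, "apd_ratio") <- r$f.root + 0.5
  g0
}

#' Compare look-up-table and direct rate evaluation
#'
#' Advances the same state by one step with and without look-up tables and
#' returns the maximum relative discrepancy across state components.
#' @param state,params,isch,dt as in [step_cell()].
#' @return maximum relative difference (scalar).
#' @export
lut_discrepancy <- function(state = cell_state(), params = tp06_params(),
                            isch = ischemia(), dt = 0.02) {
  a <- step_cell_cpp(.as_state(state), 0, dt, params, isch, 1L,
                     use_lut = TRUE)
  b <- step_cell_cpp(.as_state(state), 0, dt, params, isch, 1L,
                     use_lut = FALSE)
  max(abs(a - b) / pmax(abs(b), 1e-8))
}
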