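# Configuration and file IO.  CSV dialect: RFC-4180, '.' decimal, UTF-8,
# mandatory header row.

.default_config <- function() {
  list(
    dt = 0.02,            # ms
    dx = 0.025,           # cm
    D = 1.54,             # cm^2/s
    slope = 1.1,
    stim_amp = -52,       # pA/pF
    stim_dur = 1,         # ms
    apd_level = 0.9,
    baseline_Ko = 5.4,    # mM
    f_ref = 0.05,         # percent; g0 calibration fraction
    ramp_ms = 500,        # ischemia onset ramp
    vf_size_cm = 5,
    vf_run_ms = 3000,
    vf_analyze_ms = 2000,
    surface_n_probes = 100,
    seed = 1L)
}

#' Load and validate a run configuration
#'
#' Reads a JSON or YAML configuration (by file extension), applies package
#' defaults for missing keys, and rejects unknown keys and invalid values
#' with an itemized message.  An empty file yields all defaults.
#'
#' @param path file path (`.json`, `.yaml`/`.yml`).
#' @return a validated named list of class `run_config`, with attribute
#'   `config_hash` (a digest of the canonical JSON serialization).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list() else jsonlite::fromJSON(txt)
  } else if (ext %in% c("yaml", "yml")) {
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  } else stop("unsupported config format: .", ext)
  defaults <- .default_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw)
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(cfg$dt) && cfg$dt > 0 && cfg$dt <= 0.02,
      "dt must be in (0, 0.02] ms")
  chk(is.numeric(cfg$dx) && cfg$dx > 0, "dx must be positive")
  chk(is.numeric(cfg$D) && cfg$D >= 0, "D must be non-negative")
  chk(cfg$slope %in% c(1.1, 1.4, 1.8), "slope must be 1.1, 1.4 or 1.8")
  chk(cfg$apd_level > 0 && cfg$apd_level < 1, "apd_level must be in (0,1)")
  chk(cfg$baseline_Ko > 0, "baseline_Ko must be positive")
  chk(cfg$f_ref > 0, "f_ref must be positive")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  attr(cfg, "config_hash") <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Hash of a configuration (canonical JSON, 31-polynomial rolling hash)
#' @param cfg a configuration list.
#' @return character hash.
#' @export
config_hash <- function(cfg) {
  js <- jsonlite::toJSON(cfg[order(names(unclass(cfg)))], auto_unbox = TRUE,
                         digits = NA)
  bytes <- utf8ToInt(as.character(js))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Save a configuration
#' @param cfg a `run_config` (or plain list).
#' @param path output path (`.json` or `.yaml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- unclass(cfg); attr(cfg, "config_hash") <- NULL
  if (ext == "json")
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else if (ext %in% c("yaml", "yml")) yaml::write_yaml(cfg, path)
  else stop("unsupported config format: .", ext)
  invisible(path)
}

#' Read / write dominant-frequency recordings as CSV
#'
#' Columns: `t_s`, `df_hz`, `df_sd_hz`, `phase`.  A missing `df_sd_hz`
#' column is filled with zero (with a warning); non-monotone time is an
#' error.
#'
#' @param path CSV path.
#' @return a `df_recording`.
#' @export
read_df_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "df_hz", "phase")
  if (!all(need %in% names(d)))
    stop("missing required columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  if (!"df_sd_hz" %in% names(d)) {
    warning("df_sd_hz column missing; filled with 0")
    d$df_sd_hz <- 0
  }
  df_recording(d$t_s, d$df_hz, d$df_sd_hz, d$phase)
}

#' @rdname read_df_csv
#' @param rec a `df_recording`.
#' @export
write_df_csv <- function(rec, path) {
  stopifnot(inherits(rec, "df_recording"))
  utils::write.csv(data.frame(t_s = rec$t, df_hz = rec$df_mean,
                              df_sd_hz = rec$df_sd, phase = rec$phase),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a period surface as long-format CSV
#'
#' Columns: `Ko_mM`, `f_atp_pct`, `period_ms`, `terminated` (1 where the
#' simulated run terminated; such cells are NA in the surface).
#'
#' @param path CSV path.
#' @param smooth re-apply monotone smoothing on read (default FALSE: the
#'   stored values are trusted).
#' @return a `period_surface`.
#' @export
read_surface_csv <- function(path, smooth = FALSE) {
  d <- utils::read.csv(path)
  need <- c("Ko_mM", "f_atp_pct", "period_ms")
  if (!all(need %in% names(d)))
    stop("missing required columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  Ko <- sort(unique(d$Ko_mM)); f <- sort(unique(d$f_atp_pct))
  P <- matrix(NA_real_, length(Ko), length(f))
  ii <- match(d$Ko_mM, Ko); jj <- match(d$f_atp_pct, f)
  per <- d$period_ms
  if ("terminated" %in% names(d)) per[d$terminated > 0] <- NA_real_
  P[cbind(ii, jj)] <- per
  period_surface(Ko, f, P, smooth = smooth)
}

#' @rdname read_surface_csv
#' @param surface a `period_surface`.
#' @export
write_surface_csv <- function(surface, path) {
  stopifnot(inherits(surface, "period_surface"))
  g <- expand.grid(Ko_mM = surface$Ko, f_atp_pct = surface$f_atp)
  g$period_ms <- as.vector(surface$period)
  g$terminated <- as.integer(is.na(g$period_ms))
  utils::write.csv(g, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a tissue state fixture (plain text)
#'
#' A JSON metadata header line (geometry, diffusion, ischemia, time,
#' ionic preset) followed by the per-node state matrix in CSV.  Round
#' trips are lossless at full double precision.
#'
#' @param path file path.
#' @return a `tissue_grid`.
#' @export
read_fixture <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  meta <- jsonlite::fromJSON(readLines(con, n = 1))
  states <- as.matrix(utils::read.csv(con))
  p <- tp06_params(slope = meta$slope, g0_katp = meta$g0katp)
  g <- tissue_grid(meta$nx, meta$ny, dx = meta$dx, D = meta$D, params = p,
                   isch = ischemia(meta$Ko, meta$acidosis, meta$f_atp),
                   state0 = unname(states))
  g$t <- meta$t
  g
}

#' @rdname read_fixture
#' @param grid a `tissue_grid`.
#' @export
write_fixture <- function(grid, path) {
  stopifnot(inherits(grid, "tissue_grid"))
  meta <- list(nx = grid$nx, ny = grid$ny, dx = grid$dx, D = grid$D,
               t = grid$t, slope = grid$params$slope_variant,
               g0katp = grid$params$g0katp, Ko = grid$isch$Ko,
               acidosis = grid$isch$acidosis, f_atp = grid$isch$f_atp)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                           digits = NA)), con)
  st <- grid$states
  utils::write.csv(format(as.data.frame(st), digits = 17, trim = TRUE,
                          scientific = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort-fit summary table as CSV
#'
#' One row per recording with the estimated potassium and open-fraction
#' columns for each fit variant (the layout of a clinical summary table).
#'
#' @param cohort result of [fit_cohort()].
#' @param path CSV path.
#' @export
write_table2_csv <- function(cohort, path) {
  if (is.null(cohort$table)) stop("cohort has no successful fits")
  utils::write.csv(cohort$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
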