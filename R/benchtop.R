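# Synthetic skin heat-flux traces and the bench-top validation pathway:
# driving the body model directly from a flux trace, as a skin-simulant
# sensor behind the clothing sample would record it.

#' Generate a synthetic bench-top flux trace
#'
#' Emulates the shape of a skin heat-flux trace recorded behind a clothing
#' sample under radiant exposure: a saturating-exponential rise toward
#' `plateau_fraction * nominal` during the exposure phase and an exponential
#' decay (the discharge of stored thermal energy) during cooling, with
#' optional Gaussian noise. Deterministic for a given seed.
#'
#' @param nominal_W_m2 nominal incident flux of the exposure.
#' @param t_exp_s,t_cool_s phase durations, s.
#' @param rise_tau_s,decay_tau_s time constants of the rise and decay
#'   (defaults 40 s and 120 s: fast rise, slower storage-discharge decay).
#' @param plateau_fraction fraction of the nominal flux transmitted to the
#'   skin at the exposure plateau, in (0, 1].
#' @param seed integer seed for the noise.
#' @param noise_sd_W_m2 Gaussian noise standard deviation (0 = clean trace).
#' @param dt_s sample spacing, s.
#' @return data.frame of class `flux_trace` with columns `time_s`,
#'   `q_W_m2`; generation parameters attached as attributes.
#' @export
synthetic_flux_trace <- function(nominal_W_m2 = 8500, t_exp_s = 300,
                                 t_cool_s = 300, rise_tau_s = 40,
                                 decay_tau_s = 120, plateau_fraction = 0.12,
                                 seed = 1L, noise_sd_W_m2 = 0, dt_s = 0.1) {
  stopifnot(rise_tau_s > 0, decay_tau_s > 0,
            plateau_fraction > 0, plateau_fraction <= 1, dt_s > 0)
  time_s <- seq(0, t_exp_s + t_cool_s, by = dt_s)
  peak <- plateau_fraction * nominal_W_m2
  q <- ifelse(time_s <= t_exp_s,
              peak * (1 - exp(-time_s / rise_tau_s)),
              peak * (1 - exp(-t_exp_s / rise_tau_s)) *
                exp(-(time_s - t_exp_s) / decay_tau_s))
  if (noise_sd_W_m2 > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    q <- q + rnorm(length(q), sd = noise_sd_W_m2)
  }
  tr <- data.frame(time_s = time_s, q_W_m2 = q)
  attr(tr, "meta") <- list(nominal_W_m2 = nominal_W_m2, t_exp_s = t_exp_s,
                           t_cool_s = t_cool_s, rise_tau_s = rise_tau_s,
                           decay_tau_s = decay_tau_s,
                           plateau_fraction = plateau_fraction, seed = seed,
                           noise_sd_W_m2 = noise_sd_W_m2, dt_s = dt_s)
  class(tr) <- c("flux_trace", "data.frame")
  tr
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write / read a flux-trace CSV
#'
#' Two columns `time_s, q_W_m2` with a mandatory header line; generation
#' metadata stored as commented `# key: value` lines before the header.
#'
#' @param trace a [synthetic_flux_trace()] (or any data.frame with the two
#'   columns).
#' @param path file path.
#' @return the path (write) or a `flux_trace` data.frame (read).
#' @export
write_flux_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- attr(trace, "meta")
  for (k in names(meta)) writeLines(sprintf("# %s: %.17g", k, meta[[k]]), con)
  writeLines("time_s,q_W_m2", con)
  writeLines(sprintf("%.10g,%.10g", trace$time_s, trace$q_W_m2), con)
  invisible(path)
}

#' @rdname write_flux_trace
#' @export
read_flux_trace <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- read.csv(text = lines[!grepl("^#", lines)])
  if (!all(c("time_s", "q_W_m2") %in% names(body))) {
    stop("flux trace must have columns time_s, q_W_m2", call. = FALSE)
  }
  if (is.unsorted(body$time_s, strictly = TRUE)) {
    stop("flux trace times must be strictly increasing", call. = FALSE)
  }
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    k <- sub(":.*$", "", kv)
    meta[[trimws(k)]] <- as.numeric(trimws(sub("^[^:]*:", "", kv)))
  }
  attr(body, "meta") <- meta
  class(body) <- c("flux_trace", "data.frame")
  body
}

#' Drive the body model from a skin heat-flux trace (bench-top mode)
#'
#' The validation pathway: the recorded (or synthetic) skin heat flux is
#' applied uniformly, per unit area, as the inward boundary flux of every
#' covered segment, and the body model is stepped through the trace. This is
#' the same computational path as a coupled run, with the clothing solver
#' replaced by the sensor record.
#'
#' @param trace a flux trace (`time_s`, `q_W_m2`).
#' @param duration_s simulated duration (default: full trace span); the
#'   trace must cover it.
#' @param t_exp_s end of exposure for the metrics (default: trace metadata,
#'   else 300 s).
#' @param metabolic_W_m2,ambient_C,rh_pct body-side conditions during the
#'   exposure phase.
#' @param metabolic_cooling_W_m2 metabolic rate after `t_exp_s` (recovery at
#'   rest).
#' @param dt_s body time step, s (flux linearly interpolated).
#' @param body a [build_body()] model.
#' @param safe_core_C,burn_skin_C metric thresholds.
#' @return list of class `bench_run`: `series` (time_s, T_core_C,
#'   T_skin_mean_C, T_blood_C, q_W_m2, SW_W, CH_W) and `metrics`.
#' @export
bench_top_run <- function(trace, duration_s = NULL, t_exp_s = NULL,
                          metabolic_W_m2 = 290,
                          metabolic_cooling_W_m2 = 58.2,
                          ambient_C = 30, rh_pct = 65,
                          dt_s = 0.1, body = build_body(),
                          safe_core_C = 38.5, burn_skin_C = 44) {
  stopifnot(all(c("time_s", "q_W_m2") %in% names(trace)))
  if (is.null(duration_s)) duration_s <- max(trace$time_s)
  if (max(trace$time_s) < duration_s - 1e-9) {
    stop(sprintf("trace covers %.1f s but %.1f s were requested",
                 max(trace$time_s), duration_s), call. = FALSE)
  }
  if (is.null(t_exp_s)) {
    meta <- attr(trace, "meta")
    t_exp_s <- if (!is.null(meta$t_exp_s)) meta$t_exp_s else 300
  }
  nt <- as.integer(round(duration_s / dt_s))
  tq <- approx(trace$time_s, trace$q_W_m2, xout = seq(0, nt) * dt_s, rule = 2)$y
  state <- make_body_state(body)
  out <- matrix(NA_real_, nt + 1L, 7)
  colnames(out) <- c("time_s", "T_core_C", "T_skin_mean_C", "T_blood_C",
                     "q_W_m2", "SW_W", "CH_W")
  out[1, ] <- c(0, core_temperature(body, state),
                mean_skin_temperature(body, state), state$T81_C, tq[1], 0, 0)
  for (k in seq_len(nt)) {
    met <- if (state$time_s < t_exp_s) metabolic_W_m2 else metabolic_cooling_W_m2
    state <- step_body(body, state, tq[k], met, dt_s,
                       ambient_C, rh_pct)
    out[k + 1L, ] <- c(state$time_s, core_temperature(body, state),
                       mean_skin_temperature(body, state), state$T81_C,
                       tq[k + 1L], state$SW, state$CH)
  }
  series <- as.data.frame(out)
  series$time_s <- seq(0L, nt) * dt_s
  metrics <- strain_metrics(series$time_s, series$T_core_C,
                            series$T_skin_mean_C, t_exp_s,
                            safe_core_C, burn_skin_C)
  structure(list(series = series, metrics = metrics), class = "bench_run")
}
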