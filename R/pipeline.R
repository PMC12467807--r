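#' Serialize fits and transfer functions as JSON
#'
#' Artifact files carry a `schema` version field and unit annotations so
#' they can be consumed downstream without ambiguity.
#'
#' @param x a [phase_fit()] or [tf_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(x, path) {
  if (inherits(x, "phase_fit")) {
    obj <- list(schema = "skincal/phase_fit/1",
                units = list(A0 = "mW", A1 = "mW", A2 = "mW/min",
                             tau = "min"),
                A0 = x$A0, A1 = x$A1, A2 = x$A2, tau = x$tau,
                phase = x$phase, rmse = x$rmse, t_origin = x$t_origin)
  } else if (inherits(x, "tf_model")) {
    obj <- list(schema = "skincal/tf_model/1",
                units = list(K = "mW/W", tau_zero_s = "s", tau_pole_s = "s"),
                K = x$K, tau_zero_s = x$tau_zero, tau_pole_s = x$tau_pole,
                x = x$x)
  } else stop("unsupported object for JSON serialization")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$schema, "skincal/phase_fit/1"))
    phase_fit(obj$A0, obj$A1, obj$A2, obj$tau, phase = obj$phase,
              rmse = obj$rmse, t_origin = obj$t_origin)
  else if (identical(obj$schema, "skincal/tf_model/1"))
    tf_model(obj$K, obj$tau_zero_s, obj$tau_pole_s, x = obj$x)
  else stop("unknown artifact schema in ", path)
}

#' Run the full analysis pipeline on one session record
#'
#' Executes the standard analysis chain on a measured (or synthetic)
#' session: heat-flux reconstruction, optional subcutaneous-temperature
#' estimation, phase segmentation, two-exponential fits per phase and
#' per-phase transfer functions.  When `out_dir` is given, the flux trace
#' is written as CSV and the fits and transfer functions as JSON.
#'
#' @param record a [signal_record()] of the session.
#' @param params calibrated [calorimeter_params()].
#' @param exercise_start,exercise_end exercise bout interval, s.
#' @param W_input mechanical power of the bout, W (default 80).
#' @param R_skin skin thermal resistance, K/W; when given, a core
#'   temperature trace and fits are produced.
#' @param simplified use the constant-thermostat formula instead of the
#'   full inversion (default `FALSE`).
#' @param smooth_window passed to [reconstruct_heat_flux()].
#' @param out_dir optional output directory for artifacts.
#' @return A list of class `session_analysis`: `flux` (data frame `t`,
#'   `W1`), `reconstruction`, `fits` (exercise/recovery [phase_fit()]s),
#'   `tf` (exercise/recovery [tf_model()]s), `core` (trace + fits or
#'   `NULL`), `segmentation`.
#' @export
run_pipeline <- function(record, params, exercise_start, exercise_end,
                         W_input = 80, R_skin = NULL, simplified = FALSE,
                         smooth_window = 15, out_dir = NULL) {
  validate_record(record)
  seg <- segment_phases(exercise_start, exercise_end,
                        record$t[nrow(record)])
  if (simplified) {
    W1 <- reconstruct_simplified(record, steady_coefficients(params))
    recon <- NULL
  } else {
    recon <- reconstruct_heat_flux(record, params,
                                   smooth_window = smooth_window)
    W1 <- recon$W1
  }
  fits <- fit_session_phases(record$t, W1, seg, flux = TRUE)
  tf <- list(
    exercise = if (!is.null(fits$exercise))
      tf_from_phase_fit(fits$exercise, W_input),
    recovery = if (!is.null(fits$recovery))
      tf_from_phase_fit(fits$recovery, W_input))
  core <- NULL
  if (!is.null(R_skin)) {
    trace <- estimate_core_temperature(record, W1, R_skin, params$k)
    core <- list(trace = trace,
                 fits = fit_session_phases(trace$t, trace$T_core, seg,
                                           flux = FALSE))
  }
  out <- structure(list(flux = data.frame(t = record$t, W1 = W1),
                        reconstruction = recon, fits = fits, tf = tf,
                        core = core, segmentation = seg),
                   class = "session_analysis")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$flux, file.path(out_dir, "flux.csv"),
                     row.names = FALSE, quote = FALSE)
    for (ph in c("exercise", "recovery")) {
      if (!is.null(fits[[ph]]))
        write_fit_json(fits[[ph]], file.path(out_dir,
                                             paste0("fit_", ph, ".json")))
      if (!is.null(tf[[ph]]))
        write_fit_json(tf[[ph]], file.path(out_dir,
                                           paste0("tf_", ph, ".json")))
    }
  }
  out
}

#' @export
print.session_analysis <- function(x, ...) {
  cat("<session_analysis>\n")
  if (!is.null(x$fits$exercise)) { cat("  exercise "); print(x$fits$exercise) }
  if (!is.null(x$fits$recovery)) { cat("  recovery "); print(x$fits$recovery) }
  invisible(x)
}
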