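#' Reference response-model parameters of the studied subject
#'
#' Fitted two-exponential model parameters for the bundled case study: a
#' healthy adult exercising 30 min on a stepper at 80 W mechanical power,
#' measured on the rectus femoris with a 4 cm^2 skin calorimeter, one
#' session per thermostat set-point (28-38 degC).  `subject_flux_fits()`
#' gives the skin heat-flux fits (A0/A1 in mW, A2 in mW/min, tau in min,
#' rmse in uW); `subject_core_fits()` the subcutaneous-temperature fits
#' (degC, degC/min, min, rmse in mK).  These rows double as ground-truth
#' generator presets for the synthetic-data module.
#'
#' @param T2 optional subset of thermostat set-points, degC.
#' @param phase optional subset, `"exercise"` and/or `"recovery"`.
#' @return A data frame with columns `T2`, `phase`, `A0`, `A1`, `A2`,
#'   `tau`, `rmse`.
#' @export
subject_flux_fits <- function(T2 = NULL, phase = NULL) {
  tab <- data.frame(
    T2 = rep(c(28, 30, 32, 34, 36, 38), 2),
    phase = rep(c("exercise", "recovery"), each = 6),
    A0 = c(125.2, 143.4, 86.10, 35.40, 61.50, -24.53,
           185.6, 251.7, 185.2, 118.7, 132.9, 0.200),
    A1 = c(63.7, 111.5, 103.0, 85.7, 75.4, 29.8,
           -57.20, -108.7, -72.19, -48.35, -42.91, 29.66),
    A2 = c(-21.0, -34.3, -41.1, -26.5, -33.5, -17.0,
           11.5, -0.02, 8.90, 20.0, 4.40, 21.7),
    tau = c(5.7, 5.3, 5.3, 5.2, 5.6, 6.7,
            9.3, 11.6, 8.7, 7.2, 12.0, 6.3),
    rmse = rep(c(85.4, 78.3, 67.3, 102.9, 83.6, 105.7), 2))
  subset_fits(tab, T2, phase)
}

#' @rdname subject_flux_fits
#' @export
subject_core_fits <- function(T2 = NULL, phase = NULL) {
  tab <- data.frame(
    T2 = rep(c(28, 30, 32, 34, 36, 38), 2),
    phase = rep(c("exercise", "recovery"), each = 6),
    A0 = c(33.15, 35.00, 33.75, 33.52, 35.71, 34.05,
           35.61, 39.30, 37.54, 36.48, 38.01, 34.71),
    A1 = c(2.61, 4.45, 3.96, 3.05, 2.46, 0.82,
           -2.27, -4.39, -2.58, -1.62, -1.30, 1.25),
    A2 = c(-0.99, -1.53, -1.63, -1.06, -1.23, -0.56,
           0.56, 0.00, 0.42, 0.79, 0.22, 0.72),
    tau = c(5.7, 5.4, 5.4, 5.2, 5.7, 6.7,
            9.2, 13.8, 8.5, 7.3, 10.7, 6.5),
    rmse = rep(c(3.56, 3.01, 2.54, 3.84, 2.73, 3.35), 2))
  subset_fits(tab, T2, phase)
}

subset_fits <- function(tab, T2, phase) {
  if (!is.null(T2)) {
    if (!all(T2 %in% tab$T2)) stop("no preset for T2 = ",
                                   paste(setdiff(T2, tab$T2), collapse = ", "))
    tab <- tab[tab$T2 %in% T2, ]
  }
  if (!is.null(phase)) tab <- tab[tab$phase %in% phase, ]
  rownames(tab) <- NULL
  tab
}

#' Reference heart-rate exponential fits
#'
#' Simple-exponential heart-rate response of the studied subject:
#' `bpm = 83.2 + 80.8 (1 - exp(-t/12))` during exercise and
#' `bpm = 158.6 - 56.8 (1 - exp(-t/4.6))` during recovery (t in min).
#'
#' @return Data frame with columns `phase`, `A0`, `A1`, `tau`.
#' @export
subject_heart_rate_fits <- function() {
  data.frame(phase = c("exercise", "recovery"),
             A0 = c(83.2, 158.6), A1 = c(80.8, -56.8), tau = c(12, 4.6))
}

#' Row of a preset table as a phase fit
#'
#' @param tab a table from [subject_flux_fits()] or [subject_core_fits()].
#' @param T2 thermostat set-point of the wanted row, degC.
#' @param phase `"exercise"` or `"recovery"`.
#' @return A [phase_fit()].
#' @export
preset_phase_fit <- function(tab, T2, phase) {
  row <- tab[tab$T2 == T2 & tab$phase == phase, ]
  if (nrow(row) != 1L) stop("no unique preset row for T2 = ", T2,
                            ", phase = ", phase)
  phase_fit(A0 = row$A0, A1 = row$A1, A2 = row$A2, tau = row$tau,
            phase = phase, rmse = row$rmse)
}

#' Synthetic subject definition
#'
#' Ground-truth description of a simulated subject: skin thermal properties
#' plus the exercise/recovery phase fits that define the true heat-flux
#' trajectory of a session.  Defaults describe the bundled case-study
#' subject at a thermostat set-point of 34 degC, with the thigh-average
#' skin properties (R_skin = 30.1 K/W, C_skin = 3.0 J/K over the 4 cm^2
#' sensing area).
#'
#' @param R_skin skin thermal resistance, K/W.
#' @param C_skin skin heat capacity, J/K.
#' @param baseline_core resting subcutaneous temperature, degC.
#' @param flux_exercise,flux_recovery [phase_fit()]s defining the true
#'   heat-flux response, mW/min units.
#' @return A list of class `synthetic_subject`.
#' @export
synthetic_subject <- function(R_skin = 30.1, C_skin = 3.0,
                              baseline_core = 36.5,
                              flux_exercise = preset_phase_fit(
                                subject_flux_fits(), 34, "exercise"),
                              flux_recovery = preset_phase_fit(
                                subject_flux_fits(), 34, "recovery")) {
  if (R_skin <= 0 || C_skin < 0) stop("R_skin must be > 0 and C_skin >= 0")
  structure(list(R_skin = R_skin, C_skin = C_skin,
                 baseline_core = baseline_core,
                 flux_exercise = flux_exercise,
                 flux_recovery = flux_recovery),
            class = "synthetic_subject")
}
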