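# Centered moving average; the first and last (window-1)/2 samples are NA
# (no extrapolation at the record edges).
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window <= 1L) return(x)
  u <- (window - 1L) %/% 2L
  n <- length(x)
  if (n < window) stop("record too short for smoothing window")
  sm <- stats::filter(x, rep(1 / window, window), sides = 2)
  as.numeric(sm)
}

# Central-difference derivative of a (smoothed) series; NA where undefined.
central_diff <- function(x, h) {
  n <- length(x)
  d <- rep(NA_real_, n)
  if (n >= 3L) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * h)
  d
}

#' Reconstruct skin heat flux from a measured record
#'
#' Inverts the two-body calorimeter model sample by sample:
#' \enumerate{
#'   \item the cold-focus temperature from the thermostat balance,
#'     \eqn{T_{02} = T_2 - (W_2 + P_{12} y/k - C_2 dT_2/dt)/P_2};
#'   \item the environment offset \eqn{\Delta T_0 = T_{02} - T_{room} -
#'     \beta I_{pel}}, taken as one scalar per record (median over the
#'     initial rest segment);
#'   \item the surroundings temperature \eqn{T_{01} = T_{room} + \alpha
#'     I_{pel} + \Delta T_0};
#'   \item the skin heat flux from the plate balance,
#'     \eqn{W_1 = (C_1/k) dy/dt + y (P_1+P_{12})/k + C_1 dT_2/dt +
#'     P_1 (T_2 - T_{01})}.
#' }
#' Derivatives are estimated by central differences of a centered
#' moving-average smoothed signal; samples within half a smoothing window of
#' the record edges are returned as `NA` rather than extrapolated.
#'
#' @param record a [signal_record()].
#' @param params calibrated [calorimeter_params()].
#' @param smooth_window moving-average width in samples (odd; default 15).
#'   The default keeps the noise amplified by the derivative terms below the
#'   device's stated 5 mW flux uncertainty at nominal signal noise.
#' @param rest_window length of the initial rest segment used to estimate
#'   the scalar environment offset, s (default 120).
#' @return A list of class `reconstruction_result` with per-sample `t`,
#'   `W1` (W), `T1`, `T01`, `T02` (degC), scalar `dT0` (K) and the stated
#'   flux `uncertainty` (W, default 0.005).
#' @export
reconstruct_heat_flux <- function(record, params, smooth_window = 15,
                                  rest_window = 120) {
  validate_record(record)
  stopifnot(inherits(params, "calorimeter_params"))
  p <- params
  if (p$P2 <= 0) stop("P2 must be positive to invert the thermostat balance")
  n <- nrow(record)
  if (n < 5L) stop("record too short to estimate derivatives")
  h <- record_dt(record)
  w <- max(1L, as.integer(smooth_window))
  y_s <- moving_average(record$y, w)
  T2_s <- moving_average(record$T2, w)
  dy <- central_diff(y_s, h)
  dT2 <- central_diff(T2_s, h)

  T02 <- T2_s - (record$W2 + p$P12 * y_s / p$k - p$C2 * dT2) / p$P2
  dT0_samples <- T02 - record$Troom - p$beta * record$Ipel
  rest_idx <- which(record$t - record$t[1] <= rest_window & !is.na(dT0_samples))
  if (!length(rest_idx)) rest_idx <- which(!is.na(dT0_samples))
  dT0 <- stats::median(dT0_samples[rest_idx])
  T01 <- record$Troom + p$alpha * record$Ipel + dT0

  W1 <- (p$C1 / p$k) * dy + y_s * (p$P1 + p$P12) / p$k +
    p$C1 * dT2 + p$P1 * (T2_s - T01)
  structure(list(t = record$t, W1 = W1, T1 = T2_s + y_s / p$k,
                 T01 = T01, T02 = T02, dT0 = dT0, uncertainty = 0.005),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  ok <- !is.na(x$W1)
  cat(sprintf(
    "<reconstruction_result> %d samples (%d valid), dT0 = %.4f K\n",
    length(x$t), sum(ok), x$dT0))
  cat(sprintf("  W1: mean %.4f W, range [%.4f, %.4f] W, uncertainty %.3f W\n",
              mean(x$W1[ok]), min(x$W1[ok]), max(x$W1[ok]), x$uncertainty))
  invisible(x)
}

#' Steady-state reconstruction coefficients
#'
#' With the thermostat held at constant temperature the full inversion
#' collapses to one linear formula per sample,
#' \eqn{W_1 = c_y y + c_I I_{pel} + c_{W2} W_2}, whose coefficients follow
#' from eliminating the external temperatures from the steady two-body
#' balance:
#' \deqn{c_y = (P_1+P_{12})/k + P_1 P_{12}/(P_2 k), \quad
#'       c_I = P_1 (\beta - \alpha), \quad c_{W2} = P_1/P_2.}
#'
#' @param params a [calorimeter_params()].
#' @return A list of class `steady_coefficients` with fields `c_y` (W/V),
#'   `c_I` (W/A) and `c_W2` (dimensionless).
#' @export
steady_coefficients <- function(params) {
  stopifnot(inherits(params, "calorimeter_params"))
  p <- params
  if (p$P2 <= 0 || p$k <= 0) stop("P2 and k must be positive")
  structure(list(c_y = (p$P1 + p$P12) / p$k + p$P1 * p$P12 / (p$P2 * p$k),
                 c_I = p$P1 * (p$beta - p$alpha),
                 c_W2 = p$P1 / p$P2),
            class = "steady_coefficients")
}

#' @export
print.steady_coefficients <- function(x, ...) {
  cat(sprintf("<steady_coefficients> W1 = %.4f y %+.4f Ipel %+.5f W2\n",
              x$c_y, x$c_I, x$c_W2))
  invisible(x)
}

#' Simplified (constant-thermostat) heat-flux reconstruction
#'
#' Applies the per-sample linear formula of [steady_coefficients()].  Valid
#' when the thermostat temperature is held constant; a warning is issued if
#' the record's `T2` range exceeds 0.1 K.
#'
#' @param record a [signal_record()].
#' @param coeffs a `steady_coefficients` object.
#' @return Numeric vector of reconstructed heat flux, W, one value per
#'   sample.
#' @export
reconstruct_simplified <- function(record, coeffs) {
  validate_record(record)
  stopifnot(inherits(coeffs, "steady_coefficients"))
  if (diff(range(record$T2)) > 0.1)
    warning("thermostat temperature varies by more than 0.1 K; ",
            "the constant-thermostat formula may be inaccurate")
  coeffs$c_y * record$y + coeffs$c_I * record$Ipel + coeffs$c_W2 * record$W2
}
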