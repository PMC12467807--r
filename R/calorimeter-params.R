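#' Calorimeter parameter set
#'
#' Bundle the lumped thermal constants that define one physical skin
#' calorimeter.  The device is modelled as two heat capacities: domain 1 is
#' the aluminium measurement plate plus the probed skin volume (total
#' capacity `C1`, of which `C10` is the device-only offset), domain 2 is the
#' thermostat (`C2`).  The domains exchange heat through the measurement
#' thermopile (conductance `P12`) and each leaks to an external temperature
#' through `P1` (surroundings near the calorimeter) and `P2` (Peltier cold
#' focus).  The thermopile output is `y = k * (T1 - T2)` with `k` the
#' Seebeck coefficient.  The external temperatures shift linearly with the
#' Peltier supply current through `alpha` (surroundings side) and `beta`
#' (cold-focus side).
#'
#' @param C10 device-only (skin-free) part of the domain-1 heat capacity, J/K.
#' @param C1 total domain-1 heat capacity (plate + skin), J/K; must be >= C10.
#' @param C2 thermostat heat capacity, J/K.
#' @param P1 conductance domain 1 <-> surroundings, W/K.
#' @param P2 conductance domain 2 <-> cold focus, W/K.
#' @param P12 measurement-thermopile conductance, W/K.
#' @param k Seebeck coefficient of the measurement thermopile, V/K.
#' @param alpha cold-focus current coefficient acting on the surroundings
#'   temperature, K/A.
#' @param beta cold-focus current coefficient acting on the cold-focus
#'   temperature, K/A (typically negative: the Peltier cools).
#' @param label device identifier, e.g. `"S1"`.
#'
#' @return An object of class `calorimeter_params` (a named list).
#' @seealso [calorimeter_s1()], [calorimeter_s2()] for the bundled reference
#'   devices, [simulate_forward()], [steady_state()].
#' @export
calorimeter_params <- function(C10, C1, C2, P1, P2, P12, k,
                               alpha = 0, beta = 0, label = "device") {
  num <- c(C10 = C10, C1 = C1, C2 = C2, P1 = P1, P2 = P2, P12 = P12,
           k = k, alpha = alpha, beta = beta)
  if (!all(is.finite(num)))
    stop("all calorimeter parameters must be finite numbers")
  if (C10 <= 0 || C1 < C10)
    stop("need C1 >= C10 > 0 (skin can only add capacity to the device)")
  if (C2 <= 0) stop("C2 must be positive")
  if (P1 <= 0 || P2 <= 0 || P12 <= 0 || k <= 0)
    stop("conductances P1, P2, P12 and Seebeck coefficient k must be positive")
  structure(
    list(C10 = C10, C1 = C1, C2 = C2, P1 = P1, P2 = P2, P12 = P12,
         k = k, alpha = alpha, beta = beta, label = as.character(label)),
    class = "calorimeter_params")
}

#' @export
print.calorimeter_params <- function(x, ...) {
  cat("<calorimeter_params> ", x$label, "\n", sep = "")
  cat(sprintf("  C10 = %.3g J/K, C1 = %.3g J/K, C2 = %.3g J/K\n",
              x$C10, x$C1, x$C2))
  cat(sprintf("  P1 = %.3g W/K, P2 = %.3g W/K, P12 = %.3g W/K\n",
              x$P1, x$P2, x$P12))
  cat(sprintf("  k = %.3g V/K, alpha = %.3g K/A, beta = %.3g K/A\n",
              x$k, x$alpha, x$beta))
  invisible(x)
}

#' Reference calorimeter parameter sets
#'
#' Mean calibrated parameters of the two twin prototype skin calorimeters
#' (labelled S1 and S2) used in the exercise case study bundled with this
#' package.  Each was calibrated from 35 excitation measurements of 45 min.
#' Note `k` is stored in V/K (the published value is in mV/K).
#'
#' @return A `calorimeter_params` object.
#' @export
calorimeter_s1 <- function() {
  calorimeter_params(C10 = 2.31, C1 = 4.02, C2 = 3.8,
                     P1 = 0.029, P2 = 0.057, P12 = 0.092,
                     k = 23.7e-3, alpha = 13.6, beta = -83.5, label = "S1")
}

#' @rdname calorimeter_s1
#' @export
calorimeter_s2 <- function() {
  calorimeter_params(C10 = 2.31, C1 = 3.91, C2 = 3.7,
                     P1 = 0.029, P2 = 0.055, P12 = 0.089,
                     k = 23.0e-3, alpha = 17.4, beta = -83.8, label = "S2")
}

#' Reported calibration spread of the reference devices
#'
#' One-standard-deviation columns accompanying the reference parameter
#' means, over the 35 calibration measurements.  Used by the test-suite as
#' recovery tolerances for synthetic calibration.
#'
#' @param label `"S1"` or `"S2"`.
#' @return Named numeric vector of standard deviations (same units as the
#'   corresponding [calorimeter_params()] fields; `k` in V/K).
#' @export
calorimeter_param_sd <- function(label = "S1") {
  label <- match.arg(label, c("S1", "S2"))
  if (label == "S1")
    c(C10 = 0.07, C1 = 0.09, C2 = 0.2, P1 = 0.002, P2 = 0.005,
      P12 = 0.008, k = 1.1e-3)
  else
    c(C10 = 0.07, C1 = 0.09, C2 = 0.3, P1 = 0.002, P2 = 0.005,
      P12 = 0.009, k = 1.4e-3)
}

#' Read and write calorimeter parameter files
#'
#' Parameters are stored as a flat `key: value` text file (Debian control
#' format), one field per line, `k` in V/K.
#'
#' @param path file path.
#' @param params a `calorimeter_params` object.
#' @return `read_params()` returns a `calorimeter_params`; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  dcf <- read.dcf(path)
  if (nrow(dcf) != 1L) stop("expected a single parameter block in ", path)
  val <- function(key, default = NULL) {
    if (key %in% colnames(dcf)) as.numeric(dcf[1, key])
    else if (!is.null(default)) default
    else stop("missing required field '", key, "' in ", path)
  }
  label <- if ("label" %in% colnames(dcf)) dcf[1, "label"] else "device"
  calorimeter_params(C10 = val("C10"), C1 = val("C1"), C2 = val("C2"),
                     P1 = val("P1"), P2 = val("P2"), P12 = val("P12"),
                     k = val("k"), alpha = val("alpha", 0),
                     beta = val("beta", 0), label = label)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "calorimeter_params"))
  m <- matrix(c(vapply(params[1:9], format, "", digits = 15), params$label),
              nrow = 1)
  colnames(m) <- names(params)
  write.dcf(m, path)
  invisible(path)
}
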