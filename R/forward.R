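#' Forward-simulation inputs
#'
#' Collects the exogenous waveforms driving the two-body calorimeter model.
#' Each waveform may be a scalar (held constant) or a vector on the
#' simulation grid; values are held constant over each sampling interval
#' (zero-order hold).
#'
#' @param W1 skin heat flux entering the measurement plate, W.  Positive
#'   means heat flows from the skin into the plate.
#' @param W2 thermostat Joule heating power, W.
#' @param Ipel Peltier supply current, A.
#' @param Troom room temperature, degC.
#' @param dT0 environment temperature offset near the body, K.
#' @param initial_T1,initial_T2 initial domain temperatures, degC.  When
#'   `NULL` (default) the simulation starts from the steady state implied by
#'   the first-sample inputs.
#' @return A list of class `forward_inputs`.
#' @export
forward_inputs <- function(W1 = 0, W2 = 0, Ipel = 0, Troom = 20, dT0 = 0,
                           initial_T1 = NULL, initial_T2 = NULL) {
  structure(list(W1 = W1, W2 = W2, Ipel = Ipel, Troom = Troom, dT0 = dT0,
                 initial_T1 = initial_T1, initial_T2 = initial_T2),
            class = "forward_inputs")
}

check_grid <- function(t) {
  if (length(t) < 2L) stop("time grid needs at least 2 samples")
  dt <- diff(t)
  if (any(dt <= 0)) stop("time grid must be strictly increasing")
  if (diff(range(dt)) > 1e-9 * max(dt)) stop("time grid must be uniform")
  dt[1]
}

# Continuous-time state matrix of the two-body system, states (T1, T2).
state_matrix <- function(p) {
  matrix(c(-(p$P1 + p$P12) / p$C1, p$P12 / p$C2,
           p$P12 / p$C1, -(p$P2 + p$P12) / p$C2), 2, 2)
}

# Exact ZOH stepping of x' = A x + g(t) with g piecewise constant per
# sample, via modal (eigen) decomposition.  The RC network always has two
# distinct real negative eigenvalues (a12 * a21 > 0), so the modal
# recurrences can be run with stats::filter at C speed.
zoh_modal <- function(A, g1, g2, x0, h) {
  a11 <- A[1, 1]; a12 <- A[1, 2]; a21 <- A[2, 1]; a22 <- A[2, 2]
  disc2 <- (a11 - a22)^2 + 4 * a12 * a21
  if (disc2 <= 0) stop("degenerate state matrix (non-distinct eigenvalues)")
  disc <- sqrt(disc2)
  l1 <- (a11 + a22 + disc) / 2
  l2 <- (a11 + a22 - disc) / 2
  # eigenvector columns (a12, lambda - a11); a12 > 0 for physical params
  V <- matrix(c(a12, l1 - a11, a12, l2 - a11), 2, 2)
  detV <- V[1, 1] * V[2, 2] - V[1, 2] * V[2, 1]
  Vi <- matrix(c(V[2, 2], -V[2, 1], -V[1, 2], V[1, 1]), 2, 2) / detV
  n <- length(g1)
  w1 <- Vi[1, 1] * g1 + Vi[1, 2] * g2   # modal forcings
  w2 <- Vi[2, 1] * g1 + Vi[2, 2] * g2
  w0 <- c(Vi[1, 1] * x0[1] + Vi[1, 2] * x0[2],
          Vi[2, 1] * x0[1] + Vi[2, 2] * x0[2])
  step_mode <- function(lam, q, z0) {
    phi <- exp(lam * h)
    gain <- (phi - 1) / lam
    if (n == 1L) return(z0)
    z <- stats::filter(gain * q[-n], phi, method = "recursive", init = z0)
    c(z0, as.numeric(z))
  }
  z1 <- step_mode(l1, w1, w0[1])
  z2 <- step_mode(l2, w2, w0[2])
  list(x1 = V[1, 1] * z1 + V[1, 2] * z2,
       x2 = V[2, 1] * z1 + V[2, 2] * z2)
}

# Exact ZOH stepping of a scalar state x' = a x + g(t).
zoh_scalar <- function(a, g, x0, h) {
  n <- length(g)
  phi <- exp(a * h)
  gain <- (phi - 1) / a
  if (n == 1L) return(x0)
  x <- stats::filter(gain * g[-n], phi, method = "recursive", init = x0)
  c(x0, as.numeric(x))
}

#' Simulate the calorimeter-skin two-body model
#'
#' Integrates the heat balances of the measurement plate + skin domain and
#' of the thermostat,
#' \deqn{C_1 dT_1/dt = W_1 - P_{12}(T_1-T_2) - P_1(T_1-T_{01})}
#' \deqn{C_2 dT_2/dt = W_2 + P_{12}(T_1-T_2) - P_2(T_2-T_{02})}
#' with \eqn{T_{01} = T_{room} + \alpha I_{pel} + \Delta T_0} and
#' \eqn{T_{02} = T_{room} + \beta I_{pel} + \Delta T_0}, and returns the
#' measured channels, with \eqn{y = k (T_1 - T_2)}.  Integration is exact
#' for piecewise-constant inputs (matrix-exponential stepping per sampling
#' interval), so no solver tolerance enters the result.
#'
#' @param params a [calorimeter_params()] object.
#' @param inputs a [forward_inputs()] object.
#' @param t uniform time grid, s.
#' @return A [signal_record()]; the simulated plate temperature is attached
#'   as attribute `"T1"` and the environment offset as `"dT0"`.
#' @export
simulate_forward <- function(params, inputs, t) {
  stopifnot(inherits(params, "calorimeter_params"),
            inherits(inputs, "forward_inputs"))
  h <- check_grid(t)
  n <- length(t)
  W1 <- rep_len(inputs$W1, n); W2 <- rep_len(inputs$W2, n)
  Ipel <- rep_len(inputs$Ipel, n); Troom <- rep_len(inputs$Troom, n)
  dT0 <- rep_len(inputs$dT0, n)
  if (!all(is.finite(c(W1, W2, Ipel, Troom, dT0))))
    stop("input waveforms must be finite")
  T01 <- Troom + params$alpha * Ipel + dT0
  T02 <- Troom + params$beta * Ipel + dT0
  g1 <- (W1 + params$P1 * T01) / params$C1
  g2 <- (W2 + params$P2 * T02) / params$C2
  if (is.null(inputs$initial_T1) || is.null(inputs$initial_T2)) {
    ss <- steady_state(params, W1[1], W2[1], Ipel[1], Troom[1], dT0[1])
    x0 <- c(inputs$initial_T1 %||% ss$T1, inputs$initial_T2 %||% ss$T2)
  } else {
    x0 <- c(inputs$initial_T1, inputs$initial_T2)
  }
  xs <- zoh_modal(state_matrix(params), g1, g2, x0, h)
  rec <- signal_record(t = t, y = params$k * (xs$x1 - xs$x2), T2 = xs$x2,
                       W2 = W2, Ipel = Ipel, Troom = Troom)
  attr(rec, "T1") <- xs$x1
  attr(rec, "dT0") <- dT0
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Steady state of the two-body model
#'
#' Solves the 2x2 linear balance obtained by zeroing the time derivatives:
#' the power dissipated in each domain equals its conductive losses.
#'
#' @inheritParams simulate_forward
#' @param W1,W2 constant powers, W.
#' @param Ipel Peltier current, A.
#' @param Troom room temperature, degC.
#' @param dT0 environment offset, K.
#' @return A list of class `system_state` with fields `T1`, `T2`, `T01`,
#'   `T02`, `dT0` (degC / K) and the thermopile output `y` (V).
#' @export
steady_state <- function(params, W1 = 0, W2 = 0, Ipel = 0, Troom = 20,
                         dT0 = 0) {
  stopifnot(inherits(params, "calorimeter_params"))
  p <- params
  det <- p$P1 * p$P2 + p$P1 * p$P12 + p$P2 * p$P12
  if (det <= 0) stop("singular conductance matrix")
  T01 <- Troom + p$alpha * Ipel + dT0
  T02 <- Troom + p$beta * Ipel + dT0
  b1 <- W1 + p$P1 * T01
  b2 <- W2 + p$P2 * T02
  # M = [P1+P12, -P12; -P12, P2+P12]
  T1 <- ((p$P2 + p$P12) * b1 + p$P12 * b2) / det
  T2 <- (p$P12 * b1 + (p$P1 + p$P12) * b2) / det
  structure(list(T1 = T1, T2 = T2, dT0 = dT0, T01 = T01, T02 = T02,
                 y = p$k * (T1 - T2)),
            class = "system_state")
}
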