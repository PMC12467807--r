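#' Measurement-noise specification
#'
#' Gaussian white-noise model for the two measured channels.  The steady
#' thermostat oscillations of the real device are about +/-0.02 degC and
#' the calorimetric-signal oscillations about +/-0.5 mV; these "+/-"
#' figures are interpreted as peak-to-peak, so the default standard
#' deviations are half of them.
#'
#' @param sigma_y calorimetric-signal noise s.d., V (default 0.25 mV).
#' @param sigma_T2 thermostat-temperature noise s.d., K (default 0.01 K).
#' @param seed integer seed making every generated record reproducible.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(sigma_y = 0.25e-3, sigma_T2 = 0.01, seed = 1L) {
  if (sigma_y < 0 || sigma_T2 < 0) stop("noise sigmas must be non-negative")
  structure(list(sigma_y = sigma_y, sigma_T2 = sigma_T2,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' @rdname noise_spec
#' @export
noise_free <- function(seed = 1L) noise_spec(0, 0, seed)

add_noise <- function(rec, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  n <- nrow(rec)
  withr_seed <- noise$seed %% .Machine$integer.max
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(withr_seed)
  rec$y <- rec$y + stats::rnorm(n, 0, noise$sigma_y)
  rec$T2 <- rec$T2 + stats::rnorm(n, 0, noise$sigma_T2)
  rec
}

#' Mechanical-power protocol
#'
#' @param t uniform time grid, s.
#' @param W mechanical-power waveform, W (scalar or per-sample, >= 0).
#' @return A data frame of class `power_protocol` with columns `t`, `W`.
#' @export
power_protocol <- function(t, W) {
  check_grid(t)
  W <- rep_len(as.numeric(W), length(t))
  if (any(!is.finite(W)) || any(W < 0))
    stop("mechanical power must be finite and non-negative")
  structure(data.frame(t = t, W = W),
            class = c("power_protocol", "data.frame"))
}

#' Step exercise protocol
#'
#' The case-study protocol: rest, a constant-power bout, then recovery to
#' the end of the session.  Defaults give a 2 h session with 30 min at
#' 80 W starting after 10 min of rest.
#'
#' @param duration session length, s.
#' @param start,end exercise start and end, s.
#' @param W_ex bout power, W.
#' @param dt sampling period, s.
#' @return A [power_protocol()].
#' @export
step_protocol <- function(duration = 7200, start = 600, end = 2400,
                          W_ex = 80, dt = 1) {
  t <- seq(0, duration - dt, by = dt)
  W <- ifelse(t >= start & t < end, W_ex, 0)
  power_protocol(t, W)
}

#' Synthetic calibration excitation set
#'
#' Generates bench excitation records with known ground truth for
#' calibrating the RC model and cooling coefficients.  The design spans the
#' operating ranges used for the real calibration campaign: Peltier current
#' 0-0.2 A, plate Joule heating 0-0.2 W and thermostat powers 0-2 W (which
#' place the thermostat at roughly 28-34 degC), cycled over a factorial
#' grid.  Each record lasts 45 min (2700 samples at 1 s), starts at the
#' steady state of its initial inputs, and contains one W1 step at 600 s
#' and one W2 step at 1500 s so that both heat capacities are excited.  The
#' Peltier current is constant within each record.
#'
#' @param params ground-truth [calorimeter_params()].
#' @param n_records number of records (>= 4 for identifiability;
#'   default 35).
#' @param noise a [noise_spec()].
#' @param Troom bench room temperature, degC.
#' @param duration record length, s.
#' @return A list of class `calibration_set` with elements `records` (list
#'   of [signal_record()]s), `programs` (per-record true `W1`, `W2`
#'   waveforms) and `truth` (the generating parameters).
#' @export
make_calibration_set <- function(params, n_records = 35,
                                 noise = noise_spec(), Troom = 21.5,
                                 duration = 2700) {
  stopifnot(inherits(params, "calorimeter_params"))
  if (n_records < 4) stop("need at least 4 records for identifiability")
  t <- seq(0, duration - 1)
  n <- length(t)
  ipel_lev <- c(0, 0.05, 0.1, 0.15, 0.2)
  w1_lev <- c(0.05, 0.1, 0.15, 0.2)
  w2_lev <- c(0.5, 1, 1.5, 2)
  records <- vector("list", n_records)
  programs <- vector("list", n_records)
  for (i in seq_len(n_records)) {
    ip <- ipel_lev[(i - 1L) %% length(ipel_lev) + 1L]
    a1 <- w1_lev[(i - 1L) %% length(w1_lev) + 1L]
    b2 <- w2_lev[(i - 1L) %% length(w2_lev) + 1L]
    # step times scale with the record so short test records still carry
    # both excitations (defaults reproduce 600 s / 1500 s at 45 min)
    W1 <- ifelse(t >= round(duration * 2 / 9), a1, 0)
    W2 <- ifelse(t >= round(duration * 5 / 9), b2, b2 / 2)
    rec <- simulate_forward(params, forward_inputs(
      W1 = W1, W2 = W2, Ipel = ip, Troom = Troom, dT0 = 0), t)
    rec <- add_noise(rec, noise_spec(noise$sigma_y, noise$sigma_T2,
                                     noise$seed + i))
    records[[i]] <- rec
    programs[[i]] <- list(W1 = W1, W2 = W2, Ipel = ip)
  }
  structure(list(records = records, programs = programs, truth = params),
            class = "calibration_set")
}

# Session simulator with the thermostat PID emulated by imposing T2: the
# plate+skin state T1 is integrated exactly (single-state ZOH) against the
# imposed thermostat trajectory, and W2 is back-computed from the thermostat
# balance as the power the controller must deliver.
simulate_thermostatted <- function(params, W1, T2, Ipel, Troom, dT0, t,
                                   dT2dt = NULL) {
  p <- params
  h <- check_grid(t)
  n <- length(t)
  W1 <- rep_len(W1, n); T2 <- rep_len(T2, n)
  Ipel <- rep_len(Ipel, n); Troom <- rep_len(Troom, n)
  T01 <- Troom + p$alpha * Ipel + dT0
  T02 <- Troom + p$beta * Ipel + dT0
  a <- -(p$P12 + p$P1) / p$C1
  g <- (W1 + p$P12 * T2 + p$P1 * T01) / p$C1
  T1 <- zoh_scalar(a, g, -g[1] / a, h)
  y <- p$k * (T1 - T2)
  if (is.null(dT2dt)) dT2dt <- c(0, diff(T2)) / h
  W2 <- -p$P12 * y / p$k + p$C2 * dT2dt + p$P2 * (T2 - T02)
  rec <- signal_record(t = t, y = y, T2 = T2, W2 = W2, Ipel = Ipel,
                       Troom = Troom)
  attr(rec, "T1") <- T1
  rec
}

#' Synthetic thermostat-step property measurement
#'
#' Simulates the at-rest protocol used to estimate skin thermal properties:
#' the device, coupled through `R_skin` to a constant-temperature core,
#' receives a thermostat set-point step of `dT2_step` after `pre_duration`
#' seconds.  The imposed thermostat trace approaches the new set-point as a
#' first-order lag (slew time constant `slew_tau`), emulating the PID
#' controller; both plateaus last at least 5 min by default.
#'
#' @param params device [calorimeter_params()].
#' @param subject a [synthetic_subject()] (only `R_skin`, `C_skin`,
#'   `baseline_core` are used; the core is held constant).
#' @param T2_start initial thermostat set-point, degC.
#' @param dT2_step step amplitude, K (may be negative).
#' @param noise a [noise_spec()].
#' @param pre_duration,post_duration plateau lengths, s.
#' @param slew_tau thermostat slew time constant, s.
#' @param Ipel,Troom,dT0 operating conditions.
#' @return List of class `property_measurement`: `record`
#'   ([signal_record()]), `truth` (list with `R_skin`, `C_skin`, `C1`,
#'   `T_core`, `W1` waveform, `step_time`).
#' @export
make_property_measurement <- function(params, subject, T2_start = 30,
                                      dT2_step = 4, noise = noise_spec(),
                                      pre_duration = 600,
                                      post_duration = 600, slew_tau = 30,
                                      Ipel = 0.09, Troom = 22.5, dT0 = 0) {
  stopifnot(inherits(params, "calorimeter_params"),
            inherits(subject, "synthetic_subject"))
  t <- seq(0, pre_duration + post_duration - 1)
  h <- 1
  step_time <- pre_duration
  rel <- pmax(t - step_time, 0)
  T2 <- T2_start + dT2_step * ifelse(t < step_time, 0, 1 - exp(-rel / slew_tau))
  dT2dt <- ifelse(t < step_time, 0, dT2_step * exp(-rel / slew_tau) / slew_tau)
  C1 <- params$C10 + subject$C_skin
  p <- params
  T01 <- Troom + p$alpha * Ipel + dT0
  T02 <- Troom + p$beta * Ipel + dT0
  sim <- simulate_skin_device(p, C1 = C1, R_skin = subject$R_skin,
                              T_core = subject$baseline_core, T2 = T2,
                              Ipel = Ipel, Troom = Troom, dT0 = dT0, h = h)
  y <- sim$y
  W2 <- -p$P12 * y / p$k + p$C2 * dT2dt + p$P2 * (T2 - T02)
  rec <- signal_record(t = t, y = y, T2 = T2, W2 = W2, Ipel = Ipel,
                       Troom = Troom)
  rec <- add_noise(rec, noise)
  structure(list(record = rec,
                 truth = list(R_skin = subject$R_skin,
                              C_skin = subject$C_skin, C1 = C1,
                              T_core = subject$baseline_core,
                              W1 = sim$W1, T1 = sim$T1,
                              step_time = step_time)),
            class = "property_measurement")
}

#' Synthetic exercise session
#'
#' Generates a full constant-thermostat session: the ground-truth skin heat
#' flux is assembled from the subject's exercise phase fit (applied from
#' exercise onset) and recovery phase fit (rebased at cessation), the rest
#' segment sits at the exercise fit's baseline `A0`, and the device
#' response is simulated with the thermostat held at the set-point (PID
#' emulated by back-computing `W2`).  The true subcutaneous temperature is
#' derived from the simulated plate temperature as
#' `T_core = T1 + W1 R_skin`.
#'
#' @param params device [calorimeter_params()].
#' @param subject a [synthetic_subject()] whose `flux_exercise` /
#'   `flux_recovery` fits define the true response (mW/min units).
#' @param T2_set constant thermostat set-point, degC.
#' @param protocol a [power_protocol()]; its off->on and on->off switch
#'   times define exercise onset and cessation (the bout power itself only
#'   labels the session).
#' @param noise a [noise_spec()].
#' @param Ipel,Troom,dT0 operating conditions.
#' @param T01_dip optional amplitude of a linear surroundings-temperature
#'   dip over the exercise window, K (0 disables; the real device shows a
#'   slight dip when the subject moves).
#' @return List of class `exercise_session`: `record`, `truth` (list with
#'   `W1` waveform in W, `T_core` trace, the generating fits, `start`,
#'   `end`), and `protocol`.
#' @export
make_exercise_session <- function(params, subject, T2_set = 34,
                                  protocol = step_protocol(),
                                  noise = noise_spec(), Ipel = 0.09,
                                  Troom = 22.5, dT0 = 0, T01_dip = 0) {
  stopifnot(inherits(params, "calorimeter_params"),
            inherits(subject, "synthetic_subject"))
  t <- protocol$t
  on <- which(protocol$W > 0)
  if (length(on)) {
    start <- t[on[1]]
    end <- if (on[length(on)] < length(t)) t[on[length(on)] + 1L]
           else t[length(t)]
  } else {
    start <- end <- t[length(t)]
  }
  flux_truth <- function(tt) {
    out <- rep(subject$flux_exercise$A0, length(tt))
    ex_idx <- tt >= start & tt < end
    if (any(ex_idx))
      out[ex_idx] <- evaluate_model(subject$flux_exercise,
                                    (tt[ex_idx] - start) / 60)
    rec_idx <- tt >= end
    if (any(rec_idx) && end > start)
      out[rec_idx] <- evaluate_model(subject$flux_recovery,
                                     (tt[rec_idx] - end) / 60)
    out / 1000
  }
  W1 <- flux_truth(t)
  # the integrator holds inputs constant per step; sampling the continuous
  # flux at interval midpoints makes the discrete response second-order
  # accurate in the sampling period instead of half-sample delayed
  h <- t[2] - t[1]
  W1_mid <- flux_truth(t + h / 2)
  dT0_t <- rep_len(dT0, length(t))
  if (T01_dip != 0 && end > start) {
    ramp <- (t - start) / max(end - start, 1)
    dT0_t <- dT0_t - T01_dip * pmax(0, pmin(ramp, 1)) *
      ifelse(t < end, 1, exp(-(t - end) / 300))
  }
  rec <- simulate_thermostatted(params, W1 = W1_mid, T2 = T2_set,
                                Ipel = Ipel, Troom = Troom, dT0 = dT0_t,
                                t = t, dT2dt = rep(0, length(t)))
  T1 <- attr(rec, "T1")
  T_core <- T1 + W1 * subject$R_skin
  rec <- add_noise(rec, noise)
  structure(list(record = rec,
                 truth = list(W1 = W1, T1 = T1, T_core = T_core,
                              flux_exercise = subject$flux_exercise,
                              flux_recovery = subject$flux_recovery,
                              R_skin = subject$R_skin,
                              start = start, end = end),
                 protocol = protocol),
            class = "exercise_session")
}
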