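#' Parameters of one hand-posture simulator
#'
#' A hand-posture simulator is a two-boundary drift-diffusion process with a
#' stochastic quit-timer. Evidence starts midway between a lower (reject)
#' boundary at 0 and an upper (accept) boundary at `threshold`, offset by
#' `start_bias`, and accumulates at rate `drift_rate` (sign set by stimulus
#' congruence) with diffusion coefficient `noise_coef`. If the per-trial
#' quit-time elapses before either boundary is reached, the simulator gives up
#' and returns a reject ("it's not this hand").
#'
#' The quit-time is drawn from a log-normal distribution parameterised, by
#' default, by its arithmetic mean `quit_mean` and arithmetic standard
#' deviation `quit_sigma` (moment matching to the underlying normal); set
#' `quit_log_space = TRUE` to interpret them directly as meanlog/sdlog.
#'
#' @param drift_rate Evidence units per second accumulated toward the accept
#'   boundary for a congruent stimulus (default 0.1).
#' @param threshold Boundary separation in evidence units; must be positive
#'   (default 0.17).
#' @param start_bias Signed offset of the start point from the midpoint
#'   `threshold / 2`, in evidence units (default 0.006). Must satisfy
#'   `abs(start_bias) < threshold / 2`.
#' @param nondecision_time Seconds added to the decision time to account for
#'   early perceptual and response-generation processes (default 0.3).
#' @param quit_mean,quit_sigma Arithmetic mean and SD of the quit-time
#'   distribution in seconds (defaults 1.6 and 1), unless
#'   `quit_log_space = TRUE`.
#' @param quit_log_space If `TRUE`, `quit_mean`/`quit_sigma` are the meanlog
#'   and sdlog of the log-normal instead of its arithmetic moments.
#' @param noise_coef Diffusion coefficient in evidence units per
#'   sqrt(second); the classic 0.1 scaling convention is the default.
#' @param dt Euler integration step in seconds (default 0.001).
#'
#' @return An object of class `simulator_params` (a named list).
#' @examples
#' p <- simulator_params()
#' p$threshold
#' @export
simulator_params <- function(drift_rate = 0.1,
                             threshold = 0.17,
                             start_bias = 0.006,
                             nondecision_time = 0.3,
                             quit_mean = 1.6,
                             quit_sigma = 1,
                             quit_log_space = FALSE,
                             noise_coef = 0.1,
                             dt = 0.001) {
  p <- structure(
    list(
      drift_rate = drift_rate,
      threshold = threshold,
      start_bias = start_bias,
      nondecision_time = nondecision_time,
      quit_mean = quit_mean,
      quit_sigma = quit_sigma,
      quit_log_space = quit_log_space,
      noise_coef = noise_coef,
      dt = dt
    ),
    class = "simulator_params"
  )
  validate_simulator_params(p)
}

validate_simulator_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("drift_rate", "threshold", "start_bias", "nondecision_time",
              "quit_mean", "quit_sigma", "noise_coef", "dt")) {
    if (!num1(p[[f]])) stop("`", f, "` must be a single finite number", call. = FALSE)
  }
  if (p$threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  if (abs(p$start_bias) >= p$threshold / 2)
    stop("`start_bias` must satisfy |start_bias| < threshold / 2", call. = FALSE)
  if (p$nondecision_time < 0) stop("`nondecision_time` must be >= 0", call. = FALSE)
  if (p$quit_mean <= 0 && !p$quit_log_space)
    stop("`quit_mean` must be positive", call. = FALSE)
  if (p$quit_sigma <= 0) stop("`quit_sigma` must be positive", call. = FALSE)
  if (p$noise_coef <= 0) stop("`noise_coef` must be positive", call. = FALSE)
  if (p$dt <= 0) stop("`dt` must be positive", call. = FALSE)
  qm <- if (p$quit_log_space) exp(p$quit_mean) else p$quit_mean
  if (p$dt >= qm)
    stop("`dt` must be much smaller than the mean quit-time", call. = FALSE)
  p
}

#' @export
print.simulator_params <- function(x, ...) {
  cat("Hand-posture simulator parameters\n")
  cat(sprintf("  drift_rate       %.4g ev/s\n", x$drift_rate))
  cat(sprintf("  threshold        %.4g ev\n", x$threshold))
  cat(sprintf("  start_bias       %+.4g ev\n", x$start_bias))
  cat(sprintf("  nondecision_time %.4g s\n", x$nondecision_time))
  if (x$quit_log_space) {
    cat(sprintf("  quit-timer       lognormal(meanlog %.4g, sdlog %.4g)\n",
                x$quit_mean, x$quit_sigma))
  } else {
    cat(sprintf("  quit-timer       lognormal, mean %.4g s, sd %.4g s\n",
                x$quit_mean, x$quit_sigma))
  }
  cat(sprintf("  noise_coef       %.4g ev/sqrt(s)\n", x$noise_coef))
  cat(sprintf("  dt               %.4g s\n", x$dt))
  invisible(x)
}

#' Log-normal parameters of the quit-timer
#'
#' Converts the quit-timer specification of a [simulator_params()] object to
#' the meanlog/sdlog of the underlying normal. With the default arithmetic
#' parameterisation the conversion is the usual moment matching:
#' `sdlog^2 = log(1 + sigma^2 / mu^2)`, `meanlog = log(mu) - sdlog^2 / 2`.
#'
#' @param params A `simulator_params` object.
#' @return Named numeric vector with elements `meanlog` and `sdlog`.
#' @export
quit_lnorm_params <- function(params) {
  stopifnot(inherits(params, "simulator_params"))
  if (params$quit_log_space) {
    c(meanlog = params$quit_mean, sdlog = params$quit_sigma)
  } else {
    s2 <- log(1 + params$quit_sigma^2 / params$quit_mean^2)
    c(meanlog = log(params$quit_mean) - s2 / 2, sdlog = sqrt(s2))
  }
}

#' Draw quit-times
#'
#' Samples per-trial quit deadlines from the simulator's log-normal quit-timer
#' distribution.
#'
#' @param params A `simulator_params` object.
#' @param n Number of draws.
#' @return Numeric vector of strictly positive durations in seconds.
#' @examples
#' set.seed(1)
#' mean(draw_quit_time(simulator_params(), 1e4)) # close to 1.6
#' @export
draw_quit_time <- function(params, n = 1) {
  validate_simulator_params(params)
  lp <- quit_lnorm_params(params)
  rlnorm(n, lp[["meanlog"]], lp[["sdlog"]])
}

#' Simulate first passages of a single simulator
#'
#' Runs `n` independent trials of the Euler-Maruyama walk between the reject
#' boundary at 0 and the accept boundary at `threshold`, starting at
#' `threshold / 2 + start_bias`, with a fresh quit-time drawn per trial.
#' `drift_sign` is +1 when the stimulus is congruent with this simulator's
#' hand (drift toward accept) and -1 otherwise.
#'
#' Crossings are detected at step granularity by default. With
#' `bridge = TRUE` a Brownian-bridge hit test also detects within-step
#' boundary excursions, removing the O(sqrt(dt)) outward boundary-shift bias
#' of step-granular detection; this mode is intended for validation against
#' the continuous-time closed forms (see [absorption_oracle()]).
#'
#' @param params A `simulator_params` object.
#' @param drift_sign +1 or -1.
#' @param n Number of trials.
#' @param bridge Use sub-step Brownian-bridge crossing detection.
#' @return A tibble with columns `event` (factor: accept / reject / quit) and
#'   `decision_time` (seconds, excluding non-decision time; for quits this is
#'   exactly the drawn quit-time).
#' @examples
#' set.seed(2)
#' simulate_passage(simulator_params(), +1, n = 5)
#' @export
simulate_passage <- function(params, drift_sign, n = 1, bridge = FALSE) {
  validate_simulator_params(params)
  if (!drift_sign %in% c(-1, 1)) stop("`drift_sign` must be +1 or -1", call. = FALSE)
  qt <- draw_quit_time(params, n)
  res <- rcpp_passage_batch(
    n = as.integer(n),
    drift = drift_sign * params$drift_rate,
    threshold = params$threshold,
    start = params$threshold / 2 + params$start_bias,
    noise = params$noise_coef,
    dt = params$dt,
    quit_times = qt,
    bridge = isTRUE(bridge)
  )
  tibble::tibble(
    event = factor(c("accept", "reject", "quit")[res$event],
                   levels = c("accept", "reject", "quit")),
    decision_time = res$time
  )
}

#' Closed-form absorption probability and mean passage time
#'
#' Exact accept-boundary absorption probability and unconditional mean
#' decision time for the uncensored Wiener process implied by a
#' `simulator_params` object (quit-timer ignored). Used as an independent
#' oracle when validating the simulator.
#'
#' For drift v, diffusion coefficient s, boundaries 0 and a, start w:
#' `P(upper) = (1 - exp(-2 v w / s^2)) / (1 - exp(-2 v a / s^2))` and, by
#' optional stopping, `E(T) = (a P(upper) - w) / v`; the zero-drift limits are
#' `w / a` and `w (a - w) / s^2`.
#'
#' @param params A `simulator_params` object.
#' @param drift_sign +1 or -1.
#' @return Named numeric vector with `p_accept` and `mean_time` (seconds).
#' @examples
#' absorption_oracle(simulator_params(start_bias = 0), +1)
#' @export
absorption_oracle <- function(params, drift_sign) {
  validate_simulator_params(params)
  if (!drift_sign %in% c(-1, 1)) stop("`drift_sign` must be +1 or -1", call. = FALSE)
  a <- params$threshold
  w <- a / 2 + params$start_bias
  v <- drift_sign * params$drift_rate
  s2 <- params$noise_coef^2
  if (abs(v) < 1e-12) {
    p <- w / a
    m <- w * (a - w) / s2
  } else {
    th <- 2 * v / s2
    p <- expm1(-th * w) / expm1(-th * a)
    m <- (a * p - w) / v
  }
  c(p_accept = p, mean_time = m)
}

#' Read or write simulator parameters as YAML
#'
#' Serialises a `simulator_params` object to a plain key-value YAML file (all
#' defaults echoed, plus the boundary-geometry convention) and reads it back.
#'
#' @param params A `simulator_params` object.
#' @param path File path.
#' @return `write_simulator_params()` returns `path` invisibly;
#'   `read_simulator_params()` returns a `simulator_params` object.
#' @export
write_simulator_params <- function(params, path) {
  validate_simulator_params(params)
  out <- unclass(params)
  out$boundary_convention <-
    "boundaries at 0 (reject) and threshold (accept); start = threshold/2 + start_bias"
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_simulator_params
#' @export
read_simulator_params <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$boundary_convention <- NULL
  do.call(simulator_params, raw)
}
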