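#' Simulation configuration for the behavioral model
#'
#' The simulator implements a discrete-time Markov model of `n_fish`
#' independent fish moving between an "unassociated" state and `p`
#' receivers. An associated fish leaves its receiver with per-step
#' probability `theta`. An unassociated fish joins a receiver (chosen
#' uniformly among the `p`) with total per-step probability
#' `min(1, p * mu_step)`, where the per-receiver rate `mu_step` is either the
#' constant `mu` (scenario 1, memoryless dynamics) or the sigmoid
#' [joining_probability()] of the time `tau` spent unassociated
#' (scenarios 2 and 3). While a fish is associated it is within detection
#' range and a detection is logged at each step with probability `eta`
#' (`eta = 1`: no instrumental/environmental noise; scenario 2 is run
#' noise-free). All probabilities are per time step.
#'
#' @param scenario 1 (constant joining rate, with noise), 2 (sigmoidal
#'   joining, noise-free) or 3 (sigmoidal joining with noise).
#' @param theta per-step probability to leave a receiver, in (0, 1].
#' @param mu constant per-receiver joining probability (scenario 1).
#' @param mu_inf,K,gamma sigmoid parameters (scenarios 2-3): asymptotic
#'   joining probability, sigmoid constant and rate. The sigmoid switches
#'   from low to high values around \eqn{\tau^* = \ln(K)/\gamma}.
#' @param eta per-step detection probability while associated, in (0, 1].
#' @param n_fish number of fish.
#' @param p number of receivers.
#' @param n_steps number of recorded time steps.
#' @param burn_in unrecorded steps run before recording starts (default 0:
#'   fish start unassociated with `tau = 0` and recording begins
#'   immediately).
#' @param seed optional RNG seed applied by [simulate_detections()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(scenario, theta, mu = NULL, mu_inf = NULL, K = NULL,
                       gamma = NULL, eta = 1, n_fish = 1000, p = 2,
                       n_steps = 100000, burn_in = 0, seed = NULL) {
  if (!scenario %in% 1:3) stop("scenario must be 1, 2 or 3")
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || x <= 0 || x > 1)
      stop(nm, " must be a probability in (0, 1]")
  }
  chk_prob(theta, "theta")
  chk_prob(eta, "eta")
  if (scenario == 1) {
    if (is.null(mu)) stop("scenario 1 requires mu")
    chk_prob(mu, "mu")
  } else {
    if (is.null(mu_inf) || is.null(K) || is.null(gamma))
      stop("scenarios 2-3 require mu_inf, K and gamma")
    chk_prob(mu_inf, "mu_inf")
    if (K <= 0 || gamma <= 0) stop("K and gamma must be positive")
  }
  if (n_fish < 1 || p < 1 || n_steps < 1 || burn_in < 0)
    stop("n_fish, p and n_steps must be >= 1 and burn_in >= 0")
  structure(list(scenario = as.integer(scenario), theta = theta, mu = mu,
                 mu_inf = mu_inf, K = K, gamma = gamma, eta = eta,
                 n_fish = as.integer(n_fish), p = as.integer(p),
                 n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
                 seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  join <- if (x$scenario == 1) sprintf("mu = %g", x$mu)
          else sprintf("mu_inf = %g, K = %g, gamma = %g (tau* = %.0f)",
                       x$mu_inf, x$K, x$gamma, log(x$K) / x$gamma)
  cat(sprintf("sim_config: scenario %d | theta = %g | %s | eta = %g\n",
              x$scenario, x$theta, join, x$eta))
  cat(sprintf("  %d fish, %d receivers, %d steps%s%s\n", x$n_fish, x$p,
              x$n_steps,
              if (x$burn_in > 0) sprintf(", burn-in %d", x$burn_in) else "",
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' Sigmoidal joining probability
#'
#' Per-step, per-receiver probability that a fish which has spent `tau`
#' steps away from all receivers joins one:
#' \deqn{\mu(\tau) = \frac{\mu_\infty}{1 + K e^{-\gamma \tau}}.}
#' It rises from \eqn{\mu_\infty/(1+K)} at \eqn{\tau = 0} towards
#' \eqn{\mu_\infty}, crossing \eqn{\mu_\infty/2} at
#' \eqn{\tau^* = \ln(K)/\gamma}.
#'
#' @param tau non-negative time (steps) spent unassociated.
#' @param mu_inf asymptotic joining probability.
#' @param K sigmoid constant (> 0).
#' @param gamma sigmoid rate (> 0).
#' @return Probability value(s), vectorized over `tau`.
#' @examples
#' joining_probability(log(1000) / 0.01, 0.01, 1000, 0.01)  # = mu_inf / 2
#' @export
joining_probability <- function(tau, mu_inf, K, gamma) {
  stopifnot(all(tau >= 0), mu_inf > 0, K > 0, gamma > 0)
  mu_inf / (1 + K * exp(-gamma * tau))
}

#' Standard parameterizations of the three validation scenarios
#'
#' Returns the canonical parameter sets used to validate the MBP scan:
#' runs of 100,000 steps with 1,000 fish and 2 receivers.
#' Scenario 1 (memoryless, noisy): `theta = 2e-4`, `mu = 1e-4`, one
#' configuration per noise level `eta` in {1, 0.1, 0.01, 0.005}.
#' Scenario 2 (sigmoidal rejoining, noise-free): `theta = 0.02`,
#' `mu_inf = 0.01`, `K = 1000`, one configuration per `gamma` in
#' {0.01, 0.02, 0.04, 0.08}.
#' Scenario 3 (sigmoidal rejoining with noise): `theta = 2e-4`,
#' `mu_inf = 0.01`, `K = 1000`, `gamma = 0.01`, `eta = 0.1`.
#'
#' @return A named list with elements `scenario1` (list of 4 [sim_config()]s
#'   named by `eta`), `scenario2` (list of 4, named by `gamma`) and
#'   `scenario3` (a single [sim_config()]).
#' @examples
#' scenario_presets()$scenario3
#' @export
scenario_presets <- function() {
  s1 <- lapply(c(1, 0.1, 0.01, 0.005), function(eta)
    sim_config(1, theta = 2e-4, mu = 1e-4, eta = eta))
  names(s1) <- c("eta1", "eta0.1", "eta0.01", "eta0.005")
  s2 <- lapply(c(0.01, 0.02, 0.04, 0.08), function(g)
    sim_config(2, theta = 0.02, mu_inf = 0.01, K = 1000, gamma = g, eta = 1))
  names(s2) <- c("gamma0.01", "gamma0.02", "gamma0.04", "gamma0.08")
  s3 <- sim_config(3, theta = 2e-4, mu_inf = 0.01, K = 1000, gamma = 0.01,
                   eta = 0.1)
  list(scenario1 = s1, scenario2 = s2, scenario3 = s3)
}

#' Run the behavioral simulator
#'
#' Simulates the model of [sim_config()] and returns the logged detections
#' as a [detection_table()] (time unit `"steps"`). All fish start
#' unassociated with `tau = 0`; given the same seed the output is
#' identical between runs.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; overrides `config$seed` when given.
#' @return A [detection_table()] with integer receiver ids `"1" .. "p"`,
#'   fish ids `"1" .. "n_fish"` and times in steps `1 .. n_steps`.
#' @examples
#' cfg <- sim_config(1, theta = 0.05, mu = 0.05, eta = 1,
#'                   n_fish = 5, p = 2, n_steps = 200, seed = 7)
#' simulate_detections(cfg)
#' @export
simulate_detections <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  raw <- .sim_core(config$n_fish, config$p, config$n_steps, config$theta,
                   config$eta, config$scenario,
                   if (is.null(config$mu)) 0 else config$mu,
                   if (is.null(config$mu_inf)) 0 else config$mu_inf,
                   if (is.null(config$K)) 0 else config$K,
                   if (is.null(config$gamma)) 0 else config$gamma,
                   config$burn_in)
  if (length(raw$time) == 0L)
    stop("simulation produced no detections; increase n_steps or rates")
  fish_chr <- as.character(raw$fish)
  # character ordering of animal ids, as detection_table() uses
  ord <- order(fish_chr, raw$time, method = "radix")
  out <- data.frame(receiver_id = as.character(raw$receiver[ord]),
                    animal_id = fish_chr[ord],
                    time = as.numeric(raw$time[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "time_unit") <- "steps"
  class(out) <- c("detection_table", "data.frame")
  out
}
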