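#' Define a synthetic-cohort scenario
#'
#' A scenario is the stated generative world for a synthetic cohort: population
#' hyperparameters for every model component plus cohort size, dosing interval
#' and schedule anchor. Per-patient parameters are drawn from the population
#' prior families:
#' \itemize{
#'   \item `z = log(s) ~ Normal(a_s, precision b_s)`,
#'   \item `sigma ~ Gamma(shape a_sigma, scale b_sigma)`,
#'   \item `psi ~ vonMises(a_psi, b_psi)`,
#'   \item `omega ~ LogNormal(mean a_omega, precision b_omega)` (log scale),
#'   \item `lambda ~ Exponential(rate a_lambda)`,
#'   \item `n_total ~ Weibull(shape upsilon, scale kappa)` rounded half-up,
#'     floored at 2 (unless `n_total_fixed` pins it).
#' }
#'
#' Defaults emulate the adherence profile reported for digital-medicine use in
#' serious mental illness: median observed ingestion fraction near 0.76,
#' timing deviations concentrated within a couple of hours of schedule, rare
#' excess dosing, and observed durations of a few weeks to ~9 weeks.
#'
#' @param n_patients Cohort size.
#' @param a_s,b_s Mean and precision of the Normal prior for `z = log(s)`.
#' @param a_sigma,b_sigma Shape and scale of the Gamma prior for `sigma`.
#' @param a_psi,b_psi von Mises mean and concentration for `psi`.
#' @param a_omega,b_omega Mean and precision (log scale) of the LogNormal
#'   prior for `omega`.
#' @param a_lambda Rate of the Exponential prior for `lambda`.
#' @param upsilon,kappa Weibull shape and scale for `n_total`.
#' @param tau Dosing interval in hours.
#' @param n_total_fixed Optional fixed number of dosing opportunities for every
#'   patient (overrides the Weibull draw).
#' @param pc_fraction Optional target prompt-corrector prevalence in `[0, 1]`:
#'   each patient is forced to `p_fs = 1` with this probability, and chance
#'   `p_fs = 1` sequences among the remainder are rejected.
#' @param anchor Schedule anchor timestamp (first scheduled dose). Noon keeps
#'   realistic timing deviations inside their scheduled calendar day.
#' @return Object of class `"cohort_scenario"`.
#' @export
cohort_scenario <- function(n_patients = 80,
                            a_s = 1.7, b_s = 1.0,
                            a_sigma = 1.2, b_sigma = 0.25,
                            a_psi = 0, b_psi = 2,
                            a_omega = 1.5, b_omega = 2,
                            a_lambda = 40,
                            upsilon = 2, kappa = 55,
                            tau = 24, n_total_fixed = NULL,
                            pc_fraction = NULL,
                            anchor = "2023-01-01 12:00:00") {
  pos <- c(b_s = b_s, a_sigma = a_sigma, b_sigma = b_sigma, b_psi = b_psi,
           b_omega = b_omega, a_lambda = a_lambda, upsilon = upsilon,
           kappa = kappa, tau = tau)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stopf("domain error: precisions, shapes, scales, rates and tau must be > 0")
  }
  if (n_patients < 0 || n_patients != round(n_patients)) {
    stopf("n_patients must be a nonnegative integer")
  }
  if (!is.null(pc_fraction) && (pc_fraction < 0 || pc_fraction > 1)) {
    stopf("pc_fraction must lie in [0, 1]")
  }
  if (!is.null(n_total_fixed) && n_total_fixed < 2) {
    stopf("n_total_fixed must be >= 2")
  }
  structure(
    list(n_patients = as.integer(n_patients), a_s = a_s, b_s = b_s,
         a_sigma = a_sigma, b_sigma = b_sigma, a_psi = a_psi, b_psi = b_psi,
         a_omega = a_omega, b_omega = b_omega, a_lambda = a_lambda,
         upsilon = upsilon, kappa = kappa, tau = tau,
         n_total_fixed = n_total_fixed, pc_fraction = pc_fraction,
         anchor = anchor),
    class = "cohort_scenario")
}

#' @export
print.cohort_scenario <- function(x, ...) {
  cat(sprintf("<cohort_scenario> %d patients, tau = %g h\n", x$n_patients, x$tau))
  cat(sprintf("  z ~ N(%g, prec %g); sigma ~ Gamma(%g, scale %g)\n",
              x$a_s, x$b_s, x$a_sigma, x$b_sigma))
  cat(sprintf("  psi ~ VM(%g, %g); omega ~ LogN(%g, prec %g); lambda ~ Exp(%g)\n",
              x$a_psi, x$b_psi, x$a_omega, x$b_omega, x$a_lambda))
  cat(sprintf("  n_total ~ Weibull(%g, %g)%s\n", x$upsilon, x$kappa,
              if (!is.null(x$n_total_fixed))
                sprintf(" [fixed at %d]", x$n_total_fixed) else ""))
  invisible(x)
}

#' Draw von Mises random angles
#'
#' Best-Fisher rejection sampler; `omega = 0` reduces to the circular uniform.
#'
#' @param n Number of draws.
#' @param psi Mean direction.
#' @param omega Concentration (>= 0).
#' @return Angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, psi, omega) {
  if (omega < 0) stopf("omega must be >= 0")
  if (omega == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * omega^2)
  b <- (a - sqrt(2 * a)) / (2 * omega)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- omega * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  wrap_angle(out + psi)
}

#' Draw per-patient model parameters from a scenario
#'
#' Uses the current RNG state; [simulate_cohort()] manages per-patient seed
#' streams on top of this.
#'
#' @param scenario A [cohort_scenario()].
#' @param n Number of patients to draw (default: scenario cohort size).
#' @return `data.frame` with columns `z`, `s`, `sigma`, `psi`, `omega`,
#'   `lambda`, `n_total`, `p_ss`, `p_fs`.
#' @export
draw_patient_params <- function(scenario, n = scenario$n_patients) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  z <- stats::rnorm(n, mean = scenario$a_s, sd = 1 / sqrt(scenario$b_s))
  s <- exp(z)
  sigma <- stats::rgamma(n, shape = scenario$a_sigma, scale = scenario$b_sigma)
  psi <- rvonmises(n, scenario$a_psi, scenario$b_psi)
  omega <- stats::rlnorm(n, meanlog = scenario$a_omega,
                         sdlog = 1 / sqrt(scenario$b_omega))
  lambda <- stats::rexp(n, rate = scenario$a_lambda)
  n_total <- if (!is.null(scenario$n_total_fixed)) {
    rep(as.integer(scenario$n_total_fixed), n)
  } else {
    pmax(2L, as.integer(floor(
      stats::rweibull(n, shape = scenario$upsilon, scale = scenario$kappa) + 0.5)))
  }
  data.frame(z = z, s = s, sigma = sigma, psi = psi, omega = omega,
             lambda = lambda, n_total = n_total,
             p_ss = s / (1 + s), p_fs = sigma * s / (1 + sigma * s))
}

#' Simulate one patient's dose-event sequence
#'
#' Generates a two-state Markov chain of `n_total` dosing opportunities
#' starting at `S`, truncated at the last simulated `S` (re-drawn if no second
#' success occurs, so the sequence is anchored on observed ingestions at both
#' ends). Each success receives a timing deviation `delta = tau * theta /
#' (2*pi)` with `theta ~ vonMises(psi, omega)`, and a per-day excess dosing
#' count drawn from `Poisson(lambda)`.
#'
#' @param s,sigma Helix-coil parameters (used unless `p_ss`/`p_fs` given).
#' @param psi,omega von Mises timing parameters.
#' @param lambda Poisson excess-dosing rate.
#' @param n_total Number of scheduled opportunities before truncation (>= 2).
#' @param tau Dosing interval in hours.
#' @param patient_id Identifier for the resulting sequence.
#' @param p_ss,p_fs Optional direct transition probabilities (override
#'   `s`/`sigma`); `p_fs = 1` simulates prompt-corrector behaviour.
#' @return A `"dose_seq"` object.
#' @export
simulate_sequence <- function(s = NULL, sigma = NULL, psi = 0, omega = 0,
                              lambda = 0, n_total, tau = 24,
                              patient_id = "sim", p_ss = NULL, p_fs = NULL) {
  if (is.null(p_ss)) {
    stopifnot(!is.null(s), !is.null(sigma), s > 0, sigma > 0)
    p_ss <- s / (1 + s)
    p_fs <- sigma * s / (1 + sigma * s)
  }
  stopifnot(n_total >= 2)
  repeat {
    ev <- character(n_total)
    ev[1L] <- "S"
    for (t in 2:n_total) {
      p <- if (ev[t - 1L] == "S") p_ss else p_fs
      ev[t] <- if (stats::runif(1) < p) "S" else "F"
    }
    last_s <- max(which(ev == "S"))
    if (last_s >= 2L) break
  }
  ev <- ev[seq_len(last_s)]
  ns <- sum(ev == "S")
  theta <- rvonmises(ns, psi, omega)
  delta <- tau * theta / (2 * pi)
  excess <- stats::rpois(ns, lambda)
  new_dose_seq(patient_id, ev, delta, excess, tau)
}

# Convert a simulated dose_seq back into exact ingestion timestamps.
sequence_to_log <- function(seq, anchor, covariates = NULL) {
  anchor <- parse_timestamps(anchor)
  slots <- which(seq$events == "S") - 1L  # absolute slot indices, first = 0
  h_first <- slots * seq$tau + seq$deviations
  times_h <- h_first
  for (j in seq_along(slots)) {
    m <- seq$excess_daily_counts[j]
    if (m > 0) {
      # same calendar day (noon-anchored schedule): strictly after the first
      # ingestion, before the day boundary at slot*tau + tau/2
      room <- slots[j] * seq$tau + seq$tau / 2 - h_first[j] - 0.05
      off <- sort(stats::runif(m, 0.01, max(0.02, room)))
      times_h <- c(times_h, h_first[j] + off)
    }
  }
  times <- anchor + sort(times_h) * 3600
  ingestion_log(seq$patient_id, times, tau = seq$tau, anchor = anchor,
                covariates = covariates)
}

# Does this event sequence classify as prompt corrector (p_fs-hat == 1)?
is_pc_sequence <- function(events) {
  tc <- count_transitions(events)
  tc$n_ff == 0L && tc$n_fs >= 1L
}

#' Simulate a synthetic cohort of ingestion logs
#'
#' Draws per-patient parameters from the scenario's population priors,
#' simulates each patient's dose-event sequence, and reconstructs exact
#' ingestion timestamps (`anchor + slot * tau + delta`, excess ingestions later
#' the same day). A single master seed is split into deterministic per-patient
#' streams, so any patient's data are reproducible independently of cohort
#' size. Ground-truth parameters are returned for recovery studies.
#'
#' @param scenario A [cohort_scenario()].
#' @param seed Master RNG seed.
#' @return List with `logs` (named list of [ingestion_log()]), `truth`
#'   (`data.frame` of the generating parameters, including the realized
#'   `n_total` after truncation and the `forced_pc` indicator), and `scenario`.
#' @export
simulate_cohort <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  n <- scenario$n_patients
  logs <- vector("list", n)
  truth <- vector("list", n)
  ids <- sprintf("P%03d", seq_len(n))
  for (i in seq_len(n)) {
    set.seed(patient_seed(seed, i))
    par <- draw_patient_params(scenario, n = 1L)
    forced <- FALSE
    if (!is.null(scenario$pc_fraction)) {
      forced <- stats::runif(1) < scenario$pc_fraction
    }
    if (forced) {
      par$p_fs <- 1
      par$sigma <- Inf
    }
    for (try in 1:200) {
      sq <- simulate_sequence(psi = par$psi, omega = par$omega,
                              lambda = par$lambda, n_total = par$n_total,
                              tau = scenario$tau, patient_id = ids[i],
                              p_ss = par$p_ss, p_fs = par$p_fs)
      if (is.null(scenario$pc_fraction)) break
      pc_now <- is_pc_sequence(sq$events)
      if (forced && pc_now) break
      if (!forced && !pc_now) break
    }
    logs[[i]] <- sequence_to_log(sq, scenario$anchor)
    truth[[i]] <- cbind(data.frame(patient_id = ids[i]), par,
                        data.frame(n_total_realized = sq$n_total,
                                   forced_pc = forced))
  }
  names(logs) <- ids
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(logs = logs, truth = truth, scenario = scenario)
}

#' Write a simulated cohort to CSV
#'
#' Ingestion events go to `path` (`patient_id,timestamp,tau_hours,anchor`),
#' ground truth to `truth_path` when given.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param path Output CSV for ingestion events.
#' @param truth_path Optional output CSV for the ground-truth table.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  rows <- lapply(cohort$logs, function(lg) {
    data.frame(patient_id = lg$patient_id,
               timestamp = format(lg$times, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
               tau_hours = lg$tau,
               anchor = format(lg$anchor, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  if (!is.null(truth_path)) {
    utils::write.csv(cohort$truth, truth_path, row.names = FALSE)
  }
  invisible(path)
}
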