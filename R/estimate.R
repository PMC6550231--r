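#' Count first-order transitions of a dose-event sequence
#'
#' @param seq A `"dose_seq"` object (or a character vector of `"S"`/`"F"`).
#' @return List with integer fields `n_ss`, `n_sf`, `n_fs`, `n_ff`; their sum
#'   equals the number of events minus one.
#' @export
count_transitions <- function(seq) {
  ev <- if (inherits(seq, "dose_seq")) seq$events else seq
  stopifnot(all(ev %in% c("S", "F")))
  if (length(ev) < 2L) stopf("transition counting needs at least 2 events")
  from <- ev[-length(ev)]
  to <- ev[-1L]
  list(n_ss = sum(from == "S" & to == "S"),
       n_sf = sum(from == "S" & to == "F"),
       n_fs = sum(from == "F" & to == "S"),
       n_ff = sum(from == "F" & to == "F"))
}

#' Maximum-likelihood estimates of the Markov transition probabilities
#'
#' Closed-form MLEs of the two-state chain:
#' `p_SS = N_SS / (N_SS + N_SF)` and `p_FS = N_FS / (N_FS + N_FF)`.
#' A zero denominator (no transitions out of that state) leaves the
#' corresponding estimate `NA` with an `undefined_*` flag rather than raising
#' an error. No clipping is applied here; the raw values (including an exact
#' `p_fs == 1`) are preserved for prompt-corrector classification.
#'
#' @param counts Transition counts from [count_transitions()].
#' @return List with `p_ss`, `p_fs` and character vector `flags`.
#' @export
markov_mle <- function(counts) {
  flags <- character()
  den_s <- counts$n_ss + counts$n_sf
  den_f <- counts$n_fs + counts$n_ff
  p_ss <- if (den_s > 0) counts$n_ss / den_s else {
    flags <- c(flags, "undefined_p_ss"); NA_real_
  }
  p_fs <- if (den_f > 0) counts$n_fs / den_f else {
    flags <- c(flags, "undefined_p_fs"); NA_real_
  }
  list(p_ss = p_ss, p_fs = p_fs, flags = flags)
}

#' Helix-coil parameterization of the transition matrix
#'
#' The two-state chain is parameterized through the helix-coil transition model
#' of polymer physics: the success row has odds `s` and the failure row odds
#' `sigma * s`, giving the transition matrix
#' `A = [[s/(1+s), 1/(1+s)], [sigma*s/(1+sigma*s), 1/(1+sigma*s)]]`.
#' `helix_coil_transform()` inverts this: `s = p_ss/(1-p_ss)` and
#' `sigma = (p_fs/(1-p_fs))/s`. Probabilities at exactly 0 or 1 are clipped to
#' `[eps, 1-eps]` first, with a flag, because the odds transform is undefined
#' at the boundary.
#'
#' @param p_ss,p_fs Transition probability estimates.
#' @param eps Clipping bound (default `1e-6`).
#' @return List with `s`, `sigma`, and `flags` (`"clipped_p_ss"` /
#'   `"clipped_p_fs"` when clipping occurred).
#' @export
helix_coil_transform <- function(p_ss, p_fs, eps = 1e-6) {
  flags <- character()
  if (is.na(p_ss) || is.na(p_fs)) {
    return(list(s = if (is.na(p_ss)) NA_real_ else clip_prob(p_ss, eps) /
                  (1 - clip_prob(p_ss, eps)),
                sigma = NA_real_, flags = "undefined_input"))
  }
  if (p_ss <= 0 || p_ss >= 1) flags <- c(flags, "clipped_p_ss")
  if (p_fs <= 0 || p_fs >= 1) flags <- c(flags, "clipped_p_fs")
  ps <- clip_prob(p_ss, eps)
  pf <- clip_prob(p_fs, eps)
  s <- ps / (1 - ps)
  sigma <- (pf / (1 - pf)) / s
  list(s = s, sigma = sigma, flags = flags)
}

#' @rdname helix_coil_transform
#' @param s,sigma Helix-coil parameters (positive).
#' @return `helix_coil_matrix()` returns the 2x2 transition matrix with rows
#'   `S` and `F`; each row sums to 1 exactly.
#' @export
helix_coil_matrix <- function(s, sigma) {
  stopifnot(s > 0, sigma > 0)
  ss <- s / (1 + s)
  fs <- sigma * s / (1 + sigma * s)
  matrix(c(ss, 1 - ss, fs, 1 - fs), nrow = 2, byrow = TRUE,
         dimnames = list(c("S", "F"), c("S", "F")))
}

#' von Mises density for ingestion-timing angles
#'
#' `p(theta) = exp(omega * cos(theta - psi)) / (2 * pi * I0(omega))`, the
#' circular analogue of the normal distribution. `omega = 0` gives the circular
#' uniform density `1/(2*pi)`.
#'
#' @param theta Angles in radians.
#' @param psi Mean direction.
#' @param omega Concentration (>= 0).
#' @return Density values.
#' @export
dvonmises <- function(theta, psi, omega) {
  exp(omega * cos(theta - psi) - log(2 * pi) - log_bessel_I0(omega))
}

#' Maximum-likelihood fit of the von Mises timing-deviation distribution
#'
#' The mean direction `psi` is the circular mean (`atan2` of the mean sine and
#' mean cosine); the concentration `omega` solves `A1(omega) = Rbar`, where
#' `A1 = I1/I0` and `Rbar` is the mean resultant length, by 1-D root finding.
#' `Rbar = 1` (all angles identical) is degenerate: `omega` is capped at
#' `omega_cap` and flagged. `Rbar = 0` leaves `psi` undefined and `omega = 0`.
#'
#' @param angles Angles in radians (at least 2).
#' @param omega_cap Finite stand-in for an infinite concentration.
#' @return List with `psi`, `omega`, `Rbar`, `flags`.
#' @export
vonmises_mle <- function(angles, omega_cap = 500) {
  if (length(angles) < 2L) stopf("von Mises MLE needs at least 2 angles")
  C <- mean(cos(angles))
  S <- mean(sin(angles))
  Rbar <- sqrt(C^2 + S^2)
  flags <- character()
  if (Rbar >= 1 - 1e-12) {
    return(list(psi = atan2(S, C), omega = omega_cap, Rbar = Rbar,
                flags = "omega_capped"))
  }
  if (Rbar <= 1e-12) {
    return(list(psi = NA_real_, omega = 0, Rbar = Rbar,
                flags = "psi_undefined"))
  }
  psi <- atan2(S, C)
  # A1 is strictly increasing from 0 to 1; bracket then root-find
  hi <- 1
  while (bessel_A1(hi) < Rbar && hi < omega_cap) hi <- hi * 2
  hi <- min(hi, omega_cap)
  if (bessel_A1(hi) < Rbar) {
    return(list(psi = psi, omega = omega_cap, Rbar = Rbar,
                flags = "omega_capped"))
  }
  omega <- stats::uniroot(function(w) bessel_A1(w) - Rbar,
                          lower = 0, upper = hi, tol = 1e-10)$root
  list(psi = psi, omega = omega, Rbar = Rbar, flags = flags)
}

#' Poisson rate of excess dosing events
#'
#' The MLE of the per-day rate of excess dosing events (ingestions beyond the
#' first within a day) is the sample mean of the per-day excess counts.
#'
#' @param excess_daily_counts Integer vector of per-day excess counts.
#' @return `lambda` estimate (>= 0).
#' @export
poisson_mle <- function(excess_daily_counts) {
  if (length(excess_daily_counts) == 0L) stopf("empty day list")
  if (any(excess_daily_counts < 0)) stopf("excess counts must be nonnegative")
  mean(excess_daily_counts)
}

#' Maximum-likelihood Weibull fit of observed ingestion durations
#'
#' Fits `N_Total ~ Weibull(upsilon, kappa)` (shape, scale) across patients by
#' profile likelihood: for fixed shape `v` the scale MLE is
#' `kappa(v) = mean(x^v)^(1/v)`, and the profile score in `v` is solved by 1-D
#' root finding. The standard normalized Weibull density is used. The
#' zero-variance degenerate case (all durations equal) sends the shape to
#' infinity; it is capped at `shape_cap` and flagged.
#'
#' @param n_totals Durations in dosing intervals, all >= 1, length >= 3.
#' @param shape_cap Finite stand-in for a divergent shape.
#' @return Object of class `"weibull_fit"`: `upsilon`, `kappa`, `loglik`,
#'   `flags`, `n`.
#' @export
weibull_ml_fit <- function(n_totals, shape_cap = 500) {
  x <- as.numeric(n_totals)
  if (length(x) < 3L) stopf("Weibull fit needs at least 3 durations")
  if (any(x < 1)) stopf("durations must be >= 1 dosing interval")
  lx <- log(x)
  if (stats::sd(x) == 0) {
    fit <- list(upsilon = shape_cap, kappa = mean(x),
                loglik = weibull_loglik(x, shape_cap, mean(x)),
                flags = "shape_capped", n = length(x))
    class(fit) <- "weibull_fit"
    return(fit)
  }
  # profile score d/dv log L(v, kappa(v)) = 0
  score <- function(v) {
    xv <- x^v
    1 / v + mean(lx) - sum(xv * lx) / sum(xv)
  }
  lo <- 1e-3; hi <- 1
  while (score(hi) > 0 && hi < shape_cap) hi <- hi * 2
  if (score(hi) > 0) stopf("Weibull ML did not converge: score positive at cap")
  v <- stats::uniroot(score, lower = lo, upper = hi, tol = 1e-10)$root
  kappa <- mean(x^v)^(1 / v)
  fit <- list(upsilon = v, kappa = kappa, loglik = weibull_loglik(x, v, kappa),
              flags = character(), n = length(x))
  class(fit) <- "weibull_fit"
  fit
}

weibull_loglik <- function(x, v, kappa) {
  sum(stats::dweibull(x, shape = v, scale = kappa, log = TRUE))
}

#' @rdname weibull_ml_fit
#' @param fit A `"weibull_fit"`.
#' @param x Durations at which to evaluate the survival function.
#' @return `weibull_survival()` returns `S(x) = exp(-(x/kappa)^upsilon)`.
#' @export
weibull_survival <- function(fit, x) {
  exp(-(x / fit$kappa)^fit$upsilon)
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull ML fit (n = %d): shape upsilon = %.4g, scale kappa = %.4g\n",
              x$n, x$upsilon, x$kappa))
  cat(sprintf("  log-likelihood = %.4f%s\n", x$loglik,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Per-patient estimates for one dose-event sequence
#'
#' Composes the component MLEs: Markov transition probabilities and their
#' helix-coil transform, von Mises timing-deviation parameters, the Poisson
#' excess-dosing rate, OIP, and the prompt-corrector flag (`p_fs` exactly 1
#' with at least one observed failure).
#'
#' @param seq A `"dose_seq"` object.
#' @return One-row `data.frame` with columns `patient_id`, `p_ss`, `p_fs`, `s`,
#'   `sigma`, `psi`, `omega`, `lambda`, `n_total`, `oip`, `is_pc`, `flags`.
#' @export
estimate_patient <- function(seq) {
  stopifnot(inherits(seq, "dose_seq"))
  counts <- count_transitions(seq)
  mk <- markov_mle(counts)
  hc <- helix_coil_transform(mk$p_ss, mk$p_fs)
  theta <- timing_deviations_to_angles(seq$deviations, seq$tau)
  vm <- if (length(theta) >= 2L) vonmises_mle(theta) else
    list(psi = NA_real_, omega = NA_real_, flags = "too_few_angles")
  lam <- poisson_mle(seq$excess_daily_counts)
  n_fail_trans <- counts$n_fs + counts$n_ff
  is_pc <- !is.na(mk$p_fs) && mk$p_fs == 1 && n_fail_trans >= 1L
  flags <- c(mk$flags, hc$flags, vm$flags)
  data.frame(patient_id = seq$patient_id,
             p_ss = mk$p_ss, p_fs = mk$p_fs,
             s = hc$s, sigma = hc$sigma,
             psi = vm$psi, omega = vm$omega,
             lambda = lam, n_total = seq$n_total, oip = seq$oip,
             is_pc = is_pc,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Fit the hybrid Markov-von Mises ingestion model to a cohort
#'
#' The main fitting function. Takes raw ingestion logs (or pre-derived
#' dose-event sequences), derives each patient's binary success/failure
#' sequence over scheduled dosing opportunities, and computes per-patient
#' maximum-likelihood estimates of all model components:
#' \itemize{
#'   \item two-state Markov chain (`p_ss`, `p_fs`) with helix-coil parameters
#'     (`s`, `sigma`),
#'   \item von Mises ingestion-timing deviation distribution (`psi`, `omega`),
#'   \item Poisson excess-dosing rate (`lambda`),
#'   \item observed ingestion percent (`oip`) and duration (`n_total`),
#' }
#' plus a cohort-level Weibull ML fit of the observed ingestion durations and
#' prompt-corrector classification. Patients with fewer than two observed
#' ingestions are excluded and listed in `$exclusions`.
#'
#' The Bayesian population layer is fitted separately with [fit_population()].
#'
#' @param data A list of [ingestion_log()] objects, a list of `"dose_seq"`
#'   objects, a `data.frame` with columns `patient_id` and `timestamp`, or a
#'   path to an ingestion-event CSV (see [read_ingestion_logs()]).
#' @param tau Dosing interval in hours (used when `data` carries none).
#' @param covariates Optional `data.frame` of per-patient covariates keyed by
#'   `patient_id`.
#' @return An object of class `"dosechain"`: list with `estimates`
#'   (per-patient `data.frame`), `sequences`, `duration_fit`
#'   (`"weibull_fit"` or `NULL` when fewer than 3 patients), `exclusions`,
#'   `covariates`, `tau`, `n`.
#' @seealso [fit_population()], [classify_pc()], [compare_groups()]
#' @examples
#' sc <- cohort_scenario(n_patients = 12)
#' cohort <- simulate_cohort(sc, seed = 1)
#' fit <- dosechain(cohort$logs)
#' fit
#' summary(fit)
#' head(coef(fit))
#' @export
dosechain <- function(data, tau = 24, covariates = NULL) {
  if (is.character(data) && length(data) == 1L) {
    data <- read_ingestion_logs(data, tau = tau)
  }
  if (is.data.frame(data)) {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp), add = TRUE)
    utils::write.csv(data, tmp, row.names = FALSE)
    data <- read_ingestion_logs(tmp, tau = tau)
  }
  stopifnot(is.list(data))
  exclusions <- data.frame(patient_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  seqs <- list()
  for (x in data) {
    if (inherits(x, "dose_seq")) {
      seqs[[x$patient_id]] <- x
    } else if (inherits(x, "ingestion_log")) {
      sq <- tryCatch(derive_sequence(x), dosechain_exclusion = function(e) e)
      if (inherits(sq, "dosechain_exclusion")) {
        exclusions <- rbind(exclusions, data.frame(
          patient_id = x$patient_id, reason = conditionMessage(sq),
          stringsAsFactors = FALSE))
      } else {
        seqs[[sq$patient_id]] <- sq
      }
    } else {
      stopf("data must contain ingestion_log or dose_seq objects")
    }
  }
  if (length(seqs) == 0L) stopf("no patients left after exclusions")
  est <- do.call(rbind, lapply(seqs, estimate_patient))
  rownames(est) <- NULL
  dur_fit <- if (nrow(est) >= 3L) weibull_ml_fit(est$n_total) else NULL
  if (!is.null(covariates)) {
    stopifnot("patient_id" %in% names(covariates))
  }
  structure(
    list(estimates = est, sequences = seqs, duration_fit = dur_fit,
         exclusions = exclusions, covariates = covariates,
         tau = tau, n = nrow(est)),
    class = "dosechain")
}

#' @export
print.dosechain <- function(x, ...) {
  cat("Hybrid Markov-von Mises ingestion model\n")
  cat(sprintf("  %d patients fitted (%d excluded)\n", x$n, nrow(x$exclusions)))
  cat(sprintf("  median OIP = %.1f%%, PC fraction = %.1f%%\n",
              100 * stats::median(x$estimates$oip),
              100 * mean(x$estimates$is_pc)))
  if (!is.null(x$duration_fit)) {
    cat(sprintf("  duration: Weibull(upsilon = %.3g, kappa = %.3g)\n",
                x$duration_fit$upsilon, x$duration_fit$kappa))
  }
  invisible(x)
}

#' @export
coef.dosechain <- function(object, ...) {
  e <- object$estimates
  m <- as.matrix(e[, c("p_ss", "p_fs", "s", "sigma", "psi", "omega",
                       "lambda", "n_total", "oip")])
  rownames(m) <- e$patient_id
  m
}

quantile_summary <- function(v) {
  v <- v[is.finite(v)]
  if (!length(v)) return(c(median = NA, iqr = NA, min = NA, max = NA,
                           mean = NA, se = NA))
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], iqr = q[3] - q[1], min = min(v), max = max(v),
    mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
}

#' @export
summary.dosechain <- function(object, ...) {
  e <- object$estimates
  # helix-coil parameters are summarized over interior estimates only:
  # boundary transition probabilities map to the clip constant, not to data
  interior <- function(p) !is.na(p) & p > 0 & p < 1
  stats_tab <- t(sapply(
    list(oip_percent = 100 * e$oip,
         excess_rate_percent = 100 * e$lambda,
         duration_days = e$n_total * object$tau / 24,
         p_ss = e$p_ss, p_fs = e$p_fs,
         s = e$s[interior(e$p_ss)],
         sigma = e$sigma[interior(e$p_ss) & interior(e$p_fs)],
         psi = e$psi, omega = e$omega, lambda = e$lambda),
    quantile_summary))
  out <- list(n = object$n, n_excluded = nrow(object$exclusions),
              stats = stats_tab,
              pc_fraction = mean(e$is_pc),
              duration_fit = object$duration_fit)
  class(out) <- "summary.dosechain"
  out
}

#' @export
print.summary.dosechain <- function(x, ...) {
  cat(sprintf("Cohort of %d patients (%d excluded)\n", x$n, x$n_excluded))
  cat("Adherence characteristics (median / IQR / range / mean / se):\n")
  print(round(x$stats, 3))
  cat(sprintf("Prompt correctors: %.1f%%\n", 100 * x$pc_fraction))
  if (!is.null(x$duration_fit)) print(x$duration_fit)
  invisible(x)
}

#' Stationary success probability and expected OIP per patient
#'
#' The long-run success probability of the two-state chain is
#' `pi_S = p_fs / (1 + p_fs - p_ss)`; over a long observation window it is the
#' model-expected observed ingestion fraction.
#'
#' @param object A `"dosechain"` fit.
#' @param type `"stationary"` (default) or `"oip"` (identical value, named for
#'   its interpretation).
#' @param ... Unused.
#' @return Named numeric vector, one entry per patient (`NA` when `p_fs` is
#'   undefined).
#' @export
predict.dosechain <- function(object, type = c("stationary", "oip"), ...) {
  type <- match.arg(type)
  e <- object$estimates
  out <- stationary_success(e$p_ss, e$p_fs)
  names(out) <- e$patient_id
  out
}

#' @rdname predict.dosechain
#' @param p_ss,p_fs Transition probabilities.
#' @export
stationary_success <- function(p_ss, p_fs) {
  p_fs / (1 + p_fs - p_ss)
}

#' @export
residuals.dosechain <- function(object, ...) {
  # circular residuals: timing angles minus the fitted mean direction, wrapped
  e <- object$estimates
  res <- lapply(seq_along(object$sequences), function(i) {
    sq <- object$sequences[[i]]
    theta <- timing_deviations_to_angles(sq$deviations, sq$tau)
    psi <- e$psi[match(sq$patient_id, e$patient_id)]
    if (is.na(psi)) return(theta * NA_real_)
    wrap_angle(theta - psi)
  })
  names(res) <- names(object$sequences)
  res
}

#' Simulate cohorts from a fitted model (parametric bootstrap)
#'
#' Draws new synthetic cohorts using each fitted patient's own parameter
#' estimates (sequence length, Markov, von Mises and Poisson components),
#' i.e. a parametric bootstrap of the observed cohort.
#'
#' @param object A `"dosechain"` fit.
#' @param nsim Number of replicate cohorts.
#' @param seed RNG seed.
#' @param ... Unused.
#' @return List of length `nsim`; each element is a list of `"dose_seq"`
#'   objects.
#' @export
simulate.dosechain <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  e <- object$estimates
  lapply(seq_len(nsim), function(r) {
    out <- lapply(seq_len(nrow(e)), function(i) {
      p_fs <- if (is.na(e$p_fs[i])) 1 else e$p_fs[i]
      simulate_sequence(
        p_ss = clip_prob(e$p_ss[i]), p_fs = clip_prob(p_fs),
        psi = if (is.na(e$psi[i])) 0 else e$psi[i],
        omega = if (is.na(e$omega[i])) 0 else e$omega[i],
        lambda = e$lambda[i], n_total = e$n_total[i], tau = object$tau,
        patient_id = e$patient_id[i])
    })
    names(out) <- e$patient_id
    out
  })
}

#' @export
plot.dosechain <- function(x, which = c("oip", "lambda", "psi", "omega",
                                        "duration"), ...) {
  e <- x$estimates
  which <- match.arg(which, several.ok = TRUE)
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  if ("oip" %in% which) {
    graphics::hist(e$oip, breaks = 10, freq = FALSE, col = "grey85",
                   main = "Observed ingestion fraction", xlab = "OIP")
  }
  if ("lambda" %in% which) {
    graphics::hist(e$lambda, breaks = 10, freq = FALSE, col = "grey85",
                   main = "Excess dosing rate", xlab = expression(lambda))
  }
  if ("psi" %in% which) {
    graphics::hist(e$psi, breaks = 10, freq = FALSE, col = "grey85",
                   main = "Timing mean direction", xlab = expression(psi))
  }
  if ("omega" %in% which) {
    graphics::hist(e$omega[is.finite(e$omega)], breaks = 10, freq = FALSE,
                   col = "grey85", main = "Timing concentration",
                   xlab = expression(omega))
  }
  if ("duration" %in% which && !is.null(x$duration_fit)) {
    xs <- sort(e$n_total)
    emp <- 1 - stats::ecdf(xs)(xs)
    graphics::plot(xs, emp, type = "s", main = "Duration survival",
                   xlab = "N_Total (days)", ylab = "S(x)")
    graphics::lines(xs, weibull_survival(x$duration_fit, xs), col = "blue")
  }
  invisible(x)
}
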