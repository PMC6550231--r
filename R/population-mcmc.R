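# Hierarchical population layer: the per-patient estimates are treated as
# observations whose sampling distributions are the stated prior families
#   z(i) = log s(i) ~ Normal(a_s, precision b_s)
#   sigma(i)        ~ Gamma(shape a_sigma, scale b_sigma)
#   psi(i)          ~ vonMises(a_psi, b_psi)
#   omega(i)        ~ LogNormal(mean a_omega, precision b_omega)
#   lambda(i)       ~ Exponential(rate a_lambda)
# and the nine hyperparameters are sampled by adaptive random-walk
# Metropolis-within-Gibbs under weakly informative hyperpriors.

DC_HYPER <- c("a_s", "b_s", "a_sigma", "b_sigma", "a_psi", "b_psi",
              "a_omega", "b_omega", "a_lambda")
# which hyperparameters are constrained positive (log-scale proposals)
DC_POSITIVE <- c(a_s = FALSE, b_s = TRUE, a_sigma = TRUE, b_sigma = TRUE,
                 a_psi = FALSE, b_psi = TRUE, a_omega = FALSE, b_omega = TRUE,
                 a_lambda = TRUE)
# which observation component each hyperparameter enters
DC_COMPONENT <- c(a_s = "z", b_s = "z", a_sigma = "sigma", b_sigma = "sigma",
                  a_psi = "psi", b_psi = "psi", a_omega = "omega",
                  b_omega = "omega", a_lambda = "lambda")

#' MCMC configuration for the population layer
#'
#' Desk-scale defaults (3 chains, 20,000 kept iterations each, burn-in 5,000,
#' thinning 2) converge well within minutes for this 9-parameter posterior;
#' `full_scale = TRUE` restores the conservative full-scale settings
#' (200,000 kept, burn-in 50,000).
#'
#' @param n_chains Number of chains (>= 2; Gelman-Rubin needs several).
#' @param n_iter Kept iterations per chain after burn-in and thinning.
#' @param burn_in Iterations discarded (adaptation happens here and is then
#'   frozen, preserving detailed balance).
#' @param thin Thinning interval.
#' @param seed Master seed; chain `c` uses `seed + 1000 * c`.
#' @param proposal_scales Optional named numeric vector of initial random-walk
#'   step sizes per hyperparameter.
#' @param hyperpriors Optional named list overriding the hyperprior
#'   parameters: `location_prec` (Normal precision for `a_s`, `a_omega`),
#'   `positive_rate` (Exponential rate for all positive hyperparameters),
#'   `a_psi_conc` (von Mises concentration for `a_psi`).
#' @param full_scale If `TRUE`, use 200,000 kept iterations with 50,000
#'   burn-in per chain.
#' @return Object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 20000, burn_in = 5000,
                        thin = 2, seed = 1, proposal_scales = NULL,
                        hyperpriors = NULL, full_scale = FALSE) {
  if (full_scale) {
    n_iter <- 200000
    burn_in <- 50000
  }
  if (n_chains < 2) stopf("n_chains must be >= 2 (Gelman-Rubin needs multiple chains)")
  if (n_iter <= 0 || burn_in < 0 || thin < 1) {
    stopf("invalid MCMC settings: n_iter > 0, burn_in >= 0, thin >= 1 required")
  }
  scales <- stats::setNames(rep(0.25, length(DC_HYPER)), DC_HYPER)
  if (!is.null(proposal_scales)) scales[names(proposal_scales)] <- proposal_scales
  hp <- list(location_prec = 0.001, positive_rate = 0.01, a_psi_conc = 0.01)
  if (!is.null(hyperpriors)) hp[names(hyperpriors)] <- hyperpriors
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), proposal_scales = scales,
                 hyperpriors = hp, full_scale = full_scale),
            class = "mcmc_config")
}

# Extract per-component observation vectors from an estimates data.frame,
# applying the per-component dropping policy (undefined and degenerate values
# are dropped component-wise, never patient-wise; raw p_fs survives elsewhere
# for PC classification).
population_observations <- function(estimates) {
  e <- estimates
  z_ok <- !is.na(e$p_ss) & e$p_ss > 0 & e$p_ss < 1 & !is.na(e$s)
  z <- log(e$s[z_ok])
  sig_ok <- z_ok & !is.na(e$p_fs) & e$p_fs > 0 & e$p_fs < 1 & !is.na(e$sigma)
  sigma <- e$sigma[sig_ok]
  psi <- e$psi[!is.na(e$psi)]
  om_ok <- !is.na(e$omega) & e$omega > 0 &
    !grepl("omega_capped", e$flags %||% "")
  omega <- e$omega[om_ok]
  lambda <- e$lambda[!is.na(e$lambda)]
  list(z = z, sigma = sigma, psi = psi, omega = omega, lambda = lambda)
}

population_suffstats <- function(obs) {
  list(z = list(n = length(obs$z), sx = sum(obs$z), sx2 = sum(obs$z^2)),
       sigma = list(n = length(obs$sigma), sx = sum(obs$sigma),
                    slx = sum(log(obs$sigma))),
       psi = list(n = length(obs$psi), sc = sum(cos(obs$psi)),
                  ss = sum(sin(obs$psi))),
       omega = list(n = length(obs$omega), sy = sum(log(obs$omega)),
                    sy2 = sum(log(obs$omega)^2)),
       lambda = list(n = length(obs$lambda), sl = sum(obs$lambda)))
}

ll_normal_prec <- function(a, b, n, sx, sx2) {
  0.5 * n * log(b) - 0.5 * n * log(2 * pi) -
    0.5 * b * (sx2 - 2 * a * sx + n * a^2)
}

component_loglik <- function(comp, theta, st) {
  s <- st[[comp]]
  switch(comp,
    z = ll_normal_prec(theta[["a_s"]], theta[["b_s"]], s$n, s$sx, s$sx2),
    sigma = (theta[["a_sigma"]] - 1) * s$slx - s$sx / theta[["b_sigma"]] -
      s$n * (theta[["a_sigma"]] * log(theta[["b_sigma"]]) +
               lgamma(theta[["a_sigma"]])),
    psi = theta[["b_psi"]] * (cos(theta[["a_psi"]]) * s$sc +
                                sin(theta[["a_psi"]]) * s$ss) -
      s$n * (log(2 * pi) + log_bessel_I0(theta[["b_psi"]])),
    omega = ll_normal_prec(theta[["a_omega"]], theta[["b_omega"]],
                           s$n, s$sy, s$sy2) - s$sy,
    lambda = s$n * log(theta[["a_lambda"]]) - theta[["a_lambda"]] * s$sl)
}

hyperprior_logdens <- function(param, value, hp) {
  if (param %in% c("a_s", "a_omega")) {
    stats::dnorm(value, 0, 1 / sqrt(hp$location_prec), log = TRUE)
  } else if (param == "a_psi") {
    hp$a_psi_conc * cos(value) - log(2 * pi) - log_bessel_I0(hp$a_psi_conc)
  } else {
    stats::dexp(value, rate = hp$positive_rate, log = TRUE)
  }
}

#' Log-posterior of the population hyperparameters
#'
#' Sum of the component log-likelihoods of the individual estimates under the
#' prior families plus the hyperprior log-densities. This is the exact
#' quantity the Metropolis-within-Gibbs sampler targets (it is evaluated
#' through per-component sufficient statistics).
#'
#' @param theta Named numeric vector of the nine hyperparameters (`a_s`,
#'   `b_s`, `a_sigma`, `b_sigma`, `a_psi`, `b_psi`, `a_omega`, `b_omega`,
#'   `a_lambda`).
#' @param obs List of observation vectors as built internally from the
#'   estimates (fields `z`, `sigma`, `psi`, `omega`, `lambda`), or an
#'   estimates `data.frame` with the columns produced by [estimate_patient()].
#' @param hyperpriors Hyperprior settings (see [mcmc_config()]).
#' @return Log-posterior value (up to the constant normalizer).
#' @export
population_logpost <- function(theta, obs,
                               hyperpriors = mcmc_config()$hyperpriors) {
  if (is.data.frame(obs)) obs <- population_observations(obs)
  st <- population_suffstats(obs)
  ll <- sum(vapply(c("z", "sigma", "psi", "omega", "lambda"),
                   function(cp) component_loglik(cp, theta, st), 0))
  lp <- sum(vapply(DC_HYPER,
                   function(p) hyperprior_logdens(p, theta[[p]], hyperpriors), 0))
  ll + lp
}

# Moment-based initial values, jittered per chain for overdispersed starts.
mcmc_init <- function(obs, jitter = TRUE) {
  z <- obs$z; sg <- obs$sigma; ps <- obs$psi; y <- log(obs$omega); lam <- obs$lambda
  mom_gamma <- function(x) {
    m <- mean(x); v <- stats::var(x)
    if (!is.finite(v) || v <= 0) v <- max(m^2, 1e-4)
    c(shape = max(m^2 / v, 1e-2), scale = max(v / m, 1e-4))
  }
  g <- mom_gamma(sg)
  C <- mean(cos(ps)); S <- mean(sin(ps)); R <- sqrt(C^2 + S^2)
  b_psi0 <- tryCatch(vonmises_mle(ps)$omega, error = function(e) 1)
  init <- c(a_s = mean(z), b_s = 1 / max(stats::var(z), 1e-4),
            a_sigma = unname(g["shape"]), b_sigma = unname(g["scale"]),
            a_psi = atan2(S, C), b_psi = max(min(b_psi0, 100), 1e-2),
            a_omega = mean(y), b_omega = 1 / max(stats::var(y), 1e-4),
            a_lambda = if (sum(lam) > 0) length(lam) / sum(lam) else 100)
  if (jitter) {
    for (p in DC_HYPER) {
      if (DC_POSITIVE[[p]]) {
        init[[p]] <- init[[p]] * exp(stats::rnorm(1, 0, 0.4))
      } else if (p == "a_psi") {
        init[[p]] <- wrap_angle(init[[p]] + stats::rnorm(1, 0, 0.4))
      } else {
        init[[p]] <- init[[p]] + stats::rnorm(1, 0, 0.4)
      }
    }
  }
  init
}

run_one_chain <- function(st, hp, init, scales, burn_in, n_keep, thin, seed) {
  set.seed(seed)
  theta <- init
  comps <- c("z", "sigma", "psi", "omega", "lambda")
  cur_ll <- stats::setNames(vapply(comps, function(cp)
    component_loglik(cp, theta, st), 0), comps)
  cur_lp <- stats::setNames(vapply(DC_HYPER, function(p)
    hyperprior_logdens(p, theta[[p]], hp), 0), DC_HYPER)
  if (!all(is.finite(c(cur_ll, cur_lp)))) {
    stopf("initial hyperparameter values give non-finite log-posterior")
  }
  total <- burn_in + n_keep * thin
  draws <- matrix(NA_real_, n_keep, length(DC_HYPER),
                  dimnames = list(NULL, DC_HYPER))
  acc <- stats::setNames(integer(length(DC_HYPER)), DC_HYPER)
  batch_acc <- acc
  ridge_scale <- 0.3
  ridge_acc <- 0L
  ridge_batch <- 0L
  kept <- 0L
  for (it in seq_len(total)) {
    for (p in DC_HYPER) {
      cp <- DC_COMPONENT[[p]]
      old <- theta[[p]]
      if (DC_POSITIVE[[p]]) {
        prop <- old * exp(scales[[p]] * stats::rnorm(1))
        log_jac <- log(prop) - log(old)
      } else {
        prop <- old + scales[[p]] * stats::rnorm(1)
        if (p == "a_psi") prop <- wrap_angle(prop)
        log_jac <- 0
      }
      theta[[p]] <- prop
      new_ll <- component_loglik(cp, theta, st)
      new_lp <- hyperprior_logdens(p, prop, hp)
      lr <- (new_ll + new_lp) - (cur_ll[[cp]] + cur_lp[[p]]) + log_jac
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        cur_ll[[cp]] <- new_ll
        cur_lp[[p]] <- new_lp
        acc[[p]] <- acc[[p]] + 1L
        batch_acc[[p]] <- batch_acc[[p]] + 1L
      } else {
        theta[[p]] <- old
      }
    }
    # joint ridge move for the anti-correlated Gamma (shape, scale) pair:
    # opposite shifts in (log a_sigma, log b_sigma) preserve the Gamma mean
    # and traverse the posterior ridge; symmetric in log space (unit Jacobian)
    {
      eps <- ridge_scale * stats::rnorm(1)
      old_a <- theta[["a_sigma"]]; old_b <- theta[["b_sigma"]]
      theta[["a_sigma"]] <- old_a * exp(eps)
      theta[["b_sigma"]] <- old_b * exp(-eps)
      new_ll <- component_loglik("sigma", theta, st)
      new_lp_a <- hyperprior_logdens("a_sigma", theta[["a_sigma"]], hp)
      new_lp_b <- hyperprior_logdens("b_sigma", theta[["b_sigma"]], hp)
      lr <- (new_ll + new_lp_a + new_lp_b) -
        (cur_ll[["sigma"]] + cur_lp[["a_sigma"]] + cur_lp[["b_sigma"]])
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        cur_ll[["sigma"]] <- new_ll
        cur_lp[["a_sigma"]] <- new_lp_a
        cur_lp[["b_sigma"]] <- new_lp_b
        ridge_acc <- ridge_acc + 1L
        ridge_batch <- ridge_batch + 1L
      } else {
        theta[["a_sigma"]] <- old_a
        theta[["b_sigma"]] <- old_b
      }
    }
    if (it <= burn_in && it %% 50L == 0L) {
      # adapt toward ~0.44 acceptance; frozen once burn-in ends
      rate <- batch_acc / 50
      scales <- scales * exp(0.6 * (rate - 0.44))
      scales <- pmin(pmax(scales, 1e-4), 10)
      batch_acc[] <- 0L
      ridge_scale <- min(max(ridge_scale * exp(0.6 * (ridge_batch / 50 - 0.44)),
                             1e-4), 10)
      ridge_batch <- 0L
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- theta
    }
  }
  list(draws = draws, accept = acc / total, scales = scales)
}

#' Fit the Bayesian population layer by MCMC
#'
#' Samples the nine population hyperparameters given the individual estimates
#' via adaptive random-walk Metropolis-within-Gibbs (log-scale proposals for
#' positive hyperparameters; adaptation only during burn-in). Undefined or
#' degenerate component estimates are dropped per component: `sigma` values
#' from an exact `p_fs` of 0 or 1 and capped `omega` values do not enter their
#' population models, while each patient's remaining components are kept.
#'
#' @param estimates A `"dosechain"` fit, or a per-patient estimates
#'   `data.frame` (columns as produced by [estimate_patient()]), or a named
#'   list of observation vectors `z`, `sigma`, `psi`, `omega`, `lambda`.
#' @param config An [mcmc_config()].
#' @return Object of class `"population_fit"`: `draws` (array kept-iterations
#'   x chains x 9), `summary` (posterior mean/median/2.5%/97.5% per
#'   hyperparameter), `psrf` (Gelman-Rubin per hyperparameter), `ess`,
#'   `accept`, `obs`, `config`.
#' @seealso [gelman_rubin()], [posterior_predictive_densities()],
#'   [export_diagnostics()]
#' @export
run_mcmc <- function(estimates, config = mcmc_config()) {
  if (inherits(estimates, "dosechain")) estimates <- estimates$estimates
  if (is.data.frame(estimates)) {
    if (nrow(estimates) < 10L) {
      stopf("too few patients for the population layer (%d < 10)",
            nrow(estimates))
    }
    obs <- population_observations(estimates)
  } else {
    obs <- estimates
  }
  for (cp in c("z", "sigma", "psi", "omega", "lambda")) {
    if (length(obs[[cp]]) < 3L) {
      stopf("component '%s' has %d defined values; need >= 3", cp,
            length(obs[[cp]]))
    }
  }
  st <- population_suffstats(obs)
  hp <- config$hyperpriors
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 1000L * ch)
    init <- mcmc_init(obs, jitter = TRUE)
    chains[[ch]] <- run_one_chain(st, hp, init, config$proposal_scales,
                                  config$burn_in, config$n_iter, config$thin,
                                  seed = config$seed + 1000L * ch + 1L)
  }
  draws <- array(NA_real_, c(config$n_iter, config$n_chains, length(DC_HYPER)),
                 dimnames = list(NULL, paste0("chain", seq_len(config$n_chains)),
                                 DC_HYPER))
  for (ch in seq_len(config$n_chains)) draws[, ch, ] <- chains[[ch]]$draws
  psrf <- vapply(DC_HYPER, function(p) psrf_matrix(draws[, , p]), 0)
  ess <- vapply(DC_HYPER, function(p) ess_matrix(draws[, , p]), 0)
  pooled <- apply(draws, 3, c)
  summ <- data.frame(
    parameter = DC_HYPER,
    mean = colMeans(pooled),
    median = apply(pooled, 2, stats::median),
    q025 = apply(pooled, 2, stats::quantile, 0.025),
    q975 = apply(pooled, 2, stats::quantile, 0.975),
    psrf = psrf, ess = ess, row.names = NULL)
  accept <- Reduce(`+`, lapply(chains, `[[`, "accept")) / config$n_chains
  structure(list(draws = draws, summary = summ, psrf = psrf, ess = ess,
                 accept = accept, obs = obs, config = config),
            class = "population_fit")
}

#' @rdname run_mcmc
#' @param object A `"dosechain"` fit or estimates table.
#' @param ... Passed to [mcmc_config()] when `config` is not supplied.
#' @param config An [mcmc_config()].
#' @export
fit_population <- function(object, config = NULL, ...) {
  if (is.null(config)) config <- mcmc_config(...)
  run_mcmc(object, config)
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("Population MCMC fit: %d chains x %d kept (burn-in %d, thin %d)\n",
              x$config$n_chains, x$config$n_iter, x$config$burn_in,
              x$config$thin))
  cat(sprintf("  max Gelman-Rubin PSRF = %.4f (%s)\n", max(x$psrf),
              if (max(x$psrf) < 1.05) "converged, < 1.05" else ">= 1.05!"))
  print(x$summary, digits = 4)
  invisible(x)
}

#' @export
summary.population_fit <- function(object, ...) object$summary

#' @export
plot.population_fit <- function(x, params = DC_HYPER, ...) {
  old <- graphics::par(mfrow = c(3, ceiling(length(params) / 3)))
  on.exit(graphics::par(old))
  for (p in params) {
    graphics::matplot(x$draws[, , p], type = "l", lty = 1,
                      main = p, xlab = "iteration", ylab = p)
  }
  invisible(x)
}

# PSRF of a single (iterations x chains) matrix.
psrf_matrix <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  if (m < 2L) stopf("Gelman-Rubin requires at least 2 chains")
  if (n < 2L) stopf("Gelman-Rubin requires at least 2 draws per chain")
  W <- mean(apply(mat, 2, stats::var))
  B <- n * stats::var(colMeans(mat))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic multiple-sequence convergence diagnostic: the ratio of the
#' pooled-chain variance estimate `(n-1)/n * W + B/n` to the mean within-chain
#' variance `W`, square-rooted. Values near 1 indicate the chains have mixed;
#' the conventional convergence bound used here is 1.05.
#'
#' @param x A matrix (iterations x chains), a list of equal-length chain
#'   vectors, or a `"population_fit"`.
#' @param parameter For a `"population_fit"`, the hyperparameter name
#'   (default: all nine).
#' @return PSRF value(s).
#' @export
gelman_rubin <- function(x, parameter = NULL) {
  if (inherits(x, "population_fit")) {
    if (is.null(parameter)) return(x$psrf)
    return(psrf_matrix(x$draws[, , parameter]))
  }
  if (is.list(x) && !is.data.frame(x)) x <- do.call(cbind, x)
  psrf_matrix(as.matrix(x))
}

# Effective sample size by Geyer's initial positive sequence, summed over
# chains.
ess_matrix <- function(mat) {
  sum(apply(mat, 2, function(v) {
    n <- length(v)
    if (stats::var(v) == 0) return(n)
    rho <- stats::acf(v, lag.max = min(n - 1L, 1000L), plot = FALSE)$acf[-1]
    # pair sums Gamma_k = rho_{2k-1} + rho_{2k}; truncate at first negative
    npair <- floor(length(rho) / 2)
    tau <- 1
    for (k in seq_len(npair)) {
      g <- rho[2 * k - 1] + rho[2 * k]
      if (g < 0) break
      tau <- tau + 2 * g
    }
    n / tau
  }))
}

#' Posterior-predictive density curves
#'
#' For each model component, averages the prior-family density over posterior
#' hyperparameter draws on a fixed grid (the modeled curves of the visual
#' predictive checks). The transition-probability curves are obtained by
#' pushing joint `(s, sigma)` draws through `p_ss = s/(1+s)` and
#' `p_fs = sigma*s/(1+sigma*s)`, and the OIP curve through the chain's
#' long-run success probability `pi_S = p_fs / (1 + p_fs - p_ss)`, followed by
#' kernel density estimation on `[0, 1]`.
#'
#' @param result A `"population_fit"`.
#' @param n_draws Number of posterior draws used for averaging.
#' @param n_mc Monte-Carlo individuals per draw for the transformed curves.
#' @param grid_n Grid length per component.
#' @param psrf_threshold Convergence bound; a result above it only warns.
#' @return Named list of `data.frame`s (`x`, `density`) for `s`, `sigma`,
#'   `p_ss`, `p_fs`, `oip`, `lambda`, `psi`, `omega`.
#' @export
posterior_predictive_densities <- function(result, n_draws = 200, n_mc = 50,
                                           grid_n = 201,
                                           psrf_threshold = 1.05) {
  stopifnot(inherits(result, "population_fit"))
  if (max(result$psrf) >= psrf_threshold) {
    warnf("posterior not converged (max PSRF = %.3f >= %.2f); proceeding",
          max(result$psrf), psrf_threshold)
  }
  pooled <- apply(result$draws, 3, c)
  idx <- round(seq(1, nrow(pooled), length.out = min(n_draws, nrow(pooled))))
  th <- pooled[idx, , drop = FALSE]
  obs <- result$obs
  grid_upper <- function(v, fallback) {
    if (length(v)) stats::quantile(v, 0.99) * 1.5 else fallback
  }
  s_grid <- seq(1e-3, max(grid_upper(exp(obs$z), 20), 1), length.out = grid_n)
  sig_grid <- seq(1e-3, max(grid_upper(obs$sigma, 5), 0.5), length.out = grid_n)
  lam_grid <- seq(0, max(grid_upper(obs$lambda, 0.2), 0.05), length.out = grid_n)
  om_grid <- seq(1e-3, max(grid_upper(obs$omega, 30), 1), length.out = grid_n)
  psi_grid <- seq(-pi, pi, length.out = grid_n)
  p_grid <- seq(0, 1, length.out = grid_n)
  avg_density <- function(grid, f) {
    acc <- numeric(length(grid))
    for (i in seq_len(nrow(th))) acc <- acc + f(grid, th[i, ])
    acc / nrow(th)
  }
  out <- list(
    s = data.frame(x = s_grid, density = avg_density(s_grid, function(g, t)
      stats::dlnorm(g, meanlog = t[["a_s"]], sdlog = 1 / sqrt(t[["b_s"]])))),
    sigma = data.frame(x = sig_grid, density = avg_density(sig_grid, function(g, t)
      stats::dgamma(g, shape = t[["a_sigma"]], scale = t[["b_sigma"]]))),
    lambda = data.frame(x = lam_grid, density = avg_density(lam_grid, function(g, t)
      stats::dexp(g, rate = t[["a_lambda"]]))),
    psi = data.frame(x = psi_grid, density = avg_density(psi_grid, function(g, t)
      dvonmises(g, t[["a_psi"]], t[["b_psi"]]))),
    omega = data.frame(x = om_grid, density = avg_density(om_grid, function(g, t)
      stats::dlnorm(g, meanlog = t[["a_omega"]], sdlog = 1 / sqrt(t[["b_omega"]]))))
  )
  # Monte-Carlo transformation for p_ss, p_fs and the stationary OIP
  ps_all <- pf_all <- pi_all <- numeric(0)
  for (i in seq_len(nrow(th))) {
    t <- th[i, ]
    s_mc <- stats::rlnorm(n_mc, t[["a_s"]], 1 / sqrt(t[["b_s"]]))
    sig_mc <- stats::rgamma(n_mc, shape = t[["a_sigma"]], scale = t[["b_sigma"]])
    ps <- s_mc / (1 + s_mc)
    pf <- sig_mc * s_mc / (1 + sig_mc * s_mc)
    ps_all <- c(ps_all, ps); pf_all <- c(pf_all, pf)
    pi_all <- c(pi_all, stationary_success(ps, pf))
  }
  kde01 <- function(v) {
    d <- stats::density(v, from = 0, to = 1, n = grid_n, bw = "SJ")
    data.frame(x = d$x, density = d$y)
  }
  out$p_ss <- kde01(ps_all)
  out$p_fs <- kde01(pf_all)
  out$oip <- kde01(pi_all)
  out
}

#' Export MCMC diagnostics and overlay data as CSV
#'
#' Writes the PSRF table (one row per hyperparameter), ESS table, posterior
#' summary, thinned trace data per chain, and density-overlay files (model
#' predictive curve plus empirical histogram density of the individual
#' estimates) into `dir`.
#'
#' @param result A `"population_fit"`.
#' @param dir Output directory (created if needed).
#' @param max_trace_rows Maximum trace rows kept per chain.
#' @return Character vector of written file paths, invisibly.
#' @export
export_diagnostics <- function(result, dir, max_trace_rows = 2000) {
  stopifnot(inherits(result, "population_fit"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stopf("cannot create output directory: %s", dir)
  }
  files <- character()
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  w(data.frame(parameter = names(result$psrf), psrf = unname(result$psrf)),
    "psrf.csv")
  w(data.frame(parameter = names(result$ess), ess = unname(result$ess)),
    "ess.csv")
  w(result$summary, "posterior_summary.csv")
  n_iter <- dim(result$draws)[1]
  keep <- unique(round(seq(1, n_iter, length.out = min(max_trace_rows, n_iter))))
  for (ch in seq_len(dim(result$draws)[2])) {
    tr <- as.data.frame(result$draws[keep, ch, ])
    tr <- cbind(iteration = keep, tr)
    w(tr, sprintf("trace_chain%d.csv", ch))
  }
  pred <- suppressWarnings(posterior_predictive_densities(result))
  emp <- list(s = exp(result$obs$z), sigma = result$obs$sigma,
              lambda = result$obs$lambda, psi = result$obs$psi,
              omega = result$obs$omega)
  for (nm in names(pred)) {
    df <- pred[[nm]]
    ev <- emp[[nm]]
    if (!is.null(ev) && length(ev) > 1) {
      h <- graphics::hist(ev, breaks = "FD", plot = FALSE)
      bin <- findInterval(df$x, h$breaks, rightmost.closed = TRUE)
      df$empirical_density <- ifelse(bin >= 1 & bin <= length(h$density),
                                     h$density[pmax(bin, 1)], 0)
    }
    w(df, sprintf("overlay_%s.csv", nm))
  }
  invisible(files)
}
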