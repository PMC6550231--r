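# Small synthetic observation set shared across MCMC tests.
mcmc_test_obs <- function(n = 60, seed = 17) {
  set.seed(seed)
  list(z = rnorm(n, 1.7, 1), sigma = rgamma(n, shape = 1.2, scale = 0.25),
       psi = rvonmises(n, 0, 2), omega = rlnorm(n, 1.5, 1 / sqrt(2)),
       lambda = rexp(n, 40))
}

test_that("sampler log-posterior equals an independently coded density sum", {
  obs <- mcmc_test_obs()
  hp <- mcmc_config()$hyperpriors
  # independent route: plain d* sums over the raw observations
  oracle <- function(t) {
    sum(dnorm(obs$z, t[["a_s"]], 1 / sqrt(t[["b_s"]]), log = TRUE)) +
      sum(dgamma(obs$sigma, shape = t[["a_sigma"]], scale = t[["b_sigma"]],
                 log = TRUE)) +
      sum(t[["b_psi"]] * cos(obs$psi - t[["a_psi"]]) -
            log(2 * pi * besselI(t[["b_psi"]], 0))) +
      sum(dlnorm(obs$omega, t[["a_omega"]], 1 / sqrt(t[["b_omega"]]),
                 log = TRUE)) +
      sum(dexp(obs$lambda, rate = t[["a_lambda"]], log = TRUE)) +
      dnorm(t[["a_s"]], 0, sqrt(1000), log = TRUE) +
      dnorm(t[["a_omega"]], 0, sqrt(1000), log = TRUE) +
      sum(dexp(c(t[["b_s"]], t[["b_omega"]], t[["a_sigma"]], t[["b_sigma"]],
                 t[["a_lambda"]], t[["b_psi"]]), 0.01, log = TRUE)) +
      0.01 * cos(t[["a_psi"]]) - log(2 * pi * besselI(0.01, 0))
  }
  set.seed(2)
  for (i in 1:100) {
    theta <- c(a_s = rnorm(1, 0, 2), b_s = rexp(1) + 0.05,
               a_sigma = rexp(1) + 0.05, b_sigma = rexp(1) + 0.05,
               a_psi = runif(1, -pi, pi), b_psi = rexp(1) + 0.05,
               a_omega = rnorm(1, 0, 2), b_omega = rexp(1) + 0.05,
               a_lambda = rexp(1, 0.1) + 0.05)
    expect_equal(population_logpost(theta, obs), oracle(theta),
                 tolerance = 1e-8)
  }
})

test_that("Gelman-Rubin PSRF matches its definition", {
  # identical chains: no between-chain variance
  v <- rnorm(100)
  expect_lte(gelman_rubin(cbind(v, v)), 1 + 1e-6)
  # far-separated chains with tiny within-variance
  set.seed(5)
  expect_gt(gelman_rubin(cbind(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1))), 10)
  # hand-computed 2x4 example: chains (1,2,3,4) and (3,4,5,6):
  # W = 5/3, B = 8, varplus = 3/4*5/3 + 8/4 = 3.25, PSRF = sqrt(3.25/(5/3))
  expect_equal(gelman_rubin(cbind(1:4, 3:6)), sqrt(3.25 / (5 / 3)),
               tolerance = 1e-12)
  expect_equal(gelman_rubin(list(c(1, 2, 3, 4), c(3, 4, 5, 6))),
               1.3964240, tolerance = 1e-6)
  expect_error(gelman_rubin(matrix(1:10, ncol = 1)), "2 chains")
})

test_that("run_mcmc is deterministic and validates its inputs", {
  obs <- mcmc_test_obs(30)
  cfg <- mcmc_config(n_iter = 300, burn_in = 200, seed = 9)
  r1 <- run_mcmc(obs, cfg)
  r2 <- run_mcmc(obs, cfg)
  expect_identical(r1$draws, r2$draws)
  # draws respect the hyperparameter domains
  for (p in c("b_s", "a_sigma", "b_sigma", "b_psi", "b_omega", "a_lambda")) {
    expect_true(all(r1$draws[, , p] > 0))
  }
  # PSRF is bounded below by sqrt((n-1)/n), slightly under 1 at finite n
  expect_true(all(r1$psrf >= sqrt(299 / 300) - 1e-8))
  # too few patients
  est <- estimate_patient(make_seq("SFSSFS"))
  expect_error(run_mcmc(est[rep(1, 5), ]), "too few patients")
  expect_error(mcmc_config(n_chains = 1), "n_chains")
})

test_that("degenerate data concentrate the posterior at the shared value", {
  obs <- mcmc_test_obs(40)
  obs$z <- rep(1.3, 40)
  r <- run_mcmc(obs, mcmc_config(n_iter = 1500, burn_in = 1000, seed = 2))
  a_s <- c(r$draws[, , "a_s"])
  b_s <- c(r$draws[, , "b_s"])
  expect_equal(mean(a_s), 1.3, tolerance = 0.05)
  expect_gt(median(b_s), 50) # precision pushed very large
})

test_that("posterior means recover known hyperparameters from true draws", {
  set.seed(41)
  sc <- cohort_scenario(n_patients = 200)
  tr <- draw_patient_params(sc)
  obs <- list(z = tr$z, sigma = tr$sigma, psi = tr$psi, omega = tr$omega,
              lambda = tr$lambda)
  r <- run_mcmc(obs, mcmc_config(n_iter = 3000, burn_in = 1500, seed = 41))
  post <- r$summary
  get <- function(p, col = "mean") post[post$parameter == p, col]
  expect_lt(abs(get("a_s") - sc$a_s), 0.15)
  expect_lt(abs(get("a_sigma") - sc$a_sigma) / sc$a_sigma, 0.25)
  expect_lt(abs(get("b_sigma") - sc$b_sigma) / sc$b_sigma, 0.25)
  expect_lt(abs(get("a_lambda") - sc$a_lambda) / sc$a_lambda, 0.25)
  expect_lt(max(r$psrf), 1.05)
})

test_that("independently seeded chains land on overlapping posteriors", {
  obs <- mcmc_test_obs(80)
  r1 <- run_mcmc(obs, mcmc_config(n_iter = 1500, burn_in = 1000, seed = 1))
  r2 <- run_mcmc(obs, mcmc_config(n_iter = 1500, burn_in = 1000, seed = 2))
  for (p in c("a_s", "b_s", "a_lambda")) {
    i1 <- quantile(c(r1$draws[, , p]), c(0.05, 0.95))
    i2 <- quantile(c(r2$draws[, , p]), c(0.05, 0.95))
    lo <- max(i1[1], i2[1]); hi <- min(i1[2], i2[2])
    overlap <- (hi - lo) / min(diff(i1), diff(i2))
    expect_gt(overlap, 0.8)
  }
})

test_that("posterior predictive densities follow the prior families", {
  obs <- mcmc_test_obs(50)
  # hand-built point-mass posterior: predictive equals the single density
  theta <- c(a_s = 1.5, b_s = 1, a_sigma = 1.2, b_sigma = 0.25, a_psi = 0,
             b_psi = 2, a_omega = 1.5, b_omega = 2, a_lambda = 40)
  draws <- array(rep(theta, each = 100 * 2), c(100, 2, 9),
                 dimnames = list(NULL, c("chain1", "chain2"), names(theta)))
  fake <- structure(list(draws = draws, psrf = setNames(rep(1, 9), names(theta)),
                         ess = setNames(rep(200, 9), names(theta)),
                         obs = obs, summary = NULL,
                         config = mcmc_config(n_iter = 100)),
                    class = "population_fit")
  pd <- posterior_predictive_densities(fake, n_draws = 10, n_mc = 200)
  expect_equal(pd$s$density,
               dlnorm(pd$s$x, 1.5, 1), tolerance = 1e-12)
  expect_equal(pd$sigma$density,
               dgamma(pd$sigma$x, shape = 1.2, scale = 0.25), tolerance = 1e-12)
  expect_equal(pd$psi$density, dvonmises(pd$psi$x, 0, 2), tolerance = 1e-12)
  # transformed curves are proper densities on [0, 1]
  for (nm in c("p_ss", "p_fs", "oip")) {
    dx <- diff(pd[[nm]]$x[1:2])
    expect_equal(sum(pd[[nm]]$density) * dx, 1, tolerance = 0.1)
  }
  # non-converged input warns but proceeds
  fake$psrf["a_s"] <- 1.2
  expect_warning(posterior_predictive_densities(fake, n_draws = 5, n_mc = 20),
                 "not converged")
})

test_that("stationary success probability matches long-run simulation", {
  expect_equal(stationary_success(0.5, 0.5), 0.5)
  # algebra vs a long simulated chain
  set.seed(6)
  sq <- simulate_sequence(p_ss = 0.8, p_fs = 0.4, psi = 0, omega = 1,
                          lambda = 0, n_total = 20000)
  expect_equal(mean(sq$events == "S"), stationary_success(0.8, 0.4),
               tolerance = 0.02)
})

test_that("diagnostics export writes complete, well-formed files", {
  obs <- mcmc_test_obs(40)
  r <- run_mcmc(obs, mcmc_config(n_iter = 400, burn_in = 300, seed = 3))
  dir <- file.path(tempdir(), "diag-test")
  files <- export_diagnostics(r, dir)
  expect_true(all(file.exists(files)))
  expect_true(all(file.info(files)$size > 0))
  psrf <- read.csv(file.path(dir, "psrf.csv"))
  expect_equal(nrow(psrf), 9) # one row per hyperparameter
  # overlay grids cover the observed range of each statistic
  for (nm in c("sigma", "lambda", "omega")) {
    ov <- read.csv(file.path(dir, sprintf("overlay_%s.csv", nm)))
    expect_gte(max(ov$x), max(obs[[nm]]))
    expect_true("empirical_density" %in% names(ov))
  }
})
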