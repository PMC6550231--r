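test_that("transition counts enumerate consecutive pairs", {
  tc <- count_transitions(make_seq("SSFSFFS"))
  expect_equal(tc, list(n_ss = 1L, n_sf = 2L, n_fs = 2L, n_ff = 1L))
  expect_equal(sum(unlist(tc)), 6L)
  expect_equal(count_transitions(make_seq("SSSSS")),
               list(n_ss = 4L, n_sf = 0L, n_fs = 0L, n_ff = 0L))
  expect_equal(count_transitions(make_seq("SFS")),
               list(n_ss = 0L, n_sf = 1L, n_fs = 1L, n_ff = 0L))
  expect_error(count_transitions("S"), "at least 2")
})

test_that("Markov MLEs are the closed-form transition frequencies", {
  m <- markov_mle(list(n_ss = 1L, n_sf = 2L, n_fs = 2L, n_ff = 1L))
  expect_equal(m$p_ss, 1 / 3)
  expect_equal(m$p_fs, 2 / 3)
  # every failure followed by success: p_fs is exactly 1 (prompt corrector)
  m2 <- markov_mle(list(n_ss = 5L, n_sf = 3L, n_fs = 3L, n_ff = 0L))
  expect_identical(m2$p_fs, 1)
  # no failure states at all: p_fs undefined, flagged not thrown
  m3 <- markov_mle(count_transitions(make_seq("SSSS")))
  expect_true(is.na(m3$p_fs))
  expect_true("undefined_p_fs" %in% m3$flags)
})

test_that("Markov MLE agrees with grid likelihood maximization", {
  # all binary sequences of length 2..8 (both ends free), oracle = grid argmax
  for (len in 2:8) {
    states <- expand.grid(rep(list(c("S", "F")), len), stringsAsFactors = FALSE)
    for (r in seq_len(nrow(states))) {
      tc <- count_transitions(unlist(states[r, ], use.names = FALSE))
      m <- markov_mle(tc)
      g <- markov_grid_oracle(tc)
      if (!is.na(m$p_ss)) expect_lte(abs(m$p_ss - g$p_ss), g$step + 1e-9)
      if (!is.na(m$p_fs)) expect_lte(abs(m$p_fs - g$p_fs), g$step + 1e-9)
    }
  }
  # random sequences of length 9..12
  set.seed(99)
  for (r in 1:200) {
    len <- sample(9:12, 1)
    ev <- sample(c("S", "F"), len, replace = TRUE)
    tc <- count_transitions(ev)
    m <- markov_mle(tc)
    g <- markov_grid_oracle(tc)
    if (!is.na(m$p_ss)) expect_lte(abs(m$p_ss - g$p_ss), g$step + 1e-9)
    if (!is.na(m$p_fs)) expect_lte(abs(m$p_fs - g$p_fs), g$step + 1e-9)
  }
})

test_that("helix-coil transform inverts the transition-matrix parameterization", {
  hc <- helix_coil_transform(0.5, 0.5)
  expect_equal(hc$s, 1); expect_equal(hc$sigma, 1)
  # s = 3 forward: p_ss = 3/4
  expect_equal(helix_coil_matrix(3, 1)["S", "S"], 0.75)
  hc2 <- helix_coil_transform(1 / 3, 2 / 3)
  expect_equal(hc2$s, 0.5, tolerance = 1e-12)
  expect_equal(hc2$sigma, 4, tolerance = 1e-12)
  # substituting back into the matrix recovers the probabilities
  A <- helix_coil_matrix(hc2$s, hc2$sigma)
  expect_equal(A["S", "S"], 1 / 3, tolerance = 1e-12)
  expect_equal(A["F", "S"], 2 / 3, tolerance = 1e-12)

  # round-trip identity on 1000 random interior points, 1e-10
  set.seed(4)
  ps <- runif(1000, 0.001, 0.999); pf <- runif(1000, 0.001, 0.999)
  for (i in seq_len(1000)) {
    h <- helix_coil_transform(ps[i], pf[i])
    A <- helix_coil_matrix(h$s, h$sigma)
    expect_equal(A["S", "S"], ps[i], tolerance = 1e-10)
    expect_equal(A["F", "S"], pf[i], tolerance = 1e-10)
    expect_identical(unname(rowSums(A)), c(1, 1)) # rows sum to 1 exactly
  }
  # boundary probabilities are clipped with a flag
  hb <- helix_coil_transform(1, 0.5)
  expect_true("clipped_p_ss" %in% hb$flags)
})

test_that("von Mises MLE matches symmetry, degeneracy and simulation oracles", {
  # symmetric angles about zero
  expect_equal(vonmises_mle(c(-0.7, 0.7))$psi, 0)
  # identical angles: psi exact, omega at the cap with a flag
  vd <- vonmises_mle(rep(0.3, 5))
  expect_equal(vd$psi, 0.3)
  expect_equal(vd$omega, 500)
  expect_true("omega_capped" %in% vd$flags)
  # recovery from 5000 draws, checked against grid maximization oracle
  set.seed(12)
  th <- rvonmises(5000, 0.5, 4)
  fit <- vonmises_mle(th)
  expect_equal(fit$psi, 0.5, tolerance = 0.05)
  expect_equal(fit$omega, 4, tolerance = 4 * 0.1)
  g <- vm_grid_oracle(th)
  expect_equal(fit$psi, g$psi, tolerance = 0.01)
  expect_lte(abs(fit$omega - g$omega) / g$omega, 0.01)
  # the A1 equation is solved tightly
  expect_lt(abs(dosechain:::bessel_A1(fit$omega) - fit$Rbar), 1e-8)
})

test_that("von Mises density is a proper circular density", {
  for (om in c(0.1, 1, 5, 20)) {
    q <- integrate(dvonmises, -pi, pi, psi = 0.4, omega = om,
                   rel.tol = 1e-10)
    expect_lt(abs(q$value - 1), 1e-6)
  }
  # omega -> 0 limit is the circular uniform
  expect_equal(dvonmises(seq(-3, 3, 0.5), 1, 0), rep(1 / (2 * pi), 13))
})

test_that("Poisson excess-dose rate is the per-day sample mean", {
  expect_equal(poisson_mle(c(0, 0, 0)), 0)
  expect_equal(poisson_mle(c(0, 0, 1)), 1 / 3)
  set.seed(8)
  expect_equal(poisson_mle(rpois(10000, 0.05)), 0.05, tolerance = 0.01)
  expect_error(poisson_mle(integer(0)), "empty")
})

test_that("Weibull duration fit recovers parameters and handles degeneracy", {
  set.seed(15)
  # shape 1 is the exponential special case
  x1 <- rweibull(2000, shape = 1, scale = 50)
  x1 <- x1[x1 >= 1]
  f1 <- weibull_ml_fit(x1)
  expect_equal(f1$upsilon, 1, tolerance = 0.1)
  # recovery within 5% at n = 2000
  x2 <- rweibull(2000, shape = 2, scale = 55)
  f2 <- weibull_ml_fit(x2)
  expect_equal(f2$upsilon, 2, tolerance = 2 * 0.05)
  expect_equal(f2$kappa, 55, tolerance = 55 * 0.05)
  # independent route: intercept-only Weibull AFT (survreg)
  sr <- survival::survreg(survival::Surv(x2, rep(1, length(x2))) ~ 1,
                          dist = "weibull")
  expect_equal(f2$upsilon, 1 / sr$scale, tolerance = 1e-3)
  expect_equal(f2$kappa, exp(coef(sr)[[1]]), tolerance = 1e-3)
  # zero-variance data: shape diverges, capped with a flag
  fd <- weibull_ml_fit(rep(40, 10))
  expect_equal(fd$upsilon, 500)
  expect_true("shape_capped" %in% fd$flags)
  # shape-1 survival equals the exponential closed form
  f_exp <- list(upsilon = 1, kappa = 50)
  xs <- c(1, 10, 50, 120)
  expect_equal(weibull_survival(f_exp, xs), exp(-xs / 50))
})

test_that("estimate_patient composes all components with the PC rule", {
  # all-success patient: OIP 1, p_fs undefined, not a prompt corrector
  e1 <- estimate_patient(make_seq(strrep("S", 10)))
  expect_equal(e1$oip, 1)
  expect_true(is.na(e1$p_fs))
  expect_false(e1$is_pc)
  # every failure promptly corrected
  e2 <- estimate_patient(make_seq("SFSSFS"))
  expect_true(e2$is_pc)
  expect_identical(e2$p_fs, 1)
  # deviations feed the von Mises component
  sq <- make_seq("SSSS", deviations = c(1, 2, 1.5, 0.5))
  e3 <- estimate_patient(sq)
  th <- 2 * pi * c(1, 2, 1.5, 0.5) / 24
  expect_equal(e3$psi, atan2(mean(sin(th)), mean(cos(th))))
  # single-dose patients never reach estimation
  expect_error(derive_sequence(make_log("X", 5)), class = "dosechain_exclusion")
})

test_that("individual p_ss recovery is accurate at 56+ opportunities", {
  sc <- cohort_scenario(n_patients = 200, n_total_fixed = 60)
  co <- simulate_cohort(sc, seed = 31)
  fit <- dosechain(co$logs)
  m <- merge(fit$estimates, co$truth, by = "patient_id")
  expect_lt(median(abs(m$p_ss.x - m$p_ss.y)), 0.08)
})
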