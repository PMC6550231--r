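test_that("prompt-corrector classification follows the exact p_fs = 1 rule", {
  e <- rbind(estimate_patient(make_seq("SFSSFS")),   # p_fs = 1 -> PC
             estimate_patient(make_seq("SFFSFS")),   # p_fs = 2/3 -> NPC
             estimate_patient(make_seq("SSSSS")))    # no failures -> excluded
  e$patient_id <- c("pc", "npc", "allS")
  cls <- classify_pc(e)
  expect_equal(cls$pc_ids, "pc")
  expect_equal(cls$npc_ids, "npc")
  expect_equal(cls$excluded_ids, "allS")
  # classification uses raw p_fs, invariant to helix-coil clipping:
  # the PC row's sigma is a clipped artifact but p_fs stays exactly 1
  expect_identical(e$p_fs[1], 1)
})

test_that("Mann-Whitney agrees with exhaustive permutation enumeration", {
  # canonical separated example: U = 0, one-sided p = 1/20
  mw <- mann_whitney(1:3, 4:6)
  or <- mw_permutation_oracle(1:3, 4:6)
  expect_equal(mw$statistic, 0)
  expect_equal(or$p_one_less, 0.05)
  expect_equal(mw$p_value, 0.1) # two-sided
  # identical groups: p = 1
  expect_equal(mann_whitney(c(2, 2, 3), c(2, 3, 2))$p_value, 1)
  # random small samples, with and without ties, vs the oracle
  set.seed(23)
  for (i in 1:40) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    vals <- if (i %% 2) rnorm(n1 + n2) else sample(1:4, n1 + n2, TRUE)
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    mw <- mann_whitney(x, y)
    or <- mw_permutation_oracle(x, y)
    expect_equal(mw$statistic, or$u)
    expect_equal(mw$p_value, min(1, or$p_two))
    if (!anyDuplicated(vals)) {
      # third route: R's exact Wilcoxon
      expect_equal(mw$p_value, wilcox.test(x, y, exact = TRUE)$p.value)
    }
  }
  # large-sample normal approximation is close to the exact path
  set.seed(31)
  x <- rnorm(15); y <- rnorm(15, 0.5)
  p_approx <- mann_whitney(x, y, exact_max = 20)$p_value
  p_ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(p_approx, p_ref, tolerance = 1e-10)
})

test_that("Fisher exact matches the hypergeometric enumeration", {
  # 2x2 table [[5,0],[0,5]]: only the two perfectly separated tables are as
  # extreme; p = 2 / choose(10, 5)
  tab <- matrix(c(5, 0, 0, 5), 2)
  expect_equal(fisher.test(tab)$p.value, 2 / choose(10, 5))
})

test_that("log-rank comparison matches hand-computed observed-expected arithmetic", {
  # identical duration multisets: no separation
  km0 <- km_logrank(c(10, 20, 30), c(10, 20, 30))
  expect_lt(km0$chi_sq, 1e-8)
  expect_gt(km0$p_value, 0.99)
  # 4 vs 4 toy with interleaved event times; by hand, PC at-risk expectations
  # E = 1/2 + 3/7 + 1/2 + 2/5 + 1/2 + 1/3 + 1/2 + 0 = 3.161905 against
  # O = 4 events, and hypergeometric variances V = 1/4 + 12/49 + 1/4 + 6/25 +
  # 1/4 + 2/9 + 1/4 = 1.707120, so chi^2 = 0.838095^2 / 1.707120 = 0.411445
  km <- km_logrank(c(10, 20, 30, 40), c(15, 25, 35, 45))
  expect_equal(km$chi_sq, 0.411445, tolerance = 1e-4)
  expect_equal(km$df, 1)
  # clear separation is detected
  set.seed(3)
  d1 <- rweibull(50, 2, 40); d2 <- d1 + 30
  expect_lt(km_logrank(d1, d2)$p_value, 0.01)
  # survival curves are exported for overlay plots
  expect_true(all(c("group", "time", "survival") %in% names(km$curves)))
  expect_error(km_logrank(numeric(0), c(1, 2)), "non-empty")
})

test_that("group comparison runs the full battery with covariates", {
  sc <- cohort_scenario(n_patients = 60, n_total_fixed = 45, pc_fraction = 0.3)
  co <- simulate_cohort(sc, seed = 19)
  set.seed(19)
  cov <- data.frame(
    patient_id = names(co$logs),
    diagnosis = sample(c("schizophrenia", "bipolar1", "mdd"), 60, TRUE),
    sex = sample(c("F", "M"), 60, TRUE),
    race = sample(c("black", "white"), 60, TRUE),
    age = round(runif(60, 19, 64)),
    disease_duration_years = round(runif(60, 1, 38)),
    dose_mg = sample(c(2, 5, 10, 15, 20, 30), 60, TRUE),
    n_concomitant = sample(1:12, 60, TRUE),
    cgis = sample(1:7, 60, TRUE), psp = round(runif(60, 40, 99)))
  fit <- dosechain(co$logs, covariates = cov)
  rep <- compare_groups(fit)
  expect_s3_class(rep, "subgroup_report")
  # parameter panels + covariate tests + categorical tests + log-rank
  for (nm in c("mw_p_ss", "mw_oip", "mw_lambda", "mw_psi", "mw_omega",
               "mw_age", "mw_dose_mg", "mw_cgis", "mw_psp",
               "mw_n_concomitant", "mw_disease_duration_years",
               "chisq_diagnosis", "fisher_sex", "fisher_race",
               "logrank_duration")) {
    expect_true(nm %in% names(rep$tests), info = nm)
    expect_true(is.finite(rep$tests[[nm]]$p_value))
  }
  # a 3-diagnosis table against 2 groups has 2 degrees of freedom
  expect_equal(rep$tests$chisq_diagnosis$df, 2)
  # group summaries carry all six panels
  expect_setequal(names(rep$group_stats),
                  c("p_fs", "p_ss", "oip", "lambda", "psi", "omega"))
  expect_equal(rownames(rep$group_stats$oip), c("NPC", "PC"))
  # report files
  files <- write_subgroup_report(rep, file.path(tempdir(), "sub-test"))
  expect_true(all(file.exists(files)))
})

test_that("simulated PC prevalence concentrates at the target fraction", {
  sc <- cohort_scenario(n_patients = 400, n_total_fixed = 40,
                        pc_fraction = 0.25)
  co <- simulate_cohort(sc, seed = 13)
  fit <- dosechain(co$logs)
  cls <- classify_pc(fit)
  frac <- length(cls$pc_ids) / (length(cls$pc_ids) + length(cls$npc_ids))
  expect_gte(frac, 0.20)
  expect_lte(frac, 0.30)
})
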