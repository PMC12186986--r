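test_that("exclusions remove the union of flagged individuals", {
  fx <- exclusion_fixture(10146)
  fx$tsh <- 1.4
  r <- apply_exclusions(fx)
  expect_equal(unname(r$report["n_out"]), 9730)
  expect_equal(unname(r$report["union"]), 416)
  expect_equal(nrow(r$cohort), 9730)
  # count identity on random overlapping flags
  set.seed(1)
  d <- data.frame(goiter = rbinom(500, 1, 0.1) == 1,
                  thyroid_surgery = rbinom(500, 1, 0.1) == 1)
  r2 <- apply_exclusions(d, flags = names(d))
  expect_equal(nrow(r2$cohort),
               500 - sum(d$goiter | d$thyroid_surgery))
  # no flags set: identity
  d0 <- data.frame(goiter = rep(FALSE, 5))
  expect_equal(nrow(apply_exclusions(d0, "goiter")$cohort), 5)
  # all flagged: empty with a warning
  d1 <- data.frame(goiter = rep(TRUE, 5))
  expect_warning(r3 <- apply_exclusions(d1, "goiter"), "all individuals")
  expect_equal(nrow(r3$cohort), 0)
  expect_error(apply_exclusions(data.frame(x = 1), "absent_flag"), "flag")
})

test_that("thyroid status follows TSH thresholds with medication dominance", {
  expect_equal(as.character(classify_thyroid(1.38)), "normal")
  expect_equal(as.character(classify_thyroid(2.0, levothyroxine = TRUE)),
               "hypothyroid")
  expect_equal(as.character(classify_thyroid(0.39)), "hyperthyroid")
  expect_equal(as.character(classify_thyroid(5.1)), "hypothyroid")
  expect_equal(as.character(classify_thyroid(1.0, thiamazole = TRUE)),
               "hyperthyroid")
  # boundary values are strict: exactly 0.4 / 3.8 is normal
  expect_equal(as.character(classify_thyroid(c(0.4, 3.8))),
               c("normal", "normal"))
  # medication rescues a missing TSH; neither present is an error
  expect_equal(as.character(classify_thyroid(NA, levothyroxine = TRUE)),
               "hypothyroid")
  expect_error(classify_thyroid(NA), "neither TSH nor therapy")
})

test_that("continuous interaction model recovers a simulated coefficient", {
  set.seed(2)
  n <- 10000
  d <- rbinom(n, 2, 0.4)
  tsh <- rlnorm(n, log(1.38), 0.5)
  gamma <- 0.005
  y <- -0.01 * d + 0.002 * tsh + gamma * d * (tsh - mean(tsh)) +
    rnorm(n, 0, 0.16)
  covs <- make_covariates(n)
  f <- fit_interaction_continuous(y, d, tsh, covs)
  expect_lt(abs(f$b_interaction - gamma), 3 * f$se_interaction)
  expect_equal(f$model, "continuous_tsh")
  # reparameterization invariance: centering TSH changes neither the
  # interaction coefficient nor its p-value
  f_c <- fit_interaction_continuous(y, d, tsh - mean(tsh), covs)
  expect_equal(f_c$b_interaction, f$b_interaction, tolerance = 1e-10)
  expect_equal(f_c$p_interaction, f$p_interaction, tolerance = 1e-10)
})

test_that("categorical contrasts detect a status-specific effect doubling", {
  set.seed(3)
  n <- 12000
  d <- rbinom(n, 2, 0.4)
  status <- factor(sample(c("hyperthyroid", "normal", "hypothyroid"), n,
                          replace = TRUE, prob = c(0.017, 0.885, 0.098)),
                   levels = c("hyperthyroid", "normal", "hypothyroid"))
  beta <- -0.05
  y <- beta * d + beta * d * (status == "hypothyroid") + rnorm(n, 0, 0.16)
  fits <- fit_interaction_categorical(y, d, status)
  expect_named(fits, c("hyper_vs_normal", "hypo_vs_normal"))
  hypo <- fits$hypo_vs_normal
  expect_lt(abs(hypo$b_interaction - beta), 3 * hypo$se_interaction)
  expect_lt(hypo$p_interaction, 0.0045)
  # no interaction in the hyper contrast
  expect_gt(fits$hyper_vs_normal$p_interaction, 0.0045)
  # all-normal cohort: both contrasts skipped with warnings
  expect_warning(
    expect_warning(
      empty <- fit_interaction_categorical(y, d,
                                           factor(rep("normal", n),
                                                  levels = levels(status))),
      "hyper_vs_normal"),
    "hypo_vs_normal")
  expect_length(empty, 0)
})

test_that("interaction significance threshold is 0.05/11, strict", {
  expect_true(interaction_significant(0.00177))
  expect_true(interaction_significant(0.00154))
  expect_false(interaction_significant(0.05 / 11)) # boundary is strict
  expect_false(interaction_significant(0.0046))
  expect_false(interaction_significant(0.03))
})

test_that("predicted slopes at TSH strata follow the fitted coefficients", {
  set.seed(4)
  n <- 3000
  d <- rbinom(n, 2, 0.4)
  tsh <- rlnorm(n, log(1.38), 0.5)
  y <- -0.02 * d + 0.004 * d * tsh + rnorm(n, 0, 0.16)
  f <- fit_interaction_continuous(y, d, tsh)
  pr <- predict_at_tsh_levels(f)
  expect_equal(nrow(pr), 9) # 3 strata x dosages 0..2
  slopes <- tapply(pr$slope, pr$tsh_level, unique)
  # slope at a stratum is b_snp + b_int * tsh there
  expect_equal(unname(slopes[["average"]]),
               f$b_snp + f$b_interaction * f$tsh_mean)
  # high-low slope difference = 2 SD * b_interaction
  expect_equal(unname(slopes[["high"]] - slopes[["low"]]),
               2 * f$tsh_sd * f$b_interaction, tolerance = 1e-10)
  # fitted lines agree with the closed-form linear predictor per stratum
  line <- pr[pr$tsh_level == "average", ]
  expect_equal(diff(line$fit), rep(unname(slopes[["average"]]), 2),
               tolerance = 1e-10)
  expect_true(all(pr$lwr < pr$fit & pr$fit < pr$upr))
  # zero interaction: parallel lines
  y0 <- -0.02 * d + rnorm(n, 0, 0.16)
  f0 <- fit_interaction_continuous(y0, d, tsh)
  pr0 <- predict_at_tsh_levels(f0)
  s0 <- tapply(pr0$slope, pr0$tsh_level, unique)
  expect_equal(max(unlist(s0)) - min(unlist(s0)),
               abs(f0$b_interaction) * 2 * f0$tsh_sd, tolerance = 1e-12)
})

test_that("genotype-vs-missingness check behaves under null and alternative", {
  set.seed(5)
  d <- rbinom(1000, 2, 0.4)
  flag <- rbinom(1000, 1, 0.05) == 1
  p_null <- missingness_genotype_check(d, flag)
  expect_gt(p_null, 0.001)
  p_alt <- missingness_genotype_check(d, d > 0)
  expect_lt(p_alt, 1e-10)
  expect_error(missingness_genotype_check(d, rep(FALSE, 1000)), "non-empty")
})

test_that("municipality adjustment barely moves the SNP effect when independent", {
  tr <- small_truth(n = 5000, seed = 37, n_null = 2)
  sim <- simulate_cohort(tr)
  ph <- prepare_phenotypes(sim$phenotypes)
  y <- residualize_outcome(ph$ln_egfr, ph$age, ph$sex)
  d <- sim$dosages$values[, "rs_LOC1_lead"]
  f_plain <- fit_snp_model(y, d)
  f_mun <- fit_snp_model(y, d,
                         data.frame(municipality = factor(ph$municipality)))
  expect_lt(abs(f_plain$b - f_mun$b), 0.5 * f_plain$se)
})
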