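test_that("genotype simulation hits target frequency and LD", {
  # perfect-copy case
  g <- simulate_genotypes(0.3, n_proxies = 1, target_r2 = 1, n = 500, seed = 1)
  expect_identical(g$values[, 1], g$values[, 2])
  expect_equal(ld_r2(g$values[, 1], g$values[, 2]), 1)
  # realized EAF and r2 near spec over 20 seeds
  eafs <- r2s <- numeric(20)
  for (s in 1:20) {
    g <- simulate_genotypes(0.24, n_proxies = 1, target_r2 = 0.9,
                            n = 10000, seed = s)
    eafs[s] <- mean(g$values[, 1]) / 2
    r2s[s] <- ld_r2(g$values[, 1], g$values[, 2])
  }
  expect_true(all(eafs > 0.22 & eafs < 0.26))
  expect_true(all(r2s > 0.85 & r2s < 0.95))
  # near-zero target: proxies essentially independent
  g <- simulate_genotypes(0.5, n_proxies = 3, target_r2 = 1e-6,
                          n = 10000, seed = 9)
  mean_r2 <- mean(c(ld_r2(g$values[, 1], g$values[, 2]),
                    ld_r2(g$values[, 1], g$values[, 3]),
                    ld_r2(g$values[, 1], g$values[, 4])))
  expect_lt(mean_r2, 0.01)
  expect_error(simulate_genotypes(0.6, 1, 0.9, 100), "maf")
  expect_error(simulate_genotypes(0.3, 1, 1.5, 100), "target_r2")
  expect_error(simulate_genotypes(0.3, 1, 0.9, 1), "at least 2")
})

test_that("dosage columns satisfy Hardy-Weinberg proportions", {
  for (maf in c(0.1, 0.3, 0.5)) {
    g <- simulate_genotypes(maf, n_proxies = 2, target_r2 = 0.8,
                            n = 10000, seed = 21)
    for (j in 1:3) {
      d <- g$values[, j]
      p <- mean(d) / 2
      obs <- tabulate(d + 1, nbins = 3)
      exp_p <- c((1 - p)^2, 2 * p * (1 - p), p^2)
      chi <- sum((obs - 10000 * exp_p)^2 / (10000 * exp_p))
      expect_gt(pchisq(chi, df = 1, lower.tail = FALSE), 0.001)
    }
  }
})

test_that("simulation is deterministic given the seed and leaves RNG alone", {
  g1 <- simulate_genotypes(0.3, 2, 0.9, 200, seed = 5)
  g2 <- simulate_genotypes(0.3, 2, 0.9, 200, seed = 5)
  expect_identical(g1, g2)
  tr <- small_truth(n = 300, seed = 13, n_null = 2)
  s1 <- simulate_cohort(tr)
  s2 <- simulate_cohort(tr)
  expect_identical(s1$dosages$values, s2$dosages$values)
  expect_identical(s1$phenotypes, s2$phenotypes)
  # caller RNG state is restored, not consumed
  set.seed(99)
  invisible(simulate_cohort(tr))
  after <- rnorm(1)
  set.seed(99)
  expect_identical(rnorm(1), after)
})

test_that("dosage_matrix validates its invariants", {
  v <- data.frame(rsid = c("a", "b"), effect_allele = "A",
                  other_allele = "G", eaf = 0.5)
  expect_error(dosage_matrix(matrix(0, 3, 3), v), "column count")
  expect_error(dosage_matrix(matrix(c(0, 1, 3, 1), 2, 2), v), "\\[0, 2\\]")
  expect_s3_class(dosage_matrix(matrix(c(0, 1, 2, 1), 2, 2), v),
                  "dosage_matrix")
})

test_that("cohort generation encodes the assumed statistical structure", {
  tr <- small_truth(n = 6000, seed = 31, n_null = 3)
  sim <- simulate_cohort(tr)
  ph <- sim$phenotypes
  expect_equal(nrow(ph), 6000)
  expect_equal(ncol(sim$dosages$values), 5) # 3 + 2 variants
  # sex balance ~ 55.1% female (binomial MC error at n = 6000)
  expect_lt(abs(mean(ph$sex == "female") - 0.551),
            3.3 * sqrt(0.551 * 0.449 / 6000))
  expect_true(all(ph$age >= 18 & ph$age <= 80))
  # FT3/FT4 missing-by-design: measured iff TSH outside (0.4, 3.8)
  measured <- !is.na(ph$ft3)
  with_tsh <- !is.na(ph$tsh)
  expect_identical(measured[with_tsh],
                   (ph$tsh < 0.4 | ph$tsh > 3.8)[with_tsh])
  frac_expected <- plnorm(0.4, tr$tsh_meanlog, tr$tsh_sdlog) +
    plnorm(3.8, tr$tsh_meanlog, tr$tsh_sdlog, lower.tail = FALSE)
  expect_lt(abs(mean(measured) - frac_expected),
            3.3 * sqrt(frac_expected * (1 - frac_expected) / 6000))
  # SNP effect present on ln(eGFR) at the causal locus
  f <- fit_snp_model(ph$ln_egfr_true, sim$dosages$values[, "rs_LOC1_lead"],
                     data.frame(age = ph$age, male = ph$sex == "male"))
  expect_lt(abs(f$b - (tr$loci[[1]]$beta_gfr +
                         0.12 * -0.02)), 3 * f$se) # direct + mediated path
})

test_that("null effects give uniform downstream p-values", {
  # with all effect parameters zero, the step-1 test rejects at its level
  set.seed(17)
  rej <- logical(400)
  for (r in 1:400) {
    g <- rbinom(400, 2, 0.3)
    y <- rnorm(400, 0, 0.16)
    rej[r] <- fit_snp_model(y, g)$p_two < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 1e-9)
})

test_that("downstream traits attenuate in step 4 when caused by the outcome", {
  tr <- small_truth(n = 8000, seed = 41, n_null = 2)
  sim <- simulate_cohort(tr)
  ph <- sim$phenotypes
  g <- sim$dosages$values[, "rs_LOC1_lead"]
  covs <- data.frame(age = ph$age, male = as.numeric(ph$sex == "male"))
  f <- run_four_steps(ph$ln_egfr_true, g, ph$downstream1, covs,
                      trait_name = "downstream1")
  # trait ~ SNP unadjusted shows the induced association; adjusting for
  # ln(eGFR) knocks it down (delta_gfr path, alpha_snp = 0)
  expect_lt(abs(f$b4), abs(f$b3) / 3)
  expect_lt(f$p3, 0.05)
})

test_that("thyroid-status prevalences match the calibrated rates", {
  tr <- ground_truth(20000, loci = list(locus_spec("L", 0.3)), seed = 3)
  sim <- simulate_cohort(tr)
  ph <- sim$phenotypes
  ok <- !(is.na(ph$tsh) & is.na(ph$levothyroxine))
  st <- classify_thyroid(ph$tsh[ok], ph$levothyroxine[ok],
                         ph$thiamazole[ok], ph$propylthiouracil[ok])
  pr <- as.numeric(prop.table(table(st)))
  expect_lt(abs(pr[1] - 0.017), 0.004)  # hyperthyroid
  expect_lt(abs(pr[2] - 0.885), 0.012)  # normal
  expect_lt(abs(pr[3] - 0.098), 0.010)  # hypothyroid
})

test_that("exclusion fixture reproduces the documented counts and union", {
  fx <- exclusion_fixture(10146)
  expect_equal(colSums(fx)[c("thyroid_cancer", "kidney_cancer", "goiter",
                             "thyroid_surgery", "missing_tsh_therapy")],
               c(thyroid_cancer = 16, kidney_cancer = 1, goiter = 277,
                 thyroid_surgery = 312, missing_tsh_therapy = 4))
  expect_equal(sum(rowSums(fx) > 0), 416)
})
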