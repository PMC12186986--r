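test_that("residualization removes age and sex and centers the outcome", {
  set.seed(1)
  n <- 500
  age <- runif(n, 18, 80)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  y <- 4.8 - 0.007 * age + 0.05 * (sex == "male") + rnorm(n, 0, 0.1)
  r <- residualize_outcome(y, age, sex)
  expect_equal(mean(r), 0, tolerance = 1e-12)
  expect_lt(abs(cor(r, age)), 1e-10)
  # outcome fully explained by age: residuals vanish
  expect_equal(residualize_outcome(2 * age, age, sex), rep(0, n),
               tolerance = 1e-10)
  # missing inputs propagate as NA
  age[3] <- NA
  expect_true(is.na(residualize_outcome(y, age, sex)[3]))
})

test_that("fit_snp_model recovers a known slope and equals the closed form", {
  set.seed(2)
  n <- 10000
  d <- rbinom(n, 2, 0.3)
  y <- 0.01 * d + rnorm(n, 0, 0.2)
  f <- fit_snp_model(y, d)
  expect_lt(abs(f$b - 0.01), 3 * f$se)
  # orthogonal covariates leave the simple-regression slope unchanged
  cov_orth <- resid(lm(rnorm(n) ~ d))
  f2 <- fit_snp_model(y, d, data.frame(z = cov_orth))
  expect_equal(f2$b, cov(y, d) / var(d), tolerance = 1e-10)
  expect_equal(f$b, f2$b, tolerance = 1e-10)
  expect_error(fit_snp_model(y, rep(1, n)), "constant")
  expect_error(fit_snp_model(y, d, data.frame(a = d, b = 2 * d)),
               "collinear")
})

test_that("one-sided p-values follow the pre-specified direction", {
  expect_equal(one_sided_p(0, 1, "-"), 0.5)
  # printed-table check: b/se of the strongest locus reproduces its
  # one-sided p to input rounding
  expect_equal(one_sided_p(-0.01042, 0.00212, "-"), 4.51e-7,
               tolerance = 0.02)
  expect_equal(one_sided_p(1, 1, "-"), 1 - pnorm(-1))
  expect_equal(one_sided_p(-1, 1, "-"), pnorm(-1))
  expect_equal(one_sided_p(-1, 1, "+"), 1 - pnorm(-1))
  expect_error(one_sided_p(1, 0, "-"), "positive")
})

test_that("two-sided doubling matches the printed table pairs", {
  expect_equal(two_sided_from_one(2.85e-4), 5.70e-4)
  expect_equal(two_sided_from_one(3.00e-5), 5.99e-5, tolerance = 0.002)
  expect_equal(two_sided_from_one(0.5), 1.0)
  expect_warning(p <- two_sided_from_one(0.8), "unexpected direction")
  expect_equal(p, 0.4)
  expect_error(two_sided_from_one(0), "\\(0, 1\\]")
  # composition: one-sided then doubling equals the two-sided normal p
  z <- -3.2
  expect_equal(two_sided_from_one(one_sided_p(z, 1, "-")),
               2 * pnorm(-abs(z)))
})

test_that("ld_r2 is the squared Pearson correlation and flip-invariant", {
  set.seed(3)
  d <- rbinom(10000, 2, 0.4)
  expect_equal(ld_r2(d, d), 1)
  expect_equal(ld_r2(d, 2 - d), 1) # allele flip
  e <- rbinom(10000, 2, 0.4)
  expect_lt(ld_r2(d, e), 0.01)
  expect_error(ld_r2(d, rep(2, 10000)), "constant")
  expect_error(ld_r2(c(1, NA), c(NA, 1)), "non-missing")
})

test_that("proxy selection applies strict r2 and MAF filters and harmonizes", {
  g <- simulate_genotypes(0.3, n_proxies = 5, target_r2 = 0.9,
                          n = 4000, seed = 11, locus_name = "X")
  lead <- list(rsid = "rs_X_lead", locus = "X")
  lr <- select_proxies(lead, g$variants, g, r2_threshold = 0.8)
  expect_s3_class(lr, "locus_result")
  expect_equal(nrow(lr$proxies), 6) # lead + 5 proxies at target 0.9
  expect_true(all(lr$proxies$r2[lr$proxies$rsid != "rs_X_lead"] > 0.8))
  # strictness: with the threshold at 1, identical-variant r2 = 1 is NOT >
  g2 <- simulate_genotypes(0.3, n_proxies = 1, target_r2 = 1,
                           n = 1000, seed = 2, locus_name = "Y")
  lr2 <- select_proxies(list(rsid = "rs_Y_lead"), g2$variants, g2,
                        r2_threshold = 1)
  expect_equal(lr2$proxies$rsid, "rs_Y_lead")
  # MAF filter removes rare variants
  vals <- cbind(lead = rbinom(5000, 2, 0.3), rare = rbinom(5000, 2, 0.003))
  cand <- data.frame(rsid = c("lead", "rare"), effect_allele = "A",
                     other_allele = "G", eaf = c(0.3, 0.003))
  lr3 <- select_proxies(list(rsid = "lead"), cand, vals, maf_min = 0.005)
  expect_false("rare" %in% lr3$proxies$rsid)
  expect_true("rare" %in% lr3$dropped)
  # swapped alleles relative to the meta-analysis: dosage flipped
  vals2 <- cbind(v1 = c(0, 1, 2, 2, 1, 0, 1, 2, 0, 1))
  cand2 <- data.frame(rsid = "v1", effect_allele = "A", other_allele = "G",
                      eaf = 0.5, gwama_ea = "G", gwama_oa = "A",
                      gwama_eaf = 0.5)
  lr4 <- select_proxies(list(rsid = "v1"), cand2, vals2)
  expect_equal(as.numeric(lr4$dosages[, "v1"]), 2 - vals2[, "v1"])
  # unresolvable strand-ambiguous variant is dropped
  cand3 <- data.frame(rsid = "v1", effect_allele = "A", other_allele = "T",
                      eaf = 0.45, gwama_ea = "A", gwama_oa = "T",
                      gwama_eaf = 0.55)
  lr5 <- select_proxies(list(rsid = "v1"), cand3, vals2)
  expect_true("v1" %in% lr5$dropped)
  # missing lead: locus skipped with a warning
  expect_warning(out <- select_proxies(list(rsid = "absent"), cand, vals),
                 "skipped")
  expect_null(out)
})

test_that("locus significance uses the Bonferroni family threshold strictly", {
  expect_true(locus_significant(3.34e-4))
  expect_false(locus_significant(3.5e-4))
  expect_false(locus_significant(0.05 / 147)) # boundary is strict
  expect_true(locus_significant(c(0.2, 3.34e-4, 0.9)))
  expect_error(locus_significant(numeric(0)), "no tested")
})

test_that("family-wise false positives over 147 null loci stay near 0.05", {
  set.seed(5)
  n_rep <- 30
  fam_hits <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    # each locus' one-sided p under the null is Uniform(0,1)
    p_one <- runif(147)
    fam_hits[r] <- locus_significant(p_one)
  }
  # P(any locus significant) = 1 - (1 - 0.05/147)^147 ~ 0.049
  expect_lt(abs(mean(fam_hits) - 0.049), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
})

test_that("effective test coverage is the top-k eigenvalue fraction", {
  expect_equal(effective_test_coverage(diag(100), 98), 0.98)
  expect_equal(effective_test_coverage(matrix(1, 10, 10), 1), 1.0)
  blocks <- kronecker(diag(10), matrix(1, 5, 5))
  expect_equal(effective_test_coverage(blocks, 10), 1.0)
  expect_lt(effective_test_coverage(blocks, 9), 1.0)
  m <- diag(3); m[1, 2] <- 0.5
  expect_error(effective_test_coverage(m, 1), "symmetric")
})

test_that("genomic lambda is calibrated under the null and detects inflation", {
  expect_equal(genomic_lambda(rep(0.5, 10)), 1.0)
  set.seed(6)
  p <- runif(1e6)
  expect_equal(genomic_lambda(p), 1.0, tolerance = 0.005)
  z <- rnorm(1e5, 0, sqrt(1.1))
  p_inf <- 2 * pnorm(-abs(z))
  expect_equal(genomic_lambda(p_inf), 1.1, tolerance = 0.02)
  expect_error(genomic_lambda(c(0.5, 0)), "\\(0, 1\\]")
})
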