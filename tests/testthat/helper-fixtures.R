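# shared fixtures for the test suite; everything is generated in code

# small covariate frame (age, sex indicator, a couple of PCs)
make_covariates <- function(n, seed = 42) {
  gfrloci:::with_seed(seed, {
    data.frame(age = runif(n, 18, 80),
               sex = rbinom(n, 1, 0.55),
               PC1 = rnorm(n), PC2 = rnorm(n))
  })
}

# a compact ground truth with one causal locus, one true mediator,
# one outcome-downstream trait and a panel of null traits
small_truth <- function(n = 3000, seed = 7, n_null = 27,
                        beta_gfr = -0.02, gamma = 0) {
  loci <- list(
    locus_spec("LOC1", maf = 0.4, n_proxies = 2, target_r2 = 0.9,
               beta_gfr = beta_gfr),
    locus_spec("LOC2", maf = 0.25, n_proxies = 1, target_r2 = 0.9,
               beta_gfr = 0))
  traits <- default_trait_panel(list(
    trait_spec("mediator1", alpha_snp = 0.12, beta_trait_gfr = -0.02,
               noise_sd = 1, locus = "LOC1"),
    trait_spec("downstream1", delta_gfr = 1.5, noise_sd = 0.5,
               locus = "LOC1")), n_null = n_null)
  ground_truth(n, loci = loci, traits = traits,
               interaction_gamma = gamma, seed = seed)
}
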