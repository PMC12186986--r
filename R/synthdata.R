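#' Specify one genetic locus for simulation
#'
#' @param name locus label (e.g. a gene name).
#' @param maf minor/effect allele frequency of the lead variant, in (0, 0.5].
#' @param n_proxies number of additional variants correlated with the lead.
#' @param target_r2 target squared correlation between lead and proxies, in
#'   (0, 1].
#' @param beta_gfr per-allele effect of the lead variant on ln(eGFRcrea).
#' @return list of class `locus_spec`.
#' @export
locus_spec <- function(name, maf, n_proxies = 0, target_r2 = 0.9,
                       beta_gfr = 0) {
  if (maf <= 0 || maf > 0.5) stop("`maf` must be in (0, 0.5]")
  if (target_r2 <= 0 || target_r2 > 1) stop("`target_r2` must be in (0, 1]")
  structure(list(name = name, maf = maf, n_proxies = as.integer(n_proxies),
                 target_r2 = target_r2, beta_gfr = beta_gfr),
            class = "locus_spec")
}

#' Specify one quantitative trait for simulation
#'
#' Three generative roles are supported, matching the causal scenarios a
#' mediation screen must distinguish:
#' * `alpha_snp` — direct SNP -> trait path (pleiotropy);
#' * `delta_gfr` — ln(eGFRcrea) -> trait path (trait downstream of kidney
#'   function);
#' * `beta_trait_gfr` — trait -> ln(eGFRcrea) path (the trait is a true
#'   mediator; combined with `alpha_snp` this routes part of the SNP effect
#'   through the trait).
#'
#' `delta_gfr` and `beta_trait_gfr` cannot both be nonzero (no cycles).
#'
#' @param name trait name.
#' @param alpha_snp per-allele SNP effect on the trait.
#' @param delta_gfr effect of ln(eGFRcrea) on the trait.
#' @param beta_trait_gfr effect of the trait on ln(eGFRcrea).
#' @param noise_sd residual SD of the trait (> 0).
#' @param locus name of the locus whose lead SNP drives the trait; defaults
#'   to the first locus of the ground truth.
#' @return list of class `trait_spec`.
#' @export
trait_spec <- function(name, alpha_snp = 0, delta_gfr = 0,
                       beta_trait_gfr = 0, noise_sd = 1, locus = NULL) {
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  if (delta_gfr != 0 && beta_trait_gfr != 0) {
    stop("a trait cannot both depend on and feed into ln(eGFRcrea)")
  }
  structure(list(name = name, alpha_snp = alpha_snp, delta_gfr = delta_gfr,
                 beta_trait_gfr = beta_trait_gfr, noise_sd = noise_sd,
                 locus = locus),
            class = "trait_spec")
}

#' Ground truth for a synthetic cohort
#'
#' Collects every generative parameter of [simulate_cohort()] so that
#' downstream recovery tests know the truth. Defaults encode the study
#' conditions the analysis assumes: TSH log-normal calibrated to a median
#' of 1.38 uUI/mL with IQR 0.98-1.93; free T3/T4 measured only when TSH is
#' below `ft_thresholds["low"]` (0.4) or above `ft_thresholds["high"]`
#' (3.8) uUI/mL; thyroid medication rates calibrated so hyper/normal/hypo
#' prevalences are about 1.7%/88.5%/9.8%; exclusion-condition rates
#' matching 16/1/277/312/4 per 10,146.
#'
#' @param n_individuals cohort size.
#' @param loci list of [locus_spec()] objects.
#' @param traits list of [trait_spec()] objects.
#' @param interaction_gamma SNP x TSH coefficient on ln(eGFRcrea), applied
#'   to the first locus' lead variant with TSH centered at its mean.
#' @param tsh_meanlog,tsh_sdlog parameters of the log-normal TSH
#'   distribution.
#' @param ft_thresholds named numeric, TSH bounds outside which FT3/FT4 are
#'   measured (`low` < `high`).
#' @param med_rates named probabilities of levothyroxine, thiamazole and
#'   propylthiouracil use (sampled independently of TSH).
#' @param exclusion_rates named probabilities of the exclusion conditions.
#' @param sex_female_prob probability of female sex (0.551).
#' @param age_range uniform age range in years.
#' @param ln_egfr_intercept,age_beta,sex_male_beta,noise_sd linear-model
#'   parameters of ln(eGFRcrea).
#' @param seed integer RNG seed.
#' @return list of class `ground_truth`.
#' @export
ground_truth <- function(n_individuals,
                         loci = list(locus_spec("L1", maf = 0.3)),
                         traits = list(),
                         interaction_gamma = 0,
                         tsh_meanlog = log(1.38),
                         tsh_sdlog = 0.5024,
                         ft_thresholds = c(low = 0.4, high = 3.8),
                         med_rates = c(levothyroxine = 0.0783,
                                       thiamazole = 0.0077,
                                       propylthiouracil = 0.0026),
                         exclusion_rates = c(thyroid_cancer = 16 / 10146,
                                             kidney_cancer = 1 / 10146,
                                             goiter = 277 / 10146,
                                             thyroid_surgery = 312 / 10146,
                                             missing_tsh_therapy = 4 / 10146),
                         sex_female_prob = 0.551,
                         age_range = c(18, 80),
                         ln_egfr_intercept = 4.867,
                         age_beta = -0.007,
                         sex_male_beta = 0.01,
                         noise_sd = 0.16,
                         seed = 1L) {
  stopifnot(n_individuals >= 2, length(loci) >= 1)
  if (ft_thresholds["low"] >= ft_thresholds["high"]) {
    stop("FT measurement thresholds must satisfy low < high")
  }
  for (l in loci) stopifnot(inherits(l, "locus_spec"))
  for (t in traits) stopifnot(inherits(t, "trait_spec"))
  structure(list(n_individuals = as.integer(n_individuals), loci = loci,
                 traits = traits, interaction_gamma = interaction_gamma,
                 tsh_meanlog = tsh_meanlog, tsh_sdlog = tsh_sdlog,
                 ft_thresholds = ft_thresholds, med_rates = med_rates,
                 exclusion_rates = exclusion_rates,
                 sex_female_prob = sex_female_prob, age_range = age_range,
                 ln_egfr_intercept = ln_egfr_intercept, age_beta = age_beta,
                 sex_male_beta = sex_male_beta, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Simulate genotype dosages for one locus
#'
#' Draws a lead variant under Hardy-Weinberg equilibrium (two independent
#' haplotypes, each Bernoulli(maf)) and proxies by haplotype
#' copy-with-mutation: each proxy haplotype copies the lead allele with
#' probability \eqn{q = \sqrt{r^2_{target}}} and otherwise redraws
#' Bernoulli(maf), giving integer dosages, HWE-consistent columns, equal
#' allele frequencies and pairwise \eqn{r^2 \approx q^2} between lead and
#' proxies.
#'
#' @param maf allele frequency in (0, 0.5].
#' @param n_proxies number of proxy variants.
#' @param target_r2 target squared correlation with the lead, in (0, 1].
#' @param n number of individuals (>= 2).
#' @param seed integer seed; same seed, same matrix.
#' @param locus_name label used to name variants.
#' @return object of class `dosage_matrix`: list with `values` (n x m
#'   integer dosage matrix in \[0, 2\]), `variants` (data.frame of variant
#'   metadata) and `sample_ids`.
#' @export
simulate_genotypes <- function(maf, n_proxies = 0, target_r2 = 0.9, n,
                               seed = 1L, locus_name = "L1") {
  if (maf <= 0 || maf > 0.5) stop("`maf` must be in (0, 0.5]")
  if (target_r2 <= 0 || target_r2 > 1) stop("`target_r2` must be in (0, 1]")
  if (n < 2) stop("`n` must be at least 2")
  with_seed(seed, {
    q <- sqrt(target_r2)
    h1 <- rbinom(n, 1, maf)
    h2 <- rbinom(n, 1, maf)
    m <- 1L + n_proxies
    values <- matrix(0L, n, m)
    values[, 1] <- h1 + h2
    if (n_proxies > 0) {
      for (j in seq_len(n_proxies)) {
        copy1 <- rbinom(n, 1, q) == 1
        copy2 <- rbinom(n, 1, q) == 1
        p1 <- ifelse(copy1, h1, rbinom(n, 1, maf))
        p2 <- ifelse(copy2, h2, rbinom(n, 1, maf))
        values[, j + 1] <- p1 + p2
      }
    }
    rsid <- c(paste0("rs_", locus_name, "_lead"),
              if (n_proxies > 0) paste0("rs_", locus_name, "_px", seq_len(n_proxies)))
    colnames(values) <- rsid
    sample_ids <- sprintf("S%05d", seq_len(n))
    rownames(values) <- sample_ids
    variants <- data.frame(rsid = rsid, chr = 1L,
                           pos = seq_along(rsid) * 1000L,
                           effect_allele = "A", other_allele = "G",
                           eaf = colMeans(values) / 2,
                           stringsAsFactors = FALSE)
    dosage_matrix(values, variants, sample_ids)
  })
}

#' Construct a dosage matrix object
#'
#' @param values n x m numeric matrix of allelic dosages in \[0, 2\].
#' @param variants data.frame with one row per column of `values` (at least
#'   `rsid`, `effect_allele`, `other_allele`, `eaf`).
#' @param sample_ids character vector, one per row.
#' @return object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(values, variants, sample_ids = rownames(values)) {
  values <- as.matrix(values)
  if (ncol(values) != nrow(variants)) {
    stop("column count must equal variant count")
  }
  if (any(!is.finite(values)) || any(values < 0 | values > 2)) {
    stop("dosages must be finite and in [0, 2]")
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(nrow(values)))
  rownames(values) <- sample_ids
  colnames(values) <- variants$rsid
  structure(list(values = values, variants = variants,
                 sample_ids = sample_ids),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> %d samples x %d variants\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Simulate a full synthetic cohort
#'
#' Generates genotypes for every locus of the ground truth and a phenotype
#' table with age, sex, genetic PCs, TSH (log-normal), FT3/FT4 measured
#' only at extreme TSH, thyroid medication and exclusion flags,
#' municipality, serum creatinine back-derived from the generated
#' ln(eGFRcrea) by inverting the CKD-EPI 2009 equation (plus instrument and
#' period measurement shifts), and the quantitative trait panel.
#'
#' The linear predictor of ln(eGFRcrea) is
#' intercept + age and sex effects + sum of per-locus lead-SNP effects +
#' mediator-trait contributions + `interaction_gamma` x lead SNP x
#' (TSH - mean TSH) + Gaussian noise.
#'
#' @param truth a [ground_truth()] object.
#' @return list with elements `dosages` (a `dosage_matrix` over all loci),
#'   `phenotypes` (data.frame) and `truth`.
#' @export
simulate_cohort <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  n <- truth$n_individuals
  with_seed(truth$seed, {
    # genotypes: one sub-seed per locus, derived deterministically
    geno <- list()
    lead_dos <- list()
    for (i in seq_along(truth$loci)) {
      l <- truth$loci[[i]]
      g <- simulate_genotypes(l$maf, l$n_proxies, l$target_r2, n,
                              seed = truth$seed + 1000L + i,
                              locus_name = l$name)
      g$variants$locus <- l$name
      geno[[i]] <- g
      lead_dos[[l$name]] <- g$values[, 1]
    }
    values <- do.call(cbind, lapply(geno, function(g) g$values))
    variants <- do.call(rbind, lapply(geno, function(g) g$variants))
    sample_ids <- sprintf("S%05d", seq_len(n))
    dos <- dosage_matrix(values, variants, sample_ids)

    age <- runif(n, truth$age_range[1], truth$age_range[2])
    sex <- ifelse(runif(n) < truth$sex_female_prob, "female", "male")
    pcs <- matrix(rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("PC", 1:10)))
    tsh <- rlnorm(n, truth$tsh_meanlog, truth$tsh_sdlog)
    tsh_mean <- exp(truth$tsh_meanlog + truth$tsh_sdlog^2 / 2)

    # mediator traits are generated before the outcome
    med_idx <- which(vapply(truth$traits, function(t) t$beta_trait_gfr != 0,
                            logical(1)))
    trait_vals <- list()
    for (i in med_idx) {
      ts <- truth$traits[[i]]
      g <- lead_dos[[ts$locus %||% truth$loci[[1]]$name]]
      trait_vals[[ts$name]] <- ts$alpha_snp * g + rnorm(n, 0, ts$noise_sd)
    }

    eta <- truth$ln_egfr_intercept + truth$age_beta * age +
      truth$sex_male_beta * (sex == "male")
    for (l in truth$loci) eta <- eta + l$beta_gfr * lead_dos[[l$name]]
    for (i in med_idx) {
      ts <- truth$traits[[i]]
      m <- trait_vals[[ts$name]]
      eta <- eta + ts$beta_trait_gfr * (m - mean(m))
    }
    if (truth$interaction_gamma != 0) {
      eta <- eta + truth$interaction_gamma * lead_dos[[truth$loci[[1]]$name]] *
        (tsh - tsh_mean)
    }
    ln_egfr <- eta + rnorm(n, 0, truth$noise_sd)

    # downstream traits (pleiotropic and/or caused by kidney function)
    for (i in setdiff(seq_along(truth$traits), med_idx)) {
      ts <- truth$traits[[i]]
      g <- lead_dos[[ts$locus %||% truth$loci[[1]]$name]]
      trait_vals[[ts$name]] <- ts$alpha_snp * g + ts$delta_gfr * ln_egfr +
        rnorm(n, 0, ts$noise_sd)
    }

    # serum creatinine: invert CKD-EPI, then add measurement shifts
    scr_true <- scr_from_egfr(exp(ln_egfr), age, sex)
    instrument <- ifelse(runif(n) < 0.41, "instrA", "instrB")
    period <- sample(paste0("P", 1:8), n, replace = TRUE)
    period_shift <- setNames(rnorm(8, 0, 0.01), paste0("P", 1:8))
    scr <- scr_true + 0.02 * (instrument == "instrB") + period_shift[period]

    measured <- tsh < truth$ft_thresholds["low"] |
      tsh > truth$ft_thresholds["high"]
    ft3 <- ifelse(measured, rnorm(n, 3.0, 0.45), NA_real_)
    ft4 <- ifelse(measured, rnorm(n, 0.98, 0.16), NA_real_)

    meds <- vapply(truth$med_rates, function(r) rbinom(n, 1, r) == 1,
                   logical(n))
    excl <- vapply(truth$exclusion_rates, function(r) rbinom(n, 1, r) == 1,
                   logical(n))
    municipality <- sample(paste0("M", 1:20), n, replace = TRUE)

    pheno <- data.frame(sample_id = sample_ids, age = age, sex = sex,
                        scr = scr, instrument = instrument, period = period,
                        tsh = tsh, ft3 = ft3, ft4 = ft4,
                        municipality = municipality,
                        ln_egfr_true = ln_egfr,
                        stringsAsFactors = FALSE)
    pheno <- cbind(pheno, as.data.frame(meds), as.data.frame(excl),
                   as.data.frame(pcs))
    # missing_tsh_therapy: blank TSH and therapy info for flagged rows
    flagged <- pheno$missing_tsh_therapy
    pheno$tsh[flagged] <- NA_real_
    pheno[flagged, names(truth$med_rates)] <- NA
    for (nm in names(trait_vals)) pheno[[nm]] <- trait_vals[[nm]]
    list(dosages = dos, phenotypes = pheno, truth = truth)
  })
}

#' Default 70-trait panel specification
#'
#' A trait panel of the size the mediation screen expects: `n_null`
#' unrelated noise traits plus any explicitly supplied specs. Trait
#' correlation structure is independent noise by default; `shared_factor_sd`
#' adds a common latent factor across the null traits.
#'
#' @param specs list of [trait_spec()] objects to prepend.
#' @param n_null number of pure-noise traits to append so the panel reaches
#'   the usual size (70 including `specs`).
#' @param noise_sd residual SD for null traits.
#' @return list of `trait_spec` objects.
#' @export
default_trait_panel <- function(specs = list(), n_null = 70 - length(specs),
                                noise_sd = 1) {
  nulls <- lapply(seq_len(max(n_null, 0)), function(i) {
    trait_spec(sprintf("trait%02d", i), noise_sd = noise_sd)
  })
  c(specs, nulls)
}

#' Deterministic exclusion-flag fixture
#'
#' Builds a table of the five exclusion conditions with the documented
#' counts (thyroid cancer 16, kidney cancer 1, goiter 277, thyroid surgery
#' 312, missing TSH + therapy 4) and an overlap of 194 individuals between
#' goiter and thyroid surgery, so the union is exactly 416 and
#' `apply_exclusions` leaves `n - 416` individuals.
#'
#' @param n number of individuals (>= 416); default 10146.
#' @return data.frame of logical flag columns with `n` rows.
#' @export
exclusion_fixture <- function(n = 10146) {
  stopifnot(n >= 416)
  f <- function(idx) {
    v <- rep(FALSE, n)
    v[idx] <- TRUE
    v
  }
  data.frame(
    thyroid_surgery = f(1:312),
    goiter = f(119:395),          # 277 flags, 194 overlap with surgery
    thyroid_cancer = f(396:411),  # 16
    kidney_cancer = f(412),       # 1
    missing_tsh_therapy = f(413:416) # 4
  )
}
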