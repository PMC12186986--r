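#' Run the full locus-characterization pipeline
#'
#' Chains every stage on one cohort: phenotype preparation (creatinine
#' normalization, CKD-EPI 2009, winsorize + log, inverse-normal traits),
#' locus re-association (age/sex residuals, LD proxy selection, one-sided
#' tests, genomic control lambda, effective-test coverage), cohort versus
#' meta-analysis comparison, the mediation screen over the significant
#' loci, and the SNP-by-TSH interaction analysis after exclusions.
#'
#' With `config$truth` set, inputs are simulated from the ground truth
#' (the meta-analysis table is derived from the true effects with a large
#' effective sample size); otherwise the three input files are read.
#' Output TSVs are written under `config$outdir` when given. Identical
#' config and seed reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return list (report bundle): `phenotypes`, `loci` (per-locus test
#'   tables and flags), `lambda`, `coverage`, `comparison`, `mediation`,
#'   `interaction`, `exclusion_report`, `truth` (when synthetic).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  synthetic <- !is.null(config$truth)
  if (synthetic) {
    sim <- simulate_cohort(config$truth)
    dos <- sim$dosages
    pheno <- sim$phenotypes
    gwama <- gwama_from_truth(config$truth, dos)
  } else {
    gwama <- read_summary_stats(config$summary_stats)
    dos <- read_dosages(config$dosages)
    pheno <- read_phenotypes(config$phenotypes)
  }
  trait_cols <- config$trait_cols %||% if (synthetic) {
    vapply(config$truth$traits, `[[`, "", "name")
  } else {
    non_trait <- c("sample_id", "age", "sex", "scr", "instrument",
                   "period", "tsh", "ft3", "ft4", "municipality",
                   "ln_egfr_true", "levothyroxine", "thiamazole",
                   "propylthiouracil", "thyroid_cancer", "kidney_cancer",
                   "goiter", "thyroid_surgery", "missing_tsh_therapy")
    cand <- setdiff(names(pheno), non_trait)
    cand <- cand[!grepl("^PC\\d+$", cand)]
    cand[vapply(pheno[cand], is.numeric, logical(1))]
  }
  trait_cols <- intersect(trait_cols, names(pheno))

  # --- phenotype preparation ------------------------------------------
  pheno <- prepare_phenotypes(pheno, trait_cols = trait_cols,
                              winsor_bounds = config$winsor_bounds)
  y_resid <- residualize_outcome(pheno$ln_egfr, pheno$age, pheno$sex)
  pcs <- pheno[, grep("^PC\\d+$", names(pheno), value = TRUE), drop = FALSE]
  if (ncol(pcs) == 0) pcs <- NULL

  # --- association ----------------------------------------------------
  locus_ids <- unique(dos$variants$locus %||% "locus1")
  loci <- list()
  all_p <- numeric()
  for (ln in locus_ids) {
    vs <- dos$variants[which((dos$variants$locus %||% "locus1") == ln), ,
                       drop = FALSE]
    lead <- c(as.list(vs[1, ]), locus = ln)
    gw <- gwama[match(vs$rsid, gwama$rsid), , drop = FALSE]
    cand <- vs
    if (any(!is.na(gw$rsid))) {
      cand$gwama_ea <- gw$effect_allele
      cand$gwama_oa <- gw$other_allele
      cand$gwama_eaf <- gw$eaf
    }
    lr <- select_proxies(lead, cand, dos, config$r2_threshold,
                         config$maf_min)
    if (is.null(lr)) next
    sign_exp <- if (lead$rsid %in% gwama$rsid) {
      if (gwama$beta[match(lead$rsid, gwama$rsid)] < 0) "-" else "+"
    } else "-"
    lr <- test_locus(lr, y_resid, pcs, expected_sign = sign_exp,
                     n_loci = config$n_loci_family)
    loci[[ln]] <- lr
    all_p <- c(all_p, lr$tests$p_two)
  }
  lambda <- genomic_lambda(all_p)
  all_dos <- dos$values[, unlist(lapply(loci, function(l)
    colnames(l$dosages))), drop = FALSE]
  coverage <- if (ncol(all_dos) > 1) {
    effective_test_coverage(cor(all_dos), length(loci))
  } else 1

  sig <- names(loci)[vapply(loci, `[[`, logical(1), "significant")]

  # --- cohort vs meta-analysis ----------------------------------------
  var_y <- var(y_resid, na.rm = TRUE)
  comparison <- do.call(rbind, lapply(names(loci), function(ln) {
    lr <- loci[[ln]]
    best <- lr$best_cohort_variant
    gi <- match(best, gwama$rsid)
    if (is.na(gi)) return(NULL)
    ti <- match(best, lr$tests$rsid)
    cc <- compare_cohorts(
      list(b = lr$tests$b[ti], se = lr$tests$se[ti],
           eaf = mean(lr$dosages[, best], na.rm = TRUE) / 2),
      list(b = gwama$beta[gi], se = gwama$se[gi], eaf = gwama$eaf[gi]),
      var_y, locus_name = ln)
    cc$rsid <- best
    cc$significant <- ln %in% sig
    cc
  }))

  # --- mediation screen on significant loci ---------------------------
  covs <- cbind(data.frame(age = pheno$age,
                           sex = as.numeric(pheno$sex == "male")),
                if (is.null(pcs)) NULL else pcs)
  trait_int <- pheno[, paste0(trait_cols, "_int"), drop = FALSE]
  names(trait_int) <- trait_cols
  trait_int$scr <- pheno$scr_norm # positive control
  mediation <- NULL
  if (length(sig) > 0 && ncol(trait_int) >= 10) {
    best_dos <- do.call(cbind, lapply(sig, function(ln) {
      m <- loci[[ln]]$dosages[, loci[[ln]]$best_cohort_variant,
                              drop = FALSE]
      colnames(m) <- loci[[ln]]$best_cohort_variant
      m
    }))
    mediation <- mediation_screen(pheno$ln_egfr, best_dos, trait_int,
                                  covariates = covs,
                                  n_traits = config$n_traits,
                                  n_loci = config$n_loci_mediation,
                                  locus_names = sig)
  }

  # --- interaction ----------------------------------------------------
  excl <- apply_exclusions(pheno)
  sub <- excl$cohort
  idx <- match(sub$sample_id, pheno$sample_id)
  interaction <- NULL
  if (length(sig) > 0 && "tsh" %in% names(sub)) {
    covs_sub <- covs[idx, , drop = FALSE]
    fits <- lapply(sig, function(ln) {
      rs <- loci[[ln]]$best_cohort_variant
      f <- fit_interaction_continuous(sub$ln_egfr,
                                      loci[[ln]]$dosages[idx, rs],
                                      sub$tsh, covs_sub, rsid = rs)
      data.frame(locus_name = ln, rsid = rs,
                 b_interaction = f$b_interaction,
                 se_interaction = f$se_interaction,
                 p_interaction = f$p_interaction, n = f$n,
                 significant = interaction_significant(
                   f$p_interaction, config$n_loci_interaction),
                 stringsAsFactors = FALSE)
    })
    interaction <- do.call(rbind, fits)
  }

  bundle <- list(phenotypes = pheno, loci = loci, lambda = lambda,
                 coverage = coverage, significant_loci = sig,
                 comparison = comparison, mediation = mediation,
                 interaction = interaction,
                 exclusion_report = excl$report,
                 truth = if (synthetic) config$truth else NULL,
                 seed = config$seed)
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  bundle
}

#' Derive a meta-analysis summary table from a ground truth
#'
#' Builds the summary-statistics input the pipeline expects from the
#' generator's true effects: per lead variant, beta = true effect plus
#' noise at the meta-analysis SE implied by `n_meta`, SE =
#' `sqrt(var_y / (2 p (1-p) n_meta))`.
#'
#' @param truth a [ground_truth()].
#' @param dosages the cohort `dosage_matrix` (for variant metadata).
#' @param n_meta effective meta-analysis sample size (default 500000).
#' @param var_y assumed outcome variance (default `truth$noise_sd^2`).
#' @return summary-statistics data.frame.
#' @export
gwama_from_truth <- function(truth, dosages, n_meta = 5e5,
                             var_y = truth$noise_sd^2) {
  v <- dosages$variants
  beta_by_locus <- setNames(
    vapply(truth$loci, `[[`, numeric(1), "beta_gfr"),
    vapply(truth$loci, `[[`, "", "name"))
  with_seed(truth$seed + 77L, {
    eaf <- pmax(pmin(v$eaf, 0.999), 0.001)
    se <- sqrt(var_y / (2 * eaf * (1 - eaf) * n_meta))
    beta_true <- beta_by_locus[v$locus %||% names(beta_by_locus)[1]]
    beta <- rnorm(nrow(v), beta_true, se)
    data.frame(rsid = v$rsid, chr = v$chr, pos = v$pos,
               effect_allele = v$effect_allele,
               other_allele = v$other_allele, eaf = eaf, beta = beta,
               se = se,
               p = pmax(2 * pnorm(-abs(beta / se)), 1e-300), n = n_meta,
               stringsAsFactors = FALSE)
  })
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(d) {
    for (nm in names(d)) {
      if (is.numeric(d[[nm]])) {
        d[[nm]] <- ifelse(grepl("^p|_p$|p_", nm),
                          formatC(d[[nm]], format = "g", digits = 3),
                          formatC(d[[nm]], format = "g", digits = 6))
      }
    }
    d
  }
  tests <- do.call(rbind, lapply(names(bundle$loci), function(ln) {
    t <- bundle$loci[[ln]]$tests
    t$locus_name <- ln
    t$significant <- ln %in% bundle$significant_loci
    t
  }))
  write.table(fmt(tests), file.path(outdir, "locus_tests.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$comparison)) {
    write.table(fmt(bundle$comparison),
                file.path(outdir, "cohort_vs_meta.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$mediation)) {
    write.table(fmt(bundle$mediation), file.path(outdir, "mediation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$interaction)) {
    write.table(fmt(bundle$interaction),
                file.path(outdir, "interaction.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(c(sprintf("seed: %d", bundle$seed),
               sprintf("lambda: %.4f", bundle$lambda),
               sprintf("effective_test_coverage: %.4f", bundle$coverage),
               sprintf("significant_loci: %s",
                       paste(bundle$significant_loci, collapse = ","))),
             file.path(outdir, "run_summary.txt"))
  invisible(outdir)
}
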