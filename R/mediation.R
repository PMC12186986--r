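#' Four-step mediation regressions for one (variant, trait) pair
#'
#' Fits the four linear models of the classical mediation framework, all
#' adjusted for the supplied covariates (age, sex, genetic PCs) plus an
#' intercept, each on its own complete cases:
#' 1. `y ~ SNP + X` (total SNP effect, b1);
#' 2. `y ~ SNP + trait + X` (SNP effect adjusted for the trait, b2; trait
#'    coefficient gamma2);
#' 3. `trait ~ SNP + X` (SNP-trait association, b3);
#' 4. `trait ~ SNP + y + X` (SNP-trait association adjusted for the
#'    outcome, b4; outcome coefficient delta4).
#'
#' @param y outcome (ln eGFRcrea).
#' @param dosage allelic dosage vector.
#' @param trait quantitative trait vector (typically inverse-normal
#'   transformed).
#' @param covariates optional data.frame of adjustment covariates.
#' @param locus_name,rsid,trait_name labels carried into the result.
#' @return list of class `mediation_result` with `b1..b4`, `se1..se4`,
#'   `p1..p4`, `gamma2`, `delta4`, `n1..n4`, `pct_change`, and placeholder
#'   `outlier_flag`, `step3_significant`, `mediator_status` (filled by
#'   [mediation_screen()]); `NULL` with a warning if the trait is constant.
#' @export
run_four_steps <- function(y, dosage, trait, covariates = NULL,
                           locus_name = NA, rsid = NA, trait_name = NA) {
  if (var(trait, na.rm = TRUE) == 0 || all(is.na(trait))) {
    warning("trait ", trait_name, " is constant; skipped")
    return(NULL)
  }
  X <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  fit1 <- ols_term(y, cbind_df(data.frame(dosage = dosage), X), "dosage")
  fit2 <- ols_term(y, cbind_df(data.frame(dosage = dosage, trait = trait), X),
                   "dosage", also = "trait")
  fit3 <- ols_term(trait, cbind_df(data.frame(dosage = dosage), X), "dosage")
  fit4 <- ols_term(trait, cbind_df(data.frame(dosage = dosage, y = y), X),
                   "dosage", also = "y")
  structure(list(
    locus_name = locus_name, rsid = rsid, trait_name = trait_name,
    b1 = fit1$b, se1 = fit1$se, p1 = fit1$p, n1 = fit1$n,
    b2 = fit2$b, se2 = fit2$se, p2 = fit2$p, n2 = fit2$n,
    gamma2 = fit2$b_also,
    b3 = fit3$b, se3 = fit3$se, p3 = fit3$p, n3 = fit3$n,
    b4 = fit4$b, se4 = fit4$se, p4 = fit4$p, n4 = fit4$n,
    delta4 = fit4$b_also,
    pct_change = percent_change(fit1$b, fit2$b),
    outlier_flag = NA, step3_significant = NA, mediator_status = NA
  ), class = "mediation_result")
}

# OLS on complete cases; returns the named term's estimate/SE/p
ols_term <- function(y, predictors, term, also = NULL) {
  d <- cbind_df(data.frame(.y = y), predictors)
  d <- d[complete.cases(d), , drop = FALSE]
  fit <- lm(.y ~ ., data = d)
  sm <- summary(fit)$coefficients
  list(b = sm[term, 1], se = sm[term, 2], p = sm[term, 4], n = nrow(d),
       b_also = if (!is.null(also) && also %in% rownames(sm)) sm[also, 1]
                else NA_real_)
}

cbind_df <- function(a, b) if (is.null(b)) a else cbind(a, b)

#' Percent change of the SNP effect upon trait adjustment
#'
#' `100 * (b2 - b1) / b1`: positive when adjustment makes the SNP effect
#' larger in magnitude (same sign), negative when it attenuates it.
#' Reported rounded to the nearest integer for display; full precision is
#' kept internally.
#'
#' @param b1 unadjusted (step-1) SNP effect, nonzero.
#' @param b2 trait-adjusted (step-2) SNP effect.
#' @return percent change (numeric).
#' @export
percent_change <- function(b1, b2) {
  out <- ifelse(b1 == 0, NA_real_, 100 * (b2 - b1) / b1)
  if (any(b1 == 0)) warning("b1 = 0: percent change undefined")
  out
}

#' Stringent Tukey outlier rule on adjusted SNP effects
#'
#' Flags a step-2 coefficient as an outlier of the panel of step-2
#' coefficients across all traits (the tested value included) when it
#' falls outside
#' \deqn{[P_{10} - 1.5\,(P_{75}-P_{25}),\; P_{90} + 1.5\,(P_{75}-P_{25})]}
#' with percentiles computed by linear interpolation (quantile type 7).
#' Because the fences hang off P10/P90 instead of P25/P75, they contain
#' the classic Tukey fences, making this rule stricter (it flags a subset
#' of classic Tukey outliers).
#'
#' @param b2_panel numeric vector of step-2 coefficients across traits
#'   (length >= 10).
#' @param b2_value value(s) to test; defaults to the whole panel.
#' @return logical flag(s).
#' @export
stringent_tukey_outlier <- function(b2_panel, b2_value = b2_panel) {
  b2_panel <- b2_panel[!is.na(b2_panel)]
  if (length(b2_panel) < 10) {
    stop("need at least 10 panel values for stable percentiles")
  }
  q <- quantile(b2_panel, c(0.10, 0.25, 0.75, 0.90), type = 7, names = FALSE)
  iqr <- q[3] - q[2]
  b2_value < q[1] - 1.5 * iqr | b2_value > q[4] + 1.5 * iqr
}

#' Classify a trait as partial mediator of a SNP-outcome association
#'
#' A trait qualifies as (at least) a partial mediator when both criteria
#' hold: (i) the trait-adjusted SNP effect is an outlier of its panel
#' (substantial alteration), and (ii) the SNP associates with the trait at
#' the multiple-testing-corrected level `0.05 / (n_traits * n_loci)`
#' (6.5e-5 for 70 traits and 11 loci).
#'
#' @param outlier_flag logical, criterion (i).
#' @param p3 step-3 p-value, criterion (ii).
#' @param n_traits,n_loci multiplicity (defaults 70 and 11).
#' @return `"partial_mediator"` or `"none"`.
#' @export
classify_mediator <- function(outlier_flag, p3, n_traits = 70, n_loci = 11) {
  ifelse(outlier_flag & p3 < 0.05 / (n_traits * n_loci),
         "partial_mediator", "none")
}

#' Mediation screen over variants and a trait panel
#'
#' Runs [run_four_steps()] for every (variant, trait) combination, builds
#' the per-variant panel of step-2 coefficients across all traits, applies
#' the stringent Tukey outlier rule and the step-3 significance criterion,
#' and classifies mediators.
#'
#' @param y outcome (ln eGFRcrea).
#' @param dosages matrix of dosages (samples x variants) or
#'   `dosage_matrix`.
#' @param traits data.frame of quantitative traits (one column per trait).
#' @param covariates optional covariate data.frame.
#' @param n_traits,n_loci multiplicity for the step-3 threshold; default
#'   `ncol(traits)` and 11.
#' @param locus_names optional vector labeling each variant's locus.
#' @return long-format data.frame, one row per (variant, trait), with all
#'   four models' estimates, `pct_change`, `outlier_flag`,
#'   `step3_significant` and `mediator_status`.
#' @export
mediation_screen <- function(y, dosages, traits, covariates = NULL,
                             n_traits = ncol(traits), n_loci = 11,
                             locus_names = NULL) {
  if (inherits(dosages, "dosage_matrix")) dosages <- dosages$values
  dosages <- as.matrix(dosages)
  rows <- list()
  for (j in seq_len(ncol(dosages))) {
    rs <- colnames(dosages)[j] %||% paste0("v", j)
    ln <- if (!is.null(locus_names)) locus_names[j] else NA
    fits <- list()
    for (tn in names(traits)) {
      f <- run_four_steps(y, dosages[, j], traits[[tn]], covariates,
                          locus_name = ln, rsid = rs, trait_name = tn)
      if (!is.null(f)) fits[[tn]] <- f
    }
    panel <- vapply(fits, function(f) f$b2, numeric(1))
    out_flags <- stringent_tukey_outlier(panel)
    for (k in seq_along(fits)) {
      f <- fits[[k]]
      f$outlier_flag <- unname(out_flags[k])
      f$step3_significant <- f$p3 < 0.05 / (n_traits * n_loci)
      f$mediator_status <- classify_mediator(f$outlier_flag, f$p3,
                                             n_traits, n_loci)
      rows[[length(rows) + 1]] <-
        as.data.frame(unclass(f), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
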