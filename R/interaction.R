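#' Apply thyroid/kidney exclusion criteria
#'
#' Removes individuals carrying any of the exclusion flags (thyroid
#' cancer, kidney cancer, goiter, thyroid surgery, missing TSH measurement
#' together with missing therapy information) ahead of the interaction
#' analysis.
#'
#' @param cohort data.frame containing logical flag columns.
#' @param flags character vector of flag column names present in `cohort`.
#' @return list with `cohort` (filtered data.frame) and `report` (named
#'   counts per flag, `union` of flagged individuals, `n_in`, `n_out`).
#' @export
apply_exclusions <- function(cohort,
                             flags = c("thyroid_cancer", "kidney_cancer",
                                       "goiter", "thyroid_surgery",
                                       "missing_tsh_therapy")) {
  flags <- intersect(flags, names(cohort))
  if (length(flags) == 0) stop("no exclusion flag columns found")
  fl <- vapply(flags, function(f) !is.na(cohort[[f]]) & cohort[[f]],
               logical(nrow(cohort)))
  any_flag <- rowSums(fl) > 0
  if (all(any_flag)) warning("all individuals excluded")
  report <- c(colSums(fl), union = sum(any_flag),
              n_in = nrow(cohort), n_out = sum(!any_flag))
  list(cohort = cohort[!any_flag, , drop = FALSE], report = report)
}

#' Classify thyroid function status
#'
#' Hyperthyroidism: TSH < `low` uUI/mL or use of an antithyroid drug
#' (thiamazole, propylthiouracil). Hypothyroidism: TSH > `high` uUI/mL or
#' levothyroxine use. Otherwise normal. Medication dominates the TSH
#' value; ties at exactly the thresholds are normal (strict inequalities).
#'
#' @param tsh TSH in uUI/mL (may be `NA` when medication is informative).
#' @param levothyroxine,thiamazole,propylthiouracil logical flags
#'   (recycled).
#' @param low,high TSH thresholds (defaults 0.4 and 3.8).
#' @return factor with levels hyperthyroid/normal/hypothyroid.
#' @export
classify_thyroid <- function(tsh, levothyroxine = FALSE, thiamazole = FALSE,
                             propylthiouracil = FALSE, low = 0.4,
                             high = 3.8) {
  n <- length(tsh)
  levo <- rep_len(!is.na(levothyroxine) & levothyroxine, n)
  anti <- rep_len(!is.na(thiamazole) & thiamazole, n) |
    rep_len(!is.na(propylthiouracil) & propylthiouracil, n)
  unclassifiable <- is.na(tsh) & !levo & !anti
  if (any(unclassifiable)) {
    stop(sum(unclassifiable),
         " individual(s) have neither TSH nor therapy information")
  }
  out <- rep("normal", n)
  out[!is.na(tsh) & tsh < low] <- "hyperthyroid"
  out[!is.na(tsh) & tsh > high] <- "hypothyroid"
  # medication dominates the measured level
  out[anti] <- "hyperthyroid"
  out[levo & !anti] <- "hypothyroid"
  factor(out, levels = c("hyperthyroid", "normal", "hypothyroid"))
}

#' SNP-by-TSH interaction model (continuous TSH)
#'
#' OLS of ln(eGFRcrea) on dosage, TSH, their product and the covariates
#' (age, sex, PCs), reporting the interaction coefficient, SE and
#' two-sided p. The product-term t-test is invariant to centering TSH.
#'
#' @param y outcome vector.
#' @param dosage allelic dosage.
#' @param tsh TSH in uUI/mL (`log_tsh = TRUE` uses log(TSH)).
#' @param covariates optional covariate data.frame.
#' @param log_tsh logical, default `FALSE`.
#' @param rsid optional variant label.
#' @return list of class `interaction_result`: `model = "continuous_tsh"`,
#'   `b_snp`, `b_env`, `b_interaction`, `se_interaction`,
#'   `p_interaction`, `n`, and the underlying `fit` plus `tsh_mean`,
#'   `tsh_sd` for prediction.
#' @export
fit_interaction_continuous <- function(y, dosage, tsh, covariates = NULL,
                                       log_tsh = FALSE, rsid = NA) {
  env <- if (log_tsh) log(tsh) else tsh
  d <- data.frame(y = y, dosage = dosage, env = env)
  if (!is.null(covariates)) d <- cbind(d, as.data.frame(covariates))
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < ncol(d) + 4) stop("too few complete cases")
  covs <- setdiff(names(d), c("y", "dosage", "env"))
  fml <- stats::reformulate(c("dosage * env", covs), response = "y")
  fit <- lm(fml, data = d)
  if (any(is.na(coef(fit)))) stop("rank-deficient interaction design")
  sm <- summary(fit)$coefficients
  structure(list(rsid = rsid, model = "continuous_tsh",
                 b_snp = sm["dosage", 1], b_env = sm["env", 1],
                 b_interaction = sm["dosage:env", 1],
                 se_interaction = sm["dosage:env", 2],
                 p_interaction = sm["dosage:env", 4],
                 n = nrow(d), fit = fit,
                 tsh_mean = mean(d$env), tsh_sd = sd(d$env)),
            class = "interaction_result")
}

#' SNP-by-thyroid-status interaction models (categorical)
#'
#' Pairwise contrasts against the normal category: for each of
#' hyperthyroid and hypothyroid, the model is fit on the two categories
#' only, with an indicator, its product with dosage, and the covariates.
#' An empty contrasted stratum is skipped with a warning.
#'
#' @param y outcome vector.
#' @param dosage allelic dosage.
#' @param status factor from [classify_thyroid()].
#' @param covariates optional covariate data.frame.
#' @param rsid optional variant label.
#' @return named list of `interaction_result` objects
#'   (`hyper_vs_normal`, `hypo_vs_normal`), possibly empty.
#' @export
fit_interaction_categorical <- function(y, dosage, status, covariates = NULL,
                                        rsid = NA) {
  out <- list()
  for (contrast in c("hyperthyroid", "hypothyroid")) {
    lab <- if (contrast == "hyperthyroid") "hyper_vs_normal" else "hypo_vs_normal"
    sel <- !is.na(status) & status %in% c("normal", contrast)
    ind <- as.numeric(status == contrast)
    if (sum(sel & ind == 1, na.rm = TRUE) == 0 ||
        sum(sel & ind == 0, na.rm = TRUE) == 0) {
      warning("empty stratum for ", lab, "; contrast skipped")
      next
    }
    d <- data.frame(y = y, dosage = dosage, env = ind)[sel, , drop = FALSE]
    if (!is.null(covariates)) {
      d <- cbind(d, as.data.frame(covariates)[sel, , drop = FALSE])
    }
    d <- d[complete.cases(d), , drop = FALSE]
    covs <- setdiff(names(d), c("y", "dosage", "env"))
    fml <- stats::reformulate(c("dosage * env", covs), response = "y")
    fit <- lm(fml, data = d)
    sm <- summary(fit)$coefficients
    out[[lab]] <- structure(list(rsid = rsid, model = lab,
                                 b_snp = sm["dosage", 1],
                                 b_env = sm["env", 1],
                                 b_interaction = sm["dosage:env", 1],
                                 se_interaction = sm["dosage:env", 2],
                                 p_interaction = sm["dosage:env", 4],
                                 n = nrow(d), fit = fit),
                            class = "interaction_result")
  }
  out
}

#' Interaction significance at the locus-corrected level
#'
#' @param p_interaction interaction p-value(s).
#' @param n_loci number of loci tested (default 11, giving 0.05/11 =
#'   0.0045, strict).
#' @return logical flag(s).
#' @export
interaction_significant <- function(p_interaction, n_loci = 11) {
  p_interaction < 0.05 / n_loci
}

#' Predicted outcome-vs-dosage lines at TSH strata
#'
#' From a fitted continuous-TSH interaction model, predicts ln(eGFRcrea)
#' across dosages at TSH one SD below the mean, at the mean, and one SD
#' above, with 95% confidence intervals (other covariates held at their
#' means), plus the per-stratum SNP slope `b_snp + b_interaction * tsh`
#' and its delta-method SE from the coefficient covariance.
#'
#' @param fit an `interaction_result` from [fit_interaction_continuous()].
#' @param dosage_values dosages at which to predict (default `0:2`).
#' @param tsh_levels named TSH values; default low/average/high = mean -+
#'   SD.
#' @return data.frame with `tsh_level`, `tsh`, `dosage`, `fit`, `lwr`,
#'   `upr`, `slope`, `slope_se`.
#' @export
predict_at_tsh_levels <- function(fit, dosage_values = 0:2,
                                  tsh_levels = NULL) {
  stopifnot(inherits(fit, "interaction_result"),
            fit$model == "continuous_tsh")
  if (is.null(tsh_levels)) {
    tsh_levels <- c(low = fit$tsh_mean - fit$tsh_sd,
                    average = fit$tsh_mean,
                    high = fit$tsh_mean + fit$tsh_sd)
  }
  mf <- fit$fit$model
  covs <- setdiff(names(mf), c("y", "dosage", "env"))
  base <- as.data.frame(lapply(mf[covs], function(x) {
    if (is.numeric(x)) mean(x) else {
      tx <- table(x)
      factor(names(tx)[which.max(tx)], levels = levels(as.factor(x)))
    }
  }))
  V <- vcov(fit$fit)[c("dosage", "dosage:env"), c("dosage", "dosage:env")]
  out <- list()
  for (nm in names(tsh_levels)) {
    lvl <- tsh_levels[[nm]]
    nd <- data.frame(dosage = dosage_values, env = lvl)
    if (length(covs)) nd <- cbind(nd, base[rep(1, nrow(nd)), , drop = FALSE])
    pr <- predict(fit$fit, newdata = nd, interval = "confidence")
    slope <- fit$b_snp + fit$b_interaction * lvl
    slope_se <- sqrt(V[1, 1] + lvl^2 * V[2, 2] + 2 * lvl * V[1, 2])
    out[[nm]] <- data.frame(tsh_level = nm, tsh = lvl,
                            dosage = dosage_values,
                            fit = pr[, "fit"], lwr = pr[, "lwr"],
                            upr = pr[, "upr"], slope = slope,
                            slope_se = slope_se)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genotype distribution versus FT3/FT4 measurement status
#'
#' Two-sided Wilcoxon rank-sum test comparing allelic dosages between
#' individuals with and without measured free thyroid hormones, a
#' sensitivity check against genotype stratification induced by the
#' TSH-dependent measurement design. Exact for small samples without
#' ties, normal approximation with continuity correction otherwise.
#'
#' @param dosage allelic dosage vector.
#' @param measured_flag logical, FT3/FT4 measured.
#' @return two-sided p-value.
#' @export
missingness_genotype_check <- function(dosage, measured_flag) {
  ok <- !is.na(dosage) & !is.na(measured_flag)
  a <- dosage[ok & measured_flag]
  b <- dosage[ok & !measured_flag]
  if (length(a) == 0 || length(b) == 0) {
    stop("both measured and unmeasured groups must be non-empty")
  }
  wilcox.test(a, b, alternative = "two.sided", correct = TRUE)$p.value
}
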