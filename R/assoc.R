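#' Age- and sex-adjusted residuals of ln(eGFRcrea)
#'
#' Regresses ln(eGFRcrea) on age and sex and returns the residuals (mean
#' zero), the outcome used by the per-variant association models.
#'
#' @param ln_egfr numeric outcome.
#' @param age numeric, years.
#' @param sex character `"male"`/`"female"` (or any 2-level coding).
#' @return numeric vector of residuals, `NA` where any input is missing.
#' @export
residualize_outcome <- function(ln_egfr, age, sex) {
  d <- data.frame(y = ln_egfr, age = age, sex = as.factor(sex))
  out <- rep(NA_real_, nrow(d))
  cc <- complete.cases(d)
  fit <- lm(y ~ age + sex, data = d[cc, , drop = FALSE])
  out[cc] <- resid(fit)
  out
}

#' Per-variant association model
#'
#' Ordinary least squares of the (residualized) outcome on allelic dosage
#' plus covariates, with the slope's two-sided p-value from the t
#' distribution at the residual degrees of freedom. Principal-component
#' adjusted OLS stands in for a kinship-adjusted mixed model, to which it
#' is substantially equivalent in an unstructured cohort.
#'
#' @param y numeric outcome vector.
#' @param dosage numeric dosage vector in \[0, 2\].
#' @param covariates optional data.frame or matrix of covariates (e.g.
#'   genetic PCs, municipality factor).
#' @return list with `b`, `se`, `p_two`, `n`, `df`.
#' @export
fit_snp_model <- function(y, dosage, covariates = NULL) {
  d <- data.frame(y = y, dosage = dosage)
  if (!is.null(covariates)) d <- cbind(d, as.data.frame(covariates))
  cc <- complete.cases(d)
  d <- d[cc, , drop = FALSE]
  if (var(d$dosage) == 0) stop("dosage is constant")
  if (nrow(d) < ncol(d) + 2) stop("too few complete cases")
  fit <- lm(y ~ ., data = d)
  a <- is.na(coef(fit))
  if (any(a)) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(coef(fit))[a], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  list(b = sm["dosage", 1], se = sm["dosage", 2],
       p_two = sm["dosage", 4], n = nrow(d), df = fit$df.residual)
}

#' One-sided p-value in a pre-specified direction
#'
#' Converts an effect estimate and SE into a one-sided normal p-value for
#' the alternative that the effect has the expected sign (the direction
#' reported by the source meta-analysis after allele harmonization). An
#' estimate in the expected direction gives \eqn{\Phi(-|z|)}; a
#' wrong-direction estimate gives \eqn{1 - \Phi(-|z|)} > 0.5.
#'
#' @param b effect estimate(s).
#' @param se standard error(s), positive.
#' @param expected_sign `"-"`/`"+"` (or -1/+1), recycled.
#' @return one-sided p-value(s).
#' @export
one_sided_p <- function(b, se, expected_sign) {
  if (any(se <= 0)) stop("`se` must be positive")
  es <- ifelse(expected_sign %in% c("-", "-1") | expected_sign == -1, -1, 1)
  z <- b / se
  in_dir <- sign(z) == es | z == 0
  p <- pnorm(-abs(z))
  ifelse(z == 0, 0.5, ifelse(in_dir, p, 1 - p))
}

#' Two-sided p-value from a one-sided one
#'
#' Doubles an in-direction one-sided p-value; a wrong-direction p
#' (> 0.5) is mirrored first and flagged with a warning.
#'
#' @param p_one one-sided p-value(s) in (0, 1\].
#' @return two-sided p-value(s).
#' @export
two_sided_from_one <- function(p_one) {
  if (any(p_one <= 0 | p_one > 1)) stop("`p_one` must be in (0, 1]")
  if (any(p_one > 0.5)) {
    warning("one-sided p > 0.5: effect in the unexpected direction")
  }
  ifelse(p_one <= 0.5, 2 * p_one, 2 * (1 - p_one))
}

#' Linkage disequilibrium between two dosage vectors
#'
#' Squared Pearson correlation over shared non-missing entries; invariant
#' to allele flips (dosage -> 2 - dosage).
#'
#' @param dosage_i,dosage_j numeric dosage vectors of equal length.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(dosage_i, dosage_j) {
  ok <- !is.na(dosage_i) & !is.na(dosage_j)
  if (sum(ok) < 2) stop("need at least 2 shared non-missing values")
  if (var(dosage_i[ok]) == 0 || var(dosage_j[ok]) == 0) {
    stop("LD undefined for a constant dosage column")
  }
  cor(dosage_i[ok], dosage_j[ok])^2
}

strand_ambiguous <- function(ea, oa) {
  p <- paste0(toupper(ea), toupper(oa))
  p %in% c("AT", "TA", "CG", "GC")
}

#' Select LD proxies of a lead variant and harmonize alleles
#'
#' Retains candidate cohort variants with \eqn{r^2 > r^2_{thr}} (strict) to
#' the lead variant's dosage and cohort MAF >= `maf_min`. When a candidate
#' carries the meta-analysis orientation (columns `gwama_ea`, `gwama_oa`
#' and optionally `gwama_eaf`), its dosage is flipped (`2 - d`) if its
#' counted allele is the meta-analysis other allele; strand-ambiguous A/T
#' and C/G variants are frequency-matched when informative (MAF outside
#' \[0.4, 0.5\]) and dropped otherwise.
#'
#' @param lead list or one-row data.frame with at least `rsid`; the lead
#'   must appear among the candidates (matched by rsid) or its dosage be
#'   supplied via `lead_dosage`.
#' @param candidates data.frame of cohort variants: `rsid`,
#'   `effect_allele`, `other_allele`, `eaf`, optional `gwama_ea`,
#'   `gwama_oa`, `gwama_eaf`.
#' @param dosages numeric matrix (samples x variants) with columns named by
#'   rsid, or a `dosage_matrix`.
#' @param r2_threshold LD threshold (default 0.8, strict inequality).
#' @param maf_min minimum cohort minor allele frequency (default 0.005).
#' @param lead_dosage optional numeric vector overriding the lead's column.
#' @return list of class `locus_result`: `locus_name`, `lead`, `proxies`
#'   (data.frame with an `r2` column, lead included), `dosages`
#'   (harmonized matrix for retained variants), `dropped` (rsids).
#' @export
select_proxies <- function(lead, candidates, dosages, r2_threshold = 0.8,
                           maf_min = 0.005, lead_dosage = NULL) {
  if (inherits(dosages, "dosage_matrix")) dosages <- dosages$values
  lead <- as.list(lead)
  if (is.null(lead_dosage)) {
    if (!lead$rsid %in% colnames(dosages)) {
      warning("lead variant ", lead$rsid, " absent from dosages; locus skipped")
      return(NULL)
    }
    lead_dosage <- dosages[, lead$rsid]
  }
  keep <- character()
  dropped <- character()
  r2s <- numeric()
  mat <- list()
  for (i in seq_len(nrow(candidates))) {
    v <- candidates[i, ]
    if (!v$rsid %in% colnames(dosages)) next
    d <- dosages[, v$rsid]
    # harmonize to the meta-analysis effect allele when both orientations
    # are known (a bare dosage TSV carries no alleles: used as-is)
    if (!is.null(candidates$gwama_ea) && !is.na(v$gwama_ea) &&
        !is.na(v$effect_allele) && !is.na(v$other_allele)) {
      ea <- toupper(v$effect_allele); oa <- toupper(v$other_allele)
      gea <- toupper(v$gwama_ea); goa <- toupper(v$gwama_oa)
      if (strand_ambiguous(ea, oa)) {
        maf <- min(v$eaf, 1 - v$eaf)
        if (maf >= 0.4) {
          dropped <- c(dropped, v$rsid)
          next
        }
        gfreq <- if (!is.null(candidates$gwama_eaf)) v$gwama_eaf else NA
        if (!is.na(gfreq) && ((v$eaf < 0.5) != (gfreq < 0.5))) d <- 2 - d
      } else if (ea == goa && oa == gea) {
        d <- 2 - d
      } else if (!(ea == gea && oa == goa)) {
        dropped <- c(dropped, v$rsid) # allele mismatch
        next
      }
    }
    maf <- min(mean(d, na.rm = TRUE) / 2, 1 - mean(d, na.rm = TRUE) / 2)
    if (maf < maf_min) {
      dropped <- c(dropped, v$rsid)
      next
    }
    r2 <- ld_r2(lead_dosage, d)
    if (v$rsid == lead$rsid || r2 > r2_threshold) {
      keep <- c(keep, v$rsid)
      r2s <- c(r2s, r2)
      mat[[v$rsid]] <- d
    }
  }
  proxies <- candidates[match(keep, candidates$rsid), , drop = FALSE]
  proxies$r2 <- r2s
  structure(list(locus_name = lead$locus %||% lead$rsid, lead = lead,
                 proxies = proxies,
                 dosages = do.call(cbind, mat),
                 dropped = dropped),
            class = "locus_result")
}

#' Test every retained variant of a locus and flag significance
#'
#' Fits [fit_snp_model()] for each retained variant, converts to one-sided
#' p-values in the meta-analysis direction, identifies the cohort-best
#' variant (minimum one-sided p) and applies the family-wise threshold.
#'
#' @param locus a `locus_result` from [select_proxies()].
#' @param y outcome vector (age/sex-adjusted residuals of ln eGFRcrea).
#' @param covariates optional covariate data.frame (PCs etc.).
#' @param expected_sign `"-"` or `"+"`, the meta-analysis effect direction.
#' @param alpha_family,n_loci family-wise level and number of loci
#'   (defaults 0.05 and 147).
#' @return `locus` with added `tests` data.frame (b, se, p_two, p_one per
#'   variant), `best_cohort_variant`, `significant`.
#' @export
test_locus <- function(locus, y, covariates = NULL, expected_sign = "-",
                       alpha_family = 0.05, n_loci = 147) {
  stopifnot(inherits(locus, "locus_result"))
  res <- lapply(colnames(locus$dosages), function(rs) {
    f <- fit_snp_model(y, locus$dosages[, rs], covariates)
    data.frame(rsid = rs, b = f$b, se = f$se, p_two = f$p_two, n = f$n,
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, res)
  tests$p_one <- one_sided_p(tests$b, tests$se, expected_sign)
  locus$tests <- tests
  best <- which.min(tests$p_one)
  locus$best_cohort_variant <- tests$rsid[best]
  locus$significant <- locus_significant(tests$p_one, alpha_family, n_loci)
  locus
}

#' Locus-level significance at the Bonferroni-corrected level
#'
#' A locus is significant when the minimum one-sided p-value across its
#' retained variants falls below `alpha_family / n_loci` (0.05/147 =
#' 0.00034 by default), strictly.
#'
#' @param p_one one-sided p-values of the locus' variants.
#' @param alpha_family family-wise alpha (0.05).
#' @param n_loci number of independent loci tested (147).
#' @return logical flag.
#' @export
locus_significant <- function(p_one, alpha_family = 0.05, n_loci = 147) {
  if (length(p_one) == 0) stop("no tested variants")
  min(p_one) < alpha_family / n_loci
}

#' Cumulative variance covered by the top-k eigenvalues
#'
#' Fraction of total variance of an m-variant correlation matrix captured
#' by its k largest eigenvalues — the criterion behind treating k loci as
#' the effective number of independent tests.
#'
#' @param corr symmetric m x m correlation matrix (PSD within tolerance;
#'   eigenvalues above -1e-10 are clipped to zero).
#' @param k number of leading eigenvalues.
#' @return fraction in \[0, 1\].
#' @export
effective_test_coverage <- function(corr, k) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) ||
      max(abs(corr - t(corr))) > 1e-8) {
    stop("`corr` must be a symmetric matrix")
  }
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("`corr` is not positive semi-definite")
  ev[ev < 0] <- 0
  k <- min(k, length(ev))
  sum(sort(ev, decreasing = TRUE)[seq_len(k)]) / nrow(corr)
}

#' Genomic control inflation factor
#'
#' Median of the chi-square(1) statistics implied by the p-values, divided
#' by the null median 0.4549364.
#'
#' @param p_values two-sided p-values in (0, 1\].
#' @return lambda estimate.
#' @export
genomic_lambda <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0, 1]")
  median(qchisq(p_values, df = 1, lower.tail = FALSE)) /
    qchisq(0.5, df = 1)
}
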