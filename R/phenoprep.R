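#' Estimate GFR with the 2009 CKD-EPI creatinine equation
#'
#' Computes estimated glomerular filtration rate (eGFRcrea, in
#' ml/min/1.73m^2) from serum creatinine with the 2009 CKD-EPI equation:
#' \deqn{141 \cdot \min(S/\kappa, 1)^{\alpha} \cdot \max(S/\kappa, 1)^{-1.209}
#'   \cdot 0.993^{age} \cdot 1.018[\mathrm{female}] \cdot 1.159[\mathrm{black}]}
#' with \eqn{\kappa = 0.7} (female) / 0.9 (male) and \eqn{\alpha = -0.329}
#' (female) / -0.411 (male).
#'
#' @param scr serum creatinine in mg/dl (positive).
#' @param age age in years (positive).
#' @param sex character vector, `"male"` or `"female"`.
#' @param black logical; ethnicity coefficient (1.159). Defaults to `FALSE`.
#' @return numeric vector of eGFRcrea in ml/min/1.73m^2.
#' @export
#' @examples
#' ckd_epi_2009(0.9, 40, "male")   # ~106.5
#' ckd_epi_2009(0.7, 50, "female") # ~101.0
ckd_epi_2009 <- function(scr, age, sex, black = FALSE) {
  sex <- check_sex(sex)
  if (any(!is.na(scr) & scr <= 0)) stop("`scr` must be positive")
  if (any(!is.na(age) & age <= 0)) stop("`age` must be positive")
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  ratio <- scr / kappa
  141 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^(-1.209) * 0.993^age *
    ifelse(female, 1.018, 1) * ifelse(black, 1.159, 1)
}

#' Invert the 2009 CKD-EPI equation for serum creatinine
#'
#' Given a target eGFRcrea, recovers the serum creatinine that the 2009
#' CKD-EPI equation maps to it. The equation is a piecewise power law in
#' creatinine, strictly decreasing, so the inverse is closed-form on each
#' piece; the branch is picked from the eGFR value at the knot
#' \eqn{S = \kappa}.
#'
#' @inheritParams ckd_epi_2009
#' @param egfr target eGFRcrea in ml/min/1.73m^2 (positive).
#' @return serum creatinine in mg/dl.
#' @export
scr_from_egfr <- function(egfr, age, sex, black = FALSE) {
  sex <- check_sex(sex)
  if (any(!is.na(egfr) & egfr <= 0)) stop("`egfr` must be positive")
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  # eGFR at the knot scr == kappa
  at_knot <- 141 * 0.993^age * ifelse(female, 1.018, 1) * ifelse(black, 1.159, 1)
  ifelse(egfr <= at_knot,
         kappa * (egfr / at_knot)^(-1 / 1.209), # scr >= kappa branch
         kappa * (egfr / at_knot)^(1 / alpha))  # scr <  kappa branch
}

check_sex <- function(sex) {
  sex <- as.character(sex)
  bad <- !is.na(sex) & !sex %in% c("male", "female")
  if (any(bad)) stop("`sex` must be 'male' or 'female'")
  sex
}

#' Winsorize eGFR and take the natural log
#'
#' Clamps eGFRcrea to \[15, 200\] ml/min/1.73m^2 and applies the natural
#' logarithm, the outcome transformation used throughout the association and
#' mediation models.
#'
#' @param egfr eGFRcrea in ml/min/1.73m^2.
#' @param lower,upper winsorization bounds (defaults 15 and 200).
#' @return data.frame with columns `egfr_raw`, `egfr_winsorized`, `ln_egfr`.
#' @export
winsorize_log <- function(egfr, lower = 15, upper = 200) {
  if (any(!is.na(egfr) & egfr <= 0)) stop("`egfr` must be positive")
  w <- pmin(pmax(egfr, lower), upper)
  data.frame(egfr_raw = egfr, egfr_winsorized = w, ln_egfr = log(w))
}

#' Normalize serum creatinine for instrument and participation period
#'
#' Removes laboratory drift from serum creatinine before eGFR estimation:
#' instrument-level mean shifts are removed as fixed effects and
#' period-level shifts are removed after shrinkage toward zero (a
#' method-of-moments random-effect analogue: each period's mean deviation is
#' multiplied by \eqn{\tau^2 / (\tau^2 + s^2/n_j)} where \eqn{\tau^2} is the
#' between-period variance component and \eqn{s^2} the pooled within-period
#' variance). The grand mean is preserved. Periods with fewer than 2
#' observations contribute no shift.
#'
#' @param scr serum creatinine in mg/dl.
#' @param instrument factor/character of measurement instrument per sample.
#' @param period factor/character of participation period; `NULL` skips the
#'   period step.
#' @return numeric vector of normalized creatinine, same length as `scr`.
#' @export
normalize_scr <- function(scr, instrument, period = NULL) {
  if (any(!is.na(scr) & scr <= 0)) stop("`scr` must be positive")
  instrument <- as.character(instrument)
  out <- scr
  ok <- !is.na(scr) & !is.na(instrument)
  grand <- mean(scr[ok])
  if (length(unique(instrument[ok])) >= 2) {
    shift <- ave(scr[ok], instrument[ok], FUN = mean) - grand
    out[ok] <- scr[ok] - shift
  }
  if (!is.null(period)) {
    period <- as.character(period)
    ok2 <- ok & !is.na(period)
    x <- out[ok2]
    g <- period[ok2]
    nj <- tapply(x, g, length)
    keep <- names(nj)[nj >= 2]
    if (length(keep) >= 2) {
      mj <- tapply(x, g, mean)[keep]
      nj <- nj[keep]
      s2 <- mean(tapply(x, g, var)[keep] * (nj - 1)) * length(nj) /
        sum(nj - 1) # pooled within-period variance
      gm <- sum(mj * nj) / sum(nj)
      # method-of-moments between-period variance
      tau2 <- max(0, sum(nj * (mj - gm)^2) / sum(nj) - s2 * mean(1 / nj))
      shrink <- tau2 / (tau2 + s2 / nj)
      shift <- setNames(shrink * (mj - gm), names(mj))
      idx <- g %in% names(shift)
      x[idx] <- x[idx] - shift[g[idx]]
      out[ok2] <- x
    }
  }
  # preserve the original grand mean
  out[ok] <- out[ok] - mean(out[ok]) + grand
  out
}

#' Rank-based inverse-normal transform
#'
#' Maps values to normal scores via the Blom offset
#' \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))}, with ties sharing the average rank
#' and missing values left missing. Used to quantile-normalize the trait
#' panel ahead of the mediation screen, protecting against instrument
#' effects and outliers. A `strata` factor applies the transform separately
#' within each stratum (e.g. measurement instrument).
#'
#' @param x numeric vector.
#' @param strata optional factor; transform within levels.
#' @return numeric vector of normal scores (mean ~0, SD ~1).
#' @export
inverse_normal_transform <- function(x, strata = NULL) {
  if (!is.null(strata)) {
    out <- x
    for (s in unique(strata[!is.na(strata)])) {
      idx <- !is.na(strata) & strata == s
      out[idx] <- inverse_normal_transform(x[idx])
    }
    return(out)
  }
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 non-missing values")
  if (length(unique(x[ok])) == 1L) {
    warning("constant input; returning zeros")
    x[ok] <- 0
    return(x)
  }
  r <- rank(x[ok], ties.method = "average")
  x[ok] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  x
}

#' Build analysis phenotypes from a raw cohort table
#'
#' Convenience wrapper: normalizes creatinine by instrument and period,
#' estimates eGFRcrea (CKD-EPI 2009), winsorizes at \[15, 200\] and logs,
#' and inverse-normal transforms the trait columns.
#'
#' @param pheno data.frame with columns `scr`, `age`, `sex`, and optionally
#'   `instrument`, `period`.
#' @param trait_cols character vector of trait column names to
#'   quantile-normalize (may be empty).
#' @param winsor_bounds numeric length-2, winsorization bounds.
#' @return `pheno` with added columns `scr_norm`, `egfr`, `egfr_winsorized`,
#'   `ln_egfr`, and transformed trait columns suffixed `_int`.
#' @export
prepare_phenotypes <- function(pheno, trait_cols = character(),
                               winsor_bounds = c(15, 200)) {
  stopifnot(is.data.frame(pheno), all(c("scr", "age", "sex") %in% names(pheno)))
  if (!is.null(pheno$instrument) && length(unique(pheno$instrument)) >= 2) {
    pheno$scr_norm <- normalize_scr(pheno$scr, pheno$instrument, pheno$period)
  } else {
    pheno$scr_norm <- pheno$scr
  }
  pheno$egfr <- ckd_epi_2009(pheno$scr_norm, pheno$age, pheno$sex)
  wl <- winsorize_log(pheno$egfr, winsor_bounds[1], winsor_bounds[2])
  pheno$egfr_winsorized <- wl$egfr_winsorized
  pheno$ln_egfr <- wl$ln_egfr
  for (tc in trait_cols) {
    pheno[[paste0(tc, "_int")]] <-
      inverse_normal_transform(pheno[[tc]], strata = pheno$instrument)
  }
  pheno
}
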