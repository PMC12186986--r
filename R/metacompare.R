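#' Leave-cohort-out meta-analysis subtraction
#'
#' Removes one cohort's contribution from fixed-effect inverse-variance
#' meta-analysis summary statistics:
#' \deqn{w' = se_{meta}^{-2} - se_{cohort}^{-2}, \quad
#'   b' = (b_{meta} se_{meta}^{-2} - b_{cohort} se_{cohort}^{-2}) / w',
#'   \quad se' = w'^{-1/2}.}
#' This is the exact inverse of two-study inverse-variance meta-analysis.
#'
#' @param b_meta,se_meta meta-analysis effect and SE.
#' @param b_cohort,se_cohort the cohort's own effect and SE.
#' @return list with `b_loo`, `se_loo`.
#' @export
meta_subtract <- function(b_meta, se_meta, b_cohort, se_cohort) {
  if (any(se_meta <= 0) || any(se_cohort <= 0)) stop("SEs must be positive")
  w_meta <- se_meta^-2
  w_cohort <- se_cohort^-2
  w <- w_meta - w_cohort
  if (any(w <= 0)) {
    stop("subtraction infeasible: the meta-analysis must carry more ",
         "information than the cohort (1/se_meta^2 > 1/se_cohort^2)")
  }
  list(b_loo = (b_meta * w_meta - b_cohort * w_cohort) / w,
       se_loo = w^-0.5)
}

#' Sample-size-weighted subtraction of z-scores
#'
#' Alternative mode for inputs that only carry z-scores and sample sizes:
#' \eqn{z' = (z_{meta}\sqrt{n_{meta}} - z_{cohort}\sqrt{n_{cohort}}) /
#' \sqrt{n_{meta} - n_{cohort}}}.
#'
#' @param z_meta,n_meta meta-analysis z and total n.
#' @param z_cohort,n_cohort cohort z and n.
#' @return list with `z_loo`, `n_loo`.
#' @export
meta_subtract_z <- function(z_meta, n_meta, z_cohort, n_cohort) {
  if (any(n_meta <= n_cohort)) stop("meta-analysis n must exceed cohort n")
  list(z_loo = (z_meta * sqrt(n_meta) - z_cohort * sqrt(n_cohort)) /
         sqrt(n_meta - n_cohort),
       n_loo = n_meta - n_cohort)
}

#' Outcome variance explained by one variant
#'
#' Approximate per-variant fraction of outcome variance,
#' \eqn{b^2 \cdot 2\,p(1-p) / var(y)}.
#'
#' @param b per-allele effect.
#' @param eaf effect allele frequency in (0, 1).
#' @param var_y variance of the (age/sex-adjusted) outcome.
#' @return fraction (>= 0).
#' @export
variance_explained <- function(b, eaf, var_y) {
  if (any(eaf <= 0 | eaf >= 1)) stop("`eaf` must be in (0, 1)")
  if (any(var_y <= 0)) stop("`var_y` must be positive")
  b^2 * 2 * eaf * (1 - eaf) / var_y
}

#' Compare a cohort variant record against its meta-analysis counterpart
#'
#' Computes the effect ratio (cohort / meta), minor-allele-frequency ratio
#' and both variance-explained values for one harmonized variant.
#'
#' @param cohort,meta lists or one-row data.frames with `b`, `se`, `eaf`
#'   (alleles already harmonized to the same effect allele).
#' @param var_y variance of the adjusted outcome in the cohort.
#' @param locus_name optional label.
#' @return one-row data.frame (class `cohort_comparison`) with the effect
#'   and MAF ratios and variance-explained columns; `effect_ratio` is `NA`
#'   (with a warning) when the meta-analysis effect is zero.
#' @export
compare_cohorts <- function(cohort, meta, var_y, locus_name = NA_character_) {
  cohort <- as.list(cohort)
  meta <- as.list(meta)
  maf_c <- min(cohort$eaf, 1 - cohort$eaf)
  maf_m <- min(meta$eaf, 1 - meta$eaf)
  if (meta$b == 0) {
    warning("meta-analysis effect is zero; effect ratio undefined")
    er <- NA_real_
  } else {
    er <- cohort$b / meta$b
  }
  out <- data.frame(
    locus_name = locus_name,
    b_cohort = cohort$b, b_meta = meta$b,
    se_cohort = cohort$se, se_meta = meta$se,
    eaf_cohort = cohort$eaf, eaf_meta = meta$eaf,
    effect_ratio = er,
    maf_ratio = if (maf_m > 0) maf_c / maf_m else NA_real_,
    var_explained_cohort = variance_explained(cohort$b, cohort$eaf, var_y),
    var_explained_meta = variance_explained(meta$b, meta$eaf, var_y),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort_comparison", class(out))
  out
}
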