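#' Read a meta-analysis summary-statistics table
#'
#' Tab-separated, one row per variant, required columns `rsid`, `chr`,
#' `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`
#' (optional `n`). Allele strings are uppercased; positions are 1-based.
#'
#' @param path file path.
#' @return data.frame of validated variant records.
#' @export
read_summary_stats <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("rsid", "chr", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "p")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("summary-statistics file lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(d) == 0) stop("summary-statistics file has no rows")
  for (col in c("pos", "eaf", "beta", "se", "p")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad)) {
      stop("non-numeric ", col, " at line ", bad[1] + 1L) # +1 for header
    }
    d[[col]] <- v
  }
  if (any(d$eaf <= 0 | d$eaf >= 1, na.rm = TRUE)) {
    stop("eaf must be strictly between 0 and 1")
  }
  if (any(d$se <= 0, na.rm = TRUE)) stop("se must be positive")
  if (any(d$p <= 0 | d$p > 1, na.rm = TRUE)) stop("p must be in (0, 1]")
  d$effect_allele <- toupper(d$effect_allele)
  d$other_allele <- toupper(d$other_allele)
  if (any(d$effect_allele == d$other_allele)) {
    stop("effect and other allele must differ")
  }
  d
}

#' Write a summary-statistics table
#'
#' @param records data.frame as returned by [read_summary_stats()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage matrix from TSV or VCF
#'
#' TSV layout: first column `sample_id`, remaining columns one variant
#' each (header = variant IDs), values = allelic dosages in \[0, 2\].
#' VCF: dosages from the `DS` FORMAT field (requires the vcfR package).
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return a [dosage_matrix()].
#' @export
read_dosages <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(d) == 0 || ncol(d) < 2) {
      stop("dosage file must have a sample_id column and >= 1 variant")
    }
    ids <- as.character(d[[1]])
    vals <- as.matrix(d[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    bad <- which(!is.na(vals) & (vals < 0 | vals > 2), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("dosage outside [0, 2] at row ", bad[1, 1], ", variant ",
           colnames(vals)[bad[1, 2]])
    }
    variants <- data.frame(rsid = colnames(vals), chr = NA, pos = NA,
                           effect_allele = NA, other_allele = NA,
                           eaf = colMeans(vals, na.rm = TRUE) / 2,
                           stringsAsFactors = FALSE)
    return(dosage_matrix(vals, variants, ids))
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  if (is.null(ds) || nrow(ds) == 0) stop("no DS field found in VCF")
  vals <- t(ds)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  variants <- data.frame(rsid = fix$ID, chr = fix$CHROM,
                         pos = as.integer(fix$POS),
                         effect_allele = toupper(fix$ALT),
                         other_allele = toupper(fix$REF),
                         eaf = colMeans(vals, na.rm = TRUE) / 2,
                         stringsAsFactors = FALSE)
  colnames(vals) <- variants$rsid
  dosage_matrix(vals, variants, rownames(vals))
}

#' Write a dosage matrix to TSV or VCF
#'
#' The VCF writer emits a minimal VCFv4.2 file whose per-genotype field is
#' the `DS` dosage (ALT = effect allele, so DS counts effect alleles).
#'
#' @param dm a [dosage_matrix()].
#' @param path output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_dosages <- function(dm, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  stopifnot(inherits(dm, "dosage_matrix"))
  if (format == "tsv") {
    d <- data.frame(sample_id = dm$sample_ids, dm$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  v <- dm$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", dm$sample_ids),
                     collapse = "\t")), con)
  for (j in seq_len(nrow(v))) {
    row <- c(v$chr[j] %|na|% ".", v$pos[j] %|na|% ".", v$rsid[j],
             v$other_allele[j] %|na|% "N", v$effect_allele[j] %|na|% "N",
             ".", "PASS", ".", "DS",
             formatC(dm$values[, j], format = "g", digits = 6))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

`%|na|%` <- function(a, b) if (is.na(a)) b else as.character(a)

#' Read / write a phenotype table
#'
#' Plain TSV with a header; `sample_id` kept as character.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(d)) stop("phenotype file lacks sample_id")
  d$sample_id <- as.character(d$sample_id)
  d
}

#' @rdname read_phenotypes
#' @param pheno data.frame to write.
#' @export
write_phenotypes <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects paths, thresholds and options of [run_pipeline()]. Either the
#' three input paths or a `ground_truth` object (synthetic mode) must be
#' given. Thresholds default to the analysis' multiple-testing scheme:
#' locus level 0.05/147, mediation step-3 level 0.05/(70 x 11),
#' interaction level 0.05/11, proxy r2 > 0.8, MAF >= 0.005, winsorization
#' at 15/200, TSH thresholds 0.4/3.8.
#'
#' @param summary_stats,dosages,phenotypes input paths (or `NULL` in
#'   synthetic mode).
#' @param truth optional [ground_truth()]; when given, inputs are
#'   simulated.
#' @param n_loci_family,n_traits,n_loci_mediation,n_loci_interaction
#'   multiplicities for the three thresholds.
#' @param r2_threshold,maf_min,winsor_bounds,tsh_thresholds analysis
#'   constants.
#' @param trait_cols character vector naming the trait columns of the
#'   phenotype table; `NULL` auto-detects (synthetic mode: the ground
#'   truth's traits; file mode: numeric columns that are not identifiers,
#'   covariates, thyroid measures, PCs or flags).
#' @param seed integer seed governing all randomness.
#' @param outdir output directory (created if needed); `NULL` disables
#'   file output.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(summary_stats = NULL, dosages = NULL,
                            phenotypes = NULL, truth = NULL,
                            n_loci_family = 147, n_traits = 70,
                            n_loci_mediation = 11, n_loci_interaction = 11,
                            r2_threshold = 0.8, maf_min = 0.005,
                            winsor_bounds = c(15, 200),
                            tsh_thresholds = c(low = 0.4, high = 3.8),
                            trait_cols = NULL, seed = 1L, outdir = NULL) {
  if (is.null(truth) &&
      (is.null(summary_stats) || is.null(dosages) || is.null(phenotypes))) {
    stop("either all three input paths or a ground_truth must be given")
  }
  stopifnot(n_loci_family > 0, n_traits > 0, n_loci_mediation > 0,
            n_loci_interaction > 0, r2_threshold > 0, maf_min >= 0)
  structure(list(summary_stats = summary_stats, dosages = dosages,
                 phenotypes = phenotypes, truth = truth,
                 n_loci_family = n_loci_family, n_traits = n_traits,
                 n_loci_mediation = n_loci_mediation,
                 n_loci_interaction = n_loci_interaction,
                 r2_threshold = r2_threshold, maf_min = maf_min,
                 winsor_bounds = winsor_bounds,
                 tsh_thresholds = tsh_thresholds, trait_cols = trait_cols,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys matching [pipeline_config()] arguments.
#' @return `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the yaml package")
  }
  args <- yaml::yaml.load_file(path)
  do.call(pipeline_config, args)
}
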