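#' Analysis configuration
#'
#' Collects every tunable threshold of the escape-quantification pipeline in
#' one validated list. Defaults follow the values used throughout the
#' documentation: allelic depth filter of 8 reads, skew classification at a
#' degree of skewing (DS) of 0.3 (equivalently a XIST allelic fraction at or
#' below 0.2 / at or above 0.8), escape classification at a median escape
#' score of 0.36 across at least 3 skewed tissue samples, the 80%-within-one-sd
#' consistency rule over at least 10 individuals, and a minimum of 5 shared
#' genes for twin-pair correlations.
#'
#' @param depth_min Minimum total allelic read depth (hapA + hapB) for an
#'   observation to pass QC. Default 8.
#' @param skew_threshold Degree-of-skewing value at or above which a sample is
#'   classified as skewed. Default 0.3.
#' @param escape_cutoff Escape-score value at or above which a gene's median
#'   is called escapee. Default 0.36.
#' @param min_tissue_samples Minimum number of skewed samples of a tissue
#'   required before a gene receives an escape/silenced call there. Default 3.
#' @param min_individuals Minimum number of individuals with a score required
#'   for an inter-individual consistency call. Default 10.
#' @param band_fraction Fraction of individuals that must lie within one
#'   standard deviation of the gene's mean score for a "consistent" label.
#'   Default 0.8.
#' @param min_shared_genes Minimum number of genes scored in both co-twins for
#'   a twin pair to yield a valid correlation. Default 5.
#' @param min_skewed_samples Minimum number of skewed samples required to fit
#'   the escape model at all; below this the pipeline aborts. Default 10.
#' @param xist_gene Gene identifier of the XIST record used for skew calling.
#' @param exclude_tissues Tissue labels excluded from escape calls and
#'   downstream analyses (their skewed samples still enter the model fit).
#'   Default `"whole-blood"`.
#' @param twin_tissue Tissue in which twin concordance is evaluated.
#'   Default `"LCL"`.
#' @param both_haplotype_scope Scope of the both-haplotypes-detected QC rule:
#'   `"individual"` pools all samples of an individual (validates
#'   heterozygosity without discarding genuinely monoallelic single-sample
#'   observations), `"sample"` requires both haplotypes in every sample.
#' @param cor_method Correlation estimator for twin-pair score vectors:
#'   `"spearman"` (default) or `"pearson"`.
#' @param sd_type Standard deviation used by the consistency band:
#'   `"population"` (default, divisor n) or `"sample"` (divisor n - 1).
#' @param fisher_z If `TRUE`, the zygosity comparison t-test is run on
#'   Fisher-z transformed correlations. Default `FALSE`.
#' @param rescale_quantiles Optional length-2 numeric (e.g. `c(0.005, 0.995)`)
#'   replacing the raw residual min/max with quantiles before rescaling, as an
#'   outlier-robust alternative. `NULL` (default) uses the exact extremes.
#' @param per_tissue_fit If `TRUE`, the allelic-fold-change-on-skew model is
#'   fitted per tissue instead of pooled over the whole skewed cohort
#'   (sensitivity analysis; the pooled fit is the reference behaviour).
#' @param benchmark_cutoffs Cutoff grid for [benchmark_thresholds()].
#'
#' @return A list of class `"xci_config"`.
#' @export
#' @examples
#' cfg <- xci_config()
#' cfg$escape_cutoff
xci_config <- function(depth_min = 8,
                       skew_threshold = 0.3,
                       escape_cutoff = 0.36,
                       min_tissue_samples = 3,
                       min_individuals = 10,
                       band_fraction = 0.8,
                       min_shared_genes = 5,
                       min_skewed_samples = 10,
                       xist_gene = "XIST",
                       exclude_tissues = "whole-blood",
                       twin_tissue = "LCL",
                       both_haplotype_scope = c("individual", "sample"),
                       cor_method = c("spearman", "pearson"),
                       sd_type = c("population", "sample"),
                       fisher_z = FALSE,
                       rescale_quantiles = NULL,
                       per_tissue_fit = FALSE,
                       benchmark_cutoffs = seq(0.2, 0.6, by = 0.02)) {
  both_haplotype_scope <- match.arg(both_haplotype_scope)
  cor_method <- match.arg(cor_method)
  sd_type <- match.arg(sd_type)

  stopifnot(
    is.numeric(depth_min), length(depth_min) == 1L, depth_min >= 0,
    is.numeric(skew_threshold), skew_threshold >= 0, skew_threshold <= 0.5,
    is.numeric(escape_cutoff), escape_cutoff >= 0, escape_cutoff <= 1,
    min_tissue_samples >= 1, min_individuals >= 1,
    band_fraction >= 0, band_fraction <= 1,
    min_shared_genes >= 1, min_skewed_samples >= 2,
    is.character(xist_gene), length(xist_gene) == 1L,
    is.logical(fisher_z), is.logical(per_tissue_fit)
  )
  if (!is.null(rescale_quantiles)) {
    stopifnot(length(rescale_quantiles) == 2L,
              rescale_quantiles[1] < rescale_quantiles[2],
              all(rescale_quantiles >= 0), all(rescale_quantiles <= 1))
  }

  structure(
    list(
      depth_min = depth_min,
      skew_threshold = skew_threshold,
      escape_cutoff = escape_cutoff,
      min_tissue_samples = min_tissue_samples,
      min_individuals = min_individuals,
      band_fraction = band_fraction,
      min_shared_genes = min_shared_genes,
      min_skewed_samples = min_skewed_samples,
      xist_gene = xist_gene,
      exclude_tissues = exclude_tissues,
      twin_tissue = twin_tissue,
      both_haplotype_scope = both_haplotype_scope,
      cor_method = cor_method,
      sd_type = sd_type,
      fisher_z = fisher_z,
      rescale_quantiles = rescale_quantiles,
      per_tissue_fit = per_tissue_fit,
      benchmark_cutoffs = benchmark_cutoffs
    ),
    class = "xci_config"
  )
}

#' @export
print.xci_config <- function(x, ...) {
  cat("<xci_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(val)) "NULL" else paste(format(val), collapse = ", ")))
  }
  invisible(x)
}

#' Read a plain-text key-value configuration file
#'
#' Parses lines of the form `key = value` (or `key: value`); `#` starts a
#' comment. Values that parse as numbers become numeric; comma-separated
#' values become vectors; `true`/`false` become logical. Recognised keys
#' override [xci_config()] defaults; unknown keys raise an error.
#'
#' @param path Path to the configuration file.
#' @return An `xci_config` list.
#' @export
read_xci_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- xci_config()
  overrides <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) {
      stop("malformed config line: '", ln, "'", call. = FALSE)
    }
    key <- m[2]
    if (!key %in% names(defaults)) {
      stop("unknown config key: '", key, "'", call. = FALSE)
    }
    overrides[[key]] <- parse_config_value(trimws(m[3]))
  }
  do.call(xci_config, overrides)
}

parse_config_value <- function(x) {
  parts <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  nums <- suppressWarnings(as.numeric(parts))
  if (!anyNA(nums)) return(nums)
  if (all(tolower(parts) %in% c("true", "false"))) {
    return(tolower(parts) == "true")
  }
  parts
}
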