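#' Allele-specific expression of a gene
#'
#' Fraction of a gene's allelic reads assigned to haplotype A,
#' `ase = ac / (ac + bc)`. Values of 0 and 1 indicate monoallelic
#' expression, 0.5 completely balanced haplotypic expression. The two
#' haplotypes' fractions sum to 1 by construction.
#'
#' @param ac,bc Non-negative read counts on haplotypes A and B (vectorised).
#' @return The haplotype-A fraction in `[0, 1]`.
#' @export
#' @examples
#' compute_ase(13, 7)   # 0.65
#' compute_ase(20, 0)   # monoallelic: 1
compute_ase <- function(ac, bc) {
  check_counts(ac, bc)
  ac / (ac + bc)
}

#' Allelic fold change of a gene
#'
#' Ratio of the lower to the higher haplotype read count,
#' `afc = min(ac, bc) / max(ac, bc)`: 0 indicates monoallelic expression
#' (full silencing), 1 completely balanced expression (full escape). In a
#' skewed sample the lower-expressed haplotype is taken to sit on the
#' inactive X, so the allelic fold change estimates the inactive-to-active
#' expression ratio. Symmetric in its arguments.
#'
#' @inheritParams compute_ase
#' @return The allelic fold change in `[0, 1]`.
#' @export
#' @examples
#' compute_afc(8, 8)    # balanced: 1
#' compute_afc(0, 20)   # silenced: 0
compute_afc <- function(ac, bc) {
  check_counts(ac, bc)
  pmin(ac, bc) / pmax(ac, bc)
}

check_counts <- function(ac, bc) {
  if (any(ac < 0) || any(bc < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(ac + bc == 0)) {
    stop("undefined observation: total allelic depth is 0", call. = FALSE)
  }
  invisible(NULL)
}

#' Compute allelic observations and apply QC filters
#'
#' Turns a count table into per gene-sample allelic observations (total
#' depth, allele-specific expression, allelic fold change) and applies the
#' two QC rules: a minimum total allelic read depth (default 8 reads), and
#' the requirement that both haplotypes of the gene were detected at least
#' once — by default pooled over all samples of the observation's individual,
#' which validates that the genotype is truly heterozygous without discarding
#' genuinely monoallelic single-sample observations; a strict per-sample mode
#' is available via the configuration. Records with zero total depth are
#' dropped (with a logged count) before flags are computed.
#'
#' Attrition is reported via `message()` and attached as the `"attrition"`
#' attribute: a table whose per-filter removal counts plus the retained count
#' equal the number of input records (each dropped record is attributed to
#' the first filter it fails, in order zero-depth, low-depth,
#' single-haplotype).
#'
#' @param counts A validated count table (see [read_count_table()]).
#' @param sheet Optional sample sheet; required when
#'   `config$both_haplotype_scope == "individual"` so samples can be pooled
#'   by individual.
#' @param config An [xci_config()] list.
#' @return A tibble of observations: `gene_id`, `sample_id`, `ac`, `bc`,
#'   `tc`, `ase`, `afc`, `qc_depth`, `qc_both_haps`, `retained`.
#' @export
#' @examples
#' counts <- tibble::tibble(
#'   gene_id = c("G1", "G1", "XIST"), sample_id = c("S1", "S2", "S1"),
#'   hapA_count = c(10L, 12L, 2L), hapB_count = c(3L, 0L, 30L))
#' sheet <- tibble::tibble(sample_id = c("S1", "S2"),
#'   individual_id = c("I1", "I1"), tissue = "LCL",
#'   twin_pair_id = NA_character_, zygosity = NA_character_)
#' apply_qc(counts, sheet)
apply_qc <- function(counts, sheet = NULL, config = xci_config()) {
  obs <- tibble::as_tibble(counts)
  names(obs)[match(c("hapA_count", "hapB_count"), names(obs))] <- c("ac", "bc")
  n_in <- nrow(obs)

  zero <- obs$ac + obs$bc == 0L
  obs <- obs[!zero, , drop = FALSE]

  obs$tc <- obs$ac + obs$bc
  obs$ase <- obs$ac / obs$tc
  obs$afc <- pmin(obs$ac, obs$bc) / pmax(obs$ac, obs$bc)
  obs$qc_depth <- obs$tc >= config$depth_min

  if (config$both_haplotype_scope == "individual") {
    if (is.null(sheet)) {
      stop("sheet is required for both_haplotype_scope = 'individual'",
           call. = FALSE)
    }
    key_ind <- sheet$individual_id[match(obs$sample_id, sheet$sample_id)]
    if (anyNA(key_ind)) {
      stop("count table names sample(s) absent from the sample sheet: ",
           paste(utils::head(unique(obs$sample_id[is.na(key_ind)]), 3),
                 collapse = ", "), call. = FALSE)
    }
  } else {
    key_ind <- obs$sample_id
  }
  grp <- paste(obs$gene_id, key_ind, sep = "\r")
  seen_a <- tapply(obs$ac, grp, function(x) any(x > 0))
  seen_b <- tapply(obs$bc, grp, function(x) any(x > 0))
  both <- seen_a & seen_b
  obs$qc_both_haps <- as.vector(both[grp])

  obs$retained <- obs$qc_depth & obs$qc_both_haps

  n_low_depth <- sum(!obs$qc_depth)
  n_single_hap <- sum(obs$qc_depth & !obs$qc_both_haps)
  attrition <- tibble::tibble(
    filter = c("zero_depth", "low_depth", "single_haplotype", "retained"),
    n = c(sum(zero), n_low_depth, n_single_hap, sum(obs$retained))
  )
  stopifnot(sum(attrition$n) == n_in)
  message(sprintf(
    "QC: %d records in; %d zero-depth, %d below depth %g, %d single-haplotype; %d retained",
    n_in, sum(zero), n_low_depth, config$depth_min, n_single_hap,
    sum(obs$retained)
  ))

  out <- obs[c("gene_id", "sample_id", "ac", "bc", "tc", "ase", "afc",
               "qc_depth", "qc_both_haps", "retained")]
  attr(out, "attrition") <- attrition
  out
}
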