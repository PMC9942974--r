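#' Degree of XCI skewing
#'
#' Absolute deviation of the XIST allelic fraction from 0.5:
#' `ds = |0.5 - xist_ase|`. Because XIST is expressed exclusively from the
#' inactive X, its allelic fraction in a bulk sample reflects the mixture of
#' cells inactivating either parental X; `ds = 0` indicates random XCI
#' (balanced mosaic) and `ds = 0.5` completely skewed XCI.
#'
#' @param xist_ase XIST haplotype-A fraction(s) in `[0, 1]`.
#' @return Degree(s) of skewing in `[0, 0.5]`.
#' @export
#' @examples
#' compute_ds(0.2)  # 0.3, the skew-classification boundary
#' compute_ds(0.5)  # 0: random XCI
compute_ds <- function(xist_ase) {
  if (any(is.na(xist_ase)) || any(xist_ase < 0 | xist_ase > 1)) {
    stop("xist_ase must lie in [0, 1]", call. = FALSE)
  }
  abs(0.5 - xist_ase)
}

#' Classify a sample's XCI pattern from its degree of skewing
#'
#' A sample is skewed when `ds >= threshold` (boundary inclusive); at the
#' default threshold of 0.3 this is equivalent to a XIST allelic fraction at
#' or below 0.2, or at or above 0.8.
#'
#' @param ds Degree(s) of skewing in `[0, 0.5]`.
#' @param threshold Classification threshold, default 0.3.
#' @return Character vector, `"skewed"` or `"random"`.
#' @export
#' @examples
#' classify_skew(c(0.29, 0.30, 0.5))
classify_skew <- function(ds, threshold = 0.3) {
  if (any(is.na(ds)) || any(ds < 0 | ds > 0.5)) {
    stop("ds must lie in [0, 0.5]", call. = FALSE)
  }
  out <- rep("random", length(ds))
  out[ds >= threshold] <- "skewed"
  out
}

#' Call per-sample XCI skew from XIST allele-specific expression
#'
#' Extracts each sample's XIST observation from the QC'd observation table,
#' computes the degree of skewing and classifies the sample as skewed or
#' random. The XIST record must pass the depth filter but is exempt from the
#' both-haplotypes-detected rule: a completely skewed sample legitimately
#' shows monoallelic XIST, and requiring both haplotypes there would
#' systematically discard the most skewed — most informative — samples.
#' Samples without a depth-passing XIST observation receive status
#' `"unavailable"`. When a sample sheet is supplied, every sheet sample is
#' represented in the output even if it contributed no observations.
#'
#' @param observations Output of [apply_qc()].
#' @param sheet Optional sample sheet used to enumerate samples.
#' @param config An [xci_config()] list (uses `xist_gene` and
#'   `skew_threshold`).
#' @return A tibble: `sample_id`, `xist_ase`, `ds`, `status` (one of
#'   `"skewed"`, `"random"`, `"unavailable"`).
#' @export
call_skew <- function(observations, sheet = NULL, config = xci_config()) {
  xist <- observations[observations$gene_id == config$xist_gene &
                         observations$qc_depth, , drop = FALSE]
  calls <- tibble::tibble(
    sample_id = xist$sample_id,
    xist_ase = xist$ase,
    ds = compute_ds(xist$ase)
  )
  calls$status <- classify_skew(calls$ds, config$skew_threshold)

  all_samples <- unique(if (is.null(sheet)) observations$sample_id
                        else sheet$sample_id)
  missing <- setdiff(all_samples, calls$sample_id)
  if (length(missing) > 0) {
    calls <- dplyr::bind_rows(
      calls,
      tibble::tibble(sample_id = missing, xist_ase = NA_real_,
                     ds = NA_real_, status = "unavailable")
    )
  }
  calls[match(all_samples, calls$sample_id), , drop = FALSE]
}
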