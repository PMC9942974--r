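#' Run the full escape-quantification pipeline
#'
#' Orchestrates QC, skew calling, escape-model fitting, escape scoring,
#' gene-tissue calls, variability analyses, twin concordance and (when an
#' annotation is supplied) threshold benchmarking and overlap testing.
#' Aborts with a diagnostic when fewer than `config$min_skewed_samples`
#' skewed samples are available for the model fit. All randomness lives in
#' the simulator; given identical inputs and configuration the pipeline is
#' deterministic.
#'
#' @param counts Count table (see [read_count_table()] /
#'   [validate_count_table()]).
#' @param sheet Sample sheet.
#' @param annotation Optional reference annotation.
#' @param config An [xci_config()] list.
#' @param out_dir Optional directory; when given, every result table is
#'   written there as tab-separated text along with the persisted model.
#' @return A list of class `"xci_result"`: `observations`, `attrition`,
#'   `skew_calls`, `model`, `records`, `gene_tissue_calls`, `incidence`,
#'   `intra_donor`, `consistency`, `tissue_test`, `twin_pairs`,
#'   `zygosity`, and (with an annotation) `benchmark`, `overlap`.
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(n_genes = 60, n_mz_pairs = 4,
#'   n_dz_pairs = 3, n_singletons = 10, seed = 11))
#' res <- run_pipeline(sim$counts, sim$sheet, sim$annotation)
#' res$incidence
run_pipeline <- function(counts, sheet, annotation = NULL,
                         config = xci_config(), out_dir = NULL) {
  counts <- validate_count_table(counts)
  sheet <- validate_sample_sheet(sheet)
  if (!is.null(annotation)) {
    annotation <- validate_reference_annotation(annotation)
  }

  observations <- apply_qc(counts, sheet, config)
  skew_calls <- call_skew(observations, sheet, config)
  n_skewed <- sum(skew_calls$status == "skewed")
  message(sprintf("skew: %d skewed, %d random, %d unavailable of %d samples",
                  n_skewed, sum(skew_calls$status == "random"),
                  sum(skew_calls$status == "unavailable"),
                  nrow(skew_calls)))
  if (n_skewed < config$min_skewed_samples) {
    stop("insufficient skewed samples for model fitting (", n_skewed,
         " < ", config$min_skewed_samples, ")", call. = FALSE)
  }

  if (config$per_tissue_fit) {
    tissue_of <- sheet$tissue[match(observations$sample_id,
                                    sheet$sample_id)]
    fits <- lapply(unique(tissue_of), function(tis) {
      fit_escape_model(observations[tissue_of == tis, , drop = FALSE],
                       skew_calls, config)
    })
    model <- lapply(fits, `[[`, "model")
    records <- dplyr::bind_rows(lapply(fits, `[[`, "records"))
  } else {
    fit <- fit_escape_model(observations, skew_calls, config)
    model <- fit$model
    records <- fit$records
  }

  calls <- call_gene_tissue(records, sheet, config)
  incidence <- attr(calls, "incidence")
  intra_donor <- withCallingHandlers(
    intra_donor_summary(records, sheet, config),
    warning = function(w) invokeRestart("muffleWarning")
  )
  consistency <- consistency_call(records, sheet, calls, config)

  tissue_scores <- dplyr::inner_join(
    calls[calls$status != "no_call", c("gene_id", "tissue",
                                       "median_escscore")],
    tibble::tibble(tissue = setdiff(unique(sheet$tissue),
                                    config$exclude_tissues)),
    by = "tissue"
  )
  tissue_test <- tryCatch(
    group_difference_test(tissue_scores$median_escscore,
                          tissue_scores$tissue),
    error = function(e) NULL
  )

  twin_pairs <- twin_pair_stats(records, sheet, config)
  zygosity <- if (nrow(twin_pairs) > 0) {
    zygosity_compare(twin_pairs, config$fisher_z)
  } else {
    NULL
  }

  benchmark <- NULL
  overlap <- NULL
  if (!is.null(annotation)) {
    benchmark <- benchmark_thresholds(records, sheet, annotation, config)
    gene_status <- gene_level_status(calls)
    universe <- gene_status$gene_id
    ref_esc <- intersect(annotation$gene_id[annotation$prior_status ==
                                              "escape"], universe)
    called_esc <- gene_status$gene_id[gene_status$call == "escapee"]
    overlap <- if (length(universe) > 0) {
      overlap_test(called_esc, ref_esc, universe)
    }
  }

  result <- structure(
    list(
      observations = observations,
      attrition = attr(observations, "attrition"),
      skew_calls = skew_calls,
      model = model,
      records = records,
      gene_tissue_calls = calls,
      incidence = incidence,
      intra_donor = intra_donor,
      consistency = consistency,
      tissue_test = tissue_test,
      twin_pairs = twin_pairs,
      zygosity = zygosity,
      benchmark = benchmark,
      overlap = overlap,
      config = config
    ),
    class = "xci_result"
  )
  if (!is.null(out_dir)) write_results(result, out_dir)
  result
}

#' Write every pipeline result table to a directory
#'
#' @param result An `"xci_result"` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return `result`, invisibly.
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_result_table(result$observations, p("observations.tsv"))
  write_result_table(result$attrition, p("attrition.tsv"))
  write_result_table(result$skew_calls, p("skew_calls.tsv"))
  write_result_table(result$records, p("escscores.tsv"))
  write_result_table(result$gene_tissue_calls, p("gene_tissue_calls.tsv"))
  write_result_table(result$incidence, p("escape_incidence.tsv"))
  write_result_table(result$intra_donor$counts, p("intra_donor_counts.tsv"))
  write_result_table(result$consistency, p("consistency_calls.tsv"))
  write_result_table(result$twin_pairs, p("twin_pairs.tsv"))
  if (inherits(result$model, "escape_model")) {
    write_escape_model(result$model, p("escape_model.txt"))
  }
  if (!is.null(result$zygosity)) {
    write_result_table(tibble::as_tibble(result$zygosity),
                       p("zygosity_comparison.tsv"))
  }
  if (!is.null(result$benchmark)) {
    write_result_table(result$benchmark, p("threshold_benchmark.tsv"))
  }
  if (!is.null(result$overlap)) {
    write_result_table(tibble::as_tibble(result$overlap),
                       p("annotation_overlap.tsv"))
  }
  invisible(result)
}

#' @export
print.xci_result <- function(x, ...) {
  cat("<xci_result>\n")
  cat(sprintf("  %d retained observations across %d samples\n",
              sum(x$observations$retained),
              length(unique(x$observations$sample_id))))
  cat(sprintf("  %d skewed samples; escape model on %s observations\n",
              sum(x$skew_calls$status == "skewed"),
              if (inherits(x$model, "escape_model"))
                format(x$model$n_obs) else "per-tissue"))
  if (!is.null(x$incidence) && nrow(x$incidence) > 0) {
    cat("  escape incidence by tissue:\n")
    for (i in seq_len(nrow(x$incidence))) {
      cat(sprintf("    %-12s %3d/%3d escapees (%.0f%%)\n",
                  x$incidence$tissue[i], x$incidence$n_escapees[i],
                  x$incidence$n_called[i], 100 * x$incidence$incidence[i]))
    }
  }
  invisible(x)
}
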