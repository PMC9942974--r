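#' Intra-donor tissue sharing of escape
#'
#' Restricted to donors with at least one scored (skewed) sample in every
#' analysed tissue, summarises within each donor how many tissues each gene
#' escapes in. Per donor and tissue a gene's score is the median over that
#' donor's samples; only genes scored in all analysed tissues of the donor
#' enter the summary, and the per-bin counts (escape in 0, 1, ..., T
#' tissues) partition that gene set.
#'
#' @param records Escape-score records of skewed samples.
#' @param sheet Sample sheet.
#' @param config An [xci_config()] list (`escape_cutoff`,
#'   `exclude_tissues`).
#' @param tissues Tissues to analyse; default all tissues present in the
#'   records after exclusions.
#' @return A list with `genes` (per donor and gene: per-tissue scores kept
#'   long, plus `n_tissues_escaping`) and `counts` (per donor: number of
#'   genes per sharing bin). Zero qualifying donors yields empty tables with
#'   a warning.
#' @export
intra_donor_summary <- function(records, sheet, config = xci_config(),
                                tissues = NULL) {
  df <- join_tissue(records, sheet)
  df$individual_id <- sheet$individual_id[match(df$sample_id,
                                                sheet$sample_id)]
  df <- df[!df$tissue %in% config$exclude_tissues, , drop = FALSE]
  if (is.null(tissues)) tissues <- sort(unique(df$tissue))
  df <- df[df$tissue %in% tissues, , drop = FALSE]
  n_t <- length(tissues)

  per_dt <- df |>
    dplyr::group_by(.data$individual_id, .data$tissue, .data$gene_id) |>
    dplyr::summarise(score = stats::median(.data$escscore), .groups = "drop")

  donor_tissues <- per_dt |>
    dplyr::distinct(.data$individual_id, .data$tissue) |>
    dplyr::count(.data$individual_id, name = "n_tissues")
  qualifying <- donor_tissues$individual_id[donor_tissues$n_tissues == n_t]
  if (length(qualifying) == 0L) {
    warning("no donor has scored skewed samples in every analysed tissue")
    return(list(
      genes = tibble::tibble(individual_id = character(),
                             gene_id = character(),
                             n_tissues_escaping = integer()),
      counts = tibble::tibble(individual_id = character(),
                              n_tissues_escaping = integer(),
                              n_genes = integer())
    ))
  }

  genes <- per_dt |>
    dplyr::filter(.data$individual_id %in% qualifying) |>
    dplyr::group_by(.data$individual_id, .data$gene_id) |>
    dplyr::summarise(
      n_tissues_scored = dplyr::n(),
      n_tissues_escaping = sum(.data$score >= config$escape_cutoff),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_tissues_scored == n_t) |>
    dplyr::select("individual_id", "gene_id", "n_tissues_escaping")

  counts <- genes |>
    dplyr::count(.data$individual_id, .data$n_tissues_escaping,
                 name = "n_genes") |>
    tidyr::complete(
      individual_id = qualifying,
      n_tissues_escaping = 0:n_t,
      fill = list(n_genes = 0L)
    )
  list(genes = genes, counts = counts)
}

#' Inter-individual consistency of escape scores
#'
#' For genes escaping in at least one analysed tissue, assesses whether a
#' gene's escape score is consistent across individuals within a tissue:
#' with one score per individual (median over that individual's skewed
#' samples), the gene is `consistent` when at least `band_fraction` (default
#' 80%) of individuals lie within one standard deviation of the gene's mean
#' score in the tissue, `variable` otherwise, and `no_call` with fewer than
#' `min_individuals` (default 10) individuals. A zero standard deviation
#' places every individual inside the band (degenerate but defined).
#'
#' @param records Escape-score records of skewed samples.
#' @param sheet Sample sheet.
#' @param calls Gene-tissue calls from [call_gene_tissue()] used to restrict
#'   to genes escaping somewhere; `NULL` computes them from `records`.
#' @param config An [xci_config()] list (`min_individuals`, `band_fraction`,
#'   `sd_type`, `exclude_tissues`).
#' @return A tibble: `gene_id`, `tissue`, `n_individuals`, `mean_escscore`,
#'   `sd_escscore`, `frac_within_band`, `label`.
#' @export
consistency_call <- function(records, sheet, calls = NULL,
                             config = xci_config()) {
  if (is.null(calls)) calls <- call_gene_tissue(records, sheet, config)
  escaping_genes <- unique(calls$gene_id[calls$status == "escapee"])

  df <- join_tissue(records, sheet)
  df$individual_id <- sheet$individual_id[match(df$sample_id,
                                                sheet$sample_id)]
  df <- df[!df$tissue %in% config$exclude_tissues &
             df$gene_id %in% escaping_genes, , drop = FALSE]

  per_ind <- df |>
    dplyr::group_by(.data$gene_id, .data$tissue, .data$individual_id) |>
    dplyr::summarise(score = stats::median(.data$escscore), .groups = "drop")

  sd_fun <- if (config$sd_type == "population") {
    function(x) sqrt(mean((x - mean(x))^2))
  } else {
    stats::sd
  }

  out <- per_ind |>
    dplyr::group_by(.data$gene_id, .data$tissue) |>
    dplyr::summarise(
      n_individuals = dplyr::n(),
      mean_escscore = mean(.data$score),
      sd_escscore = sd_fun(.data$score),
      frac_within_band = mean(abs(.data$score - mean(.data$score)) <=
                                sd_fun(.data$score)),
      .groups = "drop"
    )
  out$label <- ifelse(
    out$n_individuals < config$min_individuals, "no_call",
    ifelse(out$frac_within_band >= config$band_fraction,
           "consistent", "variable")
  )
  out
}

#' Rank-based test for score differences between groups
#'
#' Kruskal-Wallis test of per-gene escape scores grouped by tissue or cell
#' type (mid-ranks with the standard tie correction). Groups with fewer than
#' two values are excluded with a warning; fewer than two usable groups is
#' an error.
#'
#' @param scores Numeric scores.
#' @param groups Group labels, same length as `scores`.
#' @return A list: `statistic` (H), `df`, `p_value`, `groups_used`,
#'   `n_per_group`.
#' @export
#' @examples
#' group_difference_test(c(1, 2, 3, 10, 11, 12),
#'                       rep(c("a", "b"), each = 3))
group_difference_test <- function(scores, groups) {
  stopifnot(length(scores) == length(groups))
  keep <- !is.na(scores) & !is.na(groups)
  scores <- scores[keep]
  groups <- as.character(groups[keep])
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0) {
    warning("excluding group(s) with fewer than 2 values: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    scores <- scores[keep]
    groups <- groups[keep]
    sizes <- table(groups)
  }
  if (length(sizes) < 2L) {
    stop("need at least 2 groups with >= 2 values each", call. = FALSE)
  }
  kw <- stats::kruskal.test(scores, factor(groups))
  list(
    statistic = unname(kw$statistic),
    df = unname(kw$parameter),
    p_value = kw$p.value,
    groups_used = names(sizes),
    n_per_group = as.integer(sizes)
  )
}

#' Cell-type escape summary with co-twin averaging
#'
#' Summarises escape per cell type (sample-sheet tissue labels) for cohorts
#' of purified cell types sampled from co-twins: per gene and cell type, the
#' score is first taken per individual (median over that individual's
#' samples) and then averaged across the individuals with data — when both
#' co-twins contribute, the gene's cell-type score is the mean of the two;
#' when only one does, that score is used directly. Reports, per cell type,
#' the mean score over genes, the escape incidence (fraction of genes at or
#' above the cutoff), and the same restricted to genes with data in every
#' cell type.
#'
#' @param records Escape-score records of skewed cell-type samples (e.g.
#'   from [score_new_samples()]).
#' @param sheet Sample sheet whose `tissue` column holds cell-type labels.
#' @param config An [xci_config()] list (`escape_cutoff`).
#' @return A list with `gene_scores` (per gene and cell type) and
#'   `summary` (per cell type: `n_genes`, `mean_escscore`, `incidence`,
#'   plus `n_genes_complete`, `mean_escscore_complete`,
#'   `incidence_complete` over the all-cell-types gene subset).
#' @export
cell_type_escape_summary <- function(records, sheet,
                                     config = xci_config()) {
  df <- join_tissue(records, sheet)
  df$individual_id <- sheet$individual_id[match(df$sample_id,
                                                sheet$sample_id)]
  gene_scores <- df |>
    dplyr::group_by(.data$gene_id, .data$tissue, .data$individual_id) |>
    dplyr::summarise(score = stats::median(.data$escscore),
                     .groups = "drop") |>
    dplyr::group_by(.data$gene_id, .data$tissue) |>
    dplyr::summarise(n_individuals = dplyr::n(),
                     score = mean(.data$score), .groups = "drop")

  n_types <- length(unique(gene_scores$tissue))
  complete_genes <- gene_scores |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n == n_types) |>
    dplyr::pull(.data$gene_id)

  summarise_types <- function(d) {
    d |>
      dplyr::group_by(.data$tissue) |>
      dplyr::summarise(
        n_genes = dplyr::n(),
        mean_escscore = mean(.data$score),
        incidence = mean(.data$score >= config$escape_cutoff),
        .groups = "drop"
      )
  }
  all_summary <- summarise_types(gene_scores)
  complete_summary <- summarise_types(
    gene_scores[gene_scores$gene_id %in% complete_genes, , drop = FALSE]
  )
  names(complete_summary)[-1] <- paste0(names(complete_summary)[-1],
                                        "_complete")
  list(
    gene_scores = gene_scores,
    summary = dplyr::left_join(all_summary, complete_summary, by = "tissue")
  )
}
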