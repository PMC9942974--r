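#' Correlation between co-twin escape-score vectors
#'
#' Correlates two co-twins' per-gene escape scores over their shared genes.
#' With fewer than `min_genes` shared genes the pair is flagged invalid and
#' the correlation left undefined (no error). Symmetric in co-twin order.
#'
#' @param scores_twin1,scores_twin2 Named numeric vectors of per-gene scores
#'   (names are gene identifiers).
#' @param min_genes Minimum number of shared genes for a valid correlation,
#'   default 5.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A list: `n_genes`, `rho`, `valid`.
#' @export
#' @examples
#' s <- stats::setNames(seq(0, 1, length.out = 10), paste0("G", 1:10))
#' pair_correlation(s, s)
pair_correlation <- function(scores_twin1, scores_twin2, min_genes = 5,
                             method = c("spearman", "pearson")) {
  method <- match.arg(method)
  shared <- intersect(names(scores_twin1), names(scores_twin2))
  n <- length(shared)
  if (n < min_genes) {
    return(list(n_genes = n, rho = NA_real_, valid = FALSE))
  }
  rho <- stats::cor(scores_twin1[shared], scores_twin2[shared],
                    method = method)
  list(n_genes = n, rho = unname(rho), valid = TRUE)
}

#' Fraction of genes with discordant XCI between co-twins
#'
#' Among genes with an escape/silenced call in both co-twins, the fraction
#' called escapee in exactly one of the two (discordant XCI). Symmetric in
#' co-twin order.
#'
#' @param calls_twin1,calls_twin2 Logical vectors (TRUE = escapee) aligned
#'   on the same genes.
#' @return Fraction in `[0, 1]`; `NA` when no genes are jointly called.
#' @export
#' @examples
#' discordance_rate(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
discordance_rate <- function(calls_twin1, calls_twin2) {
  stopifnot(length(calls_twin1) == length(calls_twin2))
  keep <- !is.na(calls_twin1) & !is.na(calls_twin2)
  if (!any(keep)) {
    warning("no genes jointly called in both co-twins")
    return(NA_real_)
  }
  mean(xor(calls_twin1[keep], calls_twin2[keep]))
}

#' Per-pair twin concordance statistics
#'
#' For each complete twin pair — both co-twins with at least one scored
#' (skewed) sample in the analysis tissue — computes the correlation of
#' co-twin escape-score vectors over shared genes and the discordance rate
#' of escape calls at the configured cutoff. Per co-twin, a gene's score is
#' the median over that co-twin's skewed samples of the tissue.
#'
#' @param records Escape-score records of skewed samples.
#' @param sheet Sample sheet with twin structure.
#' @param config An [xci_config()] list (`twin_tissue`, `min_shared_genes`,
#'   `cor_method`, `escape_cutoff`).
#' @return A tibble: `pair_id`, `zygosity`, `n_genes`, `rho`,
#'   `discordance_rate`, `valid`.
#' @export
twin_pair_stats <- function(records, sheet, config = xci_config()) {
  df <- join_tissue(records, sheet)
  meta_cols <- c("individual_id", "twin_pair_id", "zygosity")
  idx <- match(df$sample_id, sheet$sample_id)
  for (col in meta_cols) df[[col]] <- sheet[[col]][idx]
  df <- df[df$tissue == config$twin_tissue & !is.na(df$twin_pair_id), ,
           drop = FALSE]

  per_ind <- df |>
    dplyr::group_by(.data$twin_pair_id, .data$zygosity,
                    .data$individual_id, .data$gene_id) |>
    dplyr::summarise(score = stats::median(.data$escscore),
                     .groups = "drop")

  pairs <- per_ind |>
    dplyr::distinct(.data$twin_pair_id, .data$zygosity,
                    .data$individual_id) |>
    dplyr::count(.data$twin_pair_id, .data$zygosity, name = "n_twins") |>
    dplyr::filter(.data$n_twins == 2L)

  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pid <- pairs$twin_pair_id[i]
    sub <- per_ind[per_ind$twin_pair_id == pid, , drop = FALSE]
    inds <- sort(unique(sub$individual_id))
    v1 <- stats::setNames(sub$score[sub$individual_id == inds[1]],
                          sub$gene_id[sub$individual_id == inds[1]])
    v2 <- stats::setNames(sub$score[sub$individual_id == inds[2]],
                          sub$gene_id[sub$individual_id == inds[2]])
    pc <- pair_correlation(v1, v2, config$min_shared_genes,
                           config$cor_method)
    shared <- intersect(names(v1), names(v2))
    disc <- if (length(shared) > 0) {
      discordance_rate(v1[shared] >= config$escape_cutoff,
                       v2[shared] >= config$escape_cutoff)
    } else {
      NA_real_
    }
    tibble::tibble(
      pair_id = pid, zygosity = pairs$zygosity[i],
      n_genes = pc$n_genes, rho = pc$rho,
      discordance_rate = disc, valid = pc$valid
    )
  })
  dplyr::bind_rows(rows)
}

#' Compare twin concordance between zygosity groups
#'
#' Over valid pairs, reports group means of the co-twin correlation and of
#' the discordance rate for monozygotic (MZ) and dizygotic (DZ) pairs, and a
#' Welch two-sample t-test on the per-pair correlation coefficients
#' (optionally Fisher-z transformed). A group with fewer than two valid
#' pairs leaves the test unavailable while the means are still reported.
#'
#' @param pair_stats Output of [twin_pair_stats()].
#' @param fisher_z If `TRUE`, t-test on `atanh(rho)`.
#' @return A list: `n_mz`, `n_dz`, `mean_rho_mz`, `mean_rho_dz`,
#'   `mean_disc_mz`, `mean_disc_dz`, `t_statistic`, `p_value`.
#' @export
zygosity_compare <- function(pair_stats, fisher_z = FALSE) {
  valid <- pair_stats[pair_stats$valid, , drop = FALSE]
  mz <- valid[valid$zygosity == "MZ", , drop = FALSE]
  dz <- valid[valid$zygosity == "DZ", , drop = FALSE]

  mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x, na.rm = TRUE)
  out <- list(
    n_mz = nrow(mz), n_dz = nrow(dz),
    mean_rho_mz = mean_or_na(mz$rho),
    mean_rho_dz = mean_or_na(dz$rho),
    mean_disc_mz = mean_or_na(mz$discordance_rate),
    mean_disc_dz = mean_or_na(dz$discordance_rate),
    t_statistic = NA_real_, p_value = NA_real_
  )
  if (nrow(mz) >= 2L && nrow(dz) >= 2L) {
    x <- mz$rho
    y <- dz$rho
    if (fisher_z) {
      x <- atanh(pmin(pmax(x, -1 + 1e-12), 1 - 1e-12))
      y <- atanh(pmin(pmax(y, -1 + 1e-12), 1 - 1e-12))
    }
    if (stats::var(x) + stats::var(y) > 0) {
      tt <- stats::t.test(x, y)
      out$t_statistic <- unname(tt$statistic)
      out$p_value <- tt$p.value
    } else {
      out$t_statistic <- 0
      out$p_value <- 1
    }
  }
  out
}
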