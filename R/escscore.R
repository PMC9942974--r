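#' Fit the pooled escape model of allelic fold change on skew
#'
#' Across all skewed samples of the cohort (all tissues, including any later
#' excluded from escape calls), fits an ordinary least squares line with the
#' sample's degree of skewing (DS) as explanatory variable and the gene-level
#' allelic fold changes as response. Raw allelic fold changes correlate
#' negatively with DS (the more skewed a sample, the lower the expected
#' allelic balance of a silenced gene), which would bias escape measurements
#' across samples; the model residual — the escape score — removes that
#' dependence, and is min-max rescaled over the fitting set to `[0, 1]`
#' (0 complete silencing, 1 full escape). By OLS orthogonality the rescaled
#' scores are uncorrelated with DS.
#'
#' The XIST record is excluded from the fit: it is the skew instrument
#' itself, expressed only from the inactive X, and scoring it against its own
#' skew estimate would be circular.
#'
#' @param observations Output of [apply_qc()]; only retained observations of
#'   skewed samples enter the fit.
#' @param skew_calls Output of [call_skew()].
#' @param config An [xci_config()] list. `rescale_quantiles`, if set,
#'   replaces the raw residual extremes with quantiles before rescaling.
#' @return A list with elements `model` (an `"escape_model"`: `intercept`,
#'   `slope`, `n_obs`, `resid_min`, `resid_max`) and `records` (a tibble of
#'   escape-score records: `gene_id`, `sample_id`, `afc`, `ds`, `residual`,
#'   `escscore`, `clamped`).
#' @export
fit_escape_model <- function(observations, skew_calls,
                             config = xci_config()) {
  fit_set <- escape_fit_frame(observations, skew_calls, config)
  if (nrow(fit_set) < 2L) {
    stop("insufficient observations to fit the escape model", call. = FALSE)
  }
  if (length(unique(fit_set$ds)) < 2L) {
    stop("degenerate design: all DS values identical", call. = FALSE)
  }

  fit <- stats::lm(afc ~ ds, data = fit_set)
  coefs <- stats::coef(fit)
  residual <- unname(stats::resid(fit))

  if (is.null(config$rescale_quantiles)) {
    r_min <- min(residual)
    r_max <- max(residual)
  } else {
    qq <- stats::quantile(residual, config$rescale_quantiles, names = FALSE)
    r_min <- qq[1]
    r_max <- qq[2]
  }
  if (r_max - r_min < 1e-12) {
    stop("degenerate rescale: all residuals identical", call. = FALSE)
  }

  model <- structure(
    list(intercept = unname(coefs[1]), slope = unname(coefs[2]),
         n_obs = nrow(fit_set), resid_min = r_min, resid_max = r_max),
    class = "escape_model"
  )

  scaled <- rescale_minmax(residual, r_min, r_max)
  records <- tibble::tibble(
    gene_id = fit_set$gene_id,
    sample_id = fit_set$sample_id,
    afc = fit_set$afc,
    ds = fit_set$ds,
    residual = residual,
    escscore = scaled$score,
    clamped = scaled$clamped
  )
  list(model = model, records = records)
}

escape_fit_frame <- function(observations, skew_calls, config) {
  skewed <- skew_calls[skew_calls$status == "skewed", c("sample_id", "ds")]
  obs <- observations[observations$retained &
                        observations$gene_id != config$xist_gene, ,
                      drop = FALSE]
  dplyr::inner_join(obs[c("gene_id", "sample_id", "afc")], skewed,
                    by = "sample_id")
}

#' @export
print.escape_model <- function(x, ...) {
  cat("<escape_model>\n")
  cat(sprintf("  aFC = %.4f %+.4f * DS   (n = %d observations)\n",
              x$intercept, x$slope, x$n_obs))
  cat(sprintf("  residual range used for rescaling: [%.4f, %.4f]\n",
              x$resid_min, x$resid_max))
  invisible(x)
}

#' Min-max rescale residuals to the unit interval
#'
#' Affine map sending the minimum residual of the fitting set to 0 and the
#' maximum to 1, `(x - min) / (max - min)`; order preserving. Values scored
#' against stored extremes (new samples) may fall outside `[0, 1]` and are
#' clipped, with the `clamped` flag recording where clipping occurred.
#'
#' @param residuals Numeric residuals.
#' @param r_min,r_max Rescaling extremes; default the range of `residuals`.
#' @return A list with `score` (in `[0, 1]`) and logical `clamped`.
#' @export
#' @examples
#' rescale_minmax(c(-0.2, 0, 0.2))$score  # 0, 0.5, 1
rescale_minmax <- function(residuals, r_min = min(residuals),
                           r_max = max(residuals)) {
  if (r_max <= r_min) {
    stop("degenerate rescale: max residual must exceed min", call. = FALSE)
  }
  raw <- (residuals - r_min) / (r_max - r_min)
  # tolerance absorbs float noise when re-deriving residuals of the fitting
  # set from the stored line, so boundary records are not flagged
  clamped <- raw < -1e-9 | raw > 1 + 1e-9
  list(score = pmin(pmax(raw, 0), 1), clamped = clamped)
}

#' Score observations against a fitted escape model
#'
#' Computes residuals of new skewed observations against the stored
#' regression line and rescales them with the stored residual extremes,
#' clipping to `[0, 1]`. Used to score samples outside the fitting cohort
#' (e.g. purified immune cell types) on the same scale. Observations from
#' samples whose skew status is not `"skewed"` are skipped with a message.
#'
#' @param model An `"escape_model"` from [fit_escape_model()].
#' @param observations Output of [apply_qc()] for the new samples.
#' @param skew_calls Output of [call_skew()] for the new samples.
#' @param config An [xci_config()] list.
#' @return A tibble of escape-score records with the same columns as the
#'   fitting records.
#' @export
score_new_samples <- function(model, observations, skew_calls,
                              config = xci_config()) {
  stopifnot(inherits(model, "escape_model"))
  n_eligible <- sum(observations$retained &
                      observations$gene_id != config$xist_gene)
  fit_set <- escape_fit_frame(observations, skew_calls, config)
  n_skipped <- n_eligible - nrow(fit_set)
  if (n_skipped > 0) {
    message(n_skipped,
            " retained observation(s) skipped: sample not skewed or skew unavailable")
  }
  if (nrow(fit_set) == 0L) {
    return(tibble::tibble(
      gene_id = character(), sample_id = character(), afc = numeric(),
      ds = numeric(), residual = numeric(), escscore = numeric(),
      clamped = logical()
    ))
  }
  residual <- fit_set$afc - (model$intercept + model$slope * fit_set$ds)
  scaled <- rescale_minmax(residual, model$resid_min, model$resid_max)
  tibble::tibble(
    gene_id = fit_set$gene_id,
    sample_id = fit_set$sample_id,
    afc = fit_set$afc,
    ds = fit_set$ds,
    residual = residual,
    escscore = scaled$score,
    clamped = scaled$clamped
  )
}

#' Call per-gene per-tissue escape status
#'
#' For each gene and tissue, takes the median escape score across the skewed
#' samples of that tissue; genes with fewer than `min_tissue_samples`
#' (default 3) contributing samples are `no_call`, otherwise the gene is an
#' `escapee` in the tissue when the median reaches the escape cutoff
#' (default 0.36, boundary inclusive) and `silenced` below it. Tissues on
#' the configuration's exclusion list (default whole-blood) are omitted:
#' their samples support the model fit but not escape calls. Medians pool
#' all skewed samples of a tissue, including multiple samples per individual
#' and both co-twins.
#'
#' @param records Escape-score records ([fit_escape_model()] or
#'   [score_new_samples()]).
#' @param sheet Sample sheet mapping samples to tissues.
#' @param config An [xci_config()] list.
#' @return A tibble: `gene_id`, `tissue`, `n_samples`, `median_escscore`,
#'   `status`; per-tissue escape incidence is attached as attribute
#'   `"incidence"` (escapees / called genes).
#' @export
call_gene_tissue <- function(records, sheet, config = xci_config()) {
  df <- join_tissue(records, sheet)
  df <- df[!df$tissue %in% config$exclude_tissues, , drop = FALSE]
  calls <- df |>
    dplyr::group_by(.data$gene_id, .data$tissue) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      median_escscore = stats::median(.data$escscore),
      .groups = "drop"
    )
  calls$status <- ifelse(
    calls$n_samples < config$min_tissue_samples, "no_call",
    ifelse(calls$median_escscore >= config$escape_cutoff,
           "escapee", "silenced")
  )
  called <- calls[calls$status != "no_call", , drop = FALSE]
  incidence <- called |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(
      n_called = dplyr::n(),
      n_escapees = sum(.data$status == "escapee"),
      incidence = .data$n_escapees / .data$n_called,
      .groups = "drop"
    )
  attr(calls, "incidence") <- incidence
  calls
}

join_tissue <- function(records, sheet) {
  tissue <- sheet$tissue[match(records$sample_id, sheet$sample_id)]
  if (anyNA(tissue)) {
    stop("records name sample(s) absent from the sample sheet", call. = FALSE)
  }
  dplyr::mutate(records, tissue = tissue)
}

#' Benchmark escape cutoffs against a reference annotation
#'
#' For each candidate cutoff, recomputes gene-level escape calls (a gene is
#' an escapee if called escapee in at least one analysed tissue, silenced if
#' called in at least one tissue and never escapee) and tabulates agreement
#' with a reference annotation. Only genes with an unambiguous prior status
#' (`silenced` or `escape`) count; `variable` and `discordant_unknown` genes
#' are excluded from the concordance.
#'
#' @param records Escape-score records.
#' @param sheet Sample sheet.
#' @param annotation Reference annotation (see
#'   [read_reference_annotation()]).
#' @param config An [xci_config()] list; `benchmark_cutoffs` is the grid.
#' @return A tibble: `cutoff`, `n_concordant`, `n_discordant`, `concordance`.
#' @export
benchmark_thresholds <- function(records, sheet, annotation,
                                 config = xci_config()) {
  prior <- annotation[annotation$prior_status %in% c("silenced", "escape"), ,
                      drop = FALSE]
  rows <- lapply(config$benchmark_cutoffs, function(cutoff) {
    cfg <- config
    cfg$escape_cutoff <- cutoff
    calls <- call_gene_tissue(records, sheet, cfg)
    gene_status <- gene_level_status(calls)
    merged <- dplyr::inner_join(gene_status, prior, by = "gene_id")
    if (nrow(merged) == 0L) {
      return(tibble::tibble(cutoff = cutoff, n_concordant = 0L,
                            n_discordant = 0L, concordance = NA_real_))
    }
    concordant <- (merged$call == "escapee" & merged$prior_status == "escape") |
      (merged$call == "silenced" & merged$prior_status == "silenced")
    tibble::tibble(
      cutoff = cutoff,
      n_concordant = sum(concordant),
      n_discordant = sum(!concordant),
      concordance = mean(concordant)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (all(out$n_concordant + out$n_discordant == 0L)) {
    warning("no overlap between called genes and the reference annotation")
  }
  out
}

gene_level_status <- function(calls) {
  called <- calls[calls$status != "no_call", , drop = FALSE]
  called |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      call = ifelse(any(.data$status == "escapee"), "escapee", "silenced"),
      .groups = "drop"
    )
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between a called escapee set and a reference escapee set drawn
#' from a common gene universe.
#'
#' @param called,reference Character vectors of gene identifiers; both must
#'   be subsets of `universe`.
#' @param universe Character vector: all genes that could have been called.
#' @return A list: `overlap`, `n_called`, `n_reference`, `n_universe`,
#'   `p_value`.
#' @export
#' @examples
#' overlap_test(c("A", "B"), c("B", "C"), LETTERS[1:10])
overlap_test <- function(called, reference, universe) {
  universe <- unique(universe)
  called <- unique(called)
  reference <- unique(reference)
  if (length(universe) == 0L) {
    stop("empty gene universe", call. = FALSE)
  }
  if (!all(called %in% universe) || !all(reference %in% universe)) {
    stop("called and reference sets must be subsets of the universe",
         call. = FALSE)
  }
  k <- length(intersect(called, reference))
  # P(X >= k) for X ~ Hypergeometric(|reference| white, rest black, draw |called|)
  p <- stats::phyper(k - 1, length(reference),
                     length(universe) - length(reference),
                     length(called), lower.tail = FALSE)
  list(overlap = k, n_called = length(called),
       n_reference = length(reference), n_universe = length(universe),
       p_value = p)
}

#' Write / read a fitted escape model as plain text
#'
#' Persists the five numbers defining an escape model (`intercept`, `slope`,
#' `n_obs`, `resid_min`, `resid_max`) as `key<TAB>value` lines with full
#' precision, so that out-of-cohort samples can be scored later on the
#' identical scale.
#'
#' @param model An `"escape_model"`.
#' @param path File path.
#' @return `write_escape_model()`: the model, invisibly;
#'   `read_escape_model()`: the model.
#' @export
write_escape_model <- function(model, path) {
  stopifnot(inherits(model, "escape_model"))
  lines <- sprintf("%s\t%s", names(model),
                   vapply(model, function(v) format(v, digits = 17),
                          character(1)))
  writeLines(lines, path)
  invisible(model)
}

#' @rdname write_escape_model
#' @export
read_escape_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  vals <- stats::setNames(
    lapply(parts, function(p) as.numeric(p[2])),
    vapply(parts, `[[`, character(1), 1)
  )
  required <- c("intercept", "slope", "n_obs", "resid_min", "resid_max")
  if (!all(required %in% names(vals))) {
    stop(path, ": incomplete escape model file", call. = FALSE)
  }
  vals$n_obs <- as.integer(vals$n_obs)
  structure(vals[required], class = "escape_model")
}
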