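#' Simulation configuration
#'
#' Parameters of the generative model behind [simulate_dataset()]. A bulk
#' RNA-seq sample is modelled as a mosaic of cells in which either the
#' haplotype-A or the haplotype-B X is active; `p` is the fraction of cells
#' with haplotype A active. A gene with inactive-to-active expression ratio
#' (escape ratio) `e` then shows an expected haplotype-A read fraction of
#' `(p + (1 - p) e) / (1 + e)`, while the XIST record — expressed exclusively
#' from the inactive X — shows expected haplotype-A fraction `1 - p`.
#'
#' Escape ratios are organised hierarchically on the logit scale: a per-gene
#' baseline drawn from a class-specific distribution (silenced genes
#' concentrated near 0; escape genes on roughly 0.3–0.8, matching the
#' observation that tissue-level escape ratios rarely exceed 0.8; variable
#' genes wide), a gene-by-tissue effect shared across individuals, and a
#' gene-by-individual perturbation of which a fraction `heritability_weight`
#' of the variance is genetic — shared exactly between monozygotic co-twins
#' and with correlation 1/2 between dizygotic co-twins.
#'
#' @param n_genes Number of X-linked genes (excluding the XIST record).
#' @param class_fractions Named proportions (summing to 1) of gene classes
#'   `silenced`, `escape`, `variable`.
#' @param n_mz_pairs,n_dz_pairs,n_singletons Twin structure of the cohort.
#' @param tissues Character vector of tissue/cell-type labels.
#' @param tissue_availability Per-tissue probability that an individual
#'   contributes a sample of that tissue (recycled to `length(tissues)`).
#' @param heritability_weight Fraction of the gene-by-individual logit
#'   variance that is genetic, in `[0, 1]`.
#' @param individual_sd Total standard deviation of the gene-by-individual
#'   logit perturbation. The default of 1.75 places the simulated co-twin
#'   score correlations in the regime reported for adult twin cohorts
#'   (monozygotic about 0.6, dizygotic about 0.45 at the default
#'   heritability weight).
#' @param tissue_effect_sd Standard deviation of the gene-by-tissue logit
#'   effect (shared across individuals).
#' @param variable_sd_factor Multiplier applied to both perturbation sds for
#'   genes of the `variable` class.
#' @param skew_extreme_prob Mixture weight of the near-extreme skew
#'   component; with the default shapes this yields roughly a quarter of
#'   samples skewed, in line with the 14–32% per-tissue skew rates seen in
#'   adult cohorts.
#' @param skew_extreme_shape,skew_central_shape Shape parameters `a` of the
#'   symmetric `Beta(a, a)` skew components (extreme: U-shaped mass near 0
#'   and 1; central: mass near 0.5).
#' @param skew_by_individual If `TRUE`, one skew fraction is drawn per
#'   individual and shared across that individual's tissues; default draws
#'   skew independently per sample.
#' @param het_prob Probability that a gene is heterozygous (hence measurable)
#'   in an individual. The XIST record is always measurable so that skew can
#'   be called.
#' @param depth_mean,depth_size Negative-binomial mean and size (dispersion)
#'   of total allelic read depth per gene-sample.
#' @param allelic_overdispersion Beta-binomial intra-class correlation of the
#'   allelic draw; 0 (default) gives a pure binomial.
#' @param xist_gene Identifier given to the XIST record.
#' @param seed Integer seed; every random draw of [simulate_dataset()] flows
#'   from it.
#'
#' @return A list of class `"simulation_config"`.
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 50, n_singletons = 10,
#'                          n_mz_pairs = 2, n_dz_pairs = 2, seed = 7)
simulation_config <- function(n_genes = 200,
                              class_fractions = c(silenced = 0.75,
                                                  escape = 0.15,
                                                  variable = 0.10),
                              n_mz_pairs = 17,
                              n_dz_pairs = 10,
                              n_singletons = 46,
                              tissues = c("LCL", "adipose", "skin"),
                              tissue_availability = c(1, 0.8, 0.8),
                              heritability_weight = 0.6,
                              individual_sd = 1.75,
                              tissue_effect_sd = 0.4,
                              variable_sd_factor = 3,
                              skew_extreme_prob = 0.3,
                              skew_extreme_shape = 0.35,
                              skew_central_shape = 8,
                              skew_by_individual = FALSE,
                              het_prob = 0.7,
                              depth_mean = 50,
                              depth_size = 5,
                              allelic_overdispersion = 0,
                              xist_gene = "XIST",
                              seed = 1L) {
  stopifnot(
    n_genes >= 1, n_mz_pairs >= 0, n_dz_pairs >= 0, n_singletons >= 0,
    n_mz_pairs + n_dz_pairs + n_singletons >= 1,
    length(tissues) >= 1,
    heritability_weight >= 0, heritability_weight <= 1,
    individual_sd >= 0, tissue_effect_sd >= 0, variable_sd_factor > 0,
    skew_extreme_prob >= 0, skew_extreme_prob <= 1,
    skew_extreme_shape > 0, skew_central_shape > 0,
    het_prob > 0, het_prob <= 1,
    depth_mean > 0, depth_size > 0,
    allelic_overdispersion >= 0, allelic_overdispersion < 1,
    is.logical(skew_by_individual)
  )
  if (length(class_fractions) != 3L ||
      !setequal(names(class_fractions), c("silenced", "escape", "variable"))) {
    stop("class_fractions must be named silenced, escape, variable",
         call. = FALSE)
  }
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-8) {
    stop("class_fractions must be non-negative and sum to 1", call. = FALSE)
  }
  tissue_availability <- rep_len(tissue_availability, length(tissues))
  if (any(tissue_availability < 0) || any(tissue_availability > 1)) {
    stop("tissue_availability must lie in [0, 1]", call. = FALSE)
  }

  structure(
    list(
      n_genes = as.integer(n_genes),
      class_fractions = class_fractions[c("silenced", "escape", "variable")],
      n_mz_pairs = as.integer(n_mz_pairs),
      n_dz_pairs = as.integer(n_dz_pairs),
      n_singletons = as.integer(n_singletons),
      tissues = tissues,
      tissue_availability = stats::setNames(tissue_availability, tissues),
      heritability_weight = heritability_weight,
      individual_sd = individual_sd,
      tissue_effect_sd = tissue_effect_sd,
      variable_sd_factor = variable_sd_factor,
      skew_extreme_prob = skew_extreme_prob,
      skew_extreme_shape = skew_extreme_shape,
      skew_central_shape = skew_central_shape,
      skew_by_individual = skew_by_individual,
      het_prob = het_prob,
      depth_mean = depth_mean,
      depth_size = depth_size,
      allelic_overdispersion = allelic_overdispersion,
      xist_gene = xist_gene,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Expected allelic fold change of the mosaic model
#'
#' Closed-form, noise-free allelic fold change of a gene with escape ratio
#' `e` in a bulk sample in which a fraction `p` of cells have haplotype A
#' active. Haplotype-A expression is proportional to `p + (1 - p) e`,
#' haplotype-B expression to `(1 - p) + p e`; the allelic fold change is the
#' smaller divided by the larger, so the inactive-X haplotype is taken as the
#' lower-expressed one.
#'
#' @param p Fraction of cells with haplotype A active, in `[0, 1]`.
#' @param e Escape ratio (inactive/active expression), in `[0, 1]`.
#' @return Expected allelic fold change in `[0, 1]`. Vectorised over `p`
#'   and `e`.
#' @export
#' @examples
#' expected_afc(1, 0.4)    # fully skewed sample: aFC equals e
#' expected_afc(0.5, 0.7)  # balanced mosaic hides escape: aFC = 1
#' expected_afc(0.9, 0)    # silenced gene under 90:10 skew: 1/9
expected_afc <- function(p, e) {
  stopifnot(all(p >= 0 & p <= 1), all(e >= 0 & e <= 1))
  m_a <- p + (1 - p) * e
  m_b <- (1 - p) + p * e
  pmin(m_a, m_b) / pmax(m_a, m_b)
}

#' Simulate an allelic count dataset with ground truth
#'
#' Draws a cohort of twins and singletons, per-sample XCI skew fractions,
#' per gene-tissue-individual escape ratios, and gene-level haplotype read
#' counts under the mosaic model described in [simulation_config()]. Total
#' depth per gene-sample is negative-binomial; the haplotype-A count is
#' binomial (beta-binomial if `allelic_overdispersion > 0`) around the
#' mosaic's expected haplotype-A fraction. The XIST record is drawn with
#' expected haplotype-A fraction `1 - p`, i.e. exclusively from the inactive
#' X. Genes that happen to show reads on only one haplotype arise naturally
#' and are left in place so that QC filters are exercised.
#'
#' @param config A [simulation_config()] list.
#' @return A list with elements
#'   \describe{
#'     \item{counts}{count table (`gene_id`, `sample_id`, `hapA_count`,
#'       `hapB_count`).}
#'     \item{sheet}{sample sheet with twin structure.}
#'     \item{truth}{ground truth: `genes` (class and baseline escape ratio),
#'       `escape` (true `e` per gene, tissue, individual), `samples` (true
#'       active-hapA fraction `p` per sample).}
#'     \item{annotation}{reference-annotation table derived from the true
#'       gene classes (a synthetic stand-in for a published XCI catalogue).}
#'   }
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(n_genes = 30, n_mz_pairs = 2,
#'   n_dz_pairs = 2, n_singletons = 6, seed = 42))
#' head(sim$counts)
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  # --- cohort ---------------------------------------------------------------
  n_ind <- 2L * cfg$n_mz_pairs + 2L * cfg$n_dz_pairs + cfg$n_singletons
  individual_id <- sprintf("I%03d", seq_len(n_ind))
  pair_id <- rep(NA_character_, n_ind)
  zygosity <- rep("unknown", n_ind)
  idx <- 1L
  pair_counter <- 1L
  add_pairs <- function(n, zyg) {
    for (k in seq_len(n)) {
      pair_id[idx:(idx + 1L)] <<- sprintf("P%02d", pair_counter)
      zygosity[idx:(idx + 1L)] <<- zyg
      idx <<- idx + 2L
      pair_counter <<- pair_counter + 1L
    }
  }
  add_pairs(cfg$n_mz_pairs, "MZ")
  add_pairs(cfg$n_dz_pairs, "DZ")

  individuals <- tibble::tibble(
    individual_id = individual_id,
    twin_pair_id = pair_id,
    zygosity = zygosity
  )

  # --- samples --------------------------------------------------------------
  avail <- matrix(
    stats::runif(n_ind * length(cfg$tissues)) <
      rep(cfg$tissue_availability, each = n_ind),
    nrow = n_ind
  )
  # every individual contributes at least one sample (first tissue)
  none <- rowSums(avail) == 0L
  avail[none, 1L] <- TRUE
  sheet <- tidyr::expand_grid(
    individual_id = individual_id,
    tissue = cfg$tissues
  )
  sheet <- sheet[as.vector(t(avail)), , drop = FALSE]
  sheet$sample_id <- paste(sheet$individual_id, sheet$tissue, sep = "_")
  sheet <- dplyr::left_join(sheet, individuals, by = "individual_id")
  sheet <- sheet[c("sample_id", "individual_id", "tissue",
                   "twin_pair_id", "zygosity")]

  # --- skew fractions -------------------------------------------------------
  draw_skew <- function(n) {
    extreme <- stats::runif(n) < cfg$skew_extreme_prob
    p <- numeric(n)
    p[extreme] <- stats::rbeta(sum(extreme), cfg$skew_extreme_shape,
                               cfg$skew_extreme_shape)
    p[!extreme] <- stats::rbeta(sum(!extreme), cfg$skew_central_shape,
                                cfg$skew_central_shape)
    p
  }
  if (cfg$skew_by_individual) {
    p_ind <- stats::setNames(draw_skew(n_ind), individual_id)
    sheet_p <- p_ind[sheet$individual_id]
  } else {
    sheet_p <- draw_skew(nrow(sheet))
  }
  sample_truth <- tibble::tibble(sample_id = sheet$sample_id, p = sheet_p)

  # --- gene classes and escape ratios --------------------------------------
  n_g <- cfg$n_genes
  gene_id <- sprintf("GENE%04d", seq_len(n_g))
  n_per_class <- round(n_g * cfg$class_fractions)
  n_per_class["silenced"] <- n_g - n_per_class["escape"] - n_per_class["variable"]
  class <- rep(names(n_per_class), times = n_per_class)

  e0 <- numeric(n_g)
  is_sil <- class == "silenced"
  is_esc <- class == "escape"
  is_var <- class == "variable"
  e0[is_sil] <- stats::rbeta(sum(is_sil), 0.6, 12)          # mass near 0
  e0[is_esc] <- 0.3 + 0.5 * stats::rbeta(sum(is_esc), 2, 2.5) # 0.3-0.8
  e0[is_var] <- 0.8 * stats::rbeta(sum(is_var), 1.5, 3)      # wide

  genes <- tibble::tibble(gene_id = gene_id, class = class, e0 = e0)

  sd_fac <- ifelse(is_var, cfg$variable_sd_factor, 1)

  # gene x tissue effects, shared across individuals
  n_t <- length(cfg$tissues)
  delta_gt <- matrix(stats::rnorm(n_g * n_t, sd = cfg$tissue_effect_sd),
                     nrow = n_g) * sd_fac

  # gene x individual perturbation: genetic + environmental on the logit scale
  h <- cfg$heritability_weight
  genetic <- matrix(stats::rnorm(n_g * n_ind), nrow = n_g)
  # twin sharing of the genetic component
  if (cfg$n_mz_pairs + cfg$n_dz_pairs > 0) {
    for (pid in unique(stats::na.omit(individuals$twin_pair_id))) {
      cols <- which(individuals$twin_pair_id == pid)
      if (individuals$zygosity[cols[1]] == "MZ") {
        genetic[, cols[2]] <- genetic[, cols[1]]
      } else {
        genetic[, cols[2]] <- sqrt(0.5) * genetic[, cols[1]] +
          sqrt(0.5) * genetic[, cols[2]]
      }
    }
  }
  environ <- matrix(stats::rnorm(n_g * n_ind), nrow = n_g)
  z_gi <- cfg$individual_sd * (sqrt(h) * genetic + sqrt(1 - h) * environ) *
    sd_fac

  # assemble true e per gene x tissue x individual (bounded in [0, 1))
  eta0 <- stats::qlogis(pmin(pmax(e0, 1e-6), 1 - 1e-6))
  escape_truth <- tidyr::expand_grid(
    gene_idx = seq_len(n_g),
    tissue_idx = seq_len(n_t),
    ind_idx = seq_len(n_ind)
  )
  escape_truth$e <- stats::plogis(
    eta0[escape_truth$gene_idx] +
      delta_gt[cbind(escape_truth$gene_idx, escape_truth$tissue_idx)] +
      z_gi[cbind(escape_truth$gene_idx, escape_truth$ind_idx)]
  )
  escape_truth <- tibble::tibble(
    gene_id = gene_id[escape_truth$gene_idx],
    tissue = cfg$tissues[escape_truth$tissue_idx],
    individual_id = individual_id[escape_truth$ind_idx],
    e = escape_truth$e
  )

  # --- heterozygosity (measurability) per gene x individual -----------------
  het <- matrix(stats::runif(n_g * n_ind) < cfg$het_prob, nrow = n_g)

  # --- counts ---------------------------------------------------------------
  obs <- dplyr::inner_join(
    dplyr::mutate(sheet[c("sample_id", "individual_id", "tissue")],
                  p = sheet_p),
    escape_truth,
    by = c("individual_id", "tissue")
  )
  gene_idx <- match(obs$gene_id, gene_id)
  ind_idx <- match(obs$individual_id, individual_id)
  obs <- obs[het[cbind(gene_idx, ind_idx)], , drop = FALSE]

  pi_a <- (obs$p + (1 - obs$p) * obs$e) / (1 + obs$e)
  counts <- draw_allelic_counts(pi_a, nrow(obs), cfg)
  gene_counts <- tibble::tibble(
    gene_id = obs$gene_id,
    sample_id = obs$sample_id,
    hapA_count = counts$a,
    hapB_count = counts$b
  )

  # XIST: always measurable, expected hapA fraction 1 - p
  xist_counts <- draw_allelic_counts(1 - sheet_p, nrow(sheet), cfg)
  xist_tbl <- tibble::tibble(
    gene_id = cfg$xist_gene,
    sample_id = sheet$sample_id,
    hapA_count = xist_counts$a,
    hapB_count = xist_counts$b
  )

  count_table <- dplyr::arrange(
    dplyr::bind_rows(xist_tbl, gene_counts),
    .data$sample_id, .data$gene_id
  )

  annotation <- tibble::tibble(
    gene_id = gene_id,
    prior_status = class,  # silenced / escape / variable
    par_flag = FALSE
  )

  list(
    counts = count_table,
    sheet = sheet,
    truth = list(genes = genes, escape = escape_truth, samples = sample_truth),
    annotation = annotation
  )
}

draw_allelic_counts <- function(pi_a, n, cfg) {
  depth <- stats::rnbinom(n, mu = cfg$depth_mean, size = cfg$depth_size)
  rho <- cfg$allelic_overdispersion
  if (rho > 0) {
    shape <- (1 - rho) / rho
    q <- stats::rbeta(n, pmax(pi_a * shape, 1e-12),
                      pmax((1 - pi_a) * shape, 1e-12))
  } else {
    q <- pi_a
  }
  a <- stats::rbinom(n, depth, q)
  list(a = as.integer(a), b = as.integer(depth - a))
}
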