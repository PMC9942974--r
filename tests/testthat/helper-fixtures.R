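# Shared fixture builders. Everything is constructed in code; tiny file
# fixtures are written to tempfiles on demand.

make_sheet <- function(sample_id, individual_id, tissue = "LCL",
                       twin_pair_id = NA_character_,
                       zygosity = NA_character_) {
  tibble::tibble(
    sample_id = sample_id,
    individual_id = individual_id,
    tissue = tissue,
    twin_pair_id = twin_pair_id,
    zygosity = zygosity
  )
}

make_counts <- function(gene_id, sample_id, a, b) {
  tibble::tibble(
    gene_id = gene_id, sample_id = sample_id,
    hapA_count = as.integer(a), hapB_count = as.integer(b)
  )
}

write_fixture <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

# Records table in the shape produced by fit_escape_model()$records,
# for direct testing of downstream calling logic.
make_records <- function(gene_id, sample_id, escscore, ds = 0.4) {
  tibble::tibble(
    gene_id = gene_id, sample_id = sample_id,
    afc = NA_real_, ds = ds, residual = NA_real_,
    escscore = escscore, clamped = FALSE
  )
}

# Small two-tissue cohort simulation used by several files; the elevated
# skew-mixture weight keeps enough skewed samples for model fitting at this
# cohort size.
small_sim <- function(seed = 7, ...) {
  simulate_dataset(simulation_config(
    n_genes = 60, n_mz_pairs = 3, n_dz_pairs = 2, n_singletons = 10,
    tissues = c("LCL", "adipose"), tissue_availability = 1,
    skew_extreme_prob = 0.6, seed = seed, ...
  ))
}

quiet_pipeline <- function(...) suppressMessages(run_pipeline(...))

# Exhaustive upper-tail hypergeometric probability by direct summation of
# the mass function (independent of stats::phyper).
hyper_tail_oracle <- function(overlap, n_called, n_reference, n_universe) {
  i <- overlap:min(n_called, n_reference)
  sum(choose(n_reference, i) * choose(n_universe - n_reference, n_called - i)) /
    choose(n_universe, n_called)
}

# Kruskal-Wallis H from the textbook rank-sum formula with tie correction,
# written out directly (independent of stats::kruskal.test).
kw_oracle <- function(scores, groups) {
  r <- rank(scores)
  n <- length(scores)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
  ties <- table(scores)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
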