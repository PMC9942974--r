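fit_small <- function(seed = 7) {
  sim <- small_sim(seed = seed)
  obs <- suppressMessages(apply_qc(sim$counts, sim$sheet))
  skew <- call_skew(obs, sim$sheet)
  list(sim = sim, obs = obs, skew = skew,
       fit = fit_escape_model(obs, skew))
}

test_that("min-max rescaling is the order-preserving affine map to [0, 1]", {
  r <- rescale_minmax(c(-0.2, 0, 0.2))
  expect_equal(r$score, c(0, 0.5, 1))
  expect_false(any(r$clamped))

  set.seed(1)
  x <- rnorm(50)
  s <- rescale_minmax(x)$score
  expect_equal(min(s), 0)
  expect_equal(max(s), 1)
  expect_identical(rank(s), rank(x))
  expect_error(rescale_minmax(rep(0.3, 4)), "degenerate rescale")
})

test_that("escape scores are uncorrelated with skew on the fitting set", {
  f <- fit_small()
  rec <- f$fit$records
  expect_lt(abs(stats::cor(rec$escscore, rec$ds)), 1e-10)
  # and the raw dependence the residualisation removes is negative
  expect_lt(f$fit$model$slope, 0)
  expect_lt(stats::cor(rec$afc, rec$ds), 0)
})

test_that("the fitted line matches an independent least-squares computation", {
  f <- fit_small()
  rec <- f$fit$records
  # closed-form simple regression oracle from sums, not lm()
  x <- rec$ds; y <- rec$afc
  slope <- (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2)
  intercept <- mean(y) - slope * mean(x)
  expect_equal(f$fit$model$slope, slope, tolerance = 1e-10)
  expect_equal(f$fit$model$intercept, intercept, tolerance = 1e-10)
  expect_equal(rec$residual, y - (intercept + slope * x), tolerance = 1e-10)
})

test_that("degenerate fitting sets raise the documented errors", {
  obs <- tibble::tibble(
    gene_id = c("G1", "G2", "G1", "G2"),
    sample_id = c("S1", "S1", "S2", "S2"),
    ac = 10L, bc = 5L, tc = 15L, ase = 2 / 3, afc = 0.5,
    qc_depth = TRUE, qc_both_haps = TRUE, retained = TRUE
  )
  same_ds <- tibble::tibble(sample_id = c("S1", "S2"),
                            xist_ase = c(0.1, 0.1), ds = c(0.4, 0.4),
                            status = "skewed")
  expect_error(fit_escape_model(obs, same_ds), "all DS values identical")

  # afc exactly linear in ds: all residuals identical, rescale degenerate
  two_ds <- same_ds
  two_ds$ds <- c(0.3, 0.45)
  obs$afc <- 0.9 - c(0.3, 0.3, 0.45, 0.45)
  expect_error(fit_escape_model(obs, two_ds), "residuals identical")
})

test_that("scoring against a stored model reproduces fitting-set scores and clips new extremes", {
  f <- fit_small()
  rescored <- score_new_samples(f$fit$model, f$obs, f$skew)
  merged <- dplyr::inner_join(f$fit$records, rescored,
                              by = c("gene_id", "sample_id"))
  expect_equal(nrow(merged), nrow(f$fit$records))
  expect_equal(merged$escscore.x, merged$escscore.y, tolerance = 1e-12)
  expect_false(any(rescored$clamped))

  # a residual above the stored maximum clips to 1 with the flag set
  m <- f$fit$model
  ds0 <- 0.4
  big_afc <- m$intercept + m$slope * ds0 + m$resid_max + 0.05
  new_obs <- tibble::tibble(
    gene_id = "GNEW", sample_id = "SNEW",
    ac = 10L, bc = 10L, tc = 20L, ase = 0.5, afc = big_afc,
    qc_depth = TRUE, qc_both_haps = TRUE, retained = TRUE
  )
  new_skew <- tibble::tibble(sample_id = "SNEW", xist_ase = 0.1,
                             ds = ds0, status = "skewed")
  out <- score_new_samples(m, new_obs, new_skew)
  expect_equal(out$escscore, 1)
  expect_true(out$clamped)

  # non-skewed samples are skipped, empty input gives empty output
  new_skew$status <- "random"
  expect_message(out2 <- score_new_samples(m, new_obs, new_skew), "skipped")
  expect_equal(nrow(out2), 0)
})

test_that("persisted models round-trip through the plain-text format", {
  f <- fit_small()
  tf <- tempfile(fileext = ".txt")
  write_escape_model(f$fit$model, tf)
  m2 <- read_escape_model(tf)
  expect_equal(unclass(m2), unclass(f$fit$model), tolerance = 1e-15)
})

test_that("gene-tissue calls apply the median cutoff and sample-count gate", {
  sheet <- make_sheet(paste0("S", 1:3), paste0("I", 1:3), tissue = "LCL")
  rec_escapee <- make_records("G1", paste0("S", 1:3), c(0.30, 0.36, 0.50))
  calls <- call_gene_tissue(rec_escapee, sheet)
  expect_identical(calls$status, "escapee")        # median exactly 0.36
  expect_equal(calls$median_escscore, 0.36)

  rec_two <- make_records("G2", paste0("S", 1:2), c(0.10, 0.20))
  expect_identical(call_gene_tissue(rec_two, sheet)$status, "no_call")

  rec_sil <- make_records("G3", paste0("S", 1:3), c(0.1, 0.2, 0.3))
  expect_identical(call_gene_tissue(rec_sil, sheet)$status, "silenced")
})

test_that("excluded tissues contribute to the fit but never to escape calls", {
  sheet <- dplyr::bind_rows(
    make_sheet(paste0("L", 1:3), paste0("I", 1:3), tissue = "LCL"),
    make_sheet(paste0("W", 1:3), paste0("I", 4:6), tissue = "whole-blood")
  )
  rec <- dplyr::bind_rows(
    make_records("G1", paste0("L", 1:3), c(0.5, 0.6, 0.7)),
    make_records("G1", paste0("W", 1:3), c(0.5, 0.6, 0.7))
  )
  calls <- call_gene_tissue(rec, sheet)
  expect_identical(unique(calls$tissue), "LCL")
  incidence <- attr(calls, "incidence")
  expect_false("whole-blood" %in% incidence$tissue)
})

test_that("threshold benchmarking recovers degenerate and self-consistent cases", {
  sheet <- make_sheet(paste0("S", 1:3), paste0("I", 1:3), tissue = "LCL")
  rec <- dplyr::bind_rows(
    make_records("G1", paste0("S", 1:3), c(0.7, 0.8, 0.9)),   # escapee
    make_records("G2", paste0("S", 1:3), c(0.1, 0.1, 0.2))    # silenced
  )
  ann <- tibble::tibble(gene_id = c("G1", "G2"),
                        prior_status = c("escape", "silenced"),
                        par_flag = FALSE)
  cfg <- xci_config(benchmark_cutoffs = c(0, 0.36, 0.95))
  bench <- benchmark_thresholds(rec, sheet, ann, cfg)
  # cutoff 0: everything escapes; concordance = fraction of priors that escape
  expect_equal(bench$concordance[bench$cutoff == 0], 0.5)
  # at 0.36 the calls match the annotation exactly
  expect_equal(bench$concordance[bench$cutoff == 0.36], 1)
  # ambiguous priors are excluded from the concordance denominator
  ann2 <- dplyr::bind_rows(ann, tibble::tibble(
    gene_id = "G3", prior_status = "variable", par_flag = FALSE))
  bench2 <- benchmark_thresholds(rec, sheet, ann2, cfg)
  expect_equal(bench2$n_concordant + bench2$n_discordant, rep(2L, 3))
  # empty overlap warns and yields an empty concordance
  ann3 <- tibble::tibble(gene_id = "ZZZ", prior_status = "escape",
                         par_flag = FALSE)
  expect_warning(bench3 <- benchmark_thresholds(rec, sheet, ann3, cfg),
                 "no overlap")
  expect_true(all(is.na(bench3$concordance)))
})

test_that("benchmark concordance peaks near the separating cutoff on simulated truth", {
  f <- fit_small(seed = 31)
  cfg <- xci_config(benchmark_cutoffs = seq(0.1, 0.9, by = 0.1))
  bench <- benchmark_thresholds(f$fit$records, f$sim$sheet,
                                f$sim$annotation, cfg)
  best <- bench$cutoff[which.max(bench$concordance)]
  expect_gt(best, 0.1)   # neither degenerate end wins
  expect_lt(best, 0.9)
  expect_gt(max(bench$concordance), 0.8)
})

test_that("hypergeometric overlap p-value matches exhaustive tail summation", {
  # disjoint sets: P(X >= 0) = 1
  expect_equal(overlap_test(c("A", "B"), c("C", "D"), LETTERS[1:10])$p_value, 1)
  # reference = universe forces full overlap, p = 1
  expect_equal(overlap_test(LETTERS[1:4], LETTERS[1:10],
                            LETTERS[1:10])$p_value, 1)
  # |universe| = 100, |A| = 20, |B| = 30, overlap 10 vs brute-force oracle
  universe <- sprintf("g%03d", 1:100)
  called <- universe[1:20]
  reference <- c(universe[11:20], universe[31:50])  # overlap exactly 10
  res <- overlap_test(called, reference, universe)
  expect_equal(res$overlap, 10)
  expect_equal(res$p_value, hyper_tail_oracle(10, 20, 30, 100),
               tolerance = 1e-12)
  expect_error(overlap_test("A", "A", character()), "empty gene universe")
  expect_error(overlap_test("Z", "A", LETTERS[1:3]), "subsets")
})
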