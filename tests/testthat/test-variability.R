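three_tissue_sheet <- function(individuals = c("I1", "I2")) {
  tidyr::expand_grid(individual_id = individuals,
                     tissue = c("LCL", "adipose", "skin")) |>
    dplyr::mutate(sample_id = paste(individual_id, tissue, sep = "_"),
                  twin_pair_id = NA_character_,
                  zygosity = NA_character_) |>
    dplyr::select(sample_id, individual_id, tissue, twin_pair_id, zygosity)
}

test_that("intra-donor profiles bin genes by the number of tissues escaping", {
  sheet <- three_tissue_sheet("I1")
  rec <- dplyr::bind_rows(
    make_records("G1", sheet$sample_id, c(0.5, 0.5, 0.5)),  # 3 tissues
    make_records("G2", sheet$sample_id, c(0.5, 0.2, 0.2)),  # 1 tissue
    make_records("G3", sheet$sample_id, c(0.1, 0.1, 0.1))   # 0 tissues
  )
  prof <- intra_donor_summary(rec, sheet)
  counts <- prof$counts
  get_n <- function(k) counts$n_genes[counts$n_tissues_escaping == k]
  expect_equal(get_n(3), 1L)
  expect_equal(get_n(1), 1L)
  expect_equal(get_n(0), 1L)
  expect_equal(get_n(2), 0L)
  # bins partition the fully-scored gene set
  expect_equal(sum(counts$n_genes), 3L)
})

test_that("donors missing a tissue are excluded; genes not scored everywhere drop out", {
  sheet <- three_tissue_sheet(c("I1", "I2"))
  sheet <- sheet[sheet$sample_id != "I2_skin", ]  # I2 lacks skin
  rec <- dplyr::bind_rows(
    make_records("G1", paste0("I1_", c("LCL", "adipose", "skin")),
                 c(0.5, 0.5, 0.5)),
    make_records("G2", paste0("I1_", c("LCL", "adipose")), c(0.9, 0.9)),
    make_records("G1", paste0("I2_", c("LCL", "adipose")), c(0.5, 0.5))
  )
  prof <- intra_donor_summary(rec, sheet)
  expect_identical(unique(prof$counts$individual_id), "I1")
  # G2 lacks a skin score for I1 and is not counted
  expect_false("G2" %in% prof$genes$gene_id)
  # no qualifying donor at all warns and returns empty tables
  expect_warning(
    empty <- intra_donor_summary(
      rec[rec$gene_id == "G1" & grepl("I2", rec$sample_id), ], sheet,
      tissues = c("LCL", "adipose", "skin")),
    "no donor")
  expect_equal(nrow(empty$counts), 0)
})

test_that("consistency labels follow the band fraction and individual gate", {
  n <- 10
  sheet <- make_sheet(paste0("S", 1:n), paste0("I", 1:n), tissue = "LCL")
  esc_call <- tibble::tibble(gene_id = "G1", tissue = "LCL",
                             n_samples = n, median_escscore = 0.5,
                             status = "escapee")

  # 8 of 10 scores at the mean, 2 extremes: exactly 80% within 1 sd
  scores8 <- c(rep(0.5, 8), 0, 1)
  cc8 <- consistency_call(make_records("G1", sheet$sample_id, scores8),
                          sheet, calls = esc_call)
  expect_equal(cc8$frac_within_band, 0.8)
  expect_identical(cc8$label, "consistent")

  # 7 of 10 within the band: variable
  scores7 <- c(rep(0.5, 7), 0, 1, 1)
  dev <- abs(scores7 - mean(scores7))
  expect_equal(sum(dev <= sqrt(mean(dev^2))), 7)  # construction check
  cc7 <- consistency_call(make_records("G1", sheet$sample_id, scores7),
                          sheet, calls = esc_call)
  expect_equal(cc7$frac_within_band, 0.7)
  expect_identical(cc7$label, "variable")

  # 9 individuals: below the gate, no call
  cc9 <- consistency_call(
    make_records("G1", sheet$sample_id[1:9], scores8[1:9]),
    sheet, calls = esc_call)
  expect_identical(cc9$label, "no_call")

  # identical scores: sd 0, everyone inside the degenerate band
  cc_id <- consistency_call(make_records("G1", sheet$sample_id, rep(0.62, n)),
                            sheet, calls = esc_call)
  expect_equal(cc_id$frac_within_band, 1)
  expect_identical(cc_id$label, "consistent")
})

test_that("consistency is evaluated per individual and only for escaping genes", {
  # two samples of one individual collapse to their median first
  sheet <- dplyr::bind_rows(
    make_sheet(paste0("S", 1:10), paste0("I", 1:10), tissue = "LCL"),
    make_sheet("S1b", "I1", tissue = "LCL")
  )
  esc_call <- tibble::tibble(gene_id = "G1", tissue = "LCL",
                             n_samples = 11, median_escscore = 0.5,
                             status = "escapee")
  rec <- dplyr::bind_rows(
    make_records("G1", paste0("S", 1:10), c(rep(0.5, 8), 0, 1)),
    make_records("G1", "S1b", 0.9)
  )
  cc <- consistency_call(rec, sheet, calls = esc_call)
  expect_equal(cc$n_individuals, 10)

  # genes never called escapee anywhere are not assessed
  sil_call <- esc_call
  sil_call$status <- "silenced"
  cc_none <- consistency_call(rec, sheet, calls = sil_call)
  expect_equal(nrow(cc_none), 0)

  # adding individuals at the mean cannot flip a consistent label
  sheet_plus <- dplyr::bind_rows(
    sheet, make_sheet(paste0("X", 1:5), paste0("J", 1:5), tissue = "LCL"))
  rec_plus <- dplyr::bind_rows(
    rec, make_records("G1", paste0("X", 1:5), rep(cc$mean_escscore, 5)))
  cc_plus <- consistency_call(rec_plus, sheet_plus, calls = esc_call)
  expect_identical(cc_plus$label, "consistent")
  expect_gte(cc_plus$frac_within_band, cc$frac_within_band)
})

test_that("the rank test matches the hand rank-sum formula and handles degenerate groups", {
  res <- group_difference_test(c(1, 2, 3, 10, 11, 12),
                               rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, kw_oracle(c(1, 2, 3, 10, 11, 12),
                                        rep(c("a", "b"), each = 3)),
               tolerance = 1e-12)
  expect_equal(res$statistic, 12 / (6 * 7) * (36 / 3 + 225 / 3) - 3 * 7,
               tolerance = 1e-12)

  # identical groups: H = 0 (all mass in ties), p = 1
  same <- group_difference_test(rep(c(1, 2, 3), 2),
                                rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  expect_warning(
    res2 <- group_difference_test(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
    "fewer than 2")
  expect_identical(sort(res2$groups_used), c("a", "b"))
  expect_error(
    suppressWarnings(group_difference_test(c(1, 2, 9), c("a", "a", "c"))),
    "at least 2 groups")
})

test_that("rank-test p-values agree with a permutation null within Monte-Carlo error", {
  set.seed(99)
  scores <- rnorm(24) + rep(c(0, 0.4, 0.9), each = 8)
  groups <- rep(c("a", "b", "c"), each = 8)
  res <- group_difference_test(scores, groups)
  h_obs <- kw_oracle(scores, groups)
  perm <- replicate(4000, kw_oracle(scores, sample(groups)))
  p_perm <- mean(perm >= h_obs - 1e-12)
  expect_lt(abs(res$p_value - p_perm), 0.05)
})

test_that("cell-type summaries average co-twins and handle single-twin genes", {
  sheet <- tibble::tibble(
    sample_id = c("T1_mono", "T2_mono", "T1_b", "T2_b"),
    individual_id = c("T1", "T2", "T1", "T2"),
    tissue = c("monocyte", "monocyte", "B-cell", "B-cell"),
    twin_pair_id = "P1", zygosity = "MZ"
  )
  rec <- dplyr::bind_rows(
    make_records("G1", c("T1_mono", "T2_mono"), c(0.30, 0.40)),
    make_records("G1", c("T1_b", "T2_b"), c(0.50, 0.60)),
    make_records("G2", "T1_mono", 0.80)  # one co-twin only
  )
  out <- cell_type_escape_summary(rec, sheet)
  g1_mono <- out$gene_scores[out$gene_scores$gene_id == "G1" &
                               out$gene_scores$tissue == "monocyte", ]
  expect_equal(g1_mono$score, 0.35)
  g2 <- out$gene_scores[out$gene_scores$gene_id == "G2", ]
  expect_equal(g2$score, 0.80)
  expect_equal(g2$n_individuals, 1)

  mono <- out$summary[out$summary$tissue == "monocyte", ]
  expect_equal(mono$n_genes, 2)
  expect_equal(mono$mean_escscore, mean(c(0.35, 0.80)))
  expect_equal(mono$incidence, 0.5)         # G2 at 0.80 >= 0.36, G1 below
  # complete-gene subset is G1 only (scored in both cell types)
  expect_equal(mono$n_genes_complete, 1)
  expect_equal(mono$incidence_complete, 0)
  # all genes below the cutoff gives zero incidence
  b <- out$summary[out$summary$tissue == "B-cell", ]
  expect_equal(b$incidence, 1)  # G1 B-cell mean 0.55 escapes
})
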