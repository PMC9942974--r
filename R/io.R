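#' Read a gene-level haplotype count table
#'
#' Reads the long-format, tab-separated table of per gene, per sample
#' haplotype read counts that forms the pipeline input (the shape of
#' phASER-style gene-level haplotype expression output): one row per
#' heterozygous gene measured in a sample, with integer read counts assigned
#' to each haplotype.
#'
#' @param path Path to a tab-separated file with header columns `gene_id`,
#'   `sample_id`, `hapA_count`, `hapB_count`.
#' @return A tibble with those four columns (counts as integers), row order
#'   preserved.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tsample_id\thapA_count\thapB_count",
#'              "GENE1\tS1\t10\t2"), tf)
#' read_count_table(tf)
read_count_table <- function(path) {
  df <- read_tsv_chr(path, c("gene_id", "sample_id", "hapA_count", "hapB_count"))
  validate_count_table(df, where = path)
}

#' Validate an in-memory count table
#'
#' Checks the count-table contract: required columns, non-negative integer
#' counts, and unique (gene, sample) keys. Called by [read_count_table()] and
#' by [run_pipeline()] on programmatically built tables.
#'
#' @param df A data frame with columns `gene_id`, `sample_id`, `hapA_count`,
#'   `hapB_count`.
#' @param where Label used in error messages (file path or object name).
#' @return The validated table as a tibble, counts coerced to integer.
#' @export
validate_count_table <- function(df, where = "count table") {
  required <- c("gene_id", "sample_id", "hapA_count", "hapB_count")
  check_columns(df, required, where)
  df <- tibble::as_tibble(df)
  for (col in c("hapA_count", "hapB_count")) {
    df[[col]] <- check_count_column(df[[col]], col, where)
  }
  key <- paste(df$gene_id, df$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    first <- which(duplicated(key))[1]
    stop(where, ": duplicate (gene_id, sample_id) pair '", df$gene_id[first],
         "', '", df$sample_id[first], "' at row ", first, call. = FALSE)
  }
  df[required]
}

#' Read a sample sheet
#'
#' Reads the tab-separated sample metadata: sample, individual, tissue (or
#' cell type) label, and optional twin structure. A twin pair identifier must
#' map to exactly two distinct individuals and carry a zygosity of `MZ` or
#' `DZ`; samples without twin information leave `twin_pair_id` empty and may
#' state zygosity `unknown`.
#'
#' @param path Path to a tab-separated file with header columns `sample_id`,
#'   `individual_id`, `tissue`, `twin_pair_id`, `zygosity`.
#' @return A validated tibble; empty `twin_pair_id`/`zygosity` become `NA`.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_chr(
    path, c("sample_id", "individual_id", "tissue"),
    optional = c("twin_pair_id", "zygosity")
  )
  validate_sample_sheet(df, where = path)
}

#' Validate an in-memory sample sheet
#'
#' @param df Data frame with columns `sample_id`, `individual_id`, `tissue`
#'   and optionally `twin_pair_id`, `zygosity`.
#' @param where Label used in error messages.
#' @return The validated sheet as a tibble.
#' @export
validate_sample_sheet <- function(df, where = "sample sheet") {
  check_columns(df, c("sample_id", "individual_id", "tissue"), where)
  df <- tibble::as_tibble(df)
  if (!"twin_pair_id" %in% names(df)) df$twin_pair_id <- NA_character_
  if (!"zygosity" %in% names(df)) df$zygosity <- NA_character_
  df$twin_pair_id <- empty_to_na(as.character(df$twin_pair_id))
  df$zygosity <- empty_to_na(as.character(df$zygosity))

  if (anyDuplicated(df$sample_id)) {
    dup <- df$sample_id[duplicated(df$sample_id)][1]
    stop(where, ": duplicate sample_id '", dup, "'", call. = FALSE)
  }
  bad_zyg <- !is.na(df$zygosity) & !df$zygosity %in% c("MZ", "DZ", "unknown")
  if (any(bad_zyg)) {
    stop(where, ": unknown zygosity token '", df$zygosity[which(bad_zyg)[1]],
         "' at row ", which(bad_zyg)[1], " (expected MZ, DZ or unknown)",
         call. = FALSE)
  }
  paired <- !is.na(df$twin_pair_id)
  missing_zyg <- paired & (is.na(df$zygosity) | df$zygosity == "unknown")
  if (any(missing_zyg)) {
    stop(where, ": twin_pair_id set but zygosity missing/unknown at row ",
         which(missing_zyg)[1], call. = FALSE)
  }
  if (any(paired)) {
    per_pair <- tapply(df$individual_id[paired], df$twin_pair_id[paired],
                       function(x) length(unique(x)))
    bad <- names(per_pair)[per_pair != 2L]
    if (length(bad) > 0) {
      stop(where, ": twin_pair_id '", bad[1], "' maps to ",
           per_pair[bad[1]], " individuals (expected exactly 2)",
           call. = FALSE)
    }
    zyg_per_pair <- tapply(df$zygosity[paired], df$twin_pair_id[paired],
                           function(x) length(unique(x)))
    if (any(zyg_per_pair != 1L)) {
      stop(where, ": twin_pair_id '",
           names(zyg_per_pair)[zyg_per_pair != 1L][1],
           "' has inconsistent zygosity", call. = FALSE)
    }
  }
  df[c("sample_id", "individual_id", "tissue", "twin_pair_id", "zygosity")]
}

#' Read a reference XCI-status annotation
#'
#' Reads a tab-separated catalogue of previously annotated XCI statuses
#' (e.g. a published list of silenced / escape / variable genes) used for
#' benchmarking and overlap testing.
#'
#' @param path Path to a tab-separated file with header columns `gene_id`,
#'   `prior_status`, and optionally `par_flag` (`TRUE`/`FALSE`).
#' @return A tibble with unique `gene_id`, `prior_status` drawn from
#'   `silenced`, `escape`, `variable`, `discordant_unknown`, and logical
#'   `par_flag`.
#' @export
read_reference_annotation <- function(path) {
  df <- read_tsv_chr(path, c("gene_id", "prior_status"),
                     optional = "par_flag")
  validate_reference_annotation(df, where = path)
}

#' Validate an in-memory reference annotation
#'
#' @param df Data frame with columns `gene_id`, `prior_status` and optionally
#'   `par_flag`.
#' @param where Label used in error messages.
#' @return The validated annotation as a tibble.
#' @export
validate_reference_annotation <- function(df, where = "annotation") {
  check_columns(df, c("gene_id", "prior_status"), where)
  df <- tibble::as_tibble(df)
  if (!"par_flag" %in% names(df)) df$par_flag <- FALSE
  if (is.character(df$par_flag)) {
    df$par_flag <- toupper(trimws(df$par_flag)) %in% c("TRUE", "T", "1", "YES")
  }
  df$par_flag <- as.logical(df$par_flag)
  if (anyDuplicated(df$gene_id)) {
    stop(where, ": duplicate gene_id '",
         df$gene_id[duplicated(df$gene_id)][1], "'", call. = FALSE)
  }
  allowed <- c("silenced", "escape", "variable", "discordant_unknown")
  bad <- !df$prior_status %in% allowed
  if (any(bad)) {
    stop(where, ": unknown prior_status '", df$prior_status[which(bad)[1]],
         "' at row ", which(bad)[1], call. = FALSE)
  }
  df[c("gene_id", "prior_status", "par_flag")]
}

#' Write a result table as tab-separated text
#'
#' Thin wrapper over [readr::write_tsv()] so that every output table of the
#' pipeline is written with identical formatting (and therefore round-trips
#' exactly as formatted).
#'
#' @param df Table to write.
#' @param path Output path.
#' @return `df`, invisibly.
#' @export
write_result_table <- function(df, path) {
  readr::write_tsv(df, path)
  invisible(df)
}

# --- internal helpers -------------------------------------------------------

read_tsv_chr <- function(path, required, optional = character()) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  check_columns(df, required, path)
  keep <- c(required, intersect(optional, names(df)))
  df[keep]
}

check_columns <- function(df, required, where) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(where, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

check_count_column <- function(x, col, where) {
  xc <- trimws(as.character(x))
  num <- suppressWarnings(as.numeric(xc))
  bad <- is.na(num) | num < 0 | num != floor(num)
  if (any(bad)) {
    row <- which(bad)[1]
    stop(where, ": column '", col, "' must hold non-negative integers; ",
         "found '", xc[row], "' at row ", row, call. = FALSE)
  }
  as.integer(num)
}

empty_to_na <- function(x) {
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  x
}
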