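#' Coverage table construction and io
#'
#' A coverage table holds per-scaffold mean sequencing depths, one column per
#' library, together with a sample sheet assigning a sex to every library.
#' It is the central input of the whole pipeline: every downstream stage
#' (classification, W scan, sex inference) works from these depths.
#'
#' @name coverage_table
NULL

DIALECT_COMMENT <- "# zdosage coverage-table v1 (tab-separated; scaffold, length, one mean-depth column per library)"

#' Build a coverage table from depths and a sample sheet
#'
#' @param scaffolds tibble with columns `scaffold`, `length` (bp) and one
#'   numeric mean-depth column per library.
#' @param samples tibble with columns `sample` (matching the depth column
#'   names) and `sex` (`"male"` or `"female"`).
#' @return A `coverage_table` object (list with `$scaffolds`, `$samples`).
#' @export
coverage_table <- function(scaffolds, samples) {
  scaffolds <- tibble::as_tibble(scaffolds)
  samples <- tibble::as_tibble(samples)
  validate_coverage_table(scaffolds, samples)
  structure(list(scaffolds = scaffolds, samples = samples),
            class = "coverage_table")
}

validate_coverage_table <- function(scaffolds, samples) {
  if (!all(c("scaffold", "length") %in% names(scaffolds)))
    stop("coverage table needs 'scaffold' and 'length' columns", call. = FALSE)
  if (!all(c("sample", "sex") %in% names(samples)))
    stop("sample sheet needs 'sample' and 'sex' columns", call. = FALSE)
  bad_sex <- setdiff(unique(samples$sex), c("male", "female"))
  if (length(bad_sex))
    stop("unknown sex label(s) in sample sheet: ",
         paste(bad_sex, collapse = ", "), call. = FALSE)
  missing_cols <- setdiff(samples$sample, names(scaffolds))
  if (length(missing_cols))
    stop("depth column(s) missing from table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  unsheeted <- setdiff(setdiff(names(scaffolds), c("scaffold", "length")),
                       samples$sample)
  if (length(unsheeted))
    stop("depth column(s) without a sex in the sample sheet: ",
         paste(unsheeted, collapse = ", "), call. = FALSE)
  if (!any(samples$sex == "male") || !any(samples$sex == "female"))
    stop("need at least one male and one female library", call. = FALSE)
  if (any(scaffolds$length < 1))
    stop("scaffold length < 1 bp: ",
         scaffolds$scaffold[which(scaffolds$length < 1)[1]], call. = FALSE)
  for (s in samples$sample) {
    d <- scaffolds[[s]]
    if (!is.numeric(d))
      stop("depth column '", s, "' is not numeric", call. = FALSE)
    if (anyNA(d) || any(d < 0))
      stop("negative or missing depth in column '", s, "' at scaffold ",
           scaffolds$scaffold[which(is.na(d) | d < 0)[1]], call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.coverage_table <- function(x, ...) {
  cat("<coverage_table> ", nrow(x$scaffolds), " scaffolds, ",
      sum(x$samples$sex == "female"), " female / ",
      sum(x$samples$sex == "male"), " male libraries\n", sep = "")
  print(utils::head(x$scaffolds, 5))
  invisible(x)
}

#' Read a coverage table from TSV
#'
#' Expects a header row (`scaffold`, `length`, then one column per library)
#' in the style of SOAPcoverage summaries; lines starting with `#` are
#' ignored. The sample sheet may be a path to a two-column TSV
#' (`sample`, `sex`) or a data frame.
#'
#' @param path coverage TSV path.
#' @param sample_sheet path or data frame mapping library -> sex.
#' @return a [coverage_table()].
#' @export
read_coverage_table <- function(path, sample_sheet) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.character(sample_sheet)) {
    sample_sheet <- readr::read_tsv(sample_sheet, comment = "#",
                                    show_col_types = FALSE)
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  coverage_table(tab, sample_sheet)
}

#' Write a coverage table (and its sample sheet) as TSV
#'
#' @param x a coverage_table.
#' @param path output TSV for the depths.
#' @param sample_sheet_path optional output TSV for the sample sheet.
#' @return `x`, invisibly.
#' @export
write_coverage_table <- function(x, path, sample_sheet_path = NULL) {
  stopifnot(inherits(x, "coverage_table"))
  writeLines(DIALECT_COMMENT, path)
  readr::write_tsv(x$scaffolds, path, append = TRUE, col_names = TRUE)
  if (!is.null(sample_sheet_path)) {
    writeLines("# zdosage sample-sheet v1", sample_sheet_path)
    readr::write_tsv(x$samples, sample_sheet_path, append = TRUE,
                     col_names = TRUE)
  }
  invisible(x)
}

male_samples <- function(x) x$samples$sample[x$samples$sex == "male"]
female_samples <- function(x) x$samples$sample[x$samples$sex == "female"]

#' Per-sex summed depth per scaffold
#'
#' Sums the per-scaffold mean depths across libraries grouped by sex, the
#' grouping used throughout for F:M ratio computation.
#'
#' @param x a coverage_table.
#' @return tibble with `scaffold`, `length`, `female_sum`, `male_sum`.
#' @export
sex_sums <- function(x) {
  stopifnot(inherits(x, "coverage_table"))
  sc <- x$scaffolds
  fs <- as.matrix(sc[, female_samples(x), drop = FALSE])
  ms <- as.matrix(sc[, male_samples(x), drop = FALSE])
  tibble::tibble(scaffold = sc$scaffold, length = sc$length,
                 female_sum = rowSums(fs), male_sum = rowSums(ms))
}

#' Pre-filter scaffolds before Z/A classification
#'
#' Retains scaffolds longer than `min_len` whose grouped-male depth is above
#' `min_male_cov` and below the `male_pct_cap`-th percentile of grouped-male
#' depth. The percentile is computed once, on the population the filter is
#' first applied to, and stored on the result so that re-application is a
#' no-op (idempotence).
#'
#' @param x a coverage_table.
#' @param min_len minimum scaffold length in bp (strictly greater than).
#' @param min_male_cov minimum grouped-male depth (strictly greater than).
#' @param male_pct_cap upper percentile cap on grouped-male depth.
#' @return a filtered coverage_table with attribute `male_cap`.
#' @export
prefilter_scaffolds <- function(x, min_len = 1500, min_male_cov = 5,
                                male_pct_cap = 99.5) {
  stopifnot(inherits(x, "coverage_table"))
  ss <- sex_sums(x)
  cap <- attr(x, "male_cap")
  if (is.null(cap))
    cap <- stats::quantile(ss$male_sum, male_pct_cap / 100, names = FALSE)
  keep <- ss$length > min_len & ss$male_sum > min_male_cov & ss$male_sum < cap
  out <- coverage_table(x$scaffolds[keep, , drop = FALSE], x$samples)
  if (!any(keep))
    warning("prefilter removed every scaffold", call. = FALSE)
  attr(out, "male_cap") <- cap
  out
}

#' Log2 female:male depth ratio per scaffold
#'
#' Depths are summed across libraries grouped by sex and the ratio is
#' log2(female sum / male sum). No pseudocount is added: scaffolds with a
#' zero numerator or denominator are flagged non-finite and are excluded from
#' histograms and classification (adding a pseudocount would shift the
#' Z-linked mode).
#'
#' @param x a coverage_table.
#' @return tibble (`log2_profile`): `scaffold`, `length`, `female_sum`,
#'   `male_sum`, `log2_fm`, `finite`.
#' @export
log2_fm <- function(x) {
  ss <- sex_sums(x)
  ss$log2_fm <- log2(ss$female_sum / ss$male_sum)
  ss$finite <- is.finite(ss$log2_fm)
  class(ss) <- c("log2_profile", class(ss))
  ss
}
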