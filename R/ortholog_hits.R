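#' Ortholog hit tables and the reference gene map
#'
#' Hits are tabular alignments of reference-species genes against an
#' assembly (gene, scaffold, interval, score), the post-processed output of a
#' translated aligner. Intervals are stored 0-based half-open internally
#' regardless of input dialect; a single internal convention avoids
#' off-by-one churn between stages.
#'
#' @name ortholog_hits
NULL

HITS_COMMENT <- "# zdosage ortholog-hits v1 (tab-separated; 0-based half-open intervals)"

#' Read ortholog hits from a PSL-like TSV
#'
#' Required columns: `gene`, `scaffold`, `start`, `end`, `score`. `coords`
#' says how the input intervals are encoded: `"zero"` (0-based half-open,
#' PSL-native, the default) or `"one"` (1-based closed; converted on read).
#'
#' @param path TSV path; `#` lines are ignored.
#' @param coords input interval convention.
#' @return tibble of hits, 0-based half-open.
#' @export
read_ortholog_hits <- function(path, coords = c("zero", "one")) {
  coords <- match.arg(coords)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hits <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("gene", "scaffold", "start", "end", "score")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hit table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (coords == "one") hits$start <- hits$start - 1L
  validate_hits(hits)
  hits
}

validate_hits <- function(hits) {
  if (!is.numeric(hits$score))
    stop("hit scores must be numeric", call. = FALSE)
  bad <- which(hits$start >= hits$end)
  if (length(bad))
    stop("malformed interval (start >= end) for gene ", hits$gene[bad[1]],
         " on ", hits$scaffold[bad[1]], call. = FALSE)
  invisible(TRUE)
}

#' Write ortholog hits as TSV
#' @param hits hit tibble.
#' @param path output path.
#' @export
write_ortholog_hits <- function(hits, path) {
  validate_hits(hits)
  writeLines(HITS_COMMENT, path)
  readr::write_tsv(hits, path, append = TRUE, col_names = TRUE)
  invisible(hits)
}

#' Read a reference gene -> chromosome map
#'
#' @param path TSV with columns `gene`, `chrom` and optionally `ref_pos`
#'   (position of the gene along its reference chromosome, used for
#'   sliding-window profiles).
#' @return tibble.
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gm <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  miss <- setdiff(c("gene", "chrom"), names(gm))
  if (length(miss))
    stop("gene map missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  gm
}
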