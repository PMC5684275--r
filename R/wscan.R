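#' Candidate W-derived scaffold detection
#'
#' The W chromosome is female-limited and single-copy, so W-derived
#' scaffolds show (near-)zero male coverage and roughly half-autosomal
#' female coverage. Candidates are scaffolds above a length floor with
#' depth below `male_max` in every male library and strictly between
#' `female_lower` and `female_upper` times the female median in every
#' female library. The female medians are computed per library over all
#' scaffolds passing only a minimal 200 bp length floor -- not the Z/A
#' classification prefilter, whose male-coverage floor would discard
#' exactly the scaffolds sought here.
#'
#' @name wscan
NULL

#' Lenient W-filter configuration
#'
#' @param min_len minimum scaffold length, bp (strictly greater than).
#' @param male_max per-male-library depth ceiling (strict; a value of 0
#'   requires exactly zero depth).
#' @param female_lower,female_upper female depth window as fractions of the
#'   per-library female median (strict bounds).
#' @param median_floor_len length floor for the scaffold population over
#'   which female medians are taken.
#' @export
w_filter_config <- function(min_len = 1000, male_max = 1.1,
                            female_lower = 0.25, female_upper = 1,
                            median_floor_len = 200) {
  stopifnot(female_lower < female_upper, male_max >= 0)
  list(min_len = min_len, male_max = male_max, female_lower = female_lower,
       female_upper = female_upper, median_floor_len = median_floor_len)
}

#' Stringent W-filter preset
#'
#' Raises the length floor to 2000 bp and requires null coverage in every
#' male library.
#' @export
w_stringent_preset <- function() {
  cfg <- w_filter_config(min_len = 2000, male_max = 0)
  cfg
}

#' Detect candidate W-derived scaffolds
#'
#' @param x a coverage_table (unfiltered; see the median note above).
#' @param config a [w_filter_config()] or [w_stringent_preset()].
#' @param grouped_female_median use a single median of grouped (summed)
#'   female depth instead of per-library medians.
#' @return tibble of candidates: `scaffold`, `length`, the per-library
#'   depths, and attribute `preset` recording the thresholds.
#' @export
detect_w_candidates <- function(x, config = w_filter_config(),
                                grouped_female_median = FALSE) {
  stopifnot(inherits(x, "coverage_table"))
  sc <- x$scaffolds
  males <- male_samples(x)
  females <- female_samples(x)
  med_pop <- sc$length >= config$median_floor_len

  ok <- sc$length > config$min_len
  for (m in males) {
    ok <- ok & (if (config$male_max == 0) sc[[m]] == 0
                else sc[[m]] < config$male_max)
  }
  if (grouped_female_median) {
    fsum <- rowSums(as.matrix(sc[, females, drop = FALSE]))
    med <- stats::median(fsum[med_pop])
    ok <- ok & fsum > config$female_lower * med &
      fsum < config$female_upper * med
  } else {
    for (f in females) {
      med <- stats::median(sc[[f]][med_pop])
      ok <- ok & sc[[f]] > config$female_lower * med &
        sc[[f]] < config$female_upper * med
    }
  }
  out <- tibble::as_tibble(sc[ok, , drop = FALSE])
  attr(out, "preset") <- config
  out
}
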