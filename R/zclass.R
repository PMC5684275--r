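#' Z/autosome classification of scaffolds from log2(F/M) depth ratios
#'
#' In a female-heterogametic genome the Z is present in one copy in females
#' and two in males, so Z-linked scaffolds sit one log2 unit below the
#' autosomal mode of the log2(F/M) distribution. Two classifiers are
#' provided: a lenient histogram-mode rule and a stringent rule calibrated
#' against reference-chromosome homology.
#'
#' @name zclass
NULL

#' Locate the autosomal mode of a log2(F/M) distribution
#'
#' Builds an equal-width histogram with `n_bins` classes over the range of
#' the finite ratios and returns the center of the most populated bin --
#' the autosomal mode, around which males and females have equal coverage.
#' A tie between modal bins is broken toward the bin whose center is nearer
#' 0, since the autosomal peak is by assumption the dominant one.
#'
#' @param profile a `log2_profile` (from [log2_fm()]) or numeric vector.
#' @param n_bins number of histogram classes (>= 10).
#' @return the modal log2 ratio (`A_mode`).
#' @export
find_autosomal_mode <- function(profile, n_bins = 200) {
  r <- profile_ratios(profile)
  if (n_bins < 10) stop("n_bins must be >= 10", call. = FALSE)
  if (length(r) < n_bins)
    stop("too few finite ratios (", length(r), ") for a ", n_bins,
         "-class histogram", call. = FALSE)
  rng <- range(r)
  if (rng[1] == rng[2]) return(rng[1])  # point mass
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- graphics::hist(r, breaks = breaks, plot = FALSE)$counts
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  top <- which(counts == max(counts))
  centers[top[which.min(abs(centers[top]))]]
}

profile_ratios <- function(profile) {
  if (is.numeric(profile)) return(profile[is.finite(profile)])
  profile$log2_fm[profile$finite]
}

#' Lenient classification configuration
#'
#' @param n_bins histogram classes used to locate the autosomal mode.
#' @param z_offset scaffolds with ratio below `A_mode - z_offset` are Z.
#' @param a_offset scaffolds with ratio above `A_mode - a_offset` are A.
#' @export
lenient_config <- function(n_bins = 200, z_offset = 0.6, a_offset = 0.4) {
  stopifnot(n_bins >= 10, z_offset > a_offset, a_offset > 0)
  list(n_bins = n_bins, z_offset = z_offset, a_offset = a_offset)
}

#' Classify scaffolds by the lenient (histogram-mode) method
#'
#' Ratios below `A_mode - z_offset` are Z-linked, ratios above
#' `A_mode - a_offset` autosomal; everything in between (inclusive of both
#' boundary values, which the strict inequalities leave in the gap) and every
#' non-finite ratio is unclassified.
#'
#' @param profile a `log2_profile`.
#' @param config a [lenient_config()].
#' @return tibble: `scaffold`, `log2_fm`, `label` in {Z, A, unclassified},
#'   with attributes `A_mode`, `z_cutoff`, `a_cutoff`, `method`.
#' @export
classify_lenient <- function(profile, config = lenient_config()) {
  a_mode <- find_autosomal_mode(profile, config$n_bins)
  z_cut <- a_mode - config$z_offset
  a_cut <- a_mode - config$a_offset
  label <- rep("unclassified", nrow(profile))
  label[profile$finite & profile$log2_fm < z_cut] <- "Z"
  label[profile$finite & profile$log2_fm > a_cut] <- "A"
  out <- tibble::tibble(scaffold = profile$scaffold,
                        log2_fm = profile$log2_fm, label = label)
  attr(out, "A_mode") <- a_mode
  attr(out, "z_cutoff") <- z_cut
  attr(out, "a_cutoff") <- a_cut
  attr(out, "method") <- "lenient"
  out
}

#' Calibrate the stringent Z cutoff against reference-Z homology
#'
#' Sweeps candidate cutoffs from the lenient value toward stricter (lower)
#' values. At each cutoff the fraction of Z-classified, chromosome-assigned
#' scaffolds that land on the reference Z chromosome is computed; as the
#' cutoff tightens this fraction rises and then plateaus once (almost) only
#' true Z scaffolds remain. The most lenient cutoff at which the gain over a
#' sliding span of `span` log2 units drops below `tol` is returned (plateau
#' onset). If the curve is still rising at the strictest swept value, a
#' warning is issued and that value returned.
#'
#' @param profile a `log2_profile`.
#' @param assignment scaffold -> reference chromosome tibble
#'   (see [assign_chromosome()]); `NA` chromosome rows are ignored.
#' @param ref_z_id reference Z chromosome identifier.
#' @param start most lenient cutoff to sweep from; default `A_mode - 0.6`.
#' @param step sweep resolution in log2 units.
#' @param span sliding span over which the gain is measured, log2 units.
#' @param tol plateau tolerance, in fraction units (0.01 = 1 percentage point).
#' @param n_bins passed to [find_autosomal_mode()] when `start` is NULL.
#' @return the calibrated cutoff, with the sweep curve as attribute `curve`.
#' @export
calibrate_stringent_cutoff <- function(profile, assignment, ref_z_id,
                                       start = NULL, step = 0.01,
                                       span = 0.1, tol = 0.01,
                                       n_bins = 200) {
  if (is.null(start))
    start <- find_autosomal_mode(profile, n_bins) - 0.6
  asg <- assignment[!is.na(assignment$chrom), c("scaffold", "chrom")]
  dat <- dplyr::inner_join(
    tibble::as_tibble(profile)[profile$finite, c("scaffold", "log2_fm")],
    asg, by = "scaffold")
  if (!nrow(dat))
    stop("no assigned scaffolds with finite ratios to calibrate on",
         call. = FALSE)
  lo <- min(dat$log2_fm)
  cuts <- seq(start, lo, by = -step)
  frac <- vapply(cuts, function(ct) {
    z <- dat$chrom[dat$log2_fm < ct]
    if (!length(z)) NA_real_ else mean(z == ref_z_id)
  }, numeric(1))
  curve <- tibble::tibble(cutoff = cuts, frac_on_ref_z = frac)
  k <- max(1L, round(span / step))
  chosen <- NA_real_
  for (i in seq_along(cuts)) {
    j <- min(i + k, length(cuts))
    fi <- frac[i]; fj <- frac[j]
    if (is.na(fi) || is.na(fj)) next
    if (fj - fi < tol) { chosen <- cuts[i]; break }
  }
  if (is.na(chosen)) {
    warning("concordance curve never plateaued; returning strictest swept ",
            "cutoff", call. = FALSE)
    chosen <- cuts[length(cuts)]
  }
  attr(chosen, "curve") <- curve
  chosen
}

#' Stringent classification configuration
#'
#' @param z_cutoff log2(F/M) below which (together with the female-depth
#'   condition) a scaffold is Z-linked; dataset-specific, from
#'   [calibrate_stringent_cutoff()] or supplied directly.
#' @param autosome_percentile percentile of autosome-assigned ratios above
#'   which a scaffold is autosomal.
#' @param require_female_below_median require female summed depth below the
#'   female median (single-copy Z in females).
#' @export
stringent_config <- function(z_cutoff, autosome_percentile = 10,
                             require_female_below_median = TRUE) {
  stopifnot(autosome_percentile > 0, autosome_percentile < 50)
  list(z_cutoff = z_cutoff, autosome_percentile = autosome_percentile,
       require_female_below_median = require_female_below_median)
}

#' Classify scaffolds by the stringent (homology-calibrated) method
#'
#' Z-linked iff the ratio is below `z_cutoff` and (by default) the grouped
#' female depth is below the median grouped female depth of the filtered
#' set; autosomal iff the ratio is at or above the `autosome_percentile`-th
#' percentile of ratios among scaffolds assigned to reference autosomes;
#' unclassified otherwise.
#'
#' @param profile a `log2_profile` of the filtered table.
#' @param assignment scaffold -> reference chromosome tibble.
#' @param ref_z_id reference Z chromosome identifier.
#' @param config a [stringent_config()].
#' @return classification tibble as in [classify_lenient()].
#' @export
classify_stringent <- function(profile, assignment, ref_z_id, config) {
  asg <- assignment[!is.na(assignment$chrom), c("scaffold", "chrom")]
  auto_scaf <- asg$scaffold[asg$chrom != ref_z_id]
  auto_ratios <- profile$log2_fm[profile$finite &
                                   profile$scaffold %in% auto_scaf]
  if (!length(auto_ratios))
    stop("no scaffolds assigned to reference autosomes; cannot set the ",
         "autosomal limit", call. = FALSE)
  a_cut <- stats::quantile(auto_ratios, config$autosome_percentile / 100,
                           names = FALSE)
  fmed <- stats::median(profile$female_sum)
  is_z <- profile$finite & profile$log2_fm < config$z_cutoff
  if (config$require_female_below_median)
    is_z <- is_z & profile$female_sum < fmed
  is_a <- profile$finite & profile$log2_fm >= a_cut & !is_z
  label <- rep("unclassified", nrow(profile))
  label[is_z] <- "Z"
  label[is_a] <- "A"
  out <- tibble::tibble(scaffold = profile$scaffold,
                        log2_fm = profile$log2_fm, label = label)
  attr(out, "z_cutoff") <- config$z_cutoff
  attr(out, "a_cutoff") <- a_cut
  attr(out, "female_median") <- fmed
  attr(out, "method") <- "stringent"
  out
}

#' Write a classification as TSV
#' @param cls classification tibble.
#' @param path output path.
#' @export
write_classification <- function(cls, path) {
  hdr <- sprintf("# zdosage classification v1 method=%s z_cutoff=%.6g a_cutoff=%.6g",
                 attr(cls, "method"), attr(cls, "z_cutoff"),
                 attr(cls, "a_cutoff"))
  writeLines(hdr, path)
  readr::write_tsv(tibble::as_tibble(cls), path, append = TRUE,
                   col_names = TRUE)
  invisible(cls)
}
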