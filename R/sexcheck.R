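#' Sex inference for an unlabelled sample from Z vs autosomal depth
#'
#' A female (ZW or Z0) carries one Z, so her depth on Z-classified
#' scaffolds is about half her autosomal depth; a male (ZZ) shows no
#' difference. A one-tailed rank-sum test of Z depths below autosomal
#' depths makes the call. Dosage alone cannot distinguish ZW from Z0
#' females.
#'
#' @param depths tibble `scaffold`, `depth` (mean depth of the unlabelled
#'   sample per scaffold) or a named numeric vector.
#' @param classification classification tibble (`scaffold`, `label`) built
#'   independently of the tested sample.
#' @param alpha one-sided significance level for the female call.
#' @param min_n minimum scaffolds required in each class; below it the call
#'   is "indeterminate".
#' @return a `sex_call` list: `median_Z`, `median_A`, `p_value`, `call` in
#'   {male, female, indeterminate}, `alpha`, `n_Z`, `n_A`.
#' @export
infer_sex <- function(depths, classification, alpha = 0.05, min_n = 30) {
  if (is.numeric(depths) && !is.null(names(depths)))
    depths <- tibble::tibble(scaffold = names(depths),
                             depth = unname(depths))
  stopifnot(all(c("scaffold", "depth") %in% names(depths)))
  lab <- classification$label[match(depths$scaffold,
                                    classification$scaffold)]
  if (all(is.na(lab)))
    stop("no overlap between sample scaffolds and the classification",
         call. = FALSE)
  z <- depths$depth[!is.na(lab) & lab == "Z"]
  a <- depths$depth[!is.na(lab) & lab == "A"]
  res <- list(median_Z = stats::median(z), median_A = stats::median(a),
              n_Z = length(z), n_A = length(a), alpha = alpha)
  if (length(z) < min_n || length(a) < min_n) {
    res$p_value <- NA_real_
    res$call <- "indeterminate"
  } else {
    res$p_value <- stats::wilcox.test(z, a, alternative = "less",
                                      exact = FALSE)$p.value
    res$call <- if (res$p_value < alpha) "female" else "male"
  }
  structure(res, class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf(
    "sex call: %s (median_Z = %.3g; median_A = %.3g; one-tailed rank-sum P = %s; n_Z = %d, n_A = %d)\n",
    x$call, x$median_Z, x$median_A,
    if (is.na(x$p_value)) "NA" else sprintf("%.3g", x$p_value),
    x$n_Z, x$n_A))
  invisible(x)
}
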