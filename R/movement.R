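#' Gene movement onto and off the Z across a four-species phylogeny
#'
#' Per-species Z/A gene states are combined into a linkage matrix over the
#' fixed rooted topology (((bmori, cohridella), ndegeerella), tsylvina) and
#' ancestral Z content plus per-branch movement is inferred by a
#' parsimony-style rule set:
#'
#' * ancestral-Lepidoptera-Z: Z in tsylvina and in at least one other
#'   species;
#' * ancestral to the Ditrysia + ndegeerella node: the ancestral set plus
#'   genes Z in ndegeerella and both Ditrysia (counted as a gain on the
#'   stem branch of that clade);
#' * onto-Z at the Ditrysia root: Z in both Ditrysia only;
#' * species-specific onto-Z: Z in exactly one of bmori, cohridella,
#'   ndegeerella;
#' * off-Z: the mirror rules with "autosomal" substituted for "Z-linked",
#'   applied against the ancestral-Z gene set;
#' * genes Z in tsylvina only cannot be polarized (no outgroup) and are
#'   reported separately.
#'
#' @name movement
NULL

#' Fixed species set (assembly order: the two Ditrysia, then the
#' progressively deeper lineages)
#' @export
lep_species <- function() c("bmori", "cohridella", "ndegeerella", "tsylvina")

#' Branches on which onto-Z movement can be placed
#' @export
lep_branches <- function() c("dn_stem", "ditrysia_root", "bmori",
                             "cohridella", "ndegeerella")

# species descending from each branch
branch_descendants <- function(branch) {
  switch(branch,
         dn_stem = c("bmori", "cohridella", "ndegeerella"),
         ditrysia_root = c("bmori", "cohridella"),
         bmori = "bmori", cohridella = "cohridella",
         ndegeerella = "ndegeerella",
         stop("unknown branch: ", branch, call. = FALSE))
}

#' Per-pattern movement rule table
#'
#' One row per Z/A pattern over (bmori, cohridella, ndegeerella, tsylvina),
#' giving its category and the branch attribution of every implied event.
#' Patterns with Z in two non-sister ingroup species (and not tsylvina) are
#' equally parsimonious as two terminal gains or a deeper gain plus loss;
#' they are attributed as two independent terminal gains. Losses among
#' ancestral-Z genes are placed on the minimal branch set consistent with
#' the states (a double loss in both Ditrysia is one event at the Ditrysia
#' root).
#'
#' @return tibble: `pattern` (e.g. "ZZAA"), per-species state columns,
#'   `category`, `onto` and `off` (comma-separated branch lists).
#' @export
movement_rules <- function() {
  tibble::tribble(
    ~pattern, ~category, ~onto, ~off,
    "ZZZZ", "ancestral_z", "", "",
    "ZZZA", "ancestral_dn", "dn_stem", "",
    "ZZAZ", "ancestral_z", "", "ndegeerella",
    "ZZAA", "ditrysia_gain", "ditrysia_root", "",
    "ZAZZ", "ancestral_z", "", "cohridella",
    "ZAZA", "terminal_gains", "bmori,ndegeerella", "",
    "ZAAZ", "ancestral_z", "", "cohridella,ndegeerella",
    "ZAAA", "terminal_gains", "bmori", "",
    "AZZZ", "ancestral_z", "", "bmori",
    "AZZA", "terminal_gains", "cohridella,ndegeerella", "",
    "AZAZ", "ancestral_z", "", "bmori,ndegeerella",
    "AZAA", "terminal_gains", "cohridella", "",
    "AAZZ", "ancestral_z", "", "ditrysia_root",
    "AAZA", "terminal_gains", "ndegeerella", "",
    "AAAZ", "unpolarized", "", "",
    "AAAA", "all_autosomal", "", "")
}

#' Combine per-species classifications into a linkage matrix
#'
#' Each gene inherits the Z/A label of the scaffold it maps to in each
#' species; genes missing or on unclassified scaffolds get state "U". Genes
#' with a non-U state in all four species form the classified set used for
#' movement inference.
#'
#' @param classifications named list (one per species in [lep_species()])
#'   of classification tibbles (`scaffold`, `label`).
#' @param placements named list (same names) of tibbles `gene`, `scaffold`
#'   giving each gene's location in that species' assembly.
#' @return tibble (`linkage_matrix`): `gene` plus one state column per
#'   species, states in {Z, A, U}, and a logical `classified` column.
#' @export
build_linkage_matrix <- function(classifications, placements) {
  sp <- lep_species()
  miss <- setdiff(sp, names(classifications))
  if (length(miss))
    stop("classifications missing for species: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (length(setdiff(sp, names(placements))))
    stop("placements missing for species: ",
         paste(setdiff(sp, names(placements)), collapse = ", "),
         call. = FALSE)
  genes <- sort(unique(unlist(lapply(placements[sp],
                                     function(p) p$gene))))
  out <- tibble::tibble(gene = genes)
  for (s in sp) {
    pl <- placements[[s]]
    if (anyDuplicated(pl$gene))
      stop("gene mapped to two scaffolds in ", s, ": ",
           pl$gene[duplicated(pl$gene)][1], call. = FALSE)
    cls <- classifications[[s]]
    state <- cls$label[match(pl$scaffold, cls$scaffold)]
    state[is.na(state) | !state %in% c("Z", "A")] <- "U"
    out[[s]] <- state[match(genes, pl$gene)]
    out[[s]][is.na(out[[s]])] <- "U"
  }
  out$classified <- Reduce(`&`, lapply(sp, function(s) out[[s]] != "U"))
  class(out) <- c("linkage_matrix", class(out))
  out
}

matrix_patterns <- function(mat) {
  sp <- lep_species()
  do.call(paste0, lapply(sp, function(s) mat[[s]]))
}

#' Infer ancestral Z content and per-branch gene movement
#'
#' Applies the rule set of [movement_rules()] to the classified genes of a
#' linkage matrix.
#'
#' @param mat a linkage matrix from [build_linkage_matrix()] (or any tibble
#'   with the four species state columns; a `classified` column restricts
#'   the rows used, otherwise rows with any "U" are dropped).
#' @return a `movement_summary` list: `n_classified`, `ancestral_z`,
#'   `ancestral_dn`, `onto` and `off` (named counts per branch),
#'   `unpolarized_t_only`, `pattern_counts`.
#' @export
infer_movement <- function(mat) {
  sp <- lep_species()
  if (!all(sp %in% names(mat)))
    stop("linkage matrix must have columns ",
         paste(sp, collapse = ", "), call. = FALSE)
  if ("classified" %in% names(mat)) mat <- mat[mat$classified, , drop = FALSE]
  keep <- Reduce(`&`, lapply(sp, function(s) mat[[s]] %in% c("Z", "A")))
  mat <- mat[keep, , drop = FALSE]
  pat <- matrix_patterns(mat)
  counts <- table(factor(pat, levels = movement_rules()$pattern))
  rules <- movement_rules()
  onto <- stats::setNames(numeric(length(lep_branches())), lep_branches())
  off <- stats::setNames(numeric(4), c("ditrysia_root", "bmori",
                                       "cohridella", "ndegeerella"))
  for (i in seq_len(nrow(rules))) {
    n <- counts[[rules$pattern[i]]]
    if (n == 0) next
    for (b in strsplit(rules$onto[i], ",")[[1]]) onto[b] <- onto[b] + n
    for (b in strsplit(rules$off[i], ",")[[1]]) off[b] <- off[b] + n
  }
  ancestral_patterns <- rules$pattern[rules$category == "ancestral_z"]
  anc <- sum(counts[ancestral_patterns])
  structure(list(
    n_classified = nrow(mat),
    ancestral_z = anc,
    ancestral_dn = anc + counts[["ZZZA"]],
    onto = onto, off = off,
    unpolarized_t_only = counts[["AAAZ"]],
    pattern_counts = tibble::tibble(pattern = names(counts),
                                    n = as.integer(counts))),
    class = "movement_summary")
}

#' @export
print.movement_summary <- function(x, ...) {
  arrow <- function(v) paste(sprintf("%s:%g", names(v), v), collapse = "  ")
  cat("Gene movement on (((bmori, cohridella), ndegeerella), tsylvina)\n",
      "  classified genes:           ", x$n_classified, "\n",
      "  ancestral Lepidoptera Z:    ", x$ancestral_z, "\n",
      "  Z at Ditrysia+ndegeerella:  ", x$ancestral_dn, "\n",
      "  onto-Z   ", arrow(x$onto), "\n",
      "  off-Z    ", arrow(x$off), "\n",
      "  tsylvina-only Z (unpolarized): ", x$unpolarized_t_only, "\n",
      sep = "")
  invisible(x)
}

#' Build a linkage matrix from per-pattern gene counts
#'
#' Convenience constructor: given named counts of Z/A patterns over
#' (bmori, cohridella, ndegeerella, tsylvina) -- e.g. `c(ZZZZ = 69,
#' ZZAA = 5)` -- returns a linkage matrix with that many genes per
#' pattern. Useful for realizing published category totals as inputs to
#' [infer_movement()].
#'
#' @param counts named integer vector; names are 4-letter Z/A patterns.
#' @return a linkage matrix tibble.
#' @export
linkage_from_patterns <- function(counts) {
  pats <- names(counts)
  if (any(!pats %in% movement_rules()$pattern))
    stop("unknown pattern(s): ",
         paste(setdiff(pats, movement_rules()$pattern), collapse = ", "),
         call. = FALSE)
  states <- strsplit(rep(pats, counts), "")
  mat <- tibble::tibble(gene = sprintf("gene%05d", seq_along(states)))
  for (i in seq_along(lep_species()))
    mat[[lep_species()[i]]] <- vapply(states, `[`, "", i)
  mat$classified <- TRUE
  class(mat) <- c("linkage_matrix", class(mat))
  mat
}

#' Rescale a sampled movement count to a chromosome-wide estimate
#'
#' The orthologs entering the linkage matrix are a sample of the reference
#' Z gene complement; dividing a branch's movement count by the sampling
#' fraction (sampled / annotated reference Z genes) estimates the
#' chromosome-wide number of movers.
#'
#' @param moves observed movement count on the branch (>= 0).
#' @param sampled_ref_z_genes reference Z-linked genes present in the
#'   classified sample (> 0).
#' @param annotated_ref_z_genes total annotated reference Z-linked genes
#'   (> 0).
#' @return list: `estimate` (raw), `rounded` (nearest integer),
#'   `sampling_fraction`.
#' @export
rescale_total <- function(moves, sampled_ref_z_genes,
                          annotated_ref_z_genes) {
  if (moves < 0) stop("moves must be >= 0", call. = FALSE)
  if (sampled_ref_z_genes <= 0 || annotated_ref_z_genes <= 0)
    stop("gene counts must be positive (zero sampling fraction)",
         call. = FALSE)
  frac <- sampled_ref_z_genes / annotated_ref_z_genes
  est <- moves / frac
  list(estimate = est, rounded = round(est), sampling_fraction = frac)
}

#' Compare per-branch movement rates by a chi-square contingency test
#'
#' Builds a moved / not-moved by branch contingency table and applies the
#' (uncorrected) chi-square test of homogeneity.
#'
#' @param moved named vector of movement counts per branch group.
#' @param opportunity named vector of genes at risk of moving on each
#'   branch group (same names).
#' @return tibble: `statistic`, `df`, `p_value`.
#' @export
compare_branch_rates <- function(moved, opportunity) {
  if (length(moved) < 2) stop("need >= 2 branch groups", call. = FALSE)
  if (!all(names(moved) %in% names(opportunity)))
    stop("opportunity sizes missing for some branches", call. = FALSE)
  opportunity <- opportunity[names(moved)]
  if (any(moved > opportunity))
    stop("moved count exceeds opportunity size", call. = FALSE)
  tab <- rbind(moved = moved, stayed = opportunity - moved)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (min(exp_tab) < 1)
    warning("expected cell count below 1; consider an exact test",
            call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value)
}

#' Write a movement summary as TSV plus a text tree rendering
#'
#' @param x a movement_summary.
#' @param path output TSV path.
#' @param tree_path optional path for a plain-text tree with per-branch
#'   arrow counts.
#' @export
write_movement_summary <- function(x, path, tree_path = NULL) {
  tab <- tibble::tibble(
    quantity = c("n_classified", "ancestral_z", "ancestral_dn",
                 paste0("onto_", names(x$onto)),
                 paste0("off_", names(x$off)), "unpolarized_t_only"),
    value = c(x$n_classified, x$ancestral_z, x$ancestral_dn,
              unname(x$onto), unname(x$off), x$unpolarized_t_only))
  writeLines("# zdosage movement-summary v1", path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE)
  if (!is.null(tree_path)) {
    lines <- c(
      sprintf("ancestral Z: %g   Z at Ditrysia+ndegeerella node: %g",
              x$ancestral_z, x$ancestral_dn),
      sprintf("            +-- bmori        [onto %g / off %g]",
              x$onto[["bmori"]], x$off[["bmori"]]),
      sprintf("      +-----+ ditrysia_root  [onto %g / off %g]",
              x$onto[["ditrysia_root"]], x$off[["ditrysia_root"]]),
      sprintf("      |     +-- cohridella   [onto %g / off %g]",
              x$onto[["cohridella"]], x$off[["cohridella"]]),
      sprintf("  +---+ dn_stem              [onto %g]",
              x$onto[["dn_stem"]]),
      sprintf("  |   +-- ndegeerella        [onto %g / off %g]",
              x$onto[["ndegeerella"]], x$off[["ndegeerella"]]),
      sprintf("--+-- tsylvina               [%g unpolarized Z]",
              x$unpolarized_t_only))
    writeLines(lines, tree_path)
  }
  invisible(x)
}
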