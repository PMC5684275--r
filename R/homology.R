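#' Scaffold-to-reference-chromosome assignment and Z homology tests
#'
#' Ortholog hits transfer reference chromosome identity onto assembly
#' scaffolds: best hit per gene, overlap resolution, then majority vote per
#' scaffold. Per-chromosome coverage signatures then confirm Z homology and
#' reveal neo-Z additions (autosomes fused to the Z, acquiring half-dose
#' female coverage).
#'
#' @name homology
NULL

#' Keep the best-scoring location of each gene
#'
#' Ties on score are broken deterministically: lexicographically smallest
#' scaffold id, then leftmost interval.
#'
#' @param hits hit tibble (`gene`, `scaffold`, `start`, `end`, `score`).
#' @param min_score discard hits below this mapping score first.
#' @return one row per gene.
#' @export
best_hit_per_gene <- function(hits, min_score = 50) {
  hits <- hits[hits$score >= min_score, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  o <- order(hits$gene, -hits$score, hits$scaffold, hits$start)
  hits <- hits[o, , drop = FALSE]
  hits[!duplicated(hits$gene), , drop = FALSE]
}

#' Resolve gene overlaps within scaffolds
#'
#' When genes overlap on the same scaffold by more than `max_overlap` base
#' pairs, only the highest-scoring gene is kept for that location (overlap
#' of exactly `max_overlap` keeps both). Resolution is a greedy
#' score-descending sweep: hits are admitted in decreasing score order, each
#' kept only if it overlaps every already-kept hit on its scaffold by at
#' most `max_overlap` bp.
#'
#' @param hits best-per-gene hit tibble.
#' @param max_overlap tolerated overlap in bp.
#' @return the surviving hits.
#' @export
resolve_overlaps <- function(hits, max_overlap = 20) {
  if (!nrow(hits)) return(hits)
  o <- order(hits$scaffold, -hits$score, hits$start, hits$gene)
  hits <- hits[o, , drop = FALSE]
  keep <- logical(nrow(hits))
  for (idx in split(seq_len(nrow(hits)), hits$scaffold)) {
    kept_s <- numeric(0); kept_e <- numeric(0)
    for (i in idx) {  # already score-descending within scaffold
      ov <- pmin(kept_e, hits$end[i]) - pmax(kept_s, hits$start[i])
      if (!length(ov) || all(ov <= max_overlap)) {
        keep[i] <- TRUE
        kept_s <- c(kept_s, hits$start[i]); kept_e <- c(kept_e, hits$end[i])
      }
    }
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$scaffold, out$start), , drop = FALSE]
}

#' Assign scaffolds to reference chromosomes by majority vote
#'
#' Each scaffold goes to the chromosome carrying the majority of the
#' reference genes that map to it. A tie on gene count is broken by the
#' larger sum of mapping scores; a tie on both leaves the scaffold
#' unassigned (`NA`).
#'
#' @param hits overlap-resolved hit tibble.
#' @param gene_map tibble `gene`, `chrom` (reference location of each gene).
#' @return tibble `scaffold`, `chrom` (NA = unassigned), `n_genes`,
#'   `score_sum` for the winning chromosome.
#' @export
assign_chromosome <- function(hits, gene_map) {
  h <- dplyr::inner_join(hits, gene_map[, c("gene", "chrom")], by = "gene")
  per <- dplyr::summarise(
    dplyr::group_by(h, .data$scaffold, .data$chrom),
    n_genes = dplyr::n(), score_sum = sum(.data$score), .groups = "drop")
  pick <- function(df) {
    df <- df[order(-df$n_genes, -df$score_sum, df$chrom), , drop = FALSE]
    top_n <- df$n_genes == df$n_genes[1]
    if (sum(top_n) > 1) {
      cand <- df[top_n, , drop = FALSE]
      if (sum(cand$score_sum == cand$score_sum[1]) > 1) df$chrom[1] <- NA
      else df[1, ] <- cand[1, ]
    }
    df[1, , drop = FALSE]
  }
  out <- dplyr::bind_rows(lapply(split(per, per$scaffold), pick))
  out <- out[order(out$scaffold), c("scaffold", "chrom", "n_genes",
                                    "score_sum")]
  tibble::as_tibble(out)
}

#' Per-chromosome coverage signature tests and neo-Z detection
#'
#' For every reference chromosome with at least `min_group` assigned
#' scaffolds, tests whether scaffolds mapping to the reference Z have lower
#' log2(F/M) ratios (one-tailed Wilcoxon rank-sum). A chromosome is flagged
#' neo-Z when its ratios are (a) not significantly different from the
#' reference Z (two-sided at `alpha`) and (b) significantly lower than those
#' of every unflagged autosome (one-tailed at `alpha`). P values are
#' reported raw, with a Bonferroni column for transparency.
#'
#' @param profile a `log2_profile`.
#' @param assignment scaffold -> chromosome tibble.
#' @param ref_z_id reference Z chromosome id.
#' @param alpha significance level.
#' @param min_group minimum scaffolds per chromosome; smaller groups are
#'   skipped with a warning.
#' @return tibble: `chrom`, `n`, `median_ratio`, `p_z_lower` (ref-Z lower,
#'   one-tailed), `p_vs_z_two_sided`, `p_bonferroni`, `neo_z` flag.
#' @export
test_chromosome_coverage <- function(profile, assignment, ref_z_id,
                                     alpha = 0.05, min_group = 10) {
  dat <- dplyr::inner_join(
    tibble::as_tibble(profile)[profile$finite, c("scaffold", "log2_fm")],
    assignment[!is.na(assignment$chrom), c("scaffold", "chrom")],
    by = "scaffold")
  sizes <- table(dat$chrom)
  small <- names(sizes)[sizes < min_group]
  if (length(small))
    warning("chromosome(s) skipped (fewer than ", min_group,
            " scaffolds): ", paste(small, collapse = ", "), call. = FALSE)
  dat <- dat[!dat$chrom %in% small, , drop = FALSE]
  if (!ref_z_id %in% dat$chrom)
    stop("reference Z chromosome '", ref_z_id,
         "' absent (or undersized) in the assignment", call. = FALSE)
  zr <- dat$log2_fm[dat$chrom == ref_z_id]
  chroms <- setdiff(sort(unique(dat$chrom)), ref_z_id)
  rows <- lapply(chroms, function(cc) {
    cr <- dat$log2_fm[dat$chrom == cc]
    tibble::tibble(
      chrom = cc, n = length(cr), median_ratio = stats::median(cr),
      p_z_lower = stats::wilcox.test(zr, cr, alternative = "less",
                                     exact = FALSE)$p.value,
      p_vs_z_two_sided = stats::wilcox.test(zr, cr, exact = FALSE)$p.value)
  })
  rep_tab <- dplyr::bind_rows(rows)
  rep_tab$p_bonferroni <- pmin(1, rep_tab$p_z_lower * nrow(rep_tab))
  # neo-Z: coverage indistinguishable from ref-Z, lower than all autosomes
  cand <- rep_tab$p_vs_z_two_sided >= alpha
  rep_tab$neo_z <- FALSE
  for (i in which(cand)) {
    cr <- dat$log2_fm[dat$chrom == rep_tab$chrom[i]]
    autos <- rep_tab$chrom[!cand]
    lower_all <- all(vapply(autos, function(a) {
      ar <- dat$log2_fm[dat$chrom == a]
      stats::wilcox.test(cr, ar, alternative = "less",
                         exact = FALSE)$p.value < alpha
    }, logical(1)))
    rep_tab$neo_z[i] <- length(autos) > 0 && lower_all
  }
  z_row <- tibble::tibble(chrom = ref_z_id, n = length(zr),
                          median_ratio = stats::median(zr),
                          p_z_lower = NA_real_, p_vs_z_two_sided = NA_real_,
                          p_bonferroni = NA_real_, neo_z = FALSE)
  dplyr::bind_rows(z_row, rep_tab)
}

#' Sliding-window log2(F/M) profile along a reference chromosome
#'
#' Scaffolds assigned to `chrom` are ordered by the reference position of
#' their best hit and a moving average of their ratios over consecutive
#' windows of `window` scaffolds is returned, ready for plotting.
#'
#' @param profile a `log2_profile`.
#' @param assignment scaffold -> chromosome tibble.
#' @param hits overlap-resolved hits (used to order scaffolds).
#' @param gene_map gene map with `ref_pos` column.
#' @param chrom chromosome to profile.
#' @param window scaffolds per window.
#' @return tibble `position` (scaffold order index), `scaffold`, `log2_fm`,
#'   `rolling_mean` (NA where the window is incomplete).
#' @export
sliding_profile <- function(profile, assignment, hits, gene_map, chrom,
                            window = 10) {
  scafs <- assignment$scaffold[!is.na(assignment$chrom) &
                                 assignment$chrom == chrom]
  h <- dplyr::inner_join(hits, gene_map[, c("gene", "chrom", "ref_pos")],
                         by = "gene")
  h <- h[h$scaffold %in% scafs & h$chrom == chrom, , drop = FALSE]
  pos <- dplyr::summarise(dplyr::group_by(h, .data$scaffold),
                          ref_pos = .data$ref_pos[which.max(.data$score)],
                          .groups = "drop")
  dat <- dplyr::inner_join(
    pos, tibble::as_tibble(profile)[profile$finite,
                                    c("scaffold", "log2_fm")],
    by = "scaffold")
  dat <- dat[order(dat$ref_pos, dat$scaffold), , drop = FALSE]
  n <- nrow(dat)
  if (n < window) {
    warning("fewer than ", window, " scaffolds on ", chrom,
            "; returning whole-set average", call. = FALSE)
    rm_vec <- rep(NA_real_, n)
    if (n) rm_vec[n] <- mean(dat$log2_fm)
  } else {
    rm_vec <- zoo::rollmean(dat$log2_fm, k = window, fill = NA,
                            align = "right")
  }
  tibble::tibble(position = seq_len(n), scaffold = dat$scaffold,
                 ref_pos = dat$ref_pos, log2_fm = dat$log2_fm,
                 rolling_mean = rm_vec)
}
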