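# Brute-force oracles, written independently of the package internals.

# histogram-mode oracle: equal-width bins over [min, max], argmax count,
# ties toward the bin center nearest zero
oracle_hist_mode <- function(r, n_bins) {
  r <- r[is.finite(r)]
  lo <- min(r); hi <- max(r)
  if (lo == hi) return(lo)
  w <- (hi - lo) / n_bins
  idx <- pmin(n_bins, pmax(1, ceiling((r - lo) / w)))
  idx[r == lo] <- 1
  counts <- tabulate(idx, n_bins)
  centers <- lo + (seq_len(n_bins) - 0.5) * w
  best <- which(counts == max(counts))
  centers[best[order(abs(centers[best]))[1]]]
}

# independent re-application of the three prefilter rules
oracle_prefilter <- function(ct, min_len = 1500, min_male_cov = 5, pct = 99.5) {
  sc <- ct$scaffolds
  males <- ct$samples$sample[ct$samples$sex == "male"]
  msum <- rowSums(as.matrix(sc[, males, drop = FALSE]))
  cap <- quantile(msum, pct / 100, names = FALSE)
  sc$scaffold[sc$length > min_len & msum > min_male_cov & msum < cap]
}

# exhaustive overlap resolution on small hit sets: the surviving set S is
# the unique set with no pair in S overlapping by > max_ov, and every
# excluded hit overlapping some higher-scoring member of S by > max_ov
oracle_resolve <- function(hits, max_ov = 20) {
  n <- nrow(hits)
  ov <- function(i, j)
    hits$scaffold[i] == hits$scaffold[j] &&
      (min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])) > max_ov
  for (bits in 0:(2^n - 1)) {
    s <- which(bitwAnd(bits, 2^(seq_len(n) - 1)) > 0)
    pairs_ok <- TRUE
    for (i in s) for (j in s) if (i < j && ov(i, j)) pairs_ok <- FALSE
    if (!pairs_ok) next
    excl_ok <- TRUE
    for (e in setdiff(seq_len(n), s)) {
      dominated <- any(vapply(s, function(k)
        ov(e, k) && hits$score[k] > hits$score[e], logical(1)))
      if (!dominated) excl_ok <- FALSE
    }
    if (excl_ok) return(sort(hits$gene[s]))
  }
  stop("no valid resolution found")
}

# per-gene movement oracle: textual rules applied one gene at a time
# on states ordered (bmori, cohridella, ndegeerella, tsylvina)
oracle_movement <- function(states) {
  out <- list(ancestral_z = 0, ancestral_dn = 0, unpolarized = 0,
              onto = c(dn_stem = 0, ditrysia_root = 0, bmori = 0,
                       cohridella = 0, ndegeerella = 0),
              off = c(ditrysia_root = 0, bmori = 0, cohridella = 0,
                      ndegeerella = 0))
  for (i in seq_len(nrow(states))) {
    b <- states$bmori[i]; cc <- states$cohridella[i]
    n <- states$ndegeerella[i]; t <- states$tsylvina[i]
    zs <- c(b, cc, n) == "Z"
    if (t == "Z" && any(zs)) {           # ancestral Lepidoptera Z
      out$ancestral_z <- out$ancestral_z + 1
      out$ancestral_dn <- out$ancestral_dn + 1
      if (!zs[1] && !zs[2])              # lost in both Ditrysia: one event
        out$off["ditrysia_root"] <- out$off["ditrysia_root"] + 1
      else {
        if (!zs[1]) out$off["bmori"] <- out$off["bmori"] + 1
        if (!zs[2]) out$off["cohridella"] <- out$off["cohridella"] + 1
      }
      if (!zs[3]) out$off["ndegeerella"] <- out$off["ndegeerella"] + 1
    } else if (t == "Z") {               # tsylvina only: unpolarizable
      out$unpolarized <- out$unpolarized + 1
    } else if (all(zs)) {                # gained on the Ditrysia+N stem
      out$ancestral_dn <- out$ancestral_dn + 1
      out$onto["dn_stem"] <- out$onto["dn_stem"] + 1
    } else if (zs[1] && zs[2]) {         # both Ditrysia only
      out$onto["ditrysia_root"] <- out$onto["ditrysia_root"] + 1
    } else {                             # terminal gains
      if (zs[1]) out$onto["bmori"] <- out$onto["bmori"] + 1
      if (zs[2]) out$onto["cohridella"] <- out$onto["cohridella"] + 1
      if (zs[3]) out$onto["ndegeerella"] <- out$onto["ndegeerella"] + 1
    }
  }
  out
}

# independent W-filter recount
oracle_w_filter <- function(ct, min_len, male_max, flo, fhi,
                            floor_len = 200) {
  sc <- ct$scaffolds
  males <- ct$samples$sample[ct$samples$sex == "male"]
  females <- ct$samples$sample[ct$samples$sex == "female"]
  keep <- sc$length > min_len
  for (m in males)
    keep <- keep & (if (male_max == 0) sc[[m]] == 0 else sc[[m]] < male_max)
  for (f in females) {
    med <- median(sc[[f]][sc$length >= floor_len])
    keep <- keep & sc[[f]] > flo * med & sc[[f]] < fhi * med
  }
  sort(sc$scaffold[keep])
}

# rolling mean by explicit loop
oracle_rollmean <- function(x, k) {
  out <- rep(NA_real_, length(x))
  for (i in k:length(x)) out[i] <- mean(x[(i - k + 1):i])
  out
}

# all 16 Z/A patterns over the four species
all_patterns <- function() {
  g <- expand.grid(bmori = c("Z", "A"), cohridella = c("Z", "A"),
                   ndegeerella = c("Z", "A"), tsylvina = c("Z", "A"),
                   stringsAsFactors = FALSE)
  g$gene <- sprintf("p%02d", seq_len(nrow(g)))
  tibble::as_tibble(g[, c("gene", "bmori", "cohridella", "ndegeerella",
                          "tsylvina")])
}
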