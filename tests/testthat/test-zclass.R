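test_that("autosomal mode matches a brute-force histogram argmax", {
  # point mass degenerate case
  pm <- tibble::tibble(scaffold = paste0("s", 1:50),
                       log2_fm = rep(0.31, 50), finite = TRUE)
  expect_equal(find_autosomal_mode(pm, n_bins = 10), 0.31)

  # bimodal mixture: 70% near 0, 30% near -1, at both bin resolutions
  set.seed(42)
  r <- c(rnorm(700, 0, 0.05), rnorm(300, -1, 0.05))
  prof <- tibble::tibble(scaffold = paste0("s", seq_along(r)),
                         log2_fm = r, finite = TRUE)
  for (nb in c(120, 200)) {
    got <- find_autosomal_mode(prof, n_bins = nb)
    expect_equal(got, oracle_hist_mode(r, nb))
    bin_w <- diff(range(r)) / nb
    expect_lt(abs(got), bin_w)
  }
  expect_error(find_autosomal_mode(prof[1:50, ], n_bins = 120), "too few")
})

test_that("lenient rule places boundaries in the unclassified gap", {
  # pass 1 pins down A_mode for this histogram; pass 2 adds probe
  # scaffolds at exactly the two cutoffs without changing the range,
  # so the modal bin (hence A_mode) is unchanged
  base <- c(rep(0, 200), -1.2, 0.5)
  prof1 <- tibble::tibble(scaffold = paste0("b", seq_along(base)),
                          log2_fm = base, finite = TRUE)
  a_mode <- attr(classify_lenient(prof1, lenient_config(n_bins = 10)),
                 "A_mode")
  probes <- c(z_cut = a_mode - 0.6, gap = a_mode - 0.5,
              a_cut = a_mode - 0.4, below = a_mode - 0.9,
              above = a_mode - 0.1, inf = Inf)
  prof2 <- tibble::tibble(
    scaffold = c(prof1$scaffold, names(probes)),
    log2_fm = c(base, probes), finite = is.finite(c(base, probes)))
  cls <- classify_lenient(prof2, lenient_config(n_bins = 10))
  expect_equal(attr(cls, "A_mode"), a_mode)
  lab <- setNames(cls$label, cls$scaffold)
  expect_equal(unname(lab[names(probes)]),
               c("unclassified", "unclassified", "unclassified", "Z", "A",
                 "unclassified"))
})

test_that("lenient classification is exact on a noise-free genome", {
  # no prefilter here: with zero depth noise every male sum ties the
  # percentile cap, a degenerate case the filter is not meant for
  g <- noise_free_genome(seed = 31)
  prof <- log2_fm(g$ct)
  cls <- classify_lenient(prof, lenient_config(n_bins = 120))
  truth <- g$asm$truth$class[match(cls$scaffold, g$asm$truth$scaffold)]
  expect_true(all(cls$label[truth == "Z"] == "Z"))
  expect_true(all(cls$label[truth == "A"] == "A"))
})

test_that("classification labels partition the filtered set and tightening
           the Z offset never grows the Z set", {
  cfg <- sim_config(n_scaffolds = 800, rng_seed = 8)
  asm <- simulate_assembly(cfg)
  prof <- log2_fm(prefilter_scaffolds(simulate_coverage(asm$scaffolds,
                                                        asm$truth, cfg)))
  prev_z <- NULL
  for (zo in c(0.6, 0.8, 1.0)) {
    cls <- classify_lenient(prof, lenient_config(n_bins = 120,
                                                 z_offset = zo))
    expect_equal(sum(table(cls$label)), nrow(prof))
    z <- cls$scaffold[cls$label == "Z"]
    if (!is.null(prev_z)) expect_true(all(z %in% prev_z))
    prev_z <- z
  }
})

make_assigned_genome <- function(seed, dispersion = 0.02, n_scaffolds = 2000) {
  cfg <- sim_config(n_scaffolds = n_scaffolds, depth_dispersion = dispersion,
                    rng_seed = seed)
  asm <- simulate_assembly(cfg)
  ct <- simulate_coverage(asm$scaffolds, asm$truth, cfg)
  prof <- log2_fm(prefilter_scaffolds(ct))
  oh <- simulate_ortholog_hits(asm$scaffolds, asm$truth, cfg)
  asg <- assign_chromosome(resolve_overlaps(best_hit_per_gene(oh$hits)),
                           oh$gene_map)
  list(cfg = cfg, asm = asm, ct = ct, prof = prof, asg = asg)
}

test_that("stringent cutoff calibration finds the concordance plateau", {
  # true-Z scaffolds form a tight cloud at -1, all assigned to the
  # reference Z; noise scaffolds have uniform ratios and random
  # chromosomes: the concordance curve flattens once the noise is gone,
  # and the chosen cutoff must still admit nearly all true-Z scaffolds
  set.seed(17)
  nz <- 300; nn <- 200
  prof <- tibble::tibble(
    scaffold = c(paste0("z", 1:nz), paste0("n", 1:nn)),
    log2_fm = c(rnorm(nz, -1, 0.05), runif(nn, -2, 0.5)),
    finite = TRUE)
  asg <- tibble::tibble(
    scaffold = prof$scaffold,
    chrom = c(rep("chr1", nz),
              sample(paste0("chr", 2:31), nn, replace = TRUE)))
  cut <- calibrate_stringent_cutoff(prof, asg, "chr1", start = -0.6)
  z_ratios <- prof$log2_fm[1:nz]
  expect_gte(mean(z_ratios < cut), 0.95)

  # a curve that is constant at 1.0 plateaus immediately
  nf <- noise_free_genome(seed = 32)
  prof <- log2_fm(nf$ct)
  ohn <- simulate_ortholog_hits(nf$asm$scaffolds, nf$asm$truth, nf$cfg)
  asgn <- assign_chromosome(resolve_overlaps(best_hit_per_gene(ohn$hits)),
                            ohn$gene_map)
  cut0 <- calibrate_stringent_cutoff(prof, asgn, "chr1", n_bins = 120)
  curve <- attr(cut0, "curve")
  expect_equal(as.numeric(cut0), max(curve$cutoff))
})

test_that("stringent classification nests inside lenient on clean data and
           needs low female depth for a Z call", {
  nf <- noise_free_genome(seed = 33)
  prof <- log2_fm(nf$ct)
  oh <- simulate_ortholog_hits(nf$asm$scaffolds, nf$asm$truth, nf$cfg)
  asg <- assign_chromosome(resolve_overlaps(best_hit_per_gene(oh$hits)),
                           oh$gene_map)
  len <- classify_lenient(prof, lenient_config(n_bins = 120))
  cut <- calibrate_stringent_cutoff(prof, asg, "chr1", n_bins = 120)
  str <- classify_stringent(prof, asg, "chr1",
                            stringent_config(z_cutoff = as.numeric(cut)))
  expect_true(all(str$scaffold[str$label == "Z"] %in%
                    len$scaffold[len$label == "Z"]))

  # a low-ratio scaffold whose female depth sits above the median is not Z
  prof2 <- prof
  i <- which(prof2$log2_fm < -0.9)[1]
  prof2$female_sum[i] <- max(prof2$female_sum) * 2
  str2 <- classify_stringent(prof2, asg, "chr1",
                             stringent_config(z_cutoff = as.numeric(cut)))
  expect_equal(str2$label[i], "unclassified")

  expect_error(
    classify_stringent(prof, asg[asg$chrom %in% "chr1", ], "chr1",
                       stringent_config(z_cutoff = -0.6)),
    "autosomes")
})

test_that("the unclassified fraction rises from lenient to stringent on
           noisy data", {
  g <- make_assigned_genome(seed = 19, dispersion = 0.05)
  len <- classify_lenient(g$prof, lenient_config(n_bins = 120))
  cut <- calibrate_stringent_cutoff(g$prof, g$asg, "chr1")
  str <- classify_stringent(g$prof, g$asg, "chr1",
                            stringent_config(z_cutoff = as.numeric(cut)))
  expect_gt(mean(str$label == "unclassified"),
            mean(len$label == "unclassified"))
})
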