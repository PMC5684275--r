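# shared fixture builders

# tiny hand-written coverage table: 2 males, 2 females
toy_coverage <- function() {
  coverage_table(
    tibble::tibble(
      scaffold = c("s1", "s2", "s3", "s4", "s5"),
      length = c(2000, 1200, 3000, 2500, 4000),
      m1 = c(30, 30, 2, 30, 500), m2 = c(30, 30, 2, 30, 500),
      f1 = c(30, 30, 30, 15, 500), f2 = c(30, 30, 30, 15, 500)),
    tibble::tibble(sample = c("m1", "m2", "f1", "f2"),
                   sex = c("male", "male", "female", "female")))
}

# a noise-free simulated genome plus its derived objects
noise_free_genome <- function(seed = 11, n_scaffolds = 1200,
                              neo_z = NULL, w_present = TRUE) {
  cfg <- sim_config(n_scaffolds = n_scaffolds, depth_dispersion = 0,
                    noise_outlier_fraction = 0, w_present = w_present,
                    neo_z_chrom_id = neo_z, rng_seed = seed)
  asm <- simulate_assembly(cfg)
  ct <- simulate_coverage(asm$scaffolds, asm$truth, cfg)
  list(cfg = cfg, asm = asm, ct = ct)
}

# per-species classification + placements derived directly from a truth
# table (noise-free shortcut for linkage-matrix plumbing tests)
truth_classification <- function(truth) {
  tibble::tibble(scaffold = truth$scaffold,
                 label = ifelse(truth$class %in% c("Z", "neoZ"), "Z",
                                ifelse(truth$class == "A", "A",
                                       "unclassified")))
}
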