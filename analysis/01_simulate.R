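#!/usr/bin/env Rscript
# Stage 1: simulate the focal genome under the default study conditions.
#
# One ZW species: 31 chromosomes with chr1 = Z, a W, and chr18 carrying a
# planted neo-Z fusion; 3000 scaffolds, two male and two female libraries
# at 30x, gamma depth dispersion 0.02, 1% collapsed-repeat outliers.
# Writes the coverage table, sample sheet, ortholog hits, gene map and the
# truth tables under results/sim/.

suppressPackageStartupMessages(library(zdosage))

seed <- 101L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_scaffolds = 3000, neo_z_chrom_id = "chr18",
                  rng_seed = seed)
asm <- simulate_assembly(cfg)
ct <- simulate_coverage(asm$scaffolds, asm$truth, cfg)
oh <- simulate_ortholog_hits(asm$scaffolds, asm$truth, cfg)

write_coverage_table(ct, file.path(out, "coverage.tsv"),
                     file.path(out, "samples.tsv"))
write_ortholog_hits(oh$hits, file.path(out, "hits.tsv"))
readr::write_tsv(oh$gene_map, file.path(out, "gene_map.tsv"))
readr::write_tsv(asm$truth, file.path(out, "truth_scaffolds.tsv"))
readr::write_tsv(oh$gene_truth, file.path(out, "truth_genes.tsv"))
writeLines(c("# run manifest", paste0("seed\t", seed),
             paste0("n_scaffolds\t", cfg$n_scaffolds),
             paste0("neo_z\t", cfg$neo_z_chrom_id),
             paste0("depth_mean_per_sample\t", cfg$depth_mean_per_sample),
             paste0("depth_dispersion\t", cfg$depth_dispersion)),
           file.path(out, "manifest.tsv"))

cat(sprintf("simulated %d scaffolds (%d Z, %d neo-Z, %d W) and %d genes\n",
            nrow(asm$scaffolds), sum(asm$truth$class == "Z"),
            sum(asm$truth$class == "neoZ"), sum(asm$truth$class == "W"),
            nrow(oh$gene_map)))
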