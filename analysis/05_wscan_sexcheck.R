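#!/usr/bin/env Rscript
# Stage 5: W-candidate detection on the stage-1 genome (lenient and
# stringent presets, scored against planted truth) and sex inference for
# two fresh unlabelled libraries.

suppressPackageStartupMessages(library(zdosage))

simdir <- "results/sim"
out <- "results/wscan"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ct <- read_coverage_table(file.path(simdir, "coverage.tsv"),
                          file.path(simdir, "samples.tsv"))
truth <- readr::read_tsv(file.path(simdir, "truth_scaffolds.tsv"),
                         show_col_types = FALSE)
true_w <- truth$scaffold[truth$class == "W"]

for (preset in c("lenient", "stringent")) {
  cfgw <- if (preset == "lenient") w_filter_config() else w_stringent_preset()
  cand <- detect_w_candidates(ct, cfgw)
  hit <- sum(cand$scaffold %in% true_w)
  eligible <- sum(true_w %in%
                    ct$scaffolds$scaffold[ct$scaffolds$length > cfgw$min_len])
  cat(sprintf(
    "%s preset: %d candidates; precision %.2f, recall %.2f (of %d eligible W)\n",
    preset, nrow(cand), hit / max(1, nrow(cand)), hit / max(1, eligible),
    eligible))
  readr::write_tsv(cand, file.path(out, paste0("w_candidates_",
                                               preset, ".tsv")))
}

# sex inference on two new libraries of known (but unrecorded) sex
prof <- log2_fm(prefilter_scaffolds(ct))
cls <- classify_lenient(prof, lenient_config(n_bins = 120))
cfg <- sim_config(n_scaffolds = nrow(ct$scaffolds), rng_seed = 101L)
asm <- list(scaffolds = ct$scaffolds[, c("scaffold", "length")],
            truth = truth)
for (sex in c("male", "female")) {
  smp <- simulate_sample_depth(asm$scaffolds, asm$truth, cfg, sex,
                               seed = if (sex == "male") 301 else 302)
  call <- infer_sex(smp, cls)
  cat(sex, "library -> ")
  print(call)
}
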