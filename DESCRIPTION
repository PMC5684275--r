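Package: zdosage
Title: Sex-Chromosome Identification and Z-Linked Gene Movement from
    Female-to-Male Sequencing Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coverage-based comparative genomics of female-heterogametic (ZW/Z0)
    genomes, designed around fragmented short-read assemblies of Lepidoptera.
    Classifies assembly scaffolds as Z-linked or autosomal from the log2
    female:male depth ratio by a lenient histogram-mode rule and by a stringent
    homology-calibrated rule; assigns scaffolds to reference chromosomes by
    majority vote over ortholog hits; tests chromosome-level Z homology and
    flags neo-Z additions with rank-sum tests; infers gene movement onto and
    off the Z across a fixed four-species phylogeny with sampling-fraction
    rescaling; detects candidate W-derived scaffolds from female-specific
    coverage; and infers the sex of unlabelled samples from Z versus autosomal
    depth. Includes a synthetic-genome simulator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    zoo
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
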