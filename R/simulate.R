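#' Synthetic genomes with known sex-chromosome truth
#'
#' The simulator emulates the data the pipeline consumes: a fragmented
#' assembly (log-normal scaffold lengths, 200 bp floor) partitioned among
#' chromosomes including a Z, optionally a W and a neo-Z; per-library mean
#' depths with sex-linked dosage (half-dose Z and W in females, zero-dose W
#' in males) under multiplicative gamma overdispersion; ortholog hit tables
#' tying scaffolds to reference chromosomes; and four-species linkage
#' matrices with planted movement events. Every output carries a truth
#' table so recovery can be scored exactly.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults describe a plausible lepidopteran short-read study: 31
#' chromosomes (the ancestral ditrysian karyotype), chr1 = Z with ~3.7% of
#' the genome, a W when present, two male and two female libraries at 30x
#' each (grouped ~60x per sex, matching typical study depth), gamma
#' overdispersion 0.02 (~14% depth CV per library) and 1% collapsed-repeat
#' depth outliers.
#'
#' @param n_chromosomes autosome + Z count (W is extra, when present).
#' @param z_chrom_id which chromosome is the Z.
#' @param z_fraction fraction of scaffolds/genes on the Z.
#' @param w_present simulate a W chromosome.
#' @param w_fraction fraction of scaffolds that are W-derived (if present).
#' @param neo_z_chrom_id optional autosome id fused to the Z (its scaffolds
#'   get Z-like dosage while keeping their own chromosome label).
#' @param n_scaffolds scaffold count.
#' @param length_meanlog,length_sdlog log-normal scaffold length parameters
#'   (bp); lengths are floored at 200 bp.
#' @param depth_mean_per_sample expected autosomal mean depth per library.
#' @param depth_dispersion variance of the mean-1 gamma depth multiplier;
#'   0 gives the exact noise-free limit.
#' @param noise_outlier_fraction fraction of scaffolds with collapsed-repeat
#'   depth inflation (same multiplier in every library).
#' @param n_males,n_females library counts.
#' @param mean_genes_per_scaffold Poisson mean of ortholog genes per
#'   non-W scaffold.
#' @param rng_seed integer seed; all simulation draws flow from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 31, z_chrom_id = "chr1",
                       z_fraction = 0.037, w_present = TRUE,
                       w_fraction = 0.02, neo_z_chrom_id = NULL,
                       n_scaffolds = 2000,
                       length_meanlog = log(3000), length_sdlog = 0.9,
                       depth_mean_per_sample = 30,
                       depth_dispersion = 0.02,
                       noise_outlier_fraction = 0.01,
                       n_males = 2, n_females = 2,
                       mean_genes_per_scaffold = 2,
                       rng_seed = 1L) {
  chroms <- paste0("chr", seq_len(n_chromosomes))
  if (!z_chrom_id %in% chroms)
    stop("z_chrom_id must be one of the chromosome ids", call. = FALSE)
  if (!is.null(neo_z_chrom_id) && !neo_z_chrom_id %in% setdiff(chroms, z_chrom_id))
    stop("neo_z_chrom_id must name an autosome", call. = FALSE)
  if (n_scaffolds <= 0) stop("n_scaffolds must be > 0", call. = FALSE)
  if (depth_mean_per_sample <= 0)
    stop("depth_mean_per_sample must be > 0", call. = FALSE)
  if (depth_dispersion < 0) stop("depth_dispersion must be >= 0", call. = FALSE)
  if (noise_outlier_fraction < 0 || noise_outlier_fraction >= 1)
    stop("noise_outlier_fraction must be in [0, 1)", call. = FALSE)
  if (length_sdlog < 0) stop("length_sdlog must be >= 0", call. = FALSE)
  structure(list(
    n_chromosomes = n_chromosomes, chromosomes = chroms,
    z_chrom_id = z_chrom_id, z_fraction = z_fraction,
    w_present = w_present, w_fraction = w_fraction,
    neo_z_chrom_id = neo_z_chrom_id, n_scaffolds = n_scaffolds,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    depth_mean_per_sample = depth_mean_per_sample,
    depth_dispersion = depth_dispersion,
    noise_outlier_fraction = noise_outlier_fraction,
    n_males = n_males, n_females = n_females,
    mean_genes_per_scaffold = mean_genes_per_scaffold,
    rng_seed = as.integer(rng_seed)), class = "sim_config")
}

#' Simulate a fragmented assembly with chromosome truth labels
#'
#' @param config a [sim_config()].
#' @return list: `scaffolds` (tibble `scaffold`, `length`), `truth` (tibble
#'   `scaffold`, `chrom`, `class` in {Z, A, W, neoZ}).
#' @export
simulate_assembly <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  n <- config$n_scaffolds
  chroms <- config$chromosomes
  autos <- setdiff(chroms, config$z_chrom_id)
  p <- stats::setNames(rep((1 - config$z_fraction) / length(autos),
                           length(autos)), autos)
  p[config$z_chrom_id] <- config$z_fraction
  if (config$w_present) {
    p <- p * (1 - config$w_fraction)
    p["chrW"] <- config$w_fraction
  }
  chrom <- sample(names(p), n, replace = TRUE, prob = p)
  len <- pmax(200, round(stats::rlnorm(n, config$length_meanlog,
                                       config$length_sdlog)))
  cls <- rep("A", n)
  cls[chrom == config$z_chrom_id] <- "Z"
  cls[chrom == "chrW"] <- "W"
  if (!is.null(config$neo_z_chrom_id))
    cls[chrom == config$neo_z_chrom_id] <- "neoZ"
  ids <- sprintf("scaffold%05d", seq_len(n))
  list(scaffolds = tibble::tibble(scaffold = ids, length = len),
       truth = tibble::tibble(scaffold = ids, chrom = chrom, class = cls))
}

# expected per-library depth multiplier for a scaffold class and sex
dose_factor <- function(class, sex) {
  f <- rep(1, length(class))
  fem <- sex == "female"
  if (fem) f[class %in% c("Z", "neoZ", "W")] <- 0.5
  else f[class == "W"] <- 0
  f
}

#' Simulate per-library coverage with sex-linked dosage
#'
#' Expected depth is `depth_mean_per_sample` times the copy-number dose of
#' the scaffold class in that sex (autosomes 1; Z/neo-Z and W in females
#' 1/2; W in males 0). Noise is a multiplicative gamma factor with mean 1
#' and variance `depth_dispersion` (the continuous analogue of gamma-mixed
#' overdispersed counts); at dispersion 0 depths are exact. Outlier
#' scaffolds (collapsed repeats) receive one shared inflation factor,
#' drawn uniformly in [5, 20], in every library of both sexes.
#'
#' @param scaffolds scaffold tibble from [simulate_assembly()].
#' @param truth matching truth table.
#' @param config the [sim_config()].
#' @return a [coverage_table()]; the outlier flags are attached as
#'   attribute `outliers`.
#' @export
simulate_coverage <- function(scaffolds, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(scaffolds$scaffold %in% truth$scaffold))
    stop("truth table does not cover all scaffolds", call. = FALSE)
  set.seed(config$rng_seed + 1L)
  n <- nrow(scaffolds)
  cls <- truth$class[match(scaffolds$scaffold, truth$scaffold)]
  samples <- tibble::tibble(
    sample = c(sprintf("m%d", seq_len(config$n_males)),
               sprintf("f%d", seq_len(config$n_females))),
    sex = c(rep("male", config$n_males),
            rep("female", config$n_females)))
  is_out <- stats::runif(n) < config$noise_outlier_fraction
  out_mult <- ifelse(is_out, stats::runif(n, 5, 20), 1)
  tab <- scaffolds
  for (i in seq_len(nrow(samples))) {
    mu <- config$depth_mean_per_sample *
      dose_factor(cls, samples$sex[i]) * out_mult
    if (config$depth_dispersion > 0) {
      shape <- 1 / config$depth_dispersion
      noise <- stats::rgamma(n, shape = shape, rate = shape)
      mu <- mu * noise
    }
    tab[[samples$sample[i]]] <- mu
  }
  ct <- coverage_table(tab, samples)
  attr(ct, "outliers") <- scaffolds$scaffold[is_out]
  ct
}

#' Simulate ortholog hits and a reference gene map
#'
#' Genes are placed on non-W scaffolds (the W is gene-poor) at Poisson
#' numbers per scaffold and inherit the scaffold's true chromosome as
#' their reference location; a `contamination_rate` fraction instead get a
#' random wrong reference chromosome, exercising the majority vote. Each
#' gene receives one primary hit and optionally lower-scoring decoy hits
#' on random scaffolds.
#'
#' @param scaffolds,truth from [simulate_assembly()].
#' @param config the [sim_config()].
#' @param contamination_rate fraction of genes with a wrong reference
#'   chromosome.
#' @param decoy_rate fraction of genes with an extra lower-scoring hit.
#' @return list: `hits` (tibble `gene`, `scaffold`, `start`, `end`,
#'   `score`), `gene_map` (tibble `gene`, `chrom`, `ref_pos`), `gene_truth`
#'   (tibble `gene`, `scaffold`, `chrom` - the true placement).
#' @export
simulate_ortholog_hits <- function(scaffolds, truth, config,
                                   contamination_rate = 0,
                                   decoy_rate = 0.1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 2L)
  host <- truth$class != "W"
  n_genes_per <- stats::rpois(nrow(scaffolds),
                              config$mean_genes_per_scaffold) * host
  gene_scaf <- rep(scaffolds$scaffold, n_genes_per)
  gene_len <- rep(scaffolds$length, n_genes_per)
  n_g <- length(gene_scaf)
  if (!n_g) stop("no genes simulated; raise mean_genes_per_scaffold",
                 call. = FALSE)
  genes <- sprintf("gene%05d", seq_len(n_g))
  true_chrom <- truth$chrom[match(gene_scaf, truth$scaffold)]
  map_chrom <- true_chrom
  contam <- stats::runif(n_g) < contamination_rate
  if (any(contam))
    map_chrom[contam] <- vapply(true_chrom[contam], function(cc)
      sample(setdiff(config$chromosomes, cc), 1), character(1))
  # non-overlapping placement: genes laid end to end along each scaffold
  width <- pmax(150, pmin(1500, floor(gene_len / pmax(1, rep(
    n_genes_per[n_genes_per > 0], n_genes_per[n_genes_per > 0])))))
  start <- unlist(lapply(split(width, gene_scaf), function(w)
    cumsum(c(0, utils::head(w, -1)))), use.names = FALSE)
  width <- unlist(split(width, gene_scaf), use.names = FALSE)
  gene_ord <- unlist(split(seq_len(n_g), gene_scaf), use.names = FALSE)
  hits <- tibble::tibble(
    gene = genes[gene_ord], scaffold = gene_scaf[gene_ord],
    start = start, end = start + width,
    score = round(stats::runif(n_g, 60, 2000)))
  decoy <- which(stats::runif(n_g) < decoy_rate)
  if (length(decoy)) {
    didx <- match(genes[decoy], hits$gene)
    decoys <- tibble::tibble(
      gene = hits$gene[didx],
      scaffold = sample(scaffolds$scaffold, length(decoy), replace = TRUE),
      start = 0,
      end = hits$end[didx] - hits$start[didx],
      score = pmax(50, round(hits$score[didx] *
                               stats::runif(length(decoy), 0.3, 0.9))))
    hits <- dplyr::bind_rows(hits, decoys)
  }
  ref_pos <- stats::ave(seq_len(n_g), map_chrom, FUN = seq_along) * 1e4
  list(hits = hits,
       gene_map = tibble::tibble(gene = genes, chrom = map_chrom,
                                 ref_pos = ref_pos),
       gene_truth = tibble::tibble(gene = genes, scaffold = gene_scaf,
                                   chrom = true_chrom))
}

#' Simulate the depth profile of one unlabelled library
#'
#' Draws a single library of known (but unrecorded) sex under the same
#' dosage + gamma-noise model as [simulate_coverage()]; used to exercise
#' sex inference.
#'
#' @param scaffolds,truth from [simulate_assembly()].
#' @param config the [sim_config()] (its `depth_mean_per_sample` and
#'   `depth_dispersion` apply).
#' @param sex "male" or "female".
#' @param seed integer seed for this library's draws.
#' @return tibble `scaffold`, `depth`.
#' @export
simulate_sample_depth <- function(scaffolds, truth, config,
                                  sex = c("male", "female"),
                                  seed = config$rng_seed + 10L) {
  sex <- match.arg(sex)
  set.seed(as.integer(seed))
  cls <- truth$class[match(scaffolds$scaffold, truth$scaffold)]
  mu <- config$depth_mean_per_sample * dose_factor(cls, sex)
  if (config$depth_dispersion > 0) {
    shape <- 1 / config$depth_dispersion
    mu <- mu * stats::rgamma(nrow(scaffolds), shape = shape, rate = shape)
  }
  tibble::tibble(scaffold = scaffolds$scaffold, depth = mu)
}

#' Declare planted movement events for the linkage simulator
#'
#' @param branch branch name (see [lep_branches()]).
#' @param direction "onto" or "off".
#' @param n number of genes moved.
#' @export
movement_event <- function(branch, direction = c("onto", "off"), n = 1) {
  direction <- match.arg(direction)
  if (!branch %in% lep_branches())
    stop("unknown branch: ", branch, call. = FALSE)
  if (direction == "off" && branch == "dn_stem")
    stop("an off-Z event on the dn_stem is indistinguishable from a ",
         "tsylvina-only gain and cannot be polarized", call. = FALSE)
  list(branch = branch, direction = direction, n = n)
}

#' Simulate a four-species linkage matrix with planted movement
#'
#' Genes start ancestrally Z (a `frac_ancestral_z` fraction) or autosomal;
#' each planted event moves distinct genes of the compatible ancestral
#' state (onto-Z needs an ancestrally autosomal gene, off-Z an ancestrally
#' Z one) in all species descending from its branch. In this noise-free
#' setting [infer_movement()] recovers the planted counts exactly.
#'
#' @param n_genes classified gene count.
#' @param frac_ancestral_z fraction of genes ancestrally Z-linked.
#' @param events list of [movement_event()]s.
#' @param rng_seed integer seed.
#' @return list: `matrix` (linkage matrix tibble), `truth` (tibble `gene`,
#'   `ancestral`, `branch`, `direction`; NA branch = no event).
#' @export
simulate_linkage_matrix <- function(n_genes = 4132,
                                    frac_ancestral_z = 86 / 4132,
                                    events = list(), rng_seed = 1L) {
  set.seed(as.integer(rng_seed))
  sp <- lep_species()
  genes <- sprintf("og%05d", seq_len(n_genes))
  anc <- ifelse(stats::runif(n_genes) < frac_ancestral_z, "Z", "A")
  mat <- tibble::tibble(gene = genes)
  for (s in sp) mat[[s]] <- anc
  truth <- tibble::tibble(gene = genes, ancestral = anc,
                          branch = NA_character_,
                          direction = NA_character_)
  used <- logical(n_genes)
  for (ev in events) {
    if (!ev$branch %in% lep_branches())
      stop("unknown branch: ", ev$branch, call. = FALSE)
    need_state <- if (ev$direction == "onto") "A" else "Z"
    pool <- which(!used & anc == need_state)
    if (length(pool) < ev$n)
      stop("not enough unused ancestrally-", need_state,
           " genes for event on ", ev$branch, call. = FALSE)
    sel <- pool[seq_len(ev$n)]
    used[sel] <- TRUE
    new_state <- if (ev$direction == "onto") "Z" else "A"
    for (s in branch_descendants(ev$branch)) mat[[s]][sel] <- new_state
    truth$branch[sel] <- ev$branch
    truth$direction[sel] <- ev$direction
  }
  mat$classified <- TRUE
  class(mat) <- c("linkage_matrix", class(mat))
  list(matrix = mat, truth = truth)
}

#' Write a linkage matrix as TSV
#' @param mat linkage matrix.
#' @param path output path.
#' @export
write_linkage_matrix <- function(mat, path) {
  writeLines("# zdosage linkage-matrix v1", path)
  readr::write_tsv(tibble::as_tibble(mat), path, append = TRUE,
                   col_names = TRUE)
  invisible(mat)
}
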