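test_that("every Z/A pattern maps to exactly one category and the rule
           table agrees with the per-gene oracle", {
  pats <- all_patterns()
  rules <- movement_rules()
  expect_setequal(rules$pattern,
                  apply(pats[, lep_species()], 1, paste, collapse = ""))
  # inference over the full 16-pattern matrix equals the oracle
  got <- infer_movement(pats)
  want <- oracle_movement(pats)
  expect_equal(got$ancestral_z, want$ancestral_z)
  expect_equal(got$ancestral_dn, want$ancestral_dn)
  expect_equal(unname(got$unpolarized_t_only), want$unpolarized)
  expect_equal(got$onto[names(want$onto)], want$onto)
  expect_equal(got$off[names(want$off)], want$off)
  # categories partition: every pattern contributes to exactly one bucket
  expect_equal(sum(rules$category %in%
                     c("ancestral_z", "ancestral_dn", "ditrysia_gain",
                       "terminal_gains", "unpolarized", "all_autosomal")),
               16)
})

test_that("movement inference equals the oracle on random matrices", {
  for (seed in 1:40) {
    set.seed(seed + 100)
    n <- sample(10:60, 1)
    mat <- tibble::tibble(gene = paste0("g", 1:n))
    for (s in lep_species())
      mat[[s]] <- sample(c("Z", "A"), n, TRUE, prob = c(0.3, 0.7))
    got <- infer_movement(mat)
    want <- oracle_movement(mat)
    expect_equal(got$ancestral_z, want$ancestral_z, info = seed)
    expect_equal(got$ancestral_dn, want$ancestral_dn, info = seed)
    expect_equal(got$onto[names(want$onto)], want$onto, info = seed)
    expect_equal(got$off[names(want$off)], want$off, info = seed)
  }
})

test_that("an all-autosomal matrix yields zero movement everywhere", {
  mat <- tibble::tibble(gene = paste0("g", 1:20))
  for (s in lep_species()) mat[[s]] <- "A"
  mv <- infer_movement(mat)
  expect_equal(mv$ancestral_z, 0)
  expect_equal(unname(mv$ancestral_dn), 0)
  expect_true(all(mv$onto == 0) && all(mv$off == 0))
})

test_that("linkage matrices inherit scaffold labels and drop genes
           unclassified anywhere", {
  cls_z <- tibble::tibble(scaffold = c("sZ", "sA", "sU"),
                          label = c("Z", "A", "unclassified"))
  classifications <- setNames(rep(list(cls_z), 4), lep_species())
  placements <- list(
    bmori = tibble::tibble(gene = c("g1", "g2", "g3"),
                           scaffold = c("sZ", "sU", "sA")),
    cohridella = tibble::tibble(gene = c("g1", "g2", "g3"),
                                scaffold = c("sZ", "sA", "sA")),
    ndegeerella = tibble::tibble(gene = c("g1", "g3"),
                                 scaffold = c("sZ", "sA")),
    tsylvina = tibble::tibble(gene = c("g1", "g2", "g3"),
                              scaffold = c("sZ", "sA", "sA")))
  lm <- build_linkage_matrix(classifications, placements)
  expect_equal(lm$bmori[lm$gene == "g1"], "Z")
  expect_equal(lm$classified, c(TRUE, FALSE, TRUE))   # g2 U in bmori/ndeg
  expect_equal(lm$ndegeerella[lm$gene == "g2"], "U")  # missing placement

  placements$bmori <- rbind(placements$bmori,
                            tibble::tibble(gene = "g1", scaffold = "sA"))
  expect_error(build_linkage_matrix(classifications, placements),
               "two scaffolds")
})

test_that("full synthetic pipeline: classified gene count equals the
           truth-table count of fully observed genes", {
  sp <- lep_species()
  classifications <- list(); placements <- list()
  shared_genes <- sprintf("og%03d", 1:150)
  for (i in seq_along(sp)) {
    cfg <- sim_config(n_scaffolds = 300, depth_dispersion = 0,
                      noise_outlier_fraction = 0, rng_seed = 40 + i)
    asm <- simulate_assembly(cfg)
    classifications[[sp[i]]] <- truth_classification(asm$truth)
    # place the shared ortholog set on random non-W scaffolds, with a few
    # genes missing per species
    set.seed(60 + i)
    host <- asm$truth$scaffold[asm$truth$class != "W"]
    present <- sort(sample(seq_along(shared_genes), 140))
    placements[[sp[i]]] <- tibble::tibble(
      gene = shared_genes[present],
      scaffold = sample(host, length(present), replace = TRUE))
  }
  lm <- build_linkage_matrix(classifications, placements)
  in_all <- Reduce(intersect, lapply(placements, function(p) p$gene))
  expect_equal(sum(lm$classified), length(in_all))
})

test_that("planted movement events are recovered exactly from a simulated
           linkage matrix", {
  ev <- list(movement_event("ditrysia_root", "onto", 5),
             movement_event("cohridella", "onto", 91),
             movement_event("ndegeerella", "off", 3),
             movement_event("dn_stem", "onto", 8))
  sim <- simulate_linkage_matrix(n_genes = 2000, frac_ancestral_z = 0.05,
                                 events = ev, rng_seed = 9)
  mv <- infer_movement(sim$matrix)
  expect_equal(unname(mv$onto["ditrysia_root"]), 5)
  expect_equal(unname(mv$onto["cohridella"]), 91)
  expect_equal(unname(mv$off["ndegeerella"]), 3)
  expect_equal(unname(mv$onto["dn_stem"]), 8)
  expect_equal(unname(mv$onto["bmori"]), 0)

  # no events, all genes ancestrally Z: zero movement on every branch
  null <- simulate_linkage_matrix(n_genes = 50, frac_ancestral_z = 1,
                                  rng_seed = 10)
  mv0 <- infer_movement(null$matrix)
  expect_true(all(mv0$onto == 0) && all(mv0$off == 0))
  expect_equal(mv0$ancestral_z, 50)

  expect_error(movement_event("stem_of_nowhere"), "unknown branch")
  expect_error(movement_event("dn_stem", "off"), "cannot be polarized")
})

test_that("rescaling is exact on worked examples and linear in its
           arguments", {
  r <- rescale_total(5, 86, 654)
  expect_equal(r$rounded, 38)
  expect_equal(round(100 * r$sampling_fraction), 13)
  expect_equal(rescale_total(0, 86, 654)$estimate, 0)
  expect_equal(rescale_total(10, 100, 200)$estimate, 20)
  expect_error(rescale_total(5, 0, 654), "positive")
  # linear in moves, inversely linear in the sampling fraction
  expect_equal(rescale_total(10, 86, 654)$estimate,
               2 * rescale_total(5, 86, 654)$estimate)
  expect_equal(rescale_total(5, 43, 654)$estimate,
               2 * rescale_total(5, 86, 654)$estimate)
})

test_that("branch-rate comparison reproduces the textbook chi-square", {
  even <- compare_branch_rates(c(a = 5, b = 5), c(a = 80, b = 80))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)

  got <- compare_branch_rates(c(a = 5, b = 10), c(a = 77, b = 80))
  # hand-rolled 2x2 chi-square without continuity correction
  tab <- matrix(c(5, 72, 10, 70), 2)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$statistic, sum((tab - e)^2 / e))
  expect_equal(got$df, 2 - 1)

  excess <- compare_branch_rates(c(coh = 91, rest = 5),
                                 c(coh = 4046, rest = 77 + 3978))
  expect_lt(excess$p_value, 0.05)
  expect_warning(compare_branch_rates(c(a = 0, b = 1), c(a = 30, b = 2)),
                 "exact test")
})
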