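# Forward simulator: identity cases, duplication bookkeeping, closed-form
# truth Ks, retention statistics and determinism.

test_that("a scenario without events reproduces the ancestor unchanged", {
  sc <- evolution_scenario(n_chromosomes = 2, genes_per_chromosome = 4,
                           cds_codons = 25, events = list(), seed = 7)
  sim <- simulate_scenario(sc)
  expect_named(sim$genomes, "A")
  cat <- sim$genomes$A$catalog
  expect_equal(nrow(cat), 8)
  expect_equal(cat$rank, rep(0:3, 2))
  expect_equal(nrow(sim$truth$pairs), 0)
  # valid ORFs: ATG start, no internal stop
  prot <- as.character(sim$genomes$A$proteins)
  expect_true(all(substr(prot, 1, 1) == "M"))
  expect_false(any(grepl("\\*", prot)))
})

test_that("one WGD at full retention doubles the genome with unique partners", {
  sc <- evolution_scenario(n_chromosomes = 1, genes_per_chromosome = 30,
                           cds_codons = 30,
                           events = list(wgd_event(10, "A", 1.0)),
                           synonymous_rate = 2e-9, seed = 5)
  sim <- simulate_scenario(sc)
  expect_equal(nrow(sim$genomes$A$catalog), 60)
  pr <- sim$truth$pairs
  expect_equal(nrow(pr), 30)                     # one partner per ancestral gene
  expect_equal(unique(pr$event), "w1")
  # closed-form expected Ks = 2 r t
  expect_equal(unique(pr$expected_ks), 2 * 2e-9 * 10e6)
  # duplicated chromosome appended, gene order preserved among survivors
  expect_setequal(unique(sim$genomes$A$catalog$chromosome),
                  c("chr01", "chr01.w1"))
})

test_that("fractionation keeps originals and retains duplicates binomially", {
  G <- 400; rho <- 0.7
  sc <- evolution_scenario(n_chromosomes = 2, genes_per_chromosome = G / 2,
                           cds_codons = 10,
                           events = list(wgd_event(5, "A", rho)),
                           synonymous_rate = 1e-9, seed = 11)
  sim <- simulate_scenario(sc)
  n <- nrow(sim$genomes$A$catalog)
  expect_gte(n, G)                               # originals always survive
  sigma <- sqrt(G * rho * (1 - rho))
  expect_lt(abs((n - G) - G * rho), 3 * sigma)
  # ranks stay dense per chromosome after deletions
  cat <- sim$genomes$A$catalog
  for (ch in unique(cat$chromosome))
    expect_equal(sort(cat$rank[cat$chromosome == ch]),
                 seq_len(sum(cat$chromosome == ch)) - 1L)
})

test_that("downstream Ks estimation recovers a planted 2rt = 0.40 cohort", {
  # one WGD at 40 My with r = 5e-9: truth Ks 0.40 for every pair
  sc <- evolution_scenario(n_chromosomes = 1, genes_per_chromosome = 120,
                           cds_codons = 300,
                           events = list(wgd_event(40, "A", 1.0)),
                           synonymous_rate = 5e-9, omega = 0.2, seed = 21)
  sim <- simulate_scenario(sc)
  cds <- as.character(sim$genomes$A$cds)
  pr <- sim$truth$pairs
  expect_true(all(abs(pr$expected_ks - 0.40) < 1e-12))
  ks <- vapply(seq_len(nrow(pr)), function(i) {
    ng86(cds[[pr$gene_a[i]]], cds[[pr$gene_b[i]]])$Ks
  }, numeric(1))
  expect_lt(abs(mean(ks, na.rm = TRUE) - 0.40), 0.04)
})

test_that("per-pair Ks error stays under 10% for mid-range truth Ks", {
  # truth Ks 0.60 (well inside the usable <= 1 range) at 300-codon genes
  sc <- evolution_scenario(n_chromosomes = 1, genes_per_chromosome = 200,
                           cds_codons = 300,
                           events = list(wgd_event(60, "A", 1.0)),
                           synonymous_rate = 5e-9, omega = 0.2, seed = 22)
  sim <- simulate_scenario(sc)
  cds <- as.character(sim$genomes$A$cds)
  pr <- sim$truth$pairs
  ks <- vapply(seq_len(nrow(pr)), function(i) {
    ng86(cds[[pr$gene_a[i]]], cds[[pr$gene_b[i]]])$Ks
  }, numeric(1))
  rel_err <- abs(ks - pr$expected_ks) / pr$expected_ks
  expect_lt(median(rel_err, na.rm = TRUE), 0.10)
})

test_that("simulation is deterministic given the seed", {
  sc <- polygonaceae_scenario(seed = 42, n_genes = 40, cds_codons = 20)
  s1 <- simulate_scenario(sc)
  s2 <- simulate_scenario(sc)
  expect_identical(as.character(s1$genomes$ingroup$cds),
                   as.character(s2$genomes$ingroup$cds))
  expect_identical(s1$genomes$outgroup$catalog, s2$genomes$outgroup$catalog)
})

test_that("scenario validation names the offending field", {
  expect_error(evolution_scenario(synonymous_rate = 0), "synonymous_rate")
  expect_error(evolution_scenario(omega = 2), "omega")
  expect_error(evolution_scenario(
    events = list(wgd_event(10, "A", 0))), "events")
  expect_error(evolution_scenario(
    events = list(wgd_event(10, "B", 0.5))), "events")
  expect_error(evolution_scenario(
    events = list(wgd_event(10, "A", 0.5), wgd_event(20, "A", 0.5))),
    "events")
})

test_that("LTR cohorts start identical and diverge at 2rt", {
  c0 <- simulate_ltr_cohort(5, ages_my = 0, ltr_length = 500, seed = 9)
  s <- as.character(c0$seqs)
  for (id in c0$elements$element_id)
    expect_identical(s[[paste0(id, "::5p")]], s[[paste0(id, "::3p")]])
  res0 <- ltr_ages(c0)
  expect_true(all(res0$K == 0))

  ch <- simulate_ltr_cohort(200, ages_my = 3, ltr_length = 2000,
                            rate = 1.6e-9, seed = 10)
  res <- ltr_ages(ch, rate = 1.6e-9)
  # E[K] = 2rt = 0.0096; se of the cohort mean ~ sqrt(K/L)/sqrt(n) ~ 1.6e-4
  expect_lt(abs(mean(res$K) - 0.0096), 6e-4)
  expect_equal(nrow(simulate_ltr_cohort(0, ages_my = 3)$elements), 0)
  expect_error(simulate_ltr_cohort(5, ages_my = -1), "ages")
})

test_that("metabolome simulation plants effects and is reproducible", {
  m0 <- simulate_metabolome(n_metabolites = 12, effect_log2fc = 0, seed = 2)
  expect_true(all(m0$truth$status == "ns"))
  m1 <- simulate_metabolome(n_metabolites = 12, effect_log2fc = 0, seed = 2)
  expect_identical(m0$abundance, m1$abundance)
  expect_error(simulate_metabolome(group_sizes = c(1, 3)), "group_sizes")
})
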