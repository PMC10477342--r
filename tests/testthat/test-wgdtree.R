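# Collinear groups, NJ trees and the shared-vs-independent WGD verdict.

test_that("anchor graph components form cross-species groups", {
  wa <- make_blockset("A", "A", list(list(anchors = anchors_df("A1", "A2"))))
  wb <- make_blockset("B", "B", list(list(anchors = anchors_df("B1", "B2"))))
  bt <- make_blockset("A", "B", list(list(anchors = anchors_df(c("A1", "A2"),
                                                               c("B1", "B2")))))
  groups <- extract_collinear_groups(wa, wb, bt)
  expect_length(groups, 1)
  expect_setequal(names(groups[[1]]$members), c("A1", "A2", "B1", "B2"))
  expect_equal(unname(groups[[1]]$members[c("A1", "B2")]), c("A", "B"))
})

test_that("genes without a between-species anchor are excluded", {
  wa <- make_blockset("A", "A", list(list(anchors = anchors_df(c("A1", "A3"),
                                                               c("A2", "A4")))))
  wb <- make_blockset("B", "B", list(list(anchors = anchors_df("B1", "B2"))))
  bt <- make_blockset("A", "B", list(list(anchors = anchors_df(c("A1", "A2"),
                                                               c("B1", "B2")))))
  groups <- extract_collinear_groups(wa, wb, bt)
  expect_length(groups, 1)
  expect_false(any(c("A3", "A4") %in% names(groups[[1]]$members)))
})

test_that("NJ recovers the generating topology from additive distances", {
  set.seed(701)
  for (ntax in c(4, 5)) for (rep in 1:10) {
    tr <- ape::rtree(ntax, br = function(n) runif(n, 0.2, 1))
    tr <- ape::unroot(tr)
    d <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(rec), tr)[1], 0,
                 info = paste(ntax, rep))
  }
  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))),
               "taxa")
  m <- matrix(c(0, Inf, 1, Inf, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(m), "finite")
})

test_that("monophyly of remaining same-species genes reads out the verdict", {
  species <- c(A1 = "A", A2 = "A", A3 = "A", B1 = "B", B2 = "B")
  indep <- ape::read.tree(text = "(A1,((A2,A3),(B1,B2)));")
  expect_equal(classify_wgd_topology(indep, "A1", species), "independent")
  shared <- ape::read.tree(text = "(A1,((A2,B1),(A3,B2)));")
  expect_equal(classify_wgd_topology(shared, "A1", species), "shared")
  # one remaining A gene: unresolved
  two <- ape::read.tree(text = "(A1,(A2,(B1,B2)));")
  expect_equal(classify_wgd_topology(two, "A1",
                                     c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")),
               "unresolved")
  expect_error(classify_wgd_topology(indep, "Z9", species), "not a tip")
})

test_that("verdict frequencies are deterministic given the seed", {
  species <- c(A1 = "A", A2 = "A", A3 = "A", A4 = "A", B1 = "B", B2 = "B")
  tree <- ape::read.tree(text = "(A1,((A2,(A3,A4)),(B1,B2)));")
  trees <- list(g1 = list(tree = tree, members = species, status = "ok"),
                g2 = list(tree = tree, members = species, status = "ok"))
  f1 <- shared_wgd_frequency(trees, "A", n_rootings = 3, seed = 9)
  f2 <- shared_wgd_frequency(trees, "A", n_rootings = 3, seed = 9)
  expect_identical(f1$f_independent, f2$f_independent)
  expect_equal(f1$f_independent, 1.0) # A-clade monophyletic from any rooting
})

simulate_tree_test <- function(events, seed, root = "A") {
  sc <- evolution_scenario(n_chromosomes = 2, genes_per_chromosome = 100,
                           cds_codons = 60, events = events,
                           synonymous_rate = 4.3e-9, omega = 0.2,
                           seed = seed, root_lineage = root)
  sim <- simulate_scenario(sc)
  pa <- as.character(sim$genomes$A$proteins)
  pb <- as.character(sim$genomes$B$proteins)
  cds <- c(as.character(sim$genomes$A$cds), as.character(sim$genomes$B$cds))
  wa <- detect_collinear_blocks(find_homolog_pairs(pa, pa),
                                sim$genomes$A$catalog, sim$genomes$A$catalog)
  wb <- detect_collinear_blocks(find_homolog_pairs(pb, pb),
                                sim$genomes$B$catalog, sim$genomes$B$catalog)
  bt <- detect_collinear_blocks(find_homolog_pairs(pa, pb),
                                sim$genomes$A$catalog, sim$genomes$B$catalog)
  groups <- extract_collinear_groups(wa, wb, bt)
  trees <- group_gene_trees(groups, cds)
  shared_wgd_frequency(trees, "A", n_rootings = 1, seed = seed)
}

test_that("verdict frequencies flip between shared and independent histories", {
  # both WGDs precede the species split: paralogs interleave across species
  f_shared <- simulate_tree_test(list(
    wgd_event(55.8, "A", 1.0), wgd_event(40.7, "A", 1.0),
    speciation_event(27.9, "A", "B")), seed = 81)
  expect_gt(f_shared$f_shared, f_shared$f_independent)
  expect_gte(f_shared$n_classified, 100)

  # WGDs strike each lineage separately after the split
  f_indep <- simulate_tree_test(list(
    speciation_event(60, "A", "B"),
    wgd_event(40, "A", 1.0), wgd_event(38, "B", 1.0),
    wgd_event(30, "A", 1.0), wgd_event(28, "B", 1.0)), seed = 82)
  expect_gt(f_indep$f_independent, f_indep$f_shared)
})
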