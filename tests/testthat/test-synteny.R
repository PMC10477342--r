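# Collinear chaining against exhaustive enumeration, depth profiles and
# depth ratios on truth-logged simulations.

test_that("perfect collinearity yields one forward block", {
  ga <- paste0("a", 1:6); gb <- paste0("b", 1:6)
  cat_a <- make_catalog("A", list(c1 = ga))
  cat_b <- make_catalog("B", list(c1 = gb))
  blocks <- detect_collinear_blocks(make_pairs(ga, gb), cat_a, cat_b,
                                    min_anchors = 5)
  df <- as.data.frame(blocks)
  expect_equal(nrow(df), 1)
  expect_equal(df$n_anchors, 6)
  expect_equal(df$orientation, "+")
})

test_that("a transposed gene is skipped and the chain score is optimal", {
  # gene 4 of B moved to another chromosome; remaining 5 anchors chain
  ga <- paste0("a", 1:6)
  gb <- paste0("b", 1:6)
  cat_a <- make_catalog("A", list(c1 = ga))
  cat_b <- make_catalog("B", list(c1 = gb[-4], c2 = gb[4]))
  blocks <- detect_collinear_blocks(make_pairs(ga, gb), cat_a, cat_b,
                                    min_anchors = 3, gap_penalty = 0.1,
                                    match_score = 3)
  df <- as.data.frame(blocks)
  main <- df[df$chrom_b == "c1", ]
  expect_equal(main$n_anchors, 5)
  # oracle over the 5 on-chromosome anchors (ranks 0,1,2,4,5 vs 0,1,2,3,4)
  want <- oracle_best_chain_score(c(0, 1, 2, 4, 5), c(0, 1, 2, 3, 4),
                                  max_gap = 25, gap_penalty = 0.1,
                                  match_score = 3)
  expect_equal(main$score, want)
})

test_that("chain scores equal exhaustive enumeration on random anchor sets", {
  set.seed(401)
  for (rep in 1:15) {
    n <- sample(4:9, 1)
    # catalogs assign dense 0-based ranks, so draw dense rank permutations
    ra <- sample(0:(n - 1)); rb <- sample(0:(n - 1))
    ga <- paste0("a", seq_len(n)); gb <- paste0("b", seq_len(n))
    cat_a <- make_catalog("A", list(c1 = ga[order(ra)]))
    cat_b <- make_catalog("B", list(c1 = gb[order(rb)]))
    pairs <- make_pairs(ga, gb)
    blocks <- detect_collinear_blocks(pairs, cat_a, cat_b, min_anchors = 1,
                                      max_gap = 25, gap_penalty = 0.1,
                                      match_score = 3)
    df <- as.data.frame(blocks)
    got <- max(df$score)
    want <- oracle_best_chain_score(ra, rb, 25, 0.1, 3)
    expect_equal(got, want, info = paste("rep", rep))
    # every emitted block is strictly monotone
    for (b in blocks$blocks) {
      expect_true(all(diff(b$anchors$rank_a) >= 1))
      s <- if (b$orientation == "+") 1 else -1
      expect_true(all(s * diff(b$anchors$rank_b) >= 1))
    }
  }
})

test_that("scattered non-monotone anchors yield no block", {
  ga <- paste0("a", 1:4); gb <- paste0("b", 1:4)
  cat_a <- make_catalog("A", list(c1 = ga))
  cat_b <- make_catalog("B", list(c1 = gb[c(3, 1, 4, 2)]))
  blocks <- detect_collinear_blocks(
    make_pairs(ga, gb), cat_a, cat_b, min_anchors = 5)
  expect_equal(length(blocks$blocks), 0)
})

test_that("unknown gene ids in pairs are rejected", {
  cat_a <- make_catalog("A", list(c1 = paste0("a", 1:5)))
  expect_error(detect_collinear_blocks(make_pairs("a1", "zz"), cat_a, cat_a),
               "unknown gene id")
})

test_that("depth is exactly 2 per WGD round at full retention", {
  sc <- evolution_scenario(
    n_chromosomes = 1, genes_per_chromosome = 60, cds_codons = 60,
    events = list(speciation_event(60, "in", "out"),
                  wgd_event(30, "in", 1.0)),
    synonymous_rate = 3e-9, seed = 51, root_lineage = "in")
  sim <- simulate_scenario(sc)
  pairs <- find_homolog_pairs(as.character(sim$genomes$out$proteins),
                              as.character(sim$genomes$`in`$proteins))
  blocks <- detect_collinear_blocks(pairs, sim$genomes$out$catalog,
                                    sim$genomes$`in`$catalog)
  prof_out <- synteny_depth(blocks, sim$genomes$out$catalog)
  prof_in <- synteny_depth(blocks, sim$genomes$`in`$catalog)
  expect_equal(prof_out$modal_depth, 2L)
  covered <- prof_out$depth$depth[prof_out$depth$depth >= 1]
  expect_true(all(covered == 2L))
  ratio <- depth_ratio(prof_out, prof_in)
  expect_equal(ratio$label, "1:2")
})

test_that("empty block sets give zero profiles and dot plots", {
  cat_a <- make_catalog("A", list(c1 = paste0("a", 1:5)))
  empty <- detect_collinear_blocks(make_pairs(character(0), character(0)),
                                   cat_a, cat_a)
  prof <- synteny_depth(empty, cat_a)
  expect_equal(prof$modal_depth, 0L)
  expect_equal(prof$zero_fraction, 1.0)
  dp <- dotplot_export(make_pairs(character(0), character(0)), empty,
                       cat_a, cat_a)
  expect_equal(nrow(dp), 0)
})

test_that("dot-plot export marks a perfect diagonal as one block", {
  ga <- paste0("a", 1:6); gb <- paste0("b", 1:6)
  cat_a <- make_catalog("A", list(c1 = ga))
  cat_b <- make_catalog("B", list(c1 = gb))
  pairs <- make_pairs(ga, gb)
  blocks <- detect_collinear_blocks(pairs, cat_a, cat_b, min_anchors = 5)
  dp <- dotplot_export(pairs, blocks, cat_a, cat_b)
  expect_equal(nrow(dp), 6)
  expect_equal(unique(dp$block_id), "blk0001")
  expect_true(all(dp$rank_a == dp$rank_b))
})

test_that("tandem duplicates collapse to a single anchor", {
  # a2/a3 adjacent, both matched to the same partner b2
  cat_a <- make_catalog("A", list(c1 = paste0("a", 1:6)))
  cat_b <- make_catalog("B", list(c1 = paste0("b", 1:5)))
  pairs <- make_pairs(c("a1", "a2", "a3", "a4", "a5", "a6"),
                      c("b1", "b2", "b2", "b3", "b4", "b5"))
  blocks <- detect_collinear_blocks(pairs, cat_a, cat_b, min_anchors = 3)
  expect_equal(as.data.frame(blocks)$n_anchors, 5)
})
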