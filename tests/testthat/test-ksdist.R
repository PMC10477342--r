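# Codon alignment, NG86 vs pathway-enumeration oracle, block medians,
# mixture fitting, rate correction and clock dating.

test_that("codon alignment back-translates protein gaps as triplets", {
  a <- "ATGAAACCCGGG"         # M K P G
  b <- "ATGAAAGGG"            # M K G
  al <- codon_align(a, b)
  expect_equal(nchar(al$a), nchar(al$b))
  expect_equal(sum(!al$keep), 1)
  expect_true(grepl("---", al$b))
  # identical CDS: no gaps at all
  al2 <- codon_align(a, a)
  expect_true(all(al2$keep))
  expect_error(codon_align("ATGTAAAAATGA", "ATGAAAAAATGA"), "stop")
})

test_that("NG86 matches the hand-counted third-position example", {
  e <- suppressWarnings(ng86("GGGGGGGGG", "GGAGGGGGG"))
  expect_equal(e$S, 3)
  expect_equal(e$N, 6)
  expect_equal(e$Sd, 1)
  expect_equal(e$Nd, 0)
  expect_equal(e$pS, 1 / 3)
  expect_equal(e$Ks, -0.75 * log(5 / 9), tolerance = 1e-12)
  expect_equal(e$Ka, 0)
})

test_that("NG86 counts equal the brute-force pathway oracle", {
  set.seed(501)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  for (rep in 1:40) {
    c1 <- sample(sense, 1)
    # mutate 0-3 positions, resampling when a stop appears
    repeat {
      b <- strsplit(c1, "")[[1]]
      k <- sample(0:3, 1)
      if (k > 0) for (pos in sample(1:3, k))
        b[pos] <- sample(setdiff(c("A", "C", "G", "T"), b[pos]), 1)
      c2 <- paste(b, collapse = "")
      if (gc[c2] != "*") break
    }
    # embed in a shared context so S differs between codons only via c1/c2
    ctx <- paste(sample(sense, 35, replace = TRUE), collapse = "")
    got <- suppressWarnings(ng86(paste0(ctx, c1), paste0(ctx, c2)))
    want <- oracle_ng86(paste0(ctx, c1), paste0(ctx, c2))
    expect_equal(got$S, want$S, tolerance = 1e-10, info = paste(c1, c2))
    expect_equal(got$Sd, want$Sd, tolerance = 1e-10, info = paste(c1, c2))
    expect_equal(got$Nd, want$Nd, tolerance = 1e-10, info = paste(c1, c2))
  }
})

test_that("identity gives zero and saturation invalidates the estimate", {
  cds <- random_sense_cds(40)
  e <- ng86(cds, cds)
  expect_equal(e$Ks, 0)
  expect_equal(e$Ka, 0)
  expect_true(e$valid)
  # every codon pair GGT/GGC differs synonymously: pS = 1 >= 3/4
  sat <- ng86(strrep("GGT", 40), strrep("GGC", 40))
  expect_false(sat$valid)
  expect_true(is.na(sat$Ks))
})

test_that("block medians follow the median rule and drop empty blocks", {
  expect_equal(block_median_ks(c(0.30, 0.35, 0.90)), 0.35)
  expect_equal(block_median_ks(0.42), 0.42)
  expect_true(is.na(block_median_ks(c(NA_real_, NA_real_))))
})

test_that("mixture fitting recovers a single Gaussian cohort", {
  set.seed(601)
  x <- rnorm(500, 0.40, 0.05)
  fit <- fit_ks_mixture(x, seed = 1)
  expect_equal(fit$n_components, 1L)
  expect_gt(fit$components$mean, 0.38)
  expect_lt(fit$components$mean, 0.42)
  expect_error(fit_ks_mixture(numeric(0)), "too few")
  # deterministic given the seed
  fit2 <- fit_ks_mixture(x, seed = 1)
  expect_identical(fit$components, fit2$components)
})

test_that("BIC selects one component in >= 90% of single-cohort replicates", {
  set.seed(602)
  wins <- 0
  for (rep in 1:20) {
    x <- rnorm(200, 0.40, 0.05)
    fit <- fit_ks_mixture(x, seed = rep)
    if (fit$n_components == 1) wins <- wins + 1
  }
  expect_gte(wins / 20, 0.9)
})

test_that("a two-cohort mixture agrees with an independent GMM fitter", {
  skip_if_not_installed("mclust")
  skip_if_not_installed("withr")
  withr::local_package("mclust")
  set.seed(603)
  x <- c(rnorm(250, 0.35, 0.03), rnorm(250, 0.60, 0.04))
  fit <- fit_ks_mixture(x, seed = 5)
  mc <- Mclust(x, G = 1:5, verbose = FALSE)
  expect_equal(fit$n_components, mc$G)
  expect_equal(sort(fit$components$mean), sort(unname(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("rate correction rescales peaks onto a common clock", {
  # equal ortholog peaks: identity
  same <- rate_correct(c(A = 0.5, B = 0.5), c(A = 0.4, B = 0.4))
  expect_equal(unname(same[c("A", "B")]), c(0.5, 0.5))
  # species B evolves twice as fast: both corrected peaks meet at 0.45
  corr <- rate_correct(c(A = 0.3, B = 0.6), c(A = 0.4, B = 0.8))
  expect_equal(unname(corr["A"]), 0.45)
  expect_equal(unname(corr["B"]), 0.45)
  expect_error(rate_correct(c(A = 0.3, B = 0.6), c(A = 0.4)), "ortholog")
})

test_that("WGD dating is exact clock algebra", {
  expect_equal(date_wgd(0.32, 2.5e-9)$age_my, 64.0)
  expect_equal(date_wgd(0, 2.5e-9)$age_my, 0)
  expect_error(date_wgd(0.3, 0), "rate")
  # linear in Ks, inverse in rate
  set.seed(604)
  for (rep in 1:10) {
    ks <- runif(1, 0.05, 1.5); r <- runif(1, 1e-9, 1e-8); f <- runif(1, 0.5, 3)
    expect_equal(date_wgd(f * ks, r)$age_my, f * date_wgd(ks, r)$age_my)
    expect_equal(date_wgd(ks, f * r)$age_my, date_wgd(ks, r)$age_my / f)
  }
  d <- date_wgd(0.4, 5e-9, peak_sd = 0.05)
  expect_equal(unname(d$interval_my), c(35, 45))
})

test_that("anchor Ks attaches block medians and flags saturated blocks", {
  sc <- evolution_scenario(n_chromosomes = 1, genes_per_chromosome = 40,
                           cds_codons = 80,
                           events = list(wgd_event(40, "A", 1.0)),
                           synonymous_rate = 5e-9, seed = 71)
  sim <- simulate_scenario(sc)
  prot <- as.character(sim$genomes$A$proteins)
  pairs <- find_homolog_pairs(prot, prot)
  blocks <- detect_collinear_blocks(pairs, sim$genomes$A$catalog,
                                    sim$genomes$A$catalog)
  res <- anchor_ks(blocks, as.character(sim$genomes$A$cds))
  expect_gt(nrow(res$block_ks), 0)
  med <- res$block_ks$median_ks
  expect_true(all(abs(med - 0.40) < 0.08)) # truth 2rt = 0.40 per pair
})
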