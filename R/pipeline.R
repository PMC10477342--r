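# Orchestration of the inference chains: simulate -> homology -> synteny ->
# Ks -> mixture -> gene-tree test (the WGD chain), plus the LTR clock and
# metabolite DA chains. All randomness derives from one top-level seed.

#' Run the WGD inference chain on a simulated genome set
#'
#' Detects homolog pairs between the outgroup and the duplicated ingroup and
#' within the ingroup, chains collinear blocks, computes synteny depth
#' profiles and the depth ratio, estimates per-anchor Ks, fits the
#' block-median Ks mixture, and (optionally) dates the fitted peaks.
#'
#' @param sim A `wgd_simulation` with an `ingroup` and an `outgroup` lineage
#'   (names configurable).
#' @param ingroup,outgroup Lineage names in `sim$genomes`.
#' @param min_anchors,max_gap Block-chaining parameters.
#' @param k_max,fit_range Mixture-fit parameters.
#' @param seed Seed for the mixture fit restarts.
#' @param date_rate Optional synonymous rate (per site per year) to date the
#'   fitted peaks.
#' @return List of class `wgd_inference`: homolog tables, block sets, depth
#'   profiles, `depth_ratio`, `block_ks`, `mixture`, and `dates` when
#'   `date_rate` is given.
#' @export
wgd_inference <- function(sim, ingroup = "ingroup", outgroup = "outgroup",
                          min_anchors = 5, max_gap = 25,
                          k_max = 5, fit_range = c(0.02, 2.0),
                          seed = 1L, date_rate = NULL) {
  gin <- sim$genomes[[ingroup]]; gout <- sim$genomes[[outgroup]]
  if (is.null(gin) || is.null(gout))
    stop("simulation lacks the requested lineages", call. = FALSE)
  pin <- as_aa_character(gin$proteins)
  pout <- as_aa_character(gout$proteins)

  pairs_between <- find_homolog_pairs(pout, pin)
  pairs_within <- find_homolog_pairs(pin, pin)

  blocks_between <- detect_collinear_blocks(pairs_between, gout$catalog,
                                            gin$catalog,
                                            min_anchors = min_anchors,
                                            max_gap = max_gap)
  blocks_within <- detect_collinear_blocks(pairs_within, gin$catalog,
                                           gin$catalog,
                                           min_anchors = min_anchors,
                                           max_gap = max_gap)

  prof_out <- synteny_depth(blocks_between, gout$catalog)
  prof_in <- synteny_depth(blocks_between, gin$catalog)
  ratio <- depth_ratio(prof_out, prof_in)

  ks <- anchor_ks(blocks_within, gin$cds)
  med <- ks$block_ks$median_ks[!is.na(ks$block_ks$median_ks)]
  mixture <- tryCatch(
    fit_ks_mixture(med, fit_range = fit_range, k_max = k_max,
                   seed = derive_seed(seed, "fitpeaks")),
    error = function(e) NULL)

  out <- list(pairs_between = pairs_between, pairs_within = pairs_within,
              blocks_between = blocks_between, blocks_within = blocks_within,
              profile_outgroup = prof_out, profile_ingroup = prof_in,
              depth_ratio = ratio, anchors_ks = ks$anchors,
              block_ks = ks$block_ks, mixture = mixture, seed = seed)
  if (!is.null(date_rate) && !is.null(mixture)) {
    out$dates <- lapply(seq_len(nrow(mixture$components)), function(i)
      date_wgd(mixture$components$mean[i], date_rate,
               mixture$components$sd[i]))
  }
  class(out) <- "wgd_inference"
  out
}

#' @export
print.wgd_inference <- function(x, ...) {
  cat(sprintf("wgd_inference: depth ratio %s, %d within-genome blocks\n",
              x$depth_ratio$label, length(x$blocks_within$blocks)))
  if (!is.null(x$mixture))
    cat(sprintf("Ks mixture: %d component(s) at %s\n",
                x$mixture$n_components,
                paste(sprintf("%.3f", x$mixture$components$mean),
                      collapse = ", ")))
  invisible(x)
}

#' Run the full demonstration pipeline into a directory
#'
#' Executes the three inference chains on built-in simulations — the WGD
#' chain on the double-duplication scenario, the LTR insertion clock on a
#' 3-My burst cohort, and the metabolite DA chain on a planted-effect
#' metabolome — persisting every intermediate artifact plus a manifest.
#' Identical config and seed reproduce identical outputs.
#'
#' @param outdir Output directory (created; must not require network).
#' @param seed Top-level integer seed; all stage seeds derive from it.
#' @param n_genes Ancestral gene count of the WGD simulation.
#' @param retention Per-duplicate retention.
#' @param n_ltr LTR cohort size.
#' @param quiet Suppress progress messages (written to standard error).
#' @return List with the three chains' results, invisibly.
#' @export
run_wgd_demo <- function(outdir, seed = 1L, n_genes = 1000, retention = 0.7,
                         n_ltr = 200, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  say("stage simulate: double-WGD scenario")
  scen <- polygonaceae_scenario(seed = derive_seed(seed, "simulate"),
                                n_genes = n_genes, retention = retention)
  sim <- simulate_scenario(scen)
  write_simulation(sim, file.path(outdir, "simulate"))

  say("stage wgd-chain: homology, blocks, depth, Ks, peaks")
  inf <- wgd_inference(sim, seed = derive_seed(seed, "wgd"),
                       date_rate = scen$synonymous_rate)
  wdir <- file.path(outdir, "wgd")
  dir.create(wdir, showWarnings = FALSE)
  write_pairs(inf$pairs_between, file.path(wdir, "pairs.between.tsv"))
  write_pairs(inf$pairs_within, file.path(wdir, "pairs.within.tsv"))
  write_blocks(inf$blocks_between, file.path(wdir, "blocks.between.txt"))
  write_blocks(inf$blocks_within, file.path(wdir, "blocks.within.txt"))
  write_tsv(inf$profile_outgroup$depth, file.path(wdir, "depth.outgroup.tsv"))
  write_tsv(inf$profile_ingroup$depth, file.path(wdir, "depth.ingroup.tsv"))
  write_tsv(inf$block_ks, file.path(wdir, "block_ks.tsv"))
  write_tsv(dotplot_export(inf$pairs_between, inf$blocks_between,
                           sim$genomes$outgroup$catalog,
                           sim$genomes$ingroup$catalog),
            file.path(wdir, "dotplot.tsv"))
  if (!is.null(inf$mixture))
    write_mixture_json(inf$mixture, file.path(wdir, "mixture.json"))

  say("stage ltr-chain: insertion clock")
  cohort <- simulate_ltr_cohort(n_ltr, ages_my = 3, rate = 1.6e-9,
                                seed = derive_seed(seed, "ltr"))
  ages <- ltr_ages(cohort, rate = 1.6e-9)
  hist <- burst_histogram(ages$T_my, bin_width = 0.5)
  ldir <- file.path(outdir, "ltr")
  dir.create(ldir, showWarnings = FALSE)
  write_tsv(ages, file.path(ldir, "ltr_ages.tsv"))
  write_tsv(hist$table, file.path(ldir, "burst_histogram.tsv"))

  say("stage da-chain: metabolite DA scores")
  met <- simulate_metabolome(n_metabolites = 60, n_pathways = 6,
                             effect_log2fc = rep(c(3, -3, 0), each = 20),
                             noise_sd = 0.3,
                             seed = derive_seed(seed, "metabolome"))
  calls <- call_differential(met$abundance, met$groups)
  scores <- da_score(calls)
  mdir <- file.path(outdir, "da")
  dir.create(mdir, showWarnings = FALSE)
  write_tsv(as.data.frame(calls), file.path(mdir, "metabolite_calls.tsv"))
  write_tsv(scores, file.path(mdir, "da_scores.tsv"))

  write_manifest(file.path(outdir, "manifest.json"),
                 config = list(n_genes = n_genes, retention = retention,
                               n_ltr = n_ltr),
                 seed = seed,
                 inputs = c(file.path(outdir, "simulate", "scenario.json")))

  invisible(list(wgd = inf, ltr = list(ages = ages, histogram = hist),
                 da = list(calls = calls, scores = scores)))
}
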