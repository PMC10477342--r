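# Forward-time genome-evolution simulator with known truth.
#
# A scenario is a single ancestral genome evolving forward through an ordered
# series of events (whole-genome duplications and speciations). Sequences
# accumulate codon-aware point substitutions so that a duplicate pair created
# t years ago has expected synonymous divergence 2*r*t substitutions per
# synonymous site; the truth log records exactly that closed form per pair.

#' Describe a whole-genome duplication event
#'
#' @param age_my Event age in million years before present.
#' @param lineage Label of the lineage the duplication acts on.
#' @param retention Probability that each newly created duplicate gene survives
#'   fractionation, in (0, 1]. The pre-existing copy is always kept.
#' @return A list describing the event, for [evolution_scenario()].
#' @export
wgd_event <- function(age_my, lineage, retention = 1.0) {
  list(type = "wgd", age = age_my, lineage = lineage, retention = retention)
}

#' Describe a speciation event
#'
#' @param age_my Split age in million years before present.
#' @param lineage Lineage that splits.
#' @param new_lineage Label for the newly created sister lineage.
#' @return A list describing the event, for [evolution_scenario()].
#' @export
speciation_event <- function(age_my, lineage, new_lineage) {
  list(type = "speciation", age = age_my, lineage = lineage,
       new_lineage = new_lineage)
}

#' Define a genome-evolution scenario
#'
#' The scenario fixes the ancestral genome size, the event history (ordered
#' oldest first), the neutral synonymous substitution rate and the strength of
#' purifying selection on nonsynonymous changes.
#'
#' @param n_chromosomes Number of ancestral chromosomes.
#' @param genes_per_chromosome Genes per ancestral chromosome.
#' @param cds_codons Codons per gene (including the initial ATG).
#' @param events List of [wgd_event()] / [speciation_event()] entries, ages
#'   strictly decreasing toward the present within each lineage.
#' @param synonymous_rate Synonymous substitutions per synonymous site per
#'   year (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio in `[0, 1]`.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @param root_lineage Label of the starting lineage.
#' @return An object of class `evolution_scenario`.
#' @export
evolution_scenario <- function(n_chromosomes = 5, genes_per_chromosome = 200,
                               cds_codons = 100, events = list(),
                               synonymous_rate = 4.3e-9, omega = 0.2,
                               seed = 1L, root_lineage = "A") {
  if (!is.numeric(n_chromosomes) || n_chromosomes < 1)
    stop_field("n_chromosomes", "must be a positive count")
  if (!is.numeric(genes_per_chromosome) || genes_per_chromosome < 1)
    stop_field("genes_per_chromosome", "must be a positive count")
  if (!is.numeric(cds_codons) || cds_codons < 2)
    stop_field("cds_codons", "must be at least 2")
  if (!is.numeric(synonymous_rate) || synonymous_rate <= 0)
    stop_field("synonymous_rate", "must be > 0")
  if (!is.numeric(omega) || omega < 0 || omega > 1)
    stop_field("omega", "must be in [0, 1]")

  lineages <- root_lineage
  last_age <- stats::setNames(Inf, root_lineage)
  for (k in seq_along(events)) {
    ev <- events[[k]]
    if (!is.list(ev) || is.null(ev$type) || !ev$type %in% c("wgd", "speciation"))
      stop_field("events", sprintf("event %d has no valid type", k))
    if (!is.numeric(ev$age) || ev$age <= 0)
      stop_field("events", sprintf("event %d: age must be > 0 My", k))
    if (!ev$lineage %in% lineages)
      stop_field("events", sprintf("event %d: unknown lineage '%s'", k, ev$lineage))
    if (ev$age >= last_age[[ev$lineage]])
      stop_field("events",
                 sprintf("event %d: ages must be strictly decreasing within lineage '%s'",
                         k, ev$lineage))
    if (ev$type == "wgd") {
      if (!is.numeric(ev$retention) || ev$retention <= 0 || ev$retention > 1)
        stop_field("events", sprintf("event %d: retention must be in (0, 1]", k))
      last_age[[ev$lineage]] <- ev$age
    } else {
      if (is.null(ev$new_lineage) || ev$new_lineage %in% lineages)
        stop_field("events", sprintf("event %d: new_lineage missing or duplicated", k))
      lineages <- c(lineages, ev$new_lineage)
      last_age[[ev$lineage]] <- ev$age
      last_age[[ev$new_lineage]] <- ev$age
    }
  }
  ages <- vapply(events, function(e) e$age, numeric(1))
  if (length(ages) > 1 && any(diff(ages) > 0))
    stop_field("events", "events must be ordered oldest first")

  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 genes_per_chromosome = as.integer(genes_per_chromosome),
                 cds_codons = as.integer(cds_codons),
                 events = events,
                 synonymous_rate = synonymous_rate,
                 omega = omega, seed = as.integer(seed),
                 root_lineage = root_lineage),
            class = "evolution_scenario")
}

#' The default double-WGD study scenario
#'
#' An ingroup lineage carrying two successive whole-genome duplications (55.8
#' and 40.7 My, per-duplicate retention 0.7) and an outgroup lineage, split
#' 110 My ago, with no polyploidy — the configuration under which two Ks
#' cohorts sit at 0.48 and 0.35 and the outgroup:ingroup synteny depth ratio
#' is 1:4.
#'
#' @param seed Integer seed.
#' @param n_genes Total ancestral genes (split over 5 chromosomes).
#' @param retention Per-duplicate retention probability.
#' @param cds_codons Codons per gene.
#' @return An `evolution_scenario`.
#' @export
polygonaceae_scenario <- function(seed = 1L, n_genes = 1000, retention = 0.7,
                                  cds_codons = 100) {
  n_chr <- 5L
  evolution_scenario(
    n_chromosomes = n_chr,
    genes_per_chromosome = ceiling(n_genes / n_chr),
    cds_codons = cds_codons,
    events = list(
      speciation_event(110, "ingroup", "outgroup"),
      wgd_event(55.8, "ingroup", retention),
      wgd_event(40.7, "ingroup", retention)
    ),
    synonymous_rate = 4.3e-9, omega = 0.2, seed = seed,
    root_lineage = "ingroup"
  )
}

random_cds_int <- function(n_codons) {
  sense <- sense_codons()
  picks <- c("ATG", sample(sense, n_codons - 1, replace = TRUE))
  match(strsplit(paste(picks, collapse = ""), "")[[1]], .bases) - 1L
}

int_to_dna <- function(v) paste(.bases[v + 1L], collapse = "")

# Evolve every gene of a lineage table for dt_years; candidate substitution
# count per gene is Poisson(3L * r * dt), which makes the realised synonymous
# rate r per synonymous site per year (see mutate_cds_cpp).
evolve_genes <- function(tab, dt_years, rate, omega, aa_int) {
  if (dt_years <= 0 || nrow(tab) == 0) return(tab)
  L3 <- lengths(tab$cds)
  lam <- L3 * rate * dt_years
  ncand <- stats::rpois(nrow(tab), lam)
  for (i in which(ncand > 0)) {
    res <- mutate_cds_cpp(tab$cds[[i]], ncand[i], omega, aa_int)
    tab$cds[[i]] <- res$seq
  }
  tab
}

#' Run a genome-evolution scenario
#'
#' Simulates the scenario forward in time. Each WGD duplicates every
#' chromosome (duplicates appended as new chromosomes), then deletes each
#' newly created duplicate gene independently with probability
#' 1 - retention, closing ranks; speciations copy the genome into a new
#' lineage. Sequences evolve by codon-aware point substitution throughout, so
#' a pair separated at age t has expected synonymous divergence 2*r*t.
#'
#' @param scenario An [evolution_scenario()].
#' @return A list of class `wgd_simulation` with elements `genomes` (per
#'   lineage: `catalog` data frame with genome/chromosome/rank/gene_id/strand,
#'   `cds` and `proteins` as Biostrings sets), `truth` (`genes` and `pairs`
#'   data frames; `pairs` carries the closed-form expected Ks = 2*r*t per
#'   duplicate/ortholog pair) and `scenario`.
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "evolution_scenario"))
  aa_int <- codon_aa_int()
  r <- scenario$synonymous_rate
  with_seed(scenario$seed, {
    # ancestral genome
    n_anc <- scenario$n_chromosomes * scenario$genes_per_chromosome
    anc_ids <- sprintf("g%05d", seq_len(n_anc))
    tab <- data.frame(
      chromosome = rep(sprintf("chr%02d", seq_len(scenario$n_chromosomes)),
                       each = scenario$genes_per_chromosome),
      ancestral_id = anc_ids,
      strand = sample(c("+", "-"), n_anc, replace = TRUE),
      stringsAsFactors = FALSE
    )
    tab$cds <- lapply(seq_len(n_anc), function(i) random_cds_int(scenario$cds_codons))
    tab$path <- vector("list", n_anc)
    for (i in seq_len(n_anc)) tab$path[[i]] <- character(0)

    lineages <- stats::setNames(list(tab), scenario$root_lineage)
    div_age <- matrix(0, 1, 1,
                      dimnames = list(scenario$root_lineage, scenario$root_lineage))
    event_age <- numeric(0) # named by event id

    ages <- vapply(scenario$events, function(e) e$age, numeric(1))
    prev_age <- if (length(ages)) ages[1] else 0
    n_wgd <- 0L

    advance_all <- function(lineages, dt_my) {
      if (dt_my <= 0) return(lineages)
      lapply(lineages, evolve_genes, dt_years = dt_my * 1e6, rate = r,
             omega = scenario$omega, aa_int = aa_int)
    }

    for (k in seq_along(scenario$events)) {
      ev <- scenario$events[[k]]
      lineages <- advance_all(lineages, prev_age - ev$age)
      prev_age <- ev$age
      if (ev$type == "speciation") {
        new_lab <- ev$new_lineage
        lineages[[new_lab]] <- lineages[[ev$lineage]]
        labs <- rownames(div_age)
        div_age <- rbind(cbind(div_age, div_age[, ev$lineage]),
                         c(div_age[ev$lineage, ], 0))
        rownames(div_age) <- colnames(div_age) <- c(labs, new_lab)
        div_age[new_lab, ev$lineage] <- div_age[ev$lineage, new_lab] <- ev$age
      } else {
        n_wgd <- n_wgd + 1L
        eid <- sprintf("w%d", n_wgd)
        event_age[[eid]] <- ev$age
        g <- lineages[[ev$lineage]]
        dup <- g
        dup$chromosome <- paste0(dup$chromosome, ".", eid)
        keep_orig <- rep(TRUE, nrow(g))
        keep_dup <- stats::runif(nrow(dup)) < ev$retention
        for (i in seq_len(nrow(g))) g$path[[i]] <- c(g$path[[i]], stats::setNames("0", eid))
        for (i in seq_len(nrow(dup))) dup$path[[i]] <- c(dup$path[[i]], stats::setNames("1", eid))
        merged <- rbind(g[keep_orig, ], dup[keep_dup, ])
        lineages[[ev$lineage]] <- merged
      }
    }
    lineages <- advance_all(lineages, prev_age)

    # assemble outputs
    genomes <- list()
    gene_rows <- list()
    for (lab in names(lineages)) {
      g <- lineages[[lab]]
      # ranks 0-based, dense per chromosome, in stored order
      ord <- order(g$chromosome, seq_len(nrow(g)))
      g <- g[ord, , drop = FALSE]
      rk <- stats::ave(seq_len(nrow(g)), g$chromosome, FUN = seq_along) - 1L
      path_str <- vapply(g$path, function(p)
        if (length(p) == 0) "r" else paste(p, collapse = ""), character(1))
      gene_id <- sprintf("%s_%s_%s", lab, g$ancestral_id, path_str)
      catalog <- data.frame(genome = lab, chromosome = g$chromosome,
                            rank = rk, gene_id = gene_id, strand = g$strand,
                            stringsAsFactors = FALSE)
      cds_chr <- vapply(g$cds, int_to_dna, character(1))
      names(cds_chr) <- gene_id
      cds <- Biostrings::DNAStringSet(cds_chr)
      proteins <- Biostrings::translate(cds)
      origin <- vapply(g$path, function(p) {
        ones <- names(p)[p == "1"]
        if (length(ones) == 0) "ancestral" else ones[length(ones)]
      }, character(1))
      gene_rows[[lab]] <- data.frame(
        gene_id = gene_id, lineage = lab, ancestral_id = g$ancestral_id,
        duplicate_path = path_str, origin_event = origin,
        stringsAsFactors = FALSE)
      gene_rows[[lab]]$.path <- g$path
      genomes[[lab]] <- list(catalog = catalog, cds = cds, proteins = proteins)
    }
    genes_df <- do.call(rbind, gene_rows)
    rownames(genes_df) <- NULL

    pairs_df <- truth_pairs(genes_df, div_age, event_age, r)
    genes_out <- genes_df[, setdiff(names(genes_df), ".path")]

    structure(list(genomes = genomes,
                   truth = list(genes = genes_out, pairs = pairs_df,
                                event_age = event_age),
                   scenario = scenario),
              class = "wgd_simulation")
  })
}

# Closed-form truth: for every pair of genes sharing an ancestral gene, the
# divergence event is the oldest event at which their copy paths differ, else
# the lineage split; expected Ks = 2 * r * age_years.
truth_pairs <- function(genes_df, div_age, event_age, rate) {
  out <- list()
  by_anc <- split(seq_len(nrow(genes_df)), genes_df$ancestral_id)
  ev_order <- names(sort(event_age, decreasing = TRUE))
  for (idx in by_anc) {
    if (length(idx) < 2) next
    for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1):length(idx)) {
      i <- idx[a]; j <- idx[b]
      pi <- genes_df$.path[[i]]; pj <- genes_df$.path[[j]]
      li <- genes_df$lineage[i]; lj <- genes_df$lineage[j]
      shared <- intersect(names(pi), names(pj))
      shared <- ev_order[ev_order %in% shared]
      ev <- NA_character_; age <- NA_real_
      for (e in shared) if (pi[[e]] != pj[[e]]) { ev <- e; age <- event_age[[e]]; break }
      if (is.na(age)) {
        if (li == lj) next # same gene lineage path, shouldn't happen
        ev <- "speciation"; age <- div_age[li, lj]
      } else if (li != lj) {
        # paths differ at a WGD older than the split only if that WGD predates it
        split_age <- div_age[li, lj]
        if (age < split_age) { ev <- "speciation"; age <- split_age }
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_a = genes_df$gene_id[i], gene_b = genes_df$gene_id[j],
        lineage_a = li, lineage_b = lj, event = ev, age_my = age,
        expected_ks = 2 * rate * age * 1e6, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      lineage_a = character(0), lineage_b = character(0),
                      event = character(0), age_my = numeric(0),
                      expected_ks = numeric(0)))
  do.call(rbind, out)
}

#' Simulate a cohort of LTR retrotransposon pairs
#'
#' Each element's 5' and 3' LTR start identical (the state at insertion) and
#' then accumulate substitutions independently at `rate` per site per year, so
#' the expected pairwise divergence of an element of age t My is 2*r*t*1e6.
#'
#' @param n Number of elements.
#' @param ages_my Insertion ages in My (length 1 or `n`).
#' @param ltr_length LTR length in bp.
#' @param rate Substitutions per site per year.
#' @param seed Integer seed.
#' @return A list of class `ltr_cohort`: `elements` data frame (element_id,
#'   true_age_my) and `seqs`, a DNAStringSet with two records per element named
#'   `<id>::5p` / `<id>::3p`.
#' @export
simulate_ltr_cohort <- function(n, ages_my, ltr_length = 2000, rate = 1.6e-9,
                                seed = 1L) {
  if (any(ages_my < 0)) stop_field("ages_my", "ages must be >= 0")
  if (ltr_length <= 0) stop_field("ltr_length", "must be > 0")
  if (rate <= 0) stop_field("rate", "must be > 0")
  n <- as.integer(n)
  ages <- rep_len(ages_my, max(n, 1L))
  with_seed(seed, {
    ids <- sprintf("ltr%04d", seq_len(n))
    seqs <- character(2 * n)
    nm <- character(2 * n)
    for (i in seq_len(n)) {
      anc <- sample(.bases, ltr_length, replace = TRUE)
      t_yr <- ages[i] * 1e6
      for (side in 1:2) {
        s <- anc
        nsub <- stats::rpois(1, ltr_length * rate * t_yr)
        if (nsub > 0) {
          pos <- sample.int(ltr_length, nsub, replace = TRUE)
          for (p in pos) s[p] <- sample(setdiff(.bases, s[p]), 1)
        }
        k <- 2 * (i - 1) + side
        seqs[k] <- paste(s, collapse = "")
        nm[k] <- paste0(ids[i], ifelse(side == 1, "::5p", "::3p"))
      }
    }
    seqset <- Biostrings::DNAStringSet(stats::setNames(seqs, nm))
    structure(list(elements = data.frame(element_id = ids,
                                         true_age_my = ages[seq_len(n)],
                                         stringsAsFactors = FALSE),
                   seqs = seqset),
              class = "ltr_cohort")
  })
}

#' Simulate a grouped metabolite abundance table with planted effects
#'
#' Abundances are log-normal: log2 values are a per-metabolite baseline plus a
#' planted group effect (`effect_log2fc`, applied to the second group) plus
#' Gaussian noise. The planted truth status is `up`/`down` when the planted
#' |log2FC| reaches 1 (fold change 2), else `ns`.
#'
#' @param n_metabolites Number of metabolites.
#' @param n_pathways Number of pathways (metabolites assigned round-robin).
#' @param group_sizes Named or unnamed length-2 vector of replicates per
#'   group, each >= 2.
#' @param effect_log2fc Planted log2 fold change (second group over first),
#'   recycled to `n_metabolites`.
#' @param noise_sd Replicate noise sd on the log2 scale.
#' @param seed Integer seed.
#' @return A list of class `metabolome_sim`: `abundance` (metabolite, pathway,
#'   one column per sample, linear scale), `groups` (named character vector
#'   sample -> group) and `truth` (metabolite, effect_log2fc, status).
#' @export
simulate_metabolome <- function(n_metabolites = 60, n_pathways = 6,
                                group_sizes = c(summer = 3, winter = 3),
                                effect_log2fc = 0, noise_sd = 0.3, seed = 1L) {
  if (length(group_sizes) != 2 || any(group_sizes < 2))
    stop_field("group_sizes", "two groups with >= 2 replicates each are required")
  gnames <- names(group_sizes) %||% c("group1", "group2")
  if (is.null(names(group_sizes))) names(group_sizes) <- gnames
  eff <- rep_len(effect_log2fc, n_metabolites)
  with_seed(seed, {
    met <- sprintf("m%03d", seq_len(n_metabolites))
    pw <- sprintf("pw%02d", rep_len(seq_len(n_pathways), n_metabolites))
    samples <- unlist(lapply(seq_along(group_sizes), function(g)
      paste0(names(group_sizes)[g], "_", seq_len(group_sizes[g]))))
    groups <- stats::setNames(rep(names(group_sizes), group_sizes), samples)
    base <- stats::runif(n_metabolites, 14, 24)
    m <- matrix(NA_real_, n_metabolites, length(samples),
                dimnames = list(met, samples))
    for (j in seq_along(samples)) {
      shift <- if (groups[j] == names(group_sizes)[2]) eff else 0
      m[, j] <- 2^(base + shift + stats::rnorm(n_metabolites, 0, noise_sd))
    }
    status <- ifelse(eff >= 1, "up", ifelse(eff <= -1, "down", "ns"))
    ab <- data.frame(metabolite = met, pathway = pw, stringsAsFactors = FALSE)
    ab <- cbind(ab, as.data.frame(m))
    rownames(ab) <- NULL
    structure(list(abundance = ab, groups = groups,
                   truth = data.frame(metabolite = met, effect_log2fc = eff,
                                      status = status, stringsAsFactors = FALSE)),
              class = "metabolome_sim")
  })
}
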