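# Shared-vs-independent WGD test: collinear gene groups across two species,
# neighbour-joining gene trees on K2P distances, random rooting on one
# species' gene, and a monophyly verdict for that species' remaining
# paralogs. Interleaved paralogs indicate duplications predating the species
# split; a clean species clade indicates independent events.

#' Extract collinear gene groups spanning two species
#'
#' Builds the anchor graph from within-species and between-species collinear
#' blocks, keeps only genes incident to at least one between-species anchor,
#' and returns its connected components. Groups exceeding
#' `max_copies_per_species` members in either species are flagged unresolved.
#'
#' @param within_a,within_b `collinear_blocks` from each species' self
#'   comparison.
#' @param between `collinear_blocks` from the cross-species comparison.
#' @param max_copies_per_species Expected maximum copies per species
#'   (2^number of assumed WGDs; default 4).
#' @return List of groups, each with `group_id`, `members` (named character
#'   vector gene -> species), `n_per_species`, `overflow` flag.
#' @export
extract_collinear_groups <- function(within_a, within_b, between,
                                     max_copies_per_species = 4) {
  edge_df <- function(bset) {
    if (length(bset$blocks) == 0)
      return(data.frame(from = character(0), to = character(0)))
    do.call(rbind, lapply(bset$blocks, function(b)
      data.frame(from = b$anchors$gene_a, to = b$anchors$gene_b,
                 stringsAsFactors = FALSE)))
  }
  tag <- function(bset, ga, gb) {
    e <- edge_df(bset)
    if (nrow(e) == 0) return(character(0))
    stats::setNames(c(rep(ga, nrow(e)), rep(gb, nrow(e))), c(e$from, e$to))
  }
  sp <- c(tag(within_a, within_a$genome_a, within_a$genome_b),
          tag(within_b, within_b$genome_a, within_b$genome_b),
          tag(between, between$genome_a, between$genome_b))
  sp <- sp[!duplicated(names(sp))]
  eb <- edge_df(between)
  if (nrow(eb) == 0) return(list())
  linked <- unique(c(eb$from, eb$to))
  edges <- rbind(edge_df(within_a), edge_df(within_b), eb)
  conflicting <- intersect(
    unique(c(edge_df(within_a)$from, edge_df(within_a)$to)),
    unique(c(edge_df(within_b)$from, edge_df(within_b)$to)))
  if (length(conflicting))
    stop(sprintf("gene id '%s' appears in both species' within-blocks",
                 conflicting[1]), call. = FALSE)
  edges <- edges[edges$from %in% linked & edges$to %in% linked, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = linked))
  comp <- igraph::components(g)
  groups <- list()
  for (ci in seq_len(comp$no)) {
    mem <- names(comp$membership)[comp$membership == ci]
    msp <- sp[mem]
    counts <- table(factor(msp, levels = unique(sp)))
    if (sum(counts >= 1) < 2) next       # need both species represented
    if (!any(counts >= 2)) next          # need >= 2 members in one species
    gid <- sprintf("grp%04d", length(groups) + 1L)
    groups[[length(groups) + 1L]] <- list(
      group_id = gid,
      members = stats::setNames(as.character(msp), mem),
      n_per_species = counts,
      overflow = any(counts > max_copies_per_species))
  }
  groups
}

#' Neighbour-joining tree from a distance matrix
#'
#' Thin wrapper over [ape::nj()] with negative branch lengths clamped to zero
#' and taxa ordered by label for deterministic tie-breaking.
#'
#' @param d Symmetric numeric matrix with taxon dimnames, >= 3 taxa, finite.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbour-joining needs >= 3 taxa", call. = FALSE)
  if (any(!is.finite(d)))
    stop("distance matrix contains non-finite entries", call. = FALSE)
  o <- order(rownames(d))
  d <- d[o, o]
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Pairwise K2P distance matrix over a gene group
#'
#' Distances come from [k2p_distance()] on codon alignments of the members'
#' CDS (protein-guided when lengths differ). Saturated pairs give `Inf`.
#'
#' @param members Gene ids.
#' @param cds Named CDS set covering all members.
#' @return Symmetric matrix of K2P distances.
#' @export
group_distance_matrix <- function(members, cds) {
  cds <- as_dna_character(cds, "cds")
  n <- length(members)
  d <- matrix(0, n, n, dimnames = list(members, members))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- cds[[members[i]]]; sb <- cds[[members[j]]]
    if (nchar(sa) != nchar(sb)) {
      al <- codon_align(sa, sb)
      keep3 <- rep(al$keep, each = 3)
      va <- strsplit(al$a, "")[[1]][keep3]
      vb <- strsplit(al$b, "")[[1]][keep3]
      sa <- paste(va, collapse = ""); sb <- paste(vb, collapse = "")
    }
    k <- k2p_distance(sa, sb)
    d[i, j] <- d[j, i] <- if (isTRUE(k$valid)) k$K else Inf
  }
  d
}

#' Root a gene tree on one gene and test whether the species' copies separate
#'
#' The tree is rooted on the pendant edge of `rooting_gene` (a gene of the
#' focal species). The verdict is `"independent"` when the two species'
#' copies cluster apart — operationally, when the other species' genes form
#' a monophyletic clade in the rooted tree, which is exactly the unrooted
#' monophyly of the focal species' copy set. Duplications confined to each
#' lineage (after the species split) produce this separation; duplications
#' predating the split pair orthologs across species, interleaving the two
#' species' copies, and yield `"shared"`. Returns `"unresolved"` when fewer
#' than 2 focal-species genes remain after rooting or the other species has
#' fewer than 2 copies (a single foreign tip is trivially a clade and
#' carries no signal).
#'
#' @param tree An [ape::phylo] gene tree whose tips are group members.
#' @param rooting_gene Tip used as root (a member of the focal species).
#' @param species Named character vector tip -> species label.
#' @return `"independent"`, `"shared"` or `"unresolved"`.
#' @export
classify_wgd_topology <- function(tree, rooting_gene, species) {
  if (!rooting_gene %in% tree$tip.label)
    stop(sprintf("rooting gene '%s' is not a tip of the tree", rooting_gene),
         call. = FALSE)
  focal <- species[[rooting_gene]]
  rest <- setdiff(tree$tip.label, rooting_gene)
  same <- rest[species[rest] == focal]
  other <- rest[species[rest] != focal]
  if (length(same) < 2 || length(other) < 2) return("unresolved")
  rooted <- ape::root(tree, outgroup = rooting_gene, resolve.root = TRUE)
  if (ape::is.monophyletic(rooted, other)) "independent" else "shared"
}

#' Build NJ gene trees for collinear groups
#'
#' @param groups Output of [extract_collinear_groups()].
#' @param cds Named CDS set covering all group members.
#' @return Named list (by group id) of lists: `tree` ([ape::phylo] or `NULL`
#'   when the group is overflowing/saturated/too small), `members`, `status`.
#' @export
group_gene_trees <- function(groups, cds) {
  out <- list()
  for (g in groups) {
    rec <- list(tree = NULL, members = g$members, status = "ok")
    if (isTRUE(g$overflow)) {
      rec$status <- "overflow"
    } else if (length(g$members) < 3) {
      rec$status <- "too_small"
    } else {
      d <- group_distance_matrix(names(g$members), cds)
      if (any(!is.finite(d[upper.tri(d)]))) {
        rec$status <- "saturated"
      } else {
        rec$tree <- nj_tree(d)
      }
    }
    out[[g$group_id]] <- rec
  }
  out
}

#' Frequencies of gene trees supporting shared vs independent WGDs
#'
#' For each group tree, draws `n_rootings` rooting genes uniformly from the
#' focal species (seeded), classifies each rooted tree with
#' [classify_wgd_topology()], and takes the majority verdict (ties ->
#' unresolved). Frequencies are reported over classifiable groups;
#' `f_unresolved` is the share of all groups that could not be classified.
#'
#' @param trees Output of [group_gene_trees()].
#' @param focal_species Species whose genes are used for rooting and tested
#'   for monophyly.
#' @param n_rootings Rootings per group (majority vote).
#' @param seed Integer seed.
#' @return List of class `wgd_tree_test`: `f_shared`, `f_independent`,
#'   `f_unresolved`, `n_classified`, `n_groups`, `verdicts` data frame,
#'   `seed`.
#' @export
shared_wgd_frequency <- function(trees, focal_species, n_rootings = 1,
                                 seed = 1L) {
  if (length(trees) == 0) stop("no groups to classify", call. = FALSE)
  with_seed(seed, {
    verdicts <- character(length(trees))
    for (k in seq_along(trees)) {
      rec <- trees[[k]]
      if (is.null(rec$tree)) { verdicts[k] <- "unresolved"; next }
      focal_genes <- names(rec$members)[rec$members == focal_species]
      focal_genes <- intersect(focal_genes, rec$tree$tip.label)
      if (length(focal_genes) < 3) { verdicts[k] <- "unresolved"; next }
      draws <- sample(focal_genes, n_rootings, replace = TRUE)
      vs <- vapply(draws, function(rg)
        classify_wgd_topology(rec$tree, rg, rec$members), character(1))
      vs <- vs[vs != "unresolved"]
      if (length(vs) == 0) { verdicts[k] <- "unresolved"; next }
      tab <- table(vs)
      top <- names(tab)[tab == max(tab)]
      verdicts[k] <- if (length(top) == 1) top else "unresolved"
    }
    classified <- verdicts[verdicts != "unresolved"]
    if (length(classified) == 0)
      stop("no classifiable groups", call. = FALSE)
    structure(list(
      f_shared = mean(classified == "shared"),
      f_independent = mean(classified == "independent"),
      f_unresolved = mean(verdicts == "unresolved"),
      n_classified = length(classified),
      n_groups = length(verdicts),
      verdicts = data.frame(group_id = names(trees), verdict = verdicts,
                            stringsAsFactors = FALSE),
      seed = seed),
      class = "wgd_tree_test")
  })
}
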