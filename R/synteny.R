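# Collinear-block detection by monotone chaining in gene-rank space, plus
# synteny-depth profiles and depth ratios against an outgroup — the dot-plot
# evidence used to read off polyploidy level.

catalog_lookup <- function(catalog) {
  stats::setNames(seq_len(nrow(catalog)), catalog$gene_id)
}

#' Detect collinear blocks between two gene catalogs
#'
#' Homolog pairs are placed in gene-rank space (0-based rank per chromosome)
#' and chained per chromosome pair by dynamic programming: a chain is strictly
#' monotone in both genomes (increasing/increasing = `+`, increasing/
#' decreasing = `-`), consecutive anchors may skip at most `max_gap` ranks on
#' either side, and the chain score is `match_score` per anchor minus
#' `gap_penalty` per skipped rank. Chains are extracted greedily by descending
#' score, each anchor joining at most one block; chains shorter than
#' `min_anchors` are discarded. Tandem duplicates (adjacent ranks sharing a
#' partner) are collapsed to a single anchor first. For a self-comparison the
#' trivial diagonal (self-pairs) is excluded.
#'
#' @param pairs Data frame of homolog pairs (gene_a, gene_b), e.g. from
#'   [find_homolog_pairs()].
#' @param catalog_a,catalog_b Gene catalogs (genome, chromosome, rank,
#'   gene_id, strand). Pass the same catalog twice for a self-comparison.
#' @param min_anchors Minimum anchors per reported block.
#' @param max_gap Maximum rank gap between consecutive anchors (both sides).
#' @param gap_penalty Score penalty per skipped rank.
#' @param match_score Score per chained anchor.
#' @return Object of class `collinear_blocks`: list with `blocks` (list of
#'   per-block records carrying chrom pair, orientation, score, n_anchors and
#'   an anchor data frame) and the genome labels.
#' @export
detect_collinear_blocks <- function(pairs, catalog_a, catalog_b = catalog_a,
                                    min_anchors = 5, max_gap = 25,
                                    gap_penalty = 0.1, match_score = 3) {
  la <- catalog_lookup(catalog_a); lb <- catalog_lookup(catalog_b)
  self <- identical(catalog_a, catalog_b)
  if (nrow(pairs) > 0) {
    unknown <- c(setdiff(pairs$gene_a, c(names(la), names(lb))),
                 setdiff(pairs$gene_b, c(names(la), names(lb))))
    if (length(unknown))
      stop(sprintf("unknown gene id in pairs: %s", unknown[1]), call. = FALSE)
  }
  anchors <- build_anchors(pairs, catalog_a, catalog_b, la, lb, self)
  blocks <- list()
  bid <- 0L
  if (nrow(anchors) > 0) {
    anchors <- collapse_tandems(anchors)
    key <- paste(anchors$chrom_a, anchors$chrom_b, sep = "\r")
    for (cp in unique(key)) {
      sub <- anchors[key == cp, , drop = FALSE]
      repeat {
        if (nrow(sub) < min_anchors) break
        ch_p <- best_chain(sub$rank_a, sub$rank_b, +1L, max_gap, gap_penalty, match_score)
        ch_m <- best_chain(sub$rank_a, sub$rank_b, -1L, max_gap, gap_penalty, match_score)
        use_p <- ch_p$score >= ch_m$score
        ch <- if (use_p) ch_p else ch_m
        if (length(ch$idx) == 0) break
        if (length(ch$idx) < min_anchors) {
          # sub-threshold chain: consume its anchors without emitting a block
          sub <- sub[-ch$idx, , drop = FALSE]
          next
        }
        bid <- bid + 1L
        sel <- sub[ch$idx, , drop = FALSE]
        blocks[[bid]] <- list(
          block_id = sprintf("blk%04d", bid),
          genome_a = catalog_a$genome[1], genome_b = catalog_b$genome[1],
          chrom_a = sel$chrom_a[1], chrom_b = sel$chrom_b[1],
          orientation = if (use_p) "+" else "-",
          score = ch$score, n_anchors = nrow(sel),
          anchors = sel[, c("gene_a", "gene_b", "rank_a", "rank_b")],
          median_ks = NA_real_)
        sub <- sub[-ch$idx, , drop = FALSE]
      }
    }
  }
  structure(list(blocks = blocks,
                 genome_a = catalog_a$genome[1],
                 genome_b = catalog_b$genome[1],
                 params = list(min_anchors = min_anchors, max_gap = max_gap,
                               gap_penalty = gap_penalty,
                               match_score = match_score)),
            class = "collinear_blocks")
}

build_anchors <- function(pairs, catalog_a, catalog_b, la, lb, self) {
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      chrom_a = character(0), chrom_b = character(0),
                      rank_a = integer(0), rank_b = integer(0))
  if (nrow(pairs) == 0) return(empty)
  p <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
  # orient each pair so gene_a lives in catalog_a
  in_a <- p$gene_a %in% names(la) & p$gene_b %in% names(lb)
  swap <- !in_a & p$gene_b %in% names(la) & p$gene_a %in% names(lb)
  tmp <- p$gene_a[swap]; p$gene_a[swap] <- p$gene_b[swap]; p$gene_b[swap] <- tmp
  p <- p[p$gene_a %in% names(la) & p$gene_b %in% names(lb), , drop = FALSE]
  if (nrow(p) == 0) return(empty)
  ia <- la[p$gene_a]; ib <- lb[p$gene_b]
  a <- data.frame(gene_a = p$gene_a, gene_b = p$gene_b,
                  chrom_a = catalog_a$chromosome[ia],
                  chrom_b = catalog_b$chromosome[ib],
                  rank_a = catalog_a$rank[ia], rank_b = catalog_b$rank[ib],
                  stringsAsFactors = FALSE)
  if (self) {
    # one canonical copy per unordered pair: lower (chrom, rank) on side a
    flip <- a$chrom_a > a$chrom_b |
      (a$chrom_a == a$chrom_b & a$rank_a > a$rank_b)
    if (any(flip)) {
      a[flip, c("gene_a", "gene_b")] <- a[flip, c("gene_b", "gene_a")]
      a[flip, c("chrom_a", "chrom_b")] <- a[flip, c("chrom_b", "chrom_a")]
      a[flip, c("rank_a", "rank_b")] <- a[flip, c("rank_b", "rank_a")]
    }
    a <- a[!duplicated(paste(a$gene_a, a$gene_b)), , drop = FALSE]
  }
  a
}

collapse_tandems <- function(a) {
  # adjacent ranks on one side sharing the partner gene on the other
  o <- order(a$chrom_a, a$gene_b, a$rank_a)
  a <- a[o, , drop = FALSE]
  drop1 <- c(FALSE, a$gene_b[-1] == a$gene_b[-nrow(a)] &
               a$chrom_a[-1] == a$chrom_a[-nrow(a)] &
               diff(a$rank_a) == 1)
  a <- a[!drop1, , drop = FALSE]
  o <- order(a$chrom_b, a$gene_a, a$rank_b)
  a <- a[o, , drop = FALSE]
  drop2 <- c(FALSE, a$gene_a[-1] == a$gene_a[-nrow(a)] &
               a$chrom_b[-1] == a$chrom_b[-nrow(a)] &
               diff(a$rank_b) == 1)
  a[!drop2, , drop = FALSE]
}

# Highest-scoring strictly monotone chain (direction +1/-1 on side b) under a
# per-skipped-rank gap cost; O(n^2) dynamic programme over anchors.
best_chain <- function(rank_a, rank_b, dir, max_gap, gap_penalty, match_score) {
  n <- length(rank_a)
  if (n == 0) return(list(idx = integer(0), score = -Inf))
  rb <- dir * rank_b
  o <- order(rank_a, rb)
  ra <- rank_a[o]; rbo <- rb[o]
  sc <- rep(match_score, n)
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    if (i == 1) next
    j <- seq_len(i - 1)
    da <- ra[i] - ra[j]; db <- rbo[i] - rbo[j]
    ok <- da >= 1 & db >= 1 & da <= max_gap & db <= max_gap
    if (!any(ok)) next
    cand <- sc[j][ok] - gap_penalty * ((da[ok] - 1) + (db[ok] - 1))
    b <- which.max(cand)
    if (cand[b] > 0) {
      sc[i] <- match_score + cand[b]
      prev[i] <- j[ok][b]
    }
  }
  end <- which.max(sc)
  chain <- integer(0); cur <- end
  while (cur != 0L) { chain <- c(cur, chain); cur <- prev[cur] }
  list(idx = o[chain], score = sc[end])
}

#' Summarise blocks as a data frame (one row per block)
#' @param x A `collinear_blocks` object.
#' @param ... Unused.
#' @export
as.data.frame.collinear_blocks <- function(x, ...) {
  if (length(x$blocks) == 0)
    return(data.frame(block_id = character(0), genome_a = character(0),
                      genome_b = character(0), chrom_a = character(0),
                      chrom_b = character(0), orientation = character(0),
                      score = numeric(0), n_anchors = integer(0),
                      median_ks = numeric(0)))
  do.call(rbind, lapply(x$blocks, function(b)
    data.frame(block_id = b$block_id, genome_a = b$genome_a,
               genome_b = b$genome_b, chrom_a = b$chrom_a,
               chrom_b = b$chrom_b, orientation = b$orientation,
               score = b$score, n_anchors = b$n_anchors,
               median_ks = b$median_ks, stringsAsFactors = FALSE)))
}

#' @export
print.collinear_blocks <- function(x, ...) {
  cat(sprintf("collinear_blocks: %d block(s), %s vs %s\n",
              length(x$blocks), x$genome_a, x$genome_b))
  invisible(x)
}

#' Per-gene synteny depth of a reference catalog
#'
#' For every gene of the reference catalog, counts the distinct blocks whose
#' reference-side rank span covers the gene's rank — the number of syntenic
#' regions of the other genome stacked over it. The modal depth is taken over
#' covered genes (depth >= 1) and reported as 0 when nothing is covered.
#'
#' @param blocks A `collinear_blocks` object (or list of them).
#' @param reference_catalog The catalog whose genes are profiled; must match
#'   the block set's side a or side b genome.
#' @return Object of class `depth_profile`: `depth` data frame (gene_id,
#'   chromosome, rank, depth), `modal_depth`, `zero_fraction`, `genome`.
#' @export
synteny_depth <- function(blocks, reference_catalog) {
  blist <- if (inherits(blocks, "collinear_blocks")) list(blocks) else blocks
  ref_genome <- reference_catalog$genome[1]
  depth <- integer(nrow(reference_catalog))
  key <- paste(reference_catalog$chromosome, reference_catalog$rank)
  for (bset in blist) {
    side <- if (bset$genome_a == ref_genome) "a"
            else if (bset$genome_b == ref_genome) "b"
            else stop("reference catalog matches neither genome of the block set",
                      call. = FALSE)
    for (b in bset$blocks) {
      ch <- if (side == "a") b$chrom_a else b$chrom_b
      rk <- if (side == "a") b$anchors$rank_a else b$anchors$rank_b
      lo <- min(rk); hi <- max(rk)
      sel <- reference_catalog$chromosome == ch &
        reference_catalog$rank >= lo & reference_catalog$rank <= hi
      depth[sel] <- depth[sel] + 1L
    }
  }
  covered <- depth[depth >= 1]
  modal <- if (length(covered) == 0) 0L else {
    tab <- table(covered)
    as.integer(names(tab)[which.max(tab)])
  }
  structure(list(depth = data.frame(gene_id = reference_catalog$gene_id,
                                    chromosome = reference_catalog$chromosome,
                                    rank = reference_catalog$rank,
                                    depth = depth, stringsAsFactors = FALSE),
                 modal_depth = modal,
                 zero_fraction = mean(depth == 0),
                 genome = ref_genome),
            class = "depth_profile")
}

#' Reduced synteny depth ratio between two genomes
#'
#' Each genome's multiplicity is the modal coverage depth observed on the
#' *other* genome's genes: an unduplicated outgroup whose genes are covered by
#' four ingroup regions, while ingroup genes see a single outgroup region,
#' yields outgroup:ingroup = 1:4. The ratio is reduced to smallest integers;
#' support is the share of covered genes sitting exactly at the modal depth.
#'
#' @param profile_a Depth profile over genome A's genes (A covered by B).
#' @param profile_b Depth profile over genome B's genes (B covered by A).
#' @return List: `ratio` (named integer vector, multiplicity of A then B),
#'   `label` like `"1:4"`, and per-side modal depths and support fractions.
#' @export
depth_ratio <- function(profile_a, profile_b) {
  da <- profile_a$depth$depth; db <- profile_b$depth$depth
  if (length(da) == 0 && length(db) == 0)
    stop("both depth profiles are empty", call. = FALSE)
  support <- function(d, m) if (m == 0) 0 else mean(d[d >= 1] == m)
  mult_a <- profile_b$modal_depth  # copies of A per B gene
  mult_b <- profile_a$modal_depth  # copies of B per A gene
  g <- gcd2(max(mult_a, 1L), max(mult_b, 1L))
  ra <- as.integer(max(mult_a, 1L) / g); rb <- as.integer(max(mult_b, 1L) / g)
  list(ratio = stats::setNames(c(ra, rb), c(profile_a$genome, profile_b$genome)),
       label = sprintf("%d:%d", ra, rb),
       modal_depth_a = profile_a$modal_depth,
       modal_depth_b = profile_b$modal_depth,
       support_a = support(da, profile_a$modal_depth),
       support_b = support(db, profile_b$modal_depth))
}

#' Export anchors in dot-plot form
#'
#' @param pairs Homolog pair data frame.
#' @param blocks A `collinear_blocks` object over the same catalogs.
#' @param catalog_a,catalog_b Gene catalogs.
#' @return Data frame (gene_a, gene_b, chrom_a, rank_a, chrom_b, rank_b,
#'   block_id, orientation); unchained anchors carry `NA` block_id.
#' @export
dotplot_export <- function(pairs, blocks, catalog_a, catalog_b = catalog_a) {
  la <- catalog_lookup(catalog_a); lb <- catalog_lookup(catalog_b)
  self <- identical(catalog_a, catalog_b)
  a <- build_anchors(pairs, catalog_a, catalog_b, la, lb, self)
  if (nrow(a) == 0) {
    a$block_id <- character(0); a$orientation <- character(0)
    return(a)
  }
  a$block_id <- NA_character_; a$orientation <- NA_character_
  key <- paste(a$gene_a, a$gene_b)
  for (b in blocks$blocks) {
    hit <- match(paste(b$anchors$gene_a, b$anchors$gene_b), key)
    hit <- hit[!is.na(hit)]
    a$block_id[hit] <- b$block_id
    a$orientation[hit] <- b$orientation
  }
  a
}
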