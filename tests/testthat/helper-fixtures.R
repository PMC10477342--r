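# In-code fixtures: tiny catalogs, pair tables and hand-built block sets.

make_catalog <- function(genome, chrom_genes) {
  do.call(rbind, lapply(names(chrom_genes), function(ch) {
    g <- chrom_genes[[ch]]
    data.frame(genome = genome, chromosome = ch,
               rank = seq_along(g) - 1L, gene_id = g, strand = "+",
               stringsAsFactors = FALSE)
  }))
}

make_pairs <- function(a, b) {
  data.frame(gene_a = a, gene_b = b, score = rep(100, length(a)),
             identity = rep(1, length(a)), coverage = rep(1, length(a)),
             stringsAsFactors = FALSE)
}

# minimal collinear_blocks structure, one block per anchor list
make_blockset <- function(genome_a, genome_b, anchor_sets) {
  blocks <- lapply(seq_along(anchor_sets), function(i) {
    an <- anchor_sets[[i]]
    list(block_id = sprintf("%s_%s_blk%02d", genome_a, genome_b, i),
         genome_a = genome_a, genome_b = genome_b,
         chrom_a = an$chrom_a %||% "c1", chrom_b = an$chrom_b %||% "c1",
         orientation = "+", score = 3 * nrow(an$anchors),
         n_anchors = nrow(an$anchors), anchors = an$anchors,
         median_ks = NA_real_)
  })
  structure(list(blocks = blocks, genome_a = genome_a, genome_b = genome_b,
                 params = list()), class = "collinear_blocks")
}

anchors_df <- function(gene_a, gene_b, rank_a = seq_along(gene_a) - 1L,
                       rank_b = seq_along(gene_b) - 1L) {
  data.frame(gene_a = gene_a, gene_b = gene_b, rank_a = rank_a,
             rank_b = rank_b, stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# toy metabolite tables: rows = list of list(id, pw, g1 = c(...), g2 = c(...))
make_metab <- function(rows) {
  do.call(rbind, lapply(rows, function(r)
    cbind(data.frame(metabolite = r$id, pathway = r$pw,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(setNames(c(r$g1, r$g2),
                                         c(paste0("s", 1:3), paste0("w", 1:3))))))))
}

met_groups <- setNames(rep(c("summer", "winter"), each = 3),
                       c(paste0("s", 1:3), paste0("w", 1:3)))

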