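# Readers and writers for the pipeline's plain-text artifacts. Gene
# catalogs, pair tables, depth/dot-plot/Ks tables and histograms are TSV;
# blocks use an MCScanX-like text layout; mixtures and manifests are JSON;
# sequences are FASTA via Biostrings and gene models GFF3 via rtracklayer.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a gene catalog TSV (genome, chromosome, rank, gene_id, strand)
#' @param catalog Catalog data frame.
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) write_tsv(catalog, path)

#' Read a gene catalog TSV
#' @param path Input path.
#' @export
read_catalog <- function(path) read_tsv(path)

#' Write homolog pairs TSV
#' @param pairs Pair data frame from [find_homolog_pairs()].
#' @param path Output path.
#' @export
write_pairs <- function(pairs, path) write_tsv(pairs, path)

#' Read homolog pairs TSV
#' @param path Input path.
#' @export
read_pairs <- function(path) read_tsv(path)

#' Write collinear blocks in an MCScanX-like text layout
#'
#' One header line per block (`## block_id chrom_a chrom_b orientation score
#' n_anchors median_ks`) followed by one anchor pair per line.
#'
#' @param blocks A `collinear_blocks` object.
#' @param path Output path.
#' @export
write_blocks <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# collinear blocks: %s vs %s",
                     blocks$genome_a, blocks$genome_b), con)
  for (b in blocks$blocks) {
    writeLines(sprintf("## %s %s %s %s %.3f %d %s",
                       b$block_id, b$chrom_a, b$chrom_b, b$orientation,
                       b$score, b$n_anchors,
                       ifelse(is.na(b$median_ks), "NA",
                              sprintf("%.6f", b$median_ks))), con)
    writeLines(sprintf("%s\t%s\t%d\t%d", b$anchors$gene_a, b$anchors$gene_b,
                       b$anchors$rank_a, b$anchors$rank_b), con)
  }
  invisible(path)
}

#' Read blocks written by [write_blocks()]
#' @param path Input path.
#' @return A `collinear_blocks` object (genome labels from the file header).
#' @export
read_blocks <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# collinear blocks: ", "", lines[1]), " vs ")[[1]]
  blocks <- list()
  cur <- NULL
  flush_block <- function(cur, blocks) {
    if (is.null(cur)) return(blocks)
    cur$anchors <- do.call(rbind, cur$anchors)
    cur$n_anchors <- nrow(cur$anchors)
    blocks[[length(blocks) + 1L]] <- cur
    blocks
  }
  for (ln in lines[-1]) {
    if (startsWith(ln, "## ")) {
      blocks <- flush_block(cur, blocks)
      f <- strsplit(sub("^## ", "", ln), " ")[[1]]
      cur <- list(block_id = f[1], genome_a = hdr[1], genome_b = hdr[2],
                  chrom_a = f[2], chrom_b = f[3], orientation = f[4],
                  score = as.numeric(f[5]), n_anchors = as.integer(f[6]),
                  median_ks = suppressWarnings(as.numeric(f[7])),
                  anchors = list())
    } else if (nzchar(ln)) {
      f <- strsplit(ln, "\t")[[1]]
      cur$anchors[[length(cur$anchors) + 1L]] <-
        data.frame(gene_a = f[1], gene_b = f[2], rank_a = as.integer(f[3]),
                   rank_b = as.integer(f[4]), stringsAsFactors = FALSE)
    }
  }
  blocks <- flush_block(cur, blocks)
  structure(list(blocks = blocks, genome_a = hdr[1], genome_b = hdr[2],
                 params = list()), class = "collinear_blocks")
}

#' Write a gene catalog as GFF3 with synthetic coordinates
#'
#' Gene features only; each gene occupies `3 * cds_codons` bp starting at
#' `rank * spacing + 1` (1-based) on its chromosome.
#'
#' @param catalog Catalog data frame.
#' @param cds Named CDS set (for feature lengths).
#' @param path Output path.
#' @param spacing Bp between gene starts.
#' @export
write_gff3 <- function(catalog, cds, path, spacing = 2000) {
  lens <- nchar(as_dna_character(cds, "cds"))[catalog$gene_id]
  gr <- GenomicRanges::GRanges(
    seqnames = catalog$chromosome,
    ranges = IRanges::IRanges(start = catalog$rank * spacing + 1,
                              width = lens),
    strand = catalog$strand)
  gr$type <- "gene"
  gr$ID <- catalog$gene_id
  gr$source <- "wgdtrace"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a Ks mixture fit as JSON
#' @param mixture A `ks_mixture`.
#' @param path Output path.
#' @export
write_mixture_json <- function(mixture, path) {
  jsonlite::write_json(list(
    n_components = mixture$n_components,
    components = mixture$components,
    bic = as.list(mixture$bic),
    loglik = mixture$loglik,
    fit_range = mixture$fit_range,
    n = mixture$n, seed = mixture$seed), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a run manifest (config echo, seed, version, input checksums)
#' @param path Output path.
#' @param config List echoed verbatim.
#' @param seed Top-level seed.
#' @param inputs Character vector of input file paths to checksum.
#' @export
write_manifest <- function(path, config, seed, inputs = character(0)) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(list(
    package = "wgdtrace",
    version = as.character(utils::packageVersion("wgdtrace")),
    seed = seed,
    config = config,
    input_md5 = sums), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write all artifacts of a simulated genome set under one directory
#'
#' Per lineage: catalog TSV, GFF3, CDS and protein FASTA; plus truth tables,
#' a JSON scenario echo and a manifest recording the seed.
#'
#' @param sim A `wgd_simulation`.
#' @param dir Output directory (created).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lab in names(sim$genomes)) {
    g <- sim$genomes[[lab]]
    write_catalog(g$catalog, file.path(dir, paste0(lab, ".catalog.tsv")))
    write_gff3(g$catalog, g$cds, file.path(dir, paste0(lab, ".gff3")))
    Biostrings::writeXStringSet(g$cds, file.path(dir, paste0(lab, ".cds.fasta")))
    Biostrings::writeXStringSet(g$proteins, file.path(dir, paste0(lab, ".pep.fasta")))
  }
  write_tsv(sim$truth$genes, file.path(dir, "truth.genes.tsv"))
  write_tsv(sim$truth$pairs, file.path(dir, "truth.pairs.tsv"))
  sc <- sim$scenario
  jsonlite::write_json(list(
    n_chromosomes = sc$n_chromosomes,
    genes_per_chromosome = sc$genes_per_chromosome,
    cds_codons = sc$cds_codons,
    synonymous_rate = sc$synonymous_rate, omega = sc$omega,
    seed = sc$seed, root_lineage = sc$root_lineage,
    events = sc$events), file.path(dir, "scenario.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(file.path(dir, "manifest.json"),
                 config = list(stage = "simulate"), seed = sc$seed,
                 inputs = file.path(dir, "scenario.json"))
  invisible(dir)
}
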