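# Homolog-pair detection by affine-gap protein alignment with a shared
# k-mer prefilter, standing in for an all-vs-all similarity search at desk
# scale. Thresholds are identity/coverage based (defaults 0.4/0.4).

.aa_alphabet <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                  "P","S","T","W","Y","V","X","*")

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

encode_protein <- function(seq, alphabet) {
  v <- strsplit(seq, "")[[1]]
  idx <- match(v, alphabet)
  if (anyNA(idx)) stop(sprintf("illegal residue '%s' in protein sequence",
                               v[which(is.na(idx))[1]]), call. = FALSE)
  idx
}

#' Optimal pairwise protein alignment with affine gaps
#'
#' Smith-Waterman (local, the default) or Needleman-Wunsch (global) alignment
#' under BLOSUM62 with BLAST-style gap accounting: a gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param seq_a,seq_b Protein sequences (single strings, standard alphabet;
#'   trailing `*` is tolerated and trimmed).
#' @param matrix Substitution matrix name (currently `"BLOSUM62"`) or a
#'   numeric matrix with residue dimnames.
#' @param gap_open,gap_extend Gap opening / extension penalties (positive).
#' @param type `"local"` or `"global"`.
#' @return List with `score`, `identity` (matches over aligned columns,
#'   gapped columns included), `coverage` (min fraction of either sequence
#'   inside the aligned region) and `alignment` (two gapped strings).
#' @export
align_proteins <- function(seq_a, seq_b, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1,
                           type = c("local", "global")) {
  type <- match.arg(type)
  seq_a <- sub("\\*$", "", seq_a); seq_b <- sub("\\*$", "", seq_b)
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("empty protein sequence", call. = FALSE)
  sm <- if (is.matrix(matrix)) matrix else switch(matrix,
    BLOSUM62 = get_blosum62(),
    stop(sprintf("unknown substitution matrix '%s'", matrix), call. = FALSE))
  ab <- rownames(sm)
  ia <- encode_protein(seq_a, ab); ib <- encode_protein(seq_b, ab)
  res <- gotoh_cpp(ia, ib, sm, gap_open, gap_extend, type == "local")
  ap <- res$a_pos; bp <- res$b_pos
  ach <- strsplit(seq_a, "")[[1]]; bch <- strsplit(seq_b, "")[[1]]
  ga <- ifelse(ap == 0, "-", ach[pmax(ap, 1)])
  gb <- ifelse(bp == 0, "-", bch[pmax(bp, 1)])
  ncol_aln <- length(ap)
  matches <- sum(ap > 0 & bp > 0 & ga == gb)
  identity <- if (ncol_aln > 0) matches / ncol_aln else 0
  cov_a <- sum(ap > 0) / nchar(seq_a)
  cov_b <- sum(bp > 0) / nchar(seq_b)
  list(score = res$score, identity = identity,
       coverage = min(cov_a, cov_b),
       alignment = list(a = paste(ga, collapse = ""),
                        b = paste(gb, collapse = "")))
}

protein_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Detect homologous gene pairs between (or within) proteomes
#'
#' All-vs-all affine-gap local alignment, restricted by a shared k-mer
#' prefilter, reporting pairs passing identity and coverage thresholds and at
#' most `top_n` partners per gene (by score). Comparing a proteome to itself
#' finds paralogs; self-pairs are excluded and each unordered pair reported
#' once with ids in lexicographic order.
#'
#' @param proteome_a,proteome_b Named character vectors or `AAStringSet`s of
#'   protein sequences; pass the same object twice for a self-comparison.
#' @param min_identity,min_coverage Reporting thresholds in `[0, 1]` scale
#'   (values above 1 yield an empty set).
#' @param top_n Maximum partners kept per gene.
#' @param kmer k-mer size of the prefilter; `min_shared_kmers` shared k-mers
#'   are required before full alignment (set `exhaustive = TRUE` to disable).
#' @param min_shared_kmers See `kmer`.
#' @param exhaustive Align every pair, bypassing the prefilter.
#' @param gap_open,gap_extend Alignment gap penalties.
#' @return Data frame (gene_a, gene_b, score, identity, coverage).
#' @export
find_homolog_pairs <- function(proteome_a, proteome_b = proteome_a,
                               min_identity = 0.4, min_coverage = 0.4,
                               top_n = 5, kmer = 5, min_shared_kmers = 2,
                               exhaustive = FALSE,
                               gap_open = 11, gap_extend = 1) {
  pa <- as_aa_character(proteome_a)
  pb <- as_aa_character(proteome_b)
  if (anyDuplicated(names(pa)) || anyDuplicated(names(pb)))
    stop("duplicate gene ids in proteome", call. = FALSE)
  pa <- gsub("\\*$", "", pa); pb <- gsub("\\*$", "", pb)
  self <- identical(sort(names(pa)), sort(names(pb)))

  # candidate pairs by shared k-mers
  cand <- if (exhaustive) {
    expand.grid(a = names(pa), b = names(pb), stringsAsFactors = FALSE)
  } else {
    km_b <- lapply(pb, protein_kmers, k = kmer)
    index <- new.env(parent = emptyenv())
    for (g in names(km_b)) for (w in km_b[[g]])
      assign(w, c(index[[w]], g), envir = index)
    rows <- vector("list", length(pa))
    for (i in seq_along(pa)) {
      hits <- unlist(lapply(protein_kmers(pa[[i]], kmer),
                            function(w) index[[w]]), use.names = FALSE)
      if (is.null(hits)) next
      tabs <- table(hits)
      keep <- names(tabs)[tabs >= min_shared_kmers]
      if (length(keep))
        rows[[i]] <- data.frame(a = names(pa)[i], b = keep,
                                stringsAsFactors = FALSE)
    }
    do.call(rbind, rows) %||% data.frame(a = character(0), b = character(0))
  }
  if (self && nrow(cand) > 0) {
    cand <- cand[cand$a < cand$b, , drop = FALSE] # canonical, no self-pairs
  }
  if (nrow(cand) == 0 || min_identity > 1 || min_coverage > 1)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), identity = numeric(0),
                      coverage = numeric(0)))

  sm <- get_blosum62()
  n <- nrow(cand)
  score <- identity <- coverage <- numeric(n)
  for (i in seq_len(n)) {
    al <- align_proteins(pa[[cand$a[i]]], pb[[cand$b[i]]], matrix = sm,
                         gap_open = gap_open, gap_extend = gap_extend)
    score[i] <- al$score; identity[i] <- al$identity; coverage[i] <- al$coverage
  }
  out <- data.frame(gene_a = cand$a, gene_b = cand$b, score = score,
                    identity = identity, coverage = coverage,
                    stringsAsFactors = FALSE)
  out <- out[out$identity >= min_identity & out$coverage >= min_coverage, ,
             drop = FALSE]
  if (nrow(out) == 0) return(out)
  # cap partners per gene (a pair survives if within top_n of either side)
  keep <- rep(FALSE, nrow(out))
  rank_within <- function(ids) {
    for (g in unique(ids)) {
      sel <- which(ids == g)
      best <- sel[order(-out$score[sel])][seq_len(min(top_n, length(sel)))]
      keep[best] <<- TRUE
    }
  }
  rank_within(out$gene_a); rank_within(out$gene_b)
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
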