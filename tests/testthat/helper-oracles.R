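# Independent brute-force oracles. These deliberately re-derive everything
# from first principles (Biostrings::GENETIC_CODE, explicit enumeration) and
# share no code with the package internals they check.

.ORACLE_BASES <- c("A", "C", "G", "T")

oracle_translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# NG86 synonymous site count of one codon: per position, the fraction of the
# three possible changes that preserve the amino acid (stop targets count as
# nonsynonymous).
oracle_syn_sites <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  aa <- oracle_translate_codon(codon)
  syn <- 0
  for (pos in 1:3) for (alt in setdiff(.ORACLE_BASES, b[pos])) {
    b2 <- b; b2[pos] <- alt
    if (oracle_translate_codon(paste(b2, collapse = "")) == aa) syn <- syn + 1
  }
  syn / 3
}

# Pathway enumeration between two codons: average synonymous/nonsynonymous
# step counts over all substitution orders not passing through a stop codon
# (all orders when every one is blocked).
oracle_pathway_counts <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  diffpos <- which(b1 != b2)
  d <- length(diffpos)
  if (d == 0) return(c(sd = 0, nd = 0))
  orders <- if (d == 1) list(diffpos) else {
    perms <- function(v) if (length(v) == 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    perms(diffpos)
  }
  res <- lapply(orders, function(ord) {
    cur <- b1; s <- 0; n <- 0; blocked <- FALSE
    for (pos in ord) {
      aa_prev <- oracle_translate_codon(paste(cur, collapse = ""))
      cur[pos] <- b2[pos]
      aa_next <- oracle_translate_codon(paste(cur, collapse = ""))
      if (aa_next == "*") blocked <- TRUE
      if (aa_next == aa_prev) s <- s + 1 else n <- n + 1
    }
    list(s = s, n = n, blocked = blocked)
  })
  ok <- Filter(function(r) !r$blocked, res)
  if (length(ok) == 0) ok <- res
  c(sd = mean(vapply(ok, `[[`, 0, "s")), nd = mean(vapply(ok, `[[`, 0, "n")))
}

oracle_ng86 <- function(cds_a, cds_b) {
  ca <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  cb <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  S <- (sum(vapply(ca, oracle_syn_sites, 0)) +
          sum(vapply(cb, oracle_syn_sites, 0))) / 2
  counts <- mapply(function(x, y) oracle_pathway_counts(x, y), ca, cb)
  list(S = S, N = 3 * length(ca) - S,
       Sd = sum(counts["sd", ]), Nd = sum(counts["nd", ]))
}

# Exhaustive monotone-chain enumeration over anchor sets (both orientations).
oracle_best_chain_score <- function(rank_a, rank_b, max_gap, gap_penalty,
                                    match_score) {
  n <- length(rank_a)
  best <- -Inf
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    idx <- idx[order(rank_a[idx])]
    for (dir in c(1, -1)) {
      ra <- rank_a[idx]; rb <- dir * rank_b[idx]
      if (length(idx) > 1) {
        da <- diff(ra); db <- diff(rb)
        if (any(da < 1 | db < 1 | da > max_gap | db > max_gap)) next
        score <- length(idx) * match_score -
          gap_penalty * sum((da - 1) + (db - 1))
      } else score <- match_score
      if (score > best) best <- score
    }
  }
  best
}

# Exhaustive affine-gap alignment scoring by recursive path enumeration
# (no memoisation); gap of length L costs gap_open + L * gap_extend.
oracle_global_score <- function(a, b, score_fun, gap_open, gap_extend) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(va) && j > length(vb)) return(0)
    best <- -Inf
    if (i <= length(va) && j <= length(vb))
      best <- max(best, score_fun(va[i], vb[j]) + rec(i + 1, j + 1, "M"))
    if (i <= length(va)) {
      cost <- if (state == "X") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i + 1, j, "X"))
    }
    if (j <= length(vb)) {
      cost <- if (state == "Y") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "M")
}

oracle_local_score <- function(a, b, score_fun, gap_open, gap_extend) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0
  for (i1 in 1:na) for (i2 in i1:na) for (j1 in 1:nb) for (j2 in j1:nb) {
    s <- oracle_global_score(substr(a, i1, i2), substr(b, j1, j2),
                             score_fun, gap_open, gap_extend)
    if (s > best) best <- s
  }
  best
}

blosum62_score_fun <- local({
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  sm <- e$BLOSUM62
  function(x, y) sm[x, y]
})

random_peptide <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V"), n, replace = TRUE), collapse = "")
}

random_sense_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(c("ATG", sample(sense, n_codons - 1, replace = TRUE)), collapse = "")
}
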