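# Standard genetic code tables shared by the simulator and the NG86 estimator.
# Codons are indexed 1..64 as 16*b1 + 4*b2 + b3 + 1 with A,C,G,T = 0..3.

.codon_env <- new.env(parent = emptyenv())

.bases <- c("A", "C", "G", "T")

codon_index <- function(codon) {
  b <- match(strsplit(codon, "")[[1]], .bases) - 1L
  16L * b[1] + 4L * b[2] + b[3] + 1L
}

all_codons <- function() {
  g <- expand.grid(b3 = .bases, b2 = .bases, b1 = .bases,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3) # ordered to match codon_index
}

#' Amino acid per codon (one-letter, "*" = stop), indexed by codon_index
#' @noRd
codon_aa_table <- function() {
  if (!is.null(.codon_env$aa)) return(.codon_env$aa)
  gc <- Biostrings::GENETIC_CODE
  codons <- all_codons()
  aa <- unname(gc[codons])
  .codon_env$aa <- aa
  aa
}

#' Integer amino-acid codes for the C++ mutation engine (-1 = stop)
#' @noRd
codon_aa_int <- function() {
  aa <- codon_aa_table()
  ifelse(aa == "*", -1L, as.integer(factor(aa, levels = sort(unique(aa[aa != "*"])))) - 1L)
}

sense_codons <- function() all_codons()[codon_aa_table() != "*"]

#' Per-codon synonymous site counts (NG86 site definition)
#'
#' Each codon position contributes (number of synonymous one-step changes)/3
#' sites; changes creating a stop codon count as nonsynonymous, so every sense
#' codon carries exactly 3 sites split between the two classes.
#' @noRd
ng86_syn_sites <- function() {
  if (!is.null(.codon_env$syn_sites)) return(.codon_env$syn_sites)
  aa <- codon_aa_table()
  codons <- all_codons()
  s <- numeric(64)
  for (i in seq_len(64)) {
    if (aa[i] == "*") { s[i] <- NA_real_; next }
    b <- match(strsplit(codons[i], "")[[1]], .bases)
    cnt <- 0
    for (pos in 1:3) for (alt in setdiff(1:4, b[pos])) {
      b2 <- b; b2[pos] <- alt
      j <- 16L * (b2[1] - 1L) + 4L * (b2[2] - 1L) + (b2[3] - 1L) + 1L
      if (aa[j] == aa[i]) cnt <- cnt + 1 # stop targets are nonsynonymous
    }
    s[i] <- cnt / 3
  }
  .codon_env$syn_sites <- s
  s
}

#' Pathway-averaged synonymous/nonsynonymous difference counts per codon pair
#'
#' For codons differing at d positions, all d! substitution orders are
#' enumerated; orders passing through a stop codon are excluded (all orders are
#' used when every one is blocked). Returns 64 x 64 matrices Sd and Nd.
#' @noRd
ng86_diff_tables <- function() {
  if (!is.null(.codon_env$sd)) return(list(sd = .codon_env$sd, nd = .codon_env$nd))
  aa <- codon_aa_table()
  codons <- all_codons()
  base_m <- t(vapply(codons, function(cc) match(strsplit(cc, "")[[1]], .bases),
                     integer(3)))
  idx_of <- function(b) 16L * (b[1] - 1L) + 4L * (b[2] - 1L) + (b[3] - 1L) + 1L
  perms <- list(`1` = matrix(1L, 1, 1),
                `2` = rbind(c(1L, 2L), c(2L, 1L)),
                `3` = rbind(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                            c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L)))
  sd <- matrix(0, 64, 64); nd <- matrix(0, 64, 64)
  for (i in seq_len(64)) {
    if (aa[i] == "*") { sd[i, ] <- NA; nd[i, ] <- NA; next }
    for (j in seq_len(64)) {
      if (aa[j] == "*") { sd[i, j] <- NA; nd[i, j] <- NA; next }
      if (i == j) next
      diffpos <- which(base_m[i, ] != base_m[j, ])
      d <- length(diffpos)
      pm <- perms[[as.character(d)]]
      path_s <- numeric(0); path_n <- numeric(0)
      blocked_s <- numeric(0); blocked_n <- numeric(0)
      for (p in seq_len(nrow(pm))) {
        cur <- base_m[i, ]; s_cnt <- 0; n_cnt <- 0; blocked <- FALSE
        for (step in diffpos[pm[p, seq_len(d)]]) {
          prev_idx <- idx_of(cur)
          cur[step] <- base_m[j, step]
          nxt_idx <- idx_of(cur)
          if (aa[nxt_idx] == "*") blocked <- TRUE
          if (aa[nxt_idx] == aa[prev_idx]) s_cnt <- s_cnt + 1 else n_cnt <- n_cnt + 1
        }
        if (blocked) { blocked_s <- c(blocked_s, s_cnt); blocked_n <- c(blocked_n, n_cnt) }
        else { path_s <- c(path_s, s_cnt); path_n <- c(path_n, n_cnt) }
      }
      if (length(path_s) == 0) { path_s <- blocked_s; path_n <- blocked_n }
      sd[i, j] <- mean(path_s); nd[i, j] <- mean(path_n)
    }
  }
  .codon_env$sd <- sd; .codon_env$nd <- nd
  list(sd = sd, nd = nd)
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length not divisible by 3", call. = FALSE)
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}
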