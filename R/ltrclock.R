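# LTR retrotransposon insertion clock: the 5' and 3' LTR of an element are
# identical at insertion; their Kimura two-parameter divergence K dates the
# insertion via T = K / (2 r).

#' Kimura two-parameter distance between two aligned sequences
#'
#' Columns where either sequence is not an unambiguous base (gaps, Ns) are
#' excluded. Transition proportion P (A<->G, C<->T) and transversion
#' proportion Q enter `K = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`;
#' saturation (non-positive log argument) flags the estimate invalid.
#'
#' @param aligned_a,aligned_b Equal-length aligned sequences (strings or
#'   DNAString).
#' @return List: `P`, `Q`, `K`, `n_sites`, `valid`.
#' @export
k2p_distance <- function(aligned_a, aligned_b) {
  a <- toupper(as_dna_character(aligned_a, "aligned_a")[1])
  b <- toupper(as_dna_character(aligned_b, "aligned_b")[1])
  if (nchar(a) != nchar(b))
    stop("aligned sequences must have equal length", call. = FALSE)
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  ok <- va %in% .bases & vb %in% .bases
  va <- va[ok]; vb <- vb[ok]
  n <- length(va)
  if (n == 0) stop("no comparable sites", call. = FALSE)
  diff <- va != vb
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  transition <- diff & (purine[va] == purine[vb])
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  valid <- arg1 > 0 && arg2 > 0
  K <- if (valid) -0.5 * log(arg1) - 0.25 * log(arg2) else NA_real_
  list(P = P, Q = Q, K = K, n_sites = n, valid = valid)
}

#' LTR insertion time from divergence and substitution rate
#'
#' `T = K / (2 r)`, reported in million years: each LTR accumulates
#' substitutions independently after insertion, so the pair diverges at twice
#' the per-site rate.
#'
#' @param K Per-site divergence between the element's two LTRs.
#' @param rate Substitutions per site per year (> 0).
#' @return Insertion age(s) in My.
#' @export
ltr_insertion_time <- function(K, rate) {
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (any(K < 0, na.rm = TRUE)) stop("K must be >= 0", call. = FALSE)
  K / (2 * rate) / 1e6
}

#' Divergence and age of every element in an LTR cohort
#'
#' Accepts an `ltr_cohort` from [simulate_ltr_cohort()] or a `DNAStringSet` /
#' named character vector with two records per element named `<id>::5p` and
#' `<id>::3p` (the complete-LTR filter: elements missing either record are
#' dropped). LTRs of unequal length are globally aligned before the distance.
#'
#' @param x Cohort or sequence set as described.
#' @param rate Substitutions per site per year.
#' @return Data frame (element_id, P, Q, K, T_my, n_sites, valid) with the
#'   cohort's truth ages joined when available.
#' @export
ltr_ages <- function(x, rate = 1.6e-9) {
  truth <- NULL
  seqs <- if (inherits(x, "ltr_cohort")) { truth <- x$elements; x$seqs } else x
  seqs <- as_dna_character(seqs, "LTR sequences")
  ids <- sub("::[35]p$", "", names(seqs))
  side <- sub("^.*::", "", names(seqs))
  complete <- intersect(ids[side == "5p"], ids[side == "3p"])
  rows <- lapply(complete, function(id) {
    s5 <- seqs[[paste0(id, "::5p")]]; s3 <- seqs[[paste0(id, "::3p")]]
    if (nchar(s5) != nchar(s3)) {
      al <- align_nucleotide_global(s5, s3)
      s5 <- al$a; s3 <- al$b
    }
    k <- k2p_distance(s5, s3)
    data.frame(element_id = id, P = k$P, Q = k$Q, K = k$K,
               T_my = if (isTRUE(k$valid)) ltr_insertion_time(k$K, rate) else NA_real_,
               n_sites = k$n_sites, valid = k$valid, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(element_id = character(0), P = numeric(0), Q = numeric(0),
               K = numeric(0), T_my = numeric(0), n_sites = integer(0),
               valid = logical(0))
  if (!is.null(truth) && nrow(out) > 0)
    out$true_age_my <- truth$true_age_my[match(out$element_id, truth$element_id)]
  out
}

# Global affine-gap DNA alignment (match 2 / mismatch -3, gap 5 + 2L),
# returning the two gapped strings.
align_nucleotide_global <- function(a, b, match = 2, mismatch = -3,
                                    gap_open = 5, gap_extend = 2) {
  ab <- c(.bases, "N")
  sm <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
  diag(sm) <- match
  sm["N", ] <- sm[, "N"] <- 0
  ia <- match(strsplit(toupper(a), "")[[1]], ab)
  ib <- match(strsplit(toupper(b), "")[[1]], ab)
  if (anyNA(ia) || anyNA(ib)) stop("non-ACGTN base in LTR sequence", call. = FALSE)
  res <- gotoh_cpp(ia, ib, sm, gap_open, gap_extend, FALSE)
  va <- strsplit(toupper(a), "")[[1]]; vb <- strsplit(toupper(b), "")[[1]]
  list(a = paste(ifelse(res$a_pos == 0, "-", va[pmax(res$a_pos, 1)]), collapse = ""),
       b = paste(ifelse(res$b_pos == 0, "-", vb[pmax(res$b_pos, 1)]), collapse = ""))
}

#' Histogram of LTR insertion ages
#'
#' Counts ages into half-open bins `[k*w, (k+1)*w)` and reports the modal bin
#' — an insertion burst shows as a sharp mode.
#'
#' @param ages_my Insertion ages in My (NAs dropped).
#' @param bin_width Bin width in My (> 0).
#' @return List of class `ltr_histogram`: `table` (bin_start, bin_mid,
#'   count), `modal_bin` (bin_start of the count mode, `NA` when empty).
#' @export
burst_histogram <- function(ages_my, bin_width = 0.5) {
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be > 0", call. = FALSE)
  ages <- ages_my[is.finite(ages_my)]
  if (any(ages < 0)) stop("ages must be >= 0", call. = FALSE)
  if (length(ages) == 0)
    return(structure(list(table = data.frame(bin_start = numeric(0),
                                             bin_mid = numeric(0),
                                             count = integer(0)),
                          modal_bin = NA_real_), class = "ltr_histogram"))
  idx <- floor(ages / bin_width)
  tab <- table(idx)
  starts <- as.numeric(names(tab)) * bin_width
  df <- data.frame(bin_start = starts, bin_mid = starts + bin_width / 2,
                   count = as.integer(tab))
  structure(list(table = df,
                 modal_bin = df$bin_start[which.max(df$count)]),
            class = "ltr_histogram")
}
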