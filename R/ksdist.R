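# Ks estimation and peak fitting: codon alignment, Nei-Gojobori (1986)
# counting with Jukes-Cantor correction, block-median Ks distributions,
# Gaussian-mixture peak fitting with BIC, outgroup-anchored rate correction
# and molecular-clock dating of duplication peaks.

#' Back-translate a protein alignment into a codon alignment
#'
#' Gaps in the protein alignment become codon-triplet gaps. With no protein
#' alignment supplied, one is computed globally under BLOSUM62.
#'
#' @param cds_a,cds_b In-frame coding sequences (strings or DNAString),
#'   length divisible by 3, no internal stop codons.
#' @param protein_alignment Optional list with gapped strings `a` and `b`
#'   (as returned in `align_proteins()$alignment`).
#' @return Object of class `codon_alignment`: gapped codon strings `a`, `b`
#'   and `keep`, a logical flag per codon column (TRUE when gap-free).
#' @export
codon_align <- function(cds_a, cds_b, protein_alignment = NULL) {
  cds_a <- as_dna_character(cds_a, "cds_a")[1]
  cds_b <- as_dna_character(cds_b, "cds_b")[1]
  cod_a <- split_codons(cds_a); cod_b <- split_codons(cds_b)
  aa <- codon_aa_table()
  pa <- aa[vapply(cod_a, codon_index, integer(1))]
  pb <- aa[vapply(cod_b, codon_index, integer(1))]
  check_stops <- function(p, cod, label) {
    n <- length(p)
    has_term <- p[n] == "*"
    internal <- which(p[seq_len(n - has_term)] == "*")
    if (length(internal))
      stop(sprintf("internal stop codon in %s at codon %d", label, internal[1]),
           call. = FALSE)
    if (has_term) list(p = p[-n], cod = cod[-n]) else list(p = p, cod = cod)
  }
  ca <- check_stops(pa, cod_a, "cds_a"); cb <- check_stops(pb, cod_b, "cds_b")
  prot_a <- paste(ca$p, collapse = ""); prot_b <- paste(cb$p, collapse = "")
  if (is.null(protein_alignment)) {
    protein_alignment <- align_proteins(prot_a, prot_b, type = "global")$alignment
  }
  ga <- strsplit(protein_alignment$a, "")[[1]]
  gb <- strsplit(protein_alignment$b, "")[[1]]
  if (sum(ga != "-") != length(ca$p) || sum(gb != "-") != length(cb$p))
    stop("protein alignment does not match the translated CDS", call. = FALSE)
  if (!identical(ga[ga != "-"], ca$p) || !identical(gb[gb != "-"], cb$p))
    stop("protein alignment does not match the translated CDS", call. = FALSE)
  ai <- bi <- 0L
  out_a <- out_b <- character(length(ga))
  for (k in seq_along(ga)) {
    if (ga[k] == "-") out_a[k] <- "---" else { ai <- ai + 1L; out_a[k] <- ca$cod[ai] }
    if (gb[k] == "-") out_b[k] <- "---" else { bi <- bi + 1L; out_b[k] <- cb$cod[bi] }
  }
  structure(list(a = paste(out_a, collapse = ""),
                 b = paste(out_b, collapse = ""),
                 keep = out_a != "---" & out_b != "---"),
            class = "codon_alignment")
}

#' Nei-Gojobori (1986) Ka/Ks estimate from a codon alignment
#'
#' Synonymous site counts per codon follow the NG86 definition (changes to
#' stop codons are nonsynonymous); difference counts for codons differing at
#' several positions are averaged over all substitution orders not passing
#' through a stop. Proportions are corrected for multiple hits with the
#' Jukes-Cantor formula `K = -3/4 * log(1 - 4/3 * p)`; the estimate is
#' flagged invalid (saturated) when either proportion reaches 3/4.
#'
#' @param x A `codon_alignment`, or a gap-free codon string for the first
#'   sequence (then `y` gives the second).
#' @param y Second sequence when `x` is a string.
#' @return List of class `ks_estimate`: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`,
#'   `Ks`, `Ka`, `n_codons`, `valid`.
#' @export
ng86 <- function(x, y = NULL) {
  if (inherits(x, "codon_alignment")) {
    ca <- split_codons(x$a)[x$keep]
    cb <- split_codons(x$b)[x$keep]
  } else {
    ca <- split_codons(as_dna_character(x, "x")[1])
    cb <- split_codons(as_dna_character(y, "y")[1])
    if (length(ca) != length(cb))
      stop("sequences must have equal codon counts", call. = FALSE)
  }
  if (length(ca) == 0) stop("no gap-free codon columns", call. = FALSE)
  if (length(ca) < 30)
    warning("fewer than 30 aligned codons; Ks estimate will be noisy")
  ia <- vapply(ca, codon_index, integer(1))
  ib <- vapply(cb, codon_index, integer(1))
  aa <- codon_aa_table()
  if (any(aa[ia] == "*") || any(aa[ib] == "*"))
    stop("stop codon inside the aligned region", call. = FALSE)
  s_sites <- ng86_syn_sites()
  tabs <- ng86_diff_tables()
  S <- (sum(s_sites[ia]) + sum(s_sites[ib])) / 2
  N <- 3 * length(ia) - S
  Sd <- sum(tabs$sd[cbind(ia, ib)])
  Nd <- sum(tabs$nd[cbind(ia, ib)])
  if (S <= 0) stop("zero synonymous sites", call. = FALSE)
  pS <- Sd / S; pN <- Nd / N
  valid <- pS < 0.75 && pN < 0.75
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = if (valid) jc(pS) else NA_real_,
                 Ka = if (valid) jc(pN) else NA_real_,
                 n_codons = length(ia), valid = valid),
            class = "ks_estimate")
}

#' Ks of every anchor pair in a block set
#'
#' Runs [codon_align()] + [ng86()] for each anchor of each block and attaches
#' the per-block median of valid anchor Ks values (the block-median rule).
#' Blocks with no valid estimate get `NA` and are flagged.
#'
#' @param blocks A `collinear_blocks` object.
#' @param cds_a,cds_b Named CDS sets for the two genomes (a self-comparison
#'   passes the same set twice).
#' @return List: `blocks` (input with `median_ks` filled), `anchors` data
#'   frame (block_id, gene_a, gene_b, S, N, Sd, Nd, Ka, Ks, valid),
#'   `block_ks` data frame (block_id, n_valid, median_ks), `dropped` ids of
#'   blocks without any valid estimate.
#' @export
anchor_ks <- function(blocks, cds_a, cds_b = cds_a) {
  ca <- as_dna_character(cds_a, "cds_a"); cb <- as_dna_character(cds_b, "cds_b")
  rows <- list(); med <- list()
  dropped <- character(0)
  for (k in seq_along(blocks$blocks)) {
    b <- blocks$blocks[[k]]
    est <- vector("list", nrow(b$anchors))
    for (i in seq_len(nrow(b$anchors))) {
      ga <- b$anchors$gene_a[i]; gb <- b$anchors$gene_b[i]
      sa <- if (ga %in% names(ca)) ca[[ga]] else cb[[ga]]
      sb <- if (gb %in% names(cb)) cb[[gb]] else ca[[gb]]
      e <- tryCatch(suppressWarnings(ng86(codon_align(sa, sb))),
                    error = function(err) NULL)
      est[[i]] <- if (is.null(e))
        list(S = NA, N = NA, Sd = NA, Nd = NA, Ka = NA, Ks = NA, valid = FALSE)
      else e
    }
    df <- data.frame(block_id = b$block_id,
                     gene_a = b$anchors$gene_a, gene_b = b$anchors$gene_b,
                     S = vapply(est, function(e) as.numeric(e$S), 1),
                     N = vapply(est, function(e) as.numeric(e$N), 1),
                     Sd = vapply(est, function(e) as.numeric(e$Sd), 1),
                     Nd = vapply(est, function(e) as.numeric(e$Nd), 1),
                     Ka = vapply(est, function(e) as.numeric(e$Ka), 1),
                     Ks = vapply(est, function(e) as.numeric(e$Ks), 1),
                     valid = vapply(est, function(e) isTRUE(e$valid), TRUE),
                     stringsAsFactors = FALSE)
    rows[[k]] <- df
    mk <- block_median_ks(df$Ks[df$valid])
    if (is.na(mk)) dropped <- c(dropped, b$block_id)
    blocks$blocks[[k]]$median_ks <- mk
    med[[k]] <- data.frame(block_id = b$block_id, n_valid = sum(df$valid),
                           median_ks = mk, stringsAsFactors = FALSE)
  }
  anchors <- do.call(rbind, rows) %||% data.frame()
  block_ks <- do.call(rbind, med) %||% data.frame()
  list(blocks = blocks, anchors = anchors, block_ks = block_ks,
       dropped = dropped)
}

#' Median Ks representing one syntenic block
#'
#' @param ks Valid anchor Ks values of the block.
#' @return The median, or `NA` when no valid value remains (block excluded).
#' @export
block_median_ks <- function(ks) {
  ks <- ks[is.finite(ks)]
  if (length(ks) == 0) return(NA_real_)
  stats::median(ks)
}

#' Fit a Gaussian mixture to a block-median Ks distribution
#'
#' Values outside `fit_range` are removed (low-Ks allelic/tandem noise and
#' the saturated tail), then Gaussian mixtures with k = 1..`k_max` components
#' are fitted by expectation-maximisation with `restarts` seeded
#' initialisations each (quantile-spread means plus k-means starts); k is
#' selected by BIC, ties resolved toward fewer components.
#'
#' @param values Block-median Ks values.
#' @param fit_range Numeric length-2; half-open interval `(lo, hi]` retained.
#' @param k_max Largest number of components tried.
#' @param restarts EM restarts per k.
#' @param seed Integer seed (the fit is deterministic given it).
#' @param min_values Minimum retained values required.
#' @return Object of class `ks_mixture`: `components` data frame (weight,
#'   mean, sd; sorted by mean), `n_components`, `bic` (per k), `loglik`,
#'   `fit_range`, `n`, `seed`.
#' @export
fit_ks_mixture <- function(values, fit_range = c(0.02, 2.0), k_max = 5,
                           restarts = 8, seed = 1L, min_values = 20) {
  x <- values[is.finite(values) & values > fit_range[1] & values <= fit_range[2]]
  if (length(x) < min_values)
    stop(sprintf("too few Ks values in range (%d < %d)", length(x), min_values),
         call. = FALSE)
  n <- length(x)
  with_seed(seed, {
    best_by_k <- vector("list", k_max)
    for (k in seq_len(k_max)) {
      best <- NULL
      for (r in seq_len(restarts)) {
        init_mu <- if (r == 1) {
          stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
        } else if (r == 2 && k > 1) {
          km <- stats::kmeans(x, centers = k, nstart = 3)
          sort(as.numeric(km$centers))
        } else {
          sort(sample(x, k))
        }
        fit <- em_gaussian(x, init_mu)
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
      }
      best_by_k[[k]] <- best
    }
    ll <- vapply(best_by_k, function(f) f$loglik, numeric(1))
    bic <- -2 * ll + (3 * seq_len(k_max) - 1) * log(n)
    k_sel <- which.min(round(bic, 8)) # ties toward smaller k via which.min
    fit <- best_by_k[[k_sel]]
    o <- order(fit$mean)
    comp <- data.frame(weight = fit$weight[o], mean = fit$mean[o],
                       sd = fit$sd[o])
    structure(list(components = comp, n_components = k_sel,
                   bic = stats::setNames(bic, paste0("k", seq_len(k_max))),
                   loglik = ll[k_sel], fit_range = fit_range, n = n,
                   seed = seed),
              class = "ks_mixture")
  })
}

# Plain EM for a univariate Gaussian mixture; sd floored to avoid component
# collapse onto single points.
em_gaussian <- function(x, mu, max_iter = 500, tol = 1e-8, sd_floor = 1e-3) {
  k <- length(mu)
  n <- length(x)
  w <- rep(1 / k, k)
  sg <- rep(max(stats::sd(x) / k, sd_floor), k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * stats::dnorm(x, mu[j], sg[j]),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
    sg <- pmax(sg, sd_floor)
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(weight = w, mean = mu, sd = sg, loglik = ll)
}

#' @export
print.ks_mixture <- function(x, ...) {
  cat(sprintf("Ks mixture: %d component(s) on %d block-median values\n",
              x$n_components, x$n))
  print(round(x$components, 4))
  invisible(x)
}

#' Outgroup-anchored evolutionary-rate correction of paralog Ks peaks
#'
#' Lineages evolve at unequal rates; ortholog Ks peaks of each ingroup
#' species against a common outgroup measure the lineage rate, so each
#' species' paralog peak is rescaled by
#' `c_i = mean(ortholog peaks) / ortholog peak of species i`. Peaks from the
#' same event then coincide across species.
#'
#' @param paralog_peaks Named numeric vector (or named list of vectors) of
#'   raw paralog Ks peaks per species.
#' @param ortholog_peaks Named numeric vector of species-vs-outgroup ortholog
#'   Ks peaks, one per species in `paralog_peaks`.
#' @return Corrected peaks, same shape as `paralog_peaks`, plus scaling
#'   factors in attribute `scaling`.
#' @export
rate_correct <- function(paralog_peaks, ortholog_peaks) {
  species <- if (is.list(paralog_peaks)) names(paralog_peaks) else names(paralog_peaks)
  if (is.null(species) || !all(species %in% names(ortholog_peaks)))
    stop("every species needs an ortholog peak against the common outgroup",
         call. = FALSE)
  if (length(ortholog_peaks[species]) < 2)
    stop("rate correction needs ortholog peaks for >= 2 ingroup species",
         call. = FALSE)
  ref <- mean(unlist(ortholog_peaks[species]))
  scaling <- ref / unlist(ortholog_peaks[species])
  out <- if (is.list(paralog_peaks)) {
    stats::setNames(lapply(species, function(s) paralog_peaks[[s]] * scaling[[s]]),
                    species)
  } else {
    paralog_peaks * scaling[species]
  }
  attr(out, "scaling") <- scaling
  out
}

#' Date a WGD from a (corrected) Ks peak
#'
#' Molecular-clock algebra `T = Ks / (2 r)`: the peak measures the summed
#' synonymous divergence along both descendant branches.
#'
#' @param peak_ks Peak Ks (substitutions per synonymous site).
#' @param rate Synonymous substitutions per site per year (> 0).
#' @param peak_sd Optional peak standard deviation; the interval is
#'   peak +/- 1 sd on the same clock.
#' @return List of class `wgd_date`: `age_my`, and `interval_my` when
#'   `peak_sd` is given.
#' @export
date_wgd <- function(peak_ks, rate, peak_sd = NULL) {
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (any(peak_ks < 0)) stop("Ks must be >= 0", call. = FALSE)
  age <- peak_ks / (2 * rate) / 1e6
  out <- list(age_my = age)
  if (!is.null(peak_sd))
    out$interval_my <- c(lower = (peak_ks - peak_sd) / (2 * rate) / 1e6,
                         upper = (peak_ks + peak_sd) / (2 * rate) / 1e6)
  structure(out, class = "wgd_date")
}
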