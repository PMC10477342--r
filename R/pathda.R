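# Differential-metabolite calling and per-pathway differential-abundance
# (DA) scores: (n_up - n_down) / n_diff in [-1, 1], where +1 means every
# differential metabolite in the pathway moved up.

#' Call differential metabolites between two groups
#'
#' Abundances are log2-transformed; each metabolite gets a Welch two-sample
#' t-test p-value and a fold change of the second group over the first
#' (geometric, i.e. `2^(mean log2 difference)`). Status is `up` when
#' `FC >= fc_threshold` and `p < p_threshold`, `down` when
#' `FC <= 1/fc_threshold` and `p < p_threshold`, else `ns`. Metabolites with
#' fewer than 2 usable replicates in either group are excluded and flagged.
#'
#' @param abundance Data frame with columns `metabolite`, `pathway`
#'   (semicolon-separated ids allowed) and one column per sample, linear
#'   scale unless `log_input = TRUE`.
#' @param groups Named character vector sample -> group (exactly 2 groups);
#'   the second level (by first appearance) is compared against the first.
#' @param fc_threshold Fold-change threshold (default 2.0).
#' @param p_threshold p-value threshold (default 0.05).
#' @param adjust Multiple-testing adjustment passed to [stats::p.adjust()];
#'   `"none"` (the default) applies the raw p threshold.
#' @param log_input Set TRUE when abundances are already log2.
#' @return Data frame (metabolite, pathway, log2fc, fold_change, p, padj,
#'   status, excluded) of class `metabolite_calls` (also a data.frame).
#' @export
call_differential <- function(abundance, groups, fc_threshold = 2.0,
                              p_threshold = 0.05, adjust = "none",
                              log_input = FALSE) {
  samples <- intersect(names(abundance), names(groups))
  if (length(samples) == 0) stop("no sample columns match 'groups'", call. = FALSE)
  # comparison direction follows the level order of `groups` itself, so
  # reversing the vector swaps the labels and flips every fold change
  glev <- unique(unname(groups))
  if (length(glev) != 2) stop("exactly two groups are required", call. = FALSE)
  g1 <- samples[groups[samples] == glev[1]]
  g2 <- samples[groups[samples] == glev[2]]
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs >= 2 replicates", call. = FALSE)
  n <- nrow(abundance)
  log2fc <- p <- rep(NA_real_, n)
  excluded <- rep(FALSE, n)
  for (i in seq_len(n)) {
    x1 <- as.numeric(abundance[i, g1]); x2 <- as.numeric(abundance[i, g2])
    if (!log_input) { x1 <- log2(x1); x2 <- log2(x2) }
    x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
    if (length(x1) < 2 || length(x2) < 2) { excluded[i] <- TRUE; next }
    log2fc[i] <- mean(x2) - mean(x1)
    p[i] <- tryCatch(stats::t.test(x2, x1)$p.value,
                     error = function(e) NA_real_)
    if (is.na(p[i])) excluded[i] <- TRUE
  }
  padj <- stats::p.adjust(p, method = adjust)
  fc <- 2^log2fc
  status <- rep("ns", n)
  sig <- !excluded & !is.na(padj) & padj < p_threshold
  status[sig & fc >= fc_threshold] <- "up"
  status[sig & fc <= 1 / fc_threshold] <- "down"
  status[excluded] <- NA_character_
  out <- data.frame(metabolite = abundance$metabolite,
                    pathway = abundance$pathway,
                    log2fc = log2fc, fold_change = fc, p = p, padj = padj,
                    status = status, excluded = excluded,
                    stringsAsFactors = FALSE)
  attr(out, "comparison") <- sprintf("%s vs %s", glev[2], glev[1])
  class(out) <- c("metabolite_calls", "data.frame")
  out
}

#' Per-pathway differential-abundance (DA) scores
#'
#' `da_score = (n_up - n_down) / n_diff` over the pathway's differential
#' metabolites: +1 when all moved up, -1 when all moved down. Pathways
#' without differential metabolites get `NA` (excluded from charts). The
#' alternative denominator — all metabolites annotated to the pathway — is
#' available via `denominator = "annotated"` and labelled in the output.
#'
#' @param calls Output of [call_differential()].
#' @param pathways Optional pathway ids to score (default: all seen); an
#'   unknown id is an error.
#' @param denominator `"differential"` (default) or `"annotated"`.
#' @return Data frame (pathway, n_annotated, n_diff, n_up, n_down, da_score,
#'   denominator), ordered by pathway id.
#' @export
da_score <- function(calls, pathways = NULL,
                     denominator = c("differential", "annotated")) {
  denominator <- match.arg(denominator)
  keep <- !is.na(calls$status)
  pw_list <- strsplit(calls$pathway, ";\\s*")
  long <- data.frame(
    pathway = unlist(pw_list[keep]),
    status = rep(calls$status[keep], lengths(pw_list[keep])),
    stringsAsFactors = FALSE)
  seen <- sort(unique(long$pathway))
  if (is.null(pathways)) pathways <- seen
  unknown <- setdiff(pathways, seen)
  if (length(unknown))
    stop(sprintf("unknown pathway id '%s'", unknown[1]), call. = FALSE)
  rows <- lapply(pathways, function(pw) {
    st <- long$status[long$pathway == pw]
    n_up <- sum(st == "up"); n_down <- sum(st == "down")
    n_diff <- n_up + n_down
    denom <- if (denominator == "differential") n_diff else length(st)
    data.frame(pathway = pw, n_annotated = length(st), n_diff = n_diff,
               n_up = n_up, n_down = n_down,
               da_score = if (denom == 0) NA_real_ else (n_up - n_down) / denom,
               denominator = denominator, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
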