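# Small shared helpers.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a top-level seed and a stage tag
#' @noRd
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

as_aa_character <- function(x, what = "proteins") {
  if (inherits(x, "AAStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else {
    stop(sprintf("%s must be a named character vector or AAStringSet", what),
         call. = FALSE)
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == ""))
    stop(sprintf("%s must be named by gene id", what), call. = FALSE)
  out
}

as_dna_character <- function(x, what = "sequences") {
  if (inherits(x, "DNAStringSet")) as.character(x)
  else if (is.character(x)) x
  else stop(sprintf("%s must be a character vector or DNAStringSet", what),
            call. = FALSE)
}
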