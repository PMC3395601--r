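# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Deterministic derived seed for a sub-simulation stream. Keeps results
# reproducible from one user-facing integer seed while letting each
# generator consume an independent stream. Always < 2^31 - 1.
derive_seed <- function(seed, offset) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 16807 + 12345 * as.numeric(offset)
  as.integer(s %% m)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# canonical unordered genotype string "A/B" with A <= B
geno_string <- function(a1, a2) {
  ifelse(is.na(a1) | is.na(a2), NA_character_,
         paste(pmin(a1, a2), pmax(a1, a2), sep = "/"))
}

# split "A/B" -> 2-column character matrix; NA rows for missing
split_geno <- function(g) {
  out <- matrix(NA_character_, length(g), 2L)
  ok <- !is.na(g)
  if (any(ok)) {
    parts <- strsplit(g[ok], "/", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("malformed genotype(s): ",
                       paste(g[ok][bad], collapse = ", "), call. = FALSE)
    out[ok, ] <- t(vapply(parts, identity, character(2L)))
  }
  out
}

MISSING_GENO <- "./."

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
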