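#' @keywords internal
"_PACKAGE"

# Standard 20 amino-acid one-letter codes, alphabetical.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Deterministic seed derived from a base seed and identifiers
#'
#' Hashes a base integer seed together with an arbitrary set of string or
#' numeric identifiers into a reproducible integer seed below 2^31.  Used so
#' that every simulated entity (array spot, titration replicate, peak) draws
#' its noise from its own stream: subsetting or reordering the data never
#' reshuffles the noise attached to an entity.
#'
#' Uses a Lehmer-style multiplicative string hash modulo the Mersenne prime
#' 2^31 - 1; all intermediates stay below 2^53 so the arithmetic is exact in
#' doubles.
#'
#' @param seed integer base seed.
#' @param ... identifiers (coerced to character) mixed into the hash.
#' @return a single integer in [1, 2^31 - 2], usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "spot_007", 2)
derive_seed <- function(seed, ...) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  s <- paste(c(format(seed), vapply(list(...), function(x)
    paste(format(x), collapse = ","), character(1))), collapse = "|")
  m <- 2147483647  # 2^31 - 1
  h <- 1
  for (b in utf8ToInt(s)) {
    h <- (h * 48271 + b) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

# Validate a character scalar protein sequence; returns uppercase vector of
# residues.  Unknown letters are rejected.
check_sequence <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  res <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(res), AA_LETTERS)
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-standard amino-acid letters: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  res
}

# Count residues into the fixed 20-letter alphabet.
count_aa <- function(residues) {
  tab <- table(factor(residues, levels = AA_LETTERS))
  as.vector(tab, mode = "numeric") |> stats::setNames(AA_LETTERS)
}
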