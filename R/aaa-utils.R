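#' @keywords internal
"_PACKAGE"

# Run code with a locally-seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a per-scenario seed from a global seed
#'
#' Fans a single user-supplied seed out into independent per-generator
#' substreams by stable hashing of a scenario name, so that two generators run
#' under the same global seed do not share a random stream. The result is
#' always a valid 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param scenario character scenario name, e.g. `"catalog"`.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, scenario) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(scenario))
  h <- 5381
  for (b in utf8ToInt(scenario)) h <- (h * 33 + b) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 31 + h) %% 2147483647)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# codon -> single-letter amino acid, "*" for stop ("X" for ambiguous codons)
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  k <- n %/% 3L
  if (k == 0L) return(character(0))
  substring(seq, seq(1L, by = 3L, length.out = k), seq(3L, by = 3L, length.out = k))
}
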