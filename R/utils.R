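DNA_BASES <- c("A", "C", "G", "T")

# Validate that sequences are nonempty uppercase-able A/C/G/T. Ambiguity
# codes are rejected: the scoring scheme is defined on the four bases only.
check_dna <- function(x, what = "sequence") {
  if (length(x) == 0 || any(is.na(x)) || any(!nzchar(x))) {
    abort(sprintf("every %s must be a nonempty DNA string", what))
  }
  x <- toupper(x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub("[ACGT]", "", x[bad]), "")))
    abort(sprintf(
      "%s contains non-ACGT characters (%s); ambiguity codes are not supported",
      what, paste(ch, collapse = ", ")
    ))
  }
  x
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of A/C/G/T sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  x <- check_dna(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("a single integer seed is required")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one seed, so stages consume
# independent, reproducible randomness.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# offset a seed without risking integer overflow
seed_offset <- function(seed, k) {
  as.integer((as.numeric(seed) + k) %% (.Machine$integer.max - 1)) + 1L
}
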