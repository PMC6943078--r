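# Internal helpers shared across modules.

# Run code with a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# 1-based positions where two strings differ, over the shorter extent.
# '.' vs '.' is equal; '.' vs base differs.
seq_diff_positions <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(integer(0))
  av <- utf8ToInt(substr(a, 1L, n))
  bv <- utf8ToInt(substr(b, 1L, n))
  which(av != bv)
}

# Translate a (possibly gapped) nucleotide string codon-by-codon in frame 1.
# Codons containing '.', 'N' or fewer than 3 characters translate to 'X'.
translate_gapped <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(character(0))
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa) | grepl("[.N]", codons)] <- "X"
  aa
}

# Round half away from zero (commercial rounding) to `digits` decimals.
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Format a percentage column for serialization: 2 decimals, NA -> "".
format_percent <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.2f", round_half_up(x, 2L)))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
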