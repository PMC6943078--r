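# Closest-reference relationships and substitution annotations for candidate
# novel alleles. All comparisons are positional on a shared frame (the IMGT
# gap frame for V genes); alignment-based edit distance is out of scope.

#' Hamming distance on a shared gap frame
#'
#' Counts aligned positions at which two sequences differ, over the shorter
#' 3' extent only (novel V inferences are often 3'-truncated by junction
#' trimming, and the unmatched tail is not evidence of difference). A gap
#' (`.`) aligned against a base counts as a difference; a gap against a gap
#' does not.
#'
#' @param a,b Nucleotide strings on the same frame (gapped for V).
#' @return Integer count of differing aligned positions.
#' @examples
#' gapped_hamming("AC.T", "ACGT") # 1
#' @export
gapped_hamming <- function(a, b) {
  length(seq_diff_positions(a, b))
}

#' Find the closest allele by gapped Hamming distance
#'
#' @param novel One-row slice of a `reference_set` (the candidate allele), or
#'   an allele name resolved against `candidates`.
#' @param candidates A `reference_set` tibble of same-segment alleles to
#'   search (the candidate itself is excluded by name).
#' @return A one-row tibble with `name` (closest candidate) and `nt_diff`.
#'   Ties are broken by the lexicographically smallest allele name.
#' @export
closest_allele <- function(novel, candidates) {
  if (is.character(novel)) novel <- reference_row(candidates, novel)
  pool <- candidates[candidates$name != novel$name, ]
  pool <- pool[pool$segment == novel$segment, ]
  if (nrow(pool) == 0L) {
    abort(paste0("no candidate alleles to compare '", novel$name, "' against"))
  }
  d <- vapply(pool$gapped_seq, gapped_hamming, integer(1), a = novel$gapped_seq,
              USE.NAMES = FALSE)
  best <- which(d == min(d))
  pick <- best[order(pool$name[best])][1L]
  tibble(name = pool$name[pick], nt_diff = d[pick])
}

#' Nucleotide and amino-acid substitution strings between two alleles
#'
#' Formats each differing aligned position as `<refBase><position><altBase>`
#' (e.g. `G112A`), with positions on the IMGT-gapped frame for V genes and
#' 1-based coding-sequence positions for D/J genes. Amino-acid substitutions
#' (e.g. `A96N`) are derived by translating frame-1 codons of the shared
#' frame, so V codon numbers are IMGT codon numbers. Codons containing a gap
#' or `N` translate to `X` and never contribute amino-acid entries (a gap
#' column is not evidence of an amino-acid change). A base aligned against a
#' reference gap is reported as `ins<position><base>`; a gap in the novel
#' sequence against a reference base as `<base><position>del`.
#'
#' D genes lack a fixed reading frame, so their amino-acid list is empty.
#'
#' @param novel,ref One-row slices of a `reference_set`, same segment (both
#'   gapped on the same frame for V).
#' @return A list with character vectors `nt` and `aa`.
#' @examples
#' ref <- synthetic_reference_set()
#' substitution_strings(ref[ref$name == "IGHV_S1", ],
#'                      ref[ref$name == "IGHV1-69*01", ])
#' @export
substitution_strings <- function(novel, ref) {
  if (novel$segment != ref$segment) {
    abort("substitution strings require alleles of the same segment")
  }
  a <- ref$gapped_seq
  b <- novel$gapped_seq
  pos <- seq_diff_positions(b, a)
  if (length(pos) == 0L) {
    return(list(nt = character(0), aa = character(0)))
  }
  ra <- substring(a, pos, pos)
  rb <- substring(b, pos, pos)
  nt <- character(length(pos))
  plain <- ra != "." & rb != "."
  nt[plain] <- sprintf("%s%d%s", ra[plain], pos[plain], rb[plain])
  ins <- ra == "."
  nt[ins] <- sprintf("ins%d%s", pos[ins], rb[ins])
  del <- rb == "."
  nt[del] <- sprintf("%s%ddel", ra[del], pos[del])
  if (any(ins | del)) {
    inform(sprintf("%d difference(s) fall in gap columns; marked ins/del",
                   sum(ins | del)))
  }

  aa <- character(0)
  if (novel$segment != "D") {
    n <- min(nchar(a), nchar(b))
    n <- n - n %% 3L
    aa_ref <- translate_gapped(substr(a, 1L, n))
    aa_new <- translate_gapped(substr(b, 1L, n))
    differs <- aa_ref != aa_new & aa_ref != "X" & aa_new != "X"
    idx <- which(differs)
    aa <- sprintf("%s%d%s", aa_ref[idx], idx, aa_new[idx])
  }
  list(nt = nt, aa = aa)
}

#' Closest-reference annotation block for a novel allele
#'
#' Computes the full difference annotation reported for an inferred allele:
#' the closest reference allele overall, the closest allele present in the
#' subject's own genotype, nucleotide and amino-acid difference counts and
#' substitution lists. Because the subject's genotype is a subset of the
#' reference set, `nt_diff_host >= nt_diff` always.
#'
#' @param novel One-row slice of a `reference_set` (the candidate allele).
#' @param reference The full `reference_set`.
#' @param host_names Character vector of reference allele names observed in
#'   the subject's genotype.
#' @return One-row tibble with `closest_reference`, `closest_host`,
#'   `nt_diff`, `nt_diff_host`, `nt_substitutions`, `aa_diff`,
#'   `aa_substitutions` (substitution lists collapsed comma-separated).
#' @export
allele_diff <- function(novel, reference, host_names) {
  if (is.character(novel)) novel <- reference_row(reference, novel)
  pool <- reference[!reference$is_novel & reference$segment == novel$segment, ]
  best <- closest_allele(novel, pool)
  host_pool <- pool[pool$name %in% host_names, ]
  best_host <- if (nrow(host_pool) > 0L) {
    closest_allele(novel, host_pool)
  } else {
    tibble(name = NA_character_, nt_diff = NA_integer_)
  }
  subs <- substitution_strings(novel, reference_row(reference, best$name))
  tibble(
    closest_reference = best$name,
    closest_host = best_host$name,
    nt_diff = best$nt_diff,
    nt_diff_host = best_host$nt_diff,
    nt_substitutions = paste(subs$nt, collapse = ","),
    aa_diff = length(subs$aa),
    aa_substitutions = paste(subs$aa, collapse = ",")
  )
}
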