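# Independent brute-force recount of the genotype report, written against the
# word-formulas and kept separate from the package's main path: explicit
# per-read loops and character-by-character comparisons.

oracle_is_unmutated <- function(seq_alignment, vend, allele_gapped) {
  s <- strsplit(seq_alignment, "", fixed = TRUE)[[1]]
  g <- strsplit(allele_gapped, "", fixed = TRUE)[[1]]
  if (is.na(vend)) vend <- min(length(s), length(g))
  vend <- min(vend, length(s), length(g))
  for (i in seq_len(vend)) {
    if (s[i] == "N") return(FALSE)
    if (s[i] != g[i]) return(FALSE)
  }
  TRUE
}

oracle_diff_count <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- min(length(x), length(y))
  d <- 0L
  for (i in seq_len(n)) if (x[i] != y[i]) d <- d + 1L
  d
}

# Recount every field of the V-segment genotype report from scratch.
oracle_genotype <- function(reads, reference) {
  reads <- reads[reads$productive, ]
  n <- nrow(reads)
  first_call <- character(n)
  ambiguous <- logical(n)
  for (i in seq_len(n)) {
    parts <- trimws(strsplit(reads$v_call[i], ",", fixed = TRUE)[[1]])
    first_call[i] <- parts[1]
    ambiguous[i] <- length(parts) > 1
  }
  unmut <- logical(n)
  for (i in seq_len(n)) {
    j <- match(first_call[i], reference$name)
    unmut[i] <- if (ambiguous[i] || is.na(j)) FALSE else {
      oracle_is_unmutated(reads$sequence_alignment[i],
                          reads$v_germline_end[i],
                          reference$gapped_seq[j])
    }
  }
  cdr3 <- if (any(!is.na(reads$junction_aa))) reads$junction_aa else reads$cdr3
  has_umi <- any(!is.na(reads$umi))

  alleles <- sort(unique(first_call))
  out <- NULL
  total_unmut <- sum(unmut)
  for (a in alleles) {
    mine <- first_call == a
    gene <- sub("\\*.*$", "", {
      j <- match(a, reference$name)
      if (is.na(j)) a else reference$name[j]
    })
    same_gene <- vapply(first_call, function(x) {
      j <- match(x, reference$name)
      g <- if (is.na(j)) sub("\\*.*$", "", x) else reference$gene[j]
      g == gene
    }, logical(1))
    row <- data.frame(
      sequence_id = a,
      sequences = sum(mine),
      unmutated_sequences = sum(mine & unmut),
      unmutated_umis = if (has_umi) length(unique(reads$umi[mine & unmut & !is.na(reads$umi)])) else NA_integer_,
      assigned_unmutated_frequency = sum(mine & unmut) / sum(mine) * 100,
      allelic_percentage = if (sum(same_gene & unmut) > 0) {
        sum(mine & unmut) / sum(same_gene & unmut) * 100
      } else {
        NA_real_
      },
      unmutated_frequency = if (total_unmut > 0) {
        sum(mine & unmut) / total_unmut * 100
      } else {
        NA_real_
      },
      unique_vs = length(unique(na.omit(first_call[mine]))),
      unique_ds = length(unique(na.omit(reads$d_call[mine]))),
      unique_js = length(unique(na.omit(reads$j_call[mine]))),
      unique_cdr3s = length(unique(na.omit(cdr3[mine]))),
      unique_vs_unmutated = length(unique(na.omit(first_call[mine & unmut]))),
      unique_ds_unmutated = length(unique(na.omit(reads$d_call[mine & unmut]))),
      unique_js_unmutated = length(unique(na.omit(reads$j_call[mine & unmut]))),
      unique_cdr3s_unmutated = length(unique(na.omit(cdr3[mine & unmut])))
    )
    out <- rbind(out, row)
  }
  out
}
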