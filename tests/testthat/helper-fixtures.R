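# Tiny hand-built fixtures, written and read through the package's own IO so
# tests also exercise the FASTA/TSV paths.

# A minimal two-V-gene, one-D, one-J-gene reference with a novel V candidate.
# V frame: 10 columns with gaps at 3 and 7 (8 coding bases).
tiny_fasta <- function(path = tempfile(fileext = ".fasta")) {
  writeLines(c(
    ">IGHV9-1*01", "AC.GTA.CGT",
    ">IGHV9-1*02", "AC.GTA.CCT",
    ">IGHV8-2*01", "TT.GCA.GGA",
    ">IGHV_T1",    "AC.ATA.CGT",
    ">IGHD9-9*01", "GGGTT",
    ">IGHJ9*01",   "ATTACTGG",
    ">IGHJ9*02",   "ATTACTGC"
  ), path)
  path
}

tiny_reference <- function() {
  suppressMessages(read_gapped_fasta(tiny_fasta()))
}

# One rearrangement row with sensible defaults against tiny_reference():
# a full-length unmutated IGHV9-1*01 read.
tiny_read <- function(sequence_id = "r1",
                      v_call = "IGHV9-1*01",
                      j_call = "IGHJ9*01",
                      sequence_alignment = "AC.GTA.CGTAAACCCATTACTGG",
                      v_germline_end = 10L,
                      j_sequence_alignment = "ATTACTGG",
                      productive = TRUE,
                      d_call = "IGHD9-9*01",
                      junction_aa = "CAK",
                      cdr3 = "AAACCC",
                      umi = NA_character_,
                      quality = NA_character_) {
  tibble::tibble(
    sequence_id = sequence_id, v_call = v_call, j_call = j_call,
    sequence_alignment = sequence_alignment, productive = productive,
    d_call = d_call, junction_aa = junction_aa, cdr3 = cdr3, umi = umi,
    quality = quality, j_sequence_alignment = j_sequence_alignment,
    v_germline_end = as.integer(v_germline_end)
  )
}

tiny_reads <- function(...) {
  dplyr::bind_rows(...)
}

# Random gapped V pair generator for property tests: a base sequence with gap
# columns, and a variant with k substitutions at non-gap columns.
random_gapped_pair <- function(width = 60L, n_gaps = 6L, k = 3L) {
  chars <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
  gaps <- sample(seq_len(width), n_gaps)
  chars[gaps] <- "."
  base <- paste(chars, collapse = "")
  nongap <- setdiff(seq_len(width), gaps)
  pos <- sample(nongap, min(k, length(nongap)))
  alt <- chars
  for (p in pos) alt[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  list(base = base, variant = paste(alt, collapse = ""), positions = sort(pos))
}
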