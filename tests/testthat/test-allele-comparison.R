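test_that("gapped Hamming distance: identity, substitution, gap-vs-base, truncation", {
  expect_equal(gapped_hamming("ACGT", "ACGT"), 0L)
  expect_equal(gapped_hamming("ACGT", "ACGA"), 1L)
  expect_equal(gapped_hamming("AC.T", "ACGT"), 1L)
  expect_equal(gapped_hamming("AC.T", "AC.T"), 0L)
  # 3' truncated tails are not differences
  expect_equal(gapped_hamming("ACGTAA", "ACGT"), 0L)
})

test_that("gapped Hamming is symmetric and zero iff equal over the compared extent", {
  set.seed(11)
  for (i in 1:25) {
    p <- random_gapped_pair(width = 40L, n_gaps = 5L, k = sample(0:4, 1))
    expect_equal(gapped_hamming(p$base, p$variant),
                 gapped_hamming(p$variant, p$base))
    expect_equal(gapped_hamming(p$base, p$variant) == 0L,
                 p$base == p$variant)
  }
})

test_that("closest allele minimizes distance with a lexicographic tie-break", {
  ref <- tiny_reference()
  novel <- ref[ref$name == "IGHV_T1", ]
  # distance 1 to IGHV9-1*01, 2 to *02, many to IGHV8-2*01
  got <- closest_allele(novel, ref[!ref$is_novel, ])
  expect_equal(got$name, "IGHV9-1*01")
  expect_equal(got$nt_diff, 1L)

  # exhaustive tie-break check: both candidates at distance 1
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">IGHVZ*01", "ACGT",
               ">IGHVB*01", "ACGA",
               ">IGHVA*01", "ACCT"), fa)
  pool <- suppressMessages(read_gapped_fasta(fa))
  tie <- closest_allele(pool[pool$name == "IGHVZ*01", ], pool)
  expect_equal(tie$name, "IGHVA*01")  # smaller name wins at equal distance
  expect_equal(tie$nt_diff, 1L)

  expect_error(closest_allele(novel, ref[ref$segment == "J", ]), "no candidate")
})

test_that("substitution strings carry IMGT positions for V and codon-frame amino acids", {
  # nucleotide: ref G at a gapped column, novel A => G<pos>A
  ref <- tiny_reference()
  subs <- suppressMessages(substitution_strings(
    ref[ref$name == "IGHV_T1", ], ref[ref$name == "IGHV9-1*01", ]))
  expect_equal(subs$nt, "G4A")

  # amino acid at codon 96: GCT (Ala) -> AAT (Asn) gives A96N
  set.seed(5)
  chars <- sample(c("A", "C", "G", "T"), 288, replace = TRUE)
  chars[286:288] <- c("G", "C", "T")
  base <- paste(chars, collapse = "")
  chars[286:288] <- c("A", "A", "T")
  variant <- paste(chars, collapse = "")
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">IGHV7-7*01", base, ">IGHV_X1", variant), fa)
  pool <- suppressMessages(read_gapped_fasta(fa))
  subs2 <- substitution_strings(pool[pool$name == "IGHV_X1", ],
                                pool[pool$name == "IGHV7-7*01", ])
  expect_equal(subs2$nt, c("G286A", "C287A"))
  expect_true("A96N" %in% subs2$aa)

  # identity
  subs3 <- substitution_strings(pool[pool$name == "IGHV7-7*01", ],
                                pool[pool$name == "IGHV7-7*01", ])
  expect_equal(subs3$nt, character(0))
  expect_equal(subs3$aa, character(0))
})

test_that("codons touching gap columns translate to X and yield no aa entries", {
  fa <- tempfile(fileext = ".fasta")
  # difference inside the first codon, which contains a gap column
  writeLines(c(">IGHV6-6*01", "A.CGTACTG", ">IGHV_G1", "A.TGTACTG"), fa)
  pool <- suppressMessages(read_gapped_fasta(fa))
  subs <- substitution_strings(pool[pool$name == "IGHV_G1", ],
                               pool[pool$name == "IGHV6-6*01", ])
  expect_equal(subs$nt, "C3T")
  expect_equal(subs$aa, character(0))
})

test_that("nt_diff equals the substitution-list length on random pairs", {
  set.seed(202)
  for (i in 1:40) {
    p <- random_gapped_pair(width = 90L, n_gaps = 8L, k = sample(0:6, 1))
    fa <- tempfile(fileext = ".fasta")
    writeLines(c(">IGHV5-5*01", p$base, ">IGHV_R1", p$variant), fa)
    pool <- suppressMessages(read_gapped_fasta(fa))
    subs <- substitution_strings(pool[2, ], pool[1, ])
    expect_length(subs$nt, gapped_hamming(p$base, p$variant))
    expect_length(subs$nt, length(p$positions))
    # every reported position is a true difference position
    expect_equal(sort(as.integer(gsub("[^0-9]", "", subs$nt))), p$positions)
  }
})

test_that("allele_diff constrains closest_host to the subject's genotype", {
  ref <- tiny_reference()
  d <- suppressMessages(allele_diff(ref[ref$name == "IGHV_T1", ], ref,
                                    host_names = "IGHV9-1*02"))
  expect_equal(d$closest_reference, "IGHV9-1*01")
  expect_equal(d$nt_diff, 1L)
  expect_equal(d$closest_host, "IGHV9-1*02")
  expect_equal(d$nt_diff_host, 2L)
  expect_gte(d$nt_diff_host, d$nt_diff)
  expect_equal(d$nt_substitutions, "G4A")
})
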