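test_that("exact-match detection ignores gap columns and trimmed 3' tails", {
  ref <- tiny_reference()
  v01 <- ref[ref$name == "IGHV9-1*01", ]

  full <- tiny_read("r1")                                    # identical
  mut <- tiny_read("r2", sequence_alignment = "AC.GTA.CGAAAACCCATTACTGG")
  trimmed <- tiny_read("r3", sequence_alignment = "AC.GTA.CAAACCCATTACTGG",
                       v_germline_end = 8L)                  # last 2 V nt trimmed
  with_n <- tiny_read("r4", sequence_alignment = "AC.GTA.CGNAAACCCATTACTGG")
  reads <- tiny_reads(full, mut, trimmed, with_n)
  expect_equal(is_unmutated(reads, v01), c(TRUE, FALSE, TRUE, FALSE))

  # missing alignment -> NA with a warning (excluded, not counted mutated)
  na_read <- tiny_read("r5", sequence_alignment = NA_character_)
  expect_warning(flag <- is_unmutated(na_read, v01), "excluded")
  expect_true(is.na(flag))

  # J exact match is anchored at the germline 3' end (5' trimming allowed)
  j01 <- ref[ref$name == "IGHJ9*01", ]
  jreads <- tiny_reads(
    tiny_read("r6", j_sequence_alignment = "ATTACTGG"),
    tiny_read("r7", j_sequence_alignment = "TACTGG"),   # 5'-trimmed, matches
    tiny_read("r8", j_sequence_alignment = "TACTGC")    # mismatch at 3' end
  )
  expect_equal(is_unmutated(jreads, j01), c(TRUE, TRUE, FALSE))
})

test_that("percentage fields follow the report word-formulas", {
  ref <- tiny_reference()
  # 100 reads on one allele, 40 exact matches -> assigned_unmutated 40.00
  mut_seq <- "AC.GTA.CTTAAACCCATTACTGG"
  reads <- tiny_reads(
    dplyr::bind_rows(lapply(1:40, function(i) tiny_read(paste0("u", i)))),
    dplyr::bind_rows(lapply(1:60, function(i) {
      tiny_read(paste0("m", i), sequence_alignment = mut_seq)
    }))
  )
  gt <- suppressMessages(compute_genotype(reads, ref))
  row <- tidy(gt)
  expect_equal(row$sequences, 100L)
  expect_equal(row$unmutated_sequences, 40L)
  expect_equal(row$assigned_unmutated_frequency, 40)
  expect_equal(row$allelic_percentage, 100)
  expect_equal(row$unmutated_frequency, 100)

  # two alleles of one gene with 30 and 10 exact matches -> 75 / 25
  reads2 <- tiny_reads(
    dplyr::bind_rows(lapply(1:30, function(i) tiny_read(paste0("a", i)))),
    dplyr::bind_rows(lapply(1:10, function(i) {
      tiny_read(paste0("b", i), v_call = "IGHV9-1*02",
                sequence_alignment = "AC.GTA.CCTAAACCCATTACTGG")
    }))
  )
  gt2 <- suppressMessages(compute_genotype(reads2, ref))
  rows2 <- tidy(gt2)
  expect_equal(rows2$allelic_percentage[rows2$sequence_id == "IGHV9-1*01"], 75)
  expect_equal(rows2$allelic_percentage[rows2$sequence_id == "IGHV9-1*02"], 25)
  expect_equal(sum(rows2$unmutated_frequency), 100)
})

test_that("ambiguous calls count as sequences but never as exact matches", {
  ref <- tiny_reference()
  reads <- tiny_reads(
    tiny_read("r1"),
    tiny_read("r2", v_call = "IGHV9-1*01,IGHV9-1*02")
  )
  gt <- suppressMessages(compute_genotype(reads, ref))
  row <- tidy(gt)
  expect_equal(row$sequences, 2L)
  expect_equal(row$unmutated_sequences, 1L)
})

test_that("genotype matches the brute-force oracle on a simulated repertoire", {
  ref <- synthetic_reference_set()
  sim <- simulate_repertoire(sim_config(n_reads = 200, seed = 31,
                                        mutation_rate = 0.02), ref)
  gt <- suppressMessages(compute_genotype(sim$reads, ref))
  rows <- tidy(gt)
  oracle <- oracle_genotype(sim$reads, ref)
  expect_equal(rows$sequence_id, oracle$sequence_id)
  for (f in setdiff(names(oracle), "sequence_id")) {
    expect_equal(as.numeric(rows[[f]]), as.numeric(oracle[[f]]),
                 tolerance = 1e-12, label = f)
  }
})

test_that("unknown alleles get a row with empty difference fields", {
  ref <- tiny_reference()
  reads <- tiny_reads(
    tiny_read("r1"),
    tiny_read("r2", v_call = "IGHV9-9*99",
              sequence_alignment = "GGGGTTTTAAACCCATTACTGG",
              v_germline_end = NA)
  )
  gt <- suppressMessages(compute_genotype(reads, ref))
  rows <- tidy(gt)
  unk <- rows[rows$sequence_id == "IGHV9-9*99", ]
  expect_equal(unk$sequences, 1L)
  expect_true(is.na(unk$closest_reference))
  expect_equal(gt$unknown_alleles, "IGHV9-9*99")

  expect_error(suppressMessages(compute_genotype(tiny_read(productive = FALSE), ref)),
               "empty repertoire")
})

test_that("genotype CSV keeps the standard header, empty cells and 2-decimal percents", {
  ref <- tiny_reference()
  reads <- tiny_reads(
    dplyr::bind_rows(lapply(1:3, function(i) tiny_read(paste0("r", i)))),
    tiny_read("r4", sequence_alignment = "AC.GTA.CTTAAACCCATTACTGG")
  )
  gt <- suppressMessages(compute_genotype(reads, ref))
  path <- tempfile(fileext = ".csv")
  write_genotype_csv(gt, path)
  lines <- readLines(path)
  expect_identical(lines[1],
    paste0("sequence_id,sequences,closest_reference,closest_host,nt_diff,",
           "nt_diff_host,nt_substitutions,aa_diff,aa_substitutions,",
           "unmutated_sequences,assigned_unmutated_frequency,unmutated_umis,",
           "allelic_percentage,unmutated_frequency,unique_vs,unique_ds,",
           "unique_js,unique_cdr3s,unique_vs_unmutated,unique_ds_unmutated,",
           "unique_js_unmutated,unique_cdr3s_unmutated,haplotyping_gene"))
  expect_length(lines, 2L)  # header + one allele row

  # percents carry two decimals; no-UMI column yields an empty cell
  cells <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  expect_equal(cells[11], "75.00")
  expect_equal(cells[12], "")

  # round trip preserves values
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$sequences, 4L)
  expect_equal(back$unmutated_sequences, 3L)
  expect_equal(back$assigned_unmutated_frequency, 75)
})

test_that("allelic percentages are empty (not 0/0) for genes without exact matches", {
  ref <- tiny_reference()
  reads <- tiny_reads(
    tiny_read("r1"),
    tiny_read("r2", v_call = "IGHV8-2*01",
              sequence_alignment = "TT.GCA.GGTAAACCCATTACTGG")  # mutated
  )
  gt <- suppressMessages(compute_genotype(reads, ref))
  rows <- tidy(gt)
  expect_true(is.na(rows$allelic_percentage[rows$sequence_id == "IGHV8-2*01"]))
  expect_equal(rows$allelic_percentage[rows$sequence_id == "IGHV9-1*01"], 100)
})
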