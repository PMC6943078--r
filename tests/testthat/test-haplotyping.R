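test_that("allele usage tabulates unambiguous calls per gene", {
  reads <- tiny_reads(
    dplyr::bind_rows(lapply(1:5, function(i) tiny_read(paste0("a", i)))),
    dplyr::bind_rows(lapply(1:5, function(i) {
      tiny_read(paste0("b", i), j_call = "IGHJ9*02")
    })),
    tiny_read("c1", j_call = "IGHJ9*01,IGHJ9*02")  # ambiguous: not counted
  )
  u <- allele_usage(reads, segment = "J")
  expect_equal(u$gene, c("IGHJ9", "IGHJ9"))
  expect_equal(u$allele, c("IGHJ9*01", "IGHJ9*02"))
  expect_equal(u$n, c(5L, 5L))
  expect_equal(nrow(allele_usage(reads[0, ], "J")), 0L)
})

test_that("usage restricted to unmutated reads when a reference is given", {
  ref <- tiny_reference()
  reads <- tiny_reads(
    tiny_read("r1", j_sequence_alignment = "ATTACTGG"),
    tiny_read("r2", j_sequence_alignment = "ATAACTGG")  # J mutation
  )
  u <- allele_usage(reads, segment = "J", reference = ref)
  expect_equal(u$n, 1L)
  expect_true(attr(u, "unmutated_only"))
})

test_that("anchor detection needs exactly two well-supported alleles and enough reads", {
  usage <- function(n1, n2, n3 = NULL) {
    alleles <- c("IGHJ6*02", "IGHJ6*03", "IGHJ6*04")[seq_len(2 + !is.null(n3))]
    out <- tibble::tibble(gene = "IGHJ6", allele = alleles,
                          n = as.integer(c(n1, n2, n3)))
    class(out) <- c("allele_usage", class(out))
    out
  }
  # 48/52 split at total 1000 qualifies with defaults
  got <- detect_anchor(usage(480, 520))
  expect_equal(got$gene, "IGHJ6")
  expect_equal(got$allele1, "IGHJ6*03")  # larger count first
  expect_equal(got$allele2, "IGHJ6*02")

  # 95/5 fails min_minor_fraction
  expect_equal(nrow(detect_anchor(usage(950, 50))), 0L)
  # too few reads in total
  expect_equal(nrow(detect_anchor(usage(38, 42))), 0L)
  expect_equal(nrow(detect_anchor(usage(38, 42), min_total = 50)), 1L)
  # three alleles above the fraction is not heterozygosity at one locus
  expect_equal(nrow(detect_anchor(usage(340, 330, 330))), 0L)
  # candidates sorted by gene total, descending
  two <- dplyr::bind_rows(usage(480, 520),
                          tibble::tibble(gene = "IGHJ4", allele = c("IGHJ4*02", "IGHJ4*03"),
                                         n = c(800L, 700L)))
  expect_equal(detect_anchor(two)$gene, c("IGHJ4", "IGHJ6"))
})

test_that("exclusivity is strict zero on the minor haplotype with enough major reads", {
  expect_equal(exclusivity_score(25, 0, 10), tibble::tibble(exclusive = TRUE, ratio = 0))
  expect_equal(exclusivity_score(25, 1, 10), tibble::tibble(exclusive = FALSE, ratio = 0.04))
  expect_equal(exclusivity_score(0, 0, 10), tibble::tibble(exclusive = FALSE, ratio = 0))
  expect_equal(exclusivity_score(9, 0, 10)$exclusive, FALSE)  # below min_reads
  expect_equal(exclusivity_score(0, 25, 10)$exclusive, TRUE)  # symmetric
})

test_that("haplotype counts split reads by anchor allele and conserve totals", {
  mk <- function(id, v, j) tiny_read(id, v_call = v, j_call = j)
  reads <- tiny_reads(
    dplyr::bind_rows(lapply(1:10, function(i) mk(paste0("a", i), "IGHV9-1*01", "IGHJ9*01"))),
    dplyr::bind_rows(lapply(1:12, function(i) mk(paste0("b", i), "IGHV9-1*01", "IGHJ9*02"))),
    dplyr::bind_rows(lapply(1:15, function(i) mk(paste0("c", i), "IGHV_T1", "IGHJ9*02"))),
    mk("amb", "IGHV8-2*01", "IGHJ9*01,IGHJ9*02")  # ambiguous anchor: excluded
  )
  rep <- haplotype_counts(reads, "IGHJ9", c("IGHJ9*01", "IGHJ9*02"))
  expect_s3_class(rep, "haplotype_report")

  v01 <- rep[rep$allele == "IGHV9-1*01", ]
  expect_equal(c(v01$count_anchor1, v01$count_anchor2), c(10L, 12L))
  expect_false(v01$exclusive)

  t1 <- rep[rep$allele == "IGHV_T1", ]
  expect_equal(c(t1$count_anchor1, t1$count_anchor2), c(0L, 15L))
  expect_true(t1$exclusive)

  # conservation: column sums equal the unambiguous anchor-allele read counts
  expect_equal(sum(rep$count_anchor1) + sum(rep$count_anchor2), 37L)
  # IGHV8-2*01 had only the ambiguous-anchor read: absent from the report
  expect_false("IGHV8-2*01" %in% rep$allele)

  expect_error(haplotype_counts(reads, "IGHJ6", c("IGHJ6*02", "IGHJ6*03")),
               "not found")
})

test_that("simulated haplotype linkage is recovered and homozygotes yield no anchor", {
  ref <- synthetic_reference_set()
  sim <- simulate_repertoire(sim_config(n_reads = 2000, seed = 19), ref)
  reads <- suppressMessages(filter_productive(sim$reads))
  anchors <- detect_anchor(allele_usage(reads, "J", reference = ref))
  expect_equal(anchors$gene, "IGHJ6")
  rep <- haplotype_counts(reads, "IGHJ6", sort(c(anchors$allele1, anchors$allele2)))
  s1 <- rep[rep$allele == "IGHV_S1", ]
  expect_true(s1$exclusive)
  expect_equal(s1$count_anchor1, 0L)

  # column sums match the generator's anchor cross-tabulation
  ct <- sim$truth$cross_tab
  expect_equal(sum(rep$count_anchor1), sum(ct$count_anchor1))
  expect_equal(sum(rep$count_anchor2), sum(ct$count_anchor2))

  hom <- simulate_repertoire(
    sim_config(n_reads = 2000, seed = 19,
               anchor = list(gene = "IGHJ6", alleles = c("IGHJ6*02", "IGHJ6*03"),
                             split = c(1, 0)),
               linkage = c(IGHV_S1 = "IGHJ6*02")), ref)
  hreads <- suppressMessages(filter_productive(hom$reads))
  expect_equal(nrow(detect_anchor(allele_usage(hreads, "J", reference = ref))), 0L)
})
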