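# Seedable synthetic AIRR repertoire generator with exact ground truth.
# Annotation is taken as oracle-correct (emitted calls are the true alleles):
# the generator exists to validate the evidence statistics, which presuppose
# an upstream annotator.

#' A synthetic IGH germline reference set
#'
#' Builds a small, fully synthetic heavy-chain reference set used by the
#' examples, the simulator defaults and the test fixtures: four V genes with
#' two or three alleles each on a 312-column IMGT-style gap frame (gap blocks
#' in the CDR regions differ between genes), two D alleles, six J genes with
#' IGHJ6 carrying two alleles, and one candidate novel allele `IGHV_S1`
#' derived from IGHV1-69*01 by the single substitution G112A. Sequences are
#' pseudo-random but fixed (internal constant seed); they are synthetic and
#' carry no biological meaning beyond their structure.
#'
#' @return A `reference_set` tibble (locus IGH).
#' @export
synthetic_reference_set <- function() {
  local_seed(104729L, {
    width <- 312L
    rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")
    gapped_v <- function(gap_cols) {
      chars <- strsplit(rand_nt(width), "", fixed = TRUE)[[1L]]
      chars[gap_cols] <- "."
      paste(chars, collapse = "")
    }
    mutate_at <- function(seq, pos, base) {
      chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
      stopifnot(all(chars[pos] != "."))
      chars[pos] <- base
      paste(chars, collapse = "")
    }
    force_base <- function(seq, pos, base) mutate_at(seq, pos, base)

    v1_2 <- gapped_v(c(31:36, 61:63))
    v1_69 <- force_base(gapped_v(31:36), 112L, "G")
    v3_23 <- gapped_v(c(31:33, 61:66))
    v4_34 <- gapped_v(c(31:36, 61:66, 73L))

    nm <- c("IGHV1-2*02", "IGHV1-2*04",
            "IGHV1-69*01", "IGHV1-69*02", "IGHV1-69*06",
            "IGHV3-23*01", "IGHV3-23*04",
            "IGHV4-34*01", "IGHV4-34*02",
            "IGHV_S1",
            "IGHD2-2*01", "IGHD3-10*01",
            "IGHJ1*01", "IGHJ2*01", "IGHJ3*01", "IGHJ4*02", "IGHJ5*01",
            "IGHJ6*02", "IGHJ6*03")
    j6_02 <- rand_nt(62L)
    seqs <- c(
      v1_2, mutate_at(v1_2, c(45L, 201L), c("A", "T")),
      v1_69, mutate_at(v1_69, 150L, "C"), mutate_at(v1_69, c(88L, 230L), c("T", "G")),
      v3_23, mutate_at(v3_23, c(120L, 240L), c("G", "A")),
      v4_34, mutate_at(v4_34, c(99L, 187L), c("C", "A")),
      mutate_at(v1_69, 112L, "A"),
      rand_nt(22L), rand_nt(25L),
      rand_nt(52L), rand_nt(53L), rand_nt(50L), rand_nt(48L), rand_nt(51L),
      j6_02, mutate_at(j6_02, 30L, "A")
    )
    # guarantee the engineered distances survive the random draws
    stopifnot(gapped_hamming(seqs[3L], seqs[10L]) == 1L)
    if (substring(j6_02, 30L, 30L) == "A") {
      seqs[19L] <- mutate_at(j6_02, 30L, "C")
    }
    build_reference_set(nm, seqs, locus = "IGH")
  })
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a subject genotype
#' with two alleles per gene plus one novel allele, somatic mutation of the
#' V segment at a per-base rate, 3' V-end trimming at the junction, UMI
#' duplication, CDR3 diversity, a heterozygous anchor J gene, and
#' haplotype linkage of the novel allele to one anchor allele. Defaults are
#' matched to the synthetic reference set of [synthetic_reference_set()].
#'
#' @param seed Integer RNG seed; the same seed reproduces the repertoire
#'   byte-identically.
#' @param n_reads Number of reads to emit (default 10000).
#' @param genotype Data frame `allele`, `weight`: the subject's expressed
#'   alleles of the studied segment and their usage weights.
#' @param mutation_rate Per-base substitution probability over the covered V
#'   positions (default 0.01).
#' @param trim_probs Named numeric vector: probability of trimming 0, 1, ...
#'   bases from the V 3' end (names are trim lengths).
#' @param j_usage Named numeric vector of J gene usage weights.
#' @param anchor List `gene`, `alleles` (two names), `split` (usage of the
#'   two alleles within the gene). A homozygous subject is simulated with
#'   `split = c(1, 0)`.
#' @param linkage Named character vector mapping studied-segment alleles to
#'   the anchor allele they are exclusively linked to (haplotype linkage);
#'   unlisted alleles recombine with either anchor allele per `split`.
#' @param umi Emit 12-mer UMIs (default `TRUE`).
#' @param umi_dup_rate Probability that a read is a resequencing duplicate
#'   of the previous molecule, sharing its UMI and mutation pattern.
#' @param unproductive_fraction Fraction of molecules flagged non-productive
#'   (excluded from every statistic and from the ground-truth tallies).
#' @param low_qual_fraction Fraction of bases assigned the low Phred score.
#' @param low_qual_phred,high_qual_phred The two quality scores emitted.
#' @param cdr3_aa_range Inclusive range of CDR3 amino-acid lengths.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_reads = 10000L,
                       genotype = default_sim_genotype(),
                       mutation_rate = 0.01,
                       trim_probs = c("0" = 0.55, "1" = 0.2, "2" = 0.15, "3" = 0.1),
                       j_usage = c(IGHJ1 = 0.05, IGHJ2 = 0.10, IGHJ3 = 0.10,
                                   IGHJ4 = 0.35, IGHJ5 = 0.10, IGHJ6 = 0.30),
                       anchor = list(gene = "IGHJ6",
                                     alleles = c("IGHJ6*02", "IGHJ6*03"),
                                     split = c(0.5, 0.5)),
                       linkage = c(IGHV_S1 = "IGHJ6*03"),
                       umi = TRUE,
                       umi_dup_rate = 0.15,
                       unproductive_fraction = 0.05,
                       low_qual_fraction = 0.02,
                       low_qual_phred = 11L,
                       high_qual_phred = 40L,
                       cdr3_aa_range = c(10L, 16L)) {
  genotype <- as_tibble(genotype)
  stopifnot(
    all(c("allele", "weight") %in% names(genotype)),
    all(genotype$weight > 0),
    mutation_rate >= 0, mutation_rate < 1,
    all(trim_probs >= 0), !is.null(names(trim_probs)),
    length(anchor$alleles) == 2L, length(anchor$split) == 2L,
    umi_dup_rate >= 0, umi_dup_rate < 1,
    unproductive_fraction >= 0, unproductive_fraction < 1,
    low_qual_fraction >= 0, low_qual_fraction <= 1
  )
  if (length(linkage) > 0L && !all(names(linkage) %in% genotype$allele)) {
    abort("linkage map references alleles absent from the genotype")
  }
  structure(list(
    seed = as.integer(seed), n_reads = as.integer(n_reads),
    genotype = genotype, mutation_rate = mutation_rate,
    trim_probs = trim_probs / sum(trim_probs), j_usage = j_usage / sum(j_usage),
    anchor = anchor, linkage = linkage, umi = umi,
    umi_dup_rate = umi_dup_rate,
    unproductive_fraction = unproductive_fraction,
    low_qual_fraction = low_qual_fraction,
    low_qual_phred = as.integer(low_qual_phred),
    high_qual_phred = as.integer(high_qual_phred),
    cdr3_aa_range = as.integer(cdr3_aa_range)
  ), class = "sim_config")
}

default_sim_genotype <- function() {
  tibble(
    allele = c("IGHV1-2*02", "IGHV1-2*04", "IGHV1-69*01", "IGHV1-69*06",
               "IGHV3-23*01", "IGHV3-23*04", "IGHV4-34*01", "IGHV4-34*02",
               "IGHV_S1"),
    weight = c(0.16, 0.12, 0.14, 0.10, 0.14, 0.08, 0.10, 0.08, 0.08)
  )
}

#' Simulate an annotated AIRR repertoire with known ground truth
#'
#' Draws molecules from the configured genotype, applies 3' V trimming,
#' uniform substitutions over the covered non-gap V positions, a random
#' in-frame CDR3, the configured anchor-J allele (forced for
#' haplotype-linked alleles), UMI tagging and resequencing duplicates, and a
#' two-level quality string. Emitted calls are the true alleles. The ground
#' truth records per-read state and per-allele tallies of every count
#' statistic of the genotype report.
#'
#' @param config A [sim_config()] object.
#' @param reference A `reference_set`; defaults to
#'   [synthetic_reference_set()].
#' @return A list of class `sim_repertoire`: `reads` (rearrangement tibble
#'   as returned by [read_airr_tsv()]), `truth` (list `per_read`, `tallies`,
#'   `cross_tab`), `reference`, `config`.
#' @export
simulate_repertoire <- function(config, reference = synthetic_reference_set()) {
  stopifnot(inherits(config, "sim_config"))
  missing_alleles <- setdiff(
    c(config$genotype$allele, config$anchor$alleles, unname(config$linkage)),
    reference$name
  )
  if (length(missing_alleles) > 0L) {
    abort(paste0("config references allele(s) absent from the reference set: ",
                 paste(missing_alleles, collapse = ", ")))
  }
  set.seed(config$seed)
  n <- config$n_reads
  if (n == 0L) {
    return(new_sim_repertoire(empty_reads(), config, reference))
  }

  # reads -> molecules: a read is either a fresh molecule or a resequencing
  # duplicate of the previous molecule
  dup <- c(FALSE, stats::runif(n - 1L) < config$umi_dup_rate)
  mol_of_read <- cumsum(!dup)
  n_mol <- max(mol_of_read)

  # per-allele precomputation on the gap frame
  v_info <- lapply(setNames(config$genotype$allele, config$genotype$allele),
                   function(nm) {
    chars <- strsplit(reference_row(reference, nm)$gapped_seq, "", fixed = TRUE)[[1L]]
    list(chars = chars, nongap = which(chars != "."))
  })
  gene_alleles <- split(reference$name[reference$segment == "J"],
                        reference$gene[reference$segment == "J"])
  j_seq_of <- setNames(reference$ungapped_seq[reference$segment == "J"],
                       reference$name[reference$segment == "J"])
  d_alleles <- reference$name[reference$segment == "D"]

  v_name <- sample(config$genotype$allele, n_mol, replace = TRUE,
                   prob = config$genotype$weight)
  j_gene <- sample(names(config$j_usage), n_mol, replace = TRUE,
                   prob = config$j_usage)
  j_name <- vapply(j_gene, function(g) {
    if (g == config$anchor$gene) {
      sample(config$anchor$alleles, 1L, prob = config$anchor$split)
    } else {
      gene_alleles[[g]][1L]
    }
  }, "")
  linked <- config$linkage[v_name]
  j_name <- ifelse(is.na(linked), j_name, linked)
  d_name <- if (length(d_alleles) > 0L) {
    sample(d_alleles, n_mol, replace = TRUE)
  } else {
    rep(NA_character_, n_mol)
  }
  trim <- sample(as.integer(names(config$trim_probs)), n_mol, replace = TRUE,
                 prob = config$trim_probs)
  productive <- stats::runif(n_mol) >= config$unproductive_fraction
  cdr3_len <- sample(seq(config$cdr3_aa_range[1L], config$cdr3_aa_range[2L]),
                     n_mol, replace = TRUE)
  bases <- c("A", "C", "G", "T")

  v_seq <- character(n_mol)
  v_end <- integer(n_mol)
  n_mut <- integer(n_mol)
  cdr3_nt <- character(n_mol)
  for (m in seq_len(n_mol)) {
    info <- v_info[[v_name[m]]]
    covered <- length(info$nongap) - trim[m]
    vend <- info$nongap[covered]
    chars <- info$chars[seq_len(vend)]
    k <- rbinom(1L, covered, config$mutation_rate)
    if (k > 0L) {
      pos <- sample(info$nongap[seq_len(covered)], k)
      chars[pos] <- vapply(chars[pos],
                           function(b) sample(setdiff(bases, b), 1L), "")
    }
    v_seq[m] <- paste(chars, collapse = "")
    v_end[m] <- vend
    n_mut[m] <- k
    cdr3_nt[m] <- paste(sample(bases, 3L * cdr3_len[m], replace = TRUE),
                        collapse = "")
  }
  junction_aa <- vapply(cdr3_nt, function(s) paste(translate_gapped(s), collapse = ""),
                        "", USE.NAMES = FALSE)
  j_seq <- unname(j_seq_of[j_name])
  alignment <- paste0(v_seq, cdr3_nt, j_seq)
  umi <- if (config$umi) {
    vapply(seq_len(n_mol), function(m) paste(sample(bases, 12L, replace = TRUE),
                                             collapse = ""), "")
  } else {
    rep(NA_character_, n_mol)
  }
  quality <- vapply(seq_len(n_mol), function(m) {
    L <- (length(v_info[[v_name[m]]]$nongap) - trim[m]) + nchar(cdr3_nt[m]) +
      nchar(j_seq[m])
    low <- stats::runif(L) < config$low_qual_fraction
    intToUtf8(33L + ifelse(low, config$low_qual_phred, config$high_qual_phred))
  }, "")

  i <- mol_of_read
  reads <- tibble(
    sequence_id = sprintf("read%06d", seq_len(n)),
    v_call = v_name[i], j_call = j_name[i],
    sequence_alignment = alignment[i],
    productive = productive[i],
    d_call = d_name[i],
    junction_aa = junction_aa[i],
    cdr3 = cdr3_nt[i],
    umi = umi[i],
    quality = quality[i],
    j_sequence_alignment = j_seq[i],
    v_germline_end = v_end[i]
  )
  per_read <- tibble(
    sequence_id = reads$sequence_id,
    molecule = i,
    v_allele = v_name[i], d_allele = d_name[i], j_allele = j_name[i],
    trim = trim[i], n_mutations = n_mut[i],
    productive = productive[i],
    umi = umi[i], junction_aa = junction_aa[i],
    duplicate = dup
  )
  new_sim_repertoire(reads, config, reference, per_read)
}

empty_reads <- function() {
  tibble(
    sequence_id = character(), v_call = character(), j_call = character(),
    sequence_alignment = character(), productive = logical(),
    d_call = character(), junction_aa = character(), cdr3 = character(),
    umi = character(), quality = character(),
    j_sequence_alignment = character(), v_germline_end = integer()
  )
}

new_sim_repertoire <- function(reads, config, reference,
                               per_read = NULL) {
  if (is.null(per_read)) {
    per_read <- tibble(
      sequence_id = character(), molecule = integer(), v_allele = character(),
      d_allele = character(), j_allele = character(), trim = integer(),
      n_mutations = integer(), productive = logical(), umi = character(),
      junction_aa = character(), duplicate = logical()
    )
  }
  structure(
    list(reads = reads,
         truth = list(per_read = per_read,
                      tallies = truth_tallies(per_read),
                      cross_tab = truth_cross_tab(per_read, config)),
         reference = reference, config = config),
    class = "sim_repertoire"
  )
}

# Per-allele ground-truth tallies of every count field of the genotype
# report, computed directly from the per-read records.
truth_tallies <- function(per_read) {
  pr <- per_read[per_read$productive, ]
  n_na_distinct <- function(x) length(unique(x[!is.na(x)]))
  pr |>
    group_by(sequence_id = .data$v_allele) |>
    summarise(
      sequences = dplyr::n(),
      unmutated_sequences = sum(.data$n_mutations == 0L),
      unmutated_umis = n_na_distinct(.data$umi[.data$n_mutations == 0L]),
      unique_vs = n_na_distinct(.data$v_allele),
      unique_ds = n_na_distinct(.data$d_allele),
      unique_js = n_na_distinct(.data$j_allele),
      unique_cdr3s = n_na_distinct(.data$junction_aa),
      unique_vs_unmutated = n_na_distinct(.data$v_allele[.data$n_mutations == 0L]),
      unique_ds_unmutated = n_na_distinct(.data$d_allele[.data$n_mutations == 0L]),
      unique_js_unmutated = n_na_distinct(.data$j_allele[.data$n_mutations == 0L]),
      unique_cdr3s_unmutated = n_na_distinct(.data$junction_aa[.data$n_mutations == 0L]),
      .groups = "drop"
    ) |>
    arrange(.data$sequence_id)
}

truth_cross_tab <- function(per_read, config) {
  pr <- per_read[per_read$productive &
                   per_read$j_allele %in% config$anchor$alleles, ]
  if (nrow(pr) == 0L) {
    return(tibble(v_allele = character(), count_anchor1 = integer(),
                  count_anchor2 = integer()))
  }
  pr |>
    group_by(v_allele = .data$v_allele) |>
    summarise(
      count_anchor1 = sum(.data$j_allele == config$anchor$alleles[1L]),
      count_anchor2 = sum(.data$j_allele == config$anchor$alleles[2L]),
      .groups = "drop"
    ) |>
    arrange(.data$v_allele)
}

#' @export
print.sim_repertoire <- function(x, ...) {
  cat(sprintf("<sim_repertoire> %d reads (%d molecules), seed %d, mutation rate %g\n",
              nrow(x$reads), max(c(0L, x$truth$per_read$molecule)),
              x$config$seed, x$config$mutation_rate))
  invisible(x)
}

#' Write a simulated repertoire to disk as a reusable fixture
#'
#' Emits `reads.tsv` (AIRR rearrangement TSV), `germline.fasta` (gapped
#' reference alleles), `novel.fasta` (candidate novel alleles) and
#' `truth.json` (ground-truth tallies and anchor cross-tabulation).
#' Re-running with the same configuration seed reproduces the files
#' byte-identically.
#'
#' @param sim A `sim_repertoire` from [simulate_repertoire()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    reads = file.path(dir, "reads.tsv"),
    germline = file.path(dir, "germline.fasta"),
    novel = file.path(dir, "novel.fasta"),
    truth = file.path(dir, "truth.json")
  )
  reads <- sim$reads
  reads$productive <- ifelse(reads$productive, "T", "F")
  readr::write_tsv(reads, paths[["reads"]], na = "")
  write_reference_fasta(sim$reference[!sim$reference$is_novel, ], paths[["germline"]])
  write_reference_fasta(sim$reference, paths[["novel"]], novel_only = TRUE)
  jsonlite::write_json(
    list(seed = sim$config$seed, n_reads = nrow(sim$reads),
         tallies = sim$truth$tallies, cross_tab = sim$truth$cross_tab),
    paths[["truth"]], dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
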