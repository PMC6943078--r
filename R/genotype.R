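# The standardized genotype report: one row per allele observed in the
# subject's productive repertoire, with usage, exact-match (unmutated) and
# novel-allele difference statistics.

genotype_fields <- c(
  "sequence_id", "sequences", "closest_reference", "closest_host",
  "nt_diff", "nt_diff_host", "nt_substitutions", "aa_diff",
  "aa_substitutions", "unmutated_sequences", "assigned_unmutated_frequency",
  "unmutated_umis", "allelic_percentage", "unmutated_frequency",
  "unique_vs", "unique_ds", "unique_js", "unique_cdr3s",
  "unique_vs_unmutated", "unique_ds_unmutated", "unique_js_unmutated",
  "unique_cdr3s_unmutated", "haplotyping_gene"
)

#' Does a read exactly match its germline allele?
#'
#' A read is unmutated (an exact match) when its aligned segment region
#' equals the germline allele sequence over the read's covered extent.
#' Columns where both read and germline carry the IMGT gap `.` are ignored;
#' a base against a gap (either way) is a mismatch, as is any `N` in the
#' read. For V alleles the covered extent runs from IMGT position 1 to the
#' read's `v_germline_end` (3' junction-trimmed tails are not penalized);
#' for J alleles the read's J region (`j_sequence_alignment`) is compared
#' anchored at the germline 3' end, since J trimming removes 5' bases.
#'
#' @param reads Rearrangement tibble.
#' @param allele One-row slice of a `reference_set`.
#' @return Logical vector, one element per read; `NA` (with a warning) for
#'   reads lacking the needed alignment column, which are excluded from
#'   unmutated statistics.
#' @export
is_unmutated <- function(reads, allele) {
  flags <- switch(allele$segment,
    V = unmutated_v_flags(reads$sequence_alignment, reads$v_germline_end,
                          allele$gapped_seq),
    J = unmutated_j_flags(reads$j_sequence_alignment, allele$ungapped_seq),
    D = rep(NA, nrow(reads))
  )
  if (allele$segment == "D") {
    warn("exact-match status is not defined for D alleles (no fixed alignment extent); returning NA")
  } else if (anyNA(flags)) {
    warn(sprintf("%d read(s) lack the alignment needed for exact-match comparison; excluded",
                 sum(is.na(flags))))
  }
  flags
}

unmutated_v_flags <- function(seq_alignment, v_germline_end, allele_gapped) {
  out <- rep(NA, length(seq_alignment))
  ok <- !is.na(seq_alignment)
  if (!any(ok)) return(out)
  vend <- v_germline_end
  vend[is.na(vend)] <- nchar(allele_gapped)
  vend <- pmin(vend, nchar(seq_alignment), nchar(allele_gapped))
  region <- substring(seq_alignment, 1L, vend)
  germ <- substring(allele_gapped, 1L, vend)
  out[ok] <- region[ok] == germ[ok] & !grepl("N", region[ok], fixed = TRUE)
  out
}

unmutated_j_flags <- function(j_region, allele_ungapped) {
  out <- rep(NA, length(j_region))
  ok <- !is.na(j_region)
  if (!any(ok)) return(out)
  glen <- nchar(allele_ungapped)
  k <- pmin(nchar(j_region), glen)
  region <- substring(j_region, nchar(j_region) - k + 1L)
  germ <- substring(allele_ungapped, glen - k + 1L)
  out[ok] <- region[ok] == germ[ok] & !grepl("N", region[ok], fixed = TRUE)
  out
}

# Exact-match flags for every read against its assigned allele, NA where the
# allele is unknown or the alignment is missing.
unmutated_by_assignment <- function(reads, assigned, reference) {
  flags <- rep(NA, nrow(reads))
  for (nm in unique(assigned)) {
    i <- which(assigned == nm)
    j <- match(nm, reference$name)
    if (is.na(j)) next
    allele <- reference[j, ]
    if (allele$segment == "D") next
    flags[i] <- suppressWarnings(is_unmutated(reads[i, ], allele))
  }
  flags
}

#' Compute the standardized genotype report
#'
#' Builds one report row per allele of the studied segment observed among
#' productive reads, with every field of the standardized genotype:
#' assignment counts, exact-match (unmutated) counts and frequencies,
#' allelic percentages within each gene, co-occurring allele and CDR3
#' diversity, UMI-deduplicated exact matches, and closest-reference
#' difference annotations for novel alleles.
#'
#' Assignment follows the first-listed allele of the call string; reads with
#' ambiguous (multi-valued) calls count toward `sequences` but never toward
#' exact-match statistics. Percentages: `assigned_unmutated_frequency` is
#' exact matches over reads assigned to the allele; `allelic_percentage` is
#' exact matches over exact matches to any allele of the same gene (empty
#' when the gene has none); `unmutated_frequency` is exact matches over
#' exact matches to any allele of any gene. All are times 100.
#'
#' @param reads Rearrangement tibble (non-productive reads are dropped).
#' @param reference A `reference_set` containing the germline alleles plus
#'   any candidate novel alleles (flagged `is_novel`).
#' @param segment Segment under study: `"V"` (default), `"D"` or `"J"`.
#' @param anchor_genes Character vector of haplotyping anchor gene names to
#'   record in the `haplotyping_gene` field (comma-joined; empty by default).
#' @return An object of class `ig_genotype`: use [tidy()] for the per-allele
#'   tibble, [glance()] for one-row totals, [write_genotype_csv()] to
#'   serialize.
#' @examples
#' ref <- synthetic_reference_set()
#' sim <- simulate_repertoire(sim_config(n_reads = 200, seed = 1), ref)
#' gt <- compute_genotype(sim$reads, ref)
#' tidy(gt)
#' @export
compute_genotype <- function(reads, reference, segment = c("V", "D", "J"),
                             anchor_genes = character()) {
  segment <- match.arg(segment)
  reads <- filter_productive(reads)
  if (nrow(reads) == 0L) abort("empty repertoire: no productive reads")

  call_col <- c(V = "v_call", D = "d_call", J = "j_call")[[segment]]
  calls <- reads[[call_col]]
  if (anyNA(calls)) {
    warn(sprintf("dropped %d read(s) with no %s", sum(is.na(calls)), call_col))
    reads <- reads[!is.na(calls), ]
    calls <- reads[[call_col]]
  }
  if (nrow(reads) == 0L) abort("empty repertoire: no reads with a call for the studied segment")
  pc <- primary_call(calls)
  assigned <- pc$allele

  unknown <- setdiff(unique(assigned), reference$name)
  if (length(unknown) > 0L) {
    inform(paste0("allele(s) absent from reference set (difference fields left empty): ",
                  paste(unknown, collapse = ", ")))
  }

  exact <- unmutated_by_assignment(reads, assigned, reference)
  unmut <- !pc$ambiguous & !is.na(exact) & exact

  per_read <- tibble(
    allele = assigned,
    unmut = unmut,
    v_co = primary_call_or_na(reads$v_call),
    d_co = primary_call_or_na(reads$d_call),
    j_co = primary_call_or_na(reads$j_call),
    umi = reads$umi,
    cdr3 = if (any(!is.na(reads$junction_aa))) reads$junction_aa else reads$cdr3
  )
  cdr3_source <- if (any(!is.na(reads$junction_aa))) "junction_aa" else "cdr3"
  umi_present <- any(!is.na(reads$umi))

  n_na_distinct <- function(x) {
    x <- x[!is.na(x)]
    length(unique(x))
  }
  rows <- per_read |>
    group_by(.data$allele) |>
    summarise(
      sequences = dplyr::n(),
      unmutated_sequences = sum(.data$unmut),
      unmutated_umis = if (umi_present) n_na_distinct(.data$umi[.data$unmut]) else NA_integer_,
      unique_vs = n_na_distinct(.data$v_co),
      unique_ds = n_na_distinct(.data$d_co),
      unique_js = n_na_distinct(.data$j_co),
      unique_cdr3s = n_na_distinct(.data$cdr3),
      unique_vs_unmutated = n_na_distinct(.data$v_co[.data$unmut]),
      unique_ds_unmutated = n_na_distinct(.data$d_co[.data$unmut]),
      unique_js_unmutated = n_na_distinct(.data$j_co[.data$unmut]),
      unique_cdr3s_unmutated = n_na_distinct(.data$cdr3[.data$unmut]),
      .groups = "drop"
    ) |>
    rename(sequence_id = "allele")

  ref_idx <- match(rows$sequence_id, reference$name)
  rows$gene <- ifelse(is.na(ref_idx), sub("\\*.*$", "", rows$sequence_id),
                      reference$gene[ref_idx])
  rows$is_novel <- !is.na(ref_idx) & reference$is_novel[ref_idx]

  rows <- rows |>
    group_by(.data$gene) |>
    mutate(gene_unmutated = sum(.data$unmutated_sequences)) |>
    ungroup() |>
    mutate(
      assigned_unmutated_frequency = .data$unmutated_sequences / .data$sequences * 100,
      allelic_percentage = ifelse(.data$gene_unmutated > 0,
                                  .data$unmutated_sequences / .data$gene_unmutated * 100,
                                  NA_real_),
      unmutated_frequency = if (sum(.data$unmutated_sequences) > 0) {
        .data$unmutated_sequences / sum(.data$unmutated_sequences) * 100
      } else {
        NA_real_
      }
    ) |>
    select(-"gene_unmutated")

  host_names <- rows$sequence_id[!rows$is_novel & !is.na(ref_idx)]
  diffs <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    if (!rows$is_novel[i]) {
      return(tibble(closest_reference = NA_character_, closest_host = NA_character_,
                    nt_diff = NA_integer_, nt_diff_host = NA_integer_,
                    nt_substitutions = NA_character_, aa_diff = NA_integer_,
                    aa_substitutions = NA_character_))
    }
    allele_diff(reference[ref_idx[i], ], reference, host_names)
  })
  rows <- dplyr::bind_cols(rows, diffs)
  rows$haplotyping_gene <- if (length(anchor_genes) > 0L) {
    paste(anchor_genes, collapse = ",")
  } else {
    NA_character_
  }

  rows <- rows |>
    arrange(.data$gene, .data$sequence_id) |>
    select(dplyr::all_of(c("gene", "is_novel", genotype_fields)))

  structure(
    list(
      rows = rows,
      segment = segment,
      locus = attr(reference, "locus"),
      cdr3_source = cdr3_source,
      umi_present = umi_present,
      unknown_alleles = unknown,
      totals = list(
        sequences = sum(rows$sequences),
        unmutated_sequences = sum(rows$unmutated_sequences),
        excluded_from_unmutated = sum(pc$ambiguous) + sum(is.na(exact))
      )
    ),
    class = "ig_genotype"
  )
}

#' @export
print.ig_genotype <- function(x, ...) {
  cat(sprintf("<ig_genotype> locus %s, %s-segment study: %d alleles, %d reads (%d unmutated)\n",
              x$locus %||% "?", x$segment, nrow(x$rows),
              x$totals$sequences, x$totals$unmutated_sequences))
  print(x$rows, ...)
  invisible(x)
}

#' Tidy a genotype report into its per-allele tibble
#'
#' @param x An `ig_genotype` object.
#' @param ... Unused.
#' @return The per-allele tibble: every standardized-genotype field plus
#'   `gene` and `is_novel` helper columns.
#' @method tidy ig_genotype
#' @export
tidy.ig_genotype <- function(x, ...) {
  x$rows
}

#' One-row summary of a genotype report
#'
#' @param x An `ig_genotype` object.
#' @param ... Unused.
#' @return A one-row tibble: locus, segment, allele/gene counts, totals and
#'   the CDR3 column used.
#' @method glance ig_genotype
#' @export
glance.ig_genotype <- function(x, ...) {
  tibble(
    locus = x$locus %||% NA_character_,
    segment = x$segment,
    n_alleles = nrow(x$rows),
    n_genes = length(unique(x$rows$gene)),
    n_novel = sum(x$rows$is_novel),
    total_sequences = x$totals$sequences,
    total_unmutated = x$totals$unmutated_sequences,
    cdr3_source = x$cdr3_source
  )
}

#' Write the genotype report as CSV
#'
#' The header is exactly the standardized-genotype field names, in order.
#' Percentages are rendered with two decimals (half-up); fields that do not
#' apply (difference annotations of reference alleles, UMI counts without a
#' UMI column, percentages with an empty denominator) are rendered as empty
#' cells, not zeros.
#'
#' @param genotype An `ig_genotype` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(genotype, path) {
  df <- genotype$rows[, genotype_fields]
  for (col in c("assigned_unmutated_frequency", "allelic_percentage",
                "unmutated_frequency")) {
    df[[col]] <- format_percent(df[[col]])
  }
  readr::write_csv(df, path, na = "")
  invisible(path)
}
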