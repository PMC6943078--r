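# Haplotype-anchor evidence: find heterozygous anchor genes (e.g. IGHJ6),
# split studied-segment usage by anchor allele, and score exclusive
# association of novel alleles with one haplotype.

#' Allele usage per gene
#'
#' Tabulates unambiguous allele calls of one segment per gene — the data
#' behind the allele-usage diagnostic used to spot heterozygous genes. When
#' a reference set is supplied, only reads whose segment region is an exact
#' germline match are counted: somatic hypermutation can otherwise distort
#' allele ratios, so heterozygosity detection runs on unmutated reads.
#'
#' @param reads Rearrangement tibble (filtered to productive reads).
#' @param segment Segment to tabulate (`"J"` default, or `"V"`).
#' @param reference Optional `reference_set`; when given, restricts counts
#'   to unmutated reads.
#' @return A tibble of class `allele_usage` with columns `gene`, `allele`,
#'   `n`, ordered by gene then allele.
#' @export
allele_usage <- function(reads, segment = c("J", "V"), reference = NULL) {
  segment <- match.arg(segment)
  call_col <- c(J = "j_call", V = "v_call")[[segment]]
  calls <- primary_call_or_na(reads[[call_col]])
  ambiguous <- !is.na(reads[[call_col]]) & grepl(",", reads[[call_col]], fixed = TRUE)
  keep <- !is.na(calls) & !ambiguous
  if (!is.null(reference)) {
    flags <- unmutated_by_assignment(reads, calls, reference)
    keep <- keep & !is.na(flags) & flags
  }
  out <- tibble(allele = calls[keep]) |>
    count(.data$allele, name = "n") |>
    mutate(gene = sub("\\*.*$", "", .data$allele)) |>
    select("gene", "allele", "n") |>
    arrange(.data$gene, .data$allele)
  class(out) <- c("allele_usage", class(out))
  attr(out, "segment") <- segment
  attr(out, "unmutated_only") <- !is.null(reference)
  out
}

#' Detect candidate heterozygous anchor genes
#'
#' A gene qualifies as a haplotyping anchor when exactly two of its alleles
#' each carry at least `min_minor_fraction` of the gene's reads and the gene
#' total is at least `min_total`. Candidates are returned sorted by gene
#' total, descending; an empty result means haplotyping is not possible.
#'
#' @param usage An `allele_usage` tibble (typically from unmutated reads).
#' @param min_total Minimum reads on the gene (default 100).
#' @param min_minor_fraction Minimum fraction each of the two alleles must
#'   hold (default 0.2).
#' @return Tibble with `gene`, `allele1`, `allele2` (allele1 is the more
#'   used), `n1`, `n2`, `total`.
#' @export
detect_anchor <- function(usage, min_total = 100, min_minor_fraction = 0.2) {
  usage |>
    group_by(.data$gene) |>
    dplyr::group_modify(function(g, key) {
      total <- sum(g$n)
      qual <- g[g$n / total >= min_minor_fraction, ]
      if (total < min_total || nrow(qual) != 2L) {
        return(tibble(allele1 = character(), allele2 = character(),
                      n1 = integer(), n2 = integer(), total = integer()))
      }
      qual <- qual[order(-qual$n, qual$allele), ]
      tibble(allele1 = qual$allele[1L], allele2 = qual$allele[2L],
             n1 = qual$n[1L], n2 = qual$n[2L], total = total)
    }) |>
    ungroup() |>
    arrange(dplyr::desc(.data$total))
}

#' Exclusivity evidence score
#'
#' A novel allele found exclusively in association with one anchor allele
#' supports the inference (the allele lies on one haplotype). The flag is
#' strict: it requires zero reads on the minor haplotype and at least
#' `min_reads` on the major. The ratio min/max (0 when both counts are 0)
#' quantifies near-exclusive cases.
#'
#' @param count1,count2 Read counts under the two anchor alleles.
#' @param min_reads Minimum major-haplotype reads for the flag (default 10).
#' @return Tibble with logical `exclusive` and numeric `ratio`, one row per
#'   input pair.
#' @examples
#' exclusivity_score(25, 0)  # exclusive
#' exclusivity_score(25, 1)  # ratio 0.04, not exclusive
#' @export
exclusivity_score <- function(count1, count2, min_reads = 10) {
  stopifnot(all(count1 >= 0), all(count2 >= 0))
  hi <- pmax(count1, count2)
  lo <- pmin(count1, count2)
  tibble(
    exclusive = hi >= min_reads & lo == 0L,
    ratio = ifelse(hi == 0, 0, lo / hi)
  )
}

#' Split studied-segment usage by anchor allele
#'
#' For each allele of the studied segment, counts assigned reads whose
#' unambiguous anchor-segment call equals anchor allele 1 vs anchor allele 2
#' — the haplotype-split diagnostic. Reads calling other alleles or other
#' genes of the anchor segment are excluded from the split. All assigned
#' reads contribute (not only unmutated ones): the split shows the number of
#' reads of each gene per haplotype.
#'
#' @param reads Rearrangement tibble (filtered to productive reads).
#' @param anchor_gene Anchor gene name (e.g. `"IGHJ6"`).
#' @param anchor_alleles Character vector of the two anchor allele names.
#' @param segment Segment under study (`"V"` default, or `"J"` when the
#'   anchor is a V gene).
#' @param min_reads Passed to [exclusivity_score()].
#' @return A tibble of class `haplotype_report`: `gene`, `allele`,
#'   `count_anchor1`, `count_anchor2`, `ratio`, `exclusive`; anchor gene and
#'   alleles as attributes. Alleles with zero reads under both anchors do
#'   not appear.
#' @export
haplotype_counts <- function(reads, anchor_gene, anchor_alleles,
                             segment = c("V", "J"), min_reads = 10) {
  segment <- match.arg(segment)
  if (length(anchor_alleles) != 2L) {
    abort("haplotype analysis requires exactly two anchor alleles")
  }
  anchor_col <- if (segment == "V") "j_call" else "v_call"
  study_col <- if (segment == "V") "v_call" else "j_call"
  anchor_raw <- reads[[anchor_col]]
  anchor <- primary_call_or_na(anchor_raw)
  unambig <- !is.na(anchor_raw) & !grepl(",", anchor_raw, fixed = TRUE)
  in_split <- unambig & anchor %in% anchor_alleles
  if (!any(in_split)) {
    abort(paste0("anchor alleles ", paste(anchor_alleles, collapse = ", "),
                 " not found among unambiguous ", anchor_col, " values"))
  }
  study <- primary_call_or_na(reads[[study_col]])
  keep <- in_split & !is.na(study)
  out <- tibble(allele = study[keep], anchor = anchor[keep]) |>
    count(.data$allele, .data$anchor) |>
    tidyr::pivot_wider(names_from = "anchor", values_from = "n", values_fill = 0L)
  for (a in anchor_alleles) if (!a %in% names(out)) out[[a]] <- 0L
  out <- out |>
    mutate(gene = sub("\\*.*$", "", .data$allele)) |>
    select("gene", "allele",
           count_anchor1 = dplyr::all_of(anchor_alleles[1L]),
           count_anchor2 = dplyr::all_of(anchor_alleles[2L])) |>
    arrange(.data$gene, .data$allele)
  out <- dplyr::bind_cols(out, exclusivity_score(out$count_anchor1,
                                                 out$count_anchor2,
                                                 min_reads = min_reads))
  class(out) <- c("haplotype_report", class(out))
  attr(out, "anchor_gene") <- anchor_gene
  attr(out, "anchor_alleles") <- anchor_alleles
  attr(out, "segment") <- segment
  out
}

#' @export
print.haplotype_report <- function(x, ...) {
  cat(sprintf("<haplotype_report> anchor %s (%s vs %s), %s-segment usage\n",
              attr(x, "anchor_gene"), attr(x, "anchor_alleles")[1L],
              attr(x, "anchor_alleles")[2L], attr(x, "segment")))
  NextMethod()
}

#' Write a haplotype report as CSV
#'
#' @param report A `haplotype_report` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_haplotype_csv <- function(report, path) {
  df <- as_tibble(report)[, c("gene", "allele", "count_anchor1",
                              "count_anchor2", "ratio", "exclusive")]
  readr::write_csv(df, path, na = "")
  invisible(path)
}
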