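# End-to-end pipeline: reads + germline -> genotype report, haplotype
# evidence, diagnostic tables and figures, novel-allele FASTA, manifest.

#' Run the full evidence pipeline
#'
#' Reads the rearrangement TSV and germline FASTA(s), computes the
#' standardized genotype, detects haplotype anchor genes and splits usage by
#' anchor allele, builds the diagnostic panels for every novel allele, and
#' writes all outputs plus a JSON manifest recording inputs, thresholds and
#' counts. Any reference-allele sequence discrepancy against the germline
#' set is recorded in the manifest.
#'
#' Outputs written to `out_dir`: `genotype.csv`, `haplotype.csv` (when an
#' anchor exists), `novel_alleles.fasta`, per-novel-allele panel tables
#' (`*_alignment.csv`, `*_end_zoom.csv`, `*_mutation_histogram.csv`) and
#' images, `allele_usage.csv` and image, and `manifest.json`.
#'
#' @param reads_path AIRR rearrangement TSV.
#' @param germline_path Gapped germline FASTA.
#' @param novel_path Optional FASTA of candidate novel alleles, appended to
#'   the reference set and flagged novel.
#' @param out_dir Output directory (created if needed).
#' @param segment Segment under study (default `"V"`).
#' @param anchor Optional anchor gene name to force (overrides detection).
#' @param min_total,min_minor_fraction Anchor detection thresholds, see
#'   [detect_anchor()].
#' @param min_reads Exclusivity threshold, see [exclusivity_score()].
#' @param qual_threshold Low-confidence mask threshold, see
#'   [alignment_panel()].
#' @param zoom_n End-zoom width, see [end_zoom()].
#' @param colmap Optional column-name mapping, see [read_airr_tsv()].
#' @param image_format Image file extension for rendered panels (default
#'   `"png"`).
#' @return Invisibly, a list with the computed objects (`genotype`,
#'   `usage`, `anchors`, `haplotype`) and the manifest.
#' @export
run_all <- function(reads_path, germline_path, novel_path = NULL,
                    out_dir = ".", segment = "V", anchor = NULL,
                    min_total = 100, min_minor_fraction = 0.2, min_reads = 10,
                    qual_threshold = 20, zoom_n = 8, colmap = NULL,
                    image_format = "png") {
  for (p in c(reads_path, germline_path, novel_path)) {
    if (!file.exists(p)) abort(paste0("input file not found: ", p))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  reference <- read_gapped_fasta(germline_path)
  if (!is.null(novel_path)) {
    novel <- read_gapped_fasta(novel_path, novel_names = NULL)
    novel$is_novel <- TRUE
    reference <- build_reference_set(c(reference$name, novel$name),
                                     c(reference$gapped_seq, novel$gapped_seq),
                                     novel_names = novel$name,
                                     locus = attr(reference, "locus"))
  }
  reads <- filter_productive(read_airr_tsv(reads_path, colmap = colmap))

  # candidate novel alleles checked against the reference proper: each should
  # surface as "missing" (or as a sequence mismatch if a name collides)
  discrepancies <- check_against_reference(
    setNames(reference$gapped_seq[reference$is_novel],
             reference$name[reference$is_novel]),
    new_reference_set(reference[!reference$is_novel, ],
                      locus = attr(reference, "locus"))
  )

  anchor_segment <- if (segment == "V") "J" else "V"
  usage <- allele_usage(reads, segment = anchor_segment, reference = reference)
  anchors <- detect_anchor(usage, min_total = min_total,
                           min_minor_fraction = min_minor_fraction)
  if (!is.null(anchor)) {
    anchors <- anchors[anchors$gene == anchor, ]
    if (nrow(anchors) == 0L) {
      abort(paste0("requested anchor gene '", anchor,
                   "' is not heterozygous at the configured thresholds"))
    }
  }

  genotype <- compute_genotype(reads, reference, segment = segment,
                               anchor_genes = anchors$gene)
  paths <- list(genotype = file.path(out_dir, "genotype.csv"))
  write_genotype_csv(genotype, paths$genotype)
  paths$novel_fasta <- file.path(out_dir, "novel_alleles.fasta")
  write_reference_fasta(reference, paths$novel_fasta, novel_only = TRUE)

  paths$usage <- file.path(out_dir, "allele_usage.csv")
  readr::write_csv(as_tibble(usage), paths$usage)
  render(usage, file.path(out_dir, paste0("allele_usage.", image_format)))

  haplotype <- NULL
  if (nrow(anchors) > 0L) {
    haplotype <- haplotype_counts(reads, anchors$gene[1L],
                                  c(anchors$allele1[1L], anchors$allele2[1L]),
                                  segment = segment, min_reads = min_reads)
    paths$haplotype <- file.path(out_dir, "haplotype.csv")
    write_haplotype_csv(haplotype, paths$haplotype)
    render(haplotype, file.path(out_dir, paste0("haplotype.", image_format)))
  }

  novel_names <- reference$name[reference$is_novel & reference$segment == segment]
  novel_names <- intersect(novel_names, genotype$rows$sequence_id)
  for (nm in novel_names) {
    allele <- reference_row(reference, nm)
    safe <- gsub("[^A-Za-z0-9_]", "_", nm)
    panel <- alignment_panel(reads, allele, qual_threshold = qual_threshold)
    zoom <- end_zoom(panel, n = zoom_n)
    hist <- mutation_histogram(reads, allele)
    readr::write_csv(as_tibble(panel), file.path(out_dir, paste0(safe, "_alignment.csv")))
    readr::write_csv(as_tibble(zoom), file.path(out_dir, paste0(safe, "_end_zoom.csv")))
    readr::write_csv(as_tibble(hist), file.path(out_dir, paste0(safe, "_mutation_histogram.csv")))
    render(panel, file.path(out_dir, paste0(safe, "_alignment.", image_format)))
    render(zoom, file.path(out_dir, paste0(safe, "_end_zoom.", image_format)))
    render(hist, file.path(out_dir, paste0(safe, "_mutation_histogram.", image_format)))
  }

  manifest <- list(
    package_version = as.character(packageVersion("airrgenotype")),
    inputs = list(reads = reads_path, germline = germline_path,
                  novel = novel_path),
    segment = segment,
    thresholds = list(min_total = min_total,
                      min_minor_fraction = min_minor_fraction,
                      min_reads = min_reads, qual_threshold = qual_threshold,
                      zoom_n = zoom_n),
    counts = list(productive_reads = nrow(reads),
                  alleles = nrow(genotype$rows),
                  unmutated = genotype$totals$unmutated_sequences),
    anchors = anchors,
    discrepancies = discrepancies,
    novel_alleles = novel_names
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(list(genotype = genotype, usage = usage, anchors = anchors,
                 haplotype = haplotype, manifest = manifest))
}
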