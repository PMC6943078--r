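# Diagnostic panels for novel-allele evidence: per-read alignment on the
# germline frame, 3'/5' end zoom, mutation-distance histogram, and ggplot2
# renderers. Tests assert on the underlying tables; images are a view.

#' Per-read alignment panel on the germline gap frame
#'
#' Projects every read assigned to an allele onto the allele's gap frame:
#' IMGT gap columns appear as `.`, base calls below the quality threshold as
#' `-`, and positions beyond the read's covered extent as `.`. Reads without
#' quality data are rendered as-is. Reads whose covered extent exceeds the
#' allele frame are skipped with a warning.
#'
#' @param reads Rearrangement tibble; rows are subset to reads whose primary
#'   call of the allele's segment equals the allele name.
#' @param allele One-row slice of a `reference_set` (V or J).
#' @param qual_threshold Phred quality below which a base is masked as `-`
#'   (default 20).
#' @return A tibble of class `alignment_panel` with columns `sequence_id`
#'   and `row` (fixed-width alignment string); attributes `positions`
#'   (column coordinates), `germline` (allele sequence on the frame),
#'   `consensus`, `allele`, `segment` and `n_skipped`.
#' @export
alignment_panel <- function(reads, allele, qual_threshold = 20) {
  call_col <- c(V = "v_call", J = "j_call", D = "d_call")[[allele$segment]]
  assigned <- primary_call_or_na(reads[[call_col]]) == allele$name
  assigned[is.na(assigned)] <- FALSE
  reads <- reads[assigned, ]
  width <- nchar(allele$gapped_seq)
  germline <- allele$gapped_seq

  rows <- character(0)
  ids <- character(0)
  n_skipped <- 0L
  for (i in seq_len(nrow(reads))) {
    r <- panel_row(reads[i, ], allele, width, qual_threshold)
    if (is.null(r)) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows <- c(rows, r)
    ids <- c(ids, reads$sequence_id[i])
  }
  if (n_skipped > 0L) {
    warn(sprintf("skipped %d read(s) whose alignment exceeds the allele frame", n_skipped))
  }
  out <- tibble(sequence_id = ids, row = rows)
  class(out) <- c("alignment_panel", class(out))
  attr(out, "positions") <- seq_len(width)
  attr(out, "germline") <- germline
  attr(out, "allele") <- allele$name
  attr(out, "segment") <- allele$segment
  attr(out, "consensus") <- panel_consensus(rows, width)
  attr(out, "n_skipped") <- n_skipped
  out
}

# One panel row: the read's segment region on the allele frame, low-quality
# bases masked, uncovered columns filled with '.'. NULL when the read does
# not fit the frame.
panel_row <- function(read, allele, width, qual_threshold) {
  if (is.na(read$sequence_alignment)) return(NULL)
  if (allele$segment == "V") {
    vend <- read$v_germline_end
    if (is.na(vend)) vend <- min(nchar(read$sequence_alignment), width)
    if (vend > width) return(NULL)
    vend <- min(vend, nchar(read$sequence_alignment))
    region <- substr(read$sequence_alignment, 1L, vend)
    chars <- strsplit(region, "", fixed = TRUE)[[1L]]
    if (!is.na(read$quality)) {
      base_idx <- cumsum(chars != ".")
      quals <- utf8ToInt(read$quality) - 33L
      low <- chars != "." & base_idx <= length(quals) & quals[pmax(base_idx, 1L)] < qual_threshold
      chars[low] <- "-"
    }
    paste0(paste(chars, collapse = ""), strrep(".", width - vend))
  } else {
    region <- read$j_sequence_alignment
    if (is.na(region)) return(NULL)
    if (nchar(region) > width) return(NULL)
    # J reads are 3'-anchored; pad the trimmed 5' end
    paste0(strrep(".", width - nchar(region)), region)
  }
}

panel_consensus <- function(rows, width) {
  if (length(rows) == 0L) return(strrep(".", width))
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  cons <- apply(m, 2L, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1L]
  })
  paste(cons, collapse = "")
}

panel_char_matrix <- function(panel) {
  if (nrow(panel) == 0L) {
    return(matrix(character(0), nrow = 0L, ncol = length(attr(panel, "positions"))))
  }
  do.call(rbind, strsplit(panel$row, "", fixed = TRUE))
}

#' Zoom an alignment panel to its terminal columns
#'
#' The recombination process trims the 3' end of the V gene (and the 5' end
#' of the J gene), so the terminal nucleotides carry the least evidence. The
#' zoom restricts the panel to the last `n` non-gap germline columns for V,
#' or the first `n` columns for J.
#'
#' @param panel An `alignment_panel`.
#' @param segment `"V"` or `"J"`; defaults to the panel's segment.
#' @param n Number of terminal positions (default 8).
#' @return An `alignment_panel` restricted to those columns; `positions`
#'   keeps the original frame coordinates.
#' @export
end_zoom <- function(panel, segment = attr(panel, "segment"), n = 8) {
  germ_chars <- strsplit(attr(panel, "germline"), "", fixed = TRUE)[[1L]]
  width <- length(germ_chars)
  if (n > width) {
    warn(sprintf("zoom width %d exceeds panel width %d; returning full panel", n, width))
    return(panel)
  }
  cols <- if (segment == "V") {
    tail(which(germ_chars != "."), n)
  } else {
    head(seq_len(width), n)
  }
  subset_chars <- function(s) {
    if (length(cols) == 0L) return("")
    paste(strsplit(s, "", fixed = TRUE)[[1L]][cols], collapse = "")
  }
  out <- tibble(sequence_id = panel$sequence_id,
                row = vapply(panel$row, subset_chars, "", USE.NAMES = FALSE))
  class(out) <- c("alignment_panel", class(out))
  attr(out, "positions") <- attr(panel, "positions")[cols]
  attr(out, "germline") <- subset_chars(attr(panel, "germline"))
  attr(out, "allele") <- attr(panel, "allele")
  attr(out, "segment") <- attr(panel, "segment")
  attr(out, "consensus") <- subset_chars(attr(panel, "consensus"))
  attr(out, "n_skipped") <- attr(panel, "n_skipped")
  out
}

#' Mutation-distance histogram for an allele
#'
#' Distributes the reads assigned to an allele by their number of nucleotide
#' differences to the germline (or inferred, for novel alleles) sequence
#' over the read's covered extent. Bin 0 equals the allele's
#' `unmutated_sequences`: reads with ambiguous calls or missing alignments
#' are skipped, matching their exclusion from exact-match statistics.
#'
#' @param reads Rearrangement tibble.
#' @param allele One-row slice of a `reference_set` (V or J).
#' @return A tibble of class `mutation_histogram` with columns `distance`
#'   (0..max observed) and `n`; attributes `allele` and `n_skipped`.
#' @export
mutation_histogram <- function(reads, allele) {
  call_col <- c(V = "v_call", J = "j_call")[[allele$segment]]
  raw <- reads[[call_col]]
  assigned <- primary_call_or_na(raw) == allele$name
  assigned[is.na(assigned)] <- FALSE
  ambiguous <- !is.na(raw) & grepl(",", raw, fixed = TRUE)
  sub <- reads[assigned & !ambiguous, ]
  n_skipped <- sum(assigned & ambiguous)

  dist <- rep(NA_integer_, nrow(sub))
  if (nrow(sub) == 0L) {
    # fall through with no distances
  } else if (allele$segment == "V") {
    ok <- !is.na(sub$sequence_alignment)
    vend <- sub$v_germline_end
    vend[is.na(vend)] <- nchar(allele$gapped_seq)
    vend <- pmin(vend, nchar(sub$sequence_alignment), nchar(allele$gapped_seq))
    region <- substring(sub$sequence_alignment, 1L, vend)
    germ <- substring(allele$gapped_seq, 1L, vend)
    dist[ok] <- mapply(gapped_hamming, region[ok], germ[ok], USE.NAMES = FALSE)
  } else {
    ok <- !is.na(sub$j_sequence_alignment)
    glen <- nchar(allele$ungapped_seq)
    k <- pmin(nchar(sub$j_sequence_alignment), glen)
    region <- substring(sub$j_sequence_alignment,
                        nchar(sub$j_sequence_alignment) - k + 1L)
    germ <- substring(allele$ungapped_seq, glen - k + 1L)
    dist[ok] <- mapply(gapped_hamming, region[ok], germ[ok], USE.NAMES = FALSE)
  }
  n_skipped <- n_skipped + sum(is.na(dist))
  dist <- dist[!is.na(dist)]

  out <- if (length(dist) == 0L) {
    tibble(distance = integer(0), n = integer(0))
  } else {
    tibble(distance = 0:max(dist)) |>
      left_join(tibble(distance = dist) |> count(.data$distance),
                by = "distance") |>
      mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  }
  class(out) <- c("mutation_histogram", class(out))
  attr(out, "allele") <- allele$name
  attr(out, "n_skipped") <- n_skipped
  out
}

# ---- ggplot2 renderers --------------------------------------------------

#' @method autoplot alignment_panel
#' @export
autoplot.alignment_panel <- function(object, ...) {
  m <- panel_char_matrix(object)
  pos <- attr(object, "positions")
  germ <- strsplit(attr(object, "germline"), "", fixed = TRUE)[[1L]]
  ids <- c("germline", object$sequence_id)
  m <- rbind(germ, m)
  df <- tibble(
    sequence_id = rep(ids, times = length(pos)),
    position = rep(pos, each = length(ids)),
    char = as.vector(m)
  )
  df$sequence_id <- factor(df$sequence_id, levels = rev(ids))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position, levels = pos),
                                   y = .data$sequence_id, fill = .data$char)) +
    ggplot2::geom_tile(colour = "grey85", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = c(
      A = "#4daf4a", C = "#377eb8", G = "#ff7f00", "T" = "#e41a1c",
      N = "grey40", "." = "white", "-" = "grey70"), na.value = "white") +
    ggplot2::labs(x = "position (IMGT frame)", y = NULL, fill = "base",
                  title = paste0("Reads assigned to ", attr(object, "allele"))) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @method autoplot mutation_histogram
#' @export
autoplot.mutation_histogram <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$distance, y = .data$n)) +
    ggplot2::geom_col(fill = "#377eb8") +
    ggplot2::labs(x = "nucleotide differences to germline", y = "reads",
                  title = paste0("Mutation distances, ", attr(object, "allele"))) +
    ggplot2::theme_minimal()
}

#' @method autoplot allele_usage
#' @export
autoplot.allele_usage <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$gene, y = .data$n, fill = .data$allele)) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::labs(x = NULL, y = if (isTRUE(attr(object, "unmutated_only"))) {
      "unmutated reads"
    } else {
      "reads"
    }, title = paste0(attr(object, "segment"), "-allele usage by gene")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot haplotype_report
#' @export
autoplot.haplotype_report <- function(object, ...) {
  anchors <- attr(object, "anchor_alleles")
  df <- as_tibble(object) |>
    select("allele", "count_anchor1", "count_anchor2") |>
    tidyr::pivot_longer(c("count_anchor1", "count_anchor2"),
                        names_to = "anchor", values_to = "n")
  df$anchor <- ifelse(df$anchor == "count_anchor1", anchors[1L], anchors[2L])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$allele, y = .data$n,
                                   fill = .data$anchor)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "reads", fill = attr(object, "anchor_gene"),
                  title = paste0("Usage split by ", attr(object, "anchor_gene"),
                                 " anchor allele")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Render a diagnostic object to an image file
#'
#' Dispatches to the object's [autoplot()] method and writes the figure.
#' Output is deterministic: ordering is fixed by the underlying tables and
#' no randomized layout is used.
#'
#' @param x An `alignment_panel`, `mutation_histogram`, `allele_usage` or
#'   `haplotype_report` object.
#' @param path Output image path; format follows the extension (png, pdf,
#'   svg, ...).
#' @param width,height Figure size in inches.
#' @return `path`, invisibly.
#' @export
render <- function(x, path, width = 8, height = 5) {
  p <- autoplot(x)
  ggplot2::ggsave(path, plot = p, width = width, height = height, dpi = 150)
  invisible(path)
}
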