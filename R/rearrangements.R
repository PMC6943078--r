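# AIRR rearrangement IO: read the TSV, normalize productivity, and apply the
# productive-sequence filter that defines genotype membership.

airr_required_cols <- c("sequence_id", "v_call", "j_call",
                        "sequence_alignment", "productive")
airr_optional_cols <- c("d_call", "junction_aa", "cdr3", "umi", "quality",
                        "j_sequence_alignment", "v_germline_end")

#' Read an AIRR rearrangement TSV
#'
#' Reads a tab-separated rearrangement file following the AIRR rearrangement
#' schema into a tibble, one row per read. Required columns are
#' `sequence_id`, `v_call`, `j_call`, `sequence_alignment` and `productive`;
#' recognised optional columns are `d_call`, `junction_aa`, `cdr3`, `umi`,
#' `quality` (Phred+33 string over the non-gap bases of
#' `sequence_alignment`), `j_sequence_alignment` (the read's J-region
#' nucleotides) and `v_germline_end` (1-based IMGT-gapped coordinate of the
#' last V nucleotide covered by the read). Missing optional columns are
#' filled with `NA`.
#'
#' The `productive` flag accepts `T`/`F`, `TRUE`/`FALSE`, `true`/`false` and
#' `1`/`0`; any other value is treated as not productive, with a warning,
#' so that genotypes are built only from reads known to be expressed and
#' productive.
#'
#' @param path Path to the TSV file.
#' @param colmap Optional named character vector mapping schema names to the
#'   file's header names (e.g. `c(sequence_id = "read_id")`) to support
#'   other tools' exports.
#' @return A tibble with the columns above, `productive` as logical and
#'   `v_germline_end` as integer.
#' @export
read_airr_tsv <- function(path, colmap = NULL) {
  if (!file.exists(path)) abort(paste0("rearrangement file not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, na = character())
  if (!is.null(colmap)) {
    for (std in names(colmap)) {
      if (colmap[[std]] %in% names(df)) {
        names(df)[names(df) == colmap[[std]]] <- std
      }
    }
  }
  missing_req <- setdiff(airr_required_cols, names(df))
  if (length(missing_req) > 0L) {
    abort(paste0("required column ", paste(missing_req, collapse = ", "),
                 " missing from ", path))
  }
  for (col in airr_optional_cols) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  df <- df[, c(airr_required_cols, airr_optional_cols)]
  for (col in names(df)) {
    blank <- !is.na(df[[col]]) & df[[col]] == ""
    if (any(blank)) df[[col]][blank] <- NA_character_
  }

  bad_row <- is.na(df$sequence_id) | is.na(df$v_call) | is.na(df$sequence_alignment)
  if (any(bad_row)) {
    warn(sprintf("skipped %d row(s) lacking sequence_id, v_call or sequence_alignment",
                 sum(bad_row)))
    df <- df[!bad_row, ]
  }
  df$productive <- normalize_productive(df$productive)
  df$v_germline_end <- suppressWarnings(as.integer(df$v_germline_end))
  inform(sprintf("read %d rearrangement(s) from %s", nrow(df), path))
  as_tibble(df)
}

normalize_productive <- function(x) {
  up <- toupper(trimws(as.character(x)))
  out <- up %in% c("T", "TRUE", "1")
  unknown <- !up %in% c("T", "TRUE", "1", "F", "FALSE", "0")
  if (any(unknown)) {
    warn(sprintf("%d unrecognized productive value(s) treated as non-productive",
                 sum(unknown)))
  }
  out
}

#' Keep only productive rearrangements
#'
#' The genotype is defined over genes that lead to expressed productive
#' sequences, so every downstream statistic is computed on the productive
#' subset. Idempotent.
#'
#' @param reads Rearrangement tibble (see [read_airr_tsv()]).
#' @return The productive subset of `reads`.
#' @export
filter_productive <- function(reads) {
  removed <- sum(!reads$productive)
  if (removed > 0L) {
    inform(sprintf("removed %d non-productive read(s); %d retained",
                   removed, nrow(reads) - removed))
  }
  reads[reads$productive, , drop = FALSE]
}

#' Resolve the primary allele of a (possibly multi-valued) call string
#'
#' Allele call fields may list several comma-separated alleles when the
#' annotation is ambiguous. A read is assigned to the first listed allele;
#' the ambiguity flag marks reads that are excluded from exact-match
#' (unmutated) statistics so that one read cannot contribute an exact match
#' to several alleles.
#'
#' @param call Character vector of allele call strings.
#' @return A tibble with columns `allele` (first listed allele, whitespace
#'   stripped) and `ambiguous` (more than one allele listed).
#' @examples
#' primary_call(c("IGHJ6*02", "IGHV1-2*02,IGHV1-2*04"))
#' @export
primary_call <- function(call) {
  if (length(call) == 0L) {
    return(tibble(allele = character(), ambiguous = logical()))
  }
  if (any(is.na(call) | trimws(call) == "")) {
    abort("empty allele call string")
  }
  parts <- strsplit(call, ",", fixed = TRUE)
  tibble(
    allele = trimws(vapply(parts, `[[`, "", 1L)),
    ambiguous = lengths(parts) > 1L
  )
}

# Vectorized primary allele without error on NA: NA stays NA (used for
# co-occurrence counts on optional segments such as d_call).
primary_call_or_na <- function(call) {
  out <- rep(NA_character_, length(call))
  ok <- !is.na(call) & trimws(call) != ""
  if (any(ok)) {
    parts <- strsplit(call[ok], ",", fixed = TRUE)
    out[ok] <- trimws(vapply(parts, `[[`, "", 1L))
  }
  out
}
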