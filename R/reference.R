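#' Read a germline reference set from (gapped) FASTA
#'
#' Reads V, D and J germline alleles from a FASTA file into a reference-set
#' tibble. V-gene records are expected on the IMGT-gapped frame with gap
#' columns shown as `.`; `-` gap characters are accepted and normalized to
#' `.`. D and J records are ungapped. All coordinates used by the package are
#' 1-based and inclusive.
#'
#' An allele is flagged as novel (a candidate inferred allele rather than a
#' reference allele) when its name carries no `*` allele designator, matching
#' the submitter-name convention (e.g. `IGHV_S1`). Supplying `novel_names`
#' replaces that heuristic: exactly the named records are flagged novel.
#'
#' @param path Path to a FASTA file.
#' @param novel_names Optional character vector of record names to flag as
#'   novel, overriding the no-`*` heuristic.
#' @param locus Optional locus label (e.g. `"IGH"`); defaults to the first
#'   three characters of the first record name.
#' @return A tibble of class `reference_set` with one row per allele and
#'   columns `name`, `gene`, `segment`, `gapped_seq`, `ungapped_seq`,
#'   `is_novel`, and a `locus` attribute.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">IGHJ6*02", "ATTACT"), fa)
#' read_gapped_fasta(fa)
#' @export
read_gapped_fasta <- function(path, novel_names = NULL, locus = NULL) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  recs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA '", path, "': ", conditionMessage(e)))
  )
  if (length(recs) == 0L) {
    warn(paste0("empty FASTA file: ", path))
    return(new_reference_set(tibble(
      name = character(), gene = character(), segment = character(),
      gapped_seq = character(), ungapped_seq = character(), is_novel = logical()
    ), locus = locus %||% NA_character_))
  }
  nm <- sub("\\s.*$", "", names(recs))
  seqs <- toupper(as.character(recs))
  names(seqs) <- NULL
  build_reference_set(nm, seqs, novel_names = novel_names, locus = locus)
}

# Shared constructor/validator for reference sets built from names+sequences.
build_reference_set <- function(nm, seqs, novel_names = NULL, locus = NULL) {
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate allele name(s) in reference set: ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (any(grepl("-", seqs, fixed = TRUE))) {
    inform("normalizing '-' gap characters to '.'")
    seqs <- gsub("-", ".", seqs, fixed = TRUE)
  }
  bad <- gregexpr("[^ACGTN.]", seqs)
  for (i in seq_along(bad)) {
    if (bad[[i]][1L] != -1L) {
      abort(sprintf("illegal character '%s' at position %d of record '%s'",
                    substr(seqs[i], bad[[i]][1L], bad[[i]][1L]), bad[[i]][1L], nm[i]))
    }
  }
  segment <- toupper(substr(nm, 4L, 4L))
  if (any(!segment %in% c("V", "D", "J"))) {
    abort(paste0("cannot derive segment (V/D/J) from allele name(s): ",
                 paste(nm[!segment %in% c("V", "D", "J")], collapse = ", ")))
  }
  is_novel <- if (is.null(novel_names)) {
    !grepl("*", nm, fixed = TRUE)
  } else {
    nm %in% novel_names
  }
  out <- tibble(
    name = nm,
    gene = sub("\\*.*$", "", nm),
    segment = segment,
    gapped_seq = seqs,
    ungapped_seq = gsub(".", "", seqs, fixed = TRUE),
    is_novel = is_novel
  )
  v_wid <- nchar(out$gapped_seq[out$segment == "V"])
  if (length(v_wid) > 1L && length(unique(v_wid)) > 1L) {
    inform(sprintf(
      "V alleles gapped to different lengths (max %d); shorter records are treated as 3'-truncated",
      max(v_wid)))
  }
  new_reference_set(out, locus = locus %||% substr(nm[1L], 1L, 3L))
}

new_reference_set <- function(df, locus) {
  attr(df, "locus") <- locus
  class(df) <- unique(c("reference_set", class(df)))
  df
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> locus %s: %d alleles (%d V, %d D, %d J; %d novel)\n",
              attr(x, "locus") %||% "?", nrow(x),
              sum(x$segment == "V"), sum(x$segment == "D"), sum(x$segment == "J"),
              sum(x$is_novel)))
  NextMethod()
}

#' Write a reference set (or its novel subset) to FASTA
#'
#' @param reference A `reference_set` tibble.
#' @param path Output FASTA path.
#' @param novel_only Write only alleles flagged `is_novel`.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path, novel_only = FALSE) {
  df <- if (novel_only) reference[reference$is_novel, ] else reference
  set <- Biostrings::BStringSet(setNames(df$gapped_seq, df$name))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Map ungapped V positions to IMGT-gapped positions
#'
#' For a V allele on the IMGT gap frame, returns the mapping from each
#' ungapped nucleotide index to its gapped (IMGT) column. Both coordinate
#' systems are 1-based. D and J alleles use coding-sequence numbering (the
#' identity map), so calling this on them is an error.
#'
#' @param reference A `reference_set` tibble.
#' @param name Allele name to map.
#' @return A tibble with columns `ungapped` and `imgt`, strictly increasing
#'   in both.
#' @examples
#' ref <- synthetic_reference_set()
#' head(imgt_position_map(ref, "IGHV1-69*01"))
#' @export
imgt_position_map <- function(reference, name) {
  row <- reference_row(reference, name)
  if (row$segment != "V") {
    abort(paste0("IMGT position maps apply to V alleles only; '", name,
                 "' is a ", row$segment,
                 " allele (D/J numbering counts from the coding-sequence start)"))
  }
  chars <- strsplit(row$gapped_seq, "", fixed = TRUE)[[1L]]
  imgt <- which(chars != ".")
  tibble(ungapped = seq_along(imgt), imgt = imgt)
}

reference_row <- function(reference, name) {
  i <- match(name, reference$name)
  if (is.na(i)) abort(paste0("allele '", name, "' not found in reference set"))
  reference[i, ]
}

#' Check genotype alleles against a reference set
#'
#' Compares each named sequence against the same-named entry of a reference
#' set and reports discrepancies: names absent from the reference, and
#' sequences whose gap-free nucleotides differ from the reference entry.
#' Discrepancies are data, not errors.
#'
#' @param genotype_alleles Named character vector or two-column data frame
#'   (`name`, `sequence`) of allele sequences to check (gapped or ungapped).
#' @param reference A `reference_set` tibble.
#' @return A tibble with columns `name`, `kind` (`"missing"` or
#'   `"sequence_mismatch"`) and `detail`; zero rows when everything matches.
#' @export
check_against_reference <- function(genotype_alleles, reference) {
  if (is.data.frame(genotype_alleles)) {
    nm <- genotype_alleles$name
    sq <- genotype_alleles$sequence
  } else {
    nm <- names(genotype_alleles)
    sq <- unname(genotype_alleles)
  }
  sq <- gsub("[.-]", "", toupper(sq))
  out <- purrr::map2_dfr(nm, sq, function(name, seq) {
    i <- match(name, reference$name)
    if (is.na(i)) {
      return(tibble(name = name, kind = "missing",
                    detail = "name absent from reference set"))
    }
    ref_seq <- reference$ungapped_seq[i]
    if (seq == ref_seq) return(tibble(name = character(), kind = character(), detail = character()))
    d <- seq_diff_positions(seq, ref_seq)
    detail <- if (nchar(seq) != nchar(ref_seq)) {
      sprintf("length %d vs reference %d", nchar(seq), nchar(ref_seq))
    } else {
      paste(sprintf("%s%d%s", substring(ref_seq, d, d), d, substring(seq, d, d)),
            collapse = ",")
    }
    tibble(name = name, kind = "sequence_mismatch", detail = detail)
  })
  out
}
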