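# File formats: FASTA amplicons, sample sheets, typing tables.
# Sequences are Sanger-style consensus amplicons: the strict alphabet is
# ACGTN and IUPAC ambiguity codes are rejected outright.

.validate_sequences <- function(seqs, ids, where = "sequence") {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    ch <- regmatches(seqs[i], regexpr("[^ACGTN]", seqs[i]))
    abort(sprintf(
      "invalid character '%s' in %s '%s': only A/C/G/T/N are accepted",
      ch, where, ids[i]))
  }
  invisible(TRUE)
}

#' Read a FASTA file of amplicon sequences
#'
#' Sequences are uppercased and validated against the strict A/C/G/T/N
#' alphabet; record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return tibble with columns `id` (first word of the header) and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  non_blank <- which(nzchar(trimws(lines)))
  if (length(non_blank) == 0) abort(sprintf("empty FASTA file: %s", path))
  if (!startsWith(trimws(lines[non_blank[1]]), ">")) {
    abort(sprintf("malformed FASTA record at line %d of %s: expected '>'",
                  non_blank[1], path))
  }
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) abort(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicated FASTA id: %s", ids[duplicated(ids)][1]))
  }
  seqs <- str_to_upper(as.character(set))
  .validate_sequences(seqs, ids, where = "FASTA record")
  tibble(id = ids, sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param x tibble with columns `id` and `sequence` (e.g. from
#'   [generate_population()]).
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  stopifnot(all(c("id", "sequence") %in% names(x)))
  set <- Biostrings::DNAStringSet(setNames(x$sequence, x$id))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a sampling-site membership sheet
#'
#' A tab-separated table with header columns `sample_id`, `site`, `region`.
#' `sample_id` must be unique and every site must belong to exactly one
#' region.
#'
#' @param path path to the TSV file.
#' @return tibble with columns `sample_id`, `site`, `region`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet a data frame to validate in place.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "site", "region")
  if (!all(need %in% names(sheet))) {
    abort(sprintf("sample sheet must have columns %s",
                  paste(need, collapse = ", ")))
  }
  sheet <- as_tibble(sheet)[need]
  if (anyDuplicated(sheet$sample_id)) {
    abort(sprintf("duplicated sample_id in sample sheet: %s",
                  sheet$sample_id[duplicated(sheet$sample_id)][1]))
  }
  multi <- sheet |> dplyr::distinct(.data$site, .data$region) |>
    dplyr::count(.data$site) |> dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    abort(sprintf("site '%s' is assigned to more than one region",
                  multi$site[1]))
  }
  sheet
}

#' @rdname read_sample_sheet
#' @param x sample sheet tibble to write.
#' @export
write_sample_sheet <- function(x, path) {
  readr::write_tsv(validate_sample_sheet(x), path, progress = FALSE)
  invisible(path)
}

.TYPING_COLS <- c("sample_id", "site", "region", "lineage", "sublineage",
                  "pattern", "haplotype", "n_edits_vs_closest")

#' Write / read a typing table
#'
#' The typing table is the pipeline's central per-colony output: TSV with
#' columns `sample_id`, `site`, `region`, `lineage`, `sublineage`, `pattern`,
#' `haplotype`, `n_edits_vs_closest`, one row per sample in input order.
#'
#' @param results typing tibble (from [type_sequences()]).
#' @param path output path.
#' @return `path` invisibly (write); typing tibble (read).
#' @export
write_typing_table <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) {
    abort("`results` must contain at least one typing result")
  }
  missing_cols <- setdiff(.TYPING_COLS, names(results))
  if (length(missing_cols) > 0) {
    abort(sprintf("typing table is missing columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  readr::write_tsv(results[.TYPING_COLS], path, progress = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_typing_table
#' @export
read_typing_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", site = "c", region = "c", lineage = "c",
    sublineage = "c", pattern = "c", haplotype = "c",
    n_edits_vs_closest = "i"), progress = FALSE)
}
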