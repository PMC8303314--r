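# Encoded reference haplotype catalog.
#
# The published variant definitions are re-anchored onto the package's own
# synthetic master alignment: every cited variable column (84, 86, 99, 100,
# 139, 148, 252, 286, 298, 336, 337, 646, 739, 795) is a real 1-based column
# of that alignment. Family bases that the source distinguishes only by name
# (C1/C2/C3, A1e) additionally carry documented *synthetic* founder
# substitutions at reserved columns so that every catalog member has a unique
# sequence; these founder columns (560-620) are not published data.

.edit_tbl <- function(column = integer(), ref = character(),
                      alt = character(), kind = character()) {
  tibble(column = as.integer(column), ref = ref, alt = alt, kind = kind)
}

.e <- function(...) {
  m <- matrix(c(...), ncol = 4, byrow = TRUE)
  .edit_tbl(as.integer(m[, 1]), m[, 2], m[, 3], m[, 4])
}

# variant edit lists, relative to each record's family base
.CATALOG_EDITS <- list(
  A1  = .edit_tbl(),
  A1e = .e(575, "G", "A", "substitution"),                    # synthetic marker
  A1t = .e(99, "G", "A", "substitution",
           139, "-", "A", "insertion",
           646, "C", "T", "substitution"),
  A1u = .e(99, "G", "A", "substitution",
           286, "T", "C", "substitution"),
  A1w = .e(100, "-", "G", "insertion",
           646, "C", "T", "substitution"),
  A4  = .edit_tbl(),
  A4p = .e(99, "A", "G", "substitution",
           100, "-", "G", "insertion",
           646, "C", "T", "substitution"),
  A4q = .e(99, "A", "G", "substitution",
           100, "-", "G", "insertion",
           298, "-", "A", "insertion",
           646, "C", "T", "substitution"),
  A4s = .e(337, "-", "A", "insertion",
           646, "C", "T", "substitution"),
  A4t = .e(252, "T", "-", "deletion",
           337, "-", "A", "insertion",
           646, "C", "T", "substitution"),
  A4u = .e(252, "T", "-", "deletion",
           646, "C", "T", "substitution"),
  A4v = .e(252, "T", "-", "deletion",
           337, "-", "A", "insertion",
           646, "C", "T", "substitution",
           739, "A", "T", "substitution"),
  A4w = .e(252, "T", "-", "deletion",
           337, "-", "A", "insertion",
           646, "C", "T", "substitution",
           795, "A", "T", "substitution"),
  A30  = .edit_tbl(),
  A30d = .e(336, "C", "-", "deletion"),
  A30e = .e(86, "C", "A", "substitution"),
  A65  = .edit_tbl(),
  C1   = .edit_tbl(),
  C2   = .edit_tbl(),
  C2c  = .e(560, "T", "C", "substitution"),
  C2j  = .e(585, "A", "G", "substitution"),
  C2l  = .e(560, "T", "C", "substitution",
            600, "G", "A", "substitution"),
  C3   = .edit_tbl(),
  M7   = .edit_tbl(),
  M7b  = .e(84, "A", "G", "substitution"),
  M7c  = .e(84, "A", "G", "substitution",
            148, "T", "C", "substitution")
)

# founder substitutions of family bases, relative to the plain architecture
# consensus (synthetic, documented)
.FOUNDER_EDITS <- list(
  A1 = .e(99, "A", "G", "substitution"),
  C1 = .e(560, "T", "C", "substitution",
          620, "C", "T", "substitution"),
  C3 = .e(610, "A", "G", "substitution")
)

.CATALOG_RECORDS <- tibble::tribble(
  ~name,  ~family, ~lineage, ~sublineage, ~p_form,  ~n_q, ~novel, ~observed,
  "A1",   "A1",    "A",      "AI",        "P0",     1L,   FALSE,  TRUE,
  "A1e",  "A1",    "A",      "AI",        "P0",     1L,   FALSE,  TRUE,
  "A1t",  "A1",    "A",      "AI",        "P0",     1L,   TRUE,   TRUE,
  "A1u",  "A1",    "A",      "AI",        "P0",     1L,   TRUE,   TRUE,
  "A1w",  "A1",    "A",      "AI",        "P0",     1L,   TRUE,   TRUE,
  "A4",   "A4",    "A",      "AI",        "P0",     2L,   FALSE,  FALSE,
  "A4p",  "A4",    "A",      "AI",        "P0",     2L,   TRUE,   TRUE,
  "A4q",  "A4",    "A",      "AI",        "P0",     2L,   TRUE,   TRUE,
  "A4s",  "A4",    "A",      "AI",        "P0",     2L,   TRUE,   TRUE,
  "A4t",  "A4",    "A",      "AI",        "P0",     2L,   TRUE,   TRUE,
  "A4u",  "A4",    "A",      "AI",        "P0",     2L,   TRUE,   TRUE,
  "A4v",  "A4",    "A",      "AI",        "P0",     2L,   TRUE,   TRUE,
  "A4w",  "A4",    "A",      "AI",        "P0",     2L,   TRUE,   TRUE,
  "A30",  "A30",   "A",      "AIII",      "P1",     2L,   FALSE,  TRUE,
  "A30d", "A30",   "A",      "AIII",      "P1",     2L,   TRUE,   TRUE,
  "A30e", "A30",   "A",      "AIII",      "P1",     2L,   TRUE,   TRUE,
  "A65",  "A65",   "A",      "AI",        "P0",     0L,   TRUE,   TRUE,
  "C1",   "C1",    "C",      "none",      "absent", 1L,   FALSE,  TRUE,
  "C2",   "C2",    "C",      "none",      "absent", 1L,   FALSE,  TRUE,
  "C2c",  "C2",    "C",      "none",      "absent", 1L,   FALSE,  TRUE,
  "C2j",  "C2",    "C",      "none",      "absent", 1L,   FALSE,  TRUE,
  "C2l",  "C2",    "C",      "none",      "absent", 1L,   FALSE,  TRUE,
  "C3",   "C3",    "C",      "none",      "absent", 1L,   FALSE,  TRUE,
  "M7",   "M7",    "M",      "none",      "P",      2L,   FALSE,  FALSE,
  "M7b",  "M7",    "M",      "none",      "P",      2L,   TRUE,   TRUE,
  "M7c",  "M7",    "M",      "none",      "P",      2L,   TRUE,   TRUE
)

.OUTGROUP_NAME <- "Acerana_synthetic"

# synthetic outgroup founders: a divergent P0-bearing, Q-lacking row
.OUTGROUP_COLS <- c(45L, 50L, 58L, 63L, 75L,
                    530L, 540L, 550L, 655L, 665L, 675L, 685L, 695L, 705L, 715L)

.sublineage_template_of <- function(sublineage) {
  ifelse(sublineage %in% c("AI", "AII", "AIII", "Z"), sublineage, "none")
}

.length_pattern_of <- function(p_form, n_q) {
  token <- c(P0 = "P0", P = "P", P1 = "P1", P2 = "P2", absent = "")[p_form]
  paste0(token, strrep("Q", n_q))
}

#' Load the encoded reference haplotype catalog
#'
#' Builds (and caches) the catalog of tRNAleu-cox2 reference haplotypes on the
#' package's synthetic master alignment: the 24 haplotypes observed in the
#' Peruvian survey plus the two unobserved family bases (A4, M7) and a
#' synthetic *Apis cerana*-like outgroup row. Each record carries its length
#' pattern (e.g. `"P0QQ"`), lineage/sub-lineage, novelty flag and the edit
#' list that distinguishes it from its family base.
#'
#' Note: the source description names "A30d" twice; following its apparent
#' intent the position-336 deletion is encoded as A30d and the position-86
#' substitution as A30e.
#'
#' @return An object of class `haplotype_catalog`: a list with `records`
#'   (tibble, one row per haplotype, `edits` as a list-column), `alignment`
#'   (named character vector of aligned rows, including the outgroup) and
#'   `outgroup` (its name).
#' @examples
#' cat <- load_reference_catalog()
#' dplyr::filter(cat$records, name == "A65")
#' @export
load_reference_catalog <- function() {
  if (!is.null(.beemito_env$catalog)) return(.beemito_env$catalog)

  rec <- .CATALOG_RECORDS
  rec$pattern <- .length_pattern_of(rec$p_form, rec$n_q)
  rec$edits <- unname(.CATALOG_EDITS[rec$name])
  stopifnot(!anyNA(names(.CATALOG_EDITS[rec$name])))

  rows <- vector("list", nrow(rec))
  names(rows) <- rec$name
  for (i in seq_len(nrow(rec))) {
    fam <- rec$family[i]
    base_i <- match(fam, rec$name)
    row <- .aligned_row(rec$p_form[base_i], rec$n_q[base_i],
                        .sublineage_template_of(rec$sublineage[base_i]))
    if (!is.null(.FOUNDER_EDITS[[fam]])) {
      row <- .apply_edits(row, .FOUNDER_EDITS[[fam]],
                          context = paste0("catalog founder ", fam))
    }
    if (rec$name[i] != fam) {
      row <- .apply_edits(row, rec$edits[[i]],
                          context = paste0("catalog record ", rec$name[i]))
    }
    rows[[i]] <- row
  }

  # synthetic outgroup: P0 present, no Q, no DraI sites, divergent founders
  og <- .aligned_row("P0", 0L, "none")
  ref <- og[.OUTGROUP_COLS]
  og[.OUTGROUP_COLS] <- chartr("ACGT", "GTAC", ref)
  rows[[.OUTGROUP_NAME]] <- og

  rec$aligned <- unname(map_chr(rows[rec$name], paste, collapse = ""))
  rec$sequence <- unname(map_chr(rows[rec$name], .degap))
  if (anyDuplicated(rec$sequence)) {
    abort("catalog integrity error: duplicated haplotype sequences")
  }
  if (anyDuplicated(rec$name)) {
    abort("catalog integrity error: duplicated haplotype names")
  }

  alignment <- vapply(rows, paste, character(1), collapse = "")
  if (length(unique(nchar(alignment))) != 1) {
    abort("catalog integrity error: ragged master alignment")
  }

  catalog <- structure(
    list(records = rec, alignment = alignment, outgroup = .OUTGROUP_NAME),
    class = "haplotype_catalog")
  .beemito_env$catalog <- catalog
  catalog
}

#' @export
print.haplotype_catalog <- function(x, ...) {
  cat("<haplotype_catalog>", nrow(x$records), "records,",
      sum(x$records$observed), "observed,",
      sum(x$records$novel), "novel;",
      "alignment width", nchar(x$alignment[[1]]), "\n")
  print(dplyr::select(x$records, "name", "lineage", "sublineage", "pattern",
                      "novel", "observed"))
  invisible(x)
}

#' Catalog haplotype sequences as a tibble
#'
#' @param catalog a `haplotype_catalog` (default: the shipped catalog).
#' @param aligned return gapped master-alignment rows instead of degapped
#'   amplicon sequences.
#' @param observed_only drop the unobserved family bases (A4, M7).
#' @return tibble with `name` and `sequence`.
#' @export
catalog_sequences <- function(catalog = load_reference_catalog(),
                              aligned = FALSE, observed_only = FALSE) {
  rec <- catalog$records
  if (observed_only) rec <- dplyr::filter(rec, .data$observed)
  tibble(name = rec$name,
         sequence = if (aligned) rec$aligned else rec$sequence)
}
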