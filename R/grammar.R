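# Element grammar of the tRNAleu-cox2 intergenic amplicon.
#
# The amplicon is modelled as
#   tRNAleu (40 bp) | P element (0-68 bp, four forms) | Q x 0..5 (196 bp) | cox2 (300 bp)
# All reference haplotypes live on a single master alignment whose columns are
# fixed: 800 scaffold columns (the full P0QQ architecture) plus 4 insertion
# columns reserved for the 1-bp insertions that define named variants.
# Aligned rows for shorter architectures carry gaps; degapping a row yields the
# amplicon sequence.

# fixed element templates (synthetic; no TTTAAA occurs in any junction
# combination, so every DraI site in a generated amplicon is a planted one)
.TPL <- list(
  trnaleu = "TAAATGGTGTAATCCTGAGTGACGTTGAGCTCGAGGTTAG",
  p0 = "TAGTTTTTTTGGTAAGCTCCCATCAGCTAAGCAATGGGTCGCGATCAAACCTTCGTCCAATCAACCGA",
  q = paste0(
    "TGTACTAGGGCCTTGTTTGAACGTACTCCGAACGCCTTATGCGATCTGGGGATCGTAAAGTTGAGAGA",
    "GGGTTGTTCCGCATATATCAAACAGTTTCAACCTAGTATCGGCAAGTTACTACGTAGGTCGCGACAGC",
    "CTGTTTCTTACTGTCTTGGCGCTCAGTACCCGTCCCCCATGAGATCACGATAAGGTGGAC"),
  cox2 = paste0(
    "GTTACAATACGGTGATCTGTCGTGGGAACCTTCATGTCAGGTACCCGCCACCCAGTAAAGTCCTCTGT",
    "GAGTAAATTCTTATGAATTCATGGTCCGTGCCACACGAGTTTAACGTCAGCTCTCAATAGGTATCGTT",
    "TGTTACATTAATAGGTTCATCGATGGCGAGATCCAGGCCAATAGCGTAGAGAACGCGGACTAGGACGC",
    "GGTGGCAGGGCAAATTAGTTGTAAACTTAGAACGAATTTACGACCACATACCGACGGGTAAATCAGTG",
    "GCTGCCGCTCTATACGGTATGGCGTGCA")
)

.DRA_MOTIF <- "TTTAAA"

# scaffold column spans (1-based, before insertion columns are interleaved)
.BLK <- list(
  trnaleu = c(1L, 40L),
  p       = c(41L, 108L),
  q1      = c(109L, 304L),
  q2      = c(305L, 500L),
  cox2    = c(501L, 800L)
)
.SCAFFOLD_WIDTH <- 800L

# master-alignment columns reserved for 1-bp insertions (final coordinates)
.INS_COLS <- c(100L, 139L, 298L, 337L)
.ALN_WIDTH <- .SCAFFOLD_WIDTH + length(.INS_COLS)

# scaffold columns removed by each large P-element deletion
.P_DEL <- list(
  P  = 68:80,   # 13 bp from the middle of P0
  P1 = 94:108,  # 15 bp at the 3' end
  P2 = 41:58    # 18 bp at the 5' end
)
.P_FORM_LEN <- c(P0 = 68L, P = 55L, P1 = 53L, P2 = 50L, absent = 0L)

# scaffold columns of the planted DraI (TTTAAA) sites
.DRA_POS <- list(
  trnaleu = 35:40,  # 3' end of tRNAleu
  q5      = 111:116, # 5' end of the first Q element
  qmid    = 201:206  # middle of the first Q element (sub-lineage Z)
)

.P_FORMS <- c("P0", "P", "P1", "P2", "absent")
.SUBLINEAGES <- c("AI", "AII", "AIII", "Z", "none")

.scaffold_chars <- function() {
  if (is.null(.beemito_env$scaffold)) {
    .beemito_env$scaffold <- unlist(strsplit(
      paste0(.TPL$trnaleu, .TPL$p0, .TPL$q, .TPL$q, .TPL$cox2), ""),
      use.names = FALSE)
  }
  .beemito_env$scaffold
}

# map final master-alignment columns to scaffold columns (NA = insertion col)
.final_to_scaffold <- function(cols) {
  out <- cols - vapply(cols, function(f) sum(.INS_COLS < f), integer(1))
  out[cols %in% .INS_COLS] <- NA_integer_
  out
}

# a scaffold column shifts right by one for every insertion column at or
# before its final position
.scaffold_to_final <- function(cols) {
  vapply(cols, function(s) {
    shift <- 0L
    repeat {
      new_shift <- sum(.INS_COLS <= s + shift)
      if (new_shift == shift) break
      shift <- new_shift
    }
    s + shift
  }, integer(1))
}

#' Build an aligned master-alignment row for one amplicon architecture
#'
#' Internal workhorse shared by the reference catalog and the simulator.
#' Returns a character vector of length 804 over `A`,`C`,`G`,`T`,`-`.
#'
#' @param p_form one of `"P0"`, `"P"`, `"P1"`, `"P2"`, `"absent"`.
#' @param n_q number of tandem Q repeats represented on the alignment (0-2).
#' @param sublineage_template DraI planting scheme: `"AI"`/`"AIII"` (tRNAleu 3'
#'   site and first-Q 5' site), `"AII"` (tRNAleu only), `"Z"` (tRNAleu, first-Q
#'   5' and first-Q middle), `"none"`.
#' @noRd
.aligned_row <- function(p_form, n_q, sublineage_template = "none") {
  stopifnot(p_form %in% .P_FORMS, n_q %in% 0:2,
            sublineage_template %in% .SUBLINEAGES)
  sc <- .scaffold_chars()
  if (p_form == "absent") {
    sc[.BLK$p[1]:.BLK$p[2]] <- "-"
  } else if (p_form != "P0") {
    sc[.P_DEL[[p_form]]] <- "-"
  }
  if (n_q == 0L) sc[.BLK$q1[1]:.BLK$q2[2]] <- "-"
  if (n_q == 1L) sc[.BLK$q2[1]:.BLK$q2[2]] <- "-"
  dra <- strsplit(.DRA_MOTIF, "")[[1]]
  tmpl <- sublineage_template
  if (tmpl %in% c("AI", "AII", "AIII", "Z")) sc[.DRA_POS$trnaleu] <- dra
  if (tmpl %in% c("AI", "AIII", "Z") && n_q >= 1L) sc[.DRA_POS$q5] <- dra
  if (tmpl == "Z" && n_q >= 1L) sc[.DRA_POS$qmid] <- dra
  out <- rep("-", .ALN_WIDTH)
  out[-.INS_COLS] <- sc
  out
}

# apply an edit table (column, ref, alt, kind) to an aligned row, verifying
# reference states; `context` labels integrity errors
.apply_edits <- function(row, edits, context = "edit") {
  if (is.null(edits) || nrow(edits) == 0) return(row)
  for (i in seq_len(nrow(edits))) {
    col <- edits$column[i]
    if (col < 1 || col > length(row)) {
      abort(sprintf("%s: edit column %d outside the master alignment (1-%d)",
                    context, col, length(row)))
    }
    if (!identical(row[col], edits$ref[i])) {
      abort(sprintf(
        "%s: integrity error at column %d: expected reference state '%s', found '%s'",
        context, col, edits$ref[i], row[col]))
    }
    row[col] <- edits$alt[i]
  }
  row
}

.degap <- function(row) paste(row[row != "-"], collapse = "")

#' Construct a synthetic tRNAleu-cox2 amplicon sequence
#'
#' Assembles an amplicon from the element grammar of the intergenic region:
#' a 40 bp tRNAleu fragment, a P element in one of its four forms (`P0`
#' complete, `P` with the 13 bp deletion in the middle, `P1` with the 15 bp
#' deletion at the 3' end, `P2` with the 18 bp deletion at the 5' end) or
#' absent, `n_q` tandem copies of the 196 bp Q element, and a 300 bp cox2
#' fragment. DraI recognition sites (`TTTAAA`) are planted according to the
#' African sub-lineage template, and optional variant edits (in master
#' alignment coordinates) are applied last.
#'
#' @param p_form P-element form: `"P0"`, `"P"`, `"P1"`, `"P2"` or `"absent"`.
#' @param n_q integer number of tandem Q repeats, 0 to 5.
#' @param sublineage_template `"AI"`, `"AII"`, `"AIII"`, `"Z"` or `"none"`;
#'   templates other than `"none"` require `p_form` `"P0"` or `"P1"`.
#' @param variant_edits optional tibble with columns `column` (1-based master
#'   alignment column), `ref`, `alt` (bases or `"-"`) and `kind`
#'   (`"substitution"`, `"insertion"`, `"deletion"`). Only architectures with
#'   `n_q <= 2` are covered by the master alignment and can carry edits.
#'
#' @return A single uppercase DNA string.
#' @examples
#' nchar(build_amplicon("P0", 2, "AI"))          # 40 + 68 + 2*196 + 300
#' build_amplicon("absent", 1)                   # C-lineage architecture
#' @export
build_amplicon <- function(p_form, n_q, sublineage_template = "none",
                           variant_edits = NULL) {
  p_form <- match.arg(p_form, .P_FORMS)
  sublineage_template <- match.arg(sublineage_template, .SUBLINEAGES)
  if (!is.numeric(n_q) || length(n_q) != 1 || n_q < 0 || n_q > 5 ||
      n_q != as.integer(n_q)) {
    abort("`n_q` must be a single integer between 0 and 5")
  }
  n_q <- as.integer(n_q)
  if (sublineage_template != "none" && !p_form %in% c("P0", "P1")) {
    abort("African sub-lineage templates require the P0 or P1 form")
  }
  has_edits <- !is.null(variant_edits) && nrow(variant_edits) > 0
  if (has_edits && n_q > 2L) {
    abort("variant edits are only defined for architectures with n_q <= 2")
  }
  row <- .aligned_row(p_form, min(n_q, 2L), sublineage_template)
  if (has_edits) row <- .apply_edits(row, variant_edits, context = "build_amplicon")
  seq <- .degap(row)
  if (n_q > 2L) {
    # splice extra plain Q copies immediately after the second Q
    q2_final <- .scaffold_to_final(.BLK$q2[2])
    at <- sum(row[seq_len(q2_final)] != "-")
    seq <- paste0(substr(seq, 1, at), strrep(.TPL$q, n_q - 2L),
                  substr(seq, at + 1, nchar(seq)))
  }
  seq
}

#' Expected amplicon length for an architecture
#'
#' Exact closed form from the grammar constants: 40 (tRNAleu) + P-form length
#' (68/55/53/50/0) + 196 per Q repeat + 300 (cox2), before any variant indels.
#'
#' @inheritParams build_amplicon
#' @return integer length in bp
#' @export
amplicon_length <- function(p_form, n_q) {
  p_form <- match.arg(p_form, .P_FORMS)
  40L + .P_FORM_LEN[[p_form]] + 196L * as.integer(n_q) + 300L
}
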