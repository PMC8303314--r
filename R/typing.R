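# Core mitotype classifier.
#
# Detection is alignment-based (not fixed offsets) so that amplicons of
# different absolute lengths can be typed with one code path: tRNAleu and
# cox2 anchors by semi-global alignment (>= 80% identity), the P element by
# global alignment to the P0 template with gap-placement reading of the form,
# Q repeats by iterative semi-global alignment of the Q template (>= 90%
# identity per repeat). All spans are 0-based half-open internally; the
# user-facing edit columns are 1-based master-alignment columns.

.ANCHOR_MIN_PID <- 80
.Q_MIN_PID <- 90

.pw_align <- function(pattern, subject, type = "global-local") {
  Biostrings::pairwiseAlignment(
    pattern = pattern, subject = subject, type = type,
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE),
    gapOpening = 8, gapExtension = 1)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Locate the elements of a tRNAleu-cox2 amplicon
#'
#' Finds the tRNAleu and cox2 anchor fragments, the P element and its form,
#' the tandem Q repeats, and all DraI (TTTAAA) sites. Input orientation is
#' auto-detected from the anchor alignment score; sequences are assumed to be
#' consensus amplicons in forward (E2-to-H2) orientation otherwise.
#'
#' @param sequence a single DNA string (A/C/G/T/N), length >= 150.
#' @return An object of class `element_map`: list with 0-based half-open
#'   spans `trnaleu_span`, `p_span` (NULL when the P element is absent),
#'   `q_spans` (list), `cox2_span`; `p_form`; integer vector `dra1_sites`
#'   (0-based starts of TTTAAA); `reversed` flag; and `sequence` (the
#'   oriented sequence that the spans index).
#' @export
locate_elements <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- str_to_upper(sequence)
  .validate_sequences(sequence, "input", where = "sequence")
  if (nchar(sequence) < 150) abort("sequence too short to type (< 150 bp)")

  fwd_score <- .pw_score_anchors(sequence)
  rc <- .revcomp(sequence)
  rev_score <- .pw_score_anchors(rc)
  reversed <- rev_score > fwd_score
  if (reversed) sequence <- rc

  trna_aln <- .pw_align(.TPL$trnaleu, sequence)
  cox2_aln <- .pw_align(.TPL$cox2, sequence)
  trna_ok <- Biostrings::pid(trna_aln) >= .ANCHOR_MIN_PID
  cox2_ok <- Biostrings::pid(cox2_aln) >= .ANCHOR_MIN_PID
  if (!trna_ok && !cox2_ok) {
    abort("unrecognized amplicon: neither the tRNAleu nor the cox2 anchor was found")
  }
  if (!trna_ok || !cox2_ok) {
    abort(sprintf("unrecognized amplicon: %s anchor not found (identity < %d%%)",
                  if (!trna_ok) "tRNAleu" else "cox2", .ANCHOR_MIN_PID))
  }
  trna_span <- c(Biostrings::start(Biostrings::subject(trna_aln)) - 1L,
                 Biostrings::end(Biostrings::subject(trna_aln)))
  cox2_span <- c(Biostrings::start(Biostrings::subject(cox2_aln)) - 1L,
                 Biostrings::end(Biostrings::subject(cox2_aln)))
  if (trna_span[2] > cox2_span[1]) {
    abort("unrecognized amplicon: anchors overlap or are out of order")
  }

  mid_start <- trna_span[2]            # 0-based start of the inter-anchor gap
  mid_end <- cox2_span[1]              # 0-based end (exclusive)
  mid <- substr(sequence, mid_start + 1, mid_end)

  q_spans <- .find_q_repeats(mid, mid_start)
  p_span <- NULL
  p_form <- "absent"
  p_end <- if (length(q_spans) > 0) q_spans[[1]][1] else mid_end
  if (p_end - mid_start >= 20) {
    p_region <- substr(sequence, mid_start + 1, p_end)
    p_form <- .p_form_from_region(p_region)
    p_span <- c(mid_start, p_end)
  }

  m <- gregexpr("TTTAAA", sequence, fixed = TRUE)[[1]]
  dra1_sites <- if (m[1] == -1) integer() else as.integer(m) - 1L

  structure(list(
    trnaleu_span = trna_span, p_span = p_span, q_spans = q_spans,
    cox2_span = cox2_span, p_form = p_form, dra1_sites = dra1_sites,
    reversed = reversed, sequence = sequence), class = "element_map")
}

.pw_score_anchors <- function(s) {
  sc <- function(tpl) Biostrings::pairwiseAlignment(
    tpl, s, type = "global-local", scoreOnly = TRUE,
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3, baseOnly = FALSE),
    gapOpening = 8, gapExtension = 1)
  sc(.TPL$trnaleu) + sc(.TPL$cox2)
}

# iterative Q-repeat detection by semi-global alignment with masking
.find_q_repeats <- function(mid, offset) {
  spans <- list()
  masked <- mid
  while (length(spans) < 5 && sum(strsplit(masked, "")[[1]] != "N") >= 150) {
    aln <- .pw_align(.TPL$q, masked)
    if (Biostrings::pid(aln) < .Q_MIN_PID) break
    s <- Biostrings::start(Biostrings::subject(aln))
    e <- Biostrings::end(Biostrings::subject(aln))
    spans[[length(spans) + 1]] <- c(offset + s - 1L, offset + e)
    substr(masked, s, e) <- strrep("N", e - s + 1)
  }
  spans[order(vapply(spans, `[`, integer(1), 1))]
}

# read the P form off the gap placement in a global alignment to P0
.p_form_from_region <- function(region) {
  aln <- .pw_align(.TPL$p0, region, type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  # deletion runs relative to P0 = gap runs in the aligned subject
  r <- rle(sub == "-")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  p0_pos <- cumsum(pat != "-")  # P0 coordinate of each alignment column
  big <- which(r$values & r$lengths >= 10)
  if (length(big) == 0) return("P0")
  if (length(big) > 1) {
    abort("ambiguous P form: more than one large deletion in the P element")
  }
  len <- r$lengths[big]
  del_start <- p0_pos[starts[big]]
  del_end <- p0_pos[ends[big]]
  if (del_start <= 3 && len >= 16 && len <= 20) return("P2")
  if (del_end >= 66 && len >= 13 && len <= 17) return("P1")
  if (len >= 11 && len <= 15) return("P")
  abort(sprintf(
    "ambiguous P form: %d bp deletion at P0 positions %d-%d matches no known form",
    len, del_start, del_end))
}

#' Classify the P-element form of a located amplicon
#'
#' Re-reads the form from the gap placement of the P-region alignment to the
#' P0 template: no gap >= 10 bp gives P0, an internal ~13 bp gap gives P, a
#' 3'-terminal ~15 bp gap gives P1 and a 5'-terminal ~18 bp gap gives P2
#' (+/- 2 bp tolerance).
#'
#' @param element_map an [locate_elements()] result.
#' @param sequence the amplicon the map refers to (defaults to the oriented
#'   sequence stored in the map).
#' @return `"P0"`, `"P"`, `"P1"`, `"P2"` or `"absent"`.
#' @export
classify_p_form <- function(element_map, sequence = element_map$sequence) {
  stopifnot(inherits(element_map, "element_map"))
  if (is.null(element_map$p_span)) return("absent")
  region <- substr(sequence, element_map$p_span[1] + 1, element_map$p_span[2])
  .p_form_from_region(region)
}

#' Assign the evolutionary lineage from the P-element form
#'
#' P0 or P1 gives the African A lineage; the P form (13 bp mid-deletion) the
#' Western European M lineage; the P2 form the Y lineage; an absent P element
#' the Eastern European C lineage. Total function, vectorised.
#'
#' @param p_form character vector of P forms.
#' @return character vector over `A`, `M`, `C`, `Y`.
#' @export
assign_lineage <- function(p_form) {
  stopifnot(all(p_form %in% .P_FORMS))
  unname(c(P0 = "A", P1 = "A", P = "M", P2 = "Y", absent = "C")[p_form])
}

#' Assign the African sub-lineage from P form and DraI site placement
#'
#' Diagnostic windows: the last 10 bp of the tRNAleu span plus 6 bp slack,
#' the first 15 bp of the first Q repeat, and the central third of the first
#' Q repeat. P1 amplicons are AIII regardless of DraI placement; P0 amplicons
#' are AI (tRNAleu and first-Q 5' sites), AII (tRNAleu site only) or Z (all
#' three windows). A P0 amplicon with no Q element is called AI when the
#' tRNAleu site is present and `NA` ("indeterminate sub-lineage", reported
#' but not fatal) otherwise. Non-A lineages return `"none"`.
#'
#' @param p_form the P-element form.
#' @param dra1_sites integer vector of 0-based TTTAAA start positions.
#' @param element_map the corresponding [locate_elements()] map.
#' @return one of `"AI"`, `"AII"`, `"AIII"`, `"Z"`, `"none"`, or `NA`.
#' @export
assign_sublineage <- function(p_form, dra1_sites, element_map) {
  if (assign_lineage(p_form) != "A") return("none")
  if (p_form == "P1") return("AIII")
  tr <- element_map$trnaleu_span
  in_win <- function(lo, hi) any(dra1_sites >= lo & dra1_sites < hi)
  has_trna <- in_win(tr[2] - 10, tr[2] + 6)
  if (length(element_map$q_spans) == 0) {
    return(if (has_trna) "AI" else NA_character_)
  }
  q1 <- element_map$q_spans[[1]]
  q_len <- q1[2] - q1[1]
  has_q5 <- in_win(q1[1], q1[1] + 15)
  has_qmid <- in_win(q1[1] + floor(q_len / 3), q1[1] + ceiling(2 * q_len / 3))
  if (!has_trna) return(NA_character_)
  if (has_q5 && has_qmid) return("Z")
  if (has_q5) return("AI")
  if (!has_qmid) return("AII")
  NA_character_
}

#' Length pattern of a located amplicon
#'
#' Concatenates the P-form token (`P0`, `P`, `P1`, `P2`, or nothing when the
#' element is absent) with one `Q` per tandem repeat, e.g. `"P0QQ"`.
#'
#' @param element_map an [locate_elements()] result.
#' @return pattern string.
#' @export
length_pattern <- function(element_map) {
  stopifnot(inherits(element_map, "element_map"))
  .length_pattern_of(element_map$p_form, length(element_map$q_spans))
}

#' In-silico DraI digestion
#'
#' Cuts between positions 3 and 4 of every TTTAAA occurrence (TTT^AAA) and
#' returns the fragment lengths 5' to 3'. Fragment lengths always sum to the
#' sequence length.
#'
#' @param sequence a single DNA string.
#' @return integer vector of fragment lengths.
#' @examples
#' insilico_dra1_digest("CCTTTAAACC")  # 5, 5
#' @export
insilico_dra1_digest <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) > 0)
  sequence <- str_to_upper(sequence)
  m <- gregexpr("TTTAAA", sequence, fixed = TRUE)[[1]]
  if (m[1] == -1) return(nchar(sequence))
  cuts <- as.integer(m) + 2L   # last base of each 5' fragment
  diff(c(0L, cuts, nchar(sequence)))
}

#' Call the haplotype name of a typed amplicon
#'
#' The sequence is compared with catalog members sharing its length pattern.
#' An exact match returns that name. Otherwise the closest reference is the
#' member with the minimum edit count (mismatches plus indel runs in a global
#' alignment; ties broken by catalog order), the edits are reported in
#' 1-based master-alignment coordinates, and a new name is coined as the
#' closest reference's family base plus the alphabetically first unused
#' letter suffix. If no catalog member shares the pattern the colony gets a
#' provisional `X<n>` name and is flagged for curation.
#'
#' @param sequence the amplicon sequence (oriented).
#' @param element_map its [locate_elements()] map.
#' @param catalog reference catalog.
#' @return list with `haplotype`, `novel`, `closest_reference`,
#'   `edits_vs_closest` (tibble `column`,`ref`,`alt`,`kind`), `note`.
#' @export
call_haplotype <- function(sequence, element_map,
                           catalog = load_reference_catalog()) {
  stopifnot(inherits(element_map, "element_map"))
  sequence <- element_map$sequence %||% str_to_upper(sequence)
  pattern <- length_pattern(element_map)
  rec <- catalog$records
  members <- rec[rec$pattern == pattern, ]
  if (nrow(members) == 0) {
    n_x <- length(grep("^X[0-9]+$", rec$name)) + 1L
    return(list(haplotype = paste0("X", n_x), novel = TRUE,
                closest_reference = NA_character_,
                edits_vs_closest = .edit_tbl(),
                note = "no catalog member shares this length pattern; flagged for curation"))
  }
  hit <- match(sequence, members$sequence)
  if (!is.na(hit)) {
    return(list(haplotype = members$name[hit], novel = FALSE,
                closest_reference = members$name[hit],
                edits_vs_closest = .edit_tbl(), note = NA_character_))
  }
  # closest reference by minimum edit count, catalog order breaks ties
  edit_sets <- vector("list", nrow(members))
  n_edits <- integer(nrow(members))
  for (i in seq_len(nrow(members))) {
    edit_sets[[i]] <- .edits_vs_reference(sequence, members$aligned[i])
    n_edits[i] <- nrow(edit_sets[[i]])
  }
  best <- which.min(n_edits)
  closest <- members$name[best]
  family <- members$family[best]
  used <- .family_suffixes(rec$name, family)
  free <- setdiff(letters, used)
  name <- if (length(free) > 0) paste0(family, free[1]) else paste0(family, "_new")
  list(haplotype = name, novel = TRUE, closest_reference = closest,
       edits_vs_closest = edit_sets[[best]], note = NA_character_)
}

.family_suffixes <- function(names, family) {
  hits <- names[startsWith(names, family)]
  suf <- substring(hits, nchar(family) + 1)
  suf[grepl("^[a-z]$", suf)]
}

# align a sample sequence to a reference's aligned master row and express the
# differences as master-column edits
.edits_vs_reference <- function(sequence, ref_aligned) {
  ref_chars <- strsplit(ref_aligned, "")[[1]]
  ref_cols <- which(ref_chars != "-")          # master column of each ref base
  ref_seq <- paste(ref_chars[ref_cols], collapse = "")
  aln <- .pw_align(ref_seq, sequence, type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_pos <- cumsum(pat != "-")
  edits <- list()
  add <- function(column, ref, alt, kind) {
    edits[[length(edits) + 1]] <<- tibble(column = as.integer(column),
                                          ref = ref, alt = alt, kind = kind)
  }
  i <- 1
  while (i <= length(pat)) {
    if (pat[i] != "-" && sub[i] != "-") {
      if (pat[i] != sub[i]) {
        add(ref_cols[ref_pos[i]], pat[i], sub[i], "substitution")
      }
      i <- i + 1
    } else if (sub[i] == "-") {
      j <- i; while (j < length(pat) && sub[j + 1] == "-") j <- j + 1
      add(ref_cols[ref_pos[i]],
          paste(pat[i:j], collapse = ""), "-", "deletion")
      i <- j + 1
    } else {
      j <- i; while (j < length(pat) && pat[j + 1] == "-") j <- j + 1
      # place the insertion on a master gap column between the flanking
      # reference columns when one exists (the reserved insertion columns)
      left <- if (ref_pos[i] >= 1) ref_cols[ref_pos[i]] else 0L
      right <- if (ref_pos[i] + 1 <= length(ref_cols)) ref_cols[ref_pos[i] + 1] else left + 2L
      gap_cols <- setdiff(seq(left + 1L, right - 1L), integer())
      col <- if (right - left > 1) left + 1L else left
      add(col, "-", paste(sub[i:j], collapse = ""), "insertion")
      i <- j + 1
    }
  }
  if (length(edits) == 0) .edit_tbl() else dplyr::bind_rows(edits)
}

#' Type a set of amplicon sequences
#'
#' The main tidy entry point of the classifier: locates elements, determines
#' the P form, lineage, sub-lineage and length pattern, and calls the
#' haplotype of every sequence.
#'
#' @param sequences tibble with columns `id` and `sequence` (e.g. from
#'   [read_fasta()] or [generate_population()]).
#' @param sample_sheet optional tibble `sample_id`, `site`, `region`.
#' @param catalog reference catalog.
#' @param call_haplotypes set `FALSE` to skip haplotype naming (faster when
#'   only lineage/pattern classification is needed).
#' @return tibble with one row per input sequence: `sample_id`, `site`,
#'   `region`, `lineage`, `sublineage`, `pattern`, `haplotype`, `novel`,
#'   `closest_reference`, `n_edits_vs_closest`, `note`, plus list-columns
#'   `element_map` and `edits`.
#' @export
type_sequences <- function(sequences, sample_sheet = NULL,
                           catalog = load_reference_catalog(),
                           call_haplotypes = TRUE) {
  stopifnot(all(c("id", "sequence") %in% names(sequences)))
  if (!is.null(sample_sheet)) sample_sheet <- validate_sample_sheet(sample_sheet)
  # identical amplicons (common in colony surveys) are typed once
  uniq <- unique(sequences$sequence)
  rows <- vector("list", length(uniq))
  for (k in seq_along(uniq)) {
    em <- locate_elements(uniq[k])
    lin <- assign_lineage(em$p_form)
    sub <- assign_sublineage(em$p_form, em$dra1_sites, em)
    note <- if (is.na(sub)) "indeterminate sub-lineage" else NA_character_
    pat <- length_pattern(em)
    if (call_haplotypes) {
      call <- call_haplotype(em$sequence, em, catalog)
      if (!is.na(call$note)) note <- call$note
    } else {
      call <- list(haplotype = NA_character_, novel = NA,
                   closest_reference = NA_character_,
                   edits_vs_closest = .edit_tbl())
    }
    rows[[k]] <- tibble(
      lineage = lin, sublineage = sub, pattern = pat,
      haplotype = call$haplotype, novel = call$novel,
      closest_reference = call$closest_reference,
      n_edits_vs_closest = nrow(call$edits_vs_closest),
      note = note,
      element_map = list(em), edits = list(call$edits_vs_closest))
  }
  out <- dplyr::bind_rows(rows)[match(sequences$sequence, uniq), ]
  out <- dplyr::mutate(out, sample_id = sequences$id, .before = 1)
  if (!is.null(sample_sheet)) {
    out <- dplyr::left_join(out, sample_sheet, by = "sample_id")
  } else {
    out$site <- NA_character_; out$region <- NA_character_
  }
  dplyr::relocate(out, "sample_id", "site", "region")
}
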