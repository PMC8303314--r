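# Character coding of the haplotype master alignment.
#
# Polymorphic columns of the P element, the first Q repeat, the second Q
# repeat and the cox2 fragment are retained as single-step characters (gap =
# fifth state, 1-bp indels included). Large architectural deletions are
# collapsed into binary indicator characters - one mutational step each - and
# the columns they remove become missing data for the affected taxa: the 13 bp
# mid-deletion of the P form, the 15 bp 3' deletion of the P1 form, absence of
# the whole P element (C lineage), absence of the Q element, and presence of a
# second Q repeat. The two diagnostic DraI restriction sites (tRNAleu 3' end,
# first-Q 5' end) are coded as dedicated binary characters. Large-deletion
# indicators and the two DraI characters are upweighted (default 10).

.char_state_matrix <- function(catalog, taxa) {
  aln <- catalog$alignment[taxa]
  do.call(rbind, strsplit(unname(aln), ""))
}

#' Encode the catalog alignment as a weighted character matrix
#'
#' @param catalog a `haplotype_catalog`.
#' @param include_outgroup add the synthetic outgroup row (missing at
#'   indicator-collapsed positions, Q-absence coded as one step).
#' @param include_bases keep the unobserved family bases (A4, M7).
#' @param drai_weight weight of the two diagnostic DraI characters.
#' @param indel_weight weight of the large-deletion indicator characters.
#' @return object of class `char_matrix`: list with `states` (taxa x
#'   characters matrix over A/C/G/T/-, `NA` = missing), `weights`,
#'   `provenance`, `character_id`, `taxa`.
#' @export
encode_characters <- function(catalog = load_reference_catalog(),
                              include_outgroup = FALSE,
                              include_bases = TRUE,
                              drai_weight = 10, indel_weight = 10) {
  rec <- catalog$records
  if (!include_bases) rec <- dplyr::filter(rec, .data$observed)
  taxa <- rec$name
  if (include_outgroup) taxa <- c(taxa, catalog$outgroup)
  M <- .char_state_matrix(catalog, taxa)
  if (anyNA(M)) abort("unaligned input: ragged catalog alignment")
  rownames(M) <- taxa
  n <- length(taxa)

  arch <- rec[c("name", "p_form", "n_q")]
  if (include_outgroup) {
    arch <- dplyr::bind_rows(arch, tibble(name = catalog$outgroup,
                                          p_form = "P0", n_q = 0L))
  }

  final_cols <- function(scaffold_cols) .scaffold_to_final(scaffold_cols)
  blk_cols <- function(b) final_cols(.BLK[[b]][1]:.BLK[[b]][2])

  # mask large-deletion regions as missing, record indicator states
  ind <- list(
    P_del13  = as.integer(arch$p_form == "P"),
    P1_del15 = as.integer(arch$p_form == "P1"),
    P_absent = as.integer(arch$p_form == "absent"),
    Q_absent = as.integer(arch$n_q == 0L),
    Q2_present = ifelse(arch$n_q == 0L, NA_integer_,
                        as.integer(arch$n_q >= 2L))
  )
  for (i in seq_len(n)) {
    pf <- arch$p_form[i]
    if (pf == "absent") M[i, blk_cols("p")] <- NA
    else if (pf != "P0") M[i, final_cols(.P_DEL[[pf]])] <- NA
    if (arch$n_q[i] == 0L) M[i, c(blk_cols("q1"), blk_cols("q2"))] <- NA
    if (arch$n_q[i] == 1L) M[i, blk_cols("q2")] <- NA
  }
  # insertion columns: for taxa lacking the enclosing element they are missing
  ins_blocks <- vapply(.INS_COLS, function(f) {
    s_left <- .final_to_scaffold(f - 1L)
    names(.BLK)[vapply(.BLK, function(b) s_left >= b[1] && s_left <= b[2], logical(1))][1]
  }, character(1))
  for (j in seq_along(.INS_COLS)) {
    b <- ins_blocks[j]
    gone <- if (b %in% c("q1", "q2")) arch$n_q < (if (b == "q1") 1L else 2L)
            else rep(FALSE, n)
    M[gone, .INS_COLS[j]] <- NA
  }

  # DraI diagnostic characters, read off the motif windows
  dra_state <- function(scols) {
    apply(M[, final_cols(scols), drop = FALSE], 1, function(x) {
      if (anyNA(x)) NA_integer_ else as.integer(paste(x, collapse = "") == .DRA_MOTIF)
    })
  }
  dra_trna <- dra_state(.DRA_POS$trnaleu)
  dra_q5 <- dra_state(.DRA_POS$q5)
  if (include_outgroup) {
    # the outgroup is scored missing for the honey-bee-specific diagnostics
    dra_trna[n] <- NA_integer_; dra_q5[n] <- NA_integer_
    for (nm in c("P_del13", "P1_del15", "P_absent")) ind[[nm]][n] <- NA_integer_
    ind$Q2_present[n] <- NA_integer_
  }

  # ordinary columns: P, Q1, Q2, cox2 blocks plus reserved insertion columns,
  # excluding the DraI motif windows (represented by the binary characters)
  region_cols <- sort(c(blk_cols("p"), blk_cols("q1"), blk_cols("q2"),
                        blk_cols("cox2"), .INS_COLS))
  drai_cols <- final_cols(c(.DRA_POS$trnaleu, .DRA_POS$q5, .DRA_POS$qmid))
  region_cols <- setdiff(region_cols, drai_cols)
  block_of <- function(f) {
    if (f %in% .INS_COLS) f <- f - 1L
    s <- .final_to_scaffold(f)
    names(.BLK)[vapply(.BLK, function(b) s >= b[1] && s <= b[2], logical(1))][1]
  }
  poly <- vapply(region_cols, function(cc) {
    st <- unique(M[, cc]); st <- st[!is.na(st)]; length(st) >= 2
  }, logical(1))
  ord_cols <- region_cols[poly]

  states <- cbind(
    M[, ord_cols, drop = FALSE],
    matrix(as.character(do.call(cbind, ind)), nrow = n),
    dra_trnaleu = as.character(dra_trna),
    dra_first_q5 = as.character(dra_q5))
  colnames(states) <- c(paste0("col", ord_cols, recycle0 = TRUE), names(ind),
                        "dra_trnaleu", "dra_first_q5")
  provenance <- c(vapply(ord_cols, block_of, character(1)),
                  rep("indicator", length(ind)), "drai", "drai")
  weights <- c(rep(1L, length(ord_cols)),
               rep(indel_weight, 3L),  # the three large-deletion indicators
               1L, 1L,                 # Q absence, second-Q presence
               rep(drai_weight, 2L))

  # drop constant indicator / DraI characters (nothing to code)
  keep <- apply(states, 2, function(x) length(unique(x[!is.na(x)])) >= 2)
  structure(list(states = states[, keep, drop = FALSE],
                 weights = as.integer(weights[keep]),
                 provenance = provenance[keep],
                 character_id = colnames(states)[keep],
                 taxa = taxa),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("<char_matrix> ", length(x$taxa), " taxa x ", ncol(x$states),
      " characters (", sum(x$weights > 1), " upweighted)\n", sep = "")
  print(table(x$provenance))
  invisible(x)
}

#' Weighted mutational-step distance between two taxa
#'
#' Weighted count of differing characters; character pairs with a missing
#' state are skipped. Symmetric, and zero iff the taxa agree on every
#' mutually non-missing character.
#'
#' @param matrix a `char_matrix`.
#' @param taxon_a,taxon_b taxon names.
#' @return non-negative number of mutational steps.
#' @export
step_distance <- function(matrix, taxon_a, taxon_b) {
  for (t in c(taxon_a, taxon_b)) {
    if (!t %in% matrix$taxa) abort(sprintf("unknown taxon: %s", t))
  }
  a <- matrix$states[match(taxon_a, matrix$taxa), ]
  b <- matrix$states[match(taxon_b, matrix$taxa), ]
  ok <- !is.na(a) & !is.na(b)
  sum(matrix$weights[ok] * (a[ok] != b[ok]))
}

#' Pairwise step-distance matrix of a character matrix
#'
#' @param matrix a `char_matrix`.
#' @param weights optional replacement weight vector (used by the bootstrap).
#' @return symmetric numeric matrix with taxon dimnames.
#' @export
step_distance_matrix <- function(matrix, weights = matrix$weights) {
  S <- matrix$states
  n <- nrow(S)
  D <- base::matrix(0, n, n, dimnames = list(matrix$taxa, matrix$taxa))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(S[i, ]) & !is.na(S[j, ])
    D[i, j] <- D[j, i] <- sum(weights[ok] * (S[i, ok] != S[j, ok]))
  }
  D
}

#' Dump a character matrix as a tibble
#'
#' One row per character with its states per taxon, weight and provenance;
#' handy for writing an inspectable TSV.
#'
#' @param x a `char_matrix`.
#' @param ... unused.
#' @return tibble.
#' @export
tidy.char_matrix <- function(x, ...) {
  out <- tibble(character_id = x$character_id,
                provenance = x$provenance,
                weight = x$weights)
  st <- t(x$states)
  colnames(st) <- x$taxa
  dplyr::bind_cols(out, as_tibble(st))
}
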