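cat_ <- load_reference_catalog()

test_that("element location recovers the generated architecture exhaustively", {
  for (pf in c("P0", "P", "P1", "P2", "absent")) {
    for (nq in 0:5) {
      tmpls <- switch(pf, P0 = c("AI", "AII", "Z", "none"),
                      P1 = c("AIII", "none"), "none")
      for (tm in tmpls) {
        em <- locate_elements(build_amplicon(pf, nq, tm))
        expect_equal(em$p_form, pf, label = paste("p_form", pf, nq, tm))
        expect_equal(length(em$q_spans), nq, label = paste("n_q", pf, nq, tm))
        expect_equal(is.null(em$p_span), pf == "absent")
        # spans ordered and non-overlapping
        spans <- c(list(em$trnaleu_span), if (!is.null(em$p_span)) list(em$p_span),
                   em$q_spans, list(em$cox2_span))
        starts <- vapply(spans, `[`, numeric(1), 1)
        ends <- vapply(spans, `[`, numeric(1), 2)
        expect_true(all(ends[-length(ends)] <= starts[-1]))
      }
    }
  }
})

test_that("P-form classification reads the gap placement with tolerance", {
  for (pf in c("P0", "P", "P1", "P2")) {
    em <- locate_elements(build_amplicon(pf, 1))
    expect_equal(classify_p_form(em), pf)
  }
  em_c <- locate_elements(build_amplicon("absent", 1))
  expect_equal(classify_p_form(em_c), "absent")
})

test_that("lineage assignment is total over the P forms", {
  expect_equal(assign_lineage(c("P0", "P1", "P", "P2", "absent")),
               c("A", "A", "M", "Y", "C"))
  expect_error(assign_lineage("P9"))
})

test_that("sub-lineage diagnosis follows the DraI windows", {
  cases <- list(list("P0", "AI", "AI"), list("P0", "AII", "AII"),
                list("P0", "Z", "Z"), list("P1", "AIII", "AIII"))
  for (cs in cases) {
    em <- locate_elements(build_amplicon(cs[[1]], 2, cs[[2]]))
    expect_equal(assign_sublineage(em$p_form, em$dra1_sites, em), cs[[3]],
                 label = paste(cs[[1]], cs[[2]]))
  }
  # P1 is AIII regardless of planted sites
  em <- locate_elements(build_amplicon("P1", 2, "none"))
  expect_equal(assign_sublineage(em$p_form, em$dra1_sites, em), "AIII")
  # no Q element: AI on the tRNAleu site alone, indeterminate without it
  em_a65 <- locate_elements(build_amplicon("P0", 0, "AI"))
  expect_equal(assign_sublineage(em_a65$p_form, em_a65$dra1_sites, em_a65), "AI")
  em_na <- locate_elements(build_amplicon("P0", 0, "none"))
  expect_true(is.na(assign_sublineage(em_na$p_form, em_na$dra1_sites, em_na)))
  # non-A lineages are "none"
  em_c <- locate_elements(build_amplicon("absent", 1))
  expect_equal(assign_sublineage(em_c$p_form, em_c$dra1_sites, em_c), "none")
})

test_that("length patterns concatenate the P token and Q repeats", {
  expect_equal(length_pattern(locate_elements(build_amplicon("P0", 2, "AI"))), "P0QQ")
  expect_equal(length_pattern(locate_elements(build_amplicon("absent", 1))), "Q")
  expect_equal(length_pattern(locate_elements(build_amplicon("P0", 0, "AI"))), "P0")
  expect_equal(length_pattern(locate_elements(build_amplicon("P", 2))), "PQQ")
})

test_that("the classifier recovers truth labels on all catalog haplotypes", {
  obs <- dplyr::filter(cat_$records, observed)
  ty <- type_sequences(tibble::tibble(id = obs$name, sequence = obs$sequence))
  expect_equal(ty$haplotype, obs$name)
  expect_equal(ty$lineage, obs$lineage)
  expect_equal(ty$sublineage, obs$sublineage)
  expect_equal(ty$pattern, obs$pattern)
  expect_true(all(!ty$novel))
  expect_true(all(ty$n_edits_vs_closest == 0))
})

test_that("novel variants get the closest reference and a coined name", {
  reduced <- cat_
  reduced$records <- dplyr::filter(cat_$records, name != "A1t")
  a1t_seq <- cat_$records$sequence[cat_$records$name == "A1t"]
  em <- locate_elements(a1t_seq)
  call <- call_haplotype(a1t_seq, em, reduced)
  expect_true(call$novel)
  expect_equal(call$closest_reference, "A1")
  expect_equal(nrow(call$edits_vs_closest), 3)
  # letters e,t,u,w are taken in the A1 family, so the first unused is "a"
  expect_equal(call$haplotype, "A1a")
  expect_setequal(call$edits_vs_closest$column, c(99, 139, 646))

  # calling is idempotent: the named sequence keeps its name
  again <- call_haplotype(a1t_seq, em, cat_)
  expect_equal(again$haplotype, "A1t")
  expect_false(again$novel)
})

test_that("an amplicon with an unknown pattern is flagged for curation", {
  s <- build_amplicon("P2", 3)   # Y lineage, not in the catalog
  em <- locate_elements(s)
  call <- call_haplotype(s, em, cat_)
  expect_match(call$haplotype, "^X[0-9]+$")
  expect_match(call$note, "curation")
})

test_that("unrecognizable input fails loudly rather than guessing", {
  junk <- strrep("ACGT", 60)
  expect_error(locate_elements(junk), "unrecognized amplicon")
  expect_error(locate_elements("ACGT"), "too short")
})

test_that("reverse-complemented amplicons are auto-detected and typed", {
  s <- build_amplicon("P0", 2, "AI")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  em <- locate_elements(rc)
  expect_true(em$reversed)
  expect_equal(em$p_form, "P0")
  expect_equal(length(em$q_spans), 2)
})

test_that("DraI digestion conserves length and cuts TTT^AAA", {
  expect_equal(insilico_dra1_digest("AAAA"), 4L)
  expect_equal(insilico_dra1_digest("CCTTTAAACC"), c(5L, 5L))
  set.seed(404)
  for (r in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    if (r %% 3 == 0) s <- paste0(substr(s, 1, 100), "TTTAAA", substr(s, 101, 300))
    frags <- insilico_dra1_digest(s)
    expect_equal(sum(frags), nchar(s))
    n_sites <- length(gregexpr("TTTAAA", s, fixed = TRUE)[[1]])
    if (!grepl("TTTAAA", s, fixed = TRUE)) n_sites <- 0
    expect_equal(length(frags), n_sites + 1)
  }
  # generated AI amplicon: two sites, three fragments
  frags <- insilico_dra1_digest(build_amplicon("P0", 2, "AI"))
  expect_equal(length(frags), 3)
  expect_equal(sum(frags), amplicon_length("P0", 2))
})
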