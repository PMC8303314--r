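cat_ <- load_reference_catalog()
cm <- encode_characters(cat_)

test_that("published variant pairs separate by the documented steps", {
  expect_equal(step_distance(cm, "A1", "A1t"), 3)  # 99, 139, 646
  expect_equal(step_distance(cm, "M7b", "M7c"), 1) # 148 only
  expect_equal(step_distance(cm, "A30", "A30d"), 1)
  expect_equal(step_distance(cm, "A4p", "A4q"), 1)
  expect_equal(step_distance(cm, "A1", "A1"), 0)
  expect_error(step_distance(cm, "A1", "nope"), "unknown taxon")
})

test_that("two identical taxa yield no polymorphic characters", {
  sub <- cat_
  sub$records <- cat_$records[cat_$records$name %in% c("A4", "A4"), ]
  # duplicate one row under a second name
  r2 <- sub$records; r2$name <- "A4bis"
  sub$records <- dplyr::bind_rows(sub$records, r2)
  sub$alignment <- c(sub$alignment, setNames(sub$alignment["A4"], "A4bis"))
  m <- encode_characters(sub)
  expect_equal(step_distance(m, "A4", "A4bis"), 0)
  ordinary <- m$provenance %in% c("p", "q1", "q2", "cox2")
  expect_equal(sum(ordinary), 0)
})

test_that("column accounting: no polymorphic column is silently lost", {
  # every edit column of every record appears among the characters, except
  # those inside architecture regions collapsed into indicators
  ids <- cm$character_id
  for (i in seq_len(nrow(cat_$records))) {
    ed <- cat_$records$edits[[i]]
    if (nrow(ed) == 0) next
    expect_true(all(paste0("col", ed$column) %in% ids),
                label = paste("columns of", cat_$records$name[i]))
  }
  # the large deletions and the two DraI diagnostics are upweighted
  w10 <- cm$character_id[cm$weights == 10]
  expect_setequal(w10, c("P_del13", "P1_del15", "P_absent",
                         "dra_trnaleu", "dra_first_q5"))
  # indicators carry one step each for Q-architecture differences
  expect_true(all(c("Q_absent", "Q2_present") %in% ids))
})

test_that("encoding is idempotent and weight-stable", {
  cm2 <- encode_characters(cat_)
  expect_identical(cm$states, cm2$states)
  expect_identical(cm$weights, cm2$weights)
  cm5 <- encode_characters(cat_, drai_weight = 5, indel_weight = 7)
  expect_equal(sort(unique(cm5$weights)), c(1, 5, 7))
})

test_that("step distances are symmetric; triangle inequality holds away from
           whole-element missingness", {
  D <- step_distance_matrix(cm)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  # A65 lacks the whole Q element; skipping its missing characters deflates
  # its distances, the one documented exception to the triangle inequality
  keep <- setdiff(cm$taxa, "A65")
  Dk <- D[keep, keep]
  n <- nrow(Dk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    expect_true(all(Dk[i, j] <= Dk[i, ] + Dk[, j] + 1e-9))
  }
})

test_that("the outgroup is scored missing at honey-bee-specific diagnostics", {
  cmo <- encode_characters(cat_, include_outgroup = TRUE)
  og <- match(cat_$outgroup, cmo$taxa)
  for (ch in c("dra_trnaleu", "dra_first_q5", "P_del13", "P_absent")) {
    j <- match(ch, cmo$character_id)
    if (!is.na(j)) expect_true(is.na(cmo$states[og, j]), label = ch)
  }
  j <- match("Q_absent", cmo$character_id)
  expect_equal(cmo$states[og, j], "1")  # Q absence = one mutational step
})

test_that("the character dump is a complete tidy table", {
  dump <- tidy(cm)
  expect_equal(nrow(dump), ncol(cm$states))
  expect_true(all(cm$taxa %in% names(dump)))
})
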