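test_that("amplicon length is an exact function of the architecture", {
  for (pf in c("P0", "P", "P1", "P2", "absent")) {
    for (nq in 0:5) {
      tmpl <- if (pf %in% c("P0", "P1")) "AI" else "none"
      expect_equal(nchar(build_amplicon(pf, nq, tmpl)),
                   amplicon_length(pf, nq),
                   label = paste(pf, nq))
    }
  }
  # the four P forms have pairwise distinct lengths
  lens <- vapply(c("P0", "P", "P1", "P2"), function(pf)
    nchar(build_amplicon(pf, 1)), integer(1))
  expect_equal(anyDuplicated(lens), 0L)
})

test_that("DraI sites appear exactly where the sub-lineage template plants them", {
  hits <- function(s) as.integer(gregexpr("TTTAAA", s, fixed = TRUE)[[1]])
  ai <- build_amplicon("P0", 2, "AI")
  expect_equal(length(hits(ai)), 2)
  expect_true(hits(ai)[1] <= 40)                    # tRNAleu 3' end
  expect_true(hits(ai)[2] > 108 && hits(ai)[2] < 130)  # first-Q 5' end
  expect_equal(length(hits(build_amplicon("P0", 2, "AII"))), 1)
  expect_equal(length(hits(build_amplicon("P0", 2, "Z"))), 3)
  expect_equal(hits(build_amplicon("absent", 1, "none"))[1], -1L)
  expect_equal(length(hits(build_amplicon("P0", 0, "AI"))), 1)  # no Q to plant in
  # second Q copies never carry a planted site
  zz <- build_amplicon("P0", 5, "Z")
  expect_equal(length(hits(zz)), 3)
})

test_that("invalid architectures and edits are rejected", {
  expect_error(build_amplicon("P0", 6), "between 0 and 5")
  expect_error(build_amplicon("P", 2, "AI"), "P0 or P1")
  bad_edit <- tibble::tibble(column = 9999L, ref = "A", alt = "T",
                             kind = "substitution")
  expect_error(build_amplicon("P0", 2, "AI", bad_edit), "outside")
})

test_that("population generation is exact, labeled, and seed-deterministic", {
  cfg <- population_config(
    sites = tibble::tibble(site = "S1", region = "R", n = 10),
    frequencies = tibble::tibble(site = "S1", haplotype = "A4p", p = 1),
    seed = 7)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop$sequences), 10)
  expect_true(all(pop$truth$haplotype == "A4p"))
  expect_true(all(pop$truth$pattern == "P0QQ"))
  expect_equal(length(unique(pop$sequences$sequence)), 1)

  expect_identical(generate_population(cfg), pop)  # same seed, same bytes

  bad <- population_config(
    sites = tibble::tibble(site = "S1", region = "R", n = 5),
    frequencies = tibble::tibble(site = "S1", haplotype = "NOPE", p = 1),
    seed = 1)
  expect_error(generate_population(bad), "unknown haplotype")

  expect_error(population_config(
    sites = tibble::tibble(site = "S1", region = "R", n = 5),
    frequencies = tibble::tibble(site = "S1", haplotype = "A1", p = 0.7),
    seed = 1), "sum to 1")
})

test_that("multinomial sampling recovers configured frequencies", {
  p_cfg <- c(A4p = 0.5, C1 = 0.3, M7b = 0.2)
  cfg <- population_config(
    sites = tibble::tibble(site = "big", region = "R", n = 2000),
    frequencies = tibble::tibble(site = "big", haplotype = names(p_cfg),
                                 p = unname(p_cfg)),
    seed = 31)
  pop <- generate_population(cfg)
  obs <- table(pop$truth$haplotype)[names(p_cfg)] / 2000
  se <- sqrt(p_cfg * (1 - p_cfg) / 2000)
  expect_true(all(abs(obs - p_cfg) < 3 * se))
})

test_that("substitution noise respects rate, protections and identity at zero", {
  pop <- generate_population(small_population())
  same <- add_noise(pop, 0, seed = 9)
  expect_identical(same$sequences$sequence, pop$sequences$sequence)
  expect_true(all(same$sequences$n_substitutions == 0))

  noisy <- add_noise(pop, 0.01, seed = 9)
  n_total <- sum(noisy$sequences$n_substitutions)
  n_bases <- sum(nchar(pop$sequences$sequence))
  # binomial mean with 3-sigma slack (protected sites reduce the rate a bit)
  expect_gt(n_total, 0.005 * n_bases - 3 * sqrt(0.01 * n_bases))
  expect_lt(n_total, 0.01 * n_bases + 3 * sqrt(0.01 * n_bases))
  # DraI motifs survive
  for (i in seq_len(nrow(noisy$sequences))) {
    clean_hits <- gregexpr("TTTAAA", pop$sequences$sequence[i], fixed = TRUE)[[1]]
    noisy_hits <- gregexpr("TTTAAA", noisy$sequences$sequence[i], fixed = TRUE)[[1]]
    expect_true(all(clean_hits %in% noisy_hits))
  }
  expect_error(add_noise(pop, 0.5, seed = 1), "0, 0.02")
})
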