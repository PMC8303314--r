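test_that("the printed diversity table satisfies the uh identity row by row", {
  ref <- reference_site_diversity()
  expect_equal(nrow(ref), 15)
  uh <- uh_from_ne(ref$N, ref$Ne)
  expect_true(all(abs(uh - ref$uh) <= 0.001))
})

test_that("diversity summaries follow the haplotype-frequency definitions", {
  # monomorphic site
  mono <- tibble::tibble(site = "m", haplotype = rep("A1", 12))
  s <- diversity_summary(mono)
  expect_equal(s$Na, 1); expect_equal(s$Ne, 1); expect_equal(s$uh, 0)

  # worked example: N = 42, composition giving Ne near the printed 1.215
  counts <- tibble::tibble(site = "b", haplotype = c("h1", "h2", "h3"),
                           count = c(38, 3, 1))
  s2 <- diversity_summary(counts)
  expect_equal(s2$N, 42)
  expect_equal(s2$uh, uh_from_ne(42, s2$Ne))

  # bounds and private-haplotype accounting on random tables
  set.seed(77)
  for (r in 1:20) {
    tbl <- tibble::tibble(
      site = sample(paste0("s", 1:4), 60, replace = TRUE),
      haplotype = sample(paste0("h", 1:6), 60, replace = TRUE))
    out <- diversity_summary(tbl)
    expect_true(all(out$Ne >= 1 - 1e-12))
    expect_true(all(out$Ne <= out$Na + 1e-12))
    expect_true(all(out$Na <= out$N))
    expect_true(all(out$uh >= 0 & out$uh <= 1))
    expect_true(all(out$Np <= out$Na))
    expect_lte(sum(out$Np), dplyr::n_distinct(tbl$haplotype))
  }

  # single-colony site: uh undefined
  one <- diversity_summary(tibble::tibble(site = c("a", "a", "b"),
                                          haplotype = c("x", "y", "x")))
  expect_true(is.na(one$uh[one$site == "b"]))
})

test_that("PhiPT hits its endpoints and matches a brute-force oracle", {
  # identical compositions: raw PhiPT <= 0, reported 0
  d1 <- tibble::tibble(site = rep(c("a", "b"), each = 10),
                       lab = rep(c("x", "y"), 10))
  p1 <- phi_pt(d1, lab, n_permutations = 0, pairwise = FALSE)
  expect_lte(p1$overall$phi_raw, 0)
  expect_equal(p1$overall$phi, 0)

  # fixed difference: PhiPT = 1, significant
  d2 <- tibble::tibble(site = rep(c("a", "b"), each = 10),
                       lab = rep(c("x", "y"), each = 10))
  p2 <- phi_pt(d2, lab, n_permutations = 199, seed = 3, pairwise = FALSE)
  expect_equal(p2$overall$phi, 1)
  expect_lt(p2$overall$p_value, 0.05)

  # brute-force variance components on small instances (naive double loop)
  set.seed(42)
  for (r in 1:25) {
    n <- sample(6:12, 1); k <- sample(2:3, 1)
    g <- sample(rep(1:k, length.out = n))
    h <- sample(1:3, n, replace = TRUE)
    D <- outer(h, h, function(a, b) as.numeric(a != b))
    ssd_t <- sum(D[upper.tri(D)]) / n
    ssd_w <- 0
    for (gg in unique(g)) {
      idx <- which(g == gg)
      Dg <- D[idx, idx, drop = FALSE]
      ssd_w <- ssd_w + sum(Dg[upper.tri(Dg)]) / length(idx)
    }
    ms_w <- ssd_w / (n - k); ms_a <- (ssd_t - ssd_w) / (k - 1)
    n0 <- (n - sum(table(g)^2) / n) / (k - 1)
    s_a <- (ms_a - ms_w) / n0
    phi_naive <- if (s_a + ms_w <= 0) 0 else s_a / (s_a + ms_w)
    df <- tibble::tibble(site = paste0("s", g), lab = paste0("h", h))
    got <- phi_pt(df, lab, n_permutations = 0, pairwise = FALSE)
    expect_equal(got$overall$phi_raw, phi_naive, tolerance = 1e-12)
  }
})

test_that("single-colony sites are excluded with a warning", {
  d <- tibble::tibble(site = c("a", "a", "a", "b", "b", "c"),
                      lab = c("x", "x", "y", "y", "x", "x"))
  expect_warning(p <- phi_pt(d, lab, n_permutations = 0, pairwise = FALSE),
                 "fewer than 2")
  expect_setequal(p$sites, c("a", "b"))
})

test_that("pairwise PhiPT matrices are tidy-accessible", {
  d <- tibble::tibble(site = rep(c("a", "b", "c"), each = 6),
                      lab = c(rep("x", 6), rep("y", 6), rep(c("x", "y"), 3)))
  p <- phi_pt(d, lab, n_permutations = 49, seed = 11)
  expect_equal(nrow(tidy(p)), 3)
  expect_true(isSymmetric(p$matrix))
  expect_true(all(p$matrix >= 0 & p$matrix <= 1))
  g <- glance(p)
  expect_equal(g$n_sites, 3)
})

test_that("PCoA reconstructs planted geometry and orders axes", {
  set.seed(1)
  X <- matrix(rnorm(10), 5, 2)
  D <- as.matrix(stats::dist(X))
  ord <- pcoa(D)
  expect_lt(max(abs(as.matrix(stats::dist(ord$points[, 1:2])) - D)), 1e-9)
  expect_equal(sum(ord$percent), 100)
  expect_true(all(diff(ord$percent) <= 1e-9))
  # cross-check against classical MDS
  cmd <- stats::cmdscale(D, k = 2, eig = TRUE)
  expect_equal(abs(ord$points[, 1:2]), abs(cmd$points), tolerance = 1e-8,
               ignore_attr = TRUE)

  # all-zero matrix: no axes
  z <- pcoa(matrix(0, 3, 3))
  expect_equal(ncol(z$points), 0)

  # an outlier site loads axis 1 above axis 2
  m <- matrix(c(0, 1, 9, 1, 0, 9, 9, 9, 0), 3, 3)
  o <- pcoa(m)
  expect_gt(o$percent[1], o$percent[2])

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})
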