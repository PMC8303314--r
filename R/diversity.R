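# Per-site diversity parameters, AMOVA-based PhiPT and PCoA.
#
# Na, Ne, Np and uh follow the single-locus haplotype-frequency definitions
# used by population-genetics spreadsheet tools: Na = number of distinct
# haplotypes, Ne = 1 / sum(p_i^2), uh = (N/(N-1)) (1 - sum(p_i^2)), Np =
# haplotypes private to the site. Values are kept raw; rounding to 3 decimals
# happens only at the report layer.

#' Per-site diversity summary
#'
#' @param data per-colony tibble with columns `site` and `haplotype`
#'   (e.g. a typing table), or a pre-counted table with `site`, `haplotype`,
#'   `count`.
#' @return tibble with one row per site: `site`, `N`, `Na`, `Np`, `Ne`, `uh`.
#'   `uh` is `NA` for sites with fewer than two colonies.
#' @examples
#' counts <- study_population_counts()
#' diversity_summary(counts)
#' @export
diversity_summary <- function(data) {
  stopifnot(all(c("site", "haplotype") %in% names(data)))
  counts <- if ("count" %in% names(data)) {
    dplyr::summarise(data, count = sum(.data$count),
                     .by = c("site", "haplotype"))
  } else {
    dplyr::count(data, .data$site, .data$haplotype, name = "count")
  }
  counts <- dplyr::filter(counts, .data$count > 0)
  n_sites_of <- counts |>
    dplyr::summarise(n_sites = dplyr::n_distinct(.data$site),
                     .by = "haplotype")
  counts |>
    dplyr::left_join(n_sites_of, by = "haplotype") |>
    dplyr::summarise(
      N = sum(.data$count),
      Na = dplyr::n_distinct(.data$haplotype),
      Np = sum(.data$n_sites == 1),
      sum_p2 = sum((.data$count / sum(.data$count))^2),
      .by = "site") |>
    dplyr::mutate(
      Ne = 1 / .data$sum_p2,
      uh = ifelse(.data$N >= 2,
                  .data$N / (.data$N - 1) * (1 - .data$sum_p2), NA_real_)) |>
    dplyr::select("site", "N", "Na", "Np", "Ne", "uh")
}

#' Unbiased haplotype diversity from N and Ne
#'
#' The algebraic identity `uh = (N/(N-1)) (1 - 1/Ne)`, useful for checking
#' printed diversity tables where only N and Ne are reported alongside uh.
#'
#' @param N number of individuals.
#' @param Ne effective number of haplotypes.
#' @return unbiased diversity value(s).
#' @export
uh_from_ne <- function(N, Ne) N / (N - 1) * (1 - 1 / Ne)

# ---- PhiPT (AMOVA on categorical labels, binary distance) -----------------

# fast variance components for categorical labels: with a 0/1 metric the
# squared-distance sums reduce to label counts. g, h are integer vectors
# (group, label); returns c(phi_raw, sigma_among, sigma_within)
.phi_components <- function(g, h, k, H) {
  N <- length(g)
  n_g <- tabulate(g, k)
  cnt <- matrix(tabulate((h - 1L) * k + g, k * H), k, H)
  tot <- colSums(cnt)
  ssd_total <- (N^2 - sum(tot^2)) / 2 / N
  within_pairs <- (n_g^2 - rowSums(cnt^2)) / 2
  ssd_within <- sum(within_pairs / n_g)
  ssd_among <- ssd_total - ssd_within
  ms_within <- ssd_within / (N - k)
  ms_among <- ssd_among / (k - 1)
  n0 <- (N - sum(n_g^2) / N) / (k - 1)
  sigma_among <- (ms_among - ms_within) / n0
  denom <- sigma_among + ms_within
  phi <- if (denom <= 0) 0 else sigma_among / denom
  c(phi = phi, sigma_among = sigma_among, sigma_within = ms_within)
}

#' AMOVA-based PhiPT differentiation among sampling sites
#'
#' Analysis of molecular variance on colony-level categorical labels
#' (lineage, sub-lineage or haplotype) with the binary metric d(i,j) = 0 if
#' the labels agree and 1 otherwise. PhiPT is the among-site fraction of the
#' total variance; significance is assessed by permuting colonies among sites.
#' Negative estimates are reported as 0 (conventional) with the raw value
#' kept. Sites with fewer than two colonies are excluded with a warning.
#'
#' @param data per-colony tibble.
#' @param label column (tidy-select) holding the categorical label.
#' @param site column holding the site; defaults to `site`.
#' @param n_permutations permutations for the p-value (default 999); 0 skips
#'   the test.
#' @param seed integer seed, mandatory when permuting.
#' @param pairwise also compute the site-by-site PhiPT matrix (each pair
#'   tested with the same number of permutations).
#' @return object of class `phi_pt`: list with `overall` (phi, raw phi,
#'   variance components, p-value), `pairwise` tibble, `matrix` (clamped
#'   pairwise PhiPT), `sites`, `n_permutations`.
#' @export
phi_pt <- function(data, label, site = "site", n_permutations = 999,
                   seed = NULL, pairwise = TRUE) {
  lab_col <- dplyr::pull(data, {{ label }})
  site_v <- dplyr::pull(data, {{ site }})
  keep <- !is.na(lab_col) & !is.na(site_v)
  lab_col <- lab_col[keep]; site_v <- site_v[keep]
  sizes <- table(site_v)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(sprintf("excluding %d site(s) with fewer than 2 colonies: %s",
                 length(small), paste(small, collapse = ", ")))
    keep <- !site_v %in% small
    lab_col <- lab_col[keep]; site_v <- site_v[keep]
  }
  sites <- sort(unique(site_v))
  if (length(sites) < 2) abort("PhiPT needs at least two sites with >= 2 colonies")
  if (n_permutations > 0 && is.null(seed)) abort("`seed` is mandatory when permuting")

  g <- match(site_v, sites)
  labs <- sort(unique(lab_col))
  h <- match(lab_col, labs)

  run <- function(g, h, k) {
    comp <- .phi_components(g, h, k, length(labs))
    p <- NA_real_
    if (n_permutations > 0) {
      hits <- 0L
      for (b in seq_len(n_permutations)) {
        comp_b <- .phi_components(g, sample(h), k, length(labs))
        if (comp_b[1] >= comp[1] - 1e-12) hits <- hits + 1L
      }
      p <- (hits + 1) / (n_permutations + 1)
    }
    list(comp = comp, p = p)
  }

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  if (!is.null(seed)) set.seed(seed)
  overall_run <- run(g, h, length(sites))
  overall <- list(
    phi_raw = unname(overall_run$comp[1]),
    phi = max(0, unname(overall_run$comp[1])),
    sigma_among = unname(overall_run$comp[2]),
    sigma_within = unname(overall_run$comp[3]),
    p_value = overall_run$p)

  pair_tbl <- NULL; mat <- NULL
  if (pairwise && length(sites) >= 2) {
    pairs <- utils::combn(seq_along(sites), 2)
    res <- vector("list", ncol(pairs))
    mat <- matrix(0, length(sites), length(sites),
                  dimnames = list(sites, sites))
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      sel <- g %in% c(a, b)
      gg <- match(g[sel], c(a, b))
      rr <- run(gg, h[sel], 2L)
      res[[j]] <- tibble(site1 = sites[a], site2 = sites[b],
                         phi_raw = unname(rr$comp[1]),
                         phi = max(0, unname(rr$comp[1])),
                         p_value = rr$p)
      mat[a, b] <- mat[b, a] <- res[[j]]$phi
    }
    pair_tbl <- dplyr::bind_rows(res)
  }

  structure(list(overall = overall, pairwise = pair_tbl, matrix = mat,
                 sites = sites, n_permutations = n_permutations,
                 labels = labs),
            class = "phi_pt")
}

#' @export
print.phi_pt <- function(x, ...) {
  cat("<phi_pt> ", length(x$sites), " sites, PhiPT = ",
      format(x$overall$phi, digits = 4), sep = "")
  if (!is.na(x$overall$p_value)) {
    cat(" (p = ", format(x$overall$p_value, digits = 3), ", ",
        x$n_permutations, " permutations)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @rdname phi_pt
#' @param x a `phi_pt` object.
#' @param ... unused.
#' @export
tidy.phi_pt <- function(x, ...) {
  if (is.null(x$pairwise)) {
    abort("no pairwise results: rerun phi_pt() with pairwise = TRUE")
  }
  x$pairwise
}

#' @rdname phi_pt
#' @export
glance.phi_pt <- function(x, ...) {
  tibble(phi_pt = x$overall$phi, phi_pt_raw = x$overall$phi_raw,
         sigma_among = x$overall$sigma_among,
         sigma_within = x$overall$sigma_within,
         p_value = x$overall$p_value, n_sites = length(x$sites),
         n_permutations = x$n_permutations)
}

# ---- PCoA -----------------------------------------------------------------

#' Principal coordinate analysis of a distance matrix
#'
#' Gower double-centering of -0.5 D^2 followed by eigendecomposition. Axes
#' are ordered by eigenvalue; the percent variance of each retained axis is
#' its eigenvalue over the sum of positive eigenvalues. Negative eigenvalues
#' (non-Euclidean input) are excluded from the denominator and reported.
#'
#' @param d symmetric distance matrix with zero diagonal (e.g. the `matrix`
#'   element of a [phi_pt()] result), or a `dist`.
#' @return object of class `pcoa_ord`: list with `points` (rows = objects),
#'   `eigenvalues`, `percent` (per positive axis), `negative_eigenvalues`.
#' @export
pcoa <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    abort("`d` must be a symmetric distance matrix")
  }
  if (any(abs(diag(m)) > 1e-12)) abort("`d` must have a zero diagonal")
  n <- nrow(m)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (m^2) %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- which(eig$values > tol)
  neg <- eig$values[eig$values < -tol]
  points <- if (length(pos) > 0) {
    sweep(eig$vectors[, pos, drop = FALSE], 2, sqrt(eig$values[pos]), `*`)
  } else matrix(0, n, 0)
  rownames(points) <- rownames(m)
  colnames(points) <- if (length(pos) > 0) paste0("Axis", seq_along(pos))
  percent <- if (length(pos) > 0) 100 * eig$values[pos] / sum(eig$values[pos]) else numeric()
  structure(list(points = points, eigenvalues = eig$values,
                 percent = percent, negative_eigenvalues = neg),
            class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat("<pcoa_ord> ", nrow(x$points), " objects, ", ncol(x$points),
      " positive axes\n", sep = "")
  if (length(x$percent) > 0) {
    cat("percent variance:",
        paste(sprintf("%.1f", utils::head(x$percent, 4)), collapse = ", "),
        if (length(x$percent) > 4) "..." else "", "\n")
  }
  invisible(x)
}

#' @rdname pcoa
#' @param x a `pcoa_ord` object.
#' @param ... unused.
#' @export
tidy.pcoa_ord <- function(x, ...) {
  if (ncol(x$points) == 0) {
    return(tibble(object = rownames(x$points) %||% character()))
  }
  out <- as_tibble(x$points)
  out$object <- rownames(x$points) %||% as.character(seq_len(nrow(x$points)))
  dplyr::relocate(out, "object")
}

#' @rdname pcoa
#' @export
glance.pcoa_ord <- function(x, ...) {
  tibble(n_axes = ncol(x$points),
         percent_axis1 = if (length(x$percent) >= 1) x$percent[1] else NA_real_,
         percent_axis2 = if (length(x$percent) >= 2) x$percent[2] else NA_real_,
         n_negative_eigenvalues = length(x$negative_eigenvalues))
}
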