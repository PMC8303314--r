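# Synthetic population generator.
#
# Colonies are drawn per sampling site either with exact per-haplotype counts
# (used for the default study population, whose composition mirrors the
# published survey totals) or by multinomial sampling from configured
# frequencies. Each colony's amplicon is the catalog haplotype's sequence, so
# truth labels (haplotype, lineage, sub-lineage, pattern) are known exactly.

#' Configure a synthetic population
#'
#' @param sites tibble with columns `site`, `region` (and `n` when sampling by
#'   frequency).
#' @param counts tibble with columns `site`, `haplotype`, `count`: exact
#'   per-site composition. Exactly one of `counts`/`frequencies` must be given.
#' @param frequencies tibble with columns `site`, `haplotype`, `p`: per-site
#'   haplotype probabilities (summing to 1 per site); colonies are then drawn
#'   by multinomial sampling of `n` colonies per `sites` row.
#' @param seed integer seed; mandatory, all randomness derives from it.
#' @return a `population_config` list.
#' @export
population_config <- function(sites, counts = NULL, frequencies = NULL, seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory")
  if (is.null(counts) == is.null(frequencies)) {
    abort("give exactly one of `counts` or `frequencies`")
  }
  sites <- as_tibble(sites)
  stopifnot(all(c("site", "region") %in% names(sites)))
  if (anyDuplicated(sites$site)) abort("duplicated site in `sites`")
  if (!is.null(frequencies)) {
    frequencies <- as_tibble(frequencies)
    stopifnot(all(c("site", "haplotype", "p") %in% names(frequencies)))
    if (!"n" %in% names(sites)) {
      abort("`sites` needs an `n` column when sampling by frequency")
    }
    if (any(sites$n < 1)) abort("every site needs n_colonies >= 1")
    sums <- frequencies |> dplyr::summarise(s = sum(.data$p), .by = "site")
    if (any(abs(sums$s - 1) > 1e-9)) {
      abort(sprintf("haplotype frequencies for site '%s' do not sum to 1",
                    sums$site[which(abs(sums$s - 1) > 1e-9)[1]]))
    }
  } else {
    counts <- as_tibble(counts)
    stopifnot(all(c("site", "haplotype", "count") %in% names(counts)))
    if (any(counts$count < 0)) abort("counts must be non-negative")
  }
  structure(list(sites = sites, counts = counts, frequencies = frequencies,
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Generate a labeled synthetic population
#'
#' Builds one amplicon per colony from the reference catalog, together with
#' the sample sheet and a truth table. Reproducible: the same config (with its
#' seed) yields byte-identical output.
#'
#' @param config a [population_config()].
#' @param catalog reference catalog.
#' @return list with tibbles `sequences` (`id`, `sequence`), `sample_sheet`
#'   (`sample_id`, `site`, `region`) and `truth` (`sample_id`, `haplotype`,
#'   `lineage`, `sublineage`, `pattern`).
#' @export
generate_population <- function(config, catalog = load_reference_catalog()) {
  stopifnot(inherits(config, "population_config"))
  rec <- catalog$records
  comp <- if (!is.null(config$counts)) {
    config$counts
  } else {
    f <- config$frequencies
    unknown <- setdiff(f$haplotype, rec$name)
    if (length(unknown) > 0) {
      abort(sprintf("unknown haplotype name: %s", unknown[1]))
    }
    withr_seed <- config$seed
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(withr_seed)
    split(f, f$site)[unique(f$site)] |>
      purrr::imap(function(fs, site) {
        n <- config$sites$n[match(site, config$sites$site)]
        draws <- stats::rmultinom(1, n, fs$p)[, 1]
        tibble(site = site, haplotype = fs$haplotype, count = draws)
      }) |>
      dplyr::bind_rows()
  }
  unknown <- setdiff(comp$haplotype, rec$name)
  if (length(unknown) > 0) abort(sprintf("unknown haplotype name: %s", unknown[1]))
  comp <- dplyr::filter(comp, .data$count > 0)
  # deterministic colony order: site order as given, then haplotype order
  site_order <- config$sites$site
  comp <- comp |>
    dplyr::mutate(site = factor(.data$site, levels = site_order)) |>
    dplyr::arrange(.data$site, match(.data$haplotype, rec$name)) |>
    dplyr::mutate(site = as.character(.data$site))
  long <- comp[rep(seq_len(nrow(comp)), comp$count), c("site", "haplotype")]
  long <- long |>
    dplyr::mutate(
      region = config$sites$region[match(.data$site, config$sites$site)],
      idx = stats::ave(seq_len(nrow(long)), .data$site, FUN = seq_along),
      sample_id = sprintf("%s-%03d", gsub("[^A-Za-z0-9]+", "_", .data$site),
                          .data$idx))
  ri <- match(long$haplotype, rec$name)
  list(
    sequences = tibble(id = long$sample_id, sequence = rec$sequence[ri]),
    sample_sheet = tibble(sample_id = long$sample_id, site = long$site,
                          region = long$region),
    truth = tibble(sample_id = long$sample_id, haplotype = long$haplotype,
                   lineage = rec$lineage[ri], sublineage = rec$sublineage[ri],
                   pattern = rec$pattern[ri])
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Add substitution noise to generated amplicons
#'
#' Sprinkles per-base substitutions at rate `sub_rate` for robustness testing.
#' Diagnostic motifs are protected: DraI (TTTAAA) occurrences and an 8 bp
#' anchor window at each element boundary are never mutated, a documented
#' simulator limitation.
#'
#' @param sim result of [generate_population()] (uses its truth labels to
#'   locate element boundaries), or a tibble with `id`, `sequence` and
#'   `haplotype` columns.
#' @param sub_rate substitution probability per unprotected base, in [0, 0.02].
#' @param seed integer seed.
#' @param catalog reference catalog.
#' @return same structure as `sim`, with mutated `sequences` and an
#'   `n_substitutions` column added to the sequence tibble.
#' @export
add_noise <- function(sim, sub_rate, seed, catalog = load_reference_catalog()) {
  if (!is.numeric(sub_rate) || sub_rate < 0 || sub_rate > 0.02) {
    abort("`sub_rate` must be in [0, 0.02]")
  }
  if (missing(seed)) abort("`seed` is mandatory")
  as_list <- !is.data.frame(sim)
  seqs <- if (as_list) dplyr::left_join(sim$sequences,
                                        sim$truth[c("sample_id", "haplotype")],
                                        by = c(id = "sample_id")) else sim
  stopifnot(all(c("id", "sequence", "haplotype") %in% names(seqs)))
  protected <- .protected_positions(seqs$haplotype, catalog)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out_seq <- character(nrow(seqs)); n_sub <- integer(nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    v <- strsplit(seqs$sequence[i], "")[[1]]
    open <- setdiff(seq_along(v), protected[[seqs$haplotype[i]]])
    hit <- open[stats::runif(length(open)) < sub_rate]
    if (length(hit) > 0) {
      v[hit] <- vapply(v[hit], function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                       character(1))
    }
    out_seq[i] <- paste(v, collapse = ""); n_sub[i] <- length(hit)
  }
  res <- tibble(id = seqs$id, sequence = out_seq, n_substitutions = n_sub)
  if (as_list) { sim$sequences <- res; sim } else res
}

# per-haplotype protected positions: DraI motifs and 8 bp element-boundary
# anchor windows (computed on the clean catalog sequence)
.protected_positions <- function(haplotypes, catalog) {
  rec <- catalog$records
  out <- list()
  for (h in unique(haplotypes)) {
    i <- match(h, rec$name)
    if (is.na(i)) abort(sprintf("unknown haplotype name: %s", h))
    s <- rec$sequence[i]
    prot <- integer()
    m <- gregexpr("TTTAAA", s, fixed = TRUE)[[1]]
    if (m[1] != -1) prot <- c(prot, unlist(lapply(m, function(p) p:(p + 5))))
    lens <- c(40L, .P_FORM_LEN[[rec$p_form[i]]], rep(196L, rec$n_q[i]), 300L)
    # small indels shift boundaries by <=2 bp; the 8 bp window absorbs that
    bounds <- cumsum(lens[lens > 0])
    for (b in bounds[-length(bounds)]) prot <- c(prot, (b - 3):(b + 4))
    prot <- c(prot, 1:8, (nchar(s) - 7):nchar(s))
    out[[h]] <- sort(unique(pmax(1, pmin(nchar(s), prot))))
  }
  out
}

#' The default study population (synthetic allocation)
#'
#' Per-site haplotype counts for the 512-colony, 15-site, 3-region survey.
#' The global composition reproduces the published totals exactly (lineages
#' 333 A / 173 C / 6 M; sub-lineages 280 AI / 53 AIII; length patterns
#' 3 P0 / 173 Q / 55 P0Q / 222 P0QQ / 6 PQQ / 53 P1QQ; headline haplotype
#' counts A4p 117, A4t 96, A30 51, C1 94, C2j 60, A65 3) together with each
#' site's N, its haplotype richness Na, one private haplotype per site, and
#' the reported site-exclusivity of rare variants. The within-site split is a
#' synthetic reconstruction: the colony-level source table is not public.
#'
#' @return tibble with columns `region`, `site`, `haplotype`, `count`.
#' @export
study_population_counts <- function() {
  tibble::tribble(
    ~region, ~site,          ~haplotype, ~count,
    "Lima",  "Barranca",     "A1t", 2L,  "Lima", "Barranca",  "C1", 25L,
    "Lima",  "Barranca",     "C2j", 15L,
    "Lima",  "Coayllo",      "A30d", 1L, "Lima", "Coayllo",   "C1", 30L,
    "Lima",  "Coayllo",      "C2j", 7L,
    "Lima",  "Quilmana",     "A30e", 1L, "Lima", "Quilmana",  "A4p", 5L,
    "Lima",  "Quilmana",     "A4t", 4L,  "Lima", "Quilmana",  "A30", 5L,
    "Lima",  "Quilmana",     "A1", 3L,   "Lima", "Quilmana",  "A1e", 2L,
    "Lima",  "Quilmana",     "C1", 8L,   "Lima", "Quilmana",  "C2j", 6L,
    "Lima",  "Quilmana",     "C2c", 2L,
    "Lima",  "Santa Maria",  "C3", 2L,   "Lima", "Santa Maria", "C1", 20L,
    "Lima",  "Santa Maria",  "C2j", 12L, "Lima", "Santa Maria", "A4p", 3L,
    "Lima",  "Santa Maria",  "A30", 2L,
    "Lima",  "Sayan",        "C2", 4L,   "Lima", "Sayan",     "C1", 11L,
    "Lima",  "Sayan",        "C2j", 10L, "Lima", "Sayan",     "A4p", 6L,
    "Lima",  "Sayan",        "A30", 4L,
    "Piura", "Chulucanas 1", "A4q", 2L,  "Piura", "Chulucanas 1", "A4p", 20L,
    "Piura", "Chulucanas 1", "A4t", 10L, "Piura", "Chulucanas 1", "A1", 4L,
    "Piura", "Chulucanas 1", "C2c", 2L,
    "Piura", "Chulucanas 2", "M7c", 2L,  "Piura", "Chulucanas 2", "A4p", 12L,
    "Piura", "Chulucanas 2", "A4t", 8L,  "Piura", "Chulucanas 2", "A1e", 5L,
    "Piura", "Chulucanas 2", "A1", 2L,   "Piura", "Chulucanas 2", "C2j", 2L,
    "Piura", "La Matanza 1", "C2l", 3L,  "Piura", "La Matanza 1", "A65", 1L,
    "Piura", "La Matanza 1", "A4p", 4L,  "Piura", "La Matanza 1", "A4t", 3L,
    "Piura", "La Matanza 1", "A1", 2L,   "Piura", "La Matanza 1", "A1e", 1L,
    "Piura", "La Matanza 2", "M7b", 4L,  "Piura", "La Matanza 2", "A4p", 25L,
    "Piura", "La Matanza 2", "A4t", 15L, "Piura", "La Matanza 2", "A1", 4L,
    "Piura", "La Matanza 2", "A1e", 2L,  "Piura", "La Matanza 2", "C2j", 2L,
    "Piura", "Piura",        "A1u", 3L,  "Piura", "Piura",     "A65", 1L,
    "Piura", "Piura",        "A4p", 8L,  "Piura", "Piura",     "A4t", 7L,
    "Piura", "Piura",        "A1", 3L,   "Piura", "Piura",     "A1e", 4L,
    "Piura", "Piura",        "C2c", 3L,  "Piura", "Piura",     "C2j", 2L,
    "Junin", "La Merced",    "A1w", 2L,  "Junin", "La Merced", "A4p", 8L,
    "Junin", "La Merced",    "A4t", 10L, "Junin", "La Merced", "A1", 2L,
    "Junin", "La Merced",    "A1e", 3L,  "Junin", "La Merced", "A30", 4L,
    "Junin", "La Merced",    "C2j", 2L,  "Junin", "La Merced", "C2c", 1L,
    "Junin", "Perene 1",     "A4s", 2L,  "Junin", "Perene 1",  "A4p", 10L,
    "Junin", "Perene 1",     "A4t", 12L, "Junin", "Perene 1",  "A1e", 4L,
    "Junin", "Perene 1",     "A30", 5L,  "Junin", "Perene 1",  "C2j", 2L,
    "Junin", "Perene 1",     "C2c", 1L,
    "Junin", "Perene 2",     "A4v", 2L,  "Junin", "Perene 2",  "A4p", 6L,
    "Junin", "Perene 2",     "A4t", 11L, "Junin", "Perene 2",  "A1", 2L,
    "Junin", "Perene 2",     "A1e", 3L,  "Junin", "Perene 2",  "A30", 5L,
    "Junin", "San Ramon",    "A4w", 1L,  "Junin", "San Ramon", "A65", 1L,
    "Junin", "San Ramon",    "A4p", 6L,  "Junin", "San Ramon", "A4t", 10L,
    "Junin", "San Ramon",    "A30", 14L, "Junin", "San Ramon", "A1", 2L,
    "Junin", "San Ramon",    "C2c", 1L,
    "Junin", "Vitoc",        "A4u", 2L,  "Junin", "Vitoc",     "A4p", 4L,
    "Junin", "Vitoc",        "A4t", 6L,  "Junin", "Vitoc",     "A30", 12L
  )
}

#' Configuration reproducing the default study population
#'
#' @param seed integer seed (kept in the config for reproducibility of
#'   downstream permutation/bootstrap stages; colony composition itself is
#'   exact, not sampled).
#' @return a [population_config()] with exact counts.
#' @export
study_population_config <- function(seed = 1L) {
  counts <- study_population_counts()
  sites <- dplyr::distinct(counts, .data$site, .data$region)
  population_config(sites = sites,
                    counts = counts[c("site", "haplotype", "count")],
                    seed = seed)
}

#' Published per-site diversity reference values
#'
#' The printed per-site diversity table of the source survey (N, Na, Np, Ne,
#' uh for 15 sampling sites in three regions), shipped for arithmetic
#' cross-checks such as the unbiased-diversity identity
#' `uh = (N/(N-1)) (1 - 1/Ne)`.
#'
#' @return tibble with columns `region`, `site`, `N`, `Na`, `Np`, `Ne`, `uh`.
#' @export
reference_site_diversity <- function() {
  tibble::tribble(
    ~region, ~site,          ~N,  ~Na, ~Np, ~Ne,   ~uh,
    "Lima",  "Barranca",     42L, 3L,  1L,  1.215, 0.181,
    "Lima",  "Coayllo",      38L, 3L,  1L,  1.936, 0.496,
    "Lima",  "Quilmana",     36L, 9L,  1L,  4.909, 0.819,
    "Lima",  "Santa Maria",  39L, 5L,  1L,  2.164, 0.552,
    "Lima",  "Sayan",        35L, 5L,  1L,  3.840, 0.761,
    "Piura", "Chulucanas 1", 38L, 5L,  1L,  2.597, 0.632,
    "Piura", "Chulucanas 2", 31L, 6L,  1L,  3.302, 0.720,
    "Piura", "La Matanza 1", 14L, 6L,  1L,  5.444, 0.879,
    "Piura", "La Matanza 2", 52L, 6L,  1L,  4.777, 0.806,
    "Piura", "Piura",        31L, 8L,  1L,  3.469, 0.735,
    "Junin", "La Merced",    32L, 8L,  1L,  4.414, 0.798,
    "Junin", "Perene 1",     36L, 7L,  1L,  2.374, 0.595,
    "Junin", "Perene 2",     29L, 6L,  1L,  2.572, 0.633,
    "Junin", "San Ramon",    35L, 7L,  1L,  5.258, 0.834,
    "Junin", "Vitoc",        24L, 4L,  1L,  2.909, 0.685
  )
}
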