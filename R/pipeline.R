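# End-to-end orchestration: generate/read -> type -> summarise ->
# differentiate -> tree/network, with a manifest for reproducibility.

.round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Lineage and sub-lineage composition of a typing table
#'
#' Counts and percentages (rounded half-up to 1 decimal) per lineage, per
#' African sub-lineage (as share of lineage A), and per haplotype; overall
#' and per region.
#'
#' @param typing typing tibble (needs `lineage`, `sublineage`, `haplotype`,
#'   optionally `region`).
#' @return list of tibbles: `lineage`, `sublineage`, `haplotype`,
#'   `lineage_by_region`.
#' @export
lineage_composition <- function(typing) {
  n <- nrow(typing)
  lineage <- typing |>
    dplyr::count(.data$lineage, name = "count") |>
    dplyr::mutate(percent = .round_half_up(100 * .data$count / n)) |>
    dplyr::arrange(dplyr::desc(.data$count))
  a_only <- dplyr::filter(typing, .data$lineage == "A")
  sublineage <- a_only |>
    dplyr::count(.data$sublineage, name = "count") |>
    dplyr::mutate(percent = .round_half_up(100 * .data$count / nrow(a_only))) |>
    dplyr::arrange(dplyr::desc(.data$count))
  haplotype <- typing |>
    dplyr::count(.data$lineage, .data$haplotype, name = "count") |>
    dplyr::mutate(percent = .round_half_up(100 * .data$count / n)) |>
    dplyr::arrange(dplyr::desc(.data$count))
  by_region <- if ("region" %in% names(typing) && !all(is.na(typing$region))) {
    typing |>
      dplyr::count(.data$region, .data$lineage, name = "count") |>
      dplyr::mutate(percent = .round_half_up(
        100 * .data$count / sum(.data$count)), .by = "region")
  } else NULL
  list(lineage = lineage, sublineage = sublineage, haplotype = haplotype,
       lineage_by_region = by_region)
}

# pattern <-> lineage/sub-lineage bookkeeping mirrored from the survey:
# P0-prefixed patterns should be sub-lineage AI colonies, P1-prefixed AIII,
# pure-Q patterns lineage C, and P-form patterns lineage M
.check_pattern_consistency <- function(typing) {
  pat <- typing$pattern
  p0 <- startsWith(pat, "P0")
  p1 <- startsWith(pat, "P1")
  m <- startsWith(pat, "P") & !p0 & !p1
  q <- !startsWith(pat, "P")
  ok <- sum(p0) == sum(typing$sublineage == "AI", na.rm = TRUE) &&
    sum(p1) == sum(typing$sublineage == "AIII", na.rm = TRUE) &&
    sum(q) == sum(typing$lineage == "C") &&
    sum(m) == sum(typing$lineage == "M")
  if (!ok) {
    warn(paste("pattern/lineage consistency check failed:",
               "pattern prefixes do not match sub-lineage counts",
               "(expected with AII/Z or indeterminate colonies)"))
  }
  ok
}

#' Configure a pipeline run
#'
#' @param fasta,sample_sheet input paths (typed-data mode). Exactly one of
#'   the FASTA input or `simulation` must be given.
#' @param simulation a [population_config()] (simulation mode).
#' @param output_dir directory for all outputs (created if needed).
#' @param seed integer seed driving permutations/bootstrap (and simulation if
#'   its config carries none).
#' @param digest,tree,network,permutations stage toggles.
#' @param phi_label column used for differentiation (default `"lineage_sublineage"`,
#'   a combined lineage/sub-lineage label).
#' @param n_permutations,n_bootstrap,epsilon,drai_weight,indel_weight
#'   stage parameter overrides.
#' @return a `run_config` list.
#' @export
run_config <- function(fasta = NULL, sample_sheet = NULL, simulation = NULL,
                       output_dir, seed = 1L, digest = FALSE, tree = TRUE,
                       network = TRUE, permutations = TRUE,
                       phi_label = "lineage_sublineage",
                       n_permutations = 999, n_bootstrap = 1000,
                       epsilon = 0, drai_weight = 10, indel_weight = 10) {
  if (is.null(fasta) == is.null(simulation)) {
    abort("give exactly one of `fasta` or `simulation`")
  }
  if (!is.null(fasta) && is.null(sample_sheet)) {
    abort("`sample_sheet` is required with a FASTA input")
  }
  if (missing(output_dir)) abort("`output_dir` is required")
  structure(list(fasta = fasta, sample_sheet = sample_sheet,
                 simulation = simulation, output_dir = output_dir,
                 seed = as.integer(seed), digest = digest, tree = tree,
                 network = network, permutations = permutations,
                 phi_label = phi_label, n_permutations = n_permutations,
                 n_bootstrap = n_bootstrap, epsilon = epsilon,
                 drai_weight = drai_weight, indel_weight = indel_weight),
            class = "run_config")
}

#' Run the full mitotyping pipeline
#'
#' Generates or reads amplicons, types every colony, and writes the typing
#' table, composition summary, per-site diversity table, PhiPT/PCoA outputs
#' and (optionally) the DraI digest table, NJ tree and median-joining
#' network, plus a JSON manifest. Deterministic for a fixed config and seed.
#'
#' @param config a [run_config()].
#' @param catalog reference catalog.
#' @return the run manifest (list), invisibly; its `files` entry lists all
#'   outputs, `consistency_ok` the pattern/lineage bookkeeping check.
#' @export
run_pipeline <- function(config, catalog = load_reference_catalog()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  path <- function(name) file.path(out, name)

  if (!is.null(config$simulation)) {
    sim <- generate_population(config$simulation, catalog = catalog)
    if (nrow(sim$sequences) == 0) abort("simulation produced no colonies")
    write_fasta(sim$sequences, path("amplicons.fasta"))
    write_sample_sheet(sim$sample_sheet, path("sample_sheet.tsv"))
    readr::write_tsv(sim$truth, path("truth.tsv"), progress = FALSE)
    files$fasta <- path("amplicons.fasta")
    files$sample_sheet <- path("sample_sheet.tsv")
    files$truth <- path("truth.tsv")
    sequences <- sim$sequences; sheet <- sim$sample_sheet
  } else {
    sequences <- read_fasta(config$fasta)
    sheet <- read_sample_sheet(config$sample_sheet)
    missing_ids <- setdiff(sequences$id, sheet$sample_id)
    if (length(missing_ids) > 0) {
      abort(sprintf("%d sequence id(s) missing from the sample sheet (first: %s)",
                    length(missing_ids), missing_ids[1]))
    }
  }

  typing <- type_sequences(sequences, sheet, catalog = catalog)
  write_typing_table(typing, path("typing.tsv"))
  files$typing <- path("typing.tsv")

  comp <- lineage_composition(typing)
  comp_tbl <- dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(comp$lineage, level = "lineage"),
                  stratum = "lineage"),
    dplyr::mutate(dplyr::rename(comp$sublineage, level = "sublineage"),
                  stratum = "sublineage_within_A"))
  readr::write_tsv(comp_tbl, path("composition.tsv"), progress = FALSE)
  files$composition <- path("composition.tsv")
  consistency_ok <- .check_pattern_consistency(typing)

  diversity <- diversity_summary(typing)
  div_out <- dplyr::mutate(diversity,
                           Ne = round(.data$Ne, 3), uh = round(.data$uh, 3))
  readr::write_tsv(div_out, path("diversity.tsv"), progress = FALSE)
  files$diversity <- path("diversity.tsv")

  phi <- NULL
  n_perm <- if (config$permutations) config$n_permutations else 0
  typing$lineage_sublineage <- ifelse(
    typing$lineage == "A" & !is.na(typing$sublineage),
    paste0(typing$lineage, "-", typing$sublineage), typing$lineage)
  enough_sites <- sum(table(typing$site) >= 2) >= 2
  if (enough_sites) {
    phi <- phi_pt(typing, label = dplyr::all_of(config$phi_label),
                  n_permutations = n_perm,
                  seed = if (n_perm > 0) config$seed else NULL)
    readr::write_tsv(tidy(phi), path("phipt_pairwise.tsv"), progress = FALSE)
    utils::write.table(phi$matrix, path("phipt_matrix.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    files$phipt <- path("phipt_pairwise.tsv")
    ord <- pcoa(phi$matrix)
    pcoa_tbl <- tidy(ord)
    pcoa_tbl$percent_axis1 <- if (length(ord$percent) >= 1) ord$percent[1] else NA
    pcoa_tbl$percent_axis2 <- if (length(ord$percent) >= 2) ord$percent[2] else NA
    readr::write_tsv(pcoa_tbl, path("pcoa.tsv"), progress = FALSE)
    files$pcoa <- path("pcoa.tsv")
  }

  if (config$digest) {
    digest <- tibble(
      sample_id = typing$sample_id,
      fragments = vapply(typing$element_map, function(em)
        paste(insilico_dra1_digest(em$sequence), collapse = ","), character(1)))
    readr::write_tsv(digest, path("digest.tsv"), progress = FALSE)
    files$digest <- path("digest.tsv")
  }

  cm <- encode_characters(catalog, include_outgroup = TRUE,
                          drai_weight = config$drai_weight,
                          indel_weight = config$indel_weight)
  if (config$tree) {
    nb <- nj_bootstrap_tree(cm, n_bootstrap = config$n_bootstrap,
                            seed = config$seed)
    writeLines(nb$newick, path("tree.nwk"))
    files$tree <- path("tree.nwk")
  }
  if (config$network) {
    cm_obs <- encode_characters(catalog, include_outgroup = FALSE,
                                include_bases = TRUE,
                                drai_weight = config$drai_weight,
                                indel_weight = config$indel_weight)
    counts <- dplyr::count(typing, haplotype = .data$haplotype, name = "count")
    net <- median_joining_network(cm_obs, epsilon = config$epsilon,
                                  frequencies = counts)
    write_network_tables(net, path("network_edges.tsv"),
                         path("network_nodes.tsv"))
    files$network_edges <- path("network_edges.tsv")
    files$network_nodes <- path("network_nodes.tsv")
  }

  manifest <- list(
    package = as.character(utils::packageVersion("beemito")),
    seed = config$seed,
    n_samples = nrow(typing),
    n_sites = length(unique(stats::na.omit(typing$site))),
    consistency_ok = consistency_ok,
    stages = list(
      typing = nrow(typing),
      diversity = nrow(diversity),
      phipt = if (!is.null(phi)) nrow(tidy(phi)) else 0L),
    files = lapply(files, basename),
    input_md5 = as.list(tools::md5sum(c(
      config$fasta %||% files$fasta %||% character(),
      config$sample_sheet %||% files$sample_sheet %||% character()))))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
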