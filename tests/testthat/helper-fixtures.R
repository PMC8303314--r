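# shared fixture builders (everything is generated in code; no data files)

# a small three-site population covering all lineages
small_population <- function(seed = 101) {
  counts <- tibble::tribble(
    ~site, ~region, ~haplotype, ~count,
    "north", "R1", "A4p", 6L,
    "north", "R1", "A1",  3L,
    "north", "R1", "C1",  1L,
    "south", "R2", "C1",  7L,
    "south", "R2", "C2j", 2L,
    "south", "R2", "M7b", 1L,
    "east",  "R3", "A30", 5L,
    "east",  "R3", "A65", 2L,
    "east",  "R3", "A4t", 3L
  )
  population_config(
    sites = dplyr::distinct(counts, site, region),
    counts = counts[c("site", "haplotype", "count")],
    seed = seed)
}

# hand-rolled char_matrix constructor for synthetic character tests
make_char_matrix <- function(states, weights = rep(1L, ncol(states)),
                             provenance = rep("test", ncol(states))) {
  structure(list(states = states, weights = as.integer(weights),
                 provenance = provenance,
                 character_id = colnames(states) %||%
                   paste0("c", seq_len(ncol(states))),
                 taxa = rownames(states)),
            class = "char_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# perfect (homoplasy-free) binary characters from a random topology: one
# character per edge, split by the tips below that edge
perfect_characters_from_tree <- function(tree) {
  n_tip <- length(tree$tip.label)
  chars <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- if (child <= n_tip) child else {
      phangorn_free_descendants(tree, child, n_tip)
    }
    v <- rep("0", n_tip)
    v[tips] <- "1"
    chars[[e]] <- v
  }
  M <- do.call(cbind, chars)
  rownames(M) <- tree$tip.label
  make_char_matrix(M)
}

# tips below an internal node (small trees; plain traversal)
phangorn_free_descendants <- function(tree, node, n_tip) {
  out <- integer()
  stack <- node
  while (length(stack) > 0) {
    nd <- stack[1]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, kids[kids <= n_tip])
    stack <- c(stack, kids[kids > n_tip])
  }
  out
}
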