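# Neighbor-joining phylogeny with character bootstrap, and the
# median-joining haplotype network.

#' Bootstrapped neighbor-joining tree on step distances
#'
#' Neighbor joining on the weighted mutational-step distance matrix, with
#' support values from resampling characters with replacement (weights travel
#' with their characters). The tree is rooted on the outgroup when one is
#' present in the matrix.
#'
#' @param matrix a `char_matrix` with at least four taxa.
#' @param n_bootstrap bootstrap replicates (default 1000).
#' @param seed integer seed, mandatory.
#' @param outgroup taxon name to root on (default: the catalog outgroup name
#'   when present among the taxa).
#' @return object of class `nj_boot`: list with `tree` (an `ape::phylo` whose
#'   node labels are bootstrap percentages), `newick` (string) and
#'   `n_bootstrap`.
#' @export
nj_bootstrap_tree <- function(matrix, n_bootstrap = 1000, seed,
                              outgroup = NULL) {
  if (length(matrix$taxa) < 4) abort("neighbor joining needs at least 4 taxa")
  if (missing(seed)) abort("`seed` is mandatory")
  if (is.null(outgroup) && .OUTGROUP_NAME %in% matrix$taxa) {
    outgroup <- .OUTGROUP_NAME
  }
  D <- step_distance_matrix(matrix)
  tree <- ape::nj(stats::as.dist(D))
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_char <- ncol(matrix$states)
  boot <- vector("list", n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    idx <- sample.int(n_char, n_char, replace = TRUE)
    res <- matrix
    res$states <- matrix$states[, idx, drop = FALSE]
    res$weights <- matrix$weights[idx]
    Db <- step_distance_matrix(res)
    tb <- ape::nj(stats::as.dist(Db))
    if (!is.null(outgroup)) {
      tb <- tryCatch(ape::root(tb, outgroup = outgroup, resolve.root = TRUE),
                     error = function(e) tb)
    }
    boot[[b]] <- tb
  }
  class(boot) <- "multiPhylo"
  support <- ape::prop.clades(tree, boot, rooted = !is.null(outgroup))
  support[is.na(support)] <- 0
  tree$node.label <- round(100 * support / n_bootstrap)
  structure(list(tree = tree, newick = ape::write.tree(tree),
                 n_bootstrap = n_bootstrap, outgroup = outgroup),
            class = "nj_boot")
}

#' @export
print.nj_boot <- function(x, ...) {
  cat("<nj_boot> ", length(x$tree$tip.label), " tips, ", x$n_bootstrap,
      " bootstrap replicates", if (!is.null(x$outgroup))
        paste0(", rooted on ", x$outgroup), "\n", sep = "")
  invisible(x)
}

#' @rdname nj_bootstrap_tree
#' @param x an `nj_boot` object.
#' @param ... unused.
#' @export
glance.nj_boot <- function(x, ...) {
  tibble(n_tips = length(x$tree$tip.label),
         n_bootstrap = x$n_bootstrap,
         mean_support = mean(x$tree$node.label, na.rm = TRUE),
         rooted = !is.null(x$outgroup))
}

# ---- median-joining network ----------------------------------------------

# minimum-spanning-network edges: process ascending distance levels; at each
# stage add every inter-component pair within epsilon of the smallest
# connecting distance, then merge. Always contains an MST.
.msn_edges <- function(D, epsilon = 0) {
  n <- nrow(D)
  if (n == 1) return(cbind(integer(), integer()))
  comp <- seq_len(n)
  edges <- list()
  while (length(unique(comp)) > 1) {
    inter <- which(outer(comp, comp, `!=`) & upper.tri(D), arr.ind = TRUE)
    d_min <- min(D[inter])
    sel <- inter[D[inter] <= d_min + epsilon, , drop = FALSE]
    for (r in seq_len(nrow(sel))) {
      edges[[length(edges) + 1]] <- sel[r, ]
    }
    for (r in seq_len(nrow(sel))) {
      a <- comp[sel[r, 1]]; b <- comp[sel[r, 2]]
      comp[comp == b] <- a
    }
  }
  do.call(rbind, edges)
}

.vec_dist <- function(a, b, w) {
  ok <- !is.na(a) & !is.na(b)
  sum(w[ok] * (a[ok] != b[ok]))
}

# per-character majority state of a triple; ties keep the first taxon's state
.median_vector <- function(u, v, w) {
  out <- u
  for (j in seq_along(u)) {
    s <- c(u[j], v[j], w[j]); s <- s[!is.na(s)]
    if (length(s) == 0) { out[j] <- NA; next }
    tab <- table(s)
    out[j] <- if (max(tab) >= 2) names(tab)[which.max(tab)] else u[j]
  }
  out
}

#' Median-joining haplotype network
#'
#' Bandelt-style median joining on the weighted character matrix: iteratively
#' (1) build the minimum-spanning network at tolerance `epsilon`, (2) add
#' median (Steiner) vectors obtained as per-character majorities of connected
#' triplets when they shorten the triplet's connection, (3) prune median
#' vectors of degree below three; repeated to a fixpoint. The final network
#' is connected and contains a minimum spanning tree of the observed
#' haplotypes.
#'
#' @param matrix a `char_matrix` (at least 2 taxa).
#' @param epsilon non-negative tolerance of the spanning-network step;
#'   0 gives the most parsimonious network.
#' @param frequencies optional tibble `haplotype`, `count` (and optionally
#'   `region`) attached to the nodes, e.g. observed colony counts.
#' @param max_iter safety cap on median-addition rounds.
#' @return object of class `haplo_network`: list with `nodes` (tibble: `node`,
#'   `type` = observed/median, `taxa` list-column, `frequency`), `edges`
#'   (tibble: `from`, `to`, `steps`), `connected`, `epsilon`.
#' @export
median_joining_network <- function(matrix, epsilon = 0, frequencies = NULL,
                                   max_iter = 25) {
  taxa <- matrix$taxa
  if (length(taxa) < 2) abort("the network needs at least 2 taxa")
  w <- matrix$weights
  S <- matrix$states

  # collapse identical observed state vectors onto one node
  key <- apply(S, 1, function(x) paste(ifelse(is.na(x), "?", x), collapse = ""))
  uniq <- !duplicated(key)
  V <- lapply(which(uniq), function(i) S[i, ])
  node_taxa <- lapply(key[uniq], function(k) taxa[key == k])
  node_type <- rep("observed", length(V))

  med_id <- 0L
  for (iter in seq_len(max_iter)) {
    nV <- length(V)
    D <- base::matrix(0, nV, nV)
    for (i in seq_len(nV - 1)) for (j in (i + 1):nV) {
      D[i, j] <- D[j, i] <- .vec_dist(V[[i]], V[[j]], w)
    }
    E <- .msn_edges(D, epsilon)
    adj <- base::matrix(FALSE, nV, nV)
    if (nrow(E) > 0) adj[E] <- TRUE
    adj <- adj | t(adj)
    added <- FALSE
    keys_now <- vapply(V, function(x)
      paste(ifelse(is.na(x), "?", x), collapse = ""), character(1))
    for (i in seq_len(nV - 1)) for (j in (i + 1):nV) {
      if (!adj[i, j] && !any(adj[i, ] & adj[j, ])) next
      for (k in seq_len(nV)) {
        if (k == i || k == j) next
        n_links <- adj[i, j] + adj[i, k] + adj[j, k]
        if (n_links < 2) next
        m <- .median_vector(V[[i]], V[[j]], V[[k]])
        mk <- paste(ifelse(is.na(m), "?", m), collapse = "")
        if (mk %in% keys_now) next
        dm <- c(.vec_dist(m, V[[i]], w), .vec_dist(m, V[[j]], w),
                .vec_dist(m, V[[k]], w))
        if (any(dm == 0)) next
        if (sum(dm) < D[i, j] + D[i, k] + D[j, k]) {
          V[[length(V) + 1]] <- m
          node_taxa[[length(node_taxa) + 1]] <- character()
          node_type <- c(node_type, "median")
          med_id <- med_id + 1L
          keys_now <- c(keys_now, mk)
          added <- TRUE
        }
      }
    }
    if (!added) break
  }

  # prune median vectors of degree < 3 (fixpoint)
  repeat {
    nV <- length(V)
    D <- base::matrix(0, nV, nV)
    for (i in seq_len(nV - 1)) for (j in (i + 1):nV) {
      D[i, j] <- D[j, i] <- .vec_dist(V[[i]], V[[j]], w)
    }
    E <- .msn_edges(D, epsilon)
    deg <- tabulate(c(E), nV)
    drop <- which(node_type == "median" & deg < 3)
    if (length(drop) == 0) break
    V <- V[-drop]; node_taxa <- node_taxa[-drop]; node_type <- node_type[-drop]
  }

  node_names <- character(length(V))
  m_i <- 0L
  for (i in seq_along(V)) {
    if (node_type[i] == "observed") {
      node_names[i] <- node_taxa[[i]][1]
    } else {
      m_i <- m_i + 1L
      node_names[i] <- sprintf("mv%d", m_i)
    }
  }
  edges <- tibble(from = node_names[E[, 1]], to = node_names[E[, 2]],
                  steps = D[E])
  nodes <- tibble(node = node_names, type = node_type, taxa = node_taxa)
  if (!is.null(frequencies)) {
    freq <- dplyr::summarise(frequencies, count = sum(.data$count),
                             .by = "haplotype")
    nodes$frequency <- vapply(nodes$taxa, function(tx)
      sum(freq$count[freq$haplotype %in% tx]), numeric(1))
  } else {
    nodes$frequency <- ifelse(nodes$type == "observed",
                              lengths(nodes$taxa), 0)
  }
  connected <- length(unique(.components(E, length(V)))) == 1
  structure(list(nodes = nodes, edges = edges, connected = connected,
                 epsilon = epsilon),
            class = "haplo_network")
}

.components <- function(E, n) {
  comp <- seq_len(n)
  if (length(E) > 0) for (r in seq_len(nrow(E))) {
    a <- comp[E[r, 1]]; b <- comp[E[r, 2]]
    comp[comp == b] <- a
  }
  comp
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("<haplo_network> ", sum(x$nodes$type == "observed"), " observed + ",
      sum(x$nodes$type == "median"), " median nodes, ", nrow(x$edges),
      " edges (epsilon = ", x$epsilon, ", ",
      if (x$connected) "connected" else "NOT connected", ")\n", sep = "")
  invisible(x)
}

#' @rdname median_joining_network
#' @param x a `haplo_network`.
#' @param ... unused.
#' @export
tidy.haplo_network <- function(x, ...) x$edges

#' @rdname median_joining_network
#' @export
glance.haplo_network <- function(x, ...) {
  tibble(n_observed = sum(x$nodes$type == "observed"),
         n_median = sum(x$nodes$type == "median"),
         n_edges = nrow(x$edges),
         total_steps = sum(x$edges$steps),
         connected = x$connected)
}

#' Write network edge and node tables
#'
#' @param network a `haplo_network`.
#' @param edges_path,nodes_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_network_tables <- function(network, edges_path, nodes_path) {
  readr::write_tsv(network$edges, edges_path, progress = FALSE)
  nodes <- network$nodes
  nodes$taxa <- vapply(nodes$taxa, paste, character(1), collapse = ",")
  readr::write_tsv(nodes, nodes_path, progress = FALSE)
  invisible(c(edges_path, nodes_path))
}
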