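cat_ <- load_reference_catalog()

test_that("NJ recovers additive four-taxon topologies and is deterministic", {
  # additive case: perfect characters from a fixed quartet
  M <- rbind(a = c("1", "0", "1", "0", "0"),
             b = c("1", "0", "0", "1", "0"),
             c = c("0", "1", "0", "0", "1"),
             d = c("0", "1", "0", "0", "0"))
  cm <- make_char_matrix(M)
  nb <- nj_bootstrap_tree(cm, n_bootstrap = 20, seed = 2)
  expect_s3_class(nb$tree, "phylo")
  # a,b vs c,d is the unique split
  expect_true(ape::is.monophyletic(ape::unroot(nb$tree), c("a", "b")))
  nb2 <- nj_bootstrap_tree(cm, n_bootstrap = 20, seed = 2)
  expect_identical(nb$newick, nb2$newick)
  expect_error(nj_bootstrap_tree(make_char_matrix(M[1:3, ]), 10, seed = 1),
               "at least 4")
})

test_that("NJ on perfect characters recovers random 8-taxon topologies", {
  set.seed(505)
  wins <- 0
  for (r in 1:100) {
    tr <- ape::rtree(8, br = NULL)
    cm <- perfect_characters_from_tree(tr)
    nb <- nj_bootstrap_tree(cm, n_bootstrap = 1, seed = r)
    same <- ape::dist.topo(ape::unroot(nb$tree), ape::unroot(tr)) == 0
    wins <- wins + as.integer(same)
  }
  expect_equal(wins, 100)
})

test_that("the rooted catalog tree keeps the C lineage monophyletic", {
  cmo <- encode_characters(cat_, include_outgroup = TRUE)
  nb <- nj_bootstrap_tree(cmo, n_bootstrap = 100, seed = 5)
  c_taxa <- cat_$records$name[cat_$records$lineage == "C"]
  expect_true(ape::is.monophyletic(nb$tree, c_taxa))
  # European haplotypes (M and C) form one cluster
  mc <- cat_$records$name[cat_$records$lineage %in% c("C", "M")]
  expect_true(ape::is.monophyletic(nb$tree, mc))
  expect_true(grepl("^\\(", nb$newick) && grepl(";$", nb$newick))
})

test_that("two haplotypes give a single weighted edge and no medians", {
  M <- rbind(a = c("A", "A", "A"), b = c("T", "T", "T"))
  net <- median_joining_network(make_char_matrix(M))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$steps, 3)
  expect_equal(sum(net$nodes$type == "median"), 0)
  expect_true(net$connected)
})

test_that("a perfect three-way star gains its brute-force Steiner median", {
  M <- rbind(u = c("1", "1", "0"), v = c("0", "1", "1"), w = c("1", "0", "1"))
  cm <- make_char_matrix(M)
  net <- median_joining_network(cm)
  expect_equal(sum(net$nodes$type == "median"), 1)
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$steps == 1))
  expect_equal(sum(net$edges$steps), 3)  # < MST length 4

  # brute-force Steiner oracle over all 2^3 binary vectors
  dist01 <- function(x, y) sum(x != y)
  cand <- expand.grid(rep(list(c("0", "1")), 3), stringsAsFactors = FALSE)
  costs <- apply(cand, 1, function(m)
    dist01(m, M["u", ]) + dist01(m, M["v", ]) + dist01(m, M["w", ]))
  best <- as.character(unlist(cand[which.min(costs), ]))
  expect_equal(min(costs), 3)
  med_row <- net$nodes$node[net$nodes$type == "median"]
  # reconstruct the median states from edge distances: it must sit 1 step
  # from each observed node, like the oracle optimum
  expect_true(all(net$edges$steps[net$edges$from == med_row |
                                    net$edges$to == med_row] == 1))
})

test_that("the spanning-network stage contains a brute-force MST", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (r in 1:15) {
    n_tax <- 8; n_char <- 12
    M <- matrix(sample(c("0", "1"), n_tax * n_char, replace = TRUE),
                n_tax, n_char,
                dimnames = list(paste0("t", 1:n_tax), NULL))
    cm <- make_char_matrix(M)
    D <- step_distance_matrix(cm)
    E <- beemito:::.msn_edges(D, epsilon = 0)
    g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                             weighted = TRUE)
    mst <- igraph::mst(g)
    mst_edges <- igraph::as_edgelist(mst, names = FALSE)
    in_msn <- apply(mst_edges, 1, function(e)
      any((E[, 1] == min(e) & E[, 2] == max(e)) |
            (E[, 1] == max(e) & E[, 2] == min(e))))
    expect_true(all(in_msn), label = paste("replicate", r))
  }
})

test_that("median-joining on random instances keeps its structural invariants", {
  set.seed(2024)
  for (r in 1:10) {
    M <- matrix(sample(c("0", "1"), 7 * 10, replace = TRUE), 7, 10,
                dimnames = list(paste0("t", 1:7), NULL))
    cm <- make_char_matrix(M)
    net <- median_joining_network(cm)
    expect_true(net$connected)
    # every observed haplotype appears on exactly one node
    obs <- unlist(net$nodes$taxa)
    expect_setequal(obs, rownames(M))
    expect_equal(anyDuplicated(obs), 0L)
    # pruning fixpoint: all median vectors have degree >= 3
    deg <- table(c(net$edges$from, net$edges$to))
    med <- net$nodes$node[net$nodes$type == "median"]
    if (length(med) > 0) expect_true(all(deg[med] >= 3))
    expect_true(all(net$edges$steps >= 1))
  }
})

test_that("the catalog network separates the A, C and M clusters", {
  cm <- encode_characters(cat_)
  net <- median_joining_network(
    cm, frequencies = dplyr::count(
      dplyr::filter(study_population_counts(), TRUE),
      haplotype = haplotype, wt = count, name = "count"))
  expect_true(net$connected)
  lin <- setNames(cat_$records$lineage, cat_$records$name)
  # intra-lineage network edges never exceed the upweighted separation
  e_lin_from <- lin[net$edges$from]; e_lin_to <- lin[net$edges$to]
  both_obs <- !is.na(e_lin_from) & !is.na(e_lin_to)
  intra <- both_obs & e_lin_from == e_lin_to
  max_intra <- max(net$edges$steps[intra])
  # every inter-lineage step distance exceeds every intra-lineage edge
  D <- step_distance_matrix(cm)
  inter_pairs <- outer(lin[cm$taxa], lin[cm$taxa], `!=`)
  expect_gt(min(D[inter_pairs]), max_intra)
  # observed haplotype frequencies land on the nodes
  a4p <- net$nodes$frequency[vapply(net$nodes$taxa, function(t) "A4p" %in% t,
                                    logical(1))]
  expect_equal(unname(a4p), 117)
})
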