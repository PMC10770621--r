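test_that("network construction applies cutoff, whitelist and collapse rules", {
  edges <- data.frame(protein_a = c("A", "B"), protein_b = c("B", "C"),
                      confidence = c(0.95, 0.85))
  net <- make_net(edges, whitelist = c("A", "B", "C"))
  expect_equal(sort(net$nodes$gene), c("A", "B"))
  expect_equal(nrow(net$edges), 1)

  # whitelist rule: high-confidence edge to an outside protein is dropped
  edges2 <- rbind(edges, data.frame(protein_a = "A", protein_b = "D",
                                    confidence = 0.99))
  net2 <- make_net(edges2, whitelist = c("A", "B", "C"))
  expect_false("D" %in% net2$nodes$gene)

  # duplicate rows collapse to the maximum confidence either way round
  dup <- data.frame(protein_a = c("A", "B"), protein_b = c("B", "A"),
                    confidence = c(0.91, 0.93))
  net3 <- make_net(dup, whitelist = c("A", "B"))
  expect_equal(nrow(net3$edges), 1)
  expect_equal(net3$edges$confidence, 0.93)

  # self-loops vanish; an empty survivor set warns but does not error
  loop <- data.frame(protein_a = "A", protein_b = "A", confidence = 0.99)
  expect_warning(net4 <- make_net(loop, whitelist = "A"), "no edge")
  expect_equal(nrow(net4$nodes), 0)
  expect_error(build_network(edges, whitelist = character()), "whitelist")
})

test_that("degree centrality matches closed forms and sums to 2E", {
  tri <- make_net(data.frame(protein_a = c("A", "B", "C"),
                             protein_b = c("B", "C", "A")))
  expect_equal(unname(degree_centrality(tri)), c(2, 2, 2))

  star <- make_net(data.frame(protein_a = "HUB",
                              protein_b = c("L1", "L2", "L3", "L4")))
  deg <- degree_centrality(star)
  expect_equal(unname(deg["HUB"]), 4)
  expect_equal(mean(deg), 8 / 5)

  set.seed(3)
  for (rep in 1:10) {
    net <- make_net(random_ppi_edges(12, 0.3))
    if (nrow(net$edges) == 0) next
    expect_equal(sum(degree_centrality(net)), 2 * nrow(net$edges))
  }
})

test_that("betweenness follows the unordered-pair fractional convention", {
  path3 <- make_net(data.frame(protein_a = c("A", "B"),
                               protein_b = c("B", "C")))
  expect_equal(unname(betweenness_centrality(path3)), c(0, 1, 0))

  star <- make_net(data.frame(protein_a = "HUB",
                              protein_b = c("L1", "L2", "L3", "L4")))
  expect_equal(unname(betweenness_centrality(star)["HUB"]), choose(4, 2))

  square <- make_net(data.frame(protein_a = c("A", "B", "C", "D"),
                                protein_b = c("B", "C", "D", "A")))
  expect_equal(unname(betweenness_centrality(square)), rep(0.5, 4))
})

test_that("betweenness equals exhaustive path counting on random graphs", {
  set.seed(1234)
  for (rep in 1:25) {
    edges <- random_ppi_edges(sample(4:8, 1), 0.4)
    if (nrow(edges) == 0) next
    net <- make_net(edges)
    A <- adjacency_of(net)
    got <- betweenness_centrality(net)[rownames(A)]
    expect_equal(unname(got), enum_betweenness(A), tolerance = 1e-10)
  }
})

test_that("eigenvector centrality matches closed forms and dense decomposition", {
  tri <- make_net(data.frame(protein_a = c("A", "B", "C"),
                             protein_b = c("B", "C", "A")))
  expect_equal(unname(eigenvector_centrality(tri)), rep(1 / sqrt(3), 3),
               tolerance = 1e-8, ignore_attr = TRUE)

  pair <- make_net(data.frame(protein_a = "A", protein_b = "B"))
  expect_equal(unname(eigenvector_centrality(pair)), rep(1 / sqrt(2), 2),
               tolerance = 1e-8, ignore_attr = TRUE)

  star <- make_net(data.frame(protein_a = "HUB",
                              protein_b = c("L1", "L2", "L3", "L4")))
  eig <- eigenvector_centrality(star)
  expect_equal(unname(eig["HUB"]), sqrt(0.5), tolerance = 1e-8)
  expect_equal(unname(eig["HUB"] / eig["L1"]), 2, tolerance = 1e-8)
  # max normalization rescales the hub to 1
  expect_equal(unname(eigenvector_centrality(star, "max")["HUB"]), 1)

  set.seed(99)
  for (rep in 1:5) {
    edges <- random_ppi_edges(30, 0.12)
    if (nrow(edges) == 0) next
    net <- make_net(edges)
    A <- adjacency_of(net)
    comp <- igraph::components(net$graph)
    big_id <- which.max(comp$csize)
    members <- sort(names(comp$membership[comp$membership == big_id]))
    sub <- A[members, members, drop = FALSE]
    ev <- eigen(sub, symmetric = TRUE)$vectors[, 1]
    ev <- abs(ev) / sqrt(sum(ev^2))
    got <- eigenvector_centrality(net)
    expect_equal(unname(got[members]), ev, tolerance = 1e-8)
    expect_true(all(got[setdiff(names(got), members)] == 0))
  }
})

test_that("centralities are invariant under node relabeling", {
  set.seed(5)
  edges <- random_ppi_edges(8, 0.45)
  net1 <- make_net(edges)
  # reverse-map labels
  relab <- setNames(sprintf("Z%02d", seq_along(sort(unique(c(edges$protein_a, edges$protein_b))))),
                    rev(sort(unique(c(edges$protein_a, edges$protein_b)))))
  edges2 <- data.frame(protein_a = relab[edges$protein_a],
                       protein_b = relab[edges$protein_b],
                       confidence = edges$confidence)
  net2 <- make_net(edges2)
  for (f in list(degree_centrality, betweenness_centrality,
                 eigenvector_centrality)) {
    v1 <- f(net1); v2 <- f(net2)
    expect_equal(as.vector(sort(round(v1, 10))),
                 as.vector(sort(round(v2, 10))))
    expect_equal(as.vector(v2[unname(relab[names(v1)])]), as.vector(v1),
                 tolerance = 1e-8)
  }
})

test_that("raising the confidence cutoff never grows the network", {
  set.seed(21)
  edges <- random_ppi_edges(20, 0.3)
  edges$confidence <- runif(nrow(edges), 0.5, 1)
  wl <- unique(c(edges$protein_a, edges$protein_b))
  prev_nodes <- Inf; prev_edges <- Inf
  for (cut in c(0.5, 0.7, 0.9, 0.95)) {
    net <- suppressWarnings(build_network(edges, wl, cutoff = cut))
    expect_lte(nrow(net$nodes), prev_nodes)
    expect_lte(nrow(net$edges), prev_edges)
    prev_nodes <- nrow(net$nodes); prev_edges <- nrow(net$edges)
  }
})

test_that("network summaries report overlap, tops and per-cell-type counts", {
  meta <- data.frame(gene = c("A", "B", "C"),
                     cell_type = c("cardiomyocytes", "cardiomyocytes",
                                   "adipocytes"))
  net <- build_network(data.frame(protein_a = c("A", "B"),
                                  protein_b = c("B", "C"),
                                  confidence = 0.95),
                       whitelist = c("A", "B", "C"), node_metadata = meta)
  summ <- network_summary(net, reference_proteome = c("A", "C", "ZZZ"))
  expect_equal(summ$n_nodes, 3)
  expect_equal(summ$n_edges, 2)
  expect_equal(summ$reference_overlap, 2)
  expect_equal(summ$reference_overlap_pct, 67)
  expect_equal(summ$top_betweenness[1], "B")
  expect_equal(unname(summ$nodes_per_cell_type["cardiomyocytes"]), 2L)

  expect_equal(overlap_percent(c("A", "B"), character())$percent, 0)
})
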