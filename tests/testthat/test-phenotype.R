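test_that("step distance is 1 - r on the open-closed unit interval", {
  expect_equal(step_distance(1), 0)
  expect_equal(step_distance(0.7), 0.3)
  expect_equal(step_distance(c(0.5, 1)), c(0.5, 0))
  expect_error(step_distance(0), "outside")
  expect_error(step_distance(1.1), "outside")
})

test_that("shortest causal paths sum step distances along directed edges", {
  net <- make_causal(c("A", "B"), c("B", "P"), c(0.7, 0.8))
  res <- shortest_causal_path(net, "A", "P")
  expect_equal(res$dpath, 0.5)
  expect_equal(res$n_steps, 2L)
  expect_equal(res$path, c("A", "B", "P"))

  # an indirect high-reliability route beats a direct weak edge
  net2 <- make_causal(c("A", "A", "B"), c("P", "B", "P"),
                      c(0.5, 0.9, 0.9))
  res2 <- shortest_causal_path(net2, "A", "P")
  expect_equal(res2$dpath, 0.2, tolerance = 1e-12)
  expect_equal(res2$path, c("A", "B", "P"))

  # direction matters: no backward traversal
  expect_false(shortest_causal_path(net, "P", "A")$reachable)

  # sign algebra along the optimum
  net3 <- make_causal(c("A", "B"), c("B", "P"), c(0.9, 0.9),
                      effect = c("up-regulates", "down-regulates"))
  expect_equal(shortest_causal_path(net3, "A", "P")$net_sign, -1L)

  expect_warning(self <- shortest_causal_path(net, "A", "A"), "zero-length")
  expect_equal(self$dpath, 0)
})

test_that("Dpath ties break on fewer steps then lexicographic node order", {
  # two routes of equal total distance 0.2: A->M->P (2 steps) vs
  # A->X->Y->P (3 steps, r chosen so both sum to 0.2)
  net <- make_causal(c("A", "M", "A", "X", "Y"),
                     c("M", "P", "X", "Y", "P"),
                     c(0.9, 0.9, 0.95, 0.95, 0.90))
  res <- shortest_causal_path(net, "A", "P")
  expect_equal(res$dpath, 0.2, tolerance = 1e-12)
  expect_equal(res$path, c("A", "M", "P"))

  # equal distance and steps: lexicographically smaller middle node wins
  net2 <- make_causal(c("A", "A", "B", "C"), c("B", "C", "P", "P"),
                      c(0.9, 0.9, 0.9, 0.9))
  expect_equal(shortest_causal_path(net2, "A", "P")$path, c("A", "B", "P"))
})

test_that("shortest paths match exhaustive simple-path enumeration", {
  set.seed(777)
  for (rep in 1:30) {
    g <- random_causal(sample(4:10, 1), 0.25)
    if (nrow(g$edges) == 0) next
    net <- make_causal(g$edges$from, g$edges$to, g$edges$reliability)
    present <- igraph::V(net$graph)$name
    ends <- sample(present, 2)
    oracle <- enum_min_dpath(g$W, match(ends[1], g$nodes),
                             match(ends[2], g$nodes))
    got <- shortest_causal_path(net, ends[1], ends[2])
    if (is.finite(oracle$dist)) {
      expect_equal(got$dpath, oracle$dist, tolerance = 1e-9)
      expect_equal(got$n_steps, oracle$steps)
    } else {
      expect_false(got$reachable)
    }
  }
})

test_that("Dpath is monotone under edge edits and satisfies the triangle inequality", {
  set.seed(31)
  g <- random_causal(8, 0.3)
  net <- make_causal(g$edges$from, g$edges$to, g$edges$reliability)
  nodes <- igraph::V(net$graph)$name
  d_of <- function(net, a, b) shortest_causal_path(net, a, b)$dpath

  # triangle inequality over all node triples present in the graph
  for (i in 1:15) {
    abc <- sample(nodes, 3)
    dab <- d_of(net, abc[1], abc[2]); dbc <- d_of(net, abc[2], abc[3])
    dac <- d_of(net, abc[1], abc[3])
    if (is.finite(dab) && is.finite(dbc)) {
      expect_lte(dac, dab + dbc + 1e-12)
    }
  }

  # adding an edge never increases any Dpath
  extra <- rbind(g$edges[, c("from", "to", "reliability")],
                 data.frame(from = nodes[1], to = nodes[2],
                            reliability = 0.99))
  net_plus <- make_causal(extra$from, extra$to, extra$reliability)
  for (i in 1:10) {
    ab <- sample(nodes, 2)
    expect_lte(d_of(net_plus, ab[1], ab[2]), d_of(net, ab[1], ab[2]) + 1e-12)
  }

  # removing an edge never decreases any Dpath
  less <- g$edges[-1, , drop = FALSE]
  kept <- unique(c(less$from, less$to))
  net_minus <- make_causal(less$from, less$to, less$reliability)
  for (i in 1:10) {
    ab <- sample(kept, 2)
    expect_gte(d_of(net_minus, ab[1], ab[2]) + 1e-12, d_of(net, ab[1], ab[2]))
  }

  # Dpath = 0 iff an all-r=1 chain exists
  perfect <- make_causal(c("A", "B"), c("B", "P"), c(1, 1))
  expect_equal(shortest_causal_path(perfect, "A", "P")$dpath, 0)
})

test_that("the distance matrix ranks phenotypes and flags missing proteins", {
  net <- make_causal(c("A", "A", "B"), c("P1", "P2", "P1"),
                     c(0.9, 0.6, 0.8), phenotypes = c("P1", "P2"))
  expect_warning(dm <- distance_matrix(net, c("A", "B", "GHOST")),
                 "absent")
  expect_equal(dm["A", "P1"], 0.1, tolerance = 1e-12)
  expect_equal(dm["A", "P2"], 0.4, tolerance = 1e-12)
  expect_false(is.finite(dm["B", "P2"]))
  expect_true(all(!is.finite(dm["GHOST", ])))
  means <- attr(dm, "phenotype_means")
  # P1 mean (0.1, 0.2) beats P2 mean (0.4): ascending ranking
  expect_equal(names(means)[1], "P1")
  expect_equal(unname(means["P1"]), 0.15, tolerance = 1e-12)
  expect_equal(attr(dm, "missing_proteins"), "GHOST")

  one <- make_causal("X", "P", 0.9, phenotypes = "P")
  dm1 <- distance_matrix(one, "X")
  expect_equal(unname(dm1[1, 1]), 0.1, tolerance = 1e-12)
})

test_that("prioritization applies the phenotype-count and ordering rules", {
  m <- rbind(ALL7 = c(1, 1, 1, 1, 1, 1, 0.6),
             FAST7 = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
             ONLY4 = c(1, 1, 1, 1, Inf, Inf, Inf),
             FIVE = c(2, 2, 2, 2, 2, Inf, Inf))
  colnames(m) <- paste0("P", 1:7)
  dm <- make_dm(m)
  pri <- prioritize_targets(dm, min_phenotypes = 5)
  expect_setequal(pri$protein, c("ALL7", "FAST7", "FIVE"))
  # both 7-phenotype proteins outrank the 5-phenotype one; the faster
  # mean distance wins within the tie
  expect_equal(pri$protein, c("FAST7", "ALL7", "FIVE"))

  # distance cap disqualifies slow paths
  pri2 <- prioritize_targets(dm, min_phenotypes = 5, dmax = 0.75)
  expect_equal(pri2$protein, "FAST7")

  # row order invariance
  dm_shuf <- make_dm(m[c(3, 1, 4, 2), ])
  expect_equal(prioritize_targets(dm_shuf, 5), pri)
})

test_that("phenotype comparisons Bonferroni-correct Welch tests with CIs", {
  set.seed(2024)
  n <- 30
  m <- cbind(A = rnorm(n, 1, 0.1), B = rnorm(n, 2, 0.1),
             C = rnorm(n, 1, 0.1))
  dm <- make_dm(m)
  res <- compare_phenotypes(dm)
  expect_equal(nrow(res), 3)
  expect_equal(attr(res, "m_comparisons"), 3)
  ab <- res[res$phenotype_a == "A" & res$phenotype_b == "B", ]
  expect_true(ab$significant)
  expect_true(ab$ci_hi < 0) # A sits a full unit below B
  ac <- res[res$phenotype_a == "A" & res$phenotype_b == "C", ]
  expect_false(ac$significant)
  expect_true(all(res$p_bonferroni >= res$p))
  expect_true(all(res$p_bonferroni <= 1))

  # identical distance vectors: zero mean difference, never significant
  same <- make_dm(cbind(X = c(1, 2, 3), Y = c(1, 2, 3)))
  res2 <- compare_phenotypes(same)
  expect_equal(res2$mean_diff, 0)
  expect_false(res2$significant)

  # a phenotype with < 2 reachable values is skipped with a warning
  sparse <- make_dm(cbind(X = c(1, 2, 3), Y = c(1, Inf, Inf)))
  expect_warning(res3 <- compare_phenotypes(sparse), "fewer than 2")
  expect_equal(nrow(res3), 0)

  # the rank-based alternative runs through the same interface
  res4 <- compare_phenotypes(dm, method = "wilcoxon")
  expect_true(res4$significant[res4$phenotype_a == "A" &
                                 res4$phenotype_b == "B"])
})

test_that("cell types are ranked by the mean distance of their proteins", {
  m <- rbind(p1 = c(1, 1), p2 = c(2, 2), p3 = c(2, 2), p4 = c(5, Inf))
  colnames(m) <- c("P1", "P2")
  dm <- make_dm(m)
  asn <- c(p1 = "mast cells", p2 = "fibroblasts", p3 = "fibroblasts",
           p4 = "pericytes")
  rank <- cell_type_distance(dm, asn)
  expect_equal(rank$cell_type, c("mast cells", "fibroblasts", "pericytes"))
  expect_equal(rank$mean_dpath, c(1, 2, 5))
  expect_equal(rank$rank, 1:3)

  # single-protein cell type equals that protein's mean distance
  expect_equal(rank$mean_dpath[rank$cell_type == "mast cells"], 1)

  # unassigned proteins are excluded with a message
  expect_message(rank2 <- cell_type_distance(dm, asn[1:3]), "excluding")
  expect_false("pericytes" %in% rank2$cell_type)
})
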