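# Independent brute-force oracles and tiny fixture builders. The oracles
# deliberately share no code with the implementation paths they check.

# --- fixture builders -------------------------------------------------------

make_profile <- function(values, dataset_id = "D1",
                         pct = NULL, n_nuclei = 1000L) {
  # values: genes x cell-types numeric matrix with dimnames
  df <- expand.grid(gene = rownames(values), cell_type = colnames(values),
                    stringsAsFactors = FALSE)
  df$mean_lognorm_expr <- values[cbind(df$gene, df$cell_type)]
  df$pct_expressing <- if (is.null(pct)) 75 else pct[cbind(df$gene, df$cell_type)]
  df$n_nuclei <- n_nuclei
  as_expression_profile(df, dataset_id)
}

make_ztable <- function(z, dataset = "D1", gene = "G1",
                        cell_type = NULL, pct = 75) {
  n <- length(z)
  out <- data.frame(
    dataset = dataset,
    gene = if (length(gene) == 1) rep(gene, n) else gene,
    cell_type = cell_type %||% paste0("ct", seq_len(n)),
    mean_lognorm_expr = 1, pct_expressing = pct,
    z = z, p = 2 * pnorm(-abs(z)), class = "ns",
    stringsAsFactors = FALSE)
  out$class[is.na(z)] <- "undefined"
  class(out) <- c("zscore_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_net <- function(edges, whitelist = NULL, cutoff = 0.9) {
  # edges: data.frame(protein_a, protein_b) or with confidence
  if (!"confidence" %in% names(edges)) edges$confidence <- 0.95
  build_network(edges,
                whitelist = whitelist %||%
                  unique(c(edges$protein_a, edges$protein_b)),
                cutoff = cutoff)
}

make_causal <- function(src, dst, r, effect = NULL, phenotypes = character()) {
  df <- data.frame(source = src, target = dst,
                   effect = effect %||% rep("up-regulates", length(src)),
                   reliability = r, stringsAsFactors = FALSE)
  attr(df, "phenotypes") <- phenotypes
  causal_network(df)
}

make_dm <- function(m) {
  structure(m, class = c("phenotype_distance_matrix", class(m)))
}

# --- brute-force oracles ----------------------------------------------------

# Hypergeometric upper tail by explicit enumeration of all C(N, n) draws.
enum_hypergeom <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K) # annotated genes are labelled 1..K
  mean(overlaps >= k)
}

# All simple paths between two nodes of an undirected graph given as an
# adjacency matrix; returns a list of integer node sequences.
enum_simple_paths <- function(A, s, t) {
  n <- nrow(A)
  paths <- list()
  walk <- function(v, seen, path) {
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (w in which(A[v, ] > 0)) {
      if (!seen[w]) {
        seen[w] <- TRUE
        walk(w, seen, c(path, w))
        seen[w] <- FALSE
      }
    }
  }
  seen <- rep(FALSE, n)
  seen[s] <- TRUE
  walk(s, seen, s)
  paths
}

# Betweenness by enumeration: for each unordered pair, find all shortest
# paths and award each interior node its fractional share.
enum_betweenness <- function(A) {
  n <- nrow(A)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      paths <- enum_simple_paths(A, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, 1L)
      shortest <- paths[lens == min(lens)]
      for (p in shortest) {
        interior <- setdiff(p, c(s, t))
        btw[interior] <- btw[interior] + 1 / length(shortest)
      }
    }
  }
  btw
}

# Minimum-weight directed simple path by exhaustive enumeration.
# W: n x n matrix of step distances, Inf where no edge.
enum_min_dpath <- function(W, s, t) {
  n <- nrow(W)
  best <- list(dist = Inf, steps = NA_integer_)
  walk <- function(v, seen, d, steps) {
    if (v == t) {
      if (d < best$dist - 1e-12 ||
          (abs(d - best$dist) <= 1e-12 && steps < best$steps)) {
        best <<- list(dist = d, steps = steps)
      }
      return(invisible())
    }
    for (w in which(is.finite(W[v, ]))) {
      if (!seen[w]) {
        seen[w] <- TRUE
        walk(w, seen, d + W[v, w], steps + 1L)
        seen[w] <- FALSE
      }
    }
  }
  seen <- rep(FALSE, n)
  seen[s] <- TRUE
  walk(s, seen, 0, 0L)
  best
}

# Random undirected graph as edge data frame over labelled nodes.
random_ppi_edges <- function(n, p, conf = 0.95) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  data.frame(protein_a = pairs[keep, 1], protein_b = pairs[keep, 2],
             confidence = conf, stringsAsFactors = FALSE)
}

adjacency_of <- function(net) {
  nodes <- sort(net$nodes$gene)
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$protein_a[i]; b <- net$edges$protein_b[i]
    A[a, b] <- 1; A[b, a] <- 1
  }
  A
}

# Random directed reliability-weighted graph; returns edges + weight matrix.
random_causal <- function(n, p, r_range = c(0.5, 1)) {
  nodes <- sprintf("N%02d", seq_len(n))
  grid <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$from != grid$to, ]
  keep <- runif(nrow(grid)) < p
  e <- grid[keep, , drop = FALSE]
  e$reliability <- runif(nrow(e), r_range[1], r_range[2])
  W <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  # parallel duplicates impossible here (each ordered pair drawn once)
  W[cbind(match(e$from, nodes), match(e$to, nodes))] <- 1 - e$reliability
  list(nodes = nodes, edges = e, W = W)
}
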