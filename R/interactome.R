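#' Build a confidence-filtered protein interaction network
#'
#' Keeps edges whose confidence is at least `cutoff` (inclusive, matching
#' the STRING convention that 0.9 is "highest confidence") and whose both
#' endpoints belong to the query whitelist (the integrated significant gene
#' set); self-loops are dropped, duplicate pairs are collapsed keeping the
#' maximum confidence, and nodes left without any edge are excluded from
#' the network.
#'
#' @param edges Confidence edge data frame (`protein_a`, `protein_b`,
#'   `confidence` on \[0, 1\]; see [read_confidence_edges()]).
#' @param whitelist Character vector of allowed protein symbols (non-empty).
#' @param cutoff Confidence cutoff (default 0.9, inclusive).
#' @param node_metadata Optional data frame with columns `gene` plus any of
#'   `cell_type`, `direction`, attached to surviving nodes.
#' @return An `interaction_network`: list with `graph` (undirected igraph),
#'   `nodes` (metadata data frame), `edges` (filtered edge list), `cutoff`.
#'   Zero surviving edges yields an empty network with a warning, not an
#'   error.
#' @export
build_network <- function(edges, whitelist, cutoff = 0.9,
                          node_metadata = NULL) {
  if (length(whitelist) == 0) stop("whitelist must be non-empty",
                                   call. = FALSE)
  check_range(edges$confidence, 0, 1, "confidence")
  df <- data.frame(protein_a = as.character(edges$protein_a),
                   protein_b = as.character(edges$protein_b),
                   confidence = edges$confidence, stringsAsFactors = FALSE)
  df <- df[df$confidence >= cutoff &
             df$protein_a %in% whitelist &
             df$protein_b %in% whitelist &
             df$protein_a != df$protein_b, , drop = FALSE]
  if (nrow(df) > 0) {
    # canonical unordered pair, keep max confidence across duplicates
    a <- pmin(df$protein_a, df$protein_b)
    b <- pmax(df$protein_a, df$protein_b)
    df <- data.frame(protein_a = a, protein_b = b,
                     confidence = df$confidence, stringsAsFactors = FALSE)
    df <- df[order(df$protein_a, df$protein_b, -df$confidence), ,
             drop = FALSE]
    df <- df[!duplicated(paste(df$protein_a, df$protein_b)), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    warning("no edge survives cutoff ", cutoff, " within the whitelist",
            call. = FALSE)
  }
  nodes <- sort(unique(c(df$protein_a, df$protein_b)))
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = if (length(nodes)) nodes)
  node_df <- data.frame(gene = nodes, stringsAsFactors = FALSE)
  if (!is.null(node_metadata)) {
    stopifnot("gene" %in% names(node_metadata))
    i <- match(node_df$gene, node_metadata$gene)
    for (col in setdiff(names(node_metadata), "gene")) {
      node_df[[col]] <- node_metadata[[col]][i]
    }
  }
  structure(list(graph = g, nodes = node_df, edges = df, cutoff = cutoff),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("<interaction_network>", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (confidence >=", x$cutoff, ")\n")
  invisible(x)
}

#' Degree centrality
#'
#' @param net An `interaction_network`.
#' @return Named integer vector: number of edges per node. The network mean
#'   equals `2 * E / N`.
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  deg <- igraph::degree(net$graph, loops = FALSE)
  deg[order(names(deg))]
}

#' Betweenness centrality
#'
#' Fraction of shortest paths passing through each node, summed over
#' unordered endpoint pairs excluding the node itself, with fractional
#' counting over equal-length shortest paths; raw (unnormalized) values,
#' computed per connected component. Paths are unweighted: interaction
#' confidence plays no role beyond the cutoff.
#'
#' @param net An `interaction_network`.
#' @return Named numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  btw <- igraph::betweenness(net$graph, directed = FALSE, weights = NA,
                             normalized = FALSE)
  btw[order(names(btw))]
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the adjacency structure of the largest
#' connected component, with nonnegative entries. Scaled to unit Euclidean
#' norm by default (consistent with per-node values an order of magnitude
#' below 1 on a ~150-node network); `normalization = "max"` rescales the
#' largest entry to 1 instead. Nodes outside the analyzed component get 0
#' and are flagged in the `outside_component` attribute.
#'
#' @param net An `interaction_network`.
#' @param normalization `"l2"` (default) or `"max"`.
#' @return Named numeric vector of eigenvector centralities.
#' @export
eigenvector_centrality <- function(net, normalization = c("l2", "max")) {
  stopifnot(inherits(net, "interaction_network"))
  normalization <- match.arg(normalization)
  g <- net$graph
  n <- igraph::vcount(g)
  out <- stats::setNames(numeric(n), igraph::V(g)$name)
  if (n == 0) return(out)
  comp <- igraph::components(g)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1) {
    # tie on component size: take the one holding the lexicographically
    # smallest node so results do not depend on vertex insertion order
    first_node <- vapply(big, function(ci)
      min(igraph::V(g)$name[comp$membership == ci]), "")
    big <- big[order(first_node)][1]
  }
  members <- igraph::V(g)$name[comp$membership == big]
  sub <- igraph::induced_subgraph(g, members)
  if (igraph::vcount(sub) == 1) {
    vec <- stats::setNames(1, members)
  } else {
    A <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
    vec <- stats::setNames(power_eigenvector(A), rownames(A))[members]
  }
  vec <- switch(normalization,
                l2 = vec / sqrt(sum(vec^2)),
                max = vec / max(vec))
  out[names(vec)] <- vec
  out <- out[order(names(out))]
  attr(out, "outside_component") <- setdiff(igraph::V(g)$name, members)
  out
}

# Principal eigenvector of a connected nonnegative adjacency matrix by
# power iteration on A + I (the identity shift keeps the spectrum
# positive, so the iteration cannot oscillate on bipartite components,
# while leaving the eigenvectors unchanged). The fixed uniform start
# vector makes the result fully deterministic.
power_eigenvector <- function(A, tol = 1e-13, max_iter = 100000L) {
  n <- nrow(A)
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    w <- as.vector(A %*% v) + v
    w <- w / sqrt(sum(w^2))
    if (sqrt(sum((w - v)^2)) < tol) {
      lambda <- sum(w * (A %*% w))
      resid <- sqrt(sum((as.vector(A %*% w) - lambda * w)^2))
      return(abs(w))
    }
    v <- w
  }
  lambda <- sum(v * (A %*% v))
  resid <- sqrt(sum((as.vector(A %*% v) - lambda * v)^2))
  stop("eigenvector centrality failed to converge after ", max_iter,
       " iterations (residual ", format(resid, digits = 3), ")",
       call. = FALSE)
}

#' Centrality table of an interaction network
#'
#' @param net An `interaction_network`.
#' @param normalization Eigenvector scaling, see
#'   [eigenvector_centrality()].
#' @return Data frame (`node`, `degree`, `betweenness`, `eigenvector`, plus
#'   node metadata columns) with attribute `means` holding the network mean
#'   of each centrality (over all nodes).
#' @export
centrality_table <- function(net, normalization = "l2") {
  deg <- degree_centrality(net)
  btw <- betweenness_centrality(net)
  eig <- eigenvector_centrality(net, normalization)
  out <- data.frame(node = names(deg), degree = as.integer(deg),
                    betweenness = unname(btw[names(deg)]),
                    eigenvector = unname(eig[names(deg)]),
                    stringsAsFactors = FALSE)
  meta_cols <- setdiff(names(net$nodes), "gene")
  if (length(meta_cols) > 0) {
    i <- match(out$node, net$nodes$gene)
    for (col in meta_cols) out[[col]] <- net$nodes[[col]][i]
  }
  attr(out, "means") <- c(degree = mean(out$degree),
                          betweenness = mean(out$betweenness),
                          eigenvector = mean(out$eigenvector))
  out
}

#' Overlap of a gene set with a reference set
#'
#' @param genes Character vector (e.g. network nodes or prioritized
#'   targets).
#' @param reference Character reference set (e.g. a tissue-specific
#'   proteome, or externally validated genes).
#' @return List with `count` (overlap size) and `percent` (share of
#'   `genes`, rounded to the nearest integer percent; 0 for an empty input).
#' @export
overlap_percent <- function(genes, reference) {
  genes <- unique(as.character(genes))
  count <- length(intersect(genes, unique(as.character(reference))))
  pct <- if (length(genes) == 0) 0 else round(100 * count / length(genes))
  list(count = count, percent = pct)
}

#' Network-level summary with proteome-overlap validation
#'
#' @param net An `interaction_network`.
#' @param centralities Optional precomputed [centrality_table()]; computed
#'   on the fly when `NULL`.
#' @param reference_proteome Character vector of a reference proteome
#'   (e.g. tissue-specific proteins) for overlap validation.
#' @return List: node and edge counts, mean of each centrality, top 3 nodes
#'   per centrality (ties broken lexicographically), node counts per
#'   primary cell type (when node metadata carries `cell_type`), and the
#'   reference overlap count and integer percentage.
#' @export
network_summary <- function(net, centralities = NULL,
                            reference_proteome = character()) {
  stopifnot(inherits(net, "interaction_network"))
  ct <- centralities %||% centrality_table(net)
  top3 <- function(v) {
    ord <- order(-v, ct$node)
    ct$node[utils::head(ord, 3)]
  }
  by_cell_type <- NULL
  if ("cell_type" %in% names(ct)) {
    tab <- table(ct$cell_type)
    by_cell_type <- sort(tab, decreasing = TRUE)
  }
  ov <- overlap_percent(ct$node, reference_proteome)
  list(
    n_nodes = nrow(ct),
    n_edges = nrow(net$edges),
    mean_degree = mean(ct$degree),
    mean_betweenness = mean(ct$betweenness),
    mean_eigenvector = mean(ct$eigenvector),
    top_degree = top3(ct$degree),
    top_betweenness = top3(ct$betweenness),
    top_eigenvector = top3(ct$eigenvector),
    nodes_per_cell_type = by_cell_type,
    reference_overlap = ov$count,
    reference_overlap_pct = ov$percent
  )
}
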