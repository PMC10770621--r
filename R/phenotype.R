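#' Convert a reliability score to a step distance
#'
#' Each causal step carries a reliability score `r` in (0, 1\] summarizing
#' its supporting evidence; the corresponding step distance is `d = 1 - r`,
#' so perfectly supported steps are free and weakly supported steps are
#' long.
#'
#' @param r Numeric reliability score(s) in (0, 1\].
#' @return `1 - r`; values outside (0, 1\] are a hard error.
#' @export
#' @examples
#' step_distance(0.7) # 0.3
step_distance <- function(r) {
  check_range(r, 0, 1, "reliability r", lo_open = TRUE)
  1 - r
}

#' Build a directed signed causal network
#'
#' @param edges Data frame with columns `source`, `target`, `effect`
#'   (`up-regulates` / `down-regulates`), `reliability` in (0, 1\] (see
#'   [read_causal_edges()]).
#' @param phenotypes Character vector of phenotype node labels; defaults to
#'   the `phenotypes` attribute of `edges`, falling back to
#'   [cvd_phenotypes()]. Phenotype nodes absent from the edge list are kept
#'   in the declared list but will be unreachable.
#' @return A `causal_network`: list with `graph` (directed igraph whose
#'   edges carry `sign` (+1/-1), `reliability`, and `dist = 1 -
#'   reliability`), `phenotypes`, and `edges`. Phenotype nodes with
#'   outgoing edges are flagged with a warning (not an error).
#' @export
causal_network <- function(edges, phenotypes = NULL) {
  phenotypes <- phenotypes %||% attr(edges, "phenotypes") %||%
    cvd_phenotypes()
  bad <- setdiff(unique(edges$effect), CAUSAL_EFFECTS)
  if (length(bad) > 0) {
    stop("unknown causal effect token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  check_range(edges$reliability, 0, 1, "reliability", lo_open = TRUE)
  df <- data.frame(from = as.character(edges$source),
                   to = as.character(edges$target),
                   sign = ifelse(edges$effect == "up-regulates", 1L, -1L),
                   reliability = edges$reliability,
                   dist = step_distance(edges$reliability),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df, directed = TRUE)
  out_deg <- igraph::degree(g, mode = "out")
  ph_in <- intersect(phenotypes, names(out_deg))
  leaky <- ph_in[out_deg[ph_in] > 0]
  if (length(leaky) > 0) {
    warning("phenotype node(s) with outgoing edges: ",
            paste(leaky, collapse = ", "), call. = FALSE)
  }
  structure(list(graph = g, phenotypes = phenotypes, edges = df),
            class = "causal_network")
}

#' @export
print.causal_network <- function(x, ...) {
  cat("<causal_network>", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "signed edges,",
      length(x$phenotypes), "phenotype nodes\n")
  invisible(x)
}

# Dijkstra over step distances with deterministic tie-breaking:
# minimize (total distance, number of steps, lexicographic node sequence).
# All step distances are nonnegative and each step adds one to the count,
# so the tuple strictly increases along any extension and the greedy
# settle-the-minimum argument applies unchanged. Distances within `tol`
# are treated as tied.
dijkstra_tiebreak <- function(adj, node_names, src_i, tol = 1e-12) {
  n <- length(node_names)
  dist <- rep(Inf, n)
  steps <- rep(Inf, n)
  paths <- vector("list", n)
  done <- rep(FALSE, n)
  dist[src_i] <- 0
  steps[src_i] <- 0
  paths[[src_i]] <- src_i
  lex_less <- function(p1, p2) {
    # same length by construction (equal step counts)
    s1 <- node_names[p1]; s2 <- node_names[p2]
    i <- which(s1 != s2)
    if (length(i) == 0) FALSE else s1[i[1]] < s2[i[1]]
  }
  better <- function(d1, s1, p1, d2, s2, p2) {
    if (d1 < d2 - tol) return(TRUE)
    if (d1 > d2 + tol) return(FALSE)
    if (s1 != s2) return(s1 < s2)
    lex_less(p1, p2)
  }
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[1]
    for (v in cand[-1]) {
      if (better(dist[v], steps[v], paths[[v]], dist[u], steps[u],
                 paths[[u]])) u <- v
    }
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (j in seq_len(nrow(nb))) {
      v <- nb$to[j]
      if (done[v]) next
      nd <- dist[u] + nb$dist[j]
      ns <- steps[u] + 1
      np <- c(paths[[u]], v)
      if (!is.finite(dist[v]) ||
          better(nd, ns, np, dist[v], steps[v], paths[[v]])) {
        dist[v] <- nd
        steps[v] <- ns
        paths[[v]] <- np
      }
    }
  }
  list(dist = dist, steps = steps, paths = paths)
}

# adjacency list representation used by the path search
causal_adjacency <- function(net) {
  node_names <- igraph::V(net$graph)$name
  el <- net$edges
  from_i <- match(el$from, node_names)
  to_i <- match(el$to, node_names)
  adj <- vector("list", length(node_names))
  for (grp in split(seq_len(nrow(el)), from_i)) {
    u <- from_i[grp[1]]
    adj[[u]] <- data.frame(to = to_i[grp], dist = el$dist[grp],
                           sign = el$sign[grp])
  }
  list(adj = adj, node_names = node_names, edges = el,
       from_i = from_i, to_i = to_i)
}

#' Shortest reliability-weighted causal path to a phenotype
#'
#' Finds the directed path minimizing the cumulative distance
#' `Dpath = sum(1 - r)` over its steps, following edge direction only
#' (the active-flow causal model); regulation signs annotate the path but
#' never constrain the optimum, since both positive and negative regulation
#' of a phenotype count. Ties on Dpath are broken by fewer steps, then by
#' the lexicographically smallest node sequence, so the returned path is
#' deterministic.
#'
#' @param net A `causal_network`.
#' @param source Source protein symbol (must be a network node).
#' @param phenotype Target phenotype node label (must be a network node).
#' @return A `path_result` list: `source`, `phenotype`, `dpath` (`Inf` when
#'   unreachable), `n_steps`, `path` (node sequence), `net_sign` (product
#'   of step signs, `NA` when unreachable), `reachable`. A query with
#'   `source == phenotype` returns `dpath = 0` with an empty path and a
#'   warning.
#' @export
shortest_causal_path <- function(net, source, phenotype) {
  stopifnot(inherits(net, "causal_network"))
  ca <- causal_adjacency(net)
  src_i <- match(source, ca$node_names)
  dst_i <- match(phenotype, ca$node_names)
  if (is.na(src_i)) stop("source ", source, " not in network", call. = FALSE)
  if (is.na(dst_i)) stop("phenotype ", phenotype, " not in network",
                         call. = FALSE)
  if (src_i == dst_i) {
    warning("source equals phenotype; zero-length path", call. = FALSE)
    return(structure(list(source = source, phenotype = phenotype,
                          dpath = 0, n_steps = 0L, path = character(),
                          net_sign = 1L, reachable = TRUE),
                     class = "path_result"))
  }
  res <- dijkstra_tiebreak(ca$adj, ca$node_names, src_i)
  build_path_result(source, phenotype, res, dst_i, ca)
}

build_path_result <- function(source, phenotype, res, dst_i, ca) {
  if (!is.finite(res$dist[dst_i])) {
    return(structure(list(source = source, phenotype = phenotype,
                          dpath = Inf, n_steps = NA_integer_,
                          path = character(), net_sign = NA_integer_,
                          reachable = FALSE),
                     class = "path_result"))
  }
  p <- res$paths[[dst_i]]
  sgn <- 1L
  for (j in seq_len(length(p) - 1)) {
    # sign of the minimum-distance parallel edge used on this step
    hit <- which(ca$from_i == p[j] & ca$to_i == p[j + 1])
    hit <- hit[which.min(ca$edges$dist[hit])]
    sgn <- sgn * ca$edges$sign[hit]
  }
  structure(list(source = source, phenotype = phenotype,
                 dpath = res$dist[dst_i],
                 n_steps = as.integer(res$steps[dst_i]),
                 path = ca$node_names[p], net_sign = sgn, reachable = TRUE),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  if (x$reachable) {
    cat(sprintf("<path_result> %s -> %s : Dpath = %.4g over %d step(s), net sign %+d\n  %s\n",
                x$source, x$phenotype, x$dpath, x$n_steps, x$net_sign,
                paste(x$path, collapse = " -> ")))
  } else {
    cat("<path_result>", x$source, "->", x$phenotype, ": UNREACHABLE\n")
  }
  invisible(x)
}

#' Protein-by-phenotype shortest-distance matrix
#'
#' Runs one shortest-path query per (protein, phenotype) pair, sharing a
#' single-source search per protein. Unreachable pairs are `Inf` and are
#' excluded from all means.
#'
#' @param net A `causal_network`.
#' @param proteins Character vector of source proteins. Proteins absent
#'   from the network yield all-`Inf` rows and are reported in the
#'   `missing_proteins` attribute (with a warning).
#' @param phenotypes Phenotype node labels (default: the network's declared
#'   list).
#' @return A `phenotype_distance_matrix`: numeric matrix (proteins x
#'   phenotypes) of Dpath values with attributes `steps` and `sign`
#'   (matching matrices), `phenotype_means` (per-phenotype mean over
#'   reachable entries, ascending order = ranking), and
#'   `missing_proteins`.
#' @export
distance_matrix <- function(net, proteins, phenotypes = NULL) {
  stopifnot(inherits(net, "causal_network"))
  phenotypes <- phenotypes %||% net$phenotypes
  proteins <- unique(as.character(proteins))
  ca <- causal_adjacency(net)
  missing <- setdiff(proteins, ca$node_names)
  if (length(missing) > 0) {
    warning(length(missing), " protein(s) absent from the causal network: ",
            paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  ph_i <- match(phenotypes, ca$node_names)
  m <- matrix(Inf, length(proteins), length(phenotypes),
              dimnames = list(proteins, phenotypes))
  msteps <- matrix(NA_integer_, length(proteins), length(phenotypes),
                   dimnames = dimnames(m))
  msign <- matrix(NA_integer_, length(proteins), length(phenotypes),
                  dimnames = dimnames(m))
  for (pr in proteins) {
    src_i <- match(pr, ca$node_names)
    if (is.na(src_i)) next
    res <- dijkstra_tiebreak(ca$adj, ca$node_names, src_i)
    for (k in seq_along(phenotypes)) {
      if (is.na(ph_i[k])) next
      pres <- build_path_result(pr, phenotypes[k], res, ph_i[k], ca)
      m[pr, k] <- pres$dpath
      msteps[pr, k] <- pres$n_steps
      msign[pr, k] <- pres$net_sign
    }
  }
  means <- apply(m, 2, function(col) {
    r <- col[is.finite(col)]
    if (length(r) == 0) NA_real_ else mean(r)
  })
  structure(m, steps = msteps, sign = msign,
            phenotype_means = sort(means, na.last = TRUE),
            missing_proteins = missing,
            class = c("phenotype_distance_matrix", class(m)))
}

#' Prioritize multi-phenotype proteins
#'
#' A protein qualifies for a phenotype when its Dpath is at most `dmax`
#' (default: any finite Dpath, i.e. reachability). Proteins qualifying for
#' at least `min_phenotypes` phenotypes form the prioritized set, ranked by
#' descending phenotype count, then ascending mean Dpath over reachable
#' phenotypes, then name.
#'
#' @param dm A `phenotype_distance_matrix`.
#' @param min_phenotypes Minimum number of qualifying phenotypes
#'   (default 5).
#' @param dmax Distance cap for qualification (default `Inf`).
#' @return Data frame (`protein`, `n_phenotypes`, `mean_dpath`, `rank`)
#'   restricted to prioritized proteins; invariant to the row order of the
#'   input matrix.
#' @export
prioritize_targets <- function(dm, min_phenotypes = 5, dmax = Inf) {
  stopifnot(inherits(dm, "phenotype_distance_matrix"))
  qual <- is.finite(dm) & dm <= dmax
  n_ph <- rowSums(qual)
  mean_d <- apply(unclass(dm), 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f) == 0) NA_real_ else mean(f)
  })
  keep <- which(n_ph >= min_phenotypes)
  out <- data.frame(protein = rownames(dm)[keep],
                    n_phenotypes = as.integer(n_ph[keep]),
                    mean_dpath = unname(mean_d[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_phenotypes, out$mean_dpath, out$protein), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Pairwise comparison of phenotype distance distributions
#'
#' All pairwise two-sample location tests on the reachable Dpath values of
#' each phenotype, Bonferroni-corrected over `m = choose(P, 2)` pairs
#' (P = number of phenotypes in the matrix), with a 95 percent confidence
#' interval for the mean difference. Welch's unequal-variance t-test by
#' default; `method = "wilcoxon"` swaps in the Mann-Whitney test (with its
#' location-shift interval).
#'
#' @param dm A `phenotype_distance_matrix` with at least two phenotypes.
#' @param alpha Familywise significance level (default 0.001).
#' @param method `"welch"` (default) or `"wilcoxon"`.
#' @return Data frame per pair: `phenotype_a`, `phenotype_b`, `mean_diff`,
#'   `statistic`, `p`, `p_bonferroni` (`p * m` capped at 1), `significant`,
#'   `ci_lo`, `ci_hi`. Pairs involving a phenotype with fewer than two
#'   reachable values are skipped with a warning.
#' @export
compare_phenotypes <- function(dm, alpha = 0.001,
                               method = c("welch", "wilcoxon")) {
  stopifnot(inherits(dm, "phenotype_distance_matrix"))
  method <- match.arg(method)
  phenos <- colnames(dm)
  if (length(phenos) < 2) stop("need at least 2 phenotypes", call. = FALSE)
  vals <- lapply(phenos, function(p) {
    v <- dm[, p]
    v[is.finite(v)]
  })
  names(vals) <- phenos
  m <- choose(length(phenos), 2)
  pairs <- utils::combn(phenos, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    xa <- vals[[a]]; xb <- vals[[b]]
    if (length(xa) < 2 || length(xb) < 2) {
      warning("skipping pair ", a, " vs ", b,
              ": fewer than 2 reachable values", call. = FALSE)
      return(NULL)
    }
    if (method == "welch") {
      if (stats::sd(xa) == 0 && stats::sd(xb) == 0 && mean(xa) == mean(xb)) {
        # t.test errors on two identical constant samples; the null
        # is trivially not rejected
        tt <- list(statistic = c(t = 0), p.value = 1, conf.int = c(0, 0))
      } else {
        tt <- stats::t.test(xa, xb, conf.level = 0.95)
      }
    } else {
      tt <- stats::wilcox.test(xa, xb, conf.int = TRUE, conf.level = 0.95,
                               exact = FALSE)
    }
    data.frame(phenotype_a = a, phenotype_b = b,
               mean_diff = mean(xa) - mean(xb),
               statistic = unname(tt$statistic),
               p = tt$p.value,
               p_bonferroni = min(1, tt$p.value * m),
               significant = min(1, tt$p.value * m) < alpha,
               ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(phenotype_a = character(), phenotype_b = character(),
                      mean_diff = numeric(), statistic = numeric(),
                      p = numeric(), p_bonferroni = numeric(),
                      significant = logical(), ci_lo = numeric(),
                      ci_hi = numeric(), stringsAsFactors = FALSE)
  }
  attr(out, "m_comparisons") <- m
  out
}

#' Rank cell types by mean causal distance to phenotypes
#'
#' Each protein is reduced to the mean of its reachable phenotype
#' distances; cell types are then scored by the mean over their assigned
#' proteins and ranked ascending (shortest first).
#'
#' @param dm A `phenotype_distance_matrix`.
#' @param cell_type_assignment Named character vector mapping protein
#'   symbol to primary cell type. Proteins without an assignment (or with
#'   no reachable phenotype) are excluded and reported via a message.
#' @return Data frame (`cell_type`, `mean_dpath`, `n_proteins`, `rank`)
#'   sorted ascending by mean distance.
#' @export
cell_type_distance <- function(dm, cell_type_assignment) {
  stopifnot(inherits(dm, "phenotype_distance_matrix"))
  prot_mean <- apply(unclass(dm), 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f) == 0) NA_real_ else mean(f)
  })
  ct <- cell_type_assignment[rownames(dm)]
  drop <- is.na(ct) | is.na(prot_mean)
  if (any(drop)) {
    message("excluding ", sum(drop),
            " protein(s) without assignment or reachable phenotype")
  }
  ct <- ct[!drop]; prot_mean <- prot_mean[!drop]
  if (length(ct) == 0) {
    return(data.frame(cell_type = character(), mean_dpath = numeric(),
                      n_proteins = integer(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  agg <- aggregate(prot_mean, by = list(cell_type = unname(ct)), mean)
  names(agg)[2] <- "mean_dpath"
  cnt <- table(unname(ct))
  agg$n_proteins <- as.integer(cnt[agg$cell_type])
  agg <- agg[order(agg$mean_dpath, agg$cell_type), , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  agg
}
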