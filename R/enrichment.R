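#' Cumulative hypergeometric upper-tail probability
#'
#' The over-representation p-value: the probability of observing `k` or
#' more annotated genes in a query of size `n` drawn without replacement
#' from a universe of `N` genes of which `K` carry the annotation,
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Evaluated exactly through
#' the log-space hypergeometric CDF of [stats::phyper()].
#'
#' @param k Observed overlap, `0 <= k <= min(K, n)`.
#' @param K Term size within the universe.
#' @param n Effective query size.
#' @param N Universe size (annotated genes of the source).
#' @return The upper-tail probability; `1` when `k = 0`.
#' @export
#' @examples
#' hypergeom_upper_tail(4, K = 5, n = 4, N = 10) # 5/210
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (anyNA(c(k, K, n, N)) || any(c(k, K, n, N) < 0) ||
      any(c(k, K, n, N) != round(c(k, K, n, N)))) {
    stop("k, K, n, N must be non-negative integers", call. = FALSE)
  }
  if (K > N || n > N) {
    stop("term size K and query size n must not exceed universe size N",
         call. = FALSE)
  }
  if (k > min(K, n)) {
    stop("overlap k = ", k, " exceeds min(K, n) = ", min(K, n),
         call. = FALSE)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR q-values
#'
#' Step-up adjustment: on the ascending order of p-values,
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, returned in the input
#' order (delegated to [stats::p.adjust()] after domain validation).
#'
#' @param pvalues Numeric vector of p-values in (0, 1\].
#' @return q-values in input order; always `>=` the corresponding p and
#'   monotone non-decreasing along ascending p.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  check_range(pvalues, 0, 1, "p-values", lo_open = TRUE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis against annotation databases
#'
#' Tests each annotation term for enrichment in a gene query with the
#' cumulative hypergeometric test. Following standard over-representation
#' practice, only genes with at least one annotation in a source count: the
#' effective query is the query intersected with that source's universe,
#' and query genes outside the universe are dropped (and reported). Terms
#' with zero overlap are not tested (they cannot be enriched and would only
#' inflate the correction burden); this is configurable. BH correction is
#' applied within each source separately by default, mirroring per-source
#' result blocks of multi-database enrichment tools; set
#' `pool_sources = TRUE` to correct across all sources jointly.
#'
#' @param query Character vector of gene symbols.
#' @param db An `annotation_db` or a list of them.
#' @param q_max Significance threshold on the BH q-value (default 0.001).
#' @param test_zero_overlap Include k = 0 terms in the tested family
#'   (default FALSE).
#' @param pool_sources Apply BH across sources jointly (default FALSE).
#' @return Data frame of enrichment records sorted by q then term id:
#'   `source`, `term_id`, `description`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `significant`, `overlap_genes`. Attribute `unannotated` lists query
#'   genes absent from each source's universe. An empty query/universe
#'   intersection yields an empty result with a warning.
#' @export
enrich <- function(query, db, q_max = 0.001, test_zero_overlap = FALSE,
                   pool_sources = FALSE) {
  if (inherits(db, "annotation_db")) db <- list(db)
  stopifnot(all(vapply(db, inherits, TRUE, "annotation_db")))
  query <- unique(as.character(query))
  if (length(query) == 0) stop("empty query", call. = FALSE)

  unannotated <- list()
  blocks <- lapply(db, function(d) {
    universe <- db_universe(d)
    eff_query <- intersect(query, universe)
    unannotated[[d$source]] <<- setdiff(query, universe)
    if (length(eff_query) == 0) {
      warning("query has no annotated gene in source ", d$source,
              call. = FALSE)
      return(NULL)
    }
    N <- length(universe)
    n <- length(eff_query)
    rows <- lapply(names(d$terms), function(tid) {
      genes <- d$terms[[tid]]
      ov <- intersect(eff_query, genes)
      k <- length(ov)
      if (k == 0 && !test_zero_overlap) return(NULL)
      data.frame(source = d$source, term_id = tid,
                 description = unname(d$descriptions[[tid]]),
                 k = k, K = length(genes), n = n, N = N,
                 p = hypergeom_upper_tail(k, length(genes), n, N),
                 overlap_genes = paste(sort(ov), collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, blocks)
  if (is.null(out) || nrow(out) == 0) {
    out <- data.frame(source = character(), term_id = character(),
                      description = character(), k = integer(),
                      K = integer(), n = integer(), N = integer(),
                      p = numeric(), q = numeric(), significant = logical(),
                      overlap_genes = character(), stringsAsFactors = FALSE)
    attr(out, "unannotated") <- unannotated
    return(out)
  }
  if (pool_sources) {
    out$q <- bh_fdr(out$p)
  } else {
    out$q <- stats::ave(out$p, out$source, FUN = bh_fdr)
  }
  out$significant <- out$q < q_max
  out <- out[order(out$q, out$term_id), ,
             drop = FALSE][, c("source", "term_id", "description", "k", "K",
                               "n", "N", "p", "q", "significant",
                               "overlap_genes")]
  rownames(out) <- NULL
  attr(out, "unannotated") <- unannotated
  out
}
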