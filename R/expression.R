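#' Per-cell-type expression Z-scores within one dataset
#'
#' For each gene, its expression in every cell type is standardized against
#' that gene's own mean and standard deviation across all cell types of the
#' dataset: `z = (x - mean) / sd`. Two-tailed p-values come from the
#' standard normal applied to z.
#'
#' The SD is the population SD (divide by the number of cell types) by
#' default: the cell-type profiles of a dataset are the complete population
#' being standardized, not a sample from a larger one, and the population
#' form makes the two-cell-type case exactly z = (-1, +1).
#'
#' @param profile An `expression_profile` (see
#'   [read_expression_profiles()]); every gene must be measured in at least
#'   two cell types.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A `zscore_table` data frame: `dataset`, `gene`, `cell_type`,
#'   `mean_lognorm_expr`, `pct_expressing`, `z`, `p`, `class`. Classes start
#'   as `"ns"`; genes constant across cell types (SD = 0) get `z = NA` and
#'   class `"undefined"` with a warning, never an exception.
#' @seealso [classify_genes()], [significant_genes()]
#' @export
compute_zscores <- function(profile, sd_type = c("population", "sample")) {
  stopifnot(inherits(profile, "expression_profile"))
  sd_type <- match.arg(sd_type)
  df <- as.data.frame(profile)
  n_ct <- length(unique(df$cell_type))
  if (n_ct < 2) {
    stop("need at least 2 cell types to standardize, got ", n_ct,
         call. = FALSE)
  }
  # genes x cell types matrix; profile validation guarantees a full grid
  mat <- tapply(df$mean_lognorm_expr, list(df$gene, df$cell_type), identity)
  mu <- rowMeans(mat)
  dev <- mat - mu
  denom <- if (sd_type == "population") n_ct else n_ct - 1
  sd_g <- sqrt(rowSums(dev^2) / denom)
  z_mat <- dev / sd_g
  z_mat[sd_g == 0, ] <- NA_real_
  n_const <- sum(sd_g == 0)
  if (n_const > 0) {
    warning(n_const, " gene(s) constant across cell types; Z undefined",
            call. = FALSE)
  }
  idx <- cbind(match(df$gene, rownames(mat)),
               match(df$cell_type, colnames(mat)))
  out <- data.frame(
    dataset = attr(profile, "dataset_id"),
    gene = df$gene,
    cell_type = df$cell_type,
    mean_lognorm_expr = df$mean_lognorm_expr,
    pct_expressing = df$pct_expressing,
    z = z_mat[idx],
    stringsAsFactors = FALSE
  )
  out$p <- 2 * stats::pnorm(-abs(out$z))
  out$class <- ifelse(is.na(out$z), "undefined", "ns")
  class(out) <- c("zscore_table", "data.frame")
  out
}

#' Classify significant over- and under-expression
#'
#' A (gene, cell type) entry is `over` iff `z >= z_hi` and `p <= p_max`,
#' and `under` iff `z <= z_lo` and `p <= p_max`. With the default
#' thresholds the conjunction is binding through the p rule
#' (`p <= 0.001` is `|z| >= 3.29`), which is stricter than `|z| >= 2`
#' alone; both thresholds are kept explicit and configurable rather than
#' silently merged.
#'
#' @param ztable A `zscore_table` from [compute_zscores()].
#' @param z_hi Over-expression Z threshold (default 2).
#' @param z_lo Under-expression Z threshold (default -2).
#' @param p_max Two-tailed p-value threshold (default 0.001).
#' @return The table with `class` set to `over`, `under`, `ns`, or
#'   `undefined` (constant genes are never reclassified).
#' @export
classify_genes <- function(ztable, z_hi = 2, z_lo = -2, p_max = 0.001) {
  stopifnot(inherits(ztable, "zscore_table"))
  stopifnot(z_hi > z_lo, p_max > 0, p_max <= 1)
  cls <- rep("ns", nrow(ztable))
  cls[!is.na(ztable$z) & ztable$z >= z_hi & ztable$p <= p_max] <- "over"
  cls[!is.na(ztable$z) & ztable$z <= z_lo & ztable$p <= p_max] <- "under"
  cls[is.na(ztable$z)] <- "undefined"
  ztable$class <- cls
  ztable
}

#' Collapse a classified Z-score table to its significant gene set
#'
#' A gene is significant in a dataset if it is significantly over- or
#' under-expressed in at least one cell type. A gene over-expressed in one
#' cell type and under-expressed in another within the same dataset gets
#' direction `"mixed"`.
#'
#' @param ztable A classified `zscore_table`.
#' @return A `gene_signature` data frame: `gene`, `direction`
#'   (`over`/`under`/`mixed`), `cell_types` (significant cell types,
#'   `;`-separated), with attribute `dataset_id`.
#' @export
significant_genes <- function(ztable) {
  stopifnot(inherits(ztable, "zscore_table"))
  sig <- ztable[ztable$class %in% c("over", "under"), , drop = FALSE]
  if (nrow(sig) == 0) {
    out <- data.frame(gene = character(), direction = character(),
                      cell_types = character(), stringsAsFactors = FALSE)
  } else {
    genes <- sort(unique(sig$gene))
    direction <- vapply(genes, function(g) {
      d <- unique(sig$class[sig$gene == g])
      if (length(d) > 1) "mixed" else d
    }, "")
    cell_types <- vapply(genes, function(g) {
      paste(sort(unique(sig$cell_type[sig$gene == g])), collapse = ";")
    }, "")
    out <- data.frame(gene = genes, direction = unname(direction),
                      cell_types = unname(cell_types),
                      stringsAsFactors = FALSE)
  }
  attr(out, "dataset_id") <- ztable$dataset[1]
  class(out) <- c("gene_signature", "data.frame")
  out
}

#' Intersect per-dataset significant gene sets
#'
#' Keeps genes significant (in any cell type, either direction) in every
#' dataset. With `require_consistent_direction = TRUE` (default), genes
#' whose direction disagrees between datasets are excluded and reported in
#' the `dropped_inconsistent` attribute; with `FALSE` they are retained
#' with direction `"mixed"`.
#'
#' @param sets List of two or more `gene_signature` objects (one per
#'   dataset).
#' @param require_consistent_direction Logical flag; see above.
#' @return A `gene_signature` with `dataset_id = "integrated"`.
#' @export
intersect_datasets <- function(sets, require_consistent_direction = TRUE) {
  if (length(sets) == 0) stop("empty list of gene sets", call. = FALSE)
  if (length(sets) < 2) stop("need at least 2 datasets to intersect",
                             call. = FALSE)
  stopifnot(all(vapply(sets, inherits, TRUE, "gene_signature")))
  common <- Reduce(intersect, lapply(sets, function(s) s$gene))
  common <- sort(common)
  dir_of <- function(s, g) s$direction[match(g, s$gene)]
  direction <- vapply(common, function(g) {
    d <- unique(vapply(sets, dir_of, "", g))
    if (length(d) == 1 && d != "mixed") d else "mixed"
  }, "")
  dropped <- character()
  if (require_consistent_direction && length(common) > 0) {
    dropped <- common[direction == "mixed"]
    if (length(dropped) > 0) {
      message("dropping ", length(dropped),
              " gene(s) with inconsistent direction across datasets: ",
              paste(utils::head(dropped, 10), collapse = ", "))
    }
    keep <- direction != "mixed"
    common <- common[keep]
    direction <- direction[keep]
  }
  cell_types <- vapply(common, function(g) {
    cts <- unlist(lapply(sets, function(s) {
      strsplit(s$cell_types[match(g, s$gene)], ";", fixed = TRUE)[[1]]
    }))
    paste(sort(unique(cts)), collapse = ";")
  }, "")
  out <- data.frame(gene = common, direction = unname(direction),
                    cell_types = unname(cell_types),
                    stringsAsFactors = FALSE)
  attr(out, "dataset_id") <- "integrated"
  attr(out, "dropped_inconsistent") <- dropped
  class(out) <- c("gene_signature", "data.frame")
  out
}

#' Assign a gene to cell types by mean absolute Z across datasets
#'
#' The primary assignment is the cell type with the maximum mean |z| over
#' all datasets where the gene is significant in that cell type; ties break
#' lexicographically. All cell types where the gene is significant anywhere
#' are reported, so genes may count toward several cell types in per-type
#' tallies.
#'
#' @param gene Gene symbol.
#' @param ztables List of classified `zscore_table`s (one per dataset).
#' @return Data frame (`cell_type`, `mean_abs_z`, `n_datasets`) sorted by
#'   descending mean |z| then cell type; the first row is the primary
#'   assignment. Error if the gene is significant nowhere.
#' @export
assign_cell_types <- function(gene, ztables) {
  stopifnot(all(vapply(ztables, inherits, TRUE, "zscore_table")))
  rows <- do.call(rbind, lapply(ztables, function(zt) {
    zt[zt$gene == gene & zt$class %in% c("over", "under"),
       c("cell_type", "z"), drop = FALSE]
  }))
  if (is.null(rows) || nrow(rows) == 0) {
    stop("gene ", gene, " is not significant in any dataset", call. = FALSE)
  }
  agg <- aggregate(abs(rows$z), by = list(cell_type = rows$cell_type), mean)
  names(agg)[2] <- "mean_abs_z"
  cnt <- aggregate(rows$z, by = list(cell_type = rows$cell_type), length)
  agg$n_datasets <- cnt$x[match(agg$cell_type, cnt$Group.1)]
  agg <- agg[order(-agg$mean_abs_z, agg$cell_type), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Per-cell-type summary of significant genes
#'
#' For every dataset and cell type: the number of integrated-set genes
#' significant there, and the mean Z of those entries restricted to cells
#' where more than `pct_min` percent of nuclei express the gene. The
#' percent-expressing filter applies only to this summary statistic, never
#' to the significance calls themselves.
#'
#' @param ztables List of classified `zscore_table`s.
#' @param integrated A `gene_signature` restricting which genes count
#'   (e.g. the integrated set); `NULL` uses all significant genes.
#' @param pct_min Percent-expressing cutoff for the mean-Z statistic
#'   (default 50, strict `>`).
#' @return Data frame: `dataset`, `cell_type`, `n_significant`, `mean_z`
#'   (NA when no entry passes the percent filter), sorted by descending
#'   mean Z within dataset.
#' @export
summarize_cell_types <- function(ztables, integrated = NULL, pct_min = 50) {
  stopifnot(all(vapply(ztables, inherits, TRUE, "zscore_table")))
  keep_genes <- if (is.null(integrated)) NULL else integrated$gene
  out <- do.call(rbind, lapply(ztables, function(zt) {
    sig <- zt[zt$class %in% c("over", "under"), , drop = FALSE]
    if (!is.null(keep_genes)) {
      sig <- sig[sig$gene %in% keep_genes, , drop = FALSE]
    }
    cts <- sort(unique(zt$cell_type))
    do.call(rbind, lapply(cts, function(ct) {
      s <- sig[sig$cell_type == ct, , drop = FALSE]
      pass <- s[s$pct_expressing > pct_min, , drop = FALSE]
      data.frame(dataset = zt$dataset[1], cell_type = ct,
                 n_significant = length(unique(s$gene)),
                 mean_z = if (nrow(pass) > 0) mean(pass$z) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  out <- out[order(out$dataset, -xtfrm(out$mean_z), out$cell_type), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
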