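#' Read a per-cell-type expression summary table
#'
#' Reads one dataset's pseudo-profile: for every (gene, cell type) pair the
#' mean log-normalized expression, the percentage of nuclei expressing the
#' gene, and the nucleus count. This is the summary form of a single-nucleus
#' RNA-seq dataset after upstream clustering and cell-type annotation, which
#' this package deliberately does not redo.
#'
#' @param path Path to a tab-separated file with columns `gene`, `cell_type`,
#'   `mean_lognorm_expr`, `pct_expressing`, `n_nuclei`. Lines starting with
#'   `#` are skipped.
#' @param dataset_id Label attached to the profile (e.g. a data portal
#'   accession).
#' @return A data frame of class `expression_profile` with the five columns
#'   above and a `dataset_id` attribute.
#' @details Hard errors: duplicated (gene, cell type) rows (the offending
#'   pair is named), negative expression, `pct_expressing` outside
#'   \[0, 100\], negative nucleus counts, or a cell-type set that differs
#'   between genes of the same dataset.
#' @seealso [write_expression_profiles()], [compute_zscores()]
#' @export
read_expression_profiles <- function(path, dataset_id) {
  df <- read_tsv_table(path, c("gene", "cell_type", "mean_lognorm_expr",
                               "pct_expressing", "n_nuclei"))
  as_expression_profile(df, dataset_id)
}

#' Validate an in-memory expression summary
#'
#' @param df Data frame with columns `gene`, `cell_type`,
#'   `mean_lognorm_expr`, `pct_expressing`, `n_nuclei`.
#' @param dataset_id Dataset label.
#' @return The validated `expression_profile`.
#' @export
as_expression_profile <- function(df, dataset_id) {
  stopifnot(is.character(dataset_id), length(dataset_id) == 1)
  df <- data.frame(gene = as.character(df$gene),
                   cell_type = as.character(df$cell_type),
                   mean_lognorm_expr = df$mean_lognorm_expr,
                   pct_expressing = df$pct_expressing,
                   n_nuclei = df$n_nuclei,
                   stringsAsFactors = FALSE)
  key <- paste(df$gene, df$cell_type, sep = "/")
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    stop("duplicated (gene, cell_type) pair(s) in dataset ", dataset_id,
         ": ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (any(df$mean_lognorm_expr < 0)) {
    stop("negative mean_lognorm_expr in dataset ", dataset_id, call. = FALSE)
  }
  check_range(df$pct_expressing, 0, 100, "pct_expressing")
  if (any(df$n_nuclei < 0) || any(df$n_nuclei != round(df$n_nuclei))) {
    stop("n_nuclei must be non-negative integers", call. = FALSE)
  }
  ct_per_gene <- tapply(df$cell_type, df$gene,
                        function(x) paste(sort(x), collapse = "|"))
  if (length(unique(ct_per_gene)) > 1) {
    stop("cell-type label set differs between genes of dataset ",
         dataset_id, call. = FALSE)
  }
  df <- df[order(df$gene, df$cell_type), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "dataset_id") <- dataset_id
  class(df) <- c("expression_profile", "data.frame")
  df
}

#' Write an expression summary back to disk
#'
#' Rows are canonically sorted by (gene, cell type), so a
#' write-then-read round trip reproduces the profile field for field.
#'
#' @param profile An `expression_profile`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression_profiles <- function(profile, path) {
  stopifnot(inherits(profile, "expression_profile"))
  df <- as.data.frame(profile)
  df <- df[order(df$gene, df$cell_type), , drop = FALSE]
  write_tsv_table(df, path)
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("<expression_profile> dataset", attr(x, "dataset_id"), "-",
      length(unique(x$gene)), "genes x",
      length(unique(x$cell_type)), "cell types\n")
  NextMethod()
}

#' Read a protein-interaction edge list with confidence scores
#'
#' Handles the two dialects of STRING-style exports: unit-scale scores in
#' \[0, 1\] and milli-scale scores in \[0, 1000\]. Scores are always
#' normalized to \[0, 1\] on return, so normalization is idempotent.
#'
#' @param path Tab-separated file with columns `protein_a`, `protein_b`,
#'   `confidence`.
#' @param scale `"unit"`, `"milli"`, or `"auto"` (default). `"auto"` infers
#'   the milli scale when any score exceeds 1.
#' @return Data frame (`protein_a`, `protein_b`, `confidence`) with
#'   confidence on \[0, 1\] and attribute `scale = "unit"`.
#' @details A score outside both scales (e.g. 1500) is a hard error, as is a
#'   missing endpoint.
#' @export
read_confidence_edges <- function(path, scale = c("auto", "unit", "milli")) {
  scale <- match.arg(scale)
  df <- read_tsv_table(path, c("protein_a", "protein_b", "confidence"))
  df$protein_a <- as.character(df$protein_a)
  df$protein_b <- as.character(df$protein_b)
  if (anyNA(df$protein_a) || anyNA(df$protein_b) ||
      any(!nzchar(df$protein_a)) || any(!nzchar(df$protein_b))) {
    stop("confidence edge list has missing endpoint(s)", call. = FALSE)
  }
  df$confidence <- normalize_confidence(df$confidence, scale)
  attr(df, "scale") <- "unit"
  df
}

#' Normalize interaction confidence scores to the unit scale
#'
#' @param confidence Numeric scores.
#' @param scale `"unit"`, `"milli"`, or `"auto"`.
#' @return Scores on \[0, 1\]. Applying this twice equals applying it once.
#' @export
normalize_confidence <- function(confidence, scale = c("auto", "unit", "milli")) {
  scale <- match.arg(scale)
  if (!is.numeric(confidence) || anyNA(confidence)) {
    stop("confidence scores must be numeric and non-missing", call. = FALSE)
  }
  if (any(confidence < 0) || any(confidence > 1000)) {
    stop("confidence score outside both the unit [0,1] and milli [0,1000] ",
         "scales: ", paste(utils::head(
           confidence[confidence < 0 | confidence > 1000], 5),
           collapse = ", "), call. = FALSE)
  }
  if (scale == "auto") {
    scale <- if (any(confidence > 1)) "milli" else "unit"
  }
  if (scale == "milli") confidence <- confidence / 1000
  check_range(confidence, 0, 1, "normalized confidence")
  confidence
}

#' Write a confidence edge list
#'
#' @param edges Data frame from [read_confidence_edges()] (unit scale).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_confidence_edges <- function(edges, path) {
  df <- as.data.frame(edges)[, c("protein_a", "protein_b", "confidence")]
  df <- df[order(df$protein_a, df$protein_b), , drop = FALSE]
  write_tsv_table(df, path)
}

CAUSAL_EFFECTS <- c("up-regulates", "down-regulates")

#' Read a directed signed causal edge list
#'
#' Edges carry a regulation effect (`up-regulates` or `down-regulates`, a
#' closed vocabulary) and a reliability score `r` in (0, 1\] summarizing the
#' supporting evidence; `r` later becomes a step distance `d = 1 - r`.
#'
#' @param path Tab-separated file with columns `source`, `target`, `effect`,
#'   `reliability`.
#' @param phenotypes Character vector of phenotype node labels expected in
#'   the network; defaults to [cvd_phenotypes()]. Stored as an attribute.
#' @return Data frame (`source`, `target`, `effect`, `reliability`) with a
#'   `phenotypes` attribute.
#' @details Unknown effect tokens are a hard error listing the offenders;
#'   reliability must be strictly positive and at most 1.
#' @export
read_causal_edges <- function(path, phenotypes = cvd_phenotypes()) {
  df <- read_tsv_table(path, c("source", "target", "effect", "reliability"))
  df$source <- as.character(df$source)
  df$target <- as.character(df$target)
  df$effect <- as.character(df$effect)
  bad <- setdiff(unique(df$effect), CAUSAL_EFFECTS)
  if (length(bad) > 0) {
    stop("unknown causal effect token(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(CAUSAL_EFFECTS, collapse = ", "),
         call. = FALSE)
  }
  check_range(df$reliability, 0, 1, "reliability", lo_open = TRUE)
  attr(df, "phenotypes") <- phenotypes
  df
}

#' Write a causal edge list
#'
#' @param edges Data frame as returned by [read_causal_edges()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_causal_edges <- function(edges, path) {
  df <- as.data.frame(edges)[, c("source", "target", "effect", "reliability")]
  df <- df[order(df$source, df$target, df$effect), , drop = FALSE]
  write_tsv_table(df, path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one term per line, tab-separated as
#' `term_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path GMT file path.
#' @param source Label for the annotation source (e.g. `"GO:BP"`,
#'   `"KEGG"`); defaults to the file name without extension.
#' @return An `annotation_db`: list with `source`, `terms` (named list of
#'   unique gene vectors), and `descriptions` (named character vector).
#'   Terms with empty gene sets are a hard error.
#' @seealso [enrich()]
#' @export
read_gmt <- function(path, source = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short)) {
    stop("GMT line(s) with fewer than 3 fields (term, description, genes): ",
         "line ", paste(which(short), collapse = ", "), call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicated GMT term id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  terms <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(terms) <- ids
  descriptions <- vapply(fields, `[[`, "", 2L)
  names(descriptions) <- ids
  annotation_db(terms, descriptions,
                source = source %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Construct an annotation database from gene sets
#'
#' @param terms Named list of character gene vectors (term id -> gene set).
#' @param descriptions Optional named character vector of term descriptions.
#' @param source Annotation source label.
#' @return An `annotation_db` object. The statistical universe of the
#'   source is the union of its term gene sets (genes with at least one
#'   annotation).
#' @export
annotation_db <- function(terms, descriptions = NULL, source = "custom") {
  stopifnot(is.list(terms), length(terms) > 0, !is.null(names(terms)))
  empty <- vapply(terms, length, 1L) == 0L
  if (any(empty)) {
    stop("annotation term(s) with empty gene set: ",
         paste(names(terms)[empty], collapse = ", "), call. = FALSE)
  }
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(terms), names(terms))
  }
  structure(list(source = source, terms = terms,
                 descriptions = descriptions[names(terms)]),
            class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  cat("<annotation_db>", x$source, "-", length(x$terms), "terms,",
      length(db_universe(x)), "annotated genes\n")
  invisible(x)
}

#' Annotated-gene universe of an annotation source
#'
#' @param db An `annotation_db`.
#' @return Character vector: the union of all term gene sets.
#' @export
db_universe <- function(db) {
  stopifnot(inherits(db, "annotation_db"))
  sort(unique(unlist(db$terms, use.names = FALSE)))
}

#' Write an annotation database as GMT
#'
#' @param db An `annotation_db`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "annotation_db"))
  ord <- order(names(db$terms))
  lines <- vapply(ord, function(i) {
    paste(c(names(db$terms)[i], db$descriptions[[i]],
            sort(db$terms[[i]])), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a drug-target table
#'
#' Rows describe drugs, the protein they target, their mechanism of action,
#' the maximum clinical-trial phase reached, and the disease indications
#' under study (semicolon-separated).
#'
#' @param path Tab-separated file with columns `drug`, `target`,
#'   `mechanism`, `max_phase`, `indications`.
#' @return Data frame of class `drug_table`. Duplicate (drug, target) pairs
#'   are a hard error; `max_phase` must be an integer in 1..4.
#' @seealso [annotate_targets()]
#' @export
read_drug_table <- function(path) {
  df <- read_tsv_table(path, c("drug", "target", "mechanism", "max_phase",
                               "indications"))
  df$drug <- as.character(df$drug)
  df$target <- as.character(df$target)
  df$mechanism <- as.character(df$mechanism)
  df$indications <- as.character(df$indications)
  key <- paste(df$drug, df$target, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicated (drug, target) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$max_phase != round(df$max_phase)) ||
      any(df$max_phase < 1) || any(df$max_phase > 4)) {
    stop("max_phase must be an integer in 1..4", call. = FALSE)
  }
  df$max_phase <- as.integer(df$max_phase)
  df <- df[order(df$target, df$drug), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("drug_table", "data.frame")
  df
}

#' Write a pipeline report bundle
#'
#' Serializes a report as a set of human-readable TSV tables (one per named
#' data frame in the report) plus one machine-readable `summary.tsv` of
#' key-value pairs covering every scalar entry.
#'
#' @param report Named list; data frame elements become `<name>.tsv`, scalar
#'   elements are collected into `summary.tsv`.
#' @param path Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(is.list(report), !is.null(names(report)))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  scalars <- list()
  for (nm in names(report)) {
    el <- report[[nm]]
    if (is.data.frame(el)) {
      write_tsv_table(as.data.frame(el), file.path(path, paste0(nm, ".tsv")))
    } else if (is.list(el)) {
      for (k in names(el)) {
        if (length(el[[k]]) == 1 && is.atomic(el[[k]])) {
          scalars[[paste(nm, k, sep = ".")]] <- el[[k]]
        }
      }
    } else if (length(el) == 1 && is.atomic(el)) {
      scalars[[nm]] <- el
    }
  }
  if (length(scalars) > 0) {
    summ <- data.frame(key = names(scalars),
                       value = vapply(scalars, function(v)
                         format(v, scientific = FALSE, trim = TRUE), ""),
                       stringsAsFactors = FALSE)
    write_tsv_table(summ, file.path(path, "summary.tsv"))
  }
  invisible(path)
}
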