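#' Annotate prioritized targets with late-stage clinical-trial drugs
#'
#' Joins a set of prioritized protein targets against a drug-target table
#' restricted to late-stage records (`max_phase >= min_phase`, default
#' phase III), yielding the target-to-drug-to-indication map. The join is
#' a pure table operation: idempotent, order-invariant, and reproducible
#' for a fixed table snapshot.
#'
#' @param targets Character vector of target symbols; an empty set yields
#'   an empty map, not an error.
#' @param drugs A `drug_table` (see [read_drug_table()]).
#' @param min_phase Minimum clinical phase retained (default 3).
#' @return A `target_drug_map`: list with `records` (data frame `target`,
#'   `drug`, `mechanism`, `max_phase`, `indications`, ordered by (target,
#'   drug)), `by_target` (named list, one entry per requested target;
#'   targets without drugs get empty data frames, with a message), and
#'   `summary` (distinct drug / mechanism / indication counts and the
#'   number of targets with at least one drug).
#' @export
annotate_targets <- function(targets, drugs, min_phase = 3) {
  stopifnot(inherits(drugs, "drug_table"))
  stopifnot(min_phase >= 1, min_phase <= 4)
  targets <- sort(unique(as.character(targets)))
  df <- as.data.frame(drugs)
  df <- df[df$max_phase >= min_phase & df$target %in% targets, ,
           drop = FALSE]
  df <- df[order(df$target, df$drug), , drop = FALSE]
  rownames(df) <- NULL
  by_target <- lapply(targets, function(t) {
    df[df$target == t, , drop = FALSE]
  })
  names(by_target) <- targets
  no_drug <- targets[vapply(by_target, nrow, 1L) == 0]
  if (length(no_drug) > 0 && length(targets) > 0) {
    message(length(no_drug), " target(s) without late-stage drug: ",
            paste(utils::head(no_drug, 10), collapse = ", "))
  }
  indications <- unique(unlist(strsplit(df$indications, ";", fixed = TRUE)))
  indications <- indications[nzchar(indications)]
  structure(list(
    records = df[, c("target", "drug", "mechanism", "max_phase",
                     "indications")],
    by_target = by_target,
    summary = list(
      n_targets_with_drugs = length(setdiff(targets, no_drug)),
      n_drugs = length(unique(df$drug)),
      n_mechanisms = length(unique(df$mechanism)),
      n_indications = length(indications)
    )), class = "target_drug_map")
}

#' @export
print.target_drug_map <- function(x, ...) {
  s <- x$summary
  cat("<target_drug_map>", s$n_drugs, "drug(s) over",
      s$n_targets_with_drugs, "target(s);", s$n_mechanisms,
      "mechanism(s),", s$n_indications, "indication(s)\n")
  invisible(x)
}

#' Expand a target-drug map into Sankey-ready triples
#'
#' @param map A `target_drug_map`.
#' @return Data frame (`indication`, `target`, `drug`), one row per
#'   (indication, target, drug) combination, ordered.
#' @export
sankey_table <- function(map) {
  stopifnot(inherits(map, "target_drug_map"))
  df <- map$records
  if (nrow(df) == 0) {
    return(data.frame(indication = character(), target = character(),
                      drug = character(), stringsAsFactors = FALSE))
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    ind <- strsplit(df$indications[i], ";", fixed = TRUE)[[1]]
    ind <- ind[nzchar(ind)]
    data.frame(indication = ind, target = df$target[i], drug = df$drug[i],
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$indication, rows$target, rows$drug), ,
               drop = FALSE]
  rownames(rows) <- NULL
  rows
}
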