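#' Pipeline configuration
#'
#' Collects every input path and threshold of the five-stage analysis.
#' Thresholds default to the study settings: |Z| >= 2 with two-tailed
#' p <= 0.001 for expression significance, BH q < 0.001 for enrichment,
#' confidence >= 0.9 for the interaction network, reachability of at
#' least 5 phenotypes for prioritization, Bonferroni-corrected p < 0.001
#' for the phenotype comparisons, and clinical phase III or above for
#' drug records.
#'
#' @param expression Named character vector / list of expression profile
#'   TSV paths; names are the dataset ids.
#' @param annotations Character vector of GMT paths (one per source).
#' @param ppi Path to the confidence edge TSV.
#' @param causal Path to the causal edge TSV.
#' @param drugs Path to the drug table TSV.
#' @param out_dir Output directory for the report bundle.
#' @param z_hi,z_lo,p_max Expression significance thresholds.
#' @param require_consistent_direction Cross-dataset direction consistency
#'   flag for the integration step.
#' @param pct_min Percent-expressing cutoff for summary statistics.
#' @param q_max Enrichment significance threshold.
#' @param confidence_cutoff Interaction confidence cutoff.
#' @param min_phenotypes,dmax Prioritization thresholds.
#' @param alpha Familywise level of the phenotype comparisons.
#' @param min_phase Minimum clinical phase for drug records.
#' @param phenotypes Phenotype node labels.
#' @param verbose Log stage progress to standard error.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression, annotations, ppi, causal, drugs,
                            out_dir,
                            z_hi = 2, z_lo = -2, p_max = 0.001,
                            require_consistent_direction = TRUE,
                            pct_min = 50, q_max = 0.001,
                            confidence_cutoff = 0.9,
                            min_phenotypes = 5, dmax = Inf,
                            alpha = 0.001, min_phase = 3,
                            phenotypes = cvd_phenotypes(),
                            verbose = TRUE) {
  stopifnot(length(expression) >= 1, !is.null(names(expression)))
  cfg <- as.list(environment())
  for (p in c(unlist(expression), annotations, ppi, causal, drugs)) {
    if (!file.exists(p)) stop("input path does not exist: ", p,
                              call. = FALSE)
  }
  stopifnot(p_max > 0, p_max <= 1, q_max > 0, q_max <= 1,
            confidence_cutoff >= 0, confidence_cutoff <= 1,
            min_phenotypes >= 1, alpha > 0, alpha <= 1,
            min_phase >= 1, min_phase <= 4)
  class(cfg) <- "pipeline_config"
  cfg
}

stage_log <- function(verbose, stage, ...) {
  if (verbose) message("[", stage, "] ", ...)
}

stage_error <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the five-stage prioritization pipeline
#'
#' Executes expression integration, enrichment, interaction-network
#' centrality analysis, causal phenotype-distance scoring, and drug
#' annotation in order, writing per-stage TSVs plus a consolidated summary
#' into the configured output directory. The enrichment stage runs one
#' query per cellular compartment (integrated genes grouped by their
#' primary cell-type assignment) in addition to the full integrated set,
#' with BH correction within each (query, source) block. Warnings raised by the stages
#' (dropped genes, unreachable proteins, direction conflicts) are
#' collected into a machine-readable `warnings.tsv` sidecar. The run is
#' deterministic for fixed inputs and configuration; every threshold is
#' echoed into the summary for provenance.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, the report list with one block per signature:
#'   `integration`, `enrichment`, `network`, `phenotype_distance`,
#'   `drug_annotation`, plus `parameters` and `summary`. Partial outputs
#'   are retained on disk when a later stage fails.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  v <- config$verbose
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- list()
  collect <- function(stage, expr) {
    withCallingHandlers(
      stage_error(stage, expr),
      warning = function(w) {
        warnings_seen[[length(warnings_seen) + 1]] <<-
          data.frame(stage = stage, message = conditionMessage(w),
                     stringsAsFactors = FALSE)
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        warnings_seen[[length(warnings_seen) + 1]] <<-
          data.frame(stage = stage,
                     message = sub("\n$", "", conditionMessage(m)),
                     stringsAsFactors = FALSE)
        invokeRestart("muffleMessage")
      })
  }
  flush_warnings <- function() {
    df <- if (length(warnings_seen)) do.call(rbind, warnings_seen) else
      data.frame(stage = character(), message = character(),
                 stringsAsFactors = FALSE)
    write_tsv_table(df, file.path(config$out_dir, "warnings.tsv"))
  }
  on.exit(flush_warnings())

  # Stage 1: expression integration
  stage_log(v, "expression", "reading ", length(config$expression),
            " dataset(s) and computing Z-scores")
  ztables <- collect("expression", {
    lapply(names(config$expression), function(id) {
      prof <- read_expression_profiles(config$expression[[id]], id)
      classify_genes(compute_zscores(prof), z_hi = config$z_hi,
                     z_lo = config$z_lo, p_max = config$p_max)
    })
  })
  integrated <- collect("expression", {
    sets <- lapply(ztables, significant_genes)
    if (length(sets) >= 2) {
      intersect_datasets(sets, config$require_consistent_direction)
    } else sets[[1]]
  })
  cell_summary <- collect("expression",
    summarize_cell_types(ztables, integrated, pct_min = config$pct_min))
  assignment <- collect("expression", {
    if (nrow(integrated) > 0) {
      prim <- vapply(integrated$gene, function(g)
        assign_cell_types(g, ztables)$cell_type[1], "")
      stats::setNames(prim, integrated$gene)
    } else stats::setNames(character(), character())
  })
  integrated_out <- integrated
  integrated_out$primary_cell_type <-
    unname(assignment[integrated_out$gene])
  write_tsv_table(do.call(rbind, lapply(ztables, as.data.frame)),
                  file.path(config$out_dir, "zscores.tsv"))
  write_tsv_table(integrated_out,
                  file.path(config$out_dir, "integrated_genes.tsv"))
  stage_log(v, "expression", nrow(integrated), " integrated gene(s)")

  # Stage 2: enrichment — one query per cellular compartment (genes
  # grouped by primary cell-type assignment) plus the full integrated
  # set, mirroring the per-compartment queries of the study design
  stage_log(v, "enrichment", "testing ", length(config$annotations),
            " annotation source(s)")
  enr <- collect("enrichment", {
    dbs <- lapply(config$annotations, read_gmt)
    if (nrow(integrated) == 0) NULL else {
      queries <- c(list(all = integrated$gene),
                   split(integrated$gene,
                         unname(assignment[integrated$gene])))
      blocks <- lapply(names(queries), function(qn) {
        res <- enrich(queries[[qn]], dbs, q_max = config$q_max)
        if (nrow(res) == 0) NULL else cbind(query = qn, res)
      })
      do.call(rbind, blocks)
    }
  })
  if (!is.null(enr)) {
    write_tsv_table(enr, file.path(config$out_dir, "enrichment.tsv"))
  }
  n_sig_terms <- if (is.null(enr)) 0L else
    length(unique(enr$term_id[enr$significant]))
  stage_log(v, "enrichment", n_sig_terms, " significant term(s)")

  # Stage 3: interaction network
  stage_log(v, "network", "confidence cutoff ", config$confidence_cutoff)
  node_meta <- data.frame(gene = integrated$gene,
                          cell_type = unname(assignment[integrated$gene]),
                          direction = integrated$direction,
                          stringsAsFactors = FALSE)
  net <- collect("network", {
    edges <- read_confidence_edges(config$ppi)
    build_network(edges, whitelist = integrated$gene,
                  cutoff = config$confidence_cutoff,
                  node_metadata = node_meta)
  })
  centr <- collect("network", centrality_table(net))
  net_summary <- collect("network", network_summary(net, centr))
  write_tsv_table(net$edges, file.path(config$out_dir, "network_edges.tsv"))
  write_tsv_table(centr, file.path(config$out_dir, "centrality.tsv"))
  stage_log(v, "network", net_summary$n_nodes, " node(s), ",
            net_summary$n_edges, " edge(s)")

  # Stage 4: phenotype distances
  stage_log(v, "distance", "scoring causal paths to ",
            length(config$phenotypes), " phenotype(s)")
  dist_res <- collect("distance", {
    causal <- causal_network(read_causal_edges(config$causal,
                                               config$phenotypes))
    dm <- distance_matrix(causal, proteins = centr$node)
    list(dm = dm,
         prioritized = prioritize_targets(dm, config$min_phenotypes,
                                          config$dmax),
         comparisons = compare_phenotypes(dm, alpha = config$alpha),
         by_cell_type = cell_type_distance(
           dm, assignment[rownames(dm)][!is.na(assignment[rownames(dm)])]))
  })
  dm_df <- as.data.frame(unclass(dist_res$dm))
  dm_df <- cbind(protein = rownames(dm_df), dm_df)
  write_tsv_table(dm_df, file.path(config$out_dir, "distance_matrix.tsv"))
  write_tsv_table(dist_res$prioritized,
                  file.path(config$out_dir, "prioritized_targets.tsv"))
  write_tsv_table(dist_res$comparisons,
                  file.path(config$out_dir, "phenotype_comparisons.tsv"))
  write_tsv_table(dist_res$by_cell_type,
                  file.path(config$out_dir, "cell_type_distance.tsv"))
  stage_log(v, "distance", nrow(dist_res$prioritized),
            " prioritized target(s)")

  # Stage 5: drug annotation
  stage_log(v, "drugs", "minimum clinical phase ", config$min_phase)
  drug_map <- collect("drugs", {
    tab <- read_drug_table(config$drugs)
    annotate_targets(dist_res$prioritized$protein, tab,
                     min_phase = config$min_phase)
  })
  write_tsv_table(drug_map$records,
                  file.path(config$out_dir, "drug_annotation.tsv"))
  write_tsv_table(sankey_table(drug_map),
                  file.path(config$out_dir, "sankey.tsv"))
  stage_log(v, "drugs", drug_map$summary$n_drugs, " drug record(s)")

  params <- config[c("z_hi", "z_lo", "p_max", "pct_min", "q_max",
                     "confidence_cutoff", "min_phenotypes", "dmax",
                     "alpha", "min_phase")]
  report <- list(
    integration = list(n_integrated_genes = nrow(integrated),
                       n_datasets = length(ztables)),
    enrichment = list(n_significant_terms = n_sig_terms),
    network = net_summary[c("n_nodes", "n_edges", "mean_degree",
                            "mean_betweenness", "mean_eigenvector")],
    phenotype_distance = list(
      n_prioritized = nrow(dist_res$prioritized),
      n_significant_pairs = sum(dist_res$comparisons$significant)),
    drug_annotation = drug_map$summary,
    parameters = params
  )
  write_report(report, config$out_dir)
  invisible(list(report = report, integrated = integrated_out,
                 enrichment = enr, network = net, centralities = centr,
                 network_summary = net_summary,
                 distance = dist_res, drugs = drug_map))
}
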