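#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the ground-truth simulation. The defaults emulate
#' the scale of the real inputs: three datasets over a shared 2,000-gene
#' universe with 13 heart cell types, a PPI network on the order of 100+
#' nodes after filtering, and a layered causal network wired to the seven
#' canonical phenotype nodes. The whole pipeline runs on these defaults in
#' seconds.
#'
#' `marker_effect_size` is expressed in units of the baseline
#' log-expression distribution's standard deviation
#' (`sqrt(baseline_shape) * baseline_scale`, 1.0 at the defaults). The
#' within-gene across-cell-type jitter (`celltype_sd`) is deliberately
#' small relative to that unit: with 13 cell types the population-SD
#' Z-score of a single-cell-type marker is capped at `sqrt(12) = 3.46`,
#' so markers are only separable from the two-tailed p <= 0.001 rule
#' (|z| >= 3.29) when the shift dwarfs the jitter.
#'
#' @param n_datasets Number of datasets sharing the gene universe.
#' @param n_cell_types Number of cell types per dataset.
#' @param n_genes Size of the gene universe.
#' @param n_markers_per_cell_type Planted markers per cell type (split
#'   between over- and under-expressed).
#' @param marker_effect_size Marker shift in baseline-SD units.
#' @param baseline_shape,baseline_scale Gamma parameters of the per-gene
#'   baseline mean log-normalized expression.
#' @param celltype_sd SD of the within-gene across-cell-type jitter.
#' @param pct_background,pct_marker Ranges (length 2) of the
#'   percent-expressing draw for background entries and for marker genes.
#' @param n_annotation_terms Number of background annotation terms.
#' @param planted_term_size Gene-set size of planted (and background)
#'   terms.
#' @param ppi_background_p Background edge probability of the PPI graph.
#' @param n_hubs Number of planted hub proteins.
#' @param hub_connectivity Probability that a hub is wired to any given
#'   other node.
#' @param conf_background,conf_planted Confidence ranges for background
#'   and planted (hub) PPI edges.
#' @param n_intermediate_layers Layers of intermediate nodes between
#'   proteins and each phenotype in the causal network.
#' @param reliability_range Reliability range of background causal edges.
#' @param golden_reliability_range Reliability range of golden-target
#'   causal edges.
#' @param n_golden_targets Number of planted golden targets.
#' @param n_golden_phenotypes Phenotypes each golden target is wired to.
#' @param max_background_phenotypes Maximum phenotypes a non-golden
#'   protein may reach.
#' @param phenotypes Phenotype node labels.
#' @param seed Base seed; each generator derives its own sub-seed from it
#'   (fixed offsets +101, +202, +303, +404, +505 for expression,
#'   annotations, PPI, causal network and drug table respectively), so
#'   adding one generator never perturbs another's output.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_datasets = 3,
                              n_cell_types = 13,
                              n_genes = 2000,
                              n_markers_per_cell_type = 5,
                              marker_effect_size = 4,
                              baseline_shape = 4,
                              baseline_scale = 0.5,
                              celltype_sd = 0.15,
                              pct_background = c(5, 70),
                              pct_marker = c(60, 95),
                              n_annotation_terms = 50,
                              planted_term_size = 15,
                              ppi_background_p = 0.05,
                              n_hubs = 2,
                              hub_connectivity = 0.6,
                              conf_background = c(0.4, 0.95),
                              conf_planted = c(0.9, 1),
                              n_intermediate_layers = 2,
                              reliability_range = c(0.5, 1),
                              golden_reliability_range = c(0.9, 1),
                              n_golden_targets = 3,
                              n_golden_phenotypes = 6,
                              max_background_phenotypes = 4,
                              phenotypes = cvd_phenotypes(),
                              seed = 1L) {
  cfg <- list(n_datasets = n_datasets, n_cell_types = n_cell_types,
              n_genes = n_genes,
              n_markers_per_cell_type = n_markers_per_cell_type,
              marker_effect_size = marker_effect_size,
              baseline_shape = baseline_shape,
              baseline_scale = baseline_scale,
              celltype_sd = celltype_sd,
              pct_background = pct_background, pct_marker = pct_marker,
              n_annotation_terms = n_annotation_terms,
              planted_term_size = planted_term_size,
              ppi_background_p = ppi_background_p, n_hubs = n_hubs,
              hub_connectivity = hub_connectivity,
              conf_background = conf_background,
              conf_planted = conf_planted,
              n_intermediate_layers = n_intermediate_layers,
              reliability_range = reliability_range,
              golden_reliability_range = golden_reliability_range,
              n_golden_targets = n_golden_targets,
              n_golden_phenotypes = n_golden_phenotypes,
              max_background_phenotypes = max_background_phenotypes,
              phenotypes = phenotypes, seed = as.integer(seed))
  counts <- c(n_datasets, n_cell_types, n_genes, n_markers_per_cell_type,
              n_annotation_terms, planted_term_size, n_hubs,
              n_intermediate_layers, n_golden_targets, n_golden_phenotypes)
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("all simulation counts must be positive integers", call. = FALSE)
  }
  if (marker_effect_size < 0) stop("effect size must be >= 0", call. = FALSE)
  check_range(reliability_range, 0, 1, "reliability_range", lo_open = TRUE)
  check_range(golden_reliability_range, 0, 1, "golden_reliability_range",
              lo_open = TRUE)
  check_range(c(ppi_background_p, hub_connectivity), 0, 1, "probabilities")
  if (n_golden_phenotypes > length(phenotypes) ||
      max_background_phenotypes >= n_golden_phenotypes) {
    stop("need max_background_phenotypes < n_golden_phenotypes <= ",
         "number of phenotypes", call. = FALSE)
  }
  if (n_markers_per_cell_type * n_cell_types > n_genes) {
    stop("more planted markers than genes", call. = FALSE)
  }
  class(cfg) <- "simulation_config"
  cfg
}

sim_cell_types <- function(n) {
  base <- c("cardiomyocytes", "fibroblasts", "endothelial cells",
            "pericytes", "macrophages", "VSMCs", "lymphocytes",
            "endocardial cells", "adipocytes", "neuronal cells",
            "lymphatic endothelial cells", "mast cells", "epicardial cells")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("cell type %02d", seq_len(n - length(base))))
}

sim_genes <- function(n) sprintf("GENE%04d", seq_len(n))

#' Generate per-cell-type expression summaries with planted markers
#'
#' Every gene draws a baseline mean log-normalized expression from a Gamma
#' distribution (shared across datasets, as the same biology underlies
#' them) plus a small per-dataset, per-cell-type jitter. Each cell type
#' gets planted markers, consistent in direction across datasets:
#' over-expressed markers are shifted up by `marker_effect_size` baseline
#' SDs in their cell type; under-expressed markers get an elevated
#' baseline everywhere except their cell type, so their low value stays
#' nonnegative. Marker genes draw percent-expressing values biased above
#' 50 (except in the depleted cell of under-markers).
#'
#' @param config A `simulation_config`.
#' @param seed Base seed (default `config$seed`); the expression sub-seed
#'   is `seed + 101`.
#' @return List with `profiles` (list of `expression_profile`, one per
#'   dataset, named `SIM01`, `SIM02`, ...) and `truth` (list whose
#'   `markers` element is a data frame `gene`, `cell_type`, `direction`).
#' @export
generate_expression <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed + 101L)
  genes <- sim_genes(config$n_genes)
  cts <- sim_cell_types(config$n_cell_types)
  n_mark <- config$n_markers_per_cell_type * config$n_cell_types
  marker_genes <- sample(genes, n_mark)
  marker_ct <- rep(cts, each = config$n_markers_per_cell_type)
  n_over <- ceiling(config$n_markers_per_cell_type / 2)
  direction <- rep(c(rep("over", n_over),
                     rep("under", config$n_markers_per_cell_type - n_over)),
                   times = config$n_cell_types)
  markers <- data.frame(gene = marker_genes, cell_type = marker_ct,
                        direction = direction, stringsAsFactors = FALSE)

  unit_sd <- sqrt(config$baseline_shape) * config$baseline_scale
  shift <- config$marker_effect_size * unit_sd
  baseline <- stats::rgamma(config$n_genes, shape = config$baseline_shape,
                            scale = config$baseline_scale)
  names(baseline) <- genes
  is_under <- markers$direction == "under"
  baseline[markers$gene[is_under]] <- baseline[markers$gene[is_under]] + shift

  profiles <- lapply(seq_len(config$n_datasets), function(d) {
    grid <- expand.grid(gene = genes, cell_type = cts,
                        stringsAsFactors = FALSE)
    x <- baseline[grid$gene] +
      stats::rnorm(nrow(grid), 0, config$celltype_sd)
    mk <- match(paste(grid$gene, grid$cell_type),
                paste(markers$gene, markers$cell_type))
    hit <- !is.na(mk)
    x[hit] <- x[hit] + ifelse(markers$direction[mk[hit]] == "over",
                              shift, -shift)
    x <- pmax(x, 0)
    pct <- stats::runif(nrow(grid), config$pct_background[1],
                        config$pct_background[2])
    mk_gene <- grid$gene %in% markers$gene
    pct[mk_gene] <- stats::runif(sum(mk_gene), config$pct_marker[1],
                                 config$pct_marker[2])
    depleted <- rep(FALSE, nrow(grid))
    depleted[hit] <- markers$direction[mk[hit]] == "under"
    pct[depleted] <- stats::runif(sum(depleted), config$pct_background[1],
                                  min(config$pct_background[2], 40))
    nuclei <- stats::setNames(
      round(stats::runif(config$n_cell_types, 500, 160000)), cts)
    as_expression_profile(
      data.frame(gene = grid$gene, cell_type = grid$cell_type,
                 mean_lognorm_expr = x, pct_expressing = pct,
                 n_nuclei = as.integer(nuclei[grid$cell_type]),
                 stringsAsFactors = FALSE),
      dataset_id = sprintf("SIM%02d", d))
  })
  names(profiles) <- vapply(profiles, attr, "", "dataset_id")
  list(profiles = profiles, truth = list(markers = markers))
}

#' Generate annotation gene sets with planted enriched terms
#'
#' One planted term per cell type contains that cell type's markers plus
#' random padding genes; background terms are drawn uniformly from the
#' same universe.
#'
#' @param config A `simulation_config`.
#' @param truth Ground-truth list from [generate_expression()].
#' @param seed Base seed; the annotation sub-seed is `seed + 202`.
#' @return List with `db` (an `annotation_db`) and updated `truth`
#'   (element `planted_terms`: named by term id, value = cell type).
#' @export
generate_annotations <- function(config, truth, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed + 202L)
  genes <- sim_genes(config$n_genes)
  markers <- truth$markers
  cts <- unique(markers$cell_type)
  non_marker <- setdiff(genes, markers$gene)
  terms <- list()
  planted <- character()
  for (ct in cts) {
    mg <- markers$gene[markers$cell_type == ct]
    pad <- sample(non_marker, max(0, config$planted_term_size - length(mg)))
    tid <- paste0("PLANTED_", gsub("[^A-Za-z0-9]+", "_", ct))
    terms[[tid]] <- c(mg, pad)
    planted[tid] <- ct
  }
  pool <- unique(c(markers$gene, unlist(terms, use.names = FALSE)))
  for (i in seq_len(config$n_annotation_terms)) {
    # background terms from the same universe so they share the domain
    terms[[sprintf("BG%04d", i)]] <-
      sample(unique(c(pool, non_marker)), config$planted_term_size)
  }
  db <- annotation_db(terms, source = "SIM")
  truth$planted_terms <- planted
  list(db = db, truth = truth)
}

#' Generate a PPI confidence edge list with planted hubs
#'
#' A sparse random background graph over the marker universe plus a few
#' hub proteins wired to many nodes; hub edges draw confidences at or
#' above the 0.9 cutoff while most background edges fall below it, so the
#' hubs dominate every centrality after filtering.
#'
#' @param config A `simulation_config`.
#' @param truth Ground-truth list containing `markers`.
#' @param seed Base seed; the PPI sub-seed is `seed + 303`.
#' @return List with `edges` (data frame `protein_a`, `protein_b`,
#'   `confidence` on the unit scale) and updated `truth` (elements `hubs`
#'   and `ppi_nodes`, the nodes incident to at least one edge at or above
#'   the 0.9 cutoff).
#' @export
generate_ppi <- function(config, truth, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed + 303L)
  nodes <- sort(unique(truth$markers$gene))
  hubs <- sort(sample(nodes, config$n_hubs))
  pairs <- t(utils::combn(nodes, 2))
  is_hub_pair <- pairs[, 1] %in% hubs | pairs[, 2] %in% hubs
  bg <- pairs[!is_hub_pair, , drop = FALSE]
  keep_bg <- stats::runif(nrow(bg)) < config$ppi_background_p
  bg <- bg[keep_bg, , drop = FALSE]
  hp <- pairs[is_hub_pair, , drop = FALSE]
  keep_hp <- stats::runif(nrow(hp)) < config$hub_connectivity
  hp <- hp[keep_hp, , drop = FALSE]
  edges <- data.frame(
    protein_a = c(bg[, 1], hp[, 1]),
    protein_b = c(bg[, 2], hp[, 2]),
    confidence = c(stats::runif(nrow(bg), config$conf_background[1],
                                config$conf_background[2]),
                   stats::runif(nrow(hp), config$conf_planted[1],
                                config$conf_planted[2])),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$protein_a, edges$protein_b), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "scale") <- "unit"
  truth$hubs <- hubs
  keep <- edges$confidence >= 0.9
  truth$ppi_nodes <- sort(unique(c(edges$protein_a[keep],
                                   edges$protein_b[keep])))
  list(edges = edges, truth = truth)
}

#' Generate a layered signed causal network with golden targets
#'
#' Builds disjoint intermediate chains, one per phenotype
#' (`I1 -> ... -> Ik -> phenotype`), then wires proteins into them.
#' Golden targets enter each of their `n_golden_phenotypes` chains at the
#' last layer with high-reliability edges (short, cheap paths); background
#' proteins enter at the first layer of at most
#' `max_background_phenotypes` chains with background-reliability edges.
#' Chains are disjoint, so a protein reaches exactly the phenotypes it is
#' wired to, and at default prioritization settings the golden targets and
#' only the golden targets qualify.
#'
#' @param config A `simulation_config`.
#' @param truth Ground-truth list containing `markers`.
#' @param seed Base seed; the causal sub-seed is `seed + 404`.
#' @return List with `edges` (data frame `source`, `target`, `effect`,
#'   `reliability` plus a `phenotypes` attribute) and updated `truth`
#'   (element `golden_targets`: data frame `gene`, `n_phenotypes`).
#' @export
generate_causal_network <- function(config, truth, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed + 404L)
  proteins <- sort(unique(truth$markers$gene))
  phenos <- config$phenotypes
  # golden targets live inside the confidence-filtered network (they are
  # prioritized from its node set), so sample them from the nodes known
  # to survive the cutoff when that information is available
  pool <- intersect(proteins, truth$ppi_nodes %||% proteins)
  if (length(pool) < config$n_golden_targets) pool <- proteins
  golden <- sort(sample(pool, config$n_golden_targets))
  background <- setdiff(proteins, golden)
  L <- config$n_intermediate_layers
  rel_bg <- function(n) stats::runif(n, config$reliability_range[1],
                                     config$reliability_range[2])
  rel_gold <- function(n) stats::runif(n, config$golden_reliability_range[1],
                                       config$golden_reliability_range[2])
  eff <- function(n) sample(CAUSAL_EFFECTS, n, replace = TRUE)
  inode <- function(l, p) sprintf("I%d_%s", l, gsub("[^A-Za-z0-9]+", "_", p))

  rows <- list()
  for (p in phenos) {
    chain <- c(vapply(seq_len(L), inode, "", p = p), p)
    n_e <- length(chain) - 1
    rows[[length(rows) + 1]] <- data.frame(
      source = chain[-length(chain)], target = chain[-1],
      effect = eff(n_e), reliability = rel_gold(n_e),
      stringsAsFactors = FALSE)
  }
  for (g in golden) {
    ph <- sample(phenos, config$n_golden_phenotypes)
    rows[[length(rows) + 1]] <- data.frame(
      source = g, target = inode(L, ph), effect = eff(length(ph)),
      reliability = rel_gold(length(ph)), stringsAsFactors = FALSE)
  }
  for (g in background) {
    k <- sample(config$max_background_phenotypes, 1)
    ph <- sample(phenos, k)
    rows[[length(rows) + 1]] <- data.frame(
      source = g, target = inode(1L, ph), effect = eff(k),
      reliability = rel_bg(k), stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, rows)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "phenotypes") <- phenos
  truth$golden_targets <- data.frame(
    gene = golden, n_phenotypes = config$n_golden_phenotypes,
    stringsAsFactors = FALSE)
  list(edges = edges, truth = truth)
}

#' Generate a drug-target table covering the golden targets
#'
#' Each golden target gets late-stage (phase III/IV) drug records; decoy
#' records (early-phase drugs on golden targets and late-stage drugs on
#' non-prioritized proteins) exercise the phase and join filters.
#'
#' @param config A `simulation_config`.
#' @param truth Ground-truth list containing `golden_targets` and
#'   `markers`.
#' @param seed Base seed; the drug sub-seed is `seed + 505`.
#' @return List with `drugs` (a `drug_table`) and the unchanged `truth`.
#' @export
generate_drug_table <- function(config, truth, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed + 505L)
  golden <- truth$golden_targets$gene
  others <- sample(setdiff(unique(truth$markers$gene), golden), 3)
  mechs <- c("receptor agonist", "receptor antagonist", "kinase inhibitor")
  inds <- c("heart failure", "hypertension", "atrial fibrillation",
            "myocardial infarction", "atherosclerosis")
  mk <- function(targets, phase_pool, tag) {
    do.call(rbind, lapply(seq_along(targets), function(i) {
      data.frame(
        drug = sprintf("%s-%s-%d", tag, targets[i], seq_len(2)),
        target = targets[i],
        mechanism = sample(mechs, 2, replace = TRUE),
        max_phase = sample(phase_pool, 2, replace = TRUE),
        indications = vapply(1:2, function(j)
          paste(sample(inds, 2), collapse = ";"), ""),
        stringsAsFactors = FALSE)
    }))
  }
  df <- rbind(mk(golden, 3:4, "LATE"), mk(golden, 1:2, "EARLY"),
              mk(others, 3:4, "OFFTGT"))
  df <- df[order(df$target, df$drug), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("drug_table", "data.frame")
  list(drugs = df, truth = truth)
}

#' Write a complete synthetic input directory with ground truth
#'
#' Runs every generator in sequence and writes all pipeline inputs
#' (expression TSV per dataset, GMT annotations, PPI edge TSV, causal edge
#' TSV, drug TSV) plus ground-truth TSVs (`truth_markers.tsv`,
#' `truth_hubs.tsv`, `truth_golden_targets.tsv`, `truth_planted_terms.tsv`)
#' into a directory.
#'
#' @param config A `simulation_config`.
#' @param dir Output directory (created if needed).
#' @param seed Base seed (default `config$seed`).
#' @return Invisibly, a list with `paths` (named file paths) and `truth`.
#' @export
simulate_inputs <- function(config = simulation_config(), dir,
                            seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- generate_expression(config, seed)
  ann <- generate_annotations(config, expr$truth, seed)
  ppi <- generate_ppi(config, ann$truth, seed)
  cau <- generate_causal_network(config, ppi$truth, seed)
  drg <- generate_drug_table(config, cau$truth, seed)
  truth <- drg$truth

  paths <- list()
  for (nm in names(expr$profiles)) {
    p <- file.path(dir, paste0("expression_", nm, ".tsv"))
    write_expression_profiles(expr$profiles[[nm]], p)
    paths[[paste0("expression_", nm)]] <- p
  }
  paths$annotations <- file.path(dir, "annotations.gmt")
  write_gmt(ann$db, paths$annotations)
  paths$ppi <- file.path(dir, "ppi_edges.tsv")
  write_confidence_edges(ppi$edges, paths$ppi)
  paths$causal <- file.path(dir, "causal_edges.tsv")
  write_causal_edges(cau$edges, paths$causal)
  paths$drugs <- file.path(dir, "drug_table.tsv")
  write_tsv_table(as.data.frame(drg$drugs), paths$drugs)

  write_tsv_table(truth$markers, file.path(dir, "truth_markers.tsv"))
  write_tsv_table(data.frame(hub = truth$hubs),
                  file.path(dir, "truth_hubs.tsv"))
  write_tsv_table(truth$golden_targets,
                  file.path(dir, "truth_golden_targets.tsv"))
  write_tsv_table(data.frame(term_id = names(truth$planted_terms),
                             cell_type = unname(truth$planted_terms)),
                  file.path(dir, "truth_planted_terms.tsv"))
  invisible(list(paths = paths, truth = truth))
}
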