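#' Packaged reference tables
#'
#' Small plain-text tables shipped with the package:
#'
#' * `nucleus_counts()` — per-cell-type nucleus counts of the three public
#'   cardiac snRNA-seq datasets (portal accessions SCP1303, SCP1852,
#'   SCP1849). The SCP1852 per-cell-type counts sum to 100,000, not to
#'   that study's declared total; the discrepancy is in the source records
#'   and is preserved as-is.
#' * `dataset_totals()` — each dataset's declared total nucleus count;
#'   their sum is the 849,646-nucleus consolidated analysis.
#' * `cvd_trial_drugs()` — the 15 late-stage cardiovascular-trial drugs
#'   for ADRA1A, PPARG and ROCK2 (5 mechanisms, 13 indications). The
#'   per-drug indication pairing is a synthetic allocation; see the file
#'   header.
#'
#' @return A data frame (`cvd_trial_drugs()` returns a `drug_table`).
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
nucleus_counts <- function() {
  read_tsv_table(system.file("extdata", "nucleus_counts.tsv",
                             package = "cardiotarget"),
                 c("dataset", "cell_type", "n_nuclei"))
}

#' @rdname fixtures
#' @export
dataset_totals <- function() {
  read_tsv_table(system.file("extdata", "dataset_totals.tsv",
                             package = "cardiotarget"),
                 c("dataset", "declared_total"))
}

#' @rdname fixtures
#' @export
cvd_trial_drugs <- function() {
  read_drug_table(system.file("extdata", "cvd_trial_drugs_synthetic.tsv",
                              package = "cardiotarget"))
}
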