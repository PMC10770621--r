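test_that("Z-scores standardize each gene against its own cell-type profile", {
  vals <- matrix(c(0, 0, 0, 10), nrow = 1,
                 dimnames = list("G1", paste0("ct", 1:4)))
  zt <- compute_zscores(make_profile(vals))
  # mean 2.5, population SD sqrt(18.75)
  expect_equal(sort(zt$z), c(-0.57735027, -0.57735027, -0.57735027,
                             1.73205081), tolerance = 1e-7)
  expect_equal(zt$p, 2 * pnorm(-abs(zt$z)))

  # two unequal cell types are forced to -1 / +1 by the population SD
  vals2 <- matrix(c(1, 3), nrow = 1, dimnames = list("G1", c("a", "b")))
  zt2 <- compute_zscores(make_profile(vals2))
  expect_equal(sort(zt2$z), c(-1, 1))

  # constant genes are undefined with a warning, not an error
  vals3 <- matrix(c(5, 5, 5, 1, 2, 3), nrow = 2, byrow = TRUE,
                  dimnames = list(c("G1", "G2"), c("a", "b", "c")))
  expect_warning(zt3 <- compute_zscores(make_profile(vals3)), "constant")
  expect_true(all(zt3$class[zt3$gene == "G1"] == "undefined"))
  expect_true(all(is.na(zt3$z[zt3$gene == "G1"])))
  expect_false(anyNA(zt3$z[zt3$gene == "G2"]))
})

test_that("every non-constant gene's Z vector has mean 0 and population SD 1", {
  set.seed(42)
  for (rep in 1:5) {
    vals <- matrix(rgamma(20 * 13, 4, 2), nrow = 20,
                   dimnames = list(sprintf("G%02d", 1:20),
                                   sprintf("ct%02d", 1:13)))
    zt <- compute_zscores(make_profile(vals))
    for (g in unique(zt$gene)) {
      z <- zt$z[zt$gene == g]
      expect_lt(abs(mean(z)), 1e-12)
      expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-12)
    }
  }
})

test_that("classification applies the two-threshold conjunction as stated", {
  zt <- classify_genes(make_ztable(c(3.5, 2.0, -3.5, 0.5),
                                   cell_type = paste0("ct", 1:4)))
  expect_equal(zt$class, c("over", "ns", "under", "ns"))
  # p for z = 3.5 is 4.65e-4, inside the cutoff; z = 2 gives 0.0455, outside
  expect_lt(zt$p[1], 0.001)
  expect_gt(zt$p[2], 0.001)

  # relaxing p_max lets the |z| >= 2 rule bind
  zt2 <- classify_genes(make_ztable(c(3.5, 2.0, -3.5, 0.5),
                                    cell_type = paste0("ct", 1:4)),
                        p_max = 1)
  expect_equal(zt2$class, c("over", "over", "under", "ns"))

  # undefined entries stay undefined
  zt3 <- classify_genes(make_ztable(c(NA, 4), cell_type = c("a", "b")))
  expect_equal(zt3$class, c("undefined", "over"))
})

test_that("tightening thresholds never adds genes to a significant set", {
  set.seed(7)
  vals <- matrix(rgamma(50 * 8, 2, 1), nrow = 50,
                 dimnames = list(sprintf("G%02d", 1:50),
                                 sprintf("ct%d", 1:8)))
  vals[1:5, 1] <- vals[1:5, 1] + 8
  zt <- compute_zscores(make_profile(vals))
  base <- significant_genes(classify_genes(zt, z_hi = 1.5, z_lo = -1.5,
                                           p_max = 0.05))$gene
  for (zh in c(2, 2.5, 3)) {
    tighter <- significant_genes(classify_genes(zt, z_hi = zh, z_lo = -zh,
                                                p_max = 0.05))$gene
    expect_true(all(tighter %in% base))
  }
  for (pm in c(0.01, 0.001)) {
    tighter <- significant_genes(classify_genes(zt, z_hi = 1.5, z_lo = -1.5,
                                                p_max = pm))$gene
    expect_true(all(tighter %in% base))
  }
})

test_that("dataset intersection keeps common genes and handles direction", {
  sig <- function(genes, dirs, id) {
    out <- data.frame(gene = genes, direction = dirs,
                      cell_types = "cardiomyocytes",
                      stringsAsFactors = FALSE)
    attr(out, "dataset_id") <- id
    class(out) <- c("gene_signature", "data.frame")
    out
  }
  s1 <- sig(c("A", "B", "C"), rep("over", 3), "d1")
  s2 <- sig(c("B", "C", "D"), rep("over", 3), "d2")
  s3 <- sig(c("B", "C"), rep("over", 2), "d3")
  out <- intersect_datasets(list(s1, s2, s3))
  expect_equal(out$gene, c("B", "C"))

  # identical sets pass through unchanged
  same <- intersect_datasets(list(s1, s1))
  expect_equal(same$gene, c("A", "B", "C"))

  # direction conflict: excluded when consistency is on, mixed when off
  c1 <- sig("X", "over", "d1")
  c2 <- sig("X", "under", "d2")
  expect_message(strict <- intersect_datasets(list(c1, c2), TRUE),
                 "inconsistent")
  expect_equal(nrow(strict), 0)
  expect_equal(attr(strict, "dropped_inconsistent"), "X")
  loose <- intersect_datasets(list(c1, c2), FALSE)
  expect_equal(loose$direction, "mixed")

  expect_error(intersect_datasets(list()), "empty")
  expect_error(intersect_datasets(list(s1)), "at least 2")

  # adding a dataset never grows the intersection
  out4 <- intersect_datasets(list(s1, s2, s3, sig("B", "over", "d4")))
  expect_true(all(out4$gene %in% out$gene))
})

test_that("cell-type assignment picks the maximum mean |z| with lexicographic ties", {
  zts <- list(
    classify_genes(make_ztable(c(3.4, -3.1, 0.2),
                               cell_type = c("mast cells", "fibroblasts",
                                             "pericytes"), dataset = "d1")),
    classify_genes(make_ztable(c(3.4, -3.3, 0.1),
                               cell_type = c("mast cells", "fibroblasts",
                                             "pericytes"), dataset = "d2")))
  # relax p to make |z| ~3.1-3.4 significant
  zts <- lapply(zts, classify_genes, p_max = 0.01)
  asn <- assign_cell_types("G1", zts)
  expect_equal(asn$cell_type[1], "mast cells")
  expect_equal(asn$mean_abs_z[1], 3.4)
  expect_true("fibroblasts" %in% asn$cell_type)

  # exact tie broken lexicographically
  ztie <- list(classify_genes(make_ztable(c(3.4, -3.4, 0),
                                          cell_type = c("zeta", "alpha", "mid")),
                              p_max = 0.01))
  expect_equal(assign_cell_types("G1", ztie)$cell_type[1], "alpha")

  expect_error(assign_cell_types("ABSENT", zts), "not significant")
})

test_that("cell-type summaries apply the percent-expressing filter to means only", {
  zt <- make_ztable(c(3.0, 4.0, -3.5, 0.1),
                    gene = c("G1", "G2", "G3", "G4"),
                    cell_type = rep("cardiomyocytes", 4),
                    pct = c(80, 60, 40, 90))
  zt$class <- c("over", "over", "under", "ns")
  summ <- summarize_cell_types(list(zt), pct_min = 50)
  row <- summ[summ$cell_type == "cardiomyocytes", ]
  # G3 (pct 40) is excluded from the mean but still counted as significant
  expect_equal(row$mean_z, 3.5)
  expect_equal(row$n_significant, 3)
})
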