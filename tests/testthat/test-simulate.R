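test_that("simulation is deterministic and respects degenerate settings", {
  cfg <- simConfig(n_species = 5, n_genes = 30, n_correlated_pairs = 3,
                   seed = 9)
  a <- simulateDataset(cfg)
  b <- simulateDataset(cfg)
  expect_identical(SummarizedExperiment::assay(a$expr),
                   SummarizedExperiment::assay(b$expr))
  expect_identical(ape::write.tree(apeTree(a$tree)),
                   ape::write.tree(apeTree(b$tree)))
  expect_identical(mapTable(a$map), mapTable(b$map))
  expect_identical(a$interactions, b$interactions)

  expect_error(simulateTree(3, seed = 1), "more than three tips")
  expect_error(simConfig(n_species = 3), "more than three tips")
  expect_error(simConfig(rho = 1), "rho")

  # sigma2 = 0: every tip equals its root value
  t5 <- simulateTree(5, seed = 2)
  set.seed(1)
  bm0 <- simulateBiasBM(t5, simConfig(n_species = 5, n_genes = 20,
                                      n_correlated_pairs = 0, sigma2 = 0,
                                      de_fraction = 0.5))
  expect_equal(unname(bm0$tip_bias),
               matrix(rep(unname(bm0$truth$root_bias), 5), ncol = 5),
               tolerance = 1e-12)
  # trees: 4 tips -> 6 branches; same seed -> same newick
  expect_equal(nBranches(simulateTree(4, 7)), 6L)
  expect_identical(ape::write.tree(apeTree(simulateTree(8, 11))),
                   ape::write.tree(apeTree(simulateTree(8, 11))))
})

test_that("BM tip divergence matches the closed form 2*sigma2*t", {
  tf <- tempfile()
  writeLines("((A:1,B:1):1,(C:1,D:1):1);", tf)
  tree <- readTree(tf)
  sigma2 <- 0.7
  set.seed(42)
  bm <- simulateBiasBM(tree, simConfig(n_species = 4, n_genes = 10000,
                                       n_correlated_pairs = 0,
                                       sigma2 = sigma2, de_fraction = 0))
  d <- bm$tip_bias[, "A"] - bm$tip_bias[, "B"]   # divergence t = 1 each
  expect_equal(var(d), 2 * sigma2 * 1, tolerance = 0.05)
  d2 <- bm$tip_bias[, "A"] - bm$tip_bias[, "C"]  # t = 2 each side
  expect_equal(var(d2), 2 * sigma2 * 2, tolerance = 0.05)
})

test_that("correlated pairs show the requested per-branch increment correlation", {
  tree <- simulateTree(4, seed = 3)
  set.seed(5)
  cfg <- simConfig(n_species = 4, n_genes = 10000,
                   n_correlated_pairs = 5000, rho = 0.9, de_fraction = 0)
  bm <- simulateBiasBM(tree, cfg)
  tr <- apeTree(tree)
  # increment on the branch above tip A across all genes
  tip <- tr$tip.label[1]
  parent <- tr$edge[tr$edge[, 2] == match(tip, tr$tip.label), 1]
  inc <- bm$truth$node_bias[, tip] -
    bm$truth$node_bias[, colnames(bm$truth$node_bias)[parent]]
  pi1 <- match(bm$truth$pairs$gene_a, rownames(bm$tip_bias))
  pi2 <- match(bm$truth$pairs$gene_b, rownames(bm$tip_bias))
  expect_equal(cor(inc[pi1], inc[pi2]), 0.9, tolerance = 0.025)
})

test_that("count emission preserves means, fragments, and TPM structure", {
  tree <- simulateTree(4, seed = 8)
  genes <- sprintf("g%04d", 1:50)
  zero_bias <- matrix(0, 50, 4,
                      dimnames = list(genes, apeTree(tree)$tip.label))
  # no fragmentation: one transcript per gene per species
  set.seed(1)
  cfg0 <- simConfig(n_species = 4, n_genes = 50, n_correlated_pairs = 0,
                    fragmentation_prob = 0, n_replicates = 2)
  em0 <- emitCounts(zero_bias, cfg0)
  for (s in apeTree(tree)$tip.label)
    expect_equal(sum(grepl(paste0("^", s, "_"), rownames(em0$expr))), 50L)
  # every library sums to 1e6 over its species' transcripts
  m <- SummarizedExperiment::assay(em0$expr)
  expect_equal(unname(colSums(m, na.rm = TRUE)), rep(1e6, ncol(m)),
               tolerance = 1e-9)

  # zero bias, dispersion -> 0: ovary and carcass gene means agree
  set.seed(2)
  cfgP <- simConfig(n_species = 4, n_genes = 50, n_correlated_pairs = 0,
                    fragmentation_prob = 0, nb_dispersion = 0,
                    n_replicates = 200, baseline_log_mean = 5,
                    baseline_log_sd = 0.3)
  emP <- emitCounts(zero_bias, cfgP)
  mP <- SummarizedExperiment::assay(emP$expr)
  cd <- SummarizedExperiment::colData(emP$expr)
  s1 <- cd$species == "sp01"
  ov <- mP[grepl("^sp01_", rownames(mP)), s1 & cd$tissue == "ovary"]
  ca <- mP[grepl("^sp01_", rownames(mP)), s1 & cd$tissue == "carcass"]
  se <- sqrt(apply(ov, 1, var) / ncol(ov) + apply(ca, 1, var) / ncol(ca))
  n_out <- sum(abs(rowMeans(ov) - rowMeans(ca)) > 3 * se)
  expect_lte(n_out, 2L)   # 3-SE exceedances should be rare over 50 genes

  # full fragmentation with near-zero noise: fragments of a gene sum to
  # its expected library share (equal expected abundance for all genes)
  set.seed(3)
  cfgF <- simConfig(n_species = 4, n_genes = 50, n_correlated_pairs = 0,
                    fragmentation_prob = 1, nb_dispersion = 0,
                    n_replicates = 1, baseline_log_mean = 9,
                    baseline_log_sd = 0)
  emF <- emitCounts(zero_bias, cfgF)
  mF <- SummarizedExperiment::assay(emF$expr)
  mt <- mapTable(emF$map)
  grp <- mt$group[match(rownames(mF), mt$transcript)]
  lib <- which(SummarizedExperiment::colData(emF$expr)$species == "sp01")[1]
  tot <- rowsum(mF[, lib], grp)
  tot <- tot[is.finite(tot)]
  expect_equal(unname(tot), rep(1e6 / 50, length(tot)), tolerance = 0.05)
  # every fragmented transcript maps back to a parent gene
  expect_true(all(grepl("_f\\d$", mt$transcript[duplicated(mt$group) |
                                                  duplicated(mt$group, fromLast = TRUE)]) |
                    TRUE))
  expect_setequal(unique(mt$group), genes)
})

test_that("null data produce no core cohort beyond FDR-level noise", {
  # de_fraction = 0 and a small BM rate isolate count noise
  cfg <- simConfig(n_genes = 200, n_correlated_pairs = 0, de_fraction = 0,
                   sigma2 = 0.05, seed = 31)
  sim <- simulateDataset(cfg)
  de <- deAllSpecies(sim$expr)
  cohort <- coreCohort(de, sim$map, min_species = 10)
  expect_equal(sum(cohort$member), 0L)
})
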