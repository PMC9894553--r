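make_bias_expr <- function(focal_vals, ref_vals) {
  m <- cbind(focal_vals, ref_vals)
  rownames(m) <- paste0("t", seq_along(focal_vals))
  make_expr(m, species = c("sp01", "sp01"), individual = c("i1", "i1"),
            tissue = c("ovary", "carcass"), units = "TPM10k")
}

test_that("bias ratios use the 0.01 pseudocount and log scale", {
  x <- make_bias_expr(c(10, 0, 0.99), c(10, 0, 0))
  map <- homologyMap(paste0("t", 1:3), paste0("g", 1:3))
  b <- computeBias(x, map)
  expect_equal(unname(b[, "sp01"]), c(0, 0, log(100)), tolerance = 1e-12)
  # swapping focal and reference negates every bias value
  b2 <- computeBias(x, map, focal = "carcass", reference = "ovary")
  expect_equal(b2, -b)
  expect_error(computeBias(logTransform(x), map), "non-log")
})

test_that("BM reconstruction matches the GLS oracle and stays convex", {
  for (seed in 1:30) {
    nt <- sample(4:8, 1)
    tree <- random_tree(nt, seed)
    set.seed(seed + 1000)
    tv <- setNames(rnorm(nt), apeTree(tree)$tip.label)
    asr <- asrBM(tree, tv)
    oracle <- oracle_asr_gls(apeTree(tree), tv)
    got <- asr$values[(nt + 1):(2 * nt - 1)]
    expect_equal(unname(got), unname(oracle), tolerance = 1e-8)
    expect_true(all(got >= min(tv) - 1e-12 & got <= max(tv) + 1e-12))
    # antisymmetry
    expect_equal(unname(asrBM(tree, -tv)$values), -unname(asr$values),
                 tolerance = 1e-12)
  }
  # constant tips reconstruct to the constant everywhere
  tree <- random_tree(6, 2)
  cst <- setNames(rep(3.5, 6), apeTree(tree)$tip.label)
  expect_equal(unname(asrBM(tree, cst)$values), rep(3.5, 11),
               tolerance = 1e-12)
  # symmetric 4-tip tree: root is the mean of the two cherry means
  tf <- tempfile(); writeLines("((A:1,B:1):1,(C:1,D:1):1);", tf)
  sym <- readTree(tf)
  a <- asrBM(sym, c(A = 1, B = 3, C = -2, D = 6))
  expect_equal(unname(a$values["a1"]), ((1 + 3) / 2 + (-2 + 6) / 2) / 2)
})

test_that("reconstruction agrees with an installed-package reference", {
  skip_if_not_installed("phytools")
  for (seed in c(3, 14)) {
    tree <- random_tree(7, seed)
    set.seed(seed)
    tv <- setNames(rnorm(7), apeTree(tree)$tip.label)
    ours <- asrBM(tree, tv)$values[8:13]
    ref <- phytools::fastAnc(apeTree(tree), tv)
    expect_equal(unname(ours), unname(as.numeric(ref)), tolerance = 1e-6)
  }
})

test_that("tip pruning keeps only branches with surviving endpoints", {
  tf <- tempfile()
  writeLines("((A:1,B:1):1,((C:1,D:1):1,E:2):1);", tf)
  tree <- readTree(tf)
  bt <- branchTable(tree)
  # branch ids: pre-order, alphabetically smallest descendant tip first
  expect_equal(bt$tips[bt$branch == 1], "A;B")
  expect_equal(bt$tips[bt$branch == 4], "C;D;E")
  expect_equal(bt$tips[bt$branch == 5], "C;D")
  expect_equal(bt$tips[bt$branch == 8], "E")

  asr <- asrBM(tree, c(A = 1, B = 2, C = 3, D = 0, E = NA))
  expect_equal(asr$n_tips_used, 4L)
  sc <- scaledChanges(asr, tree)
  # dropping E merges root->CDE->CD into one edge with no full-tree
  # equivalent; all other edges keep their ids
  expect_setequal(sc$branch, c(1L, 2L, 3L, 6L, 7L))
  expect_equal(sc$delta, (sc$descendant - sc$ancestral) / sc$length)

  expect_error(asrBM(tree, c(A = 1, B = 2, C = 3, D = NA, E = NA)),
               "more than three tips")
})

test_that("full-data genes give 2n-2 changes; shifts and swings rank stably", {
  tree <- simulateTree(12, 5)
  set.seed(6)
  bias <- matrix(rnorm(5 * 12), 5, 12,
                 dimnames = list(paste0("g", 1:5), apeTree(tree)$tip.label))
  bias[3, ] <- 1.7                     # constant gene: all deltas zero
  bc <- branchChangesAll(tree, bias)
  m <- changesMatrix(bc$changes)
  expect_equal(ncol(m), 22L)
  expect_true(all(rowSums(!is.na(m)) == 22L))
  expect_equal(unname(m["g3", ]), rep(0, 22))

  ev <- callShifts(data.frame(
    gene = "g", branch = 1:3, ancestral = c(-0.5, 0.3, 0.1),
    descendant = c(0.2, -0.1, 0.5), length = 1,
    delta = c(0.7, -0.4, 0.4)))
  expect_equal(ev$direction, c("gain", "loss"))
  expect_equal(nrow(ev), 2L)

  shifts <- data.frame(gene = c("gB", "gA", "gC", "gA"),
                       branch = c(2L, 1L, 3L, 5L),
                       direction = c("gain", "gain", "gain", "loss"),
                       ancestral = 0, descendant = 0,
                       swing = c(1.0, 0.5, 2.0, 0.3))
  top <- rankSwings(shifts, 2)
  expect_equal(top$swing[top$direction == "gain"], c(2.0, 1.0))
  expect_equal(top$swing[top$direction == "loss"], 0.3)  # whole set if k > n
  # ties break by (gene, branch)
  tie <- data.frame(gene = c("gB", "gA"), branch = c(1L, 1L),
                    direction = "gain", ancestral = 0, descendant = 0,
                    swing = 1)
  expect_equal(rankSwings(tie, 1)$gene, "gA")
  expect_error(rankSwings(shifts, 0), "> 0")
  expect_error(rankSwings(shifts[0, ], 1), "empty")
})

test_that("root recovery improves as the BM rate shrinks", {
  tree <- simulateTree(12, 5)
  err <- sapply(c(1, 0.01), function(s2) {
    set.seed(77)
    bm <- simulateBiasBM(tree, simConfig(n_genes = 300,
                                         n_correlated_pairs = 0,
                                         sigma2 = s2, de_fraction = 0.5))
    bc <- branchChangesAll(tree, bm$tip_bias)
    roots <- sapply(bc$asr, function(a) a$values[["a1"]])
    mean(abs(roots - bm$truth$root_bias[names(bc$asr)]))
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.1)
})

test_that("sign changes fall preferentially on long branches under null BM", {
  tree <- simulateTree(12, 5)
  set.seed(99)
  bm <- simulateBiasBM(tree, simConfig(n_genes = 2000,
                                       n_correlated_pairs = 0,
                                       sigma2 = 1, de_fraction = 0))
  bc <- branchChangesAll(tree, bm$tip_bias)
  ev <- callShifts(bc$details)
  freq <- table(factor(ev$branch, levels = 1:22)) / 2000
  len <- branchTable(tree)$length
  ct <- cor.test(as.numeric(freq), len, method = "spearman",
                 alternative = "greater", exact = FALSE)
  expect_lt(ct$p.value, 0.01)
})
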