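t12 <- simulateTree(12, 5)

test_that("correlation matrix matches the textbook formula and is well-formed", {
  set.seed(4)
  m <- matrix(rnorm(5 * 22), 5, dimnames = list(paste0("g", 1:5), NULL))
  m[2, ] <- -m[1, ]                  # exact negation
  cm <- correlationMatrix(make_changes(m, t12))
  expect_equal(unname(diag(cm$r)), rep(1, 5))
  expect_equal(cm$r["g1", "g2"], -1)
  expect_equal(cm$r, t(cm$r))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(cm$r[i, j], oracle_pearson(m[i, ], m[j, ]),
                 tolerance = 1e-12)
  expect_equal(cm$n_comparisons, 25)
  expect_equal(cm$n_distinct, 10)

  # permutation of genes permutes the matrix consistently
  perm <- c(3, 1, 5, 2, 4)
  cmp <- correlationMatrix(make_changes(m[perm, ], t12))
  expect_equal(cmp$r, cm$r[perm, perm])

  # incomplete rows are dropped; zero-variance rows give NA pairs
  m2 <- m; m2[3, 5] <- NA
  expect_message(cm2 <- correlationMatrix(make_changes(m2, t12)),
                 "dropped")
  expect_equal(cm2$n_genes, 4L)
  m3 <- m; m3[3, ] <- 2
  cm3 <- correlationMatrix(make_changes(m3, t12))
  expect_true(all(is.na(cm3$r["g3", setdiff(rownames(m3), "g3")])))
})

test_that("outlier genes are removed by the 2-SD whole-matrix rule", {
  m <- rbind(g1 = c(0, 0, 0, 0, 0, 20), g2 = rep(0, 6))
  tree4 <- branchTree(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  ch <- make_changes(m, tree4)
  out <- removeOutliers(ch)
  # oracle arithmetic over ALL entries, sample SD
  mu <- mean(m); sdv <- sd(as.vector(m))
  expect_true(any(abs(m["g1", ] - mu) > 2 * sdv))
  expect_true(all(abs(m["g2", ] - mu) <= 2 * sdv))
  expect_equal(rownames(changesMatrix(out)), "g2")
  expect_equal(attr(out, "removed"), "g1")

  # all-equal entries: zero SD, nothing removed
  flat <- make_changes(matrix(3, 2, 6, dimnames = list(c("a", "b"), NULL)),
                       tree4)
  expect_equal(nrow(changesMatrix(removeOutliers(flat))), 2L)
  # infinite cutoff is the identity
  expect_equal(changesMatrix(removeOutliers(ch, k_sd = Inf)),
               changesMatrix(ch))
})

test_that("interaction comparisons detect shifts and stay null under the null", {
  set.seed(10)
  G <- 120
  genes <- sprintf("g%03d", 1:G)
  r <- matrix(0, G, G, dimnames = list(genes, genes))
  vals <- pmin(pmax(rnorm(G * (G - 1) / 2, 0, 0.2), -0.99), 0.99)
  r[upper.tri(r)] <- vals
  r <- r + t(r); diag(r) <- 1
  map <- homologyMap(genes, genes, toupper(genes))
  pick <- cbind(sample(G, 300, replace = TRUE), sample(G, 300, replace = TRUE))
  pick <- pick[pick[, 1] != pick[, 2], ][1:250, ]
  inter_shift <- data.frame(gene_a = toupper(genes[pick[, 1]]),
                            gene_b = toupper(genes[pick[, 2]]),
                            class = "physical")
  r_shift <- r
  r_shift[pick] <- r_shift[cbind(pick[, 2], pick[, 1])] <-
    pmin(0.3 + rnorm(nrow(pick), 0, 0.05), 0.99)
  rep_shift <- compareToInteractions(make_cm(r_shift),
                                     normalizeInteractions(inter_shift),
                                     map, n_sample = 5000, n_repeats = 20,
                                     seed = 1)
  expect_lt(rep_shift$classes$max_p, 0.001)
  expect_gt(rep_shift$classes$mean_r, 0.2)

  # same-distribution class: max p over repeats stays large
  rep_null <- compareToInteractions(make_cm(r),
                                    normalizeInteractions(inter_shift),
                                    map, n_sample = 5000, n_repeats = 20,
                                    seed = 2)
  expect_gt(rep_null$classes$max_p, 0.001)

  # class with identical multiset as the whole unknown pool: t exactly 0
  g4 <- paste0("h", 1:4)
  r4 <- matrix(0, 4, 4, dimnames = list(g4, g4)); diag(r4) <- 1
  r4["h1", "h2"] <- r4["h2", "h1"] <- 0.1
  r4["h3", "h4"] <- r4["h4", "h3"] <- -0.1
  r4["h1", "h3"] <- r4["h3", "h1"] <- 0.1
  r4["h2", "h4"] <- r4["h4", "h2"] <- -0.1
  r4["h1", "h4"] <- r4["h4", "h1"] <- 0.1
  r4["h2", "h3"] <- r4["h3", "h2"] <- -0.1
  map4 <- homologyMap(g4, g4, toupper(g4))
  inter4 <- data.frame(gene_a = c("H1", "H3"), gene_b = c("H2", "H4"),
                       class = "physical")
  rep4 <- compareToInteractions(make_cm(r4), inter4, map4,
                                n_sample = 100, n_repeats = 5, seed = 3)
  expect_equal(rep4$classes$mean_t, 0, tolerance = 1e-12)
  expect_equal(rep4$classes$max_p, 1, tolerance = 1e-9)

  # enhancement vs suppression single test; sparse class warning
  inter_es <- data.frame(
    gene_a = toupper(genes[c(1, 3, 5, 7, 9, 11)]),
    gene_b = toupper(genes[c(2, 4, 6, 8, 10, 12)]),
    class = rep(c("enhancement", "suppression"), each = 3))
  rep_es <- compareToInteractions(make_cm(r), inter_es, map,
                                  n_sample = 1000, n_repeats = 3, seed = 4)
  expect_false(is.null(rep_es$enh_vs_sup))
  expect_warning(
    compareToInteractions(make_cm(r),
                          data.frame(gene_a = "G001", gene_b = "G002",
                                     class = "physical"),
                          map, n_sample = 10, n_repeats = 2, seed = 5),
    "fewer than 2")
})

test_that("network extraction applies the strict 0.825 threshold", {
  genes <- c("yp1", "p1", "p2", "p3")
  r <- diag(4); dimnames(r) <- list(genes, genes)
  r["yp1", "p1"] <- r["p1", "yp1"] <- 0.9
  r["yp1", "p2"] <- r["p2", "yp1"] <- -0.9
  r["yp1", "p3"] <- r["p3", "yp1"] <- 0.825
  net <- extractNetwork(make_cm(r), "yp1")
  expect_setequal(net$gene_b, c("p1", "p2"))
  expect_equal(net$sign[net$gene_b == "p1"], "positive")
  expect_equal(net$sign[net$gene_b == "p2"], "negative")
  expect_false("p3" %in% net$gene_b)       # 0.825 exactly: excluded
  expect_error(extractNetwork(make_cm(r), "absent"), "available")
})

test_that("the correlation machinery matches the 22-point Pearson null on iid changes", {
  set.seed(1)
  m <- matrix(rnorm(400 * 22), 400,
              dimnames = list(sprintf("g%03d", 1:400), NULL))
  cm <- correlationMatrix(make_changes(m, t12))
  rs <- cm$r[cbind(seq(1, 399, by = 2), seq(2, 400, by = 2))]
  ks <- suppressWarnings(stats::ks.test(rs, pearson_null_cdf(22)))
  expect_gt(ks$p.value, 0.01)
})
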