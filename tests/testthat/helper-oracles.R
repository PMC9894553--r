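# Independent oracles and small fixture builders, kept deliberately
# brute-force and separate from the implementation paths they check.

# GLS / ML Brownian-motion ancestral states by direct solution of the
# normal equations of sum over edges of (v_child - v_parent)^2 / len:
# the weighted graph Laplacian restricted to internal nodes.
oracle_asr_gls <- function(tr, tip_values) {
  n <- length(tr$tip.label)
  nn <- n + tr$Nnode
  W <- matrix(0, nn, nn)
  for (i in seq_len(nrow(tr$edge))) {
    a <- tr$edge[i, 1L]; b <- tr$edge[i, 2L]
    w <- 1 / tr$edge.length[i]
    W[a, b] <- W[a, b] + w; W[b, a] <- W[b, a] + w
  }
  L <- diag(rowSums(W)) - W
  int <- (n + 1L):nn
  x <- unname(tip_values[tr$tip.label])
  v <- solve(L[int, int, drop = FALSE], -L[int, seq_len(n), drop = FALSE] %*% x)
  drop(v)
}

# textbook Pearson formula, no cor()
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# sequential two-factor ANOVA proportions via lm()
oracle_anova_props <- function(y, tissue, species) {
  a <- stats::anova(stats::lm(y ~ factor(tissue) + factor(species)))
  ss <- a[["Sum Sq"]]
  ss / sum(ss)
}

# CDF of the Pearson correlation null with N points
pearson_null_cdf <- function(N) {
  function(r) stats::pt(r * sqrt((N - 2) / (1 - r^2)), N - 2)
}

# random ultrametric BranchTree with n tips
random_tree <- function(n, seed) simulateTree(n, seed)

# small TissueExpr fixture
make_expr <- function(values, species, individual, tissue, units = "TPM",
                      log_applied = FALSE) {
  ids <- paste(species, individual, tissue, sep = "_")
  colnames(values) <- ids
  tissueExpr(values,
             data.frame(library_id = ids, species = species,
                        individual = individual, tissue = tissue),
             units = units, log_applied = log_applied)
}

# genes x branches BranchChanges with arbitrary entries on a tree with
# the matching branch count
make_changes <- function(m, tree) {
  colnames(m) <- as.character(seq_len(ncol(m)))
  new("BranchChanges", changes = m, tree = tree)
}

# bare corrMatrix from an r matrix (for comparison-stage tests)
make_cm <- function(r) {
  structure(list(r = r, n_genes = nrow(r), n_points = 22,
                 n_comparisons = nrow(r)^2,
                 n_distinct = nrow(r) * (nrow(r) - 1) / 2),
            class = "corrMatrix")
}
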