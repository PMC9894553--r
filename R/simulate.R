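# Synthetic data with the statistical structure the analysis assumes:
# a coalescent-shaped ultrametric species tree, log expression bias
# evolving by (optionally correlated) Brownian motion on that tree,
# negative-binomial count noise, and assembly-style transcript
# fragmentation.

#' Simulation configuration
#'
#' Bundles every knob of the generator, validated once. Defaults are the
#' study conditions the pipeline targets: 12 species, 3 tissues
#' (ovary/head/carcass), 3 replicate individuals, a depth-1.0 ultrametric
#' tree, a 10% fraction of truly ovary-biased genes with a 2-fold
#' (ln 2) root bias, Brownian rate 1 per unit time on the log-bias
#' scale, and NB dispersion 0.1 (Var = mu + phi mu^2).
#'
#' @param n_species number of tips (>= 4; ancestral reconstruction needs
#'   more than three tips with data)
#' @param tree_depth root-to-tip depth in relative time units
#' @param n_genes number of homology groups
#' @param n_correlated_pairs number of gene pairs evolving under
#'   correlated BM
#' @param rho BM cross-correlation for those pairs, in (-1, 1)
#' @param sigma2 BM rate (variance per unit time) of log bias
#' @param baseline_log_mean,baseline_log_sd log-normal parameters of the
#'   per-gene carcass expected abundance
#' @param nb_dispersion NB dispersion phi, Var = mu + phi mu^2
#' @param n_replicates replicate individuals per species
#' @param fragmentation_prob probability a species' transcript of a gene
#'   is split into 2-4 assembly fragments
#' @param de_fraction fraction of genes with a true ovary bias at the
#'   root
#' @param ovary_bias natural-log root bias of truly biased genes
#'   (default ln 2, i.e. 2-fold)
#' @param head_bias logical; also evolve an independent head-vs-carcass
#'   bias (off by default: one contrast exercises the machinery)
#' @param seed integer seed; same config + seed gives byte-identical
#'   output
#' @return a validated list of class `simConfig`
#' @export
simConfig <- function(n_species = 12L, tree_depth = 1.0, n_genes = 500L,
                      n_correlated_pairs = 20L, rho = 0.9, sigma2 = 1.0,
                      baseline_log_mean = 3, baseline_log_sd = 1.5,
                      nb_dispersion = 0.1, n_replicates = 3L,
                      fragmentation_prob = 0.1, de_fraction = 0.1,
                      ovary_bias = log(2), head_bias = FALSE, seed = 1L) {
  cfg <- list(n_species = as.integer(n_species), tree_depth = tree_depth,
              n_genes = as.integer(n_genes),
              n_correlated_pairs = as.integer(n_correlated_pairs),
              rho = rho, sigma2 = sigma2,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              nb_dispersion = nb_dispersion,
              n_replicates = as.integer(n_replicates),
              fragmentation_prob = fragmentation_prob,
              de_fraction = de_fraction, ovary_bias = ovary_bias,
              head_bias = isTRUE(head_bias), seed = as.integer(seed))
  if (cfg$n_species < 4L)
    stop("n_species must be >= 4: ancestral state reconstruction requires more than three tips with data")
  if (abs(cfg$rho) >= 1) stop("|rho| must be < 1")
  if (cfg$sigma2 < 0) stop("sigma2 must be >= 0")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  for (p in c("fragmentation_prob", "de_fraction"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  if (2L * cfg$n_correlated_pairs > cfg$n_genes)
    stop("too many correlated pairs for n_genes")
  class(cfg) <- "simConfig"
  cfg
}

#' Simulate an ultrametric species tree
#'
#' Coalescent-style random topology and node heights ([ape::rcoal]),
#' rescaled to the requested depth. Tips get 4-letter codes
#' `sp01 ... spNN`.
#'
#' @param n_tips number of species (>= 4)
#' @param seed integer seed
#' @param depth root-to-tip depth (default 1.0)
#' @return a [BranchTree-class], ultrametric, depth as requested
#' @export
simulateTree <- function(n_tips, seed, depth = 1.0) {
  if (n_tips < 4L)
    stop("n_tips must be >= 4: ancestral state reconstruction requires more than three tips with data")
  set.seed(seed)
  tr <- ape::rcoal(n_tips, tip.label = sprintf("sp%02d", seq_len(n_tips)))
  d <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (depth / d)
  branchTree(tr, require_ultrametric = TRUE)
}

# BM on the tree for n_genes traits; pairs (2-column index matrix) evolve
# with per-branch increment correlation rho. root: vector of root values.
# Returns genes x nodes matrix over all ape node numbers.
bmOnTree <- function(tree, n_genes, root, sigma2, pairs = NULL, rho = 0) {
  tr <- apeTree(tree)
  n <- length(tr$tip.label)
  nn <- n + tr$Nnode
  val <- matrix(NA_real_, n_genes, nn)
  val[, n + 1L] <- root
  # correlated pair structure: second member's increment mixes with first's
  partner <- rep(NA_integer_, n_genes)
  if (!is.null(pairs) && nrow(pairs)) partner[pairs[, 2L]] <- pairs[, 1L]
  ord <- order(numberBranches(tr))        # preorder: parents before children
  for (i in ord) {
    p <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
    sd_b <- sqrt(sigma2 * tr$edge.length[i])
    z <- stats::rnorm(n_genes, 0, sd_b)
    mix <- which(!is.na(partner))
    if (length(mix))
      z[mix] <- rho * z[partner[mix]] + sqrt(1 - rho^2) * z[mix]
    val[, ch] <- val[, p] + z
  }
  colnames(val) <- c(tr$tip.label, sprintf("n%02d", (n + 1L):nn))
  val
}

#' Simulate expression bias evolving by Brownian motion
#'
#' Each gene's natural-log ovary-vs-carcass bias starts at a root value
#' (0 for unbiased genes, `ovary_bias` for a `de_fraction` of truly
#' biased genes) and accrues Gaussian increments of variance
#' `sigma2 * branch length` along every branch. `n_correlated_pairs`
#' disjoint gene pairs receive increments with correlation `rho` on
#' every branch (bivariate BM).
#'
#' Draws from the current RNG stream; seed it (or use
#' [simulateDataset()]) for reproducibility.
#'
#' @param tree a `BranchTree`
#' @param config a [simConfig()]
#' @return list with `tip_bias` (genes x species matrix), and `truth`
#'   (node values for all nodes, biased gene ids, correlated pair table)
#' @export
simulateBiasBM <- function(tree, config) {
  G <- config$n_genes
  genes <- sprintf("g%04d", seq_len(G))
  n_biased <- round(config$de_fraction * G)
  biased <- if (n_biased) sample(genes, n_biased) else character(0)
  root <- ifelse(genes %in% biased, config$ovary_bias, 0)
  pairs <- NULL
  if (config$n_correlated_pairs > 0) {
    idx <- sample(G, 2L * config$n_correlated_pairs)
    pairs <- matrix(idx, ncol = 2L)
  }
  nodeval <- bmOnTree(tree, G, root, config$sigma2, pairs, config$rho)
  rownames(nodeval) <- genes
  sp <- apeTree(tree)$tip.label
  truth <- list(
    node_bias = nodeval,
    root_bias = stats::setNames(root, genes),
    biased_genes = sort(biased),
    pairs = if (is.null(pairs)) {
      data.frame(gene_a = character(0), gene_b = character(0), rho = numeric(0))
    } else {
      data.frame(gene_a = genes[pairs[, 1L]], gene_b = genes[pairs[, 2L]],
                 rho = config$rho, stringsAsFactors = FALSE)
    })
  list(tip_bias = nodeval[, sp, drop = FALSE], truth = truth)
}

# NB draw with Var = mu + phi mu^2; phi -> 0 degenerates to Poisson
rnbinomDisp <- function(n, mu, phi) {
  if (phi <= 1e-12) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Emit a TPM expression table from simulated tip biases
#'
#' Builds one library per species x replicate individual x tissue
#' (ovary, head, carcass). A gene's carcass expected abundance is drawn
#' log-normally once per gene; its ovary expectation is
#' `mu * exp(bias)`; head mirrors carcass unless a head-bias matrix is
#' supplied. With probability `fragmentation_prob` a species' transcript
#' is split into 2-4 fragments whose expectations are a Dirichlet split
#' of the parent's (they sum to it exactly before sampling). Counts are
#' NB-sampled and each library is scaled to sum to 1e6, so the emitted
#' values are genuine TPM. Cells of transcripts from other species'
#' references are NA.
#'
#' Draws from the current RNG stream; seed it (or use
#' [simulateDataset()]) for reproducibility.
#'
#' @param tip_bias genes x species matrix of natural-log ovary bias
#' @param config a [simConfig()]
#' @param head_bias optional genes x species matrix for head-vs-carcass
#'   bias
#' @return list: `expr` ([TissueExpr-class], TPM), `map`
#'   ([HomologyMap-class] fragments -> groups, group symbols
#'   `gene<id>`), `fragments` (data.frame transcript/species/gene)
#' @export
emitCounts <- function(tip_bias, config, head_bias = NULL) {
  genes <- rownames(tip_bias)
  G <- length(genes)
  sp <- colnames(tip_bias)
  reps <- seq_len(config$n_replicates)
  tissues <- c("ovary", "head", "carcass")
  mu0 <- exp(stats::rnorm(G, config$baseline_log_mean, config$baseline_log_sd))

  # per (species, gene) fragmentation plan and Dirichlet weights
  frag_rows <- list(); weights <- list(); tx_species <- list()
  for (s in sp) {
    nf <- ifelse(stats::runif(G) < config$fragmentation_prob,
                 sample(2:4, G, replace = TRUE), 1L)
    w <- lapply(seq_len(G), function(g) {
      if (nf[g] == 1L) return(1)
      a <- stats::rgamma(nf[g], shape = 2)
      a / sum(a)
    })
    ids <- unlist(lapply(seq_len(G), function(g)
      if (nf[g] == 1L) paste0(s, "_", genes[g])
      else paste0(s, "_", genes[g], "_f", seq_len(nf[g]))))
    frag_rows[[s]] <- data.frame(
      transcript = ids, species = s,
      gene = rep(genes, nf), stringsAsFactors = FALSE)
    weights[[s]] <- w
    tx_species[[s]] <- rep(seq_len(G), nf)
  }
  frag_df <- do.call(rbind, frag_rows)
  rownames(frag_df) <- NULL

  lib_meta <- expand.grid(tissue = tissues, individual = reps, species = sp,
                          stringsAsFactors = FALSE)[, 3:1]
  lib_meta$individual <- paste0("i", lib_meta$individual)
  lib_meta$library_id <- paste(lib_meta$species, lib_meta$individual,
                               lib_meta$tissue, sep = "_")

  mat <- matrix(NA_real_, nrow(frag_df), nrow(lib_meta),
                dimnames = list(frag_df$transcript, lib_meta$library_id))
  for (li in seq_len(nrow(lib_meta))) {
    s <- lib_meta$species[li]; t <- lib_meta$tissue[li]
    bias <- switch(t,
                   ovary = tip_bias[, s],
                   head = if (is.null(head_bias)) rep(0, G) else head_bias[, s],
                   carcass = rep(0, G))
    mu_g <- mu0 * exp(bias)
    mu_tx <- unlist(weights[[s]]) * mu_g[tx_species[[s]]]
    counts <- rnbinomDisp(length(mu_tx), mu_tx, config$nb_dispersion)
    tot <- sum(counts)
    tpm <- if (tot > 0) counts / tot * 1e6 else counts
    mat[frag_df$species == s, li] <- tpm
  }

  map <- homologyMap(frag_df$transcript, frag_df$gene,
                     sub("^g", "gene", frag_df$gene))
  expr <- tissueExpr(mat, lib_meta, units = "TPM")
  list(expr = expr, map = map, fragments = frag_df)
}

#' Simulate a complete dataset with ground truth
#'
#' Seeds the RNG from `config$seed` and runs [simulateTree()],
#' [simulateBiasBM()] and [emitCounts()]; correlated pairs are labeled
#' as `physical` interactions between their reference gene symbols.
#' Identical config gives byte-identical output.
#'
#' @param config a [simConfig()]
#' @return list: `expr`, `tree`, `map`, `interactions`, `truth` (which
#'   also records the fragment map and, when enabled, the head-bias tip
#'   matrix)
#' @export
simulateDataset <- function(config = simConfig()) {
  tree <- simulateTree(config$n_species, config$seed, config$tree_depth)
  set.seed(config$seed + 1L)
  bm <- simulateBiasBM(tree, config)
  hb <- NULL
  if (config$head_bias) {
    hb_cfg <- config; hb_cfg$n_correlated_pairs <- 0L
    hb <- simulateBiasBM(tree, hb_cfg)$tip_bias
  }
  em <- emitCounts(bm$tip_bias, config, head_bias = hb)
  truth <- bm$truth
  truth$tip_bias <- bm$tip_bias
  truth$head_bias <- hb
  truth$fragments <- em$fragments
  sym <- function(g) sub("^g", "gene", g)
  inter <- if (nrow(truth$pairs)) {
    normalizeInteractions(data.frame(gene_a = sym(truth$pairs$gene_a),
                                     gene_b = sym(truth$pairs$gene_b),
                                     class = "physical",
                                     stringsAsFactors = FALSE))
  } else {
    data.frame(gene_a = character(0), gene_b = character(0),
               class = character(0))
  }
  list(expr = em$expr, tree = tree, map = em$map, interactions = inter,
       truth = truth, config = config)
}

#' Write a simulated dataset to a directory
#'
#' Emits `expression.tsv`, `meta.tsv`, `tree.nwk`, `homology_map.tsv`,
#' `interactions.tsv` and `truth.json` under `out_dir`.
#'
#' @param sim result of [simulateDataset()]
#' @param out_dir output directory (created if needed)
#' @return `out_dir`, invisibly
#' @export
writeSimulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeExpressionTable(sim$expr, file.path(out_dir, "expression.tsv"),
                       file.path(out_dir, "meta.tsv"))
  writeTree(sim$tree, file.path(out_dir, "tree.nwk"))
  writeHomologyMap(sim$map, file.path(out_dir, "homology_map.tsv"))
  writeInteractions(sim$interactions, file.path(out_dir, "interactions.tsv"))
  truth <- list(biased_genes = sim$truth$biased_genes,
                pairs = sim$truth$pairs,
                root_bias = as.list(sim$truth$root_bias),
                tip_bias = apply(sim$truth$tip_bias, 1, as.list,
                                 simplify = FALSE))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
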