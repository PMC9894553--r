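# Expression bias between tissues, Brownian-motion ancestral state
# reconstruction on the species tree, per-branch scaled changes, and
# qualitative gain/loss calls.

#' Compute per-species log expression-bias ratios
#'
#' For every individual with both a focal- and a reference-tissue
#' library, the per-transcript bias is
#' `ln((TPM10k_focal + 0.01) / (TPM10k_reference + 0.01))` — the ratio
#' is taken per library pair BEFORE any averaging, then averaged over
#' homology-group members and over replicate individuals. Positive
#' values mean focal-tissue enrichment; 0 means equal expression
#' (including the all-zero case, by the pseudocount). Species without a
#' complete library pair are `NA`.
#'
#' @param x a [TissueExpr-class] in (non-log) TPM10k units
#' @param map a [HomologyMap-class]
#' @param focal focal tissue (default `"ovary"`)
#' @param reference reference tissue (default `"carcass"`)
#' @param pseudocount added to both numerator and denominator
#'   (default 0.01)
#' @return homology-groups x species numeric matrix of mean log bias
#' @export
computeBias <- function(x, map, focal = "ovary", reference = "carcass",
                        pseudocount = 0.01) {
  stopifnot(is(x, "TissueExpr"))
  if (isTRUE(metadata(x)$log_applied))
    stop("bias ratios are computed from non-log TPM10k values")
  cd <- colData(x)
  m <- assay(x, "expr")
  cols <- list(); meta_rows <- list()
  for (s in unique(cd$species)) {
    for (ind in unique(cd$individual[cd$species == s])) {
      f <- which(cd$species == s & cd$individual == ind & cd$tissue == focal)
      r <- which(cd$species == s & cd$individual == ind &
                   cd$tissue == reference)
      if (length(f) == 1L && length(r) == 1L) {
        id <- paste(s, ind, sep = "_")
        cols[[id]] <- log((m[, f] + pseudocount) / (m[, r] + pseudocount))
        meta_rows[[id]] <- data.frame(library_id = id, species = s,
                                      individual = ind, tissue = "whole")
      }
    }
  }
  if (!length(cols)) stop("no individual has both tissues")
  ratio <- do.call(cbind, cols)
  rownames(ratio) <- rownames(m)
  # reuse the averaging machinery: group means, then per-species means
  rexpr <- tissueExpr(ratio, do.call(rbind, meta_rows), units = "TPM10k",
                      log_applied = TRUE)   # values already on log scale
  grp <- averageByGroup(rexpr, map)
  avg <- averageReplicates(grp)
  out <- assay(avg, "expr")
  colnames(out) <- colData(avg)$species
  out[, order(colnames(out)), drop = FALSE]
}

#' Brownian-motion ancestral state reconstruction for one gene
#'
#' Maximum-likelihood (equivalently GLS under the BM covariance) node
#' values: the assignment minimizing the sum over edges of
#' `(v_child - v_parent)^2 / length`, computed by a two-pass Gaussian
#' message-passing scheme (linear time in the number of nodes; the BM
#' rate cancels from the point estimates). Tips without data are dropped
#' first; reconstruction requires more than three tips with data.
#' Reconstructed values are convex combinations of tip values and so lie
#' within their range.
#'
#' @param tree a [BranchTree-class]
#' @param tip_values named numeric vector over species codes; `NA` =
#'   no data
#' @return list of class `asrResult`: `values` (named vector over all
#'   nodes of the pruned tree: tips then internal nodes `a1, a2, ...`
#'   with `a1` the root), `pruned` (the pruned `ape::phylo`),
#'   `n_tips_used`
#' @export
asrBM <- function(tree, tip_values) {
  stopifnot(is(tree, "BranchTree"))
  tr <- apeTree(tree)
  vals <- tip_values[tr$tip.label]
  have <- names(vals)[!is.na(vals)]
  if (length(have) <= 3L)
    stop("ancestral state reconstruction requires more than three tips with data (have ",
         length(have), ")")
  pr <- if (length(have) < length(tr$tip.label))
    ape::drop.tip(tr, setdiff(tr$tip.label, have)) else tr
  n <- length(pr$tip.label)
  nn <- n + pr$Nnode
  x <- unname(vals[pr$tip.label])

  ch <- nodeChildren(pr)
  parent <- integer(nn); blen <- numeric(nn)   # branch above each node
  for (i in seq_len(nrow(pr$edge))) {
    parent[pr$edge[i, 2L]] <- pr$edge[i, 1L]
    blen[pr$edge[i, 2L]] <- pr$edge.length[i]
  }
  root <- n + 1L
  u <- numeric(nn); U <- numeric(nn)          # upward messages
  u[seq_len(n)] <- x; U[seq_len(n)] <- 0
  rec_up <- function(nd) {
    if (nd <= n) return(invisible(NULL))
    for (k in ch[[nd]]) rec_up(k)
    L <- U[ch[[nd]]] + blen[ch[[nd]]]
    prec <- sum(1 / L)
    U[nd] <<- 1 / prec
    u[nd] <<- sum(u[ch[[nd]]] / L) / prec
  }
  rec_up(root)

  d <- rep(NA_real_, nn); D <- rep(Inf, nn)   # downward messages
  est <- numeric(nn)
  est[seq_len(n)] <- x
  est[root] <- u[root]
  rec_down <- function(nd) {
    kids <- ch[[nd]]
    if (is.null(kids)) return(invisible(NULL))
    for (k in kids) {
      sibs <- setdiff(kids, k)
      prec <- sum(1 / (U[sibs] + blen[sibs]))
      mean_num <- sum(u[sibs] / (U[sibs] + blen[sibs]))
      if (is.finite(D[nd])) {
        prec <- prec + 1 / D[nd]
        mean_num <- mean_num + d[nd] / D[nd]
      }
      D[k] <<- 1 / prec + blen[k]
      d[k] <<- mean_num / prec
      if (k > n)
        est[k] <<- (u[k] / U[k] + d[k] / D[k]) / (1 / U[k] + 1 / D[k])
      rec_down(k)
    }
  }
  rec_down(root)

  node_labels <- c(pr$tip.label, paste0("a", seq_len(pr$Nnode)))
  structure(list(values = stats::setNames(est, node_labels), pruned = pr,
                 n_tips_used = n), class = "asrResult")
}

#' Scaled per-branch changes for one reconstructed gene
#'
#' For every branch of the gene's (possibly pruned) tree that is
#' equivalent to a branch of the full species tree — same parent and
#' child node, identified by descendant tip sets — the scaled change is
#' `(descendant - ancestral) / branch length`. Branches merged by tip
#' pruning have no full-tree equivalent and are omitted.
#'
#' @param asr an `asrResult` from [asrBM()]
#' @param tree the full-species [BranchTree-class]
#' @return data.frame: `branch` (full-tree id), `ancestral`,
#'   `descendant`, `length`, `delta`
#' @export
scaledChanges <- function(asr, tree) {
  stopifnot(inherits(asr, "asrResult"), is(tree, "BranchTree"))
  pr <- asr$pruned
  ids <- matchBranches(tree, pr)
  keep <- !is.na(ids)
  anc <- asr$values[pr$edge[keep, 1L]]
  des <- asr$values[pr$edge[keep, 2L]]
  len <- pr$edge.length[keep]
  out <- data.frame(branch = ids[keep], ancestral = unname(anc),
                    descendant = unname(des), length = len,
                    delta = unname((des - anc) / len),
                    stringsAsFactors = FALSE)
  out[order(out$branch), , drop = FALSE]
}

#' Reconstruct all genes and assemble the genes-by-branches matrix
#'
#' Runs [asrBM()] and [scaledChanges()] for every row of a bias matrix.
#' Genes with three or fewer data tips are skipped (reported). Matrix
#' columns are the full tree's `2n - 2` branch ids; cells without an
#' equivalent branch are `NA`.
#'
#' @param tree a [BranchTree-class]
#' @param bias genes x species matrix (e.g. from [computeBias()])
#' @return list: `changes` (a [BranchChanges-class]), `details` (long
#'   data.frame gene/branch/ancestral/descendant/length/delta), `asr`
#'   (named list of `asrResult`), `skipped` (gene ids)
#' @export
branchChangesAll <- function(tree, bias) {
  stopifnot(is(tree, "BranchTree"))
  nb <- nBranches(tree)
  genes <- rownames(bias)
  mat <- matrix(NA_real_, length(genes), nb,
                dimnames = list(genes, as.character(seq_len(nb))))
  details <- list(); asr_list <- list(); skipped <- character(0)
  for (g in genes) {
    tv <- bias[g, ]
    if (sum(!is.na(tv)) <= 3L) { skipped <- c(skipped, g); next }
    asr <- asrBM(tree, tv)
    sc <- scaledChanges(asr, tree)
    mat[g, sc$branch] <- sc$delta
    sc$gene <- g
    details[[g]] <- sc
    asr_list[[g]] <- asr
  }
  if (length(skipped))
    message(length(skipped), " gene(s) skipped (<= 3 tips with data)")
  mat <- mat[setdiff(genes, skipped), , drop = FALSE]
  det <- if (length(details)) do.call(rbind, details) else
    data.frame(branch = integer(0), ancestral = numeric(0),
               descendant = numeric(0), length = numeric(0),
               delta = numeric(0), gene = character(0))
  rownames(det) <- NULL
  list(changes = new("BranchChanges", changes = mat, tree = tree),
       details = det[, c("gene", "branch", "ancestral", "descendant",
                         "length", "delta")],
       asr = asr_list, skipped = skipped)
}

#' Call qualitative gains and losses of tissue bias
#'
#' A shift event is a branch on which the reconstructed bias changes
#' sign: a gain when the ancestral value is <= 0 and the descendant
#' > 0, a loss in the converse case.
#'
#' @param details long data.frame from [branchChangesAll()]
#' @return data.frame: `gene`, `branch`, `direction` (`gain`/`loss`),
#'   `ancestral`, `descendant`, `swing` (= `|descendant - ancestral|`)
#' @export
callShifts <- function(details) {
  gain <- details$ancestral <= 0 & details$descendant > 0
  loss <- details$ancestral > 0 & details$descendant <= 0
  ev <- details[gain | loss, , drop = FALSE]
  ev$direction <- ifelse(ev$ancestral <= 0, "gain", "loss")
  ev$swing <- abs(ev$descendant - ev$ancestral)
  rownames(ev) <- NULL
  ev[, c("gene", "branch", "direction", "ancestral", "descendant", "swing")]
}

#' Rank the largest qualitative expression swings
#'
#' Returns the `k` largest-magnitude sign-changing swings in each
#' direction separately, ordered by decreasing `swing`; ties broken by
#' (gene, branch) lexicographic order. `k` larger than the available
#' set returns the whole set.
#'
#' @param shifts output of [callShifts()]
#' @param k events to keep per direction (> 0)
#' @return subset of `shifts`, ordered
#' @export
rankSwings <- function(shifts, k) {
  if (k <= 0) stop("k must be > 0")
  if (!nrow(shifts)) stop("empty shift set")
  pick <- function(dir) {
    s <- shifts[shifts$direction == dir, , drop = FALSE]
    s <- s[order(-s$swing, s$gene, s$branch), , drop = FALSE]
    utils::head(s, k)
  }
  out <- rbind(pick("gain"), pick("loss"))
  rownames(out) <- NULL
  out
}
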