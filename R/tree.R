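# Tree plumbing: stable branch numbering, ultrametricity, pruning
# equivalence. Node conventions follow ape: tips 1..n, root n+1.

#' @importFrom ape read.tree write.tree is.binary is.rooted drop.tip
#'   getMRCA node.depth.edgelength is.monophyletic
NULL

# children of every node, as a list indexed by node number
nodeChildren <- function(tr) {
  nn <- length(tr$tip.label) + tr$Nnode
  ch <- vector("list", nn)
  for (i in seq_len(nrow(tr$edge)))
    ch[[tr$edge[i, 1L]]] <- c(ch[[tr$edge[i, 1L]]], tr$edge[i, 2L])
  ch
}

# sorted descendant tip labels for every node (tips included)
cladeTips <- function(tr) {
  n <- length(tr$tip.label)
  nn <- n + tr$Nnode
  ch <- nodeChildren(tr)
  out <- vector("list", nn)
  rec <- function(nd) {
    if (nd <= n) {
      out[[nd]] <<- tr$tip.label[nd]
    } else {
      kids <- ch[[nd]]
      for (k in kids) rec(k)
      out[[nd]] <<- sort(unlist(out[kids]))
    }
  }
  rec(n + 1L)
  out
}

# Deterministic edge numbering: pre-order from the root, children at each
# node visited in alphabetical order of their smallest descendant tip
# label. Returns an integer vector aligned with tr$edge rows.
numberBranches <- function(tr) {
  n <- length(tr$tip.label)
  ch <- nodeChildren(tr)
  tips <- cladeTips(tr)
  edge_key <- paste(tr$edge[, 1L], tr$edge[, 2L])
  ids <- integer(nrow(tr$edge))
  counter <- 0L
  rec <- function(nd) {
    kids <- ch[[nd]]
    if (is.null(kids)) return(invisible(NULL))
    kids <- kids[order(vapply(kids, function(k) tips[[k]][1L], character(1)))]
    for (k in kids) {
      counter <<- counter + 1L
      ids[match(paste(nd, k), edge_key)] <<- counter
      rec(k)
    }
  }
  rec(n + 1L)
  ids
}

#' Build a BranchTree from an ape phylo
#'
#' Validates the pipeline's tree requirements (rooted, strictly
#' bifurcating, positive branch lengths) and assigns deterministic branch
#' ids (see [BranchTree-class]). Ultrametricity is assessed as (max tip
#' depth - min tip depth) / max depth <= 1e-6.
#'
#' @param tree an `ape::phylo`
#' @param require_ultrametric if TRUE, error unless ultrametric
#' @return a `BranchTree`
#' @export
branchTree <- function(tree, require_ultrametric = FALSE) {
  if (!inherits(tree, "phylo")) stop("need an ape phylo")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  if (!ape::is.binary(tree))
    stop("tree contains a polytomy; the pipeline assumes a strictly bifurcating tree")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (any(tree$edge.length <= 0)) stop("all branch lengths must be > 0")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  ultra <- (max(depths) - min(depths)) / max(depths) <= 1e-6
  if (require_ultrametric && !ultra)
    stop("tree is not ultrametric within tolerance")
  new("BranchTree", tree = tree, branchId = numberBranches(tree),
      ultrametric = ultra)
}

#' Read a species tree from a newick file
#'
#' @param path newick file; tips labeled with species codes, branch
#'   lengths required
#' @param require_ultrametric if TRUE, error unless ultrametric within
#'   relative tolerance 1e-6
#' @return a `BranchTree` with deterministic branch numbering
#' @export
readTree <- function(path, require_ultrametric = FALSE) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path)
  branchTree(tr, require_ultrametric = require_ultrametric)
}

#' Write a BranchTree to newick
#' @param x a `BranchTree`
#' @param path output file
#' @export
writeTree <- function(x, path) {
  ape::write.tree(apeTree(x), file = path)
  invisible(path)
}

# Map each edge of a pruned tree onto the full tree's branch ids.
#
# Nodes are identified across trees by their descendant tip sets: a pruned
# node corresponds to the MRCA (in the full tree) of its surviving tips. A
# pruned edge is "equivalent" to a full-tree branch only when its two
# endpoint nodes are both nodes of the full tree AND are directly
# connected there; edges created by collapsing a path through removed
# nodes map to NA (conservative rule: genes with dropped tips contribute
# only to branches whose endpoints both survive).
#
# Returns an integer vector along pruned$edge rows: full branch id or NA.
matchBranches <- function(full, pruned) {
  stopifnot(is(full, "BranchTree"))
  ftr <- apeTree(full)
  n_full <- length(ftr$tip.label)
  # full-tree node for each pruned node
  ptips <- cladeTips(pruned)
  nn <- length(pruned$tip.label) + pruned$Nnode
  fullNode <- integer(nn)
  for (nd in seq_len(nn)) {
    tl <- ptips[[nd]]
    if (length(tl) == 1L) {
      fullNode[nd] <- match(tl, ftr$tip.label)
    } else {
      fullNode[nd] <- ape::getMRCA(ftr, tl)
    }
  }
  fkey <- paste(ftr$edge[, 1L], ftr$edge[, 2L])
  out <- integer(nrow(pruned$edge))
  for (i in seq_len(nrow(pruned$edge))) {
    p <- fullNode[pruned$edge[i, 1L]]
    c_ <- fullNode[pruned$edge[i, 2L]]
    hit <- match(paste(p, c_), fkey)
    out[i] <- if (is.na(hit)) NA_integer_ else full@branchId[hit]
  }
  out
}

#' Check that a tip set is monophyletic in a tree
#' @param x a `BranchTree`
#' @param tips character vector of tip labels
#' @return TRUE/FALSE
#' @export
isMonophyleticClade <- function(x, tips) {
  tr <- apeTree(x)
  missing <- setdiff(tips, tr$tip.label)
  if (length(missing))
    stop("tips not in tree: ", paste(missing, collapse = ", "))
  if (length(tips) == length(tr$tip.label)) return(TRUE)
  ape::is.monophyletic(tr, tips)
}
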