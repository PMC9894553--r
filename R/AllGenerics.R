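#' Number of branches (edges) of a tree
#' @param x a `BranchTree`
#' @return integer, `2n - 2` for an n-tip rooted binary tree
#' @export
setGeneric("nBranches", function(x) standardGeneric("nBranches"))

#' @rdname nBranches
#' @export
setMethod("nBranches", "BranchTree", function(x) nrow(x@tree$edge))

#' @rdname nBranches
#' @export
setMethod("nBranches", "BranchChanges", function(x) ncol(x@changes))

#' Branch table of a BranchTree
#'
#' One row per edge, ordered by branch id: parent and child node numbers
#' (ape convention: tips are 1..n), branch length, and the child clade's
#' tip labels collapsed with `;`.
#'
#' @param x a `BranchTree`
#' @return data.frame with columns `branch`, `parent`, `child`,
#'   `length`, `tips`
#' @export
setGeneric("branchTable", function(x) standardGeneric("branchTable"))

#' @rdname branchTable
#' @export
setMethod("branchTable", "BranchTree", function(x) {
  tr <- x@tree
  ord <- order(x@branchId)
  desc <- cladeTips(tr)
  data.frame(branch = x@branchId[ord],
             parent = tr$edge[ord, 1L],
             child = tr$edge[ord, 2L],
             length = tr$edge.length[ord],
             tips = vapply(tr$edge[ord, 2L],
                           function(nd) paste(desc[[nd]], collapse = ";"),
                           character(1)),
             stringsAsFactors = FALSE)
})

#' Matrix of scaled changes
#' @param x a `BranchChanges`
#' @return numeric genes-by-branches matrix
#' @export
setGeneric("changesMatrix", function(x) standardGeneric("changesMatrix"))

#' @rdname changesMatrix
#' @export
setMethod("changesMatrix", "BranchChanges", function(x) x@changes)

#' Underlying ape phylo of a BranchTree
#' @param x a `BranchTree`
#' @return an `ape::phylo`
#' @export
setGeneric("apeTree", function(x) standardGeneric("apeTree"))

#' @rdname apeTree
#' @export
setMethod("apeTree", "BranchTree", function(x) x@tree)

#' Homology map as a data.frame
#' @param x a `HomologyMap`
#' @return data.frame with columns `transcript`, `group`, `parent_gene`
#' @export
setGeneric("mapTable", function(x) standardGeneric("mapTable"))

#' @rdname mapTable
#' @export
setMethod("mapTable", "HomologyMap", function(x) x@map)
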