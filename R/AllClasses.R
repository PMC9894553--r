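#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

setOldClass("phylo")

#' Tissue enumeration
#'
#' The four tissue labels the pipeline accepts for a sequencing library.
#' @export
TISSUES <- c("ovary", "head", "carcass", "whole")

#' TissueExpr: expression matrix with library metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding a
#' transcripts-by-libraries (or homology-groups-by-libraries) abundance
#' matrix in the assay `"expr"`, with `colData` columns `species`
#' (4-letter code), `individual` and `tissue` (one of
#' `ovary`, `head`, `carcass`, `whole`). `metadata()` carries `units`
#' (`"TPM"` or `"TPM10k"`) and `log_applied`.
#'
#' Values must be non-negative before log transformation; `NA` marks a
#' transcript absent from the library's species reference (each species
#' has its own reference, so a combined matrix needs an absent marker).
#'
#' @export
setClass("TissueExpr", contains = "SummarizedExperiment")

setValidity("TissueExpr", function(object) {
  cd <- colData(object)
  need <- c("species", "individual", "tissue")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain:", paste(need, collapse = ", ")))
  bad <- setdiff(unique(as.character(cd$tissue)), TISSUES)
  if (length(bad))
    return(sprintf("unknown tissue label(s): %s (allowed: %s)",
                   paste(bad, collapse = ", "), paste(TISSUES, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    return("duplicate transcript ids")
  m <- assay(object, "expr")
  if (!isTRUE(metadata(object)$log_applied) && any(m < 0, na.rm = TRUE))
    return("negative abundance values")
  TRUE
})

#' Construct a TissueExpr object
#'
#' @param values numeric matrix, rows = transcripts (or homology groups),
#'   columns = libraries. `NA` marks values absent from a species'
#'   reference; all present values must be non-negative.
#' @param meta data.frame with one row per column of `values` and columns
#'   `library_id`, `species`, `individual`, `tissue`. Matched to the
#'   columns of `values` by `library_id`; the species code match is
#'   case-insensitive downstream.
#' @param units unit label, `"TPM"` or `"TPM10k"`.
#' @param log_applied logical; whether natural log has been applied.
#' @return a `TissueExpr`
#' @export
tissueExpr <- function(values, meta, units = "TPM", log_applied = FALSE) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("expression matrix must have library ids as column names")
  meta <- as.data.frame(meta)
  if (!all(c("library_id", "species", "individual", "tissue") %in% names(meta)))
    stop("metadata needs columns library_id, species, individual, tissue")
  if (anyDuplicated(meta$library_id))
    stop("duplicate library_id in metadata")
  missing_meta <- setdiff(colnames(values), meta$library_id)
  if (length(missing_meta))
    stop("libraries without metadata: ", paste(missing_meta, collapse = ", "))
  meta <- meta[match(colnames(values), meta$library_id), , drop = FALSE]
  bad <- !(meta$tissue %in% TISSUES)
  if (any(bad))
    stop(sprintf("unknown tissue label '%s' for library '%s'",
                 meta$tissue[which(bad)[1]], meta$library_id[which(bad)[1]]))
  cd <- DataFrame(species = as.character(meta$species),
                  individual = as.character(meta$individual),
                  tissue = as.character(meta$tissue),
                  row.names = meta$library_id)
  se <- SummarizedExperiment(assays = list(expr = values), colData = cd,
                             metadata = list(units = units,
                                             log_applied = log_applied))
  new("TissueExpr", se)
}

#' BranchTree: rooted bifurcating phylogeny with stable branch ids
#'
#' Wraps an [ape::phylo] tree. Branch ids label the `2n - 2` edges of a
#' rooted binary n-tip tree deterministically: edges are numbered in
#' pre-order from the root, with children at every node visited in
#' alphabetical order of their smallest descendant tip label. The
#' numbering is therefore invariant to rotations of the input newick.
#'
#' @slot tree an `ape::phylo`, rooted, strictly bifurcating, all branch
#'   lengths positive
#' @slot branchId integer vector aligned with `tree$edge` rows
#' @slot ultrametric logical flag (checked at construction within
#'   relative tolerance 1e-6 of tip-depth spread)
#' @export
setClass("BranchTree",
         representation(tree = "phylo", branchId = "integer",
                        ultrametric = "logical"))

setValidity("BranchTree", function(object) {
  tr <- object@tree
  n <- length(tr$tip.label)
  if (is.null(tr$edge.length)) return("tree has no branch lengths")
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length <= 0))
    return("all branch lengths must be positive")
  if (!ape::is.binary(tr)) return("tree must be strictly bifurcating")
  if (!ape::is.rooted(tr)) return("tree must be rooted")
  if (nrow(tr$edge) != 2L * n - 2L) return("edge count is not 2n-2")
  if (length(object@branchId) != nrow(tr$edge))
    return("branchId not aligned with edges")
  if (!setequal(object@branchId, seq_len(nrow(tr$edge))))
    return("branchId must be a bijection onto 1..2n-2")
  TRUE
})

#' BranchChanges: genes-by-branches matrix of scaled evolutionary changes
#'
#' Rows are genes (homology groups), columns are the branches of the full
#' species tree in branch-id order. Entry (g, b) is the scaled change
#' \eqn{\Delta = (v_{child} - v_{parent}) / \ell_b} of reconstructed
#' expression bias on branch b; `NA` where the gene's pruned tree has no
#' branch equivalent to b.
#'
#' @slot changes numeric matrix, colnames are branch ids
#' @slot tree the `BranchTree` the columns refer to
#' @export
setClass("BranchChanges",
         representation(changes = "matrix", tree = "BranchTree"))

setValidity("BranchChanges", function(object) {
  nb <- nBranches(object@tree)
  if (ncol(object@changes) != nb)
    return(sprintf("changes must have %d columns (one per branch)", nb))
  TRUE
})

#' HomologyMap: transcript-level homology and annotation map
#'
#' Maps each transcript to its cross-species homology group and,
#' optionally, to a reference parent gene symbol (several transcripts and
#' several parent genes may share one group).
#'
#' @slot map data.frame with columns `transcript`, `group`,
#'   `parent_gene` (NA when unannotated)
#' @export
setClass("HomologyMap", representation(map = "data.frame"))

setValidity("HomologyMap", function(object) {
  m <- object@map
  if (!all(c("transcript", "group", "parent_gene") %in% names(m)))
    return("map needs columns transcript, group, parent_gene")
  if (anyDuplicated(m$transcript))
    return("a transcript may be mapped at most once")
  if (any(is.na(m$group) | m$group == ""))
    return("every mapped transcript needs a non-empty group")
  TRUE
})

#' Construct a HomologyMap
#' @param transcript character vector of transcript ids
#' @param group homology group id per transcript
#' @param parent_gene reference gene symbol per transcript (NA allowed)
#' @return a `HomologyMap`
#' @export
homologyMap <- function(transcript, group, parent_gene = NA_character_) {
  new("HomologyMap",
      map = data.frame(transcript = as.character(transcript),
                       group = as.character(group),
                       parent_gene = as.character(parent_gene),
                       stringsAsFactors = FALSE))
}

setMethod("show", "TissueExpr", function(object) {
  cat(sprintf("TissueExpr: %d features x %d libraries [%s%s]\n",
              nrow(object), ncol(object),
              metadata(object)$units %||% "?",
              if (isTRUE(metadata(object)$log_applied)) ", ln" else ""))
  cd <- colData(object)
  cat(sprintf("  species: %d  tissues: %s\n",
              length(unique(cd$species)),
              paste(sort(unique(cd$tissue)), collapse = "/")))
})

setMethod("show", "BranchTree", function(object) {
  cat(sprintf("BranchTree: %d tips, %d branches%s\n",
              length(object@tree$tip.label), nBranches(object),
              if (object@ultrametric) ", ultrametric" else ""))
})

setMethod("show", "BranchChanges", function(object) {
  cat(sprintf("BranchChanges: %d genes x %d branches (%d complete rows)\n",
              nrow(object@changes), ncol(object@changes),
              sum(stats::complete.cases(object@changes))))
})

setMethod("show", "HomologyMap", function(object) {
  cat(sprintf("HomologyMap: %d transcripts, %d groups, %d annotated\n",
              nrow(object@map), length(unique(object@map$group)),
              sum(!is.na(object@map$parent_gene))))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
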