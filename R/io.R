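# TSV readers/writers for every external format the pipeline touches.
# All files are UTF-8, tab-delimited, "." decimal.

#' Read an expression table with library metadata
#'
#' The expression file is a TSV whose header row holds library ids and
#' whose first column holds transcript ids; the metadata file is a TSV
#' with columns `library_id`, `species`, `individual`, `tissue`.
#' Libraries without a metadata row are rejected; duplicate transcript
#' ids, negative values and unknown tissue labels are hard errors.
#' Empty cells are read as `NA` (transcript absent from that library's
#' species reference).
#'
#' @param path expression TSV
#' @param meta_path metadata TSV
#' @param units unit label recorded on the object (default `"TPM"`)
#' @return a [TissueExpr-class]
#' @export
readExpressionTable <- function(path, meta_path, units = "TPM") {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate transcript id: ", ids[duplicated(ids)][1L])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (any(m < 0, na.rm = TRUE))
    stop("negative abundance value in ", path)
  meta <- utils::read.delim(meta_path, colClasses = "character")
  tissueExpr(m, meta, units = units, log_applied = FALSE)
}

#' Write a TissueExpr expression matrix and its metadata to TSV
#'
#' Inverse of [readExpressionTable()]: writing then reading yields an
#' identical object (up to numeric text round-trip, 15 significant
#' digits).
#'
#' @param x a `TissueExpr`
#' @param path expression TSV to write
#' @param meta_path metadata TSV to write
#' @export
writeExpressionTable <- function(x, path, meta_path) {
  m <- assay(x, "expr")
  df <- data.frame(transcript = rownames(m),
                   signif(m, 15), check.names = FALSE)
  colnames(df) <- c("transcript", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(colData(x))
  meta <- data.frame(library_id = rownames(cd), cd, row.names = NULL)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a transcript homology/annotation map
#'
#' TSV with columns `transcript`, `group` and optionally `parent_gene`
#' (reference gene symbol; empty = unannotated).
#'
#' @param path TSV file
#' @return a [HomologyMap-class]
#' @export
readHomologyMap <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = c("NA", ""))
  if (!"parent_gene" %in% names(df)) df$parent_gene <- NA_character_
  homologyMap(df$transcript, df$group, df$parent_gene)
}

#' Write a HomologyMap to TSV
#' @param x a `HomologyMap`
#' @param path output TSV
#' @export
writeHomologyMap <- function(x, path) {
  utils::write.table(mapTable(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

INTERACTION_CLASSES <- c("physical", "enhancement", "suppression")

#' Read a gene-pair interaction table
#'
#' TSV with columns `gene_a`, `gene_b`, `class` where class is one of
#' `physical`, `enhancement`, `suppression`. Pairs are unordered:
#' (x, y) and (y, x) of the same class are deduplicated; the same pair
#' may appear under several classes. Self-pairs are dropped with a
#' warning; an unknown class is a hard error.
#'
#' @param path TSV file
#' @return data.frame with columns `gene_a`, `gene_b`, `class`
#'   (`gene_a` < `gene_b` lexicographically)
#' @export
readInteractions <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  normalizeInteractions(df)
}

#' Normalize an interaction data.frame
#'
#' Same contract as [readInteractions()] for an in-memory data.frame.
#' @param df data.frame with columns `gene_a`, `gene_b`, `class`
#' @return deduplicated data.frame of unordered pairs
#' @export
normalizeInteractions <- function(df) {
  stopifnot(all(c("gene_a", "gene_b", "class") %in% names(df)))
  bad <- setdiff(unique(df$class), INTERACTION_CLASSES)
  if (length(bad))
    stop("unknown interaction class: ", paste(bad, collapse = ", "))
  self <- df$gene_a == df$gene_b
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped")
    df <- df[!self, , drop = FALSE]
  }
  a <- pmin(df$gene_a, df$gene_b)
  b <- pmax(df$gene_a, df$gene_b)
  out <- data.frame(gene_a = a, gene_b = b, class = df$class,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("gene_a", "gene_b", "class")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an interaction table to TSV
#' @param df interaction data.frame (as from [readInteractions()])
#' @param path output TSV
#' @export
writeInteractions <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
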