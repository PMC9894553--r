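# Cross-species normalization: TPM -> TPM10k -> natural log, then
# averaging over homology groups and replicate individuals (in that
# order).

#' Convert TPM to cross-species-comparable TPM10k
#'
#' TPM is a within-library relative unit and is not directly comparable
#' between references of different sizes; TPM10k rescales each value by
#' the number of genes in that library's species reference divided by
#' 10^4: `TPM10k = TPM * n_ref / 1e4`. With a 10,000-gene reference TPM
#' and TPM10k coincide.
#'
#' @param x a [TissueExpr-class] in TPM units
#' @param n_reference_genes named integer vector, reference gene count
#'   per species (here: collapsed homology-group count). Species match
#'   is case-insensitive. A single unnamed value is recycled to all
#'   species.
#' @return a `TissueExpr` in TPM10k units
#' @export
tpm10k <- function(x, n_reference_genes) {
  stopifnot(is(x, "TissueExpr"))
  if (!identical(metadata(x)$units, "TPM"))
    stop("input must be in TPM units (got ", metadata(x)$units, ")")
  sp <- tolower(colData(x)$species)
  if (is.null(names(n_reference_genes))) {
    if (length(n_reference_genes) != 1L)
      stop("n_reference_genes must be named per species or a single value")
    n_ref <- rep(n_reference_genes, ncol(x))
  } else {
    names(n_reference_genes) <- tolower(names(n_reference_genes))
    missing <- setdiff(unique(sp), names(n_reference_genes))
    if (length(missing))
      stop("no reference gene count for species: ",
           paste(missing, collapse = ", "))
    n_ref <- unname(n_reference_genes[sp])
  }
  if (any(n_ref <= 0)) stop("n_reference_genes must be > 0")
  m <- sweep(assay(x, "expr"), 2L, n_ref / 1e4, `*`)
  out <- x
  SummarizedExperiment::assay(out, "expr") <- m
  metadata(out)$units <- "TPM10k"
  out
}

#' Natural-log transform a normalized table
#'
#' Applies `ln(x + eps_log)` cellwise, at most once. With the default
#' `eps_log = 0`, zeros have no finite log and are masked to `NA`
#' (excluded from downstream modeling) rather than pseudocounted; the
#' bias-ratio stage has its own 0.01 pseudocount and is unaffected.
#'
#' @param x a `TissueExpr` (not yet log-transformed)
#' @param eps_log small constant added before the log (default 0)
#' @return a `TissueExpr` with `log_applied = TRUE`
#' @export
logTransform <- function(x, eps_log = 0) {
  stopifnot(is(x, "TissueExpr"))
  if (isTRUE(metadata(x)$log_applied))
    stop("log already applied to this table")
  m <- log(assay(x, "expr") + eps_log)
  m[!is.finite(m)] <- NA_real_
  out <- x
  SummarizedExperiment::assay(out, "expr") <- m
  metadata(out)$log_applied <- TRUE
  out
}

#' Average transcript values over homology groups
#'
#' For each library, a group's value is the arithmetic mean of its member
#' transcripts' values in that library; `NA` members (absent from the
#' species' reference, or masked zeros after log) are ignored, and a
#' group with no finite member in a library is `NA` there. Unmapped
#' transcripts are dropped with a message; groups with no surviving
#' member are dropped with a warning.
#'
#' @param x a `TissueExpr` (transcript rows)
#' @param map a [HomologyMap-class]
#' @return a `TissueExpr` with homology groups as rows
#' @export
averageByGroup <- function(x, map) {
  stopifnot(is(x, "TissueExpr"), is(map, "HomologyMap"))
  m <- assay(x, "expr")
  mt <- mapTable(map)
  grp <- mt$group[match(rownames(m), mt$transcript)]
  unmapped <- is.na(grp)
  if (any(unmapped))
    message(sum(unmapped), " unmapped transcript(s) dropped")
  empty <- setdiff(unique(mt$group), grp[!unmapped])
  if (length(empty))
    warning(length(empty), " homology group(s) with no expressed member dropped")
  m <- m[!unmapped, , drop = FALSE]
  grp <- grp[!unmapped]
  pres <- !is.na(m)
  mz <- m; mz[!pres] <- 0
  sums <- rowsum(mz, grp)
  counts <- rowsum(pres + 0, grp)
  avg <- sums / counts               # 0/0 -> NaN where no member present
  avg[counts == 0] <- NA_real_
  avg[is.nan(avg)] <- NA_real_
  cd <- as.data.frame(colData(x))
  meta <- data.frame(library_id = rownames(cd), cd, row.names = NULL)
  tissueExpr(avg, meta, units = metadata(x)$units,
             log_applied = isTRUE(metadata(x)$log_applied))
}

#' Average over replicate individuals
#'
#' Collapses libraries to one column per (species, tissue): the mean
#' over replicate individuals, ignoring `NA`s. A (species, tissue) cell
#' with no finite replicate is `NA` (a missing marker, never 0).
#'
#' @param x a `TissueExpr`
#' @return a `TissueExpr` with columns `species_tissue` and
#'   `individual = "avg"`
#' @export
averageReplicates <- function(x) {
  stopifnot(is(x, "TissueExpr"))
  cd <- colData(x)
  key <- paste(cd$species, cd$tissue, sep = "_")
  m <- assay(x, "expr")
  pres <- !is.na(m)
  mz <- m; mz[!pres] <- 0
  sums <- t(rowsum(t(mz), key))
  counts <- t(rowsum(t(pres + 0), key))
  avg <- sums / counts
  avg[counts == 0] <- NA_real_
  avg[is.nan(avg)] <- NA_real_
  uk <- colnames(avg)
  first <- match(uk, key)
  meta <- data.frame(library_id = uk,
                     species = cd$species[first],
                     individual = "avg",
                     tissue = cd$tissue[first])
  tissueExpr(avg, meta, units = metadata(x)$units,
             log_applied = isTRUE(metadata(x)$log_applied))
}
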