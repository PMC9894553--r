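# Per-gene two-factor decomposition of expression variance into tissue,
# species and residual components, and the TVG/SVG classification.
#
# Inputs are replicate- and group-averaged natural-log TPM10k values,
# one value per (species, tissue) cell, so the design is balanced and
# sequential (type-I) sums of squares are order-invariant (asserted by
# test). Tissue is entered first.

#' Partition per-gene expression variance into tissue/species/residual
#'
#' Sequential two-factor ANOVA (tissue first, then species, no
#' interaction) on one value per (species, tissue); proportions are
#' each factor's sum of squares over the total. Genes with any missing
#' cell are excluded, as are constant genes (zero total SS); both are
#' reported in attributes `"excluded_missing"` / `"excluded_constant"`.
#'
#' @param x a [TissueExpr-class] of replicate-averaged log values
#'   (columns one per species_tissue)
#' @param tissues the two tissues to contrast (default ovary vs carcass)
#' @param species species subset (default: all species in `x`); at
#'   least 2
#' @return data.frame: `group`, `prop_tissue`, `prop_species`,
#'   `prop_residual`, `n_observations`
#' @export
partitionVariance <- function(x, tissues = c("ovary", "carcass"),
                              species = NULL) {
  stopifnot(is(x, "TissueExpr"), length(tissues) == 2L)
  cd <- colData(x)
  if (is.null(species)) species <- unique(cd$species)
  if (length(species) < 2L) stop("need >= 2 species")
  keep <- cd$species %in% species & cd$tissue %in% tissues
  m <- assay(x, "expr")[, keep, drop = FALSE]
  tis <- cd$tissue[keep]; spe <- cd$species[keep]
  S <- length(unique(spe)); Tt <- length(unique(tis))
  if (length(unique(tis)) != 2L)
    stop("both tissues must be present")
  complete <- stats::complete.cases(m)
  excluded_missing <- rownames(m)[!complete]
  y <- m[complete, , drop = FALSE]
  n <- ncol(y)
  gm <- rowMeans(y)
  ss_total <- rowSums((y - gm)^2)
  # balanced one-obs-per-cell design: factor SS from marginal means
  tmeans <- t(rowsum(t(y), tis)) / S              # genes x tissues
  smeans <- t(rowsum(t(y), spe)) / Tt             # genes x species
  ss_tissue <- S * rowSums((tmeans - gm)^2)
  ss_species <- Tt * rowSums((smeans - gm)^2)
  ss_resid <- ss_total - ss_tissue - ss_species
  const <- ss_total <= .Machine$double.eps * n
  out <- data.frame(group = rownames(y)[!const],
                    prop_tissue = (ss_tissue / ss_total)[!const],
                    prop_species = (ss_species / ss_total)[!const],
                    prop_residual = (ss_resid / ss_total)[!const],
                    n_observations = rep(n, sum(!const)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$prop_residual <- pmax(out$prop_residual, 0)   # guard tiny negatives
  attr(out, "excluded_missing") <- excluded_missing
  attr(out, "excluded_constant") <- rownames(y)[const]
  out
}

#' Classify genes as tissue-variable (TVG) or species-variable (SVG)
#'
#' A gene is highly variable when residual variance is below 25%
#' (`rule = "residual25"`, the default) or when a single factor explains
#' at least 75% (`rule = "factor75"`, the stricter variant). Highly
#' variable genes are SVGs when the species proportion is at least
#' `ratio`-fold (default 2) the tissue proportion, TVGs in the converse
#' case, otherwise `neither`. TVG and SVG are mutually exclusive.
#'
#' @param vp output of [partitionVariance()]
#' @param rule `"residual25"` or `"factor75"`
#' @param ratio fold-dominance required between the two factors
#' @return `vp` with added `label` (`TVG`/`SVG`/`neither`) and
#'   `rule_trace` columns
#' @export
classifyGenes <- function(vp, rule = c("residual25", "factor75"),
                          ratio = 2) {
  rule <- match.arg(rule)
  hv <- if (rule == "residual25") vp$prop_residual < 0.25
        else pmax(vp$prop_tissue, vp$prop_species) >= 0.75
  svg <- hv & vp$prop_species >= ratio * vp$prop_tissue
  tvg <- hv & vp$prop_tissue >= ratio * vp$prop_species & !svg
  vp$label <- ifelse(tvg, "TVG", ifelse(svg, "SVG", "neither"))
  vp$rule_trace <- ifelse(!hv, paste0("not highly variable (", rule, ")"),
                   ifelse(svg, "species >= ratio x tissue",
                   ifelse(tvg, "tissue >= ratio x species",
                          "highly variable, no 2-fold dominance")))
  vp
}

#' Variance partitioning over nested clades or all species pairs
#'
#' Runs [partitionVariance()] + [classifyGenes()] on each clade (a
#' named list of tip sets, checked for monophyly) or, with
#' `pairwise = TRUE`, on every pair of species in the tree (pairs are
#' not required to be monophyletic).
#'
#' @param x replicate-averaged log `TissueExpr`
#' @param tree a [BranchTree-class]
#' @param clades named list of character vectors of species codes
#' @param pairwise if TRUE, analyse all species pairs instead
#' @param tissues two tissues to contrast
#' @param rule,ratio passed to [classifyGenes()]
#' @return list: `partitions` (named list of classified data.frames)
#'   and `summary` (one row per analysis: n genes, class counts, mean
#'   proportions)
#' @export
cladeSweep <- function(x, tree, clades = NULL, pairwise = FALSE,
                       tissues = c("ovary", "carcass"),
                       rule = "residual25", ratio = 2) {
  stopifnot(is(tree, "BranchTree"))
  sets <- list()
  if (pairwise) {
    sp <- sort(apeTree(tree)$tip.label)
    cmb <- utils::combn(sp, 2L)
    for (i in seq_len(ncol(cmb)))
      sets[[paste(cmb[, i], collapse = "-")]] <- cmb[, i]
  } else {
    if (is.null(clades) || !length(clades)) stop("no clades given")
    for (nm in names(clades)) {
      if (!isMonophyleticClade(tree, clades[[nm]]))
        stop(sprintf("clade '%s' is not monophyletic (tips: %s)", nm,
                     paste(clades[[nm]], collapse = ", ")))
      sets[[nm]] <- clades[[nm]]
    }
  }
  partitions <- list()
  rows <- list()
  for (nm in names(sets)) {
    vp <- classifyGenes(partitionVariance(x, tissues = tissues,
                                          species = sets[[nm]]),
                        rule = rule, ratio = ratio)
    partitions[[nm]] <- vp
    rows[[nm]] <- data.frame(
      clade = nm, n_species = length(sets[[nm]]), n_genes = nrow(vp),
      n_tvg = sum(vp$label == "TVG"), n_svg = sum(vp$label == "SVG"),
      n_neither = sum(vp$label == "neither"),
      mean_prop_tissue = mean(vp$prop_tissue),
      mean_prop_species = mean(vp$prop_species),
      mean_prop_residual = mean(vp$prop_residual),
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(partitions = partitions, summary = summary)
}
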