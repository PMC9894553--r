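# End-to-end convenience: normalize -> DE -> cohort -> variance
# partition -> bias -> ASR/changes -> coevolution network.

#' Reference gene counts per species
#'
#' The number of homology-group-collapsed genes in each species'
#' reference: groups with at least one transcript present (non-`NA`
#' anywhere) in that species' libraries. Used as the TPM10k reference
#' size.
#'
#' @param x a transcript-level [TissueExpr-class]
#' @param map a [HomologyMap-class]
#' @return named integer vector over species codes
#' @export
referenceGeneCounts <- function(x, map) {
  cd <- colData(x)
  m <- assay(x, "expr")
  mt <- mapTable(map)
  grp <- mt$group[match(rownames(m), mt$transcript)]
  out <- integer(0)
  for (s in unique(cd$species)) {
    present <- rowSums(!is.na(m[, cd$species == s, drop = FALSE])) > 0
    out[s] <- length(unique(grp[present & !is.na(grp)]))
  }
  out
}

#' Run the full comparative-expression pipeline
#'
#' From a transcript-level TPM table, species tree and homology map:
#' TPM10k normalization; log + group + replicate averaging;
#' per-species NB differential expression (focal vs reference tissue)
#' and the core cohort; variance partitioning over all species (and
#' over any supplied clades / all pairs); log bias ratios; BM ancestral
#' reconstruction with per-branch scaled changes and shift calls; the
#' evolutionary correlation matrix (optionally outlier-filtered) and,
#' when interactions are supplied, the interaction-class comparison.
#'
#' @param expr a [TissueExpr-class] in TPM units
#' @param tree a [BranchTree-class]
#' @param map a [HomologyMap-class]
#' @param interactions optional interaction data.frame
#' @param focal,reference tissues contrasted (default ovary vs carcass)
#' @param alpha DE significance threshold
#' @param min_species core-cohort membership threshold
#' @param clades optional named list of tip sets for [cladeSweep()]
#' @param pairwise also run all-pairs variance partitioning
#' @param drop_outliers remove 2-SD outlier genes before correlation
#' @param threshold network edge threshold
#' @param n_sample,n_repeats interaction-comparison resampling sizes
#' @param seed seed for the resampling stage
#' @param n_reference_genes optional named override of the per-species
#'   reference sizes (default: computed by [referenceGeneCounts()])
#' @return list with elements `norm`, `grouped`, `averaged`, `de`,
#'   `cohort`, `varpart`, `bias`, `branch_changes`, `shifts`,
#'   `correlation`, `comparison` (NULL without interactions),
#'   `n_reference_genes`
#' @export
runPipeline <- function(expr, tree, map, interactions = NULL,
                        focal = "ovary", reference = "carcass",
                        alpha = 0.01, min_species = 10L, clades = NULL,
                        pairwise = FALSE, drop_outliers = FALSE,
                        threshold = 0.825, n_sample = 5000L,
                        n_repeats = 100L, seed = 1L,
                        n_reference_genes = NULL) {
  if (is.null(n_reference_genes))
    n_reference_genes <- referenceGeneCounts(expr, map)
  norm <- tpm10k(expr, n_reference_genes)
  grouped <- averageByGroup(logTransform(norm), map)
  averaged <- averageReplicates(grouped)

  de <- deAllSpecies(expr, focal = focal, reference = reference,
                     alpha = alpha)
  cohort <- coreCohort(de, map, min_species = min_species)

  all_clade <- list(all = apeTree(tree)$tip.label)
  vp <- cladeSweep(averaged, tree,
                   clades = if (is.null(clades)) all_clade else clades,
                   tissues = c(focal, reference))
  vp_pairs <- if (pairwise)
    cladeSweep(averaged, tree, pairwise = TRUE,
               tissues = c(focal, reference)) else NULL

  bias <- computeBias(norm, map, focal = focal, reference = reference)
  bc <- branchChangesAll(tree, bias)
  shifts <- callShifts(bc$details)

  changes <- if (drop_outliers) removeOutliers(bc$changes) else bc$changes
  cm <- correlationMatrix(changes)
  cmp <- if (!is.null(interactions) && nrow(interactions))
    compareToInteractions(cm, interactions, map, n_sample = n_sample,
                          n_repeats = n_repeats, seed = seed) else NULL

  list(norm = norm, grouped = grouped, averaged = averaged, de = de,
       cohort = cohort, varpart = vp, varpart_pairs = vp_pairs,
       bias = bias, branch_changes = bc, shifts = shifts,
       correlation = cm, comparison = cmp,
       n_reference_genes = n_reference_genes)
}

#' Write the main pipeline outputs to TSV/JSON files
#'
#' @param res result of [runPipeline()]
#' @param out_dir output directory (created if needed)
#' @return `out_dir`, invisibly
#' @export
writePipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in names(res$de)) wt(res$de[[s]], paste0("de_", s, ".tsv"))
  wt(res$cohort, "core_cohort.tsv")
  wt(res$varpart$summary, "varpart_summary.tsv")
  wt(data.frame(group = rownames(res$bias), res$bias, check.names = FALSE),
     "bias_table.tsv")
  wt(res$branch_changes$details, "branch_changes.tsv")
  wt(res$shifts, "shifts.tsv")
  m <- changesMatrix(res$branch_changes$changes)
  wt(data.frame(gene = rownames(m), m, check.names = FALSE),
     "branch_change_matrix.tsv")
  if (!is.null(res$comparison))
    jsonlite::write_json(res$comparison,
                         file.path(out_dir, "comparison_report.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
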