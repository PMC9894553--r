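# Per-species differential expression between a focal tissue and
# carcass, core tissue-specific cohorts across species, and the
# reference-atlas enrichment rule.
#
# The DE test is a deliberately simple negative-binomial Wald test:
# method-of-moments dispersion (no shrinkage), log2 fold change from the
# mean ratio with a 0.5 pseudocount, delta-method variance, BH
# correction. Downstream stages consume only log2FC / padj.

#' Negative-binomial Wald test between two tissues
#'
#' For each transcript with replicate abundances in a focal and a
#' reference tissue: the NB dispersion phi (Var = mu + phi mu^2) is
#' moment-estimated per group as `(s^2 - m) / m^2`, pooled with
#' df weights and floored at 1e-8; the effect is
#' `log2FC = log2((m_f + 0.5) / (m_r + 0.5))`; its delta-method variance
#' is `sum_i (1/(m_i + 0.5) + phi) / n_i` (natural-log scale, rescaled
#' to log2); the Wald p-value is two-sided normal, and BH adjustment is
#' applied across all tested transcripts. Transcripts with all-zero
#' abundances in both tissues are excluded and reported in the
#' `"excluded"` attribute.
#'
#' @param focal transcripts x replicates matrix of abundances in the
#'   focal tissue
#' @param reference same, reference tissue (carcass); same rows
#' @param alpha significance threshold on the adjusted p-value
#'   (default 0.01)
#' @return data.frame: `transcript`, `mean_focal`, `mean_reference`,
#'   `log2FC`, `p`, `padj`, `significant`, `direction` (`up`/`down`);
#'   attribute `excluded` lists all-zero transcripts
#' @export
deTest <- function(focal, reference, alpha = 0.01) {
  focal <- as.matrix(focal); reference <- as.matrix(reference)
  stopifnot(nrow(focal) == nrow(reference))
  if (ncol(focal) < 2L || ncol(reference) < 2L)
    stop("need >= 2 replicates per tissue")
  allzero <- rowSums(focal, na.rm = TRUE) == 0 &
    rowSums(reference, na.rm = TRUE) == 0
  excluded <- rownames(focal)[allzero]
  f <- focal[!allzero, , drop = FALSE]
  r <- reference[!allzero, , drop = FALSE]
  n1 <- ncol(f); n2 <- ncol(r)
  m1 <- rowMeans(f); m2 <- rowMeans(r)
  v1 <- apply(f, 1L, stats::var); v2 <- apply(r, 1L, stats::var)
  momPhi <- function(m, v) ifelse(m > 0, (v - m) / m^2, 0)
  phi <- ((n1 - 1) * momPhi(m1, v1) + (n2 - 1) * momPhi(m2, v2)) /
    (n1 + n2 - 2)
  phi <- pmax(phi, 1e-8)
  l2fc <- log2((m1 + 0.5) / (m2 + 0.5))
  vlog <- (1 / (m1 + 0.5) + phi) / n1 + (1 / (m2 + 0.5) + phi) / n2
  se <- sqrt(vlog) / log(2)
  z <- ifelse(se > 0, l2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(transcript = rownames(f), mean_focal = m1,
                    mean_reference = m2, log2FC = l2fc, p = p, padj = padj,
                    significant = padj < alpha,
                    direction = ifelse(l2fc >= 0, "up", "down"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Run the DE test per species
#'
#' Splits a [TissueExpr-class] by species, restricts to transcripts
#' present in that species' reference (non-`NA`), and tests focal vs
#' reference tissue with [deTest()].
#'
#' @param x a `TissueExpr` (transcript-level abundances)
#' @param focal focal tissue (default `"ovary"`)
#' @param reference reference tissue (default `"carcass"`)
#' @param alpha significance threshold (default 0.01)
#' @return named list (one entry per species) of [deTest()] results
#' @export
deAllSpecies <- function(x, focal = "ovary", reference = "carcass",
                         alpha = 0.01) {
  stopifnot(is(x, "TissueExpr"))
  cd <- colData(x)
  m <- assay(x, "expr")
  out <- list()
  for (s in unique(cd$species)) {
    fcols <- which(cd$species == s & cd$tissue == focal)
    rcols <- which(cd$species == s & cd$tissue == reference)
    if (length(fcols) < 2L || length(rcols) < 2L)
      stop(sprintf("species %s: need >= 2 replicates of both %s and %s",
                   s, focal, reference))
    present <- rowSums(!is.na(m[, c(fcols, rcols), drop = FALSE])) > 0
    out[[s]] <- deTest(m[present, fcols, drop = FALSE],
                       m[present, rcols, drop = FALSE], alpha = alpha)
  }
  out
}

#' Identify the core tissue-specific gene cohort across species
#'
#' A parent gene is a cohort member when at least one of its transcripts
#' is significantly differentially regulated in the stated direction in
#' at least `min_species` species. Transcripts without a parent-gene
#' annotation are excluded (message). The default of 10 (of 12) follows
#' the operational "ten or more" form; the stricter "more than ten" is
#' `min_species = 11`.
#'
#' @param de_by_species named list of per-species [deTest()] results
#' @param map a [HomologyMap-class] carrying parent-gene annotations
#' @param min_species membership threshold (default 10)
#' @param direction `"up"` (default) or `"down"`
#' @return data.frame: `gene`, `n_supporting_species`, `member`,
#'   sorted by support then gene
#' @export
coreCohort <- function(de_by_species, map, min_species = 10L,
                       direction = "up") {
  if (min_species > length(de_by_species))
    stop("min_species exceeds the number of species analysed (",
         length(de_by_species), ")")
  mt <- mapTable(map)
  support <- list()
  n_unannot <- 0L
  for (s in names(de_by_species)) {
    de <- de_by_species[[s]]
    hits <- de$transcript[de$significant & de$direction == direction]
    genes <- mt$parent_gene[match(hits, mt$transcript)]
    n_unannot <- n_unannot + sum(is.na(genes))
    support[[s]] <- unique(genes[!is.na(genes)])
  }
  if (n_unannot)
    message(n_unannot, " significant transcript(s) without parent-gene annotation excluded")
  tab <- table(unlist(support))
  out <- data.frame(gene = names(tab),
                    n_supporting_species = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$member <- out$n_supporting_species >= min_species
  out <- out[order(-out$n_supporting_species, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tissue-enrichment calls from a reference expression atlas
#'
#' Enrichment of a gene in a tissue is its FPKM divided by the
#' whole-body FPKM, with a pseudocount of 2 added to empty (`NA`) values
#' to avoid division by zero. A gene is called ovary-enriched when ovary
#' is the maximum enrichment across all tissues excluding head, brain
#' and eye; head-enriched when the maximum excluding ovary is one of
#' head/brain/eye. Genes with a missing whole-body value get the same
#' pseudocount.
#'
#' @param atlas data.frame: column `gene`, one numeric FPKM column per
#'   tissue, and a whole-body column
#' @param wholebody_col name of the whole-body column (default
#'   `"wholebody"`)
#' @param head_tissues tissues treated as the head compartment (default
#'   `c("head", "brain", "eye")`)
#' @return data.frame: `gene`, one `enr_<tissue>` column per tissue,
#'   `ovary_enriched`, `head_enriched`, and `top_tissue` (overall argmax)
#' @export
referenceEnrichment <- function(atlas, wholebody_col = "wholebody",
                                head_tissues = c("head", "brain", "eye")) {
  stopifnot("gene" %in% names(atlas), wholebody_col %in% names(atlas))
  tissues <- setdiff(names(atlas)[vapply(atlas, is.numeric, logical(1))],
                     wholebody_col)
  wb <- ifelse(is.na(atlas[[wholebody_col]]), 2, atlas[[wholebody_col]])
  enr <- sapply(tissues, function(t) {
    v <- ifelse(is.na(atlas[[t]]), 2, atlas[[t]])
    v / wb
  })
  enr <- matrix(enr, nrow = nrow(atlas), dimnames = list(NULL, tissues))
  argmax <- function(cols) {
    sub <- enr[, cols, drop = FALSE]
    cols[apply(sub, 1L, which.max)]
  }
  ovary_pool <- setdiff(tissues, head_tissues)
  head_pool <- setdiff(tissues, "ovary")
  out <- data.frame(gene = atlas$gene, stringsAsFactors = FALSE)
  out$ovary_enriched <- if ("ovary" %in% ovary_pool)
    argmax(ovary_pool) == "ovary" else FALSE
  out$head_enriched <- argmax(head_pool) %in% head_tissues
  out$top_tissue <- argmax(tissues)
  colnames(enr) <- paste0("enr_", tissues)
  cbind(out[, "gene", drop = FALSE], as.data.frame(enr),
        out[, c("ovary_enriched", "head_enriched", "top_tissue")])
}
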