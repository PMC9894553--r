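# Evolutionary correlation between genes: Pearson coefficients of
# scaled bias changes over equivalent branches, outlier filtering,
# interaction-class comparisons with resampled t-tests, and thresholded
# network extraction.

#' Pairwise evolutionary correlation matrix
#'
#' Pearson correlation of per-branch scaled bias changes between every
#' pair of genes with full species representation (a complete row of
#' the branch-change matrix, i.e. all `2n - 2` equivalent branches).
#' Genes with incomplete rows are dropped with a message. The reported
#' pairwise-comparison count is `G^2` (all ordered pairs including
#' self — the convention under which 1,143 genes give 1,306,449
#' comparisons); the distinct unordered count is also returned. Pairs
#' involving a zero-variance gene have undefined `r` and are `NA`.
#'
#' @param changes a [BranchChanges-class]
#' @param min_branches minimum shared branches required (default 3)
#' @return list of class `corrMatrix`: `r` (G x G symmetric, unit
#'   diagonal), `n_genes`, `n_points` (branches used),
#'   `n_comparisons` (= G^2), `n_distinct` (= G(G-1)/2)
#' @export
correlationMatrix <- function(changes, min_branches = 3L) {
  stopifnot(is(changes, "BranchChanges"))
  m <- changesMatrix(changes)
  complete <- stats::complete.cases(m)
  if (any(!complete))
    message(sum(!complete),
            " gene(s) without full species representation dropped")
  m <- m[complete, , drop = FALSE]
  if (ncol(m) < min_branches)
    stop("fewer than ", min_branches, " shared branches")
  r <- suppressWarnings(stats::cor(t(m)))    # zero-variance rows -> NA
  diag(r)[!is.na(diag(r))] <- 1
  G <- nrow(m)
  structure(list(r = r, n_genes = G, n_points = ncol(m),
                 n_comparisons = as.numeric(G)^2,
                 n_distinct = G * (G - 1) / 2),
            class = "corrMatrix")
}

#' Remove genes with outlying scaled changes
#'
#' Computes the mean and sample standard deviation over ALL entries of
#' the branch-change matrix and removes every gene (row) containing at
#' least one change more than `k_sd` standard deviations from that
#' mean. With zero overall SD nothing is removed. Removed gene ids are
#' in the `"removed"` attribute.
#'
#' @param changes a [BranchChanges-class]
#' @param k_sd cutoff in standard deviations (default 2)
#' @return a filtered `BranchChanges`
#' @export
removeOutliers <- function(changes, k_sd = 2) {
  stopifnot(is(changes, "BranchChanges"))
  m <- changesMatrix(changes)
  v <- m[!is.na(m)]
  mu <- mean(v); sdv <- stats::sd(v)
  if (!is.finite(sdv) || sdv == 0) {
    out <- changes
    attr(out, "removed") <- character(0)
    return(out)
  }
  bad <- apply(m, 1L, function(row)
    any(abs(row - mu) > k_sd * sdv, na.rm = TRUE))
  out <- new("BranchChanges", changes = m[!bad, , drop = FALSE],
             tree = changes@tree)
  attr(out, "removed") <- rownames(m)[bad]
  out
}

# resolve gene symbols to homology groups; NA when unknown/ambiguous-free
symbolToGroup <- function(map) {
  mt <- mapTable(map)
  mt <- mt[!is.na(mt$parent_gene), c("parent_gene", "group")]
  mt <- unique(mt)
  # a symbol mapping to several groups keeps its first group (sorted)
  mt <- mt[order(mt$parent_gene, mt$group), ]
  mt[!duplicated(mt$parent_gene), ]
}

#' Compare correlation coefficients across interaction classes
#'
#' For each interaction class, the correlation coefficients of its
#' gene pairs are compared to a fresh random sample of `n_sample`
#' coefficients of pairs with unknown interactions, with a two-sample
#' t-test (Welch by default), repeated `n_repeats` times; the maximum
#' p-value over the repeats is reported. Enhancement and suppression
#' classes are additionally compared to each other with a single
#' t-test. Interaction symbols are resolved to homology groups through
#' the map; pairs falling in the same group are dropped, as are pairs
#' not present in the matrix.
#'
#' @param cm a `corrMatrix` from [correlationMatrix()]
#' @param interactions data.frame from [readInteractions()]
#' @param map a [HomologyMap-class]
#' @param n_sample unknown-pair sample size per repeat (default 5000)
#' @param n_repeats number of repeats (default 100)
#' @param pooled_var use the pooled-variance t-test instead of Welch
#' @param seed optional integer seed for the resampling
#' @return list: `classes` (data.frame per class: `n_pairs`, `mean_r`,
#'   `mean_t`, `max_p`), `enh_vs_sup` (list `t`, `p` or NULL),
#'   `n_unknown`, `n_sample`, `n_repeats`
#' @export
compareToInteractions <- function(cm, interactions, map, n_sample = 5000L,
                                  n_repeats = 100L, pooled_var = FALSE,
                                  seed = NULL) {
  stopifnot(inherits(cm, "corrMatrix"))
  if (!is.null(seed)) set.seed(seed)
  genes <- rownames(cm$r)
  s2g <- symbolToGroup(map)
  ga <- s2g$group[match(interactions$gene_a, s2g$parent_gene)]
  gb <- s2g$group[match(interactions$gene_b, s2g$parent_gene)]
  ok <- !is.na(ga) & !is.na(gb) & ga %in% genes & gb %in% genes
  same <- ok & ga == gb
  if (any(same))
    message(sum(same), " pair(s) mapping to a single homology group dropped")
  ok <- ok & !same
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  labeled <- unique(key(ga[ok], gb[ok]))

  # unknown pairs: every unordered distinct pair not labeled in any class
  idx <- which(upper.tri(cm$r), arr.ind = TRUE)
  all_keys <- key(genes[idx[, 1L]], genes[idx[, 2L]])
  rvals <- cm$r[idx]
  unknown <- rvals[!(all_keys %in% labeled) & !is.na(rvals)]

  rows <- list(); class_r <- list()
  for (cl in unique(interactions$class)) {
    sel <- ok & interactions$class == cl
    rr <- cm$r[cbind(match(ga[sel], genes), match(gb[sel], genes))]
    rr <- rr[!is.na(rr)]
    if (length(rr) < 2L) {
      warning("class '", cl, "' has fewer than 2 mapped pairs; skipped")
      next
    }
    class_r[[cl]] <- rr
    ps <- numeric(n_repeats); ts <- numeric(n_repeats)
    for (i in seq_len(n_repeats)) {
      samp <- if (length(unknown) > n_sample)
        sample(unknown, n_sample) else unknown
      tt <- stats::t.test(rr, samp, var.equal = pooled_var)
      ps[i] <- tt$p.value; ts[i] <- unname(tt$statistic)
    }
    rows[[cl]] <- data.frame(class = cl, n_pairs = length(rr),
                             mean_r = mean(rr), mean_t = mean(ts),
                             max_p = max(ps), stringsAsFactors = FALSE)
  }
  classes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = character(0), n_pairs = integer(0),
               mean_r = numeric(0), mean_t = numeric(0),
               max_p = numeric(0))
  rownames(classes) <- NULL
  enh_vs_sup <- NULL
  if (all(c("enhancement", "suppression") %in% names(class_r))) {
    tt <- stats::t.test(class_r$enhancement, class_r$suppression,
                        var.equal = pooled_var)
    enh_vs_sup <- list(t = unname(tt$statistic), p = tt$p.value)
  }
  list(classes = classes, enh_vs_sup = enh_vs_sup,
       n_unknown = length(unknown), n_sample = n_sample,
       n_repeats = n_repeats)
}

#' Extract the strong-correlation network around focus genes
#'
#' Edges from each focus gene to every partner whose absolute
#' correlation strictly exceeds the threshold (default 0.825), with the
#' sign of the correlation retained. Self-edges and duplicate
#' focus-focus edges are excluded.
#'
#' @param cm a `corrMatrix`
#' @param focus character vector of focus gene (homology group) ids
#' @param threshold edge threshold on `|r|` (strict; default 0.825)
#' @return data.frame: `gene_a` (focus), `gene_b`, `r`, `sign`
#'   (`positive`/`negative`)
#' @export
extractNetwork <- function(cm, focus, threshold = 0.825) {
  stopifnot(inherits(cm, "corrMatrix"))
  genes <- rownames(cm$r)
  missing <- setdiff(focus, genes)
  if (length(missing))
    stop("focus gene(s) not in matrix: ", paste(missing, collapse = ", "),
         "; available: ", paste(utils::head(genes, 10), collapse = ", "),
         if (length(genes) > 10) ", ..." else "")
  rows <- list()
  for (f in focus) {
    r <- cm$r[f, ]
    hit <- which(!is.na(r) & abs(r) > threshold & genes != f)
    if (length(hit))
      rows[[f]] <- data.frame(gene_a = f, gene_b = genes[hit],
                              r = unname(r[hit]), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0), r = numeric(0))
  # drop duplicate focus-focus edges (keep a < b orientation once)
  dup <- out$gene_a %in% focus & out$gene_b %in% focus &
    out$gene_a > out$gene_b
  out <- out[!dup, , drop = FALSE]
  out$sign <- ifelse(out$r >= 0, "positive", "negative")
  rownames(out) <- NULL
  out
}
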