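#' Library-size normalize and log-transform a count matrix
#'
#' Scales every cell to a fixed total count (default 10,000) and applies
#' `log1p`. Cells with zero total counts are dropped with a warning.
#'
#' @param counts genes x cells non-negative count matrix.
#' @param scale_factor target per-cell total.
#' @return genes x cells matrix of `log1p(count * scale_factor / total)`.
#' @export
normalize_log <- function(counts, scale_factor = 1e4) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " zero-count cell(s) dropped")
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  log1p(sweep(counts, 2, totals / scale_factor, "/"))
}

# Vectorized two-sided Mann-Whitney (Wilcoxon rank-sum) test of the cells in
# `idx_a` against all others, one test per row of `x`. Normal approximation
# with tie and continuity corrections (the large-sample path of
# stats::wilcox.test).
rank_sum_rows <- function(x, idx_a) {
  n <- ncol(x)
  n1 <- length(idx_a)
  n2 <- n - n1
  stopifnot(n1 >= 1, n2 >= 1)
  p <- numeric(nrow(x))
  for (g in seq_len(nrow(x))) {
    r <- rank(x[g, ])
    u <- sum(r[idx_a]) - n1 * (n1 + 1) / 2
    tie_tab <- table(x[g, ])
    tie_term <- sum(tie_tab^3 - tie_tab)
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1))))
    if (sigma == 0) {
      p[g] <- 1
    } else {
      z <- u - n1 * n2 / 2
      z <- (z - sign(z) * 0.5) / sigma  # continuity correction
      p[g] <- min(2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)), 1)
    }
  }
  pmin(p, 1)
}

#' Differentially expressed genes per cluster
#'
#' Tests each gene with a Wilcoxon rank-sum test of one cluster against all
#' other cells on log-normalized values, with Benjamini-Hochberg adjustment
#' across genes within the cluster. Two retention modes:
#' \describe{
#'   \item{`"subcluster"`}{fold change > 1.5 and FDR < 0.1 — the rule used
#'     to resolve plasma-cell subclusters. The fold threshold is applied to
#'     up-regulation in the cluster; set `positive_only = FALSE` to also
#'     keep genes down-regulated past 1/1.5 (library-composition shifts make
#'     the down direction prone to spurious calls).}
#'   \item{`"marker"`}{adjusted p < 0.05 and (by default) positive log fold
#'     change — the cell-type marker rule.}
#' }
#' The fold change is the ratio of mean normalized expression
#' (`expm1` of cluster means of the log values, pseudo-count 1e-9).
#'
#' @param norm genes x cells log-normalized matrix ([normalize_log()]).
#' @param labels cluster label per cell (column).
#' @param mode `"subcluster"` or `"marker"`.
#' @param fc_thresh,fdr_thresh subcluster-mode thresholds.
#' @param p_thresh marker-mode adjusted-p threshold.
#' @param positive_only marker mode: require log fold change > 0.
#' @return named list (one element per cluster) of data.frames with `gene`,
#'   `p`, `fdr`, `fold_change`, `log2_fc` for the retained genes; the
#'   unfiltered per-gene tables are in attribute `"full"`.
#' @export
select_degs <- function(norm, labels, mode = c("subcluster", "marker"),
                        fc_thresh = 1.5, fdr_thresh = 0.1, p_thresh = 0.05,
                        positive_only = NULL) {
  mode <- match.arg(mode)
  positive_only <- positive_only %||% TRUE
  stopifnot(ncol(norm) == length(labels))
  labels <- as.character(labels)
  sizes <- table(labels)
  if (any(sizes < 3)) {
    stop("cluster(s) with fewer than 3 cells: ",
         paste(names(sizes)[sizes < 3], collapse = ", "), call. = FALSE)
  }
  eps <- 1e-9
  full <- list()
  kept <- list()
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    p <- rank_sum_rows(norm, idx)
    fdr <- p.adjust(p, "BH")
    mean_in <- rowMeans(norm[, idx, drop = FALSE])
    mean_out <- rowMeans(norm[, -idx, drop = FALSE])
    fold <- (expm1(mean_in) + eps) / (expm1(mean_out) + eps)
    tab <- data.frame(gene = rownames(norm), p = p, fdr = fdr,
                      fold_change = fold, log2_fc = log2(fold),
                      stringsAsFactors = FALSE)
    full[[cl]] <- tab
    keep <- if (mode == "subcluster") {
      (tab$fold_change > fc_thresh |
         (!positive_only & tab$fold_change < 1 / fc_thresh)) &
        tab$fdr < fdr_thresh
    } else {
      tab$fdr < p_thresh & (!positive_only | tab$log2_fc > 0)
    }
    res <- tab[keep, , drop = FALSE]
    rownames(res) <- NULL
    kept[[cl]] <- res
  }
  attr(kept, "full") <- full
  kept
}

#' Hypergeometric pathway overrepresentation test
#'
#' Upper-tail hypergeometric p-value for the overlap of a DEG set with each
#' pathway (both intersected with the gene universe), followed by
#' Benjamini-Hochberg adjustment across pathways. An empty DEG set yields
#' q = 1 everywhere.
#'
#' @param deg_set character vector of genes (subset of `universe`).
#' @param universe character vector of all testable genes.
#' @param pathway_sets named list of gene vectors (e.g. from a GMT file, see
#'   [read_gmt()]).
#' @return data.frame with `pathway`, `overlap`, `pathway_size`, `p`, `q`.
#' @export
enrich_pathways <- function(deg_set, universe, pathway_sets) {
  stopifnot(length(universe) >= 1, length(pathway_sets) >= 1)
  deg_set <- intersect(deg_set, universe)
  k <- length(deg_set)
  res <- lapply(names(pathway_sets), function(pw) {
    genes <- intersect(pathway_sets[[pw]], universe)
    m <- length(genes)
    ov <- length(intersect(deg_set, genes))
    p <- if (k == 0 || m == 0) 1 else
      phyper(ov - 1, m, length(universe) - m, k, lower.tail = FALSE)
    data.frame(pathway = pw, overlap = ov, pathway_size = m, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

#' Group subpopulations by correlation of their pathway-enrichment profiles
#'
#' Restricts the enrichment matrix to pathways significant (q below
#' `sig_thresh`) in at least one subpopulation, transforms q-values to
#' -log10, computes pairwise Pearson correlations between subpopulations,
#' and cuts an average-linkage hierarchical clustering of the distance
#' `1 - r` into `n_groups` groups. Subpopulations with a constant
#' transformed profile (undefined correlation) are excluded with a warning.
#'
#' @param enrichment subpopulations x pathways matrix of q-values in (0, 1].
#' @param sig_thresh significance threshold defining the pathway restriction.
#' @param n_groups number of groups to cut the dendrogram into.
#' @return list with `r` (correlation matrix), `groups` (named integer
#'   vector), `hclust`, and `excluded` (names of dropped subpopulations).
#' @export
enrichment_correlation_clusters <- function(enrichment, sig_thresh = 0.05,
                                            n_groups = 3) {
  stopifnot(nrow(enrichment) >= 2)
  if (any(enrichment <= 0 | enrichment > 1)) {
    stop("enrichment q-values must lie in (0, 1]", call. = FALSE)
  }
  sig_cols <- apply(enrichment < sig_thresh, 2, any)
  if (!any(sig_cols)) stop("no significant pathways", call. = FALSE)
  x <- -log10(enrichment[, sig_cols, drop = FALSE])
  const <- apply(x, 1, sd) < 1e-12
  if (any(const)) {
    warning(sum(const), " subpopulation(s) with constant enrichment profile excluded")
    x <- x[!const, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("fewer than two usable subpopulations", call. = FALSE)
  r <- cor(t(x))
  hc <- hclust(as.dist(1 - r), method = "average")
  groups <- cutree(hc, k = min(n_groups, nrow(x)))
  list(r = r, groups = groups, hclust = hc,
       excluded = rownames(enrichment)[const] %||% character(0))
}

#' Sample-sample expression correlation within each cell type
#'
#' For each cell type, identifies marker genes (rank-sum test of the type
#' against all other cells; adjusted p < 0.05 and positive log fold change),
#' averages their normalized expression within each sample's cells of that
#' type, and reports the pairwise Pearson correlation matrix across samples.
#' Samples lacking the cell type contribute missing entries.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param annotations data.frame with `cell`, `sample`, `cell_type` matching
#'   the matrix columns.
#' @param p_thresh marker adjusted-p threshold.
#' @return named list per cell type: list with `markers`, `sample_means`
#'   (genes x samples), `r` (sample correlation matrix).
#' @export
celltype_sample_correlation <- function(norm, annotations, p_thresh = 0.05) {
  stopifnot(all(c("cell", "sample", "cell_type") %in% names(annotations)))
  ann <- annotations[match(colnames(norm), annotations$cell), , drop = FALSE]
  samples <- unique(ann$sample)
  if (length(samples) < 2) {
    stop("need at least two samples for a correlation analysis", call. = FALSE)
  }
  markers_by_type <- select_degs(norm, ann$cell_type, mode = "marker",
                                 p_thresh = p_thresh)
  out <- list()
  for (ct in names(markers_by_type)) {
    markers <- markers_by_type[[ct]]$gene
    if (length(markers) < 2) next
    cells_ct <- ann$cell_type == ct
    means <- vapply(samples, function(s) {
      sel <- cells_ct & ann$sample == s
      if (!any(sel)) return(rep(NA_real_, length(markers)))
      rowMeans(norm[markers, sel, drop = FALSE])
    }, numeric(length(markers)))
    colnames(means) <- samples
    r <- suppressWarnings(cor(means, use = "pairwise.complete.obs"))
    out[[ct]] <- list(markers = markers, sample_means = means, r = r)
  }
  out
}

#' Stratified gene-program QC check across cell types
#'
#' Splits cells into strata by expressed-gene count (>= `ngene_thresh` vs
#' below), scores every cell by the mean normalized expression of `gene_set`,
#' and reports per cell type and stratum the cell count and mean score, plus
#' a rank-sum comparison of the two strata within each cell type. A program
#' whose elevation in one cell type persists in both strata is not an
#' artifact of library quality.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param annotations data.frame with `cell`, `cell_type`,
#'   `n_genes_expressed`.
#' @param gene_set character vector of program genes; genes absent from the
#'   matrix contribute zero.
#' @param ngene_thresh stratum boundary on expressed-gene count.
#' @return list with `summary` (cell_type, stratum, n_cells, mean_score) and
#'   `tests` (cell_type, p of the stratum comparison, `NA` when a stratum is
#'   empty).
#' @export
qc_stratified_check <- function(norm, annotations, gene_set,
                                ngene_thresh = 1000) {
  stopifnot(length(gene_set) >= 1)
  ann <- annotations[match(colnames(norm), annotations$cell), , drop = FALSE]
  present <- intersect(gene_set, rownames(norm))
  score <- if (length(present)) {
    colSums(norm[present, , drop = FALSE]) / length(gene_set)
  } else {
    setNames(rep(0, ncol(norm)), colnames(norm))
  }
  hi_lab <- paste0(">=", ngene_thresh)
  lo_lab <- paste0("<", ngene_thresh)
  stratum <- ifelse(ann$n_genes_expressed >= ngene_thresh, hi_lab, lo_lab)
  grid <- expand.grid(cell_type = unique(ann$cell_type),
                      stratum = c(hi_lab, lo_lab),
                      stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- ann$cell_type == grid$cell_type[i] & stratum == grid$stratum[i]
    data.frame(cell_type = grid$cell_type[i], stratum = grid$stratum[i],
               n_cells = sum(sel),
               mean_score = if (any(sel)) mean(score[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  empty <- summary$n_cells == 0
  if (any(empty)) {
    warning("empty stratum for: ",
            paste(unique(summary$cell_type[empty]), collapse = ", "))
  }
  tests <- do.call(rbind, lapply(unique(ann$cell_type), function(ct) {
    hi <- score[ann$cell_type == ct & stratum == hi_lab]
    lo <- score[ann$cell_type == ct & stratum == lo_lab]
    p <- if (length(hi) && length(lo)) {
      suppressWarnings(wilcox.test(hi, lo)$p.value)
    } else {
      NA_real_
    }
    data.frame(cell_type = ct, p = p, stringsAsFactors = FALSE)
  }))
  rownames(summary) <- rownames(tests) <- NULL
  list(summary = summary, tests = tests)
}
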