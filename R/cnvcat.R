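#' Ordered copy-number category levels
#'
#' The five ordered categories used for all copy-number calls:
#' deletion < loss < neutral < gain < amplification.
#' @export
cnv_levels <- c("deletion", "loss", "neutral", "gain", "amplification")

# platform-specific log2-ratio cutoffs between consecutive categories
cnv_cutoffs <- list(
  bulk  = c(-1, -0.25, 0.2, 0.7),
  scrna = c(-1, -0.4, 0.3, 0.7)
)

#' Map log2 copy-ratio values to the five ordered categories
#'
#' With cutoffs (c1, c2, c3, c4): deletion if x < c1; loss if c1 <= x < c2;
#' neutral if c2 <= x < c3; gain if c3 <= x < c4; amplification if x >= c4 —
#' each boundary belongs to the higher category. Cutoffs are
#' (-1, -0.25, 0.2, 0.7) for bulk DNA platforms and (-1, -0.4, 0.3, 0.7)
#' for expression-derived (scRNA) copy ratios.
#'
#' @param log2_ratio finite numeric vector of log2 copy ratios (neutral = 0).
#' @param platform `"bulk"` or `"scrna"`.
#' @return ordered factor with levels [cnv_levels].
#' @export
categorize <- function(log2_ratio, platform = c("bulk", "scrna")) {
  if (length(platform) != 1 || !platform %in% names(cnv_cutoffs)) {
    platform <- match.arg(platform)
  }
  if (any(!is.finite(log2_ratio))) {
    stop("log2 ratios must be finite", call. = FALSE)
  }
  cuts <- cnv_cutoffs[[platform]]
  idx <- findInterval(log2_ratio, cuts, left.open = FALSE) + 1L
  factor(cnv_levels[idx], levels = cnv_levels, ordered = TRUE)
}

#' Transform relative expression intensities to clipped log2 ratios
#'
#' Expression-derived copy-number intensities are on a linear scale with
#' neutral = 1; this maps them to log2 ratios for [categorize()]. Values
#' <= 0 are clipped to 1e-3 (with a warning) before the log, and the result
#' is clipped to [-3, 3].
#'
#' @param intensity numeric vector of relative intensities.
#' @return numeric vector of log2 ratios in [-3, 3].
#' @export
infercnv_to_log2 <- function(intensity) {
  if (any(intensity <= 0, na.rm = TRUE)) {
    warning(sum(intensity <= 0, na.rm = TRUE),
            " non-positive intensity value(s) clipped to 1e-3")
    intensity <- pmax(intensity, 1e-3)
  }
  pmin(pmax(log2(intensity), -3), 3)
}

#' Flag cells (and the sample) for a chromosome-level deletion
#'
#' A cell is flagged when its mean relative copy value (linear scale,
#' neutral = 1) over the chromosome is strictly below `threshold` (default
#' 0.76, the chromosome 13 deletion rule). The sample-level flag is TRUE
#' when any cell is flagged.
#'
#' @param profile data.frame with `cell`, `chrom`, `value` (relative copy,
#'   > 0), or a cells x chromosomes matrix.
#' @param chrom chromosome to test.
#' @param threshold strict lower bound on the per-cell mean copy value.
#' @return list with `cell_flags` (named logical per cell) and `sample_flag`.
#' @export
chrom_deletion_flag <- function(profile, chrom, threshold = 0.76) {
  if (is.matrix(profile)) {
    if (!chrom %in% colnames(profile)) {
      stop(sprintf("chromosome '%s' absent from profile", chrom), call. = FALSE)
    }
    vals <- profile[, chrom]
    cell_means <- setNames(as.numeric(vals),
                           rownames(profile) %||% seq_len(nrow(profile)))
  } else {
    sub <- profile[profile$chrom == chrom, , drop = FALSE]
    if (nrow(sub) == 0) {
      stop(sprintf("chromosome '%s' absent from profile", chrom), call. = FALSE)
    }
    cell_means <- vapply(split(sub$value, sub$cell), mean, numeric(1))
  }
  flags <- cell_means < threshold
  list(cell_flags = flags, sample_flag = any(flags))
}

#' Subcluster cells on a CNV gene panel by density clustering
#'
#' Reduces the panel-restricted matrix to its top principal components, then
#' runs DBSCAN over a grid of (eps, minPts) values, selecting the parameter
#' pair that maximizes the mean silhouette coefficient computed on non-noise
#' points (at least two clusters required; ties broken toward larger eps,
#' then larger minPts). When no grid point yields two clusters, all cells
#' are returned as a single cluster with a warning.
#'
#' @param cnv_matrix cells x genes numeric matrix, already restricted to the
#'   CNV-informative gene panel.
#' @param eps_grid candidate eps values; default 20 log-spaced values
#'   spanning the 5th-95th percentile of pairwise distances in PC space.
#' @param minpts_grid candidate minPts values.
#' @param n_components number of principal components used (capped by the
#'   matrix dimensions).
#' @param seed integer seed (kept for interface symmetry; the procedure is
#'   deterministic).
#' @return object of class `cnv_subclustering`: list with `labels` (noise =
#'   -1), `eps`, `minpts`, `silhouette`, `n_clusters`, and the evaluated
#'   `grid`.
#' @export
dbscan_subcluster <- function(cnv_matrix, eps_grid = NULL,
                              minpts_grid = c(5, 10, 15, 20),
                              n_components = 10, seed = 1L) {
  stopifnot(nrow(cnv_matrix) >= 2, ncol(cnv_matrix) >= 1)
  k <- min(n_components, ncol(cnv_matrix), nrow(cnv_matrix) - 1L)
  pcs <- if (all(apply(cnv_matrix, 2, sd) < 1e-12)) {
    matrix(0, nrow(cnv_matrix), 1L)  # degenerate: all rows identical
  } else {
    prcomp(cnv_matrix, center = TRUE, scale. = FALSE, rank. = k)$x
  }
  d <- as.matrix(dist(pcs))
  if (is.null(eps_grid)) {
    dv <- d[upper.tri(d)]
    qs <- quantile(dv[dv > 0], c(0.05, 0.95))
    if (!all(is.finite(qs)) || qs[1] <= 0 || qs[2] <= qs[1]) {
      eps_grid <- max(mean(dv), 1e-6)
    } else {
      eps_grid <- exp(seq(log(qs[1]), log(qs[2]), length.out = 20))
    }
  }

  grid <- expand.grid(eps = eps_grid, minpts = minpts_grid)
  grid$n_clusters <- NA_integer_
  grid$silhouette <- NA_real_
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    labels <- dbscan_labels(d, grid$eps[i], grid$minpts[i])
    ok <- labels > 0
    ncl <- length(unique(labels[ok]))
    grid$n_clusters[i] <- ncl
    if (ncl < 2) next
    sil <- cluster::silhouette(labels[ok], dmatrix = d[ok, ok, drop = FALSE])
    s <- mean(sil[, "sil_width"])
    grid$silhouette[i] <- s
    better <- is.null(best) ||
      s > best$silhouette + 1e-12 ||
      (abs(s - best$silhouette) <= 1e-12 &&
         (grid$eps[i] > best$eps ||
            (grid$eps[i] == best$eps && grid$minpts[i] > best$minpts)))
    if (better) {
      best <- list(labels = labels, eps = grid$eps[i],
                   minpts = grid$minpts[i], silhouette = s, n_clusters = ncl)
    }
  }
  if (is.null(best)) {
    warning("no (eps, minPts) grid point produced >= 2 clusters; ",
            "returning a single cluster")
    best <- list(labels = rep(1L, nrow(cnv_matrix)), eps = NA_real_,
                 minpts = NA_real_, silhouette = NA_real_, n_clusters = 1L)
  }
  names(best$labels) <- rownames(cnv_matrix)
  structure(c(best, list(grid = grid)), class = "cnv_subclustering")
}

#' @export
print.cnv_subclustering <- function(x, ...) {
  cat(sprintf("CNV subclustering: %d clusters (%d noise cells), eps = %s, minPts = %s, silhouette = %s\n",
              x$n_clusters, sum(x$labels == -1L),
              format(x$eps, digits = 4), format(x$minpts),
              format(x$silhouette, digits = 4)))
  invisible(x)
}
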