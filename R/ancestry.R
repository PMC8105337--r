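#' Threshold-based genotype calling from allele read counts
#'
#' Calls a biallelic genotype from reference/alternate read counts:
#' hom-ref when ref >= 8 and alt < 4; het when ref >= 4 and alt >= 4;
#' hom-alt when ref < 4 and alt >= 8; missing otherwise. The three positive
#' rules are mutually exclusive, so exactly one outcome applies to any count
#' pair. Vectorized over its arguments.
#'
#' @param ref_count,alt_count non-negative integer vectors.
#' @return character vector in `{"hom-ref", "het", "hom-alt", "missing"}`.
#' @export
call_genotype <- function(ref_count, alt_count) {
  if (any(ref_count < 0 | alt_count < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  out <- rep("missing", length(ref_count))
  out[ref_count >= 8 & alt_count < 4] <- "hom-ref"
  out[ref_count >= 4 & alt_count >= 4] <- "het"
  out[ref_count < 4 & alt_count >= 8] <- "hom-alt"
  out[is.na(ref_count) | is.na(alt_count)] <- "missing"
  out
}

#' Dosage genotype matrix from per-sample read-count matrices
#'
#' Applies [call_genotype()] elementwise and encodes hom-ref/het/hom-alt as
#' dosages 0/1/2 with `NA` for missing.
#'
#' @param ref,alt samples x markers count matrices with matching dimnames.
#' @return samples x markers numeric dosage matrix.
#' @export
genotype_matrix <- function(ref, alt) {
  stopifnot(identical(dim(ref), dim(alt)))
  calls <- call_genotype(as.vector(ref), as.vector(alt))
  dose <- c("hom-ref" = 0, "het" = 1, "hom-alt" = 2, "missing" = NA_real_)[calls]
  matrix(unname(dose), nrow(ref), ncol(ref), dimnames = dimnames(ref))
}

#' Drop markers with excessive missingness
#'
#' A marker is retained iff its missing-call fraction is at most
#' `max_missing_frac` (default 0.05, i.e. markers vacant in more than 5% of
#' samples are removed).
#'
#' @param geno samples x markers dosage matrix with `NA` for missing calls.
#' @param max_missing_frac maximum tolerated missing fraction.
#' @return integer indices of retained markers.
#' @export
filter_markers <- function(geno, max_missing_frac = 0.05) {
  if (is.null(dim(geno)) || nrow(geno) == 0 || ncol(geno) == 0) {
    stop("genotype matrix is empty", call. = FALSE)
  }
  which(colMeans(is.na(geno)) <= max_missing_frac)
}

#' Fit a reference PCA projection and ancestry classifier
#'
#' Encodes reference genotypes as dosages, imputes missing calls with the
#' per-marker mean, centers and scales each marker (sd floor 1e-8), and
#' extracts the top `K` principal components. A random-forest classifier is
#' trained on the reference coordinates using a stratified `split_frac`
#' train/test split; the held-out accuracy is stored with the model. Query
#' samples are later projected into this fixed space with
#' [project_and_classify()] — the reference statistics are never refit.
#'
#' @param reference_geno samples x markers dosage matrix (`NA` = missing).
#' @param labels population label per reference sample.
#' @param K number of principal components retained (default 20).
#' @param split_frac training fraction of the stratified split.
#' @param seed integer seed (PCA is deterministic; the split and forest are
#'   seeded).
#' @param ntree number of trees in the forest.
#' @return an `ancestry_projection` object: marker names, centering means,
#'   scale factors, loadings (markers x K), reference coordinates and labels,
#'   the fitted classifier, and `heldout_accuracy`.
#' @export
fit_projection <- function(reference_geno, labels, K = 20, split_frac = 0.8,
                           seed = 1L, ntree = 500) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two populations", call. = FALSE)
  if (any(table(labels) < 2)) {
    stop("every population needs at least two reference samples", call. = FALSE)
  }
  if (ncol(reference_geno) < K) {
    stop("fewer retained markers than requested components", call. = FALSE)
  }
  means <- colMeans(reference_geno, na.rm = TRUE)
  x <- reference_geno
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- means[j]
  mu <- colMeans(x)
  sds <- pmax(apply(x, 2, sd), 1e-8)
  xs <- scale(x, center = mu, scale = sds)
  pc <- prcomp(xs, center = FALSE, scale. = FALSE, rank. = K)
  loadings <- pc$rotation[, seq_len(K), drop = FALSE]
  scores <- pc$x[, seq_len(K), drop = FALSE]
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(K))

  with_seed(seed, {
    train <- unlist(lapply(split(seq_along(labels), labels), function(idx) {
      sample(idx, max(1L, round(split_frac * length(idx))))
    }), use.names = FALSE)
    test <- setdiff(seq_along(labels), train)
    rf <- randomForest::randomForest(
      x = scores[train, , drop = FALSE], y = labels[train], ntree = ntree
    )
    heldout <- if (length(test)) {
      mean(predict(rf, scores[test, , drop = FALSE]) == labels[test])
    } else {
      NA_real_
    }
    structure(
      list(markers = colnames(reference_geno), impute_means = means,
           center = mu, scale = sds, loadings = loadings, K = K,
           ref_coords = scores, ref_labels = labels, classifier = rf,
           heldout_accuracy = heldout),
      class = "ancestry_projection"
    )
  })
}

#' @export
print.ancestry_projection <- function(x, ...) {
  cat(sprintf("Ancestry projection: %d markers, %d PCs, %d reference samples (%d populations)\n",
              length(x$markers), x$K, nrow(x$ref_coords), nlevels(x$ref_labels)))
  cat(sprintf("Held-out classification accuracy: %s\n",
              format(x$heldout_accuracy, digits = 4)))
  invisible(x)
}

#' Project query samples into reference PC space and classify ancestry
#'
#' Query dosages are aligned to the model's marker set (markers absent from
#' the query, and missing calls, are imputed with the reference per-marker
#' mean), centered and scaled with the stored reference statistics, and
#' multiplied by the stored loadings. Predicted population labels and class
#' probabilities come from the stored classifier.
#'
#' @param model an [fit_projection()] result.
#' @param query_geno samples x markers dosage matrix; must share at least
#'   `model$K` markers with the model.
#' @return list with `coordinates` (samples x K), `labels`, `probabilities`.
#' @export
project_and_classify <- function(model, query_geno) {
  stopifnot(inherits(model, "ancestry_projection"))
  shared <- intersect(colnames(query_geno), model$markers)
  if (length(shared) < model$K) {
    stop(sprintf("query shares only %d markers with the model (need >= K = %d)",
                 length(shared), model$K), call. = FALSE)
  }
  if (any(rowSums(!is.na(query_geno[, shared, drop = FALSE])) == 0)) {
    stop("query sample with no non-missing shared genotype", call. = FALSE)
  }
  x <- matrix(rep(model$impute_means, each = nrow(query_geno)),
              nrow(query_geno), length(model$markers),
              dimnames = list(rownames(query_geno), model$markers))
  q <- query_geno[, shared, drop = FALSE]
  q[is.na(q)] <- matrix(rep(model$impute_means[shared], each = nrow(q)),
                        nrow(q), length(shared))[is.na(q)]
  x[, shared] <- q
  xs <- scale(x, center = model$center, scale = model$scale)
  coords <- xs %*% model$loadings
  probs <- predict(model$classifier, coords, type = "prob")
  labels <- factor(colnames(probs)[max.col(probs, ties.method = "first")],
                   levels = levels(model$ref_labels))
  list(coordinates = coords, labels = labels, probabilities = probs)
}
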