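# Classic DBSCAN over a precomputed distance matrix.
#
# Core point: >= minpts neighbours within eps (the point itself included,
# the usual convention). Clusters grow by seed-list expansion from core
# points; border points join the first cluster that reaches them; noise is
# labelled -1. Deterministic: points are visited in row order.
dbscan_labels <- function(d, eps, minpts) {
  n <- nrow(d)
  neighbours <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  is_core <- vapply(neighbours, length, integer(1)) >= minpts
  labels <- rep(0L, n)  # 0 = unvisited
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !is_core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    seeds <- neighbours[[i]]
    k <- 1L
    while (k <= length(seeds)) {
      j <- seeds[k]
      k <- k + 1L
      if (labels[j] == -1L) labels[j] <- cl       # noise becomes border
      if (labels[j] != 0L) next
      labels[j] <- cl
      if (is_core[j]) seeds <- c(seeds, neighbours[[j]])
    }
  }
  labels[labels == 0L] <- -1L
  labels
}
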