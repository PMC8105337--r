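test_that("log-normalization fixes library size and drops empty cells", {
  counts <- matrix(c(10, 0, 5, 20, 0, 10, 0, 0, 0), 3,
                   dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  expect_warning(nm <- normalize_log(counts), "zero-count")
  expect_equal(ncol(nm), 2)
  # doubling a cell's counts leaves its normalized vector unchanged
  expect_equal(nm[, "c2"], normalize_log(counts[, 1:2] * 2,
                                         scale_factor = 1e4)[, "c2"])
  # closed-form spot check
  expect_equal(nm["g1", "c1"], log1p(10 * 1e4 / 15))
  expect_error(normalize_log(-counts), "non-negative")
})

test_that("the vectorized rank-sum test matches stats::wilcox.test", {
  set.seed(51)
  x <- matrix(rnbinom(30 * 40, mu = 5, size = 1), 30, 40)
  idx <- 1:15
  p_fast <- myelotrace:::rank_sum_rows(x, idx)
  p_ref <- apply(x, 1, function(row)
    suppressWarnings(wilcox.test(row[idx], row[-idx])$p.value))
  expect_equal(p_fast, unname(p_ref), tolerance = 1e-10)
})

test_that("DEG selection recovers planted programs and controls the null", {
  spec <- data.frame(cluster = c("a", "b", "c"), fraction = c(0.4, 0.3, 0.3))
  prog <- list(list(name = "p", genes = 1:60, clusters = "b", fold = 3))
  ex <- gen_expression(spec, 360, 400, planted_programs = prog, seed = 53)
  nm <- normalize_log(ex$counts)
  degs <- select_degs(nm, ex$cells$cluster)
  planted <- rownames(nm)[1:60]
  sens <- mean(planted %in% degs$b$gene)
  fdr <- if (nrow(degs$b)) mean(!(degs$b$gene %in% planted)) else 0
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.1)

  # permuting cell order leaves the DEG sets unchanged
  perm <- sample(ncol(nm))
  degs_perm <- select_degs(nm[, perm], ex$cells$cluster[perm])
  expect_equal(lapply(degs_perm, function(d) sort(d$gene)),
               lapply(degs, function(d) sort(d$gene)))

  # marker mode honors its own thresholds
  mk <- select_degs(nm, ex$cells$cluster, mode = "marker")
  expect_true(all(mk$b$fdr < 0.05 & mk$b$log2_fc > 0))

  expect_error(select_degs(nm[, 1:5], c("a", "a", "a", "b", "b")),
               "fewer than 3")
})

test_that("null expression data yield a median DEG count of zero", {
  spec <- data.frame(cluster = c("a", "b"), fraction = c(0.5, 0.5))
  n_deg <- vapply(1:50, function(s) {
    ex <- gen_expression(spec, 120, 250, seed = 1000 + s)
    nm <- normalize_log(ex$counts)
    sum(vapply(select_degs(nm, ex$cells$cluster), nrow, integer(1)))
  }, integer(1))
  expect_equal(median(n_deg), 0)
})

test_that("hypergeometric enrichment matches combinatorial enumeration", {
  universe <- paste0("g", 1:100)
  pw <- list(hit = universe[1:10], miss = universe[90:100])
  degs <- universe[c(1:5, 50:54)]   # overlap 5 with 'hit'
  res <- enrich_pathways(degs, universe, pw)
  # oracle: explicit sum over the hypergeometric tail
  p_oracle <- sum(vapply(5:10, function(i)
    choose(10, i) * choose(90, 10 - i), numeric(1))) / choose(100, 10)
  expect_equal(res$p[res$pathway == "hit"], p_oracle, tolerance = 1e-12)

  # DEG set identical to a pathway attains the minimal possible p
  res_full <- enrich_pathways(universe[1:10], universe, pw)
  p_min <- choose(90, 0) * choose(10, 10) / choose(100, 10)
  expect_equal(res_full$p[res_full$pathway == "hit"], p_min, tolerance = 1e-12)
  # empty DEG set -> all q = 1
  expect_true(all(enrich_pathways(character(0), universe, pw)$q == 1))
  # zero overlap -> nothing significant
  res0 <- enrich_pathways(universe[60:69], universe, list(pwA = universe[1:10]))
  expect_true(all(res0$q > 0.05))
  # BH preserves order and q >= p
  expect_true(all(res$q >= res$p - 1e-15))
})

test_that("enrichment-correlation grouping recovers planted archetypes", {
  set.seed(61)
  # three archetypes of -log10 q profiles over 40 pathways
  arch_profiles <- matrix(runif(3 * 40, 0.2, 6), 3, 40)
  subpops <- do.call(rbind, lapply(1:12, function(i) {
    pmax(arch_profiles[(i - 1) %% 3 + 1, ] + rnorm(40, 0, 0.3), 0.05)
  }))
  q <- 10^(-subpops)
  rownames(q) <- paste0("sp", 1:12)
  res <- enrichment_correlation_clusters(q, n_groups = 3)
  truth <- rep(1:3, 4)
  expect_gte(mclust::adjustedRandIndex(res$groups, truth), 0.9)

  # identical profiles correlate at 1 and share a group
  q2 <- rbind(a = q[1, ], b = q[1, ], c = q[2, ], d = q[2, ])
  res2 <- enrichment_correlation_clusters(q2, n_groups = 2)
  expect_equal(res2$r["a", "b"], 1)
  expect_equal(res2$groups[["a"]], res2$groups[["b"]])

  # invariance under pathway permutation
  perm <- sample(ncol(q))
  res3 <- enrichment_correlation_clusters(q[, perm], n_groups = 3)
  expect_equal(res3$groups, res$groups)

  # degenerate inputs
  expect_error(enrichment_correlation_clusters(matrix(1, 3, 4)), "no significant")
  qc <- rbind(a = q[1, ], b = q[1, ], const = rep(1e-3, 40))
  expect_warning(res4 <- enrichment_correlation_clusters(qc, n_groups = 2),
                 "constant")
  expect_false("const" %in% names(res4$groups))
})

test_that("cell-type marker correlation finds within-archetype similarity", {
  spec <- data.frame(
    cluster = c("p1", "p2", "p3", "p4", "t1", "t2", "t3", "t4"),
    fraction = 1,
    sample = rep(c("s1", "s2", "s3", "s4"), 2),
    cell_type = rep(c("Plasma", "Tcell"), each = 4),
    stringsAsFactors = FALSE
  )
  # plasma cells carry a strong marker program; samples s1/s2 share a second
  # program, s3/s4 another -> within-archetype correlation exceeds between
  progs <- list(
    list(name = "plasma", genes = 1:40, clusters = paste0("p", 1:4), fold = 6),
    list(name = "arch1", genes = 41:70, clusters = c("p1", "p2"), fold = 4),
    list(name = "arch2", genes = 71:100, clusters = c("p3", "p4"), fold = 4)
  )
  ex <- gen_expression(spec, 480, 300, planted_programs = progs, seed = 63)
  nm <- normalize_log(ex$counts)
  ann <- data.frame(cell = ex$cells$cell, sample = ex$cells$sample,
                    cell_type = ex$cells$cell_type, stringsAsFactors = FALSE)
  res <- celltype_sample_correlation(nm, ann)
  expect_true("Plasma" %in% names(res))
  r <- res$Plasma$r
  within <- c(r["s1", "s2"], r["s3", "s4"])
  between <- c(r["s1", "s3"], r["s1", "s4"], r["s2", "s3"], r["s2", "s4"])
  expect_gt(min(within), max(between))

  # two pseudo-samples drawn from the same cells correlate at ~1
  ann2 <- ann
  ann2$sample <- rep(c("x", "y"), length.out = nrow(ann2))
  res2 <- celltype_sample_correlation(nm, ann2)
  expect_gt(res2$Plasma$r["x", "y"], 0.98)

  expect_error(celltype_sample_correlation(nm, transform(ann, sample = "s1")),
               "two samples")
})

test_that("subpopulation matching labels stable, gained and lost patterns", {
  mk_prof <- function(id, centroid, cnv) {
    subpopulation_profile(id, "s", 10, centroid, cnv)
  }
  set.seed(71)
  c1 <- setNames(runif(50), paste0("g", 1:50))
  c2 <- setNames(runif(50), paste0("g", 1:50))
  cnvA <- setNames(rep("neutral", 3), c("chr1", "chr13", "chr14"))
  cnvB <- setNames(c("loss", "neutral", "gain"), c("chr1", "chr13", "chr14"))
  p1 <- list(mk_prof("A", c1, cnvA), mk_prof("B", c2, cnvB))

  # identical sets -> all stable with similarity 1
  res <- match_subpopulations(p1, p1)
  expect_equal(sort(res$matches$similarity), c(1, 1))
  expect_true(all(res$patterns$pattern == "stable"))

  # one novel profile at t2 -> gained; removing one at t2 -> lost
  c3 <- setNames(runif(50), paste0("g", 1:50))
  cnvC <- setNames(rep("amplification", 3), c("chr1", "chr13", "chr14"))
  p2 <- c(p1, list(mk_prof("C", c3, cnvC)))
  res2 <- match_subpopulations(p1, p2)
  expect_equal(res2$patterns$pattern[res2$patterns$id == "C"], "gained")
  expect_equal(sum(res2$patterns$pattern == "gained"), 1)

  # symmetry: swapping timepoints exchanges gained and lost
  res3 <- match_subpopulations(p2, p1)
  expect_equal(res3$patterns$pattern[res3$patterns$id == "C"], "lost")
  expect_equal(res2$matches$similarity, res3$matches$similarity)

  # empty sides
  res4 <- match_subpopulations(list(), p1)
  expect_true(all(res4$patterns$pattern == "gained"))
  res5 <- match_subpopulations(p1, list())
  expect_true(all(res5$patterns$pattern == "lost"))
})

test_that("QC stratification shows program elevation in both nGene strata", {
  spec <- data.frame(cluster = c("plasma", "tcell"), fraction = c(0.5, 0.5),
                     cell_type = c("Plasma", "Tcell"))
  prog <- list(list(name = "AP1", genes = 1:20, clusters = "plasma", fold = 5))
  ex <- gen_expression(spec, 400, 300, planted_programs = prog, seed = 73)
  nm <- normalize_log(ex$counts)
  ann <- data.frame(cell = ex$cells$cell, cell_type = ex$cells$cell_type,
                    n_genes_expressed = ex$cells$n_genes_expressed,
                    stringsAsFactors = FALSE)
  thresh <- median(ann$n_genes_expressed)
  res <- qc_stratified_check(nm, ann, rownames(nm)[1:20],
                             ngene_thresh = thresh)
  s <- res$summary
  for (st in unique(s$stratum)) {
    hi <- s$mean_score[s$cell_type == "Plasma" & s$stratum == st]
    lo <- s$mean_score[s$cell_type == "Tcell" & s$stratum == st]
    if (!is.na(hi) && !is.na(lo)) expect_gt(hi, lo)
  }

  # absent gene set -> all-zero means, no crash
  res0 <- qc_stratified_check(nm, ann, c("nope1", "nope2"), thresh)
  expect_true(all(res0$summary$mean_score[!is.na(res0$summary$mean_score)] == 0))
  # single-stratum input warns but returns
  ann_one <- transform(ann, n_genes_expressed = 10)
  expect_warning(res1 <- qc_stratified_check(nm, ann_one, rownames(nm)[1:20],
                                             ngene_thresh = 5),
                 "empty stratum")
  expect_true(all(is.na(res1$tests$p)))
})
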