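#' Simulate a multi-population genotype panel with read counts
#'
#' Balding-Nichols model: each marker has an ancestral allele frequency
#' drawn Uniform(0.05, 0.95); each population draws its own frequency from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with divergence parameter `fst` (at
#' `fst = 0` every population uses the ancestral frequency, so labels are
#' exchangeable). Diploid genotypes follow Hardy-Weinberg within population;
#' sequencing evidence is a Poisson read depth with alternate reads
#' `Binomial(depth, dosage/2)`. A `missing_rate` fraction of (sample, marker)
#' cells is emitted with zero reads. This panel emulates a coding-SNP
#' reference resource (common markers, minor allele frequency bounded away
#' from zero) for the ancestry-projection stage.
#'
#' @param n_pops number of populations (>= 2 for classification use).
#' @param n_per_pop samples per population.
#' @param n_markers number of biallelic markers.
#' @param fst Balding-Nichols divergence in [0, 1).
#' @param mean_depth mean sequencing depth per (sample, marker).
#' @param missing_rate fraction of cells zeroed out.
#' @param seed integer seed.
#'
#' @return list with integer matrices `ref` and `alt` (samples x markers),
#'   `population` labels, `genotype` (true dosage 0/1/2), and `freq`
#'   (markers x populations allele-frequency matrix).
#' @export
gen_genotype_panel <- function(n_pops, n_per_pop, n_markers, fst = 0.1,
                               mean_depth = 30, missing_rate = 0.02, seed = 1L) {
  stopifnot(n_pops >= 1, n_per_pop >= 1, n_markers >= 1)
  stop_if_not_scalar_prob(fst, "fst")
  stop_if_not_scalar_prob(missing_rate, "missing_rate")

  with_seed(seed, {
    p_anc <- runif(n_markers, 0.05, 0.95)
    freq <- matrix(NA_real_, n_markers, n_pops,
                   dimnames = list(NULL, paste0("pop", seq_len(n_pops))))
    for (k in seq_len(n_pops)) {
      freq[, k] <- if (fst == 0) p_anc else
        rbeta(n_markers, p_anc * (1 - fst) / fst, (1 - p_anc) * (1 - fst) / fst)
    }
    n <- n_pops * n_per_pop
    population <- rep(colnames(freq), each = n_per_pop)
    samples <- sprintf("s%04d", seq_len(n))
    geno <- matrix(NA_integer_, n, n_markers,
                   dimnames = list(samples, sprintf("m%05d", seq_len(n_markers))))
    for (k in seq_len(n_pops)) {
      rows <- which(population == colnames(freq)[k])
      geno[rows, ] <- vapply(seq_len(n_markers), function(j) {
        rbinom(length(rows), 2L, freq[j, k])
      }, integer(length(rows)))
    }
    depth <- matrix(rpois(n * n_markers, mean_depth), n, n_markers)
    depth[matrix(runif(n * n_markers) < missing_rate, n, n_markers)] <- 0L
    alt <- matrix(rbinom(n * n_markers, depth, geno / 2), n, n_markers,
                  dimnames = dimnames(geno))
    ref <- depth - alt
    dimnames(ref) <- dimnames(geno)

    list(ref = ref, alt = alt, population = population,
         genotype = geno, freq = freq)
  })
}

#' Simulate a per-cell log2 copy-ratio matrix from a clonal architecture
#'
#' Each cell inherits its subclone's per-chromosome relative copy ratio
#' (neutral = 1); the value reported for a gene is the log2 of the ratio of
#' the gene's chromosome plus Gaussian noise, mimicking a smoothed
#' expression-derived copy-number signal on a marker gene panel.
#'
#' @param arch a [gen_architecture()] result.
#' @param timepoint timepoint whose occupancy is sampled.
#' @param n_cells number of cells.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param gene_panel data.frame with columns `gene` and `chrom` assigning each
#'   panel gene to a chromosome of the architecture.
#' @param seed integer seed.
#'
#' @return list with `matrix` (cells x genes log2 ratios) and `cells`
#'   (truth: cell, subclone, and `cluster` — the distinct copy-ratio profile
#'   group, the recoverable clustering target when subclones share a
#'   profile).
#' @export
gen_cnv_matrix <- function(arch, timepoint, n_cells, noise_sd, gene_panel,
                           seed = 1L) {
  stopifnot(inherits(arch, "clonal_architecture"))
  if (is.null(gene_panel) || nrow(gene_panel) == 0) {
    stop("`gene_panel` must contain at least one gene", call. = FALSE)
  }
  if (!all(gene_panel$chrom %in% arch$chromosomes)) {
    stop("gene panel references chromosomes absent from the architecture",
         call. = FALSE)
  }
  occ <- subclone_occupancy(arch, timepoint)

  with_seed(seed, {
    cells <- data.frame(
      cell = sprintf("c%05d", seq_len(n_cells)),
      subclone = sample(as.integer(names(occ)), n_cells, replace = TRUE,
                        prob = occ),
      stringsAsFactors = FALSE
    )
    # clustering truth is the distinct copy-ratio profile, not the subclone
    # id: subclones sharing a profile are indistinguishable from CNV alone
    profile_key <- apply(arch$copy_ratio, 1, paste, collapse = "|")
    cells$cluster <- match(profile_key[as.character(cells$subclone)],
                           unique(profile_key[unique(as.character(cells$subclone))]))
    ratio <- arch$copy_ratio[as.character(cells$subclone),
                             gene_panel$chrom, drop = FALSE]
    m <- log2(ratio) + matrix(rnorm(n_cells * nrow(gene_panel), 0, noise_sd),
                              n_cells, nrow(gene_panel))
    dimnames(m) <- list(cells$cell, gene_panel$gene)
    list(matrix = m, cells = cells)
  })
}

#' Simulate a clustered single-cell expression count matrix
#'
#' Negative-binomial counts with lognormal library-size variation and
#' per-cluster planted gene programs: genes listed in a program have their
#' expected expression multiplied by `fold` in the designated clusters (the
#' canonical use is an AP-1-like transcription-factor program planted in one
#' plasma-cell subcluster). At `fold = 1` the program leaves no signal, which
#' is the null case for differential-expression error control.
#'
#' @param cluster_spec data.frame with one row per cluster: columns `cluster`
#'   (id), `fraction` (expected cell share, normalized internally), and
#'   optionally `sample`, `timepoint`, `cell_type` carried into the cell
#'   annotations.
#' @param n_cells,n_genes matrix dimensions.
#' @param planted_programs list of programs, each a list with `name`, `genes`
#'   (gene names or indices), `clusters` (cluster ids), `fold` (> 0).
#' @param seed integer seed.
#' @param dispersion negative-binomial size parameter.
#'
#' @return list with `counts` (genes x cells integer matrix), `cells`
#'   (annotations incl. per-cell expressed-gene count `n_genes_expressed`),
#'   and `genes` (gene, program membership).
#' @export
gen_expression <- function(cluster_spec, n_cells, n_genes,
                           planted_programs = list(), seed = 1L,
                           dispersion = 2) {
  stopifnot(nrow(cluster_spec) >= 1, n_cells >= 1, n_genes >= 1)
  genes <- sprintf("g%05d", seq_len(n_genes))
  for (pr in planted_programs) {
    if (!all(pr$clusters %in% cluster_spec$cluster)) {
      stop(sprintf("program '%s' references unknown cluster", pr$name),
           call. = FALSE)
    }
    if (is.numeric(pr$genes) && any(pr$genes > n_genes)) {
      stop(sprintf("program '%s' references gene index beyond n_genes", pr$name),
           call. = FALSE)
    }
  }

  with_seed(seed, {
    frac <- cluster_spec$fraction / sum(cluster_spec$fraction)
    cl_idx <- sample.int(nrow(cluster_spec), n_cells, replace = TRUE, prob = frac)
    cells <- data.frame(
      cell = sprintf("c%05d", seq_len(n_cells)),
      cluster = cluster_spec$cluster[cl_idx],
      sample = (cluster_spec$sample %||% rep("s1", nrow(cluster_spec)))[cl_idx],
      timepoint = (cluster_spec$timepoint %||% rep(1L, nrow(cluster_spec)))[cl_idx],
      cell_type = (cluster_spec$cell_type %||%
                     rep("Plasma", nrow(cluster_spec)))[cl_idx],
      stringsAsFactors = FALSE
    )
    base_mu <- rlnorm(n_genes, meanlog = 0, sdlog = 1)
    size_factor <- rlnorm(n_cells, meanlog = 0, sdlog = 0.3)

    # per-cluster fold matrix (genes x clusters), programs multiply in
    fold <- matrix(1, n_genes, nrow(cluster_spec))
    gene_program <- rep(NA_character_, n_genes)
    for (pr in planted_programs) {
      gi <- if (is.numeric(pr$genes)) pr$genes else match(pr$genes, genes)
      ci <- match(pr$clusters, cluster_spec$cluster)
      fold[gi, ci] <- fold[gi, ci] * pr$fold
      gene_program[gi] <- pr$name
    }
    mu <- base_mu * fold[, cl_idx, drop = FALSE] *
      rep(size_factor, each = n_genes)
    counts <- matrix(rnbinom(n_genes * n_cells, mu = mu, size = dispersion),
                     n_genes, n_cells, dimnames = list(genes, cells$cell))
    cells$n_genes_expressed <- colSums(counts > 0)

    list(counts = counts, cells = cells,
         genes = data.frame(gene = genes, program = gene_program,
                            stringsAsFactors = FALSE))
  })
}
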