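test_that("architecture generator respects the lineage and assignment invariants", {
  # degenerate single clone: everything truncal, CCF 1 everywhere
  a1 <- gen_architecture(1, 3, 5, seed = 7)
  expect_true(all(a1$ccf == 1))
  expect_true(all(a1$variants$subclone == 1))
  expect_silent(validate_architecture(a1))

  # exhaustive constraint check over several seeds and shapes
  for (seed in 1:5) {
    arch <- gen_architecture(3 + seed %% 3, 2, 12, seed = seed)
    expect_silent(validate_architecture(arch))
    par <- arch$subclones$parent
    for (i in seq_along(par)) {
      if (!is.na(par[i])) {
        expect_true(all(arch$ccf[i, ] <= arch$ccf[par[i], ] + 1e-12))
      }
    }
    for (t in seq_len(ncol(arch$ccf))) {
      occ <- myelotrace:::subclone_occupancy(arch, t)
      expect_true(all(occ >= -1e-12))
      expect_equal(sum(occ), 1, tolerance = 1e-9)
    }
  }

  expect_identical(gen_architecture(3, 2, 10, seed = 11),
                   gen_architecture(3, 2, 10, seed = 11))
  expect_error(gen_architecture(5, 2, 3, seed = 1), "n_variants")
})

test_that("tagged-read generator is noise-faithful, CCF-calibrated and deterministic", {
  arch <- fixture_arch(seed = 3)
  tr <- gen_tagged_reads(arch, 1, n_cells = 60, mean_depth = 12,
                         error_rate = 0, seed = 5)

  # noiseless limit: every covered carrier cell shows >= 1 alt read
  v <- arch$variants
  for (vi in sample(nrow(v), 3)) {
    carriers <- tr$cells$barcode[vapply(tr$cells$subclone, function(s)
      v$subclone[vi] %in% myelotrace:::lineage_of(arch, s), logical(1))]
    reads_v <- tr$records[grepl(v$variant_id[vi], tr$records$qname), ]
    alt_base <- substr(reads_v$seq, v$pos[vi] - reads_v$pos + 1L,
                       v$pos[vi] - reads_v$pos + 1L)
    covered_carriers <- intersect(carriers, unique(reads_v$cb))
    for (b in covered_carriers) {
      expect_true(any(alt_base[reads_v$cb == b] == v$alt[vi]))
    }
  }

  # alt-supporting cell fraction matches lineage CCF within a binomial CI
  arch1 <- gen_architecture(2, 1, 2, seed = 9)
  trc <- gen_tagged_reads(arch1, 1, n_cells = 400, mean_depth = 20,
                          error_rate = 0, seed = 6)
  v2 <- arch1$variants[arch1$variants$subclone == 2, ][1, ]
  carrier <- vapply(trc$cells$subclone, function(s)
    2L %in% myelotrace:::lineage_of(arch1, s), logical(1))
  ccf <- arch1$ccf[2, 1]
  ci <- qbinom(c(0.025, 0.975), 400, ccf) / 400
  expect_gte(mean(carrier), ci[1])
  expect_lte(mean(carrier), ci[2])

  expect_identical(gen_tagged_reads(arch, 1, 20, 5, seed = 2),
                   gen_tagged_reads(arch, 1, 20, 5, seed = 2))
  expect_error(gen_tagged_reads(arch, 99, 20, 5, seed = 2), "timepoint")
})

test_that("generated SAM validates: header, coordinate order, tags everywhere", {
  arch <- fixture_arch(seed = 4)
  tr <- gen_tagged_reads(arch, 1, 25, 6, seed = 8)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(tr, path)
  lines <- readLines(path)
  hdr <- grep("^@", lines, value = TRUE)
  expect_true(any(grepl("^@HD", hdr)))
  expect_setequal(sub(".*SN:([^\t]+).*", "\\1", grep("^@SQ", hdr, value = TRUE)),
                  arch$chromosomes)
  body <- strsplit(grep("^@", lines, value = TRUE, invert = TRUE), "\t")
  rname <- vapply(body, `[[`, character(1), 3)
  pos <- as.integer(vapply(body, `[[`, character(1), 4))
  for (ch in unique(rname)) expect_false(is.unsorted(pos[rname == ch]))
  expect_true(all(vapply(body, function(f)
    any(grepl("^CB:Z:", f)) && any(grepl("^UB:Z:", f)), logical(1))))
})

test_that("linked-read generator produces haplotype-faithful molecules", {
  arch <- fixture_arch(seed = 2)
  lr <- gen_linked_reads(arch, 200, error_rate = 0, seed = 3)

  # noiseless: every het observation matches the molecule's haplotype allele
  ph_key <- paste(lr$phase$chrom, lr$phase$pos)
  for (m in sample(nrow(lr$molecules), 20)) {
    mol <- lr$molecules[m, ]
    o <- lr$observations[lr$observations$barcode == mol$barcode &
                           lr$observations$locus_type == "het", ]
    ph <- lr$phase[match(paste(o$chrom, o$pos), ph_key), ]
    expected <- if (mol$haplotype == 1) ph$hap1 else ph$hap2
    expect_identical(o$allele, expected)
  }

  # alt-molecule fraction ~ CCF/2 for a one-haplotype variant (binomial CI)
  arch1 <- gen_architecture(1, 1, 1, seed = 21, chromosomes = "chr1")
  lr1 <- gen_linked_reads(arch1, 600, error_rate = 0, seed = 4)
  v <- arch1$variants[1, ]
  span <- lr1$molecules$start <= v$pos & lr1$molecules$end >= v$pos
  alt <- lr1$observations$barcode[lr1$observations$pos == v$pos &
                                    lr1$observations$allele == v$alt]
  n <- sum(span)
  ci <- qbinom(c(0.025, 0.975), n, 0.5) / n
  frac <- length(alt) / n
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])

  expect_identical(gen_linked_reads(arch, 50, seed = 5),
                   gen_linked_reads(arch, 50, seed = 5))
  expect_error(gen_linked_reads(arch, 10, molecule_len_bp = 100,
                                het_spacing_bp = 5000, seed = 1),
               "molecule_len_bp")
  # molecules spanning no het are emitted but flagged uninformative
  lr_sparse <- gen_linked_reads(arch, 100, molecule_len_bp = 2000,
                                het_spacing_bp = 1900, seed = 6)
  expect_true(all(lr_sparse$molecules$informative %in% c(TRUE, FALSE)))
})

test_that("genotype panel follows Hardy-Weinberg and Balding-Nichols structure", {
  pan <- gen_genotype_panel(2, 250, 60, fst = 0, mean_depth = 30,
                            missing_rate = 0, seed = 13)
  # at fst = 0 heterozygosity per marker ~ 2p(1-p), 95% binomial CI
  het <- colMeans(pan$genotype == 1)
  p <- pan$freq[, 1]
  n <- nrow(pan$genotype)
  lo <- qbinom(0.0005, n, 2 * p * (1 - p)) / n   # Bonferroni over 60 markers
  hi <- qbinom(0.9995, n, 2 * p * (1 - p)) / n
  expect_true(all(het >= lo & het <= hi))

  expect_identical(gen_genotype_panel(3, 10, 50, seed = 2),
                   gen_genotype_panel(3, 10, 50, seed = 2))
  pan_miss <- gen_genotype_panel(2, 50, 100, missing_rate = 0.1, seed = 3)
  zero <- pan_miss$ref + pan_miss$alt == 0
  expect_gt(mean(zero), 0.05)
})

test_that("CNV matrix generator plants exact log2 profiles plus noise", {
  arch <- fixture_arch(seed = 6)
  panel <- data.frame(gene = paste0("G", 1:12),
                      chrom = rep(arch$chromosomes, each = 4))
  cm0 <- gen_cnv_matrix(arch, 1, 100, noise_sd = 0, gene_panel = panel, seed = 4)
  # noiseless: value is exactly log2(subclone ratio) for the gene's chromosome
  for (i in sample(100, 10)) {
    expected <- log2(arch$copy_ratio[as.character(cm0$cells$subclone[i]),
                                     panel$chrom])
    expect_equal(unname(cm0$matrix[i, ]), unname(expected))
  }
  # CLT oracle: per-cluster gene means within 3 sd / sqrt(n)
  cm <- gen_cnv_matrix(arch, 1, 400, noise_sd = 0.2, gene_panel = panel, seed = 5)
  for (s in unique(cm$cells$subclone)) {
    rows <- cm$cells$subclone == s
    n <- sum(rows)
    if (n < 10) next
    planted <- log2(arch$copy_ratio[as.character(s), panel$chrom])
    dev <- abs(colMeans(cm$matrix[rows, , drop = FALSE]) - planted)
    expect_true(all(dev <= 4 * 0.2 / sqrt(n)))
  }
  expect_identical(gen_cnv_matrix(arch, 1, 30, 0.1, panel, seed = 9),
                   gen_cnv_matrix(arch, 1, 30, 0.1, panel, seed = 9))
  expect_error(gen_cnv_matrix(arch, 1, 30, 0.1, panel[0, ], seed = 9),
               "gene_panel")
})

test_that("expression generator plants programs at the requested fold", {
  spec <- data.frame(cluster = c("a", "b"), fraction = c(0.5, 0.5))
  prog <- list(list(name = "p1", genes = 1:30, clusters = "b", fold = 3))
  ex <- gen_expression(spec, 600, 200, planted_programs = prog, seed = 17)
  in_b <- ex$cells$cluster == "b"
  planted <- 1:30
  ratio <- rowSums(ex$counts[planted, in_b]) / sum(in_b) /
    (rowSums(ex$counts[planted, !in_b]) / sum(!in_b))
  # ratio-of-means oracle: empirical fold near 3 on average
  expect_equal(mean(ratio), 3, tolerance = 0.25)

  expect_identical(gen_expression(spec, 50, 40, seed = 2),
                   gen_expression(spec, 50, 40, seed = 2))
  bad <- list(list(name = "p1", genes = 1:3, clusters = "zzz", fold = 2))
  expect_error(gen_expression(spec, 20, 10, planted_programs = bad, seed = 1),
               "unknown cluster")
})

test_that("truth tables reference generated entities bijectively", {
  arch <- fixture_arch(seed = 8)
  tr <- gen_tagged_reads(arch, 1, 30, 5, seed = 10)
  expect_setequal(unique(tr$records$cb), intersect(tr$cells$barcode,
                                                   unique(tr$records$cb)))
  expect_true(all(tr$cells$subclone %in% c(0L, arch$subclones$id)))
  lr <- gen_linked_reads(arch, 40, seed = 11)
  expect_setequal(unique(lr$observations$barcode),
                  lr$molecules$barcode[lr$molecules$informative |
                                         lr$molecules$barcode %in%
                                         lr$observations$barcode])
  expect_true(!anyDuplicated(lr$molecules$barcode))
})
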