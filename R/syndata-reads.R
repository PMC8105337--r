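#' Simulate barcode-tagged single-cell alignments over somatic variant loci
#'
#' Draws cells from the architecture's subclones in proportion to their
#' exclusive CCF occupancy (plus a normal compartment of size 1 - purity),
#' then emits coordinate-sorted single-end SAM records covering every somatic
#' variant locus. Each record carries a cell barcode and a UMI tag, the
#' droplet convention consumed by [extract_observations()]. A read reports the
#' alternate base iff its cell's subclone lineage carries the variant, with a
#' symmetric ref/alt flip at rate `error_rate`.
#'
#' Reads are single-end, 100 bp, perfectly aligned (CIGAR `100M`, MAPQ 60)
#' with no mismatches away from the variant locus: the consumers under test
#' operate on alignments, not raw reads, so read-level realism adds nothing.
#'
#' @param arch a [gen_architecture()] result.
#' @param timepoint which timepoint's CCFs to sample cells from.
#' @param n_cells number of cells.
#' @param mean_depth Poisson mean of per-cell, per-locus read depth.
#' @param error_rate per-read probability of flipping ref and alt, in [0, 0.5).
#' @param seed integer seed.
#' @param read_len read length in bp.
#' @param cb_tag,umi_tag SAM tag names for cell barcode and UMI.
#'
#' @return list with `records` (data.frame of SAM fields plus `cb`, `umi`),
#'   `header` (character vector of SAM header lines), and `cells`
#'   (truth table: barcode, subclone; subclone 0 is normal).
#' @seealso [write_sam()] to serialize, [extract_observations()] to consume.
#' @export
gen_tagged_reads <- function(arch, timepoint, n_cells, mean_depth,
                             error_rate = 0.01, seed = 1L, read_len = 100L,
                             cb_tag = "CB", umi_tag = "UB") {
  stopifnot(inherits(arch, "clonal_architecture"), n_cells >= 1, mean_depth > 0)
  stop_if_not_scalar_prob(error_rate, "error_rate", upper = 0.5)
  occ <- subclone_occupancy(arch, timepoint)  # errors on bad timepoint

  with_seed(seed, {
    barcodes <- random_barcodes(n_cells)
    subclone <- sample(as.integer(names(occ)), n_cells, replace = TRUE, prob = occ)
    cells <- data.frame(barcode = barcodes, subclone = subclone,
                        stringsAsFactors = FALSE)

    v <- arch$variants
    recs <- vector("list", n_cells * nrow(v))
    k <- 0L
    for (ci in seq_len(n_cells)) {
      carried <- variants_in_lineage(arch, subclone[ci])
      for (vi in seq_len(nrow(v))) {
        depth <- rpois(1L, mean_depth)
        if (depth == 0L) next
        n_umi <- max(1L, rbinom(1L, depth, 0.8))
        umis <- random_barcodes(n_umi, width = 10L)
        umi_of_read <- umis[sample.int(n_umi, depth, replace = TRUE)]
        is_alt <- rep(v$variant_id[vi] %in% carried, depth)
        flip <- runif(depth) < error_rate
        is_alt <- xor(is_alt, flip)
        offset <- sample.int(read_len, depth, replace = TRUE) - 1L
        start <- pmax(1L, v$pos[vi] - offset)
        base <- ifelse(is_alt, v$alt[vi], v$ref[vi])
        seqs <- vapply(seq_len(depth), function(r) {
          s <- rep("A", read_len)
          s[v$pos[vi] - start[r] + 1L] <- base[r]
          paste(s, collapse = "")
        }, character(1))
        k <- k + 1L
        recs[[k]] <- data.frame(
          qname = sprintf("r_%s_%s_%03d", barcodes[ci], v$variant_id[vi],
                          seq_len(depth)),
          flag = 0L, rname = v$chrom[vi], pos = start, mapq = 60L,
          cigar = sprintf("%dM", read_len),
          seq = seqs, cb = barcodes[ci], umi = umi_of_read,
          stringsAsFactors = FALSE
        )
      }
    }
    records <- if (k) do.call(rbind, recs[seq_len(k)]) else
      data.frame(qname = character(), flag = integer(), rname = character(),
                 pos = integer(), mapq = integer(), cigar = character(),
                 seq = character(), cb = character(), umi = character())
    ord <- order(match(records$rname, arch$chromosomes), records$pos)
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL

    seq_lens <- vapply(arch$chromosomes, function(ch) {
      p <- v$pos[v$chrom == ch]
      as.integer(if (length(p)) max(p) + 1000L else 1e6L)
    }, integer(1))
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", arch$chromosomes, seq_lens))

    list(records = records, header = header, cells = cells,
         cb_tag = cb_tag, umi_tag = umi_tag)
  })
}

#' Write simulated tagged alignments to a SAM file
#'
#' @param tagged a [gen_tagged_reads()] result.
#' @param path output SAM path.
#' @return `path` invisibly.
#' @export
write_sam <- function(tagged, path) {
  r <- tagged$records
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\t%s:Z:%s\t%s:Z:%s",
                   r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar, r$seq,
                   strrep("I", nchar(r$seq)),
                   tagged$cb_tag %||% "CB", r$cb,
                   tagged$umi_tag %||% "UB", r$umi)
  writeLines(c(tagged$header, lines), path)
  invisible(path)
}

#' Simulate linked-read molecules spanning phased germline hets and somatic sites
#'
#' Emulates a linked-read (barcoded long-molecule) library: each molecule has
#' a unique droplet barcode, an originating germline haplotype, and a source
#' subclone drawn from the architecture's occupancy at `timepoint`. The
#' molecule reports the haplotype allele at every phased germline het it
#' spans (flipped to the opposite het allele at rate `error_rate`) and, at a
#' somatic site it spans, the alternate allele iff both its haplotype and its
#' source lineage carry the variant. This is the substrate for deciding
#' whether two somatic mutations on one haplotype arose in the same subclone
#' or independently.
#'
#' @param arch a [gen_architecture()] result.
#' @param n_molecules number of molecules.
#' @param molecule_len_bp molecule length (must exceed `het_spacing_bp`).
#' @param het_spacing_bp spacing of phased germline het sites.
#' @param error_rate per-observation allele flip probability, in [0, 0.5).
#' @param seed integer seed.
#' @param timepoint timepoint whose subclone occupancy is sampled.
#'
#' @return list with `observations` (barcode, chrom, pos, allele, locus_type),
#'   `phase` (chrom, pos, hap1, hap2 alleles per het), `molecules` (truth:
#'   barcode, chrom, start, end, haplotype, subclone, informative — FALSE when
#'   the molecule spans no het), and `variants` (the architecture's SNVs).
#' @export
gen_linked_reads <- function(arch, n_molecules, molecule_len_bp = 50000,
                             het_spacing_bp = 5000, error_rate = 0.01,
                             seed = 1L, timepoint = 1L) {
  stopifnot(inherits(arch, "clonal_architecture"))
  if (molecule_len_bp <= het_spacing_bp) {
    stop("`molecule_len_bp` must exceed `het_spacing_bp`", call. = FALSE)
  }
  stop_if_not_scalar_prob(error_rate, "error_rate", upper = 0.5)
  occ <- subclone_occupancy(arch, timepoint)
  v <- arch$variants
  chroms <- unique(v$chrom)

  with_seed(seed, {
    # phased het scaffold around the somatic loci on each chromosome
    phase <- do.call(rbind, lapply(chroms, function(ch) {
      p <- v$pos[v$chrom == ch]
      lo <- max(1, min(p) - 2L * molecule_len_bp)
      hi <- max(p) + 2L * molecule_len_bp
      pos <- seq(lo, hi, by = het_spacing_bp)
      pos <- setdiff(pos, p)
      h1 <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
      data.frame(chrom = ch, pos = as.integer(pos), hap1 = h1,
                 hap2 = other_base(h1), stringsAsFactors = FALSE)
    }))

    mol_chrom <- sample(chroms, n_molecules, replace = TRUE)
    start <- integer(n_molecules)
    for (ch in chroms) {
      sel <- mol_chrom == ch
      lo <- min(phase$pos[phase$chrom == ch])
      hi <- max(phase$pos[phase$chrom == ch]) - molecule_len_bp
      start[sel] <- as.integer(floor(runif(sum(sel), lo, hi)))
    }
    molecules <- data.frame(
      barcode = random_barcodes(n_molecules),
      chrom = mol_chrom, start = start,
      end = start + as.integer(molecule_len_bp) - 1L,
      haplotype = sample(1:2, n_molecules, replace = TRUE),
      subclone = sample(as.integer(names(occ)), n_molecules,
                        replace = TRUE, prob = occ),
      stringsAsFactors = FALSE
    )

    phase_by_chrom <- split(phase, phase$chrom)
    var_by_chrom <- split(v, v$chrom)
    lineage_sets <- lapply(setNames(nm = names(occ)), function(s)
      variants_in_lineage(arch, as.integer(s)))
    o_bar <- o_chrom <- o_allele <- o_type <- vector("list", n_molecules)
    o_pos <- vector("list", n_molecules)
    informative <- logical(n_molecules)
    for (m in seq_len(n_molecules)) {
      ph <- phase_by_chrom[[molecules$chrom[m]]]
      in_span <- ph$pos >= molecules$start[m] & ph$pos <= molecules$end[m]
      ph_pos <- ph$pos[in_span]
      informative[m] <- length(ph_pos) > 0
      het_allele <- character(0)
      if (length(ph_pos)) {
        on_hap <- molecules$haplotype[m] == 1L
        het_allele <- if (on_hap) ph$hap1[in_span] else ph$hap2[in_span]
        opposite <- if (on_hap) ph$hap2[in_span] else ph$hap1[in_span]
        flip <- runif(length(ph_pos)) < error_rate
        het_allele[flip] <- opposite[flip]
      }
      vv <- var_by_chrom[[molecules$chrom[m]]]
      vsel <- vv$pos >= molecules$start[m] & vv$pos <= molecules$end[m]
      vv_pos <- vv$pos[vsel]
      som_allele <- character(0)
      if (length(vv_pos)) {
        carried <- vv$variant_id[vsel] %in%
          lineage_sets[[as.character(molecules$subclone[m])]]
        is_alt <- carried & vv$haplotype[vsel] == molecules$haplotype[m]
        is_alt <- xor(is_alt, runif(length(vv_pos)) < error_rate)
        som_allele <- ifelse(is_alt, vv$alt[vsel], vv$ref[vsel])
      }
      n_obs <- length(ph_pos) + length(vv_pos)
      o_bar[[m]] <- rep(molecules$barcode[m], n_obs)
      o_chrom[[m]] <- rep(molecules$chrom[m], n_obs)
      o_pos[[m]] <- c(ph_pos, vv_pos)
      o_allele[[m]] <- c(het_allele, som_allele)
      o_type[[m]] <- c(rep("het", length(ph_pos)), rep("somatic", length(vv_pos)))
    }
    molecules$informative <- informative
    observations <- data.frame(
      barcode = unlist(o_bar), chrom = unlist(o_chrom),
      pos = unlist(o_pos), allele = unlist(o_allele),
      locus_type = unlist(o_type), stringsAsFactors = FALSE
    )

    list(observations = observations, phase = phase,
         molecules = molecules, variants = v)
  })
}
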