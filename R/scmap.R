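#' Per-cell allele observations for somatic SNVs from tagged alignments
#'
#' For every read whose alignment covers a somatic SNV position with an
#' aligned (non-gap, non-clipped) base and mapping quality at or above
#' `min_mapq`, emits one observation recording the cell barcode, UMI, and
#' which allele (ref / alt / other) the read carries at the site. Reads that
#' are unmapped, secondary, supplementary, duplicate-flagged, or lacking
#' either barcode tag are skipped and counted. This is the per-cell
#' ref/alt tracing step that links somatic mutations from bulk DNA
#' sequencing to individual cells of a droplet scRNA-seq library.
#'
#' @param alignments either a path to a BAM/SAM file or a data.frame of
#'   alignment records with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`, `cb`, `umi` (as produced by [gen_tagged_reads()]).
#' @param variants data.frame of somatic SNVs with `variant_id`, `chrom`,
#'   `pos` (1-based), `ref`, `alt`. Non-SNV rows (ref or alt not a single
#'   A/C/G/T base) are rejected at load with a message.
#' @param min_mapq minimum mapping quality.
#' @param cb_tag,umi_tag tag names holding the cell barcode and UMI when
#'   reading from a file.
#' @param barcode_whitelist optional character vector restricting cell
#'   barcodes.
#' @return data.frame with `variant_id`, `barcode`, `umi`, `allele`
#'   (`"ref"`/`"alt"`/`"other"`), `read_id`; attribute `skipped` counts
#'   excluded reads by reason.
#' @export
extract_observations <- function(alignments, variants, min_mapq = 10,
                                 cb_tag = "CB", umi_tag = "UB",
                                 barcode_whitelist = NULL) {
  variants <- load_snvs(variants)
  if (is.character(alignments) && length(alignments) == 1L) {
    recs <- read_tagged_alignments(alignments, variants, cb_tag, umi_tag)
  } else {
    recs <- as.data.frame(alignments, stringsAsFactors = FALSE)
  }

  skipped <- c(flag = 0L, no_tag = 0L, mapq = 0L, whitelist = 0L)
  bad_flag <- bitwAnd(recs$flag, 0x4 + 0x100 + 0x400 + 0x800) != 0L
  skipped["flag"] <- sum(bad_flag)
  recs <- recs[!bad_flag, , drop = FALSE]
  no_tag <- is.na(recs$cb) | is.na(recs$umi) | recs$cb == "" | recs$umi == ""
  skipped["no_tag"] <- sum(no_tag)
  recs <- recs[!no_tag, , drop = FALSE]
  low_q <- recs$mapq < min_mapq
  skipped["mapq"] <- sum(low_q)
  recs <- recs[!low_q, , drop = FALSE]
  if (!is.null(barcode_whitelist)) {
    off <- !(recs$cb %in% barcode_whitelist)
    skipped["whitelist"] <- sum(off)
    recs <- recs[!off, , drop = FALSE]
  }

  out <- vector("list", nrow(variants))
  for (vi in seq_len(nrow(variants))) {
    v <- variants[vi, ]
    cand <- recs[recs$rname == v$chrom & recs$pos <= v$pos, , drop = FALSE]
    if (nrow(cand) == 0) next
    base <- vapply(seq_len(nrow(cand)), function(r) {
      aligned_base_at(cand$pos[r], cand$cigar[r], cand$seq[r], v$pos)
    }, character(1))
    covered <- !is.na(base)
    if (!any(covered)) next
    cand <- cand[covered, , drop = FALSE]
    base <- toupper(base[covered])
    allele <- ifelse(base == toupper(v$ref), "ref",
                     ifelse(base == toupper(v$alt), "alt", "other"))
    out[[vi]] <- data.frame(
      variant_id = v$variant_id, barcode = cand$cb, umi = cand$umi,
      allele = allele, read_id = cand$qname, stringsAsFactors = FALSE
    )
  }
  obs <- do.call(rbind, out)
  if (is.null(obs)) {
    obs <- data.frame(variant_id = character(), barcode = character(),
                      umi = character(), allele = character(),
                      read_id = character(), stringsAsFactors = FALSE)
  }
  rownames(obs) <- NULL
  attr(obs, "skipped") <- skipped
  obs
}

# validate an SNV table; non-SNV rows rejected with a message
load_snvs <- function(variants) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (is.null(variants$variant_id)) {
    variants$variant_id <- paste(variants$chrom, variants$pos,
                                 variants$ref, variants$alt, sep = ":")
  }
  is_snv <- grepl("^[ACGTacgt]$", variants$ref) &
    grepl("^[ACGTacgt]$", variants$alt)
  if (any(!is_snv)) {
    message(sum(!is_snv), " non-SNV variant(s) rejected (single-base ref/alt required)")
    variants <- variants[is_snv, , drop = FALSE]
  }
  variants
}

# Walk a CIGAR string to find the query base aligned at reference position
# `target`; NA when the position falls in a deletion/skip or outside the
# alignment. Hand-rolled: M/=/X consume both, I/S query only, D/N ref only.
aligned_base_at <- function(aln_start, cigar, seq, target) {
  ops_len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  rpos <- aln_start
  qpos <- 1L
  for (k in seq_along(ops)) {
    len <- ops_len[k]
    op <- ops[k]
    if (op %in% c("M", "=", "X")) {
      if (target >= rpos && target < rpos + len) {
        return(substr(seq, qpos + (target - rpos), qpos + (target - rpos)))
      }
      rpos <- rpos + len
      qpos <- qpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      if (target >= rpos && target < rpos + len) return(NA_character_)
      rpos <- rpos + len
    }  # H, P consume nothing
  }
  NA_character_
}

# read records overlapping the variant loci from a BAM (or SAM, converted)
read_tagged_alignments <- function(path, variants, cb_tag, umi_tag) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path,
                             destination = tempfile(fileext = ""),
                             overwrite = TRUE, indexDestination = TRUE)
  } else if (!file.exists(paste0(path, ".bai"))) {
    Rsamtools::indexBam(path)
  }
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
  unknown <- setdiff(unique(variants$chrom), names(hdr))
  if (length(unknown)) {
    stop("variant chromosome(s) absent from alignment header: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  which <- GenomicRanges::GRanges(variants$chrom,
                                  IRanges::IRanges(variants$pos, variants$pos))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = c(cb_tag, umi_tag), which = which
  )
  chunks <- Rsamtools::scanBam(path, param = param)
  recs <- do.call(rbind, lapply(chunks, function(ch) {
    n <- length(ch$qname)
    if (n == 0) return(NULL)
    data.frame(qname = ch$qname, flag = ch$flag,
               rname = as.character(ch$rname), pos = ch$pos, mapq = ch$mapq,
               cigar = ch$cigar, seq = as.character(ch$seq),
               cb = ch$tag[[cb_tag]] %||% rep(NA_character_, n),
               umi = ch$tag[[umi_tag]] %||% rep(NA_character_, n),
               stringsAsFactors = FALSE)
  }))
  if (is.null(recs)) {
    recs <- data.frame(qname = character(), flag = integer(),
                       rname = character(), pos = integer(), mapq = integer(),
                       cigar = character(), seq = character(),
                       cb = character(), umi = character(),
                       stringsAsFactors = FALSE)
  }
  # a read can overlap several query ranges; observations are per read x variant
  unique(recs)
}

#' Collapse read-level allele observations to per-cell UMI counts
#'
#' Within each (cell, variant, UMI) group the consensus allele is the strict
#' majority of that UMI's reads; tied UMIs are discarded. Per (cell, variant)
#' the UMI counts by consensus allele define the cell's status:
#' `alt-detected` when at least one alt UMI is present, `ref-only` when there
#' are no alt UMIs but at least one ref UMI, `no-coverage` otherwise.
#'
#' @param observations output of [extract_observations()].
#' @return data.frame with `variant_id`, `barcode`, `ref_umis`, `alt_umis`,
#'   `other_umis`, `status`.
#' @export
collapse_umis <- function(observations) {
  if (nrow(observations) == 0) {
    return(data.frame(variant_id = character(), barcode = character(),
                      ref_umis = integer(), alt_umis = integer(),
                      other_umis = integer(), status = character(),
                      stringsAsFactors = FALSE))
  }
  umi_key <- paste(observations$variant_id, observations$barcode,
                   observations$umi, sep = "\r")
  consensus <- vapply(split(observations$allele, umi_key), function(a) {
    tab <- sort(table(a), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) NA_character_ else names(tab)[1]
  }, character(1))
  keys <- do.call(rbind, strsplit(names(consensus), "\r", fixed = TRUE))
  umis <- data.frame(variant_id = keys[, 1], barcode = keys[, 2],
                     allele = unname(consensus), stringsAsFactors = FALSE)
  umis <- umis[!is.na(umis$allele), , drop = FALSE]

  cell_key <- paste(umis$variant_id, umis$barcode, sep = "\r")
  counts <- lapply(split(umis$allele, cell_key), function(a) {
    c(ref = sum(a == "ref"), alt = sum(a == "alt"), other = sum(a == "other"))
  })
  keys <- do.call(rbind, strsplit(names(counts), "\r", fixed = TRUE))
  cm <- do.call(rbind, counts)
  status <- ifelse(cm[, "alt"] >= 1, "alt-detected",
                   ifelse(cm[, "ref"] >= 1, "ref-only", "no-coverage"))
  out <- data.frame(variant_id = keys[, 1], barcode = keys[, 2],
                    ref_umis = unname(cm[, "ref"]),
                    alt_umis = unname(cm[, "alt"]),
                    other_umis = unname(cm[, "other"]),
                    status = status, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$variant_id, out$barcode), , drop = FALSE]
}

#' Per-group single-cell VAF summary
#'
#' For each (variant, cell group) combination counts alt-detected and
#' ref-only cells and reports the single-cell VAF, defined at the cell level
#' as alt-detected / (alt-detected + ref-only). Groups with no covered cell
#' get `NA` (missing, distinct from zero). A UMI-level VAF (alt UMIs over
#' ref+alt UMIs pooled across the group's cells) is reported as a secondary
#' column.
#'
#' @param calls output of [collapse_umis()].
#' @param cell_annotations data.frame mapping `barcode` to `group` (e.g. cell
#'   type, sample, or their interaction).
#' @return data.frame per (variant_id, group): `n_alt_cells`,
#'   `n_refonly_cells`, `scvaf`, `umi_vaf`; attribute `n_unannotated` counts
#'   excluded barcodes.
#' @export
group_summary <- function(calls, cell_annotations) {
  stopifnot(all(c("barcode", "group") %in% names(cell_annotations)))
  grp <- cell_annotations$group[match(calls$barcode, cell_annotations$barcode)]
  n_unannotated <- sum(is.na(grp))
  calls <- calls[!is.na(grp), , drop = FALSE]
  grp <- grp[!is.na(grp)]

  grid <- expand.grid(variant_id = unique(calls$variant_id),
                      group = unique(cell_annotations$group),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- calls$variant_id == grid$variant_id[i] & grp == grid$group[i]
    x <- calls[sel, , drop = FALSE]
    n_alt <- sum(x$status == "alt-detected")
    n_ref <- sum(x$status == "ref-only")
    covered <- n_alt + n_ref
    data.frame(
      variant_id = grid$variant_id[i], group = grid$group[i],
      n_alt_cells = n_alt, n_refonly_cells = n_ref,
      scvaf = if (covered > 0) n_alt / covered else NA_real_,
      umi_vaf = if (sum(x$ref_umis + x$alt_umis) > 0)
        sum(x$alt_umis) / sum(x$ref_umis + x$alt_umis) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out <- out[order(out$variant_id, out$group), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unannotated") <- n_unannotated
  out
}

#' Within-cell co-occurrence of somatic mutation pairs
#'
#' For every unordered variant pair, restricted to cells with UMI coverage of
#' both variants, counts cells where both are alt-detected, one only, or
#' neither. Mutations detected together in the same cells support a shared
#' lineage; disjoint detection suggests distinct subclones.
#'
#' @param calls output of [collapse_umis()].
#' @return data.frame per pair: `variant_a`, `variant_b`, `both_alt`,
#'   `a_only`, `b_only`, `neither`, `n_cells_covered_both`; zero rows when
#'   fewer than two variants are present.
#' @export
cooccurrence <- function(calls) {
  vars <- sort(unique(calls$variant_id))
  empty <- data.frame(variant_a = character(), variant_b = character(),
                      both_alt = integer(), a_only = integer(),
                      b_only = integer(), neither = integer(),
                      n_cells_covered_both = integer(), stringsAsFactors = FALSE)
  if (length(vars) < 2) return(empty)
  covered <- calls[calls$status != "no-coverage", , drop = FALSE]
  pairs <- combn(vars, 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    ca <- covered[covered$variant_id == a, , drop = FALSE]
    cb <- covered[covered$variant_id == b, , drop = FALSE]
    common <- intersect(ca$barcode, cb$barcode)
    alt_a <- ca$barcode[ca$status == "alt-detected"]
    alt_b <- cb$barcode[cb$status == "alt-detected"]
    both <- sum(common %in% alt_a & common %in% alt_b)
    a_only <- sum(common %in% alt_a & !(common %in% alt_b))
    b_only <- sum(!(common %in% alt_a) & common %in% alt_b)
    data.frame(variant_a = a, variant_b = b, both_alt = both,
               a_only = a_only, b_only = b_only,
               neither = length(common) - both - a_only - b_only,
               n_cells_covered_both = length(common), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
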