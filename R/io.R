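# Plain-format readers/writers for the pipeline's external interfaces.

#' Write a somatic SNV list as minimal VCF v4.2
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` and optional
#'   `variant_id`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_vcf <- function(variants, path) {
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=VID,Number=1,Type=String,Description=\"Variant id\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  id <- variants$variant_id %||% rep(".", nrow(variants))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tVID=%s",
                  variants$chrom, variants$pos, id, variants$ref,
                  variants$alt, id)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read somatic SNVs from a VCF file
#'
#' Thin wrapper over `vcfR`; returns the (chrom, pos, ref, alt) table the
#' mapping functions consume. Multi-allelic records are split into one row
#' per alternate allele.
#'
#' @param path VCF path.
#' @return data.frame with `variant_id`, `chrom`, `pos`, `ref`, `alt`.
#' @export
read_snv_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
               ref = toupper(fix$REF[i]), alt = toupper(alts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$variant_id <- ifelse(is.na(fix$ID[match(paste(out$chrom, out$pos),
                                              paste(fix$CHROM, fix$POS))]),
                           paste(out$chrom, out$pos, out$ref, out$alt, sep = ":"),
                           fix$ID[match(paste(out$chrom, out$pos),
                                        paste(fix$CHROM, fix$POS))])
  out[, c("variant_id", "chrom", "pos", "ref", "alt")]
}

#' Read pathway gene sets from a GMT file
#'
#' @param path GMT path (one pathway per line: name, description, genes).
#' @return named list of gene vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    stop("reading GMT requires the 'fgsea' package", call. = FALSE)
  }
  fgsea::gmtPathways(path)
}

#' Write pathway gene sets to a GMT file
#'
#' @param pathway_sets named list of gene vectors.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_gmt <- function(pathway_sets, path) {
  lines <- vapply(names(pathway_sets), function(pw) {
    paste(c(pw, "na", pathway_sets[[pw]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a count matrix as MatrixMarket + gene/barcode sidecars
#'
#' @param counts genes x cells matrix.
#' @param dir output directory (created if absent); writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`.
#' @return `dir` invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a count matrix written by [write_counts_mtx()]
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return genes x cells dense matrix.
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  m
}
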