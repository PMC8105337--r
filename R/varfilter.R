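#' Merge per-caller somatic call sets by 2-of-3 consensus
#'
#' SNVs are retained when reported by at least two callers of the SNV trio
#' (conventionally Mutect, VarScan, Strelka) and indels when reported by at
#' least two of the indel trio (VarScan, Strelka, Pindel). Variants are keyed
#' by (chrom, pos, ref, alt) with alleles upper-cased; a retained record
#' carries the union of supporting caller ids and, across callers, the
#' maximum of each depth and VAF field.
#'
#' @param call_sets named list (caller id -> data.frame) of calls with columns
#'   `chrom`, `pos`, `ref`, `alt`, `class` ("SNV"/"INDEL"), `tumor_depth`,
#'   `normal_depth`, `tumor_vaf`, `normal_vaf`.
#' @param snv_trio,indel_trio caller-id triplets defining the two consensus
#'   votes.
#' @return data.frame of retained calls with a `callers` column
#'   (comma-separated supporting ids) and an `n_callers` count.
#' @export
consensus_merge <- function(call_sets,
                            snv_trio = c("mutect", "varscan", "strelka"),
                            indel_trio = c("varscan", "strelka", "pindel")) {
  stopifnot(is.list(call_sets), !is.null(names(call_sets)))
  known <- union(snv_trio, indel_trio)
  bad <- setdiff(names(call_sets), known)
  if (length(bad)) {
    stop("unknown caller id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  all_calls <- do.call(rbind, lapply(names(call_sets), function(id) {
    x <- call_sets[[id]]
    if (nrow(x) == 0) return(NULL)
    x$caller <- id
    x$ref <- toupper(x$ref)
    x$alt <- toupper(x$alt)
    x
  }))
  if (is.null(all_calls) || nrow(all_calls) == 0) {
    return(empty_merge_result())
  }
  # one position, two ref alleles across callers is inconsistent input
  by_pos <- split(all_calls$ref, paste(all_calls$chrom, all_calls$pos))
  if (any(vapply(by_pos, function(r) length(unique(r)) > 1, logical(1)))) {
    stop("conflicting ref alleles reported at the same position", call. = FALSE)
  }
  key <- paste(all_calls$chrom, all_calls$pos, all_calls$ref, all_calls$alt,
               sep = ":")
  merged <- lapply(split(all_calls, key), function(g) {
    cls <- unique(g$class)
    if (length(cls) != 1) {
      stop("same variant key labeled both SNV and INDEL", call. = FALSE)
    }
    trio <- if (cls == "SNV") snv_trio else indel_trio
    voters <- intersect(unique(g$caller), trio)
    if (length(voters) < 2) return(NULL)
    data.frame(
      chrom = g$chrom[1], pos = g$pos[1], ref = g$ref[1], alt = g$alt[1],
      class = cls,
      tumor_depth = max(g$tumor_depth), normal_depth = max(g$normal_depth),
      tumor_vaf = max(g$tumor_vaf), normal_vaf = max(g$normal_vaf),
      callers = paste(sort(unique(g$caller)), collapse = ","),
      n_callers = length(unique(g$caller)),
      stringsAsFactors = FALSE
    )
  })
  merged <- do.call(rbind, merged)
  if (is.null(merged)) return(empty_merge_result())
  merged <- merged[order(merged$chrom, merged$pos), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

empty_merge_result <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), class = character(), tumor_depth = numeric(),
             normal_depth = numeric(), tumor_vaf = numeric(),
             normal_vaf = numeric(), callers = character(),
             n_callers = integer(), stringsAsFactors = FALSE)
}

#' Coverage and VAF filter for merged somatic calls
#'
#' Retains a call iff tumor depth >= 14, normal depth >= 8, tumor VAF >= 0.05
#' and normal VAF <= 0.02 (all boundaries inclusive at the stated value).
#' Records with a missing required field are rejected; their keys and reasons
#' are attached as the `"rejected"` attribute.
#'
#' @param calls data.frame with `tumor_depth`, `normal_depth`, `tumor_vaf`,
#'   `normal_vaf`.
#' @param min_tumor_depth,min_normal_depth,min_tumor_vaf,max_normal_vaf the
#'   four cutoffs.
#' @return the retained subset, with attribute `rejected` describing records
#'   dropped for missing fields.
#' @export
somatic_filter <- function(calls, min_tumor_depth = 14, min_normal_depth = 8,
                           min_tumor_vaf = 0.05, max_normal_vaf = 0.02) {
  req <- c("tumor_depth", "normal_depth", "tumor_vaf", "normal_vaf")
  missing_cols <- setdiff(req, names(calls))
  if (length(missing_cols)) {
    stop("calls lack required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  incomplete <- !complete.cases(calls[, req, drop = FALSE])
  rejected <- if (any(incomplete)) {
    data.frame(row = which(incomplete), reason = "missing field",
               stringsAsFactors = FALSE)
  } else {
    data.frame(row = integer(), reason = character(), stringsAsFactors = FALSE)
  }
  x <- calls[!incomplete, , drop = FALSE]
  keep <- x$tumor_depth >= min_tumor_depth &
    x$normal_depth >= min_normal_depth &
    x$tumor_vaf >= min_tumor_vaf &
    x$normal_vaf <= max_normal_vaf
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Score filter for somatic structural variants
#'
#' Removes events with somatic score < 30 or junction somatic score < 30.
#'
#' @param svs data.frame with `somatic_score` and `junction_score` columns.
#' @param min_score minimum score applied to both columns.
#' @return the retained subset.
#' @export
sv_filter <- function(svs, min_score = 30) {
  stopifnot(all(c("somatic_score", "junction_score") %in% names(svs)))
  if (any(svs$somatic_score < 0 | svs$junction_score < 0, na.rm = TRUE)) {
    stop("SV scores must be >= 0", call. = FALSE)
  }
  out <- svs[svs$somatic_score >= min_score & svs$junction_score >= min_score, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample-identity check from germline VAFs at a fixed locus panel
#'
#' Longitudinal samples from one patient share germline variant allele
#' fractions; samples from different individuals do not. For every sample
#' pair, computes the Pearson correlation of germline VAFs over the loci
#' covered (non-missing) in both, and flags the pair as same-patient when
#' `r >= r_thresh`. Pairs sharing fewer than `min_shared` loci are left
#' unresolved (`NA`).
#'
#' @param vaf_table numeric matrix, samples x loci, `NA` for uncovered loci.
#' @param min_shared minimum shared covered loci for a defined comparison.
#' @param r_thresh correlation threshold for the same-patient call.
#' @return list with `r` (correlation matrix, unit diagonal), `n_shared`
#'   (shared-locus counts) and `same_patient` (logical matrix, `NA` =
#'   unresolved).
#' @export
identity_check <- function(vaf_table, min_shared = 5, r_thresh = 0.8) {
  vaf_table <- as.matrix(vaf_table)
  n <- nrow(vaf_table)
  ids <- rownames(vaf_table) %||% paste0("sample", seq_len(n))
  r <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  n_shared <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(r) <- 1
  diag(n_shared) <- rowSums(!is.na(vaf_table))
  if (n < 2) {
    return(list(r = r[0, 0, drop = FALSE], n_shared = n_shared,
                same_patient = r[0, 0, drop = FALSE]))
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(vaf_table[i, ]) & !is.na(vaf_table[j, ])
      n_shared[i, j] <- n_shared[j, i] <- sum(ok)
      if (sum(ok) >= min_shared) {
        r[i, j] <- r[j, i] <-
          suppressWarnings(cor(vaf_table[i, ok], vaf_table[j, ok]))
      }
    }
  }
  same <- r >= r_thresh
  diag(same) <- TRUE
  list(r = r, n_shared = n_shared, same_patient = same)
}
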