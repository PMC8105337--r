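#' Simulate a clonal architecture for a longitudinal tumor
#'
#' Generates a subclone tree with per-timepoint cancer-cell fractions (CCF),
#' somatic SNVs assigned to subclones and germline haplotypes, and
#' per-chromosome relative copy ratios. This object is the shared ground truth
#' that every other generator in the package consumes, emulating the
#' multi-timepoint subclonal structure of a myeloma patient (smoldering stage,
#' primary, relapse).
#'
#' The tree respects the lineage constraint that a descendant subclone can
#' never exceed its parent's CCF at any timepoint; in addition the summed CCF
#' of the children of any node never exceeds the parent's CCF, so that the
#' exclusive occupancy of each node (cells belonging to that subclone and to
#' no descendant) is well defined and non-negative.
#'
#' @param n_subclones number of subclones (>= 1); subclone 1 is the truncal
#'   clone with CCF 1 at every timepoint.
#' @param n_timepoints number of longitudinal samples.
#' @param n_variants number of somatic SNVs (>= `n_subclones`; every subclone
#'   receives at least one variant).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @param chromosomes chromosome names used for variant placement and copy
#'   ratios.
#' @param purity tumor purity per timepoint in (0, 1]; recycled to
#'   `n_timepoints`.
#' @param cnv_prob probability that a non-truncal subclone acquires a
#'   chromosome-level copy-ratio change (set to 0.5 or 1.5) on one chromosome.
#'
#' @return an object of class `clonal_architecture`: a list with `subclones`
#'   (data.frame id/parent), `ccf` (subclones x timepoints matrix),
#'   `copy_ratio` (subclones x chromosomes matrix, neutral = 1; row "0" is the
#'   normal-cell profile), `variants` (data.frame chrom, pos, ref, alt,
#'   subclone, haplotype), and `purity`.
#' @export
gen_architecture <- function(n_subclones, n_timepoints, n_variants, seed,
                             chromosomes = c("chr1", "chr13", "chr14"),
                             purity = 1, cnv_prob = 0.7) {
  stopifnot(n_subclones >= 1, n_timepoints >= 1)
  if (n_variants < n_subclones) {
    stop("`n_variants` must be >= `n_subclones` so every subclone carries a variant",
         call. = FALSE)
  }
  purity <- rep_len(purity, n_timepoints)
  if (any(purity <= 0 | purity > 1)) stop("`purity` must lie in (0, 1]", call. = FALSE)

  with_seed(seed, {
    parent <- c(NA_integer_,
                if (n_subclones > 1)
                  vapply(2:n_subclones,
                         function(i) sample.int(i - 1L, 1L), integer(1)))

    # available[i, t]: CCF of node i not yet claimed by its children
    ccf <- matrix(0, n_subclones, n_timepoints,
                  dimnames = list(subclone = seq_len(n_subclones),
                                  timepoint = seq_len(n_timepoints)))
    ccf[1, ] <- 1
    avail <- ccf
    if (n_subclones > 1) {
      for (i in 2:n_subclones) {
        p <- parent[i]
        frac <- runif(n_timepoints, 0.15, 0.85)
        ccf[i, ] <- avail[p, ] * frac
        avail[p, ] <- avail[p, ] - ccf[i, ]
        avail[i, ] <- ccf[i, ]
      }
    }

    # copy ratios: truncal clone neutral, children inherit then may alter one chrom
    nc <- length(chromosomes)
    copy_ratio <- matrix(1, n_subclones + 1L, nc,
                         dimnames = list(subclone = c("0", seq_len(n_subclones)),
                                         chrom = chromosomes))
    if (n_subclones > 1) {
      for (i in 2:n_subclones) {
        copy_ratio[i + 1L, ] <- copy_ratio[parent[i] + 1L, ]
        if (runif(1) < cnv_prob) {
          copy_ratio[i + 1L, sample.int(nc, 1L)] <- sample(c(0.5, 1.5), 1L)
        }
      }
    }

    # variants: each subclone gets >= 1, remainder assigned at random
    assignment <- c(seq_len(n_subclones),
                    if (n_variants > n_subclones)
                      sample.int(n_subclones, n_variants - n_subclones, replace = TRUE))
    assignment <- sample(assignment)  # shuffle so ids are not ordered by clone
    chrom <- sample(chromosomes, n_variants, replace = TRUE)
    pos <- integer(n_variants)
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      pos[sel] <- sort(sample.int(2e8 - 1e6, sum(sel))) + 1e6
    }
    ref <- sample(c("A", "C", "G", "T"), n_variants, replace = TRUE)
    alt <- other_base(ref)
    variants <- data.frame(
      variant_id = sprintf("v%03d", seq_len(n_variants)),
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      subclone = assignment,
      haplotype = sample(1:2, n_variants, replace = TRUE),
      stringsAsFactors = FALSE
    )

    structure(
      list(
        subclones = data.frame(id = seq_len(n_subclones), parent = parent),
        ccf = ccf,
        copy_ratio = copy_ratio,
        variants = variants,
        purity = purity,
        chromosomes = chromosomes
      ),
      class = "clonal_architecture"
    )
  })
}

#' @export
print.clonal_architecture <- function(x, ...) {
  cat(sprintf("Clonal architecture: %d subclones, %d timepoints, %d variants\n",
              nrow(x$subclones), ncol(x$ccf), nrow(x$variants)))
  cat("CCF matrix:\n")
  print(round(x$ccf, 3))
  invisible(x)
}

#' Validate the invariants of a clonal architecture
#'
#' Checks the lineage CCF constraint (child <= parent at every timepoint),
#' variant assignment (exactly one subclone and one haplotype each, positions
#' unique per chromosome), and positive copy ratios. Used by the generators
#' and exposed for property testing.
#'
#' @param arch a `clonal_architecture`.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_architecture <- function(arch) {
  stopifnot(inherits(arch, "clonal_architecture"))
  par <- arch$subclones$parent
  for (i in seq_along(par)) {
    if (!is.na(par[i]) && any(arch$ccf[i, ] > arch$ccf[par[i], ] + 1e-12)) {
      stop(sprintf("subclone %d exceeds parent CCF", i), call. = FALSE)
    }
  }
  v <- arch$variants
  if (anyNA(v$subclone) || !all(v$subclone %in% arch$subclones$id)) {
    stop("variant assigned to unknown subclone", call. = FALSE)
  }
  if (!all(v$haplotype %in% 1:2)) stop("haplotype must be 1 or 2", call. = FALSE)
  if (any(duplicated(v[, c("chrom", "pos")]))) {
    stop("variant positions must be unique per chromosome", call. = FALSE)
  }
  if (any(arch$copy_ratio <= 0)) stop("copy ratios must be > 0", call. = FALSE)
  if (any(v$ref == v$alt)) stop("ref and alt must differ", call. = FALSE)
  invisible(TRUE)
}

# ids on the root-to-node path (inclusive); subclone 0 (normal) has empty lineage
lineage_of <- function(arch, subclone) {
  if (subclone == 0L) return(integer(0))
  path <- integer(0)
  i <- subclone
  while (!is.na(i)) {
    path <- c(i, path)
    i <- arch$subclones$parent[i]
  }
  path
}

# variant ids carried by cells of `subclone` (all variants on its lineage)
variants_in_lineage <- function(arch, subclone) {
  arch$variants$variant_id[arch$variants$subclone %in% lineage_of(arch, subclone)]
}

# exclusive occupancy per node at a timepoint: ccf minus summed child ccf,
# scaled by purity, with the normal compartment as label 0
subclone_occupancy <- function(arch, timepoint) {
  n <- nrow(arch$subclones)
  if (timepoint < 1 || timepoint > ncol(arch$ccf)) {
    stop(sprintf("timepoint %s outside architecture (1..%d)",
                 timepoint, ncol(arch$ccf)), call. = FALSE)
  }
  occ <- arch$ccf[, timepoint]
  for (i in seq_len(n)) {
    kids <- which(arch$subclones$parent == i)
    if (length(kids)) occ[i] <- occ[i] - sum(arch$ccf[kids, timepoint])
  }
  occ <- pmax(occ, 0)
  pur <- arch$purity[timepoint]
  c("0" = 1 - pur, setNames(occ * pur / sum(occ), seq_len(n)))
}
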