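#' Reconstruct barcoded DNA molecules from allele observations
#'
#' Observations sharing a droplet barcode on one chromosome are grouped into
#' a molecule as long as consecutive observed positions are at most
#' `max_gap_bp` apart; larger gaps split the barcode into separate molecules
#' (distant reuse of one barcode cannot come from a single DNA fragment).
#' The consensus allele at each locus is the strict majority of that
#' molecule's observations there; ties drop the locus.
#'
#' @param observations data.frame with `barcode`, `chrom`, `pos`, `allele`.
#' @param max_gap_bp maximum within-molecule gap between consecutive observed
#'   positions.
#' @return list with `molecules` (molecule_id, barcode, chrom, start, end,
#'   n_loci) and `alleles` (molecule_id, pos, allele consensus per locus).
#' @export
build_molecules <- function(observations, max_gap_bp = 50000) {
  stopifnot(all(c("barcode", "chrom", "pos", "allele") %in% names(observations)))
  if (nrow(observations) == 0) {
    return(list(
      molecules = data.frame(molecule_id = character(), barcode = character(),
                             chrom = character(), start = integer(),
                             end = integer(), n_loci = integer(),
                             stringsAsFactors = FALSE),
      alleles = data.frame(molecule_id = character(), pos = integer(),
                           allele = character(), stringsAsFactors = FALSE)
    ))
  }
  obs <- observations[order(observations$barcode, observations$chrom,
                            observations$pos), , drop = FALSE]
  key <- paste(obs$barcode, obs$chrom, sep = "\r")
  mol_rows <- list()
  allele_rows <- list()
  mid <- 0L
  for (g in split(seq_len(nrow(obs)), key)) {
    pos <- obs$pos[g]
    brk <- c(0L, cumsum(diff(pos) > max_gap_bp))
    for (piece in split(g, brk)) {
      mid <- mid + 1L
      id <- sprintf("mol%06d", mid)
      p <- obs$pos[piece]
      cons <- vapply(split(obs$allele[piece], p), function(a) {
        tab <- sort(table(a), decreasing = TRUE)
        if (length(tab) > 1 && tab[1] == tab[2]) NA_character_ else names(tab)[1]
      }, character(1))
      keep <- !is.na(cons)
      mol_rows[[mid]] <- data.frame(
        molecule_id = id, barcode = obs$barcode[piece[1]],
        chrom = obs$chrom[piece[1]],
        start = min(p), end = max(p), n_loci = sum(keep),
        stringsAsFactors = FALSE
      )
      if (any(keep)) {
        allele_rows[[length(allele_rows) + 1L]] <- data.frame(
          molecule_id = id,
          pos = as.integer(names(cons)[keep]),
          allele = unname(cons[keep]), stringsAsFactors = FALSE
        )
      }
    }
  }
  molecules <- do.call(rbind, mol_rows)
  alleles <- if (length(allele_rows)) do.call(rbind, allele_rows) else
    data.frame(molecule_id = character(), pos = integer(),
               allele = character(), stringsAsFactors = FALSE)
  rownames(molecules) <- rownames(alleles) <- NULL
  list(molecules = molecules, alleles = alleles)
}

#' Assign a somatic variant to a germline haplotype by linked-read voting
#'
#' Every molecule carrying the somatic alternate allele votes for the
#' haplotype matching the majority of the phased germline hets it covers
#' (molecules tied across the two haplotypes, or covering no het, abstain).
#' The aggregate assignment is the majority haplotype provided the vote
#' count reaches `min_votes` and the winning fraction reaches
#' `purity_thresh`; otherwise the variant is reported ambiguous.
#'
#' @param molecules a [build_molecules()] result.
#' @param phased_block data.frame of phased hets with `pos`, `hap1`, `hap2`
#'   (the two alleles differ at every het).
#' @param somatic_variant one-row data.frame (or list) with `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param min_votes minimum number of informative alt-molecule votes.
#' @param purity_thresh minimum winning vote fraction.
#' @return list with `haplotype` (`1`, `2`, or `"ambiguous"`), `votes`
#'   (named count vector for haplotypes 1 and 2), and `n_alt_molecules`.
#' @export
assign_haplotype <- function(molecules, phased_block, somatic_variant,
                             min_votes = 2, purity_thresh = 0.8) {
  stopifnot(all(phased_block$hap1 != phased_block$hap2))
  al <- molecules$alleles
  alt_mols <- al$molecule_id[al$pos == somatic_variant$pos &
                               al$allele == somatic_variant$alt]
  votes <- c(`1` = 0L, `2` = 0L)
  for (m in alt_mols) {
    ma <- al[al$molecule_id == m & al$pos %in% phased_block$pos, , drop = FALSE]
    if (nrow(ma) == 0) next
    ph <- phased_block[match(ma$pos, phased_block$pos), , drop = FALSE]
    n1 <- sum(ma$allele == ph$hap1)
    n2 <- sum(ma$allele == ph$hap2)
    if (n1 > n2) votes["1"] <- votes["1"] + 1L
    else if (n2 > n1) votes["2"] <- votes["2"] + 1L
    # tied molecule abstains
  }
  total <- sum(votes)
  hap <- "ambiguous"
  if (total >= min_votes) {
    win <- which.max(votes)
    if (votes[win] / total >= purity_thresh && votes[1] != votes[2]) {
      hap <- names(votes)[win]
    }
  }
  list(haplotype = hap, votes = votes, n_alt_molecules = length(alt_mols))
}

#' Classify a somatic mutation pair as cis or independent subclones
#'
#' Considers only molecules whose consensus alleles cover both variant
#' positions. If at least `min_cis` molecules carry both alternate alleles
#' the pair is classified `cis` (same DNA molecule, hence same lineage).
#' Otherwise, if each variant's alternate allele is observed among the
#' both-covering molecules and their number reaches `min_cover`, the pair is
#' `independent` (two mutations that never co-occur on a shared molecule
#' despite joint coverage arose in distinct subclones, even when both sit on
#' the same germline haplotype). Anything else is `unresolved`.
#'
#' @param molecules a [build_molecules()] result.
#' @param var_a,var_b one-row data.frames (or lists) with `chrom`, `pos`,
#'   `ref`, `alt`; both on one chromosome.
#' @param min_cover minimum number of both-covering molecules needed to call
#'   `independent`.
#' @param min_cis minimum number of both-alt molecules needed to call `cis`.
#' @return list with `relationship` (`"cis"`, `"independent"`,
#'   `"unresolved"`) and `counts` (named vector: both_alt, a_only, b_only,
#'   neither, n_covering).
#' @export
classify_pair <- function(molecules, var_a, var_b, min_cover = 3, min_cis = 1) {
  if (!identical(var_a$chrom, var_b$chrom)) {
    stop("both variants must lie on one chromosome", call. = FALSE)
  }
  al <- molecules$alleles
  a_obs <- al[al$pos == var_a$pos, , drop = FALSE]
  b_obs <- al[al$pos == var_b$pos, , drop = FALSE]
  both_ids <- intersect(a_obs$molecule_id, b_obs$molecule_id)
  a_alt <- a_obs$molecule_id[a_obs$allele == var_a$alt]
  b_alt <- b_obs$molecule_id[b_obs$allele == var_b$alt]
  both_alt <- sum(both_ids %in% a_alt & both_ids %in% b_alt)
  a_only <- sum(both_ids %in% a_alt & !(both_ids %in% b_alt))
  b_only <- sum(!(both_ids %in% a_alt) & both_ids %in% b_alt)
  counts <- c(both_alt = both_alt, a_only = a_only, b_only = b_only,
              neither = length(both_ids) - both_alt - a_only - b_only,
              n_covering = length(both_ids))
  relationship <- if (both_alt >= min_cis) {
    "cis"
  } else if (a_only >= 1 && b_only >= 1 && length(both_ids) >= min_cover) {
    "independent"
  } else {
    "unresolved"
  }
  list(relationship = relationship, counts = counts)
}
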