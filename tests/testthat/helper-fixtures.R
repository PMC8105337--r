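# Shared fixture builders. All fixtures are generated in code at test time.

# small three-subclone architecture with guaranteed-distinct chromosome events
fixture_arch <- function(seed = 1, n_timepoints = 2, n_variants = 10) {
  gen_architecture(3, n_timepoints, n_variants, seed = seed, cnv_prob = 1)
}

# hand-built SAM fixture: 20 reads over 2 SNVs with known expected
# observations (see test-scmap.R for the by-hand enumeration)
fixture_sam_records <- function() {
  v <- data.frame(variant_id = c("vA", "vB"), chrom = c("chr1", "chr1"),
                  pos = c(150L, 400L), ref = c("A", "C"), alt = c("T", "G"),
                  stringsAsFactors = FALSE)
  mk <- function(qname, flag, pos, mapq, cigar, seq, cb, umi) {
    data.frame(qname = qname, flag = flag, rname = "chr1", pos = pos,
               mapq = mapq, cigar = cigar, seq = seq, cb = cb, umi = umi,
               stringsAsFactors = FALSE)
  }
  base100 <- function(at, base) {
    s <- rep("G", 100); s[at] <- base; paste(s, collapse = "")
  }
  recs <- rbind(
    # reads 1-6: plain 100M over vA at 150
    mk("r01", 0L, 101L, 60L, "100M", base100(50, "A"), "CELL1", "U01"),  # ref
    mk("r02", 0L, 101L, 60L, "100M", base100(50, "T"), "CELL1", "U02"),  # alt
    mk("r03", 0L, 120L, 60L, "100M", base100(31, "T"), "CELL2", "U03"),  # alt
    mk("r04", 0L, 150L, 60L, "100M", base100(1, "C"), "CELL2", "U04"),   # other
    mk("r05", 0L, 101L, 60L, "100M", base100(50, "A"), "CELL3", "U05"),  # ref
    mk("r06", 0L, 140L, 60L, "100M", base100(11, "T"), "CELL3", "U06"),  # alt
    # r07: deletion spans vA: 40M at 111-150 would hit 150 at 40th.. use
    # 30M10D60M starting 115: matches 115-144, deletes 145-154 (covers 150)
    mk("r07", 0L, 115L, 60L, "30M10D60M", paste(rep("A", 90), collapse = ""),
       "CELL1", "U07"),
    # r08: soft-clip leading; 10S90M from 120 covers 120-209; base at 150 is
    # query index 10 + (150-120) + 1 = 41
    mk("r08", 0L, 120L, 60L, "10S90M",
       paste(c(rep("N", 10), rep("G", 30), "T", rep("G", 59)), collapse = ""),
       "CELL2", "U08"),
    # r09: insertion before locus; 20M5I75M from 131: ref 131-150 (20M),
    # insertion, then 151.. ; 150 is the 20th match -> query 20
    mk("r09", 0L, 131L, 60L, "20M5I75M",
       paste(c(rep("G", 19), "A", rep("G", 80)), collapse = ""),
       "CELL3", "U09"),
    # r10: ends just before vA (no coverage)
    mk("r10", 0L, 50L, 60L, "100M", base100(1, "G"), "CELL1", "U10"),
    # r11: low mapq -> skipped
    mk("r11", 0L, 101L, 5L, "100M", base100(50, "T"), "CELL1", "U11"),
    # r12: duplicate flag -> skipped
    mk("r12", 1024L, 101L, 60L, "100M", base100(50, "T"), "CELL2", "U12"),
    # r13: missing cell barcode -> skipped
    mk("r13", 0L, 101L, 60L, "100M", base100(50, "T"), NA_character_, "U13"),
    # reads 14-18 over vB at 400
    mk("r14", 0L, 351L, 60L, "100M", base100(50, "C"), "CELL1", "U14"),  # ref
    mk("r15", 0L, 351L, 60L, "100M", base100(50, "G"), "CELL2", "U15"),  # alt
    mk("r16", 0L, 400L, 60L, "100M", base100(1, "G"), "CELL2", "U16"),   # alt
    mk("r17", 0L, 390L, 60L, "100M", base100(11, "C"), "CELL3", "U17"),  # ref
    # r18: skip (N) spans vB: 30M20N70M from 360: matches 360-389,
    # skips 390-409 (covers 400)
    mk("r18", 0L, 360L, 60L, "30M20N70M", base100(1, "G"), "CELL3", "U18"),
    # r19: covers both vA (at 150) and vB? span 101-200 only vA; make a long
    # skip read covering both: 50M200N50M from 101: matches 101-150 (vA at
    # query 50), skips 151-350, matches 351-400 (vB at query 100)
    mk("r19", 0L, 101L, 60L, "50M200N50M",
       paste(c(rep("G", 49), "T", rep("G", 49), "G"), collapse = ""),
       "CELL1", "U19"),
    # r20: secondary alignment -> skipped
    mk("r20", 256L, 101L, 60L, "100M", base100(50, "T"), "CELL3", "U20")
  )
  list(records = recs, variants = v,
       header = c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:100000"))
}

# the by-hand CIGAR-walk enumeration for the fixture above
fixture_sam_expected <- function() {
  data.frame(
    variant_id = c("vA", "vA", "vA", "vA", "vA", "vA", "vA", "vA", "vA",
                   "vB", "vB", "vB", "vB", "vB"),
    barcode = c("CELL1", "CELL1", "CELL2", "CELL2", "CELL3", "CELL3",
                "CELL2", "CELL3", "CELL1",
                "CELL1", "CELL2", "CELL2", "CELL3", "CELL1"),
    umi = c("U01", "U02", "U03", "U04", "U05", "U06", "U08", "U09", "U19",
            "U14", "U15", "U16", "U17", "U19"),
    allele = c("ref", "alt", "alt", "other", "ref", "alt", "alt", "ref",
               "alt", "ref", "alt", "alt", "ref", "alt"),
    read_id = c("r01", "r02", "r03", "r04", "r05", "r06", "r08", "r09",
                "r19", "r14", "r15", "r16", "r17", "r19"),
    stringsAsFactors = FALSE
  )
}

sort_obs <- function(x) {
  x <- x[order(x$variant_id, x$read_id), c("variant_id", "barcode", "umi",
                                           "allele", "read_id")]
  rownames(x) <- NULL
  x
}

# two-timepoint tracking scenario: clusters A, B, C at t1; A, B, D at t2.
# Program blocks make centroids cluster-specific; CNV category profiles are
# fully distinct across clusters, identical within a cluster across time.
fixture_tracking_scenario <- function(seed) {
  spec <- data.frame(
    cluster = c("A1", "B1", "C1", "A2", "B2", "D2"),
    fraction = c(1, 1, 1, 1, 1, 1),
    sample = rep(c("t1", "t2"), each = 3),
    timepoint = rep(1:2, each = 3),
    cell_type = "Plasma",
    stringsAsFactors = FALSE
  )
  programs <- list(
    list(name = "progB", genes = 1:40, clusters = c("B1", "B2"), fold = 4),
    list(name = "progC", genes = 41:80, clusters = "C1", fold = 4),
    list(name = "progD", genes = 81:120, clusters = "D2", fold = 4)
  )
  ex <- gen_expression(spec, n_cells = 360, n_genes = 300,
                       planted_programs = programs, seed = seed)
  nm <- normalize_log(ex$counts)
  cnv_levels_of <- list(A = rep("neutral", 4), B = rep("loss", 4),
                        C = rep("gain", 4), D = rep("amplification", 4))
  panel <- rownames(nm)[1:120]
  profs <- lapply(c("A1", "B1", "C1", "A2", "B2", "D2"), function(cl) {
    cells <- ex$cells$cell[ex$cells$cluster == cl]
    subpopulation_profile(
      id = cl, sample = unique(ex$cells$sample[ex$cells$cluster == cl]),
      n_cells = length(cells),
      centroid = rowMeans(nm[panel, cells, drop = FALSE]),
      cnv_profile = setNames(cnv_levels_of[[substr(cl, 1, 1)]],
                             paste0("chr", c(1, 13, 14, 17)))
    )
  })
  names(profs) <- c("A1", "B1", "C1", "A2", "B2", "D2")
  list(expression = ex, norm = nm,
       t1 = profs[c("A1", "B1", "C1")], t2 = profs[c("A2", "B2", "D2")])
}
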