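#' Construct a subpopulation profile
#'
#' A subpopulation's fingerprint used for cross-timepoint matching: its
#' expression centroid over a shared variable-gene panel and its
#' per-chromosome copy-number category profile.
#'
#' @param id subpopulation identifier.
#' @param sample originating sample name.
#' @param n_cells number of cells (>= 1).
#' @param centroid named numeric vector of mean normalized expression over
#'   the shared gene panel.
#' @param cnv_profile named character/factor vector of [cnv_levels]
#'   categories, one per chromosome.
#' @param deg_set optional character vector of the subpopulation's DEGs.
#' @return object of class `subpopulation_profile`.
#' @export
subpopulation_profile <- function(id, sample, n_cells, centroid, cnv_profile,
                                  deg_set = character(0)) {
  stopifnot(n_cells >= 1, length(centroid) >= 2, !is.null(names(centroid)))
  cnv_profile <- setNames(factor(as.character(cnv_profile),
                                 levels = cnv_levels, ordered = TRUE),
                          names(cnv_profile))
  if (anyNA(cnv_profile)) stop("invalid CNV category in profile", call. = FALSE)
  structure(list(id = id, sample = sample, n_cells = n_cells,
                 centroid = centroid, cnv_profile = cnv_profile,
                 deg_set = deg_set),
            class = "subpopulation_profile")
}

# similarity = w_expr * Pearson(centroids) + w_cnv * CNV category concordance
profile_similarity <- function(a, b, w_expr = 0.5, w_cnv = 0.5) {
  genes <- intersect(names(a$centroid), names(b$centroid))
  if (length(genes) < 2) stop("profiles share fewer than 2 panel genes", call. = FALSE)
  r <- suppressWarnings(cor(a$centroid[genes], b$centroid[genes]))
  if (is.na(r)) r <- 0
  chroms <- intersect(names(a$cnv_profile), names(b$cnv_profile))
  conc <- if (length(chroms)) {
    mean(a$cnv_profile[chroms] == b$cnv_profile[chroms])
  } else {
    0
  }
  w_expr * r + w_cnv * conc
}

#' Match subpopulations across adjacent timepoints
#'
#' Pairwise similarity between every earlier- and later-timepoint
#' subpopulation combines expression-centroid correlation and per-chromosome
#' copy-number category concordance (`w_expr`, `w_cnv`). A greedy best-first
#' one-to-one matching accepts pairs in decreasing similarity order while
#' the similarity is at least `match_thresh`. Matched subpopulations are
#' `stable`; later-timepoint subpopulations left unmatched are `gained`,
#' earlier-timepoint ones `lost` — the three patterns of subpopulation shift
#' during disease progression.
#'
#' @param profiles_t1,profiles_t2 lists of [subpopulation_profile()]s for
#'   the earlier and later timepoint (either may be empty).
#' @param w_expr,w_cnv similarity weights.
#' @param match_thresh minimum similarity for a match.
#' @return object of class `tracking_result`: list with `matches`
#'   (data.frame id_t1, id_t2, similarity), `patterns` (data.frame id,
#'   timepoint, pattern), and `similarity` (full t1 x t2 matrix).
#' @export
match_subpopulations <- function(profiles_t1, profiles_t2, w_expr = 0.5,
                                 w_cnv = 0.5, match_thresh = 0.6) {
  ids1 <- vapply(profiles_t1, `[[`, character(1), "id")
  ids2 <- vapply(profiles_t2, `[[`, character(1), "id")
  sim <- matrix(NA_real_, length(ids1), length(ids2),
                dimnames = list(ids1, ids2))
  for (i in seq_along(profiles_t1)) {
    for (j in seq_along(profiles_t2)) {
      sim[i, j] <- profile_similarity(profiles_t1[[i]], profiles_t2[[j]],
                                      w_expr, w_cnv)
    }
  }
  matches <- data.frame(id_t1 = character(), id_t2 = character(),
                        similarity = numeric(), stringsAsFactors = FALSE)
  s <- sim
  while (length(s) && any(s >= match_thresh, na.rm = TRUE)) {
    best <- which(s == max(s, na.rm = TRUE), arr.ind = TRUE)[1, , drop = FALSE]
    matches <- rbind(matches, data.frame(
      id_t1 = rownames(s)[best[1]], id_t2 = colnames(s)[best[2]],
      similarity = s[best], stringsAsFactors = FALSE
    ))
    s <- s[-best[1], -best[2], drop = FALSE]
  }
  patterns <- rbind(
    data.frame(id = ids1, timepoint = rep(1L, length(ids1)),
               pattern = ifelse(ids1 %in% matches$id_t1, "stable", "lost"),
               stringsAsFactors = FALSE),
    data.frame(id = ids2, timepoint = rep(2L, length(ids2)),
               pattern = ifelse(ids2 %in% matches$id_t2, "stable", "gained"),
               stringsAsFactors = FALSE)
  )
  structure(list(matches = matches, patterns = patterns, similarity = sim),
            class = "tracking_result")
}

#' @export
print.tracking_result <- function(x, ...) {
  tab <- table(x$patterns$pattern[!(x$patterns$timepoint == 2L &
                                      x$patterns$pattern == "stable")])
  cat("Subpopulation tracking: ",
      paste(sprintf("%d %s", tab, names(tab)), collapse = ", "), "\n", sep = "")
  if (nrow(x$matches)) {
    cat("Matches:\n")
    print(x$matches, row.names = FALSE)
  }
  invisible(x)
}
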