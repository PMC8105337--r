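#' @keywords internal
"_PACKAGE"

#' @importFrom stats prcomp predict cor p.adjust phyper rnorm runif rpois
#'   rbinom rbeta rnbinom rlnorm quantile dist hclust cutree as.dist sd
#'   pnorm setNames aggregate wilcox.test complete.cases
#' @importFrom utils write.table head combn
NULL

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators are pure functions of (parameters, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# n distinct fixed-length barcodes over ACGT; collision-free by construction
# (sampled without replacement from the index space).
random_barcodes <- function(n, width = 16L) {
  stopifnot(n >= 1)
  alphabet <- c("A", "C", "G", "T")
  idx <- sample.int(4^min(width, 15L), n)  # distinct indices
  vapply(idx, function(i) {
    i <- i - 1L
    chars <- character(width)
    for (k in seq_len(width)) {
      chars[k] <- alphabet[(i %% 4) + 1L]
      i <- i %/% 4L
    }
    paste(chars, collapse = "")
  }, character(1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if_not_scalar_prob <- function(x, name, upper = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x >= upper + 1e-12) {
    stop(sprintf("`%s` must be a single value in [0, %s)", name, upper), call. = FALSE)
  }
  invisible(x)
}

other_base <- function(base) {
  alphabet <- c("A", "C", "G", "T")
  vapply(base, function(b) sample(setdiff(alphabet, b), 1L), character(1))
}
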