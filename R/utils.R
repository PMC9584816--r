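# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are deterministic without
#' clobbering the caller's RNG stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Adjusted Rand index between two label vectors (contingency-table closed form).
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Row-wise L2 normalization; zero rows are left at zero.
l2_normalize_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  x / nrm
}

# Column ranks (midranks) of a dense matrix.
col_ranks <- function(x) {
  apply(x, 2, rank, ties.method = "average")
}

# Per-column tie correction term sum(t^3 - t) over tied groups.
col_tie_terms <- function(x) {
  apply(x, 2, function(v) {
    t <- rle(sort(v))$lengths
    sum(t^3 - t)
  })
}
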