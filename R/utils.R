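#' @importFrom stats quantile var cor rpois rmultinom runif setNames
#' @importFrom utils read.table write.table head tail
NULL

# Linear-interpolation percentile (R default type 7), used for the variance
# filter cutoff and the permutation-null threshold alike.
percentile <- function(x, pct) {
  stopifnot(is.numeric(x), length(x) >= 1, pct >= 0, pct <= 100)
  unname(stats::quantile(x, probs = pct / 100, type = 7, names = FALSE))
}

# Center a vector and scale to unit Euclidean norm. Returns the zero vector
# (with attribute degenerate=TRUE) when the input has zero variance.
standardize_segment <- function(x) {
  x <- as.numeric(x)
  x <- x - mean(x)
  nrm <- sqrt(sum(x^2))
  if (nrm < .Machine$double.eps^0.5) {
    out <- rep(0, length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- x / nrm
  attr(out, "degenerate") <- FALSE
  out
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so library code never clobbers the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
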