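# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately written the slow, obvious way so it can
# serve as a reference for the vectorized implementations in the package.

# Direct summation KL divergence: p log(p/q) term by term.
brute_kl <- function(y, params, grid = -50:50) {
  p <- y / sum(y)
  f <- sapply(grid, function(t) mixture_density(t, params))
  q <- f / sum(f)
  total <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) {
      if (q[i] <= 0) return(Inf)
      total <- total + p[i] * log(p[i] / q[i])
    }
  }
  total
}

# O(n^2) silhouette with explicit per-point loops under correlation distance.
brute_silhouette <- function(mat, labels) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    d[i, j] <- 1 - cor(mat[i, ], mat[j, ])
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { widths[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(sapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l])))
    widths[i] <- (b - a) / max(a, b)
  }
  mean(widths)
}

# Four well-separated signature shape pairs: peaks at distinct locations so
# pairwise profile correlations are near zero, and no shape is the mirror
# image of another (mirrors would be conflated by orientation-aware
# scanning).
shape_library <- function() {
  list(
    list(pol2 = mixture_params(c(0.85, 0.05, 0.10), mu = c(0, 40),
                               beta = c(3, 3)),
         h3k4 = mixture_params(c(0.45, 0.45, 0.10), mu = c(-15, 15),
                               beta = c(3, 3))),
    list(pol2 = mixture_params(c(0.85, 0.05, 0.10), mu = c(30, 45),
                               beta = c(3, 3)),
         h3k4 = mixture_params(c(0.85, 0.05, 0.10), mu = c(10, 40),
                               beta = c(3, 3))),
    list(pol2 = mixture_params(c(0.45, 0.45, 0.10), mu = c(-30, 30),
                               beta = c(3, 3)),
         h3k4 = mixture_params(c(0.85, 0.05, 0.10), mu = c(0, 40),
                               beta = c(10, 3))),
    list(pol2 = mixture_params(c(0.85, 0.05, 0.10), mu = c(-15, 40),
                               beta = c(3, 3)),
         h3k4 = mixture_params(c(0.85, 0.05, 0.10), mu = c(25, 45),
                               beta = c(4, 3))))
}

# n_per noisy copies of each planted shape pair: density scaled to a signal
# level plus Gaussian noise with sd = noise_frac * peak signal.
make_planted_matrix <- function(shapes, n_per = 40, noise_frac = 0.1,
                                seed = 1, grid = -50:50, signal = 100) {
  set.seed(seed)
  rows <- list()
  truth <- integer(0)
  for (s in seq_along(shapes)) {
    q1 <- signal * mixture_density(grid, shapes[[s]]$pol2)
    q2 <- signal * mixture_density(grid, shapes[[s]]$h3k4)
    for (i in seq_len(n_per)) {
      noise1 <- rnorm(length(grid), 0, noise_frac * max(q1))
      noise2 <- rnorm(length(grid), 0, noise_frac * max(q2))
      rows[[length(rows) + 1]] <- c(q1 + noise1, q2 + noise2)
      truth <- c(truth, s)
    }
  }
  list(mat = do.call(rbind, rows), truth = truth)
}

# Promoter-like random mixture parameters for recovery studies: two peaks on
# opposite sides of the TSS, moderate scales, a visible uniform share.
random_promoter_params <- function() {
  pi1 <- runif(1, 0.25, 0.4)
  pi2 <- runif(1, 0.25, 0.4)
  mixture_params(c(pi1, pi2, 1 - pi1 - pi2),
                 mu = c(runif(1, -35, -6), runif(1, 6, 35)),
                 beta = c(runif(1, 3, 10), runif(1, 3, 10)))
}

random_seeded_params <- function(seed) {
  set.seed(seed)
  random_promoter_params()
}

# Fraction of cluster labels agreeing with a 2-class plant truth, maximized
# over the label permutation.
label_agreement2 <- function(labels, truth) {
  max(mean(labels == truth), mean((3 - labels) == truth))
}

# Build a coverage_track directly from a named list of binned vectors.
track_from_bins <- function(bins, bin_width = 100L) {
  promsig:::new_coverage_track(bins, bin_width)
}
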