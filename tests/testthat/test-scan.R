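# A small fitted model pair used across the scan tests.
scan_models <- local({
  shapes <- shape_library()[1:2]
  grid <- -50:50
  lapply(1:2, function(i) {
    s1 <- promsig:::standardize_segment(
      promsig:::mixture_grid_probs(shapes[[i]]$pol2, grid))
    s2 <- promsig:::standardize_segment(
      promsig:::mixture_grid_probs(shapes[[i]]$h3k4, grid))
    structure(list(cluster_id = i,
                   fit_pol2 = list(params = shapes[[i]]$pol2),
                   fit_h3k4 = list(params = shapes[[i]]$h3k4),
                   template = c(as.numeric(s1), as.numeric(s2)),
                   n_members = 1L, degenerate = FALSE, grid = grid),
              class = "signature_model")
  })
})

test_that("window correlation is exact on self, constant and negated input", {
  m <- scan_models[[1]]
  grid <- -50:50
  w1 <- promsig:::mixture_grid_probs(m$fit_pol2$params, grid)
  w2 <- promsig:::mixture_grid_probs(m$fit_h3k4$params, grid)
  expect_equal(window_correlation(w1, w2, m), 1, tolerance = 1e-12)
  expect_equal(window_correlation(rep(2, 101), rep(5, 101), m), 0)
  expect_equal(window_correlation(-w1, -w2, m), -1, tolerance = 1e-12)
  expect_error(window_correlation(w1[1:50], w2, m), "length")
})

test_that("window correlation is invariant to per-track affine transforms", {
  set.seed(61)
  m <- scan_models[[2]]
  w1 <- rpois(101, 5); w2 <- rpois(101, 5)
  r0 <- window_correlation(w1, w2, m)
  expect_equal(window_correlation(10 * w1 + 3, 0.5 * w2 - 1, m), r0,
               tolerance = 1e-12)
})

test_that("the scan localizes planted templates and identifies the model", {
  set.seed(62)
  grid <- -50:51 * 0 # placeholder; real grid from models
  nbins <- 3000
  v1 <- as.numeric(rpois(nbins, 1)); v2 <- as.numeric(rpois(nbins, 1))
  # plant model 2's exact shape at bin 1001 (1-based center)
  q1 <- promsig:::mixture_grid_probs(scan_models[[2]]$fit_pol2$params, -50:50)
  q2 <- promsig:::mixture_grid_probs(scan_models[[2]]$fit_h3k4$params, -50:50)
  span <- 951:1051
  v1[span] <- v1[span] + 5000 * q1
  v2[span] <- v2[span] + 5000 * q2
  pol2 <- track_from_bins(list(chrT = v1)); h3k4 <- track_from_bins(list(chrT = v2))
  cp <- scan_genome(pol2, h3k4, scan_models)
  pr <- cp$chroms$chrT
  top <- which.max(pr$value)
  expect_lte(abs(pr$pos[top] - 1000 * 100), 100)       # center bin +- 1 bin
  expect_equal(pr$template[top], 2L)

  # all-zero tracks give all-zero correlations
  z <- track_from_bins(list(chrT = numeric(500)))
  cpz <- scan_genome(z, z, scan_models)
  expect_true(all(cpz$chroms$chrT$value == 0))
})

test_that("reversed plants are caught by the opposite-orientation templates", {
  set.seed(63)
  nbins <- 1500
  v1 <- as.numeric(rpois(nbins, 1)); v2 <- as.numeric(rpois(nbins, 1))
  # shape 2 is strongly asymmetric, so its reverse is a distinct profile
  q1 <- rev(promsig:::mixture_grid_probs(scan_models[[2]]$fit_pol2$params,
                                         -50:50))
  q2 <- rev(promsig:::mixture_grid_probs(scan_models[[2]]$fit_h3k4$params,
                                         -50:50))
  span <- 651:751
  v1[span] <- v1[span] + 5000 * q1
  v2[span] <- v2[span] + 5000 * q2
  pol2 <- track_from_bins(list(c = v1)); h3k4 <- track_from_bins(list(c = v2))
  cp <- scan_genome(pol2, h3k4, scan_models)
  top <- which.max(cp$chroms$c$value)
  expect_equal(cp$chroms$c$orientation[top], "-")
  expect_gt(cp$chroms$c$value[top], 0.9)
  # without orientation scanning the reversed plant scores much lower
  cp1 <- scan_genome(pol2, h3k4, scan_models, scan_both_orientations = FALSE)
  expect_lt(max(cp1$chroms$c$value), max(cp$chroms$c$value))
})

test_that("permutation null is seeded, sane and thresholded by percentile", {
  set.seed(64)
  prof <- structure(list(
    tss = data.frame(chrom = "c", pos = 1:30, strand = "+",
                     gene_id = paste0("g", 1:30)),
    y1 = matrix(rpois(30 * 101, 4), 30), y2 = matrix(rpois(30 * 101, 4), 30),
    skipped = NULL, bin_width = 100L, half_bins = 50L),
    class = "tss_profiles")
  # include a window that is exactly model 1's signal: permutation destroys it
  prof$y1[1, ] <- 5000 * promsig:::mixture_grid_probs(
    scan_models[[1]]$fit_pol2$params, -50:50)
  prof$y2[1, ] <- 5000 * promsig:::mixture_grid_probs(
    scan_models[[1]]$fit_h3k4$params, -50:50)
  n1 <- permutation_null(prof, scan_models, n_perm = 500, seed = 9)
  n2 <- permutation_null(prof, scan_models, n_perm = 500, seed = 9)
  expect_identical(n1$correlations, n2$correlations)
  expect_lt(n1$threshold_z, 0.5)             # well below the self-correlation 1
  expect_equal(n1$threshold_z, percentile(n1$correlations, 95))
  expect_error(permutation_null(prof, scan_models, n_perm = 50, seed = 1),
               "n_perm")
})

test_that("region calling groups, merges and clips as specified", {
  mkprof <- function(values, bw = 100L) {
    structure(list(chroms = list(cX = list(
      pos = (seq_along(values) - 1L + 50L) * bw, value = values,
      template = rep(1L, length(values)),
      orientation = rep("+", length(values)),
      chrom_len = (length(values) + 100L) * bw)),
      bin_width = bw, stride = bw, window_bins = 101L),
      class = "correlation_profile")
  }
  vals <- rep(0.1, 400)
  vals[100:110] <- c(0.5, 0.6, 0.9, 0.7, 0.5, 0.45, 0.5, 0.6, 0.5, 0.45, 0.42)
  cp <- mkprof(vals)
  reg <- call_regions(cp, 0.4, merge_gap = 5000)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$center, (101 + 50) * 100) # position of the run maximum
  expect_equal(reg$end - reg$start, 10100)   # full window footprint

  # two runs 20 kb apart stay separate at a 5-kb merge gap
  vals2 <- rep(0, 400)
  vals2[c(50, 250)] <- 0.9
  reg2 <- call_regions(mkprof(vals2), 0.4)
  expect_equal(nrow(reg2), 2)
  # ...but merge when the gap allows
  reg2b <- call_regions(mkprof(vals2), 0.4, merge_gap = 30000)
  expect_equal(nrow(reg2b), 1)

  # threshold above the global maximum: no calls
  expect_equal(nrow(call_regions(cp, 0.95)), 0)
  expect_error(call_regions(cp, 1.2), "threshold")
})
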