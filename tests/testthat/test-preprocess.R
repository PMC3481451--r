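test_that("binning sums per-base coverage and keeps the trailing partial bin", {
  tr <- track_from_bins(list(chr1 = c(1, 1, 1, 1)), 1L)
  expect_equal(bin_coverage(tr, 2)$counts$chr1, c(2, 2))
  tr2 <- track_from_bins(list(chr1 = c(1, 2, 3)), 1L)
  expect_equal(bin_coverage(tr2, 2)$counts$chr1, c(3, 3))
  tr0 <- track_from_bins(list(chr1 = numeric(10)), 1L)
  expect_equal(bin_coverage(tr0, 5)$counts$chr1, c(0, 0))
  expect_error(bin_coverage(tr, 0), "bin_width")
})

test_that("moving-average smoothing shrinks its window at the edges", {
  expect_equal(smooth_moving_average(c(1, 2, 3, 4), 3), c(1.5, 2, 3, 3.5))
  expect_equal(smooth_moving_average(rep(7, 10), 3), rep(7, 10))
  expect_equal(smooth_moving_average(c(5, 1, 9), 1), c(5, 1, 9))
  expect_error(smooth_moving_average(1:4, 2), "odd")
})

test_that("smoothing preserves total mass up to edge effects", {
  set.seed(7)
  for (i in 1:20) {
    x <- rpois(sample(10:200, 1), 5)
    s <- smooth_moving_average(x, 3)
    n <- length(x)
    bound <- (x[1] + x[2] + x[n] + x[n - 1]) / 3 + 1e-9
    expect_lte(abs(sum(s) - sum(x)), bound)
  }
})

test_that("profile extraction is windowed, oriented and boundary-safe", {
  nbins <- 200
  set.seed(3)
  v1 <- as.numeric(rpois(nbins, 2)); v2 <- as.numeric(rpois(nbins, 2))
  pol2 <- track_from_bins(list(chr1 = v1)); h3k4 <- track_from_bins(list(chr1 = v2))
  tss <- data.frame(chrom = "chr1", pos = c(5900, 900), strand = c("+", "+"),
                    gene_id = c("ok", "edge"))
  expect_message(prof <- extract_profiles(pol2, h3k4, tss, 50), "skipped")
  expect_equal(nrow(prof$y1), 1)
  expect_equal(prof$skipped$gene_id, "edge")
  # TSS at 5900 -> bin 60 (1-based); window = bins 10..110
  expect_equal(prof$y1[1, ], v1[10:110])
  expect_equal(ncol(prof$y1), 101)

  # minus-strand profile is the reverse of the plus-strand extraction
  tssm <- data.frame(chrom = "chr1", pos = 5900, strand = c("+", "-"),
                     gene_id = c("p", "m"))
  pm <- extract_profiles(pol2, h3k4, tssm, 50)
  expect_equal(pm$y1[2, ], rev(pm$y1[1, ]))

  # strand symmetry: reversing the chromosome and flipping strand
  # reproduces the identical profile
  L <- nbins
  polr <- track_from_bins(list(chr1 = rev(v1)))
  h3kr <- track_from_bins(list(chr1 = rev(v2)))
  pos_rev <- (L - 1 - 59) * 100            # the TSS bin mirrored
  tssr <- data.frame(chrom = "chr1", pos = pos_rev, strand = "-",
                     gene_id = "p")
  pr <- extract_profiles(polr, h3kr, tssr, 50)
  expect_equal(pr$y1[1, ], prof$y1[1, ])
  expect_equal(pr$y2[1, ], prof$y2[1, ])

  h3kb <- track_from_bins(list(chr1 = v2), 50L)
  expect_error(extract_profiles(pol2, h3kb, tss), "bin width")
})

test_that("TSS isolation filter removes all members of close pairs", {
  tss <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                    pos = c(1000, 9000, 30000, 9000),
                    strand = "+", gene_id = letters[1:4])
  kept <- filter_isolated_tss(tss, 10000)
  expect_equal(kept$gene_id, c("c", "d"))    # 8-kb pair removed; chr2 is alone
  far <- data.frame(chrom = "chr1", pos = c(1000, 12000), strand = "+",
                    gene_id = c("a", "b"))
  expect_equal(nrow(filter_isolated_tss(far, 10000)), 2)
  one <- far[1, ]
  expect_equal(filter_isolated_tss(one, 10000), one)
})

test_that("low-signal filter thresholds the joint maximum at the boundary", {
  prof <- structure(list(
    tss = data.frame(chrom = "c", pos = c(1, 2, 3), strand = "+",
                     gene_id = c("lo", "edge", "hi")),
    y1 = rbind(rep(1, 5), rep(2, 5), rep(9, 5)),
    y2 = rbind(c(3, 1, 1, 1, 1), c(4, 1, 1, 1, 1), rep(1, 5)),
    skipped = NULL, bin_width = 100L, half_bins = 2L),
    class = "tss_profiles")
  fs <- filter_low_signal(prof, 4)
  expect_equal(fs$retained$tss$gene_id, c("edge", "hi"))  # max 4 is retained
  expect_equal(fs$removed$tss$gene_id, "lo")              # max 3 is removed
  empty <- promsig:::subset_profiles(prof, logical(3) & FALSE)
  both <- filter_low_signal(empty, 4)
  expect_equal(nrow(both$retained$y1), 0)
})

test_that("variance filter cutoff matches the interpolated percentile", {
  # ten pairs whose concatenated variances are exactly 1..10
  base <- c(rep(0, 5), 1, 3, 7, 2, 5)       # arbitrary non-constant shape
  rows <- t(sapply(1:10, function(v) base * sqrt(v / var(c(base, rep(0, 10))))))
  prof <- structure(list(
    tss = data.frame(chrom = "c", pos = 1:10, strand = "+",
                     gene_id = paste0("g", 1:10)),
    y1 = rows, y2 = matrix(0, 10, 10), skipped = NULL,
    bin_width = 100L, half_bins = 2L), class = "tss_profiles")
  vs <- apply(cbind(prof$y1, prof$y2), 1, var)
  expect_equal(vs, 1:10, tolerance = 1e-12, ignore_attr = TRUE)
  fv <- filter_low_variance(prof, 10)
  expect_equal(fv$cutoff, 1.9)               # linear interpolation of 1..10
  expect_equal(fv$removed$tss$gene_id, "g1")
  expect_equal(nrow(fv$retained$y1), 9)

  # equal variances: strict < removes nothing
  prof_eq <- prof
  prof_eq$y1 <- rows[rep(1, 10), ]
  expect_equal(nrow(filter_low_variance(prof_eq, 10)$retained$y1), 10)
  # pct = 0 removes nothing
  expect_equal(nrow(filter_low_variance(prof, 0)$retained$y1), 10)
  expect_error(filter_low_variance(promsig:::subset_profiles(prof, 1), 10),
               "at least 2")
})
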