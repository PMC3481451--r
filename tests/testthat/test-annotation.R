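mkregion <- function(chrom, center, id = 1L) {
  data.frame(chrom = chrom, start = center - 5000, end = center + 5100,
             center = center, correlation = 0.9, signature_id = id,
             orientation = "+", category = NA_character_,
             stringsAsFactors = FALSE)
}

mkiv <- function(chrom, start, end, category) {
  data.frame(chrom = chrom, start = start, end = end, name = ".", score = 0,
             strand = ".", category = category, stringsAsFactors = FALSE)
}

test_that("catalog building pads promoters and validates categories", {
  tss <- data.frame(chrom = "chr1", pos = 5000L, strand = "+",
                    gene_id = "g1")
  cat1 <- suppressWarnings(build_catalog(list(RefSeq_promoter = tss)))
  pw <- cat1$entries$RefSeq_promoter$intervals
  expect_equal(pw$start, 4000)
  expect_equal(pw$end, 6000)
  expect_error(build_catalog(list()), "empty")
  expect_error(suppressWarnings(
    build_catalog(list(bogus = mkiv("c", 1, 2, "x")))), "unknown")
  expect_warning(build_catalog(list(EST = mkiv("c", 1, 2, "EST"))), "absent")
})

test_that("center-window overlap respects half-open boundary arithmetic", {
  r <- mkregion("chr1", 10000)
  expect_true(region_overlaps(r, mkiv("chr1", 10900, 11500, "EST"),
                              "center_window"))
  expect_false(region_overlaps(r, mkiv("chr1", 11000, 11500, "EST"),
                               "center_window"))
  expect_false(region_overlaps(r, mkiv("chr2", 10900, 11500, "EST"),
                               "center_window"))
  expect_true(region_overlaps(r, mkiv("chr1", 14000, 14500, "CpG"),
                              "direct"))
})

test_that("hierarchical labels take the first category and partition regions", {
  tss <- data.frame(chrom = "chr1", pos = 10000L, strand = "+",
                    gene_id = "g")
  catalog <- suppressWarnings(build_catalog(list(
    RefSeq_promoter = tss,
    EST = mkiv("chr1", c(9500, 50000), c(10500, 50400), "EST"),
    CpG = mkiv("chr1", 9800, 10200, "CpG"),
    CTCF = mkiv("chr1", 80000, 80200, "CTCF"))))
  regions <- rbind(mkregion("chr1", 10000),    # promoter + EST + CpG
                   mkregion("chr1", 50100),    # EST only
                   mkregion("chr1", 80100),    # CTCF only
                   mkregion("chr1", 200000))   # nothing
  res <- annotate_hierarchical(regions, catalog)
  expect_equal(res$regions$category,
               c("RefSeq_promoter", "EST", "CTCF", "unmapped"))
  expect_equal(sum(res$hierarchical_counts), nrow(regions))
  # the CTCF-labeled region overlaps no higher category
  ctcf_region <- res$regions[res$regions$category == "CTCF", ]
  for (nm in c("RefSeq_promoter", "EST", "CpG"))
    expect_false(region_overlaps(ctcf_region,
                                 catalog$entries[[nm]]$intervals,
                                 catalog$entries[[nm]]$rule))
})

test_that("six-region fixture matches brute-force enumeration both ways", {
  tss <- data.frame(chrom = "chrA", pos = c(20000L, 90000L), strand = "+",
                    gene_id = c("g1", "g2"))
  catalog <- suppressWarnings(build_catalog(list(
    RefSeq_promoter = tss,
    EST = mkiv("chrA", c(19500, 40000), c(20500, 41000), "EST"),
    CpG = mkiv("chrA", c(19800, 60000), c(20200, 60500), "CpG"),
    CTCF = mkiv("chrA", 120000, 120300, "CTCF"))))
  regions <- rbind(mkregion("chrA", 20000), mkregion("chrA", 40500),
                   mkregion("chrA", 60250), mkregion("chrA", 90000),
                   mkregion("chrA", 120150), mkregion("chrA", 300000))
  res <- annotate_hierarchical(regions, catalog)

  # brute force: explicit double loop over regions x categories
  rules <- sapply(catalog$entries, function(e) e$rule)
  brute_hit <- matrix(FALSE, nrow(regions), length(catalog$entries),
                      dimnames = list(NULL, names(catalog$entries)))
  for (i in seq_len(nrow(regions))) {
    for (nm in names(catalog$entries)) {
      iv <- catalog$entries[[nm]]$intervals
      if (rules[[nm]] == "center_window") {
        qs <- regions$center[i] - 1000; qe <- regions$center[i] + 1000
      } else {
        qs <- regions$start[i]; qe <- regions$end[i]
      }
      for (j in seq_len(nrow(iv)))
        if (iv$chrom[j] == regions$chrom[i] && qs < iv$end[j] &&
            iv$start[j] < qe) brute_hit[i, nm] <- TRUE
    }
  }
  brute_label <- apply(brute_hit, 1, function(h)
    if (any(h)) names(h)[which(h)[1]] else "unmapped")
  expect_equal(res$regions$category, unname(brute_label))
  expect_equal(unname(res$independent_counts), unname(colSums(brute_hit)))
  # independent >= hierarchical per category, and hierarchy partitions
  for (nm in names(catalog$entries))
    expect_gte(res$independent_counts[[nm]], res$hierarchical_counts[[nm]])
  expect_equal(sum(res$hierarchical_counts), nrow(regions))
})

test_that("catalog order changes hierarchical but never independent counts", {
  set.seed(71)
  for (rep in 1:5) {
    centers <- sample(seq(20000, 480000, by = 1000), 8)
    regions <- do.call(rbind, lapply(centers, function(ct)
      mkregion("chrR", ct)))
    ivs <- list(
      EST = mkiv("chrR", centers[1:4] - 500, centers[1:4] + 500, "EST"),
      CpG = mkiv("chrR", centers[3:6] - 300, centers[3:6] + 300, "CpG"),
      CTCF = mkiv("chrR", centers[5:8] - 100, centers[5:8] + 100, "CTCF"))
    c1 <- suppressWarnings(build_catalog(ivs))
    c2 <- c1
    c2$entries <- rev(c2$entries)            # reversed hierarchy order
    i1 <- annotate_independent(regions, c1)
    i2 <- annotate_independent(regions, c2)
    expect_equal(i1[sort(names(i1))], i2[sort(names(i2))])
    h1 <- annotate_hierarchical(regions, c1)$hierarchical_counts
    expect_equal(sum(h1), nrow(regions))
  }
})

test_that("zero regions yield all-zero counts", {
  catalog <- suppressWarnings(build_catalog(list(
    EST = mkiv("c", 1, 100, "EST"))))
  none <- mkregion("c", 1000)[0, ]
  expect_equal(unname(annotate_independent(none, catalog)), 0)
  res <- annotate_hierarchical(none, catalog)
  expect_equal(sum(res$hierarchical_counts), 0)
})
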