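#' Sum per-base coverage into fixed-width bins
#'
#' Each bin value is the sum of per-base coverage over
#' \code{[i*bin_width, (i+1)*bin_width)}; a trailing partial bin is kept.
#'
#' @param track A per-base \code{coverage_track} (bin_width 1).
#' @param bin_width Bin width in base pairs (default 100).
#' @param agg \code{"sum"} (default) for true per-base read coverage;
#'   \code{"mean"} recovers bin values from a bin-resolution bedGraph that
#'   was expanded to per-base on reading.
#' @return A \code{coverage_track} with the new bin width.
#' @export
bin_coverage <- function(track, bin_width = 100L, agg = c("sum", "mean")) {
  stopifnot(inherits(track, "coverage_track"))
  agg <- match.arg(agg)
  if (bin_width < 1) stop("bin_width must be >= 1")
  if (track$bin_width != 1L)
    stop("bin_coverage expects a per-base track (bin_width 1), got ",
         track$bin_width)
  bw <- as.integer(bin_width)
  f <- if (agg == "sum") sum else mean
  counts <- lapply(track$counts, function(v) {
    n <- length(v)
    if (n == 0) return(numeric(0))
    idx <- (seq_len(n) - 1L) %/% bw
    as.numeric(tapply(v, idx, f))
  })
  new_coverage_track(counts, bin_width = bw)
}

#' Moving-average smoothing with edge shrinkage
#'
#' Replaces each value with the mean over a centered window of \code{window}
#' values; at the vector ends the window shrinks to what is available, so
#' length is preserved and no data is invented.
#'
#' @param x Numeric vector of bin counts.
#' @param window Odd window size (default 3, i.e. the average of three
#'   consecutive bins).
#' @return Smoothed numeric vector, same length as \code{x}.
#' @export
smooth_moving_average <- function(x, window = 3L) {
  if (window %% 2 == 0) stop("window must be odd")
  if (window < 1) stop("window must be >= 1")
  n <- length(x)
  if (n == 0 || window == 1) return(as.numeric(x))
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, as.numeric(x)))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth every chromosome of a binned track
#'
#' @param track A \code{coverage_track}.
#' @param window Odd window size passed to \code{\link{smooth_moving_average}}.
#' @return The smoothed \code{coverage_track}.
#' @export
smooth_track <- function(track, window = 3L) {
  stopifnot(inherits(track, "coverage_track"))
  track$counts <- lapply(track$counts, smooth_moving_average, window = window)
  track
}

#' Drop TSSs with a close neighbour
#'
#' A TSS is retained only if no other TSS (either strand) on the same
#' chromosome lies strictly within \code{min_gap} base pairs, so that
#' neighbouring genes cannot contaminate each other's profile windows.
#'
#' @param tss TSS table (\code{\link{read_tss_table}}).
#' @param min_gap Minimum distance to the nearest other TSS (default 10 kb).
#' @return The filtered TSS table.
#' @export
filter_isolated_tss <- function(tss, min_gap = 10000L) {
  if (nrow(tss) < 2) return(tss)
  keep <- vapply(seq_len(nrow(tss)), function(i) {
    same <- tss$chrom == tss$chrom[i]
    same[i] <- FALSE
    !any(abs(tss$pos[same] - tss$pos[i]) < min_gap)
  }, logical(1))
  out <- tss[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract gene-oriented TSS profile pairs
#'
#' Cuts a window of \code{2*half_bins + 1} bins centered on the bin containing
#' each TSS out of both tracks. Profiles on the minus strand are reversed, so
#' negative window positions are always upstream in gene orientation. TSSs
#' whose window would leave the chromosome are skipped and reported in the
#' \code{skipped} element.
#'
#' @param pol2,h3k4 Binned \code{coverage_track}s sharing a bin width.
#' @param tss TSS table.
#' @param half_bins Number of bins on each side of the TSS bin (default 50,
#'   giving a 101-bin window: positions -50..50).
#' @return A \code{tss_profiles} object: matrices \code{y1} (Pol-II) and
#'   \code{y2} (H3K4me2) with one row per retained TSS and one column per
#'   window position, plus the retained TSS table and the skipped one.
#' @export
extract_profiles <- function(pol2, h3k4, tss, half_bins = 50L) {
  stopifnot(inherits(pol2, "coverage_track"), inherits(h3k4, "coverage_track"))
  if (pol2$bin_width != h3k4$bin_width)
    stop("tracks have mismatched bin widths: ", pol2$bin_width, " vs ",
         h3k4$bin_width)
  bw <- pol2$bin_width
  m <- 2L * half_bins + 1L
  ok <- logical(nrow(tss))
  y1 <- matrix(0, nrow(tss), m)
  y2 <- matrix(0, nrow(tss), m)
  for (i in seq_len(nrow(tss))) {
    ch <- tss$chrom[i]
    v1 <- pol2$counts[[ch]]
    v2 <- h3k4$counts[[ch]]
    if (is.null(v1) || is.null(v2)) next
    cbin <- tss$pos[i] %/% bw + 1L            # 1-based bin index
    lo <- cbin - half_bins
    hi <- cbin + half_bins
    if (lo < 1L || hi > min(length(v1), length(v2))) next
    a <- v1[lo:hi]; b <- v2[lo:hi]
    if (tss$strand[i] == "-") { a <- rev(a); b <- rev(b) }
    y1[i, ] <- a; y2[i, ] <- b
    ok[i] <- TRUE
  }
  if (any(!ok))
    message(sum(!ok), " TSS record(s) skipped: window leaves the chromosome")
  structure(list(tss = tss[ok, , drop = FALSE],
                 y1 = y1[ok, , drop = FALSE],
                 y2 = y2[ok, , drop = FALSE],
                 skipped = tss[!ok, , drop = FALSE],
                 bin_width = bw, half_bins = as.integer(half_bins)),
            class = "tss_profiles")
}

#' @export
print.tss_profiles <- function(x, ...) {
  cat("<tss_profiles>", nrow(x$y1), "profile pair(s) x",
      ncol(x$y1), "bins of", x$bin_width, "bp\n")
  invisible(x)
}

subset_profiles <- function(profiles, keep) {
  profiles$tss <- profiles$tss[keep, , drop = FALSE]
  profiles$y1 <- profiles$y1[keep, , drop = FALSE]
  profiles$y2 <- profiles$y2[keep, , drop = FALSE]
  profiles
}

#' Concatenated profile matrix
#'
#' One row per TSS: the Pol-II window followed by the H3K4me2 window.
#'
#' @param profiles A \code{tss_profiles} object.
#' @return Numeric matrix with \code{2 * (2*half_bins + 1)} columns.
#' @export
profile_matrix <- function(profiles) {
  cbind(profiles$y1, profiles$y2)
}

#' Remove profile pairs with weak binding
#'
#' A pair is removed when the maximum (smoothed) count over both tracks and
#' all window bins falls below \code{min_max_count}.
#'
#' @param profiles A \code{tss_profiles} object.
#' @param min_max_count Threshold on the joint maximum (default 4).
#' @return List with elements \code{retained} and \code{removed}.
#' @export
filter_low_signal <- function(profiles, min_max_count = 4) {
  mx <- pmax(apply(profiles$y1, 1, max), apply(profiles$y2, 1, max))
  if (nrow(profiles$y1) == 0) mx <- numeric(0)
  keep <- mx >= min_max_count
  list(retained = subset_profiles(profiles, keep),
       removed = subset_profiles(profiles, !keep))
}

#' Remove low-variance profile pairs
#'
#' The variance of each concatenated (Pol-II, H3K4me2) vector is computed;
#' pairs strictly below the \code{pct}-th percentile (linear interpolation)
#' of those variances are removed, preventing near-flat regions from
#' degenerating the clustering.
#'
#' @param profiles A \code{tss_profiles} object with at least 2 pairs.
#' @param pct Percentile cutoff (default 10).
#' @return List with \code{retained}, \code{removed} and the numeric
#'   \code{cutoff} used.
#' @export
filter_low_variance <- function(profiles, pct = 10) {
  n <- nrow(profiles$y1)
  if (n < 2) stop("variance filter needs at least 2 profiles")
  v <- apply(profile_matrix(profiles), 1, stats::var)
  cutoff <- percentile(v, pct)
  keep <- v >= cutoff
  list(retained = subset_profiles(profiles, keep),
       removed = subset_profiles(profiles, !keep),
       cutoff = cutoff)
}

#' Run the full pre-processing chain
#'
#' Fixed order: smooth both tracks (moving average), drop TSSs with a
#' neighbour within \code{min_gap}, extract gene-oriented windows, drop
#' low-signal pairs, drop low-variance pairs. The returned report reconciles
#' exactly: \code{n_retained = n_input - (boundary + isolation + low signal +
#' low variance removals)}.
#'
#' @param pol2,h3k4 Binned \code{coverage_track}s.
#' @param tss TSS table.
#' @param half_bins,smooth_window,min_gap,min_max_count,variance_pct Stage
#'   parameters; defaults are the method's standard settings.
#' @return List with \code{profiles} (retained \code{tss_profiles}) and
#'   \code{report} (a \code{filter_report}).
#' @export
preprocess_profiles <- function(pol2, h3k4, tss, half_bins = 50L,
                                smooth_window = 3L, min_gap = 10000L,
                                min_max_count = 4, variance_pct = 10) {
  pol2 <- smooth_track(pol2, smooth_window)
  h3k4 <- smooth_track(h3k4, smooth_window)
  n_input <- nrow(tss)
  tss_iso <- filter_isolated_tss(tss, min_gap)
  n_iso <- n_input - nrow(tss_iso)
  prof <- extract_profiles(pol2, h3k4, tss_iso, half_bins)
  n_boundary <- nrow(prof$skipped)
  sig <- filter_low_signal(prof, min_max_count)
  n_sig <- nrow(sig$removed$y1)
  vv <- filter_low_variance(sig$retained, variance_pct)
  n_var <- nrow(vv$removed$y1)
  report <- structure(list(
    n_input = n_input,
    n_removed_isolation = n_iso,
    n_removed_boundary = n_boundary,
    n_removed_low_signal = n_sig,
    n_removed_low_variance = n_var,
    n_retained = nrow(vv$retained$y1),
    variance_cutoff = vv$cutoff), class = "filter_report")
  stopifnot(report$n_retained ==
              n_input - n_iso - n_boundary - n_sig - n_var)
  list(profiles = vv$retained, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  cat("  input TSSs:          ", x$n_input, "\n")
  cat("  removed (isolation): ", x$n_removed_isolation, "\n")
  cat("  removed (boundary):  ", x$n_removed_boundary, "\n")
  cat("  removed (signal):    ", x$n_removed_low_signal, "\n")
  cat("  removed (variance):  ", x$n_removed_low_variance,
      sprintf(" [cutoff %.4g]", x$variance_cutoff), "\n")
  cat("  retained:            ", x$n_retained, "\n")
  invisible(x)
}
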