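#' Correlation of one window pair with a signature template
#'
#' Each data segment is standardized (zero mean, unit norm) and the
#' concatenated vector is Pearson-correlated with the model template. Because
#' template and data halves are each zero-mean unit-norm, the correlation is
#' the mean of the per-mark correlations, so a region must resemble both the
#' Pol-II and the H3K4me2 model to score highly. A zero-variance data segment
#' yields 0.
#'
#' @param pol2_window,h3k4_window Numeric windows of the template's grid
#'   length.
#' @param model A \code{signature_model}.
#' @return Correlation in [-1, 1].
#' @export
window_correlation <- function(pol2_window, h3k4_window, model) {
  m <- length(model$grid)
  if (length(pol2_window) != m || length(h3k4_window) != m)
    stop("window length does not match the template grid")
  s1 <- standardize_segment(pol2_window)
  s2 <- standardize_segment(h3k4_window)
  if (isTRUE(attr(s1, "degenerate")) || isTRUE(attr(s2, "degenerate")))
    return(0)
  (sum(s1 * model$template[seq_len(m)]) +
     sum(s2 * model$template[(m + 1L):(2L * m)])) / 2
}

# Sliding correlation of one track against one zero-mean unit-norm template
# half, at every full-window bin position. Returns NA where the local window
# has (numerically) zero variance.
slide_segment_correlation <- function(v, tmpl) {
  m <- length(tmpl)
  n <- length(v)
  if (n < m) return(numeric(0))
  npos <- n - m + 1L
  s <- numeric(npos)
  for (j in seq_len(m))                       # m vectorized adds, O(n*m) total
    s <- s + v[j:(j + npos - 1L)] * tmpl[j]
  cs <- cumsum(c(0, v))
  cs2 <- cumsum(c(0, v^2))
  wsum <- cs[(m + 1L):(n + 1L)] - cs[1:npos]
  wss <- cs2[(m + 1L):(n + 1L)] - cs2[1:npos]
  varm <- wss - wsum^2 / m                    # ||w - mean(w)||^2
  out <- ifelse(varm > 1e-12, s / sqrt(pmax(varm, 1e-300)), NA_real_)
  out
}

#' Scan binned tracks for signature-shaped regions
#'
#' Slides the concatenated Pol-II + H3K4me2 window across each chromosome
#' and records, at every position, the maximum template correlation over all
#' (non-degenerate) signature models — and over both template orientations,
#' since training profiles were gene-oriented but the genome is not. The
#' profile value at a position is the correlation of the window centered
#' there; windows that would leave the chromosome are skipped.
#'
#' @param pol2,h3k4 Binned \code{coverage_track}s with a shared bin width.
#' @param models List of \code{signature_model}s.
#' @param stride Step between evaluated positions, in base pairs (default:
#'   one bin).
#' @return A \code{correlation_profile}: per chromosome, \code{pos} (0-based
#'   bp of the center-bin start), \code{value} (max correlation, 0 where the
#'   window is flat) and \code{template} / \code{orientation} of the argmax.
#' @param scan_both_orientations Also score the reversed template (default
#'   TRUE).
#' @export
scan_genome <- function(pol2, h3k4, models, stride = NULL,
                        scan_both_orientations = TRUE) {
  stopifnot(inherits(pol2, "coverage_track"), inherits(h3k4, "coverage_track"))
  if (pol2$bin_width != h3k4$bin_width) stop("tracks share no bin width")
  models <- Filter(function(m) !m$degenerate, models)
  if (length(models) == 0) stop("no non-degenerate signature model to scan with")
  bw <- pol2$bin_width
  stride <- stride %||% bw
  stride_bins <- max(1L, as.integer(round(stride / bw)))
  m <- length(models[[1]]$grid)
  half <- (m - 1L) %/% 2L
  chroms <- intersect(names(pol2$counts), names(h3k4$counts))
  res <- list()
  for (ch in chroms) {
    v1 <- pol2$counts[[ch]]
    v2 <- h3k4$counts[[ch]]
    n <- min(length(v1), length(v2))
    if (n < m) next
    v1 <- v1[seq_len(n)]; v2 <- v2[seq_len(n)]
    npos <- n - m + 1L
    best <- rep(-Inf, npos)
    best_tpl <- integer(npos)
    best_ori <- character(npos)
    for (k in seq_along(models)) {
      t1 <- models[[k]]$template[seq_len(m)]
      t2 <- models[[k]]$template[(m + 1L):(2L * m)]
      oris <- if (scan_both_orientations) c("+", "-") else "+"
      for (ori in oris) {
        tt1 <- if (ori == "+") t1 else rev(t1)
        tt2 <- if (ori == "+") t2 else rev(t2)
        r <- (slide_segment_correlation(v1, tt1) +
                slide_segment_correlation(v2, tt2)) / 2
        r[is.na(r)] <- 0
        upd <- r > best
        best[upd] <- r[upd]
        best_tpl[upd] <- models[[k]]$cluster_id
        best_ori[upd] <- ori
      }
    }
    keep <- seq(1L, npos, by = stride_bins)
    centers <- (keep - 1L + half) * bw        # 0-based bp of center-bin start
    res[[ch]] <- list(pos = centers, value = best[keep],
                      template = best_tpl[keep], orientation = best_ori[keep],
                      chrom_len = n * bw)
  }
  structure(list(chroms = res, bin_width = bw, stride = stride_bins * bw,
                 window_bins = m),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat("<correlation_profile> stride", x$stride, "bp; window", x$window_bins,
      "bins\n")
  for (ch in names(x$chroms))
    cat("  ", ch, ": ", length(x$chroms[[ch]]$pos), " positions, max r = ",
        format(max(x$chroms[[ch]]$value), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Permutation null distribution of the scan statistic
#'
#' Approximates the null of the max-over-models window correlation by
#' repeatedly drawing a source window pair, independently permuting the bin
#' order within each mark's window (destroying shape, preserving counts), and
#' scoring it exactly as the scan does. The detection threshold is the
#' chosen percentile of these null correlations.
#'
#' @param profiles A \code{tss_profiles} object supplying source windows
#'   (typically the retained training profiles).
#' @param models List of \code{signature_model}s.
#' @param n_perm Number of permutation draws (default 10000, minimum 100).
#' @param seed Integer seed.
#' @param pct Percentile defining the threshold (default 95).
#' @param scan_both_orientations Match the scan's decision rule (default
#'   TRUE).
#' @return A \code{null_distribution}: \code{correlations}, \code{n_perm},
#'   \code{seed}, \code{pct} and \code{threshold_z}.
#' @export
permutation_null <- function(profiles, models, n_perm = 10000L, seed = 1L,
                             pct = 95, scan_both_orientations = TRUE) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  n <- nrow(profiles$y1)
  if (n == 0) stop("no source windows for the permutation null")
  models <- Filter(function(m) !m$degenerate, models)
  if (length(models) == 0) stop("no non-degenerate model")
  m <- length(models[[1]]$grid)
  tmpl1 <- lapply(models, function(x) x$template[seq_len(m)])
  tmpl2 <- lapply(models, function(x) x$template[(m + 1L):(2L * m)])
  if (scan_both_orientations) {
    tmpl1 <- c(tmpl1, lapply(tmpl1, rev))
    tmpl2 <- c(tmpl2, lapply(tmpl2, rev))
  }
  cors <- with_seed(seed, {
    src <- sample.int(n, n_perm, replace = TRUE)
    vapply(seq_len(n_perm), function(i) {
      w1 <- profiles$y1[src[i], ][sample.int(m)]
      w2 <- profiles$y2[src[i], ][sample.int(m)]
      s1 <- standardize_segment(w1)
      s2 <- standardize_segment(w2)
      if (isTRUE(attr(s1, "degenerate")) || isTRUE(attr(s2, "degenerate")))
        return(0)
      max(vapply(seq_along(tmpl1), function(k)
        (sum(s1 * tmpl1[[k]]) + sum(s2 * tmpl2[[k]])) / 2, numeric(1)))
    }, numeric(1))
  })
  structure(list(correlations = cors, n_perm = as.integer(n_perm),
                 seed = seed, pct = pct,
                 threshold_z = percentile(cors, pct)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution>", x$n_perm, "permutations; threshold (",
      x$pct, "th pct) = ", format(x$threshold_z, digits = 4), "\n")
  invisible(x)
}

#' Call signature-matching regions from a correlation profile
#'
#' Positions with correlation above the threshold are grouped; groups closer
#' than \code{merge_gap} merge, so one locus yields one call. Each region is
#' centered on its group's correlation maximum and spans the full scan-window
#' footprint around that center, clipped to the chromosome.
#'
#' @param profile A \code{correlation_profile}.
#' @param threshold_z Correlation threshold (from
#'   \code{\link{permutation_null}}).
#' @param merge_gap Maximum bp gap between super-threshold runs merged into
#'   one region (default 5000).
#' @return data.frame of regions: \code{chrom, start, end, center,
#'   correlation, signature_id, orientation, category} (category is filled by
#'   annotation).
#' @export
call_regions <- function(profile, threshold_z, merge_gap = 5000L) {
  stopifnot(inherits(profile, "correlation_profile"))
  if (threshold_z <= -1 || threshold_z >= 1)
    stop("threshold_z must lie in (-1, 1)")
  bw <- profile$bin_width
  half_span <- (profile$window_bins %/% 2L) * bw   # 10-kb window footprint
  out <- list()
  for (ch in names(profile$chroms)) {
    pr <- profile$chroms[[ch]]
    idx <- which(pr$value > threshold_z)
    if (!length(idx)) next
    gap_bp <- diff(pr$pos[idx])
    grp <- cumsum(c(1L, as.integer(gap_bp > merge_gap)))
    chrom_len <- pr$chrom_len
    for (g in unique(grp)) {
      ii <- idx[grp == g]
      top <- ii[which.max(pr$value[ii])]
      center <- pr$pos[top]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = max(0, center - half_span),
        end = min(chrom_len, center + half_span + bw),
        center = center,
        correlation = pr$value[top],
        signature_id = pr$template[top],
        orientation = pr$orientation[top],
        category = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), center = numeric(0),
                      correlation = numeric(0), signature_id = integer(0),
                      orientation = character(0), category = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
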