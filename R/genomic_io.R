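#' Read a coverage track into dense per-base counts
#'
#' Parses a bedGraph, wiggle (fixed or variable step) or BAM file into a
#' \code{coverage_track}: one dense numeric vector of per-base counts per
#' chromosome, with bases absent from the input set to zero. All coordinates
#' in the package are 0-based half-open; conversion from the 1-based
#' conventions of wiggle and BAM happens here, at the boundary.
#'
#' Overlapping bedGraph intervals are rejected: they would make the per-base
#' coverage ambiguous. Fractional bedGraph values are accepted; nothing in the
#' downstream method requires integer counts. BAM input (requires an index and
#' the \pkg{GenomicAlignments} package) is converted by straight pileup of
#' aligned read positions, with no fragment extension or shifting.
#'
#' @param path Path to the coverage file.
#' @param format One of \code{"auto"}, \code{"bedGraph"}, \code{"wig"},
#'   \code{"bam"}. \code{"auto"} guesses from the file extension.
#' @return A \code{coverage_track}: list with \code{counts} (named list of
#'   per-chromosome numeric vectors) and \code{bin_width} (1 for per-base).
#' @export
read_coverage <- function(path, format = c("auto", "bedGraph", "wig", "bam")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("coverage file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      bedgraph = "bedGraph", bg = "bedGraph",
      wig = "wig", wiggle = "wig",
      bam = "bam",
      stop("cannot guess coverage format from extension of: ", path))
  }
  gr <- switch(format,
    bedGraph = read_bedgraph_granges(path),
    wig = rtracklayer::import(path, format = "wig"),
    bam = bam_coverage_granges(path))
  granges_to_track(gr)
}

# Validate a bedGraph line-by-line so parse errors carry a line number, then
# hand the actual parsing to rtracklayer.
read_bedgraph_granges <- function(path) {
  lines <- readLines(path)
  body <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  for (i in which(body)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 4 || anyNA(suppressWarnings(as.numeric(f[2:4]))))
      stop("malformed bedGraph line ", i, " in ", path, ": ", lines[i])
    if (as.numeric(f[3]) <= as.numeric(f[2]))
      stop("malformed bedGraph line ", i, " in ", path, ": end <= start")
  }
  if (!any(body)) return(GenomicRanges::GRanges())
  gr <- rtracklayer::import(path, format = "bedGraph")
  hits <- IRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(hits) > 0)
    stop("overlapping bedGraph intervals in ", path,
         ": per-base coverage is ambiguous")
  gr
}

bam_coverage_granges <- function(path) {
  if (!requireNamespace("GenomicAlignments", quietly = TRUE))
    stop("BAM input requires the GenomicAlignments package")
  cov <- GenomicAlignments::coverage(GenomicAlignments::readGAlignments(path))
  gr <- GenomicRanges::GRanges(cov)
  names(S4Vectors::mcols(gr)) <- "score"
  gr
}

# GRanges (1-based closed) with a score column -> dense per-base track
# (0-based half-open internally).
granges_to_track <- function(gr) {
  counts <- list()
  if (length(gr) > 0) {
    chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
    for (ch in chroms) {
      g <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
      len <- max(GenomicRanges::end(g))
      v <- numeric(len)
      sc <- S4Vectors::mcols(g)$score
      st <- GenomicRanges::start(g)
      en <- GenomicRanges::end(g)
      for (j in seq_along(g)) if (sc[j] != 0) v[st[j]:en[j]] <- sc[j]
      counts[[ch]] <- v
    }
  }
  new_coverage_track(counts, bin_width = 1L)
}

new_coverage_track <- function(counts, bin_width) {
  stopifnot(is.list(counts), bin_width >= 1)
  structure(list(counts = counts, bin_width = as.integer(bin_width)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> bin_width =", x$bin_width, "bp;",
      length(x$counts), "chromosome(s)\n")
  for (ch in names(x$counts))
    cat("  ", ch, ": ", length(x$counts[[ch]]), " bins, total ",
        format(sum(x$counts[[ch]])), "\n", sep = "")
  invisible(x)
}

#' Read a TSS table
#'
#' Accepts BED6 (chrom, start, end, name, score, strand) or a tab-separated
#' table with header columns \code{chrom, txStart, txEnd, strand, gene_id}.
#' The TSS is \code{txStart} for + strand genes and \code{txEnd - 1} for -
#' strand genes (0-based). Records duplicated on (chrom, pos, strand) are
#' collapsed to one.
#'
#' @param path Path to the TSS file.
#' @return data.frame with columns \code{chrom, pos, strand, gene_id}.
#' @export
read_tss_table <- function(path) {
  if (!file.exists(path)) stop("TSS file not found: ", path)
  first <- readLines(path, n = 1)
  if (grepl("chrom", first, fixed = TRUE)) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("chrom", "txStart", "txEnd", "strand", "gene_id")
    if (!all(need %in% names(df)))
      stop("TSS table must have columns: ", paste(need, collapse = ", "))
  } else {
    df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 6)
      stop("BED TSS input needs 6 columns (strand is required)")
    df <- data.frame(chrom = df[[1]], txStart = df[[2]], txEnd = df[[3]],
                     gene_id = as.character(df[[4]]), strand = df[[6]],
                     stringsAsFactors = FALSE)
  }
  if (any(!df$strand %in% c("+", "-")))
    stop("every TSS record needs strand + or - (profiles are gene-oriented)")
  pos <- ifelse(df$strand == "+", df$txStart, df$txEnd - 1L)
  out <- data.frame(chrom = df$chrom, pos = as.integer(pos),
                    strand = df$strand, gene_id = as.character(df$gene_id),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("chrom", "pos", "strand")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an annotation interval set
#'
#' Reads a BED3+ file into a sorted interval table tagged with a category
#' label. Coordinates stay 0-based half-open (BED native).
#'
#' @param path Path to a BED file.
#' @param category Label attached to every interval (e.g. \code{"EST"}).
#' @return data.frame with columns \code{chrom, start, end, name, score,
#'   strand, category}, sorted by (chrom, start).
#' @export
read_intervals <- function(path, category) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  body <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  rows <- lapply(which(body), function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 3 || anyNA(suppressWarnings(as.numeric(f[2:3]))))
      stop("malformed BED line ", i, " in ", path, ": ", lines[i])
    st <- as.numeric(f[2]); en <- as.numeric(f[3])
    if (en <= st)
      stop("BED line ", i, " in ", path, ": end <= start (", st, ", ", en, ")")
    data.frame(chrom = f[1], start = st, end = en,
               name = if (length(f) >= 4) f[4] else ".",
               score = if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else 0,
               strand = if (length(f) >= 6) f[6] else ".",
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               name = character(0), score = numeric(0), strand = character(0),
               stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  df$score[is.na(df$score)] <- 0
  df$category <- rep(category, nrow(df))
  rownames(df) <- NULL
  df
}

#' Write called regions as BED6 plus a full-precision sidecar TSV
#'
#' The BED name field carries the matching signature id and (when annotated)
#' the category; the BED score is the correlation scaled by 1000 and clamped
#' to [0, 1000]. The sidecar \code{<path>.tsv} keeps all fields at full
#' precision.
#'
#' @param regions data.frame of called regions (see \code{\link{call_regions}}).
#' @param path Output BED path; the sidecar is written to \code{<path>.tsv}.
#' @export
write_regions <- function(regions, path) {
  stopifnot(is.data.frame(regions))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  if (nrow(regions) > 0) {
    nm <- paste0("sig", regions$signature_id,
                 ifelse(is.na(regions$category) | regions$category == "",
                        "", paste0("|", regions$category)))
    score <- pmin(pmax(round(regions$correlation * 1000), 0), 1000)
    bed <- data.frame(regions$chrom, format(regions$start, scientific = FALSE,
                                            trim = TRUE),
                      format(regions$end, scientific = FALSE, trim = TRUE),
                      nm, score, ".")
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(regions, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a binned track as bedGraph
#'
#' @param track A \code{coverage_track}.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  bw <- track$bin_width
  for (ch in names(track$counts)) {
    v <- track$counts[[ch]]
    nz <- which(v != 0)
    if (!length(nz)) next
    # merge consecutive equal-value bins into single intervals
    brk <- c(TRUE, diff(nz) != 1 | diff(v[nz]) != 0)
    grp <- cumsum(brk)
    st <- (nz[!duplicated(grp)] - 1) * bw
    en <- nz[rev(!duplicated(rev(grp)))] * bw
    val <- v[nz[!duplicated(grp)]]
    writeLines(paste(ch, format(st, scientific = FALSE, trim = TRUE),
                     format(en, scientific = FALSE, trim = TRUE), val,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write an interval table as BED6
#'
#' @param intervals data.frame as returned by \code{\link{read_intervals}}.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  if (nrow(intervals) > 0) {
    bed <- data.frame(intervals$chrom,
                      format(intervals$start, scientific = FALSE, trim = TRUE),
                      format(intervals$end, scientific = FALSE, trim = TRUE),
                      intervals$name %||% ".", intervals$score %||% 0,
                      intervals$strand %||% ".")
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
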