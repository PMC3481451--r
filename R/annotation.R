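#' Annotation category hierarchy
#'
#' The fixed order in which called regions are matched against annotation
#' sets: a region takes the first category it overlaps, so e.g. a region
#' inside both a RefSeq promoter and a CpG island is a promoter hit.
#' @export
ANNOTATION_HIERARCHY <- c("RefSeq_promoter", "gene_body", "ncRNA", "EST",
                          "RNAseq_transcript", "ER", "AR", "CpG", "CTCF")

default_rule <- function(category) {
  # transcript-like categories are matched through the 2-kb window around the
  # region center; compact site/feature categories by direct region overlap
  if (category %in% c("RefSeq_promoter", "ncRNA", "EST", "RNAseq_transcript"))
    "center_window" else "direct"
}

#' Build an annotation catalog
#'
#' Assembles the hierarchical catalog from per-category interval sets. For
#' \code{RefSeq_promoter} either a TSS table (data.frame with \code{chrom,
#' pos, strand}) or a BED path/interval table of TSS points is accepted and
#' each TSS is expanded to the promoter window \code{[pos - promoter_pad,
#' pos + promoter_pad)}. \code{gene_body} intervals, when derived from
#' RefSeq records, should already exclude promoter windows. Categories
#' absent from \code{config} are skipped with a warning and the hierarchy
#' simply omits that level.
#'
#' @param config Named list mapping category names (subset of
#'   \code{\link{ANNOTATION_HIERARCHY}}) to a BED path, an interval
#'   data.frame (\code{\link{read_intervals}}) or, for the promoter level, a
#'   TSS table.
#' @param promoter_pad Promoter half-window around each TSS (default 1000).
#' @param center_pad Half-window around a region center used by the
#'   center-window overlap rule (default 1000).
#' @param rules Optional named character vector overriding the per-category
#'   overlap rule (\code{"center_window"} or \code{"direct"}).
#' @return An \code{annotation_catalog}.
#' @export
build_catalog <- function(config, promoter_pad = 1000L, center_pad = 1000L,
                          rules = NULL) {
  if (length(config) == 0) stop("empty annotation config")
  bad <- setdiff(names(config), ANNOTATION_HIERARCHY)
  if (length(bad))
    stop("unknown annotation categories: ", paste(bad, collapse = ", "),
         "; valid: ", paste(ANNOTATION_HIERARCHY, collapse = ", "))
  missing <- setdiff(ANNOTATION_HIERARCHY, names(config))
  if (length(missing))
    warning("categories absent from catalog (hierarchy skips them): ",
            paste(missing, collapse = ", "))
  entries <- list()
  for (cat_name in intersect(ANNOTATION_HIERARCHY, names(config))) {
    x <- config[[cat_name]]
    if (is.character(x)) x <- read_intervals(x, cat_name)
    if (cat_name == "RefSeq_promoter" && "pos" %in% names(x)) {
      x <- data.frame(chrom = x$chrom,
                      start = pmax(0, x$pos - promoter_pad),
                      end = x$pos + promoter_pad,
                      name = if ("gene_id" %in% names(x)) x$gene_id else ".",
                      score = 0, strand = ".", category = cat_name,
                      stringsAsFactors = FALSE)
    }
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    rule <- if (!is.null(rules) && cat_name %in% names(rules))
      rules[[cat_name]] else default_rule(cat_name)
    entries[[cat_name]] <- list(category = cat_name, intervals = x,
                                rule = match.arg(rule, c("center_window",
                                                         "direct")))
  }
  structure(list(entries = entries, promoter_pad = promoter_pad,
                 center_pad = center_pad),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat("<annotation_catalog>\n")
  for (e in x$entries)
    cat(sprintf("  %-18s %6d interval(s)  [%s]\n", e$category,
                nrow(e$intervals), e$rule))
  invisible(x)
}

# Vectorized overlap of regions against one interval set under one rule.
# All coordinates 0-based half-open; overlap iff q_start < i_end and
# i_start < q_end.
regions_overlap_set <- function(regions, intervals, rule, center_pad) {
  if (nrow(regions) == 0) return(logical(0))
  if (nrow(intervals) == 0) return(rep(FALSE, nrow(regions)))
  if (rule == "center_window") {
    qs <- regions$center - center_pad
    qe <- regions$center + center_pad
  } else {
    qs <- regions$start
    qe <- regions$end
  }
  q <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(start = qs + 1, end = qe))
  s <- GenomicRanges::GRanges(intervals$chrom,
                              IRanges::IRanges(start = intervals$start + 1,
                                               end = intervals$end))
  # disjoint chromosome sets between query and subject are routine here
  # (a category may live on other chromosomes entirely)
  suppressWarnings(IRanges::overlapsAny(q, s))
}

#' Does a region overlap an interval set?
#'
#' @param region One-row region data.frame.
#' @param intervals Interval table.
#' @param rule \code{"center_window"} (2-kb window around the region center)
#'   or \code{"direct"} (the full region span).
#' @param center_pad Half-width of the center window (default 1000).
#' @return TRUE/FALSE.
#' @export
region_overlaps <- function(region, intervals,
                            rule = c("center_window", "direct"),
                            center_pad = 1000L) {
  rule <- match.arg(rule)
  as.logical(regions_overlap_set(region, intervals, rule, center_pad))
}

#' Hierarchical annotation of called regions
#'
#' Each region is labeled with the first category, in hierarchy order, whose
#' intervals it overlaps under that category's rule; regions hitting nothing
#' are \code{"unmapped"}. Counts therefore partition the region set.
#'
#' @param regions Region data.frame from \code{\link{call_regions}}.
#' @param catalog An \code{annotation_catalog}.
#' @return List: \code{regions} (with \code{category} filled),
#'   \code{hierarchical_counts} (named, includes \code{unmapped}) and
#'   \code{independent_counts} (see \code{\link{annotate_independent}}).
#' @export
annotate_hierarchical <- function(regions, catalog) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  if (length(catalog$entries) == 0) stop("catalog has no categories")
  cat_names <- names(catalog$entries)
  label <- rep("unmapped", nrow(regions))
  unassigned <- rep(TRUE, nrow(regions))
  for (nm in cat_names) {
    e <- catalog$entries[[nm]]
    hit <- regions_overlap_set(regions, e$intervals, e$rule,
                               catalog$center_pad)
    take <- unassigned & hit
    label[take] <- nm
    unassigned <- unassigned & !take
  }
  regions$category <- label
  hc <- stats::setNames(vapply(c(cat_names, "unmapped"),
                               function(nm) sum(label == nm), numeric(1)),
                        c(cat_names, "unmapped"))
  list(regions = regions, hierarchical_counts = hc,
       independent_counts = annotate_independent(regions, catalog))
}

#' Independent per-category overlap counts
#'
#' For every category separately, the number of regions overlapping it; a
#' region may count toward several categories, so these counts do not
#' partition the region set (unlike the hierarchical ones) and are always at
#' least as large per category.
#'
#' @param regions Region data.frame.
#' @param catalog An \code{annotation_catalog}.
#' @return Named numeric vector of counts.
#' @export
annotate_independent <- function(regions, catalog) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  if (length(catalog$entries) == 0) stop("catalog has no categories")
  vapply(catalog$entries, function(e)
    sum(regions_overlap_set(regions, e$intervals, e$rule,
                            catalog$center_pad)), numeric(1))
}
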