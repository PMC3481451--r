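#' Simulation configuration
#'
#' Bundles everything the synthetic-genome generator needs. Defaults emulate
#' the study conditions the method assumes: a 1-Mb genome, 20 planted
#' signature regions at 5,000 reads per mark per plant over a Poisson(1)
#' per-bin background, 100-bp bins and a 101-bin profile window. Plants are
#' kept at least 20 kb apart and 10 kb clear of chromosome ends so planted
#' windows never interfere.
#'
#' @param seed Master seed; all randomness flows from it.
#' @param genome Named integer vector of chromosome lengths in bp.
#' @param n_plants Number of planted signature regions.
#' @param reads_per_plant Reads per plant per track.
#' @param background_rate Poisson mean per bin per track.
#' @param plant_params List of plant shapes, each a list with elements
#'   \code{pol2} and \code{h3k4} (both \code{\link{mixture_params}}).
#'   Defaults to two canonical promoter shapes: a unimodal Pol-II peak with
#'   bimodal H3K4me2, and a shifted-peak variant with a heavier downstream
#'   tail.
#' @param bin_width,half_bins Grid geometry (defaults 100 bp, 50 bins).
#' @param tss_density Synthetic background TSSs per Mb (for catalog
#'   fixtures).
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L, genome = c(chrS = 1000000L), n_plants = 20L,
                       reads_per_plant = 5000L, background_rate = 1,
                       plant_params = default_plant_params(),
                       bin_width = 100L, half_bins = 50L, tss_density = 10) {
  structure(list(seed = as.integer(seed), genome = genome,
                 n_plants = as.integer(n_plants),
                 reads_per_plant = as.integer(reads_per_plant),
                 background_rate = background_rate,
                 plant_params = plant_params,
                 bin_width = as.integer(bin_width),
                 half_bins = as.integer(half_bins),
                 tss_density = tss_density),
            class = "sim_config")
}

#' Canonical planted promoter shapes
#'
#' Two signature shapes used by default: (1) unimodal Pol-II centered on the
#' TSS with a downstream-tail uniform share, paired with bimodal H3K4me2
#' flanking the TSS; (2) a downstream-shifted Pol-II peak with a heavier
#' tail, paired with an asymmetric H3K4me2 doublet.
#'
#' @return List of two plant shape pairs.
#' @export
default_plant_params <- function() {
  list(
    list(pol2 = mixture_params(c(0.55, 0.25, 0.20), mu = c(0, 12),
                               beta = c(4, 10)),
         h3k4 = mixture_params(c(0.45, 0.45, 0.10), mu = c(-8, 8),
                               beta = c(5, 5))),
    list(pol2 = mixture_params(c(0.45, 0.20, 0.35), mu = c(6, 25),
                               beta = c(6, 12)),
         h3k4 = mixture_params(c(0.55, 0.30, 0.15), mu = c(-12, 10),
                               beta = c(6, 8))))
}

#' Draw one profile from a mixture shape
#'
#' Multinomial draw of \code{n_reads} reads over the grid bins with
#' probabilities given by the normalized mixture density, i.e. the generator
#' respects exactly the model the fitter assumes.
#'
#' @param params A \code{mixture_params} object.
#' @param n_reads Total reads (>= 0).
#' @param seed Optional integer seed.
#' @param grid Bin coordinates (default \code{-50:50}).
#' @return Integer count vector on the grid summing to \code{n_reads}.
#' @export
simulate_profile <- function(params, n_reads, seed = NULL, grid = -50:50) {
  if (n_reads < 0) stop("n_reads must be >= 0")
  q <- mixture_grid_probs(params, grid)
  if (anyNA(q)) stop("invalid mixture parameters: density sums to zero")
  if (n_reads == 0) return(integer(length(grid)))
  with_seed(seed, as.integer(stats::rmultinom(1, size = n_reads, prob = q)))
}

#' Simulate a two-track genome with planted signatures
#'
#' Per-bin background counts are Poisson with the configured rate,
#' independently per track; each plant adds a multinomial profile draw from
#' its shape pair, reversed with probability 1/2 to exercise orientation
#' handling. The returned ground truth records every plant.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List: \code{pol2} and \code{h3k4} (binned
#'   \code{coverage_track}s), \code{truth} (data.frame: chrom, center bp,
#'   param index, orientation, reads per track).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bw <- config$bin_width
  hb <- config$half_bins
  m <- 2L * hb + 1L
  grid <- -hb:hb
  min_space <- 20000L
  edge <- 10000L
  # feasibility: plants on a min_space lattice inside the edge margins
  capacity <- sum(vapply(config$genome, function(L)
    max(0, (L - 2 * edge) %/% min_space + 1), numeric(1)))
  if (config$n_plants > capacity)
    stop("spacing infeasible: at most ", capacity, " plants fit this genome")
  with_seed(config$seed, {
    pol2 <- h3k4 <- list()
    truth <- list()
    for (ch in names(config$genome)) {
      nbins <- as.integer(ceiling(config$genome[[ch]] / bw))
      pol2[[ch]] <- as.numeric(stats::rpois(nbins, config$background_rate))
      h3k4[[ch]] <- as.numeric(stats::rpois(nbins, config$background_rate))
    }
    # place plants chromosome-proportionally, rejection-sampled for spacing
    chrom_of <- sample(names(config$genome), config$n_plants, replace = TRUE,
                       prob = as.numeric(config$genome) / sum(config$genome))
    centers <- stats::setNames(vector("list", length(config$genome)),
                               names(config$genome))
    for (i in seq_len(config$n_plants)) {
      ch <- chrom_of[i]
      L <- config$genome[[ch]]
      for (try in 1:100000) {
        cand <- edge + floor(stats::runif(1) * (L - 2 * edge))
        cand <- (cand %/% bw) * bw            # snap to a bin start
        if (all(abs(unlist(centers[[ch]]) - cand) >= min_space) ||
            length(centers[[ch]]) == 0) break
        if (try == 100000) stop("could not place plant ", i,
                                " under spacing rules")
      }
      centers[[ch]] <- c(centers[[ch]], cand)
      pidx <- ((i - 1L) %% length(config$plant_params)) + 1L
      flip <- stats::runif(1) < 0.5
      prof1 <- simulate_profile(config$plant_params[[pidx]]$pol2,
                                config$reads_per_plant, grid = grid)
      prof2 <- simulate_profile(config$plant_params[[pidx]]$h3k4,
                                config$reads_per_plant, grid = grid)
      if (flip) { prof1 <- rev(prof1); prof2 <- rev(prof2) }
      cbin <- cand %/% bw + 1L
      span <- (cbin - hb):(cbin + hb)
      pol2[[ch]][span] <- pol2[[ch]][span] + prof1
      h3k4[[ch]][span] <- h3k4[[ch]][span] + prof2
      truth[[i]] <- data.frame(chrom = ch, center = cand,
                               param_index = pidx,
                               orientation = if (flip) "-" else "+",
                               reads = config$reads_per_plant,
                               stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(chrom = character(0), center = numeric(0),
                 param_index = integer(0), orientation = character(0),
                 reads = numeric(0), stringsAsFactors = FALSE)
    list(pol2 = new_coverage_track(pol2, bw),
         h3k4 = new_coverage_track(h3k4, bw),
         truth = truth)
  })
}

#' Synthetic annotation catalogs around planted regions
#'
#' Assigns each plant a category with the given proportions: plants drawn as
#' \code{RefSeq} get a TSS at their center (entering both the TSS table and
#' the promoter level of the catalog); \code{EST}, \code{CpG} and \code{CTCF}
#' plants get an interval of the respective kind over their center; the
#' \code{none} share gets nothing (such plants should come out
#' \code{"unmapped"}). Also sprinkles background TSSs at the configured
#' density away from plants.
#'
#' @param truth Ground-truth data.frame from \code{\link{simulate_genome}}.
#' @param config The \code{\link{sim_config}} used.
#' @param seed Integer seed.
#' @param proportions Named numeric vector over \code{RefSeq}, \code{EST},
#'   \code{CpG}, \code{CTCF}, \code{none}; must sum to <= 1 (remainder goes
#'   to \code{none}).
#' @return List: \code{tss} (TSS table data.frame), \code{intervals} (named
#'   list of interval tables by category), \code{assignment} (category per
#'   plant).
#' @export
simulate_annotations <- function(truth, config, seed = 1L,
                                 proportions = c(RefSeq = 0.5, EST = 0.2,
                                                 CpG = 0.15, CTCF = 0.05,
                                                 none = 0.1)) {
  if (sum(proportions) > 1 + 1e-9)
    stop("annotation proportions must sum to <= 1")
  cats <- c("RefSeq", "EST", "CpG", "CTCF", "none")
  pr <- stats::setNames(numeric(5), cats)
  pr[names(proportions)] <- proportions
  pr["none"] <- pr["none"] + max(0, 1 - sum(pr))
  with_seed(seed, {
    n <- nrow(truth)
    assign_cat <- if (n) sample(cats, n, replace = TRUE, prob = pr) else
      character(0)
    tss_rows <- list(); est <- list(); cpg <- list(); ctcf <- list()
    for (i in seq_len(n)) {
      ch <- truth$chrom[i]; ct <- truth$center[i]
      if (assign_cat[i] == "RefSeq") {
        ori <- truth$orientation[i]
        # the TSS (txStart for +, txEnd - 1 for -) must sit at the plant center
        tss_rows[[length(tss_rows) + 1L]] <-
          data.frame(chrom = ch,
                     txStart = if (ori == "+") ct else ct - 5000L,
                     txEnd = if (ori == "+") ct + 5000L else ct + 1L,
                     strand = ori,
                     gene_id = sprintf("plant_gene_%d", i),
                     stringsAsFactors = FALSE)
      } else if (assign_cat[i] == "EST") {
        est[[length(est) + 1L]] <- interval_row(ch, ct - 300L, ct + 700L,
                                                sprintf("est_%d", i), "EST")
      } else if (assign_cat[i] == "CpG") {
        cpg[[length(cpg) + 1L]] <- interval_row(ch, ct - 400L, ct + 400L,
                                                sprintf("cpg_%d", i), "CpG")
      } else if (assign_cat[i] == "CTCF") {
        ctcf[[length(ctcf) + 1L]] <- interval_row(ch, ct - 150L, ct + 150L,
                                                  sprintf("ctcf_%d", i),
                                                  "CTCF")
      }
    }
    # background TSSs away from plants, for realistic promoter catalogs
    for (ch in names(config$genome)) {
      L <- config$genome[[ch]]
      n_bg <- stats::rpois(1, config$tss_density * L / 1e6)
      if (n_bg == 0) next
      pos <- sort(floor(stats::runif(n_bg) * L))
      near_plant <- vapply(pos, function(p)
        any(truth$chrom == ch & abs(truth$center - p) < 15000), logical(1))
      pos <- pos[!near_plant]
      for (p in pos)
        tss_rows[[length(tss_rows) + 1L]] <-
          data.frame(chrom = ch, txStart = p, txEnd = p + 3000L,
                     strand = sample(c("+", "-"), 1),
                     gene_id = sprintf("bg_gene_%s_%d", ch, p),
                     stringsAsFactors = FALSE)
    }
    tss <- if (length(tss_rows)) do.call(rbind, tss_rows) else
      data.frame(chrom = character(0), txStart = integer(0),
                 txEnd = integer(0), strand = character(0),
                 gene_id = character(0), stringsAsFactors = FALSE)
    bind <- function(x, cat_name) if (length(x)) do.call(rbind, x) else
      empty_intervals(cat_name)
    list(tss = tss,
         intervals = list(EST = bind(est, "EST"), CpG = bind(cpg, "CpG"),
                          CTCF = bind(ctcf, "CTCF")),
         assignment = assign_cat)
  })
}

interval_row <- function(chrom, start, end, name, category) {
  data.frame(chrom = chrom, start = max(0, start), end = end, name = name,
             score = 0, strand = ".", category = category,
             stringsAsFactors = FALSE)
}

empty_intervals <- function(category) {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             name = character(0), score = numeric(0), strand = character(0),
             category = character(0), stringsAsFactors = FALSE)
}

#' Write a TSS table as TSV
#'
#' @param tss data.frame with \code{chrom, txStart, txEnd, strand, gene_id}.
#' @param path Output path.
#' @export
write_tss_table <- function(tss, path) {
  utils::write.table(tss[c("chrom", "txStart", "txEnd", "strand", "gene_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
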