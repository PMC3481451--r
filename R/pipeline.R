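#' Pipeline configuration
#'
#' All tunables of the discovery pipeline in one place. Defaults are the
#' method's standard settings: 100-bp bins, a 101-bin window (5 kb each side
#' of the TSS), 3-bin smoothing, 10-kb TSS isolation, low-signal cutoff 4,
#' 10th-percentile variance cutoff, silhouette-selected k over 2..8, 16
#' mixture-fit restarts, pattern-search limits of 20000 evaluations / 2000
#' iterations / 1e-6 tolerances, a 10000-draw permutation null and its 95th
#' percentile as threshold.
#'
#' @param seed Master seed; each stage derives its own by a fixed offset.
#' @param ... Overrides for any listed default.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(seed = as.integer(seed), bin_width = 100L, half_bins = 50L,
              smooth_window = 3L, min_gap = 10000L, min_max_count = 4,
              variance_pct = 10, k_range = 2:8, n_init = 10L, n_starts = 16L,
              max_evals = 20000L, max_iters = 2000L, step_tol = 1e-6,
              ftol = 1e-6, n_perm = 10000L, threshold_pct = 95,
              stride = NULL, merge_gap = 5000L, scan_both_orientations = TRUE,
              genome_length = 1000000L, n_plants = 20L,
              reads_per_plant = 5000L, background_rate = 1)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(run_dir, stage, config, inputs, outputs) {
  manifest <- list(stage = stage, config = unclass(config),
                   config_hash = config_hash(config), seed = config$seed,
                   inputs = inputs, outputs = outputs,
                   package_version = as.character(utils::packageVersion("promsig")))
  jsonlite::write_json(manifest, file.path(run_dir,
                                           paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

need_artifact <- function(run_dir, file, producer) {
  p <- file.path(run_dir, file)
  if (!file.exists(p))
    stop("missing artifact '", file, "': run stage '", producer, "' first")
  p
}

#' Run one pipeline stage (or all of them)
#'
#' Stages communicate exclusively through plain-text artifacts in
#' \code{run_dir} (bedGraph tracks, TSV tables, JSON models and reports), so
#' each stage can be re-run independently and a re-run with the same config
#' and seed reproduces its artifacts byte for byte. Stage seeds are the
#' master seed plus a fixed per-stage offset.
#'
#' @param stage One of \code{"simulate"}, \code{"preprocess"},
#'   \code{"cluster"}, \code{"fit"}, \code{"scan"}, \code{"annotate"},
#'   \code{"all"}.
#' @param config A \code{\link{pipeline_config}}.
#' @param run_dir Directory for stage artifacts (created if needed).
#' @return Invisibly, the run directory.
#' @export
run_stage <- function(stage = c("all", "simulate", "preprocess", "cluster",
                                "fit", "scan", "annotate"),
                      config = pipeline_config(), run_dir) {
  stage <- match.arg(stage)
  if (!dir.exists(run_dir)) dir.create(run_dir, recursive = TRUE)
  if (stage == "all") {
    for (s in c("simulate", "preprocess", "cluster", "fit", "scan",
                "annotate"))
      run_stage(s, config, run_dir)
    return(invisible(run_dir))
  }
  switch(stage,
         simulate = stage_simulate(config, run_dir),
         preprocess = stage_preprocess(config, run_dir),
         cluster = stage_cluster(config, run_dir),
         fit = stage_fit(config, run_dir),
         scan = stage_scan(config, run_dir),
         annotate = stage_annotate(config, run_dir))
  invisible(run_dir)
}

stage_simulate <- function(config, run_dir) {
  sc <- sim_config(seed = config$seed,
                   genome = c(chrS = as.integer(config$genome_length)),
                   n_plants = config$n_plants,
                   reads_per_plant = config$reads_per_plant,
                   background_rate = config$background_rate,
                   bin_width = config$bin_width, half_bins = config$half_bins)
  sim <- simulate_genome(sc)
  ann <- simulate_annotations(sim$truth, sc, seed = config$seed + 4L)
  write_bedgraph(sim$pol2, file.path(run_dir, "pol2.bedGraph"))
  write_bedgraph(sim$h3k4, file.path(run_dir, "h3k4.bedGraph"))
  truth_iv <- data.frame(chrom = sim$truth$chrom,
                         start = sim$truth$center,
                         end = sim$truth$center + config$bin_width,
                         name = paste0("plant_shape", sim$truth$param_index),
                         score = sim$truth$reads,
                         strand = sim$truth$orientation)
  write_bed(truth_iv, file.path(run_dir, "truth.bed"))
  write_tss_table(ann$tss, file.path(run_dir, "tss.tsv"))
  for (nm in names(ann$intervals))
    write_bed(ann$intervals[[nm]], file.path(run_dir,
                                             paste0("annot_", nm, ".bed")))
  write_manifest(run_dir, "simulate", config, character(0),
                 c("pol2.bedGraph", "h3k4.bedGraph", "truth.bed", "tss.tsv"))
}

load_binned_tracks <- function(config, run_dir) {
  p1 <- need_artifact(run_dir, "pol2.bedGraph", "simulate")
  p2 <- need_artifact(run_dir, "h3k4.bedGraph", "simulate")
  # simulate writes bin-resolution bedGraph; mean-rebinning recovers the bins
  pol2 <- bin_coverage(read_coverage(p1), config$bin_width, agg = "mean")
  h3k4 <- bin_coverage(read_coverage(p2), config$bin_width, agg = "mean")
  list(pol2 = pol2, h3k4 = h3k4)
}

stage_preprocess <- function(config, run_dir) {
  tr <- load_binned_tracks(config, run_dir)
  tss <- read_tss_table(need_artifact(run_dir, "tss.tsv", "simulate"))
  pp <- preprocess_profiles(tr$pol2, tr$h3k4, tss,
                            half_bins = config$half_bins,
                            smooth_window = config$smooth_window,
                            min_gap = config$min_gap,
                            min_max_count = config$min_max_count,
                            variance_pct = config$variance_pct)
  prof <- pp$profiles
  tab <- cbind(prof$tss,
               stats::setNames(as.data.frame(prof$y1),
                               paste0("y1_", seq_len(ncol(prof$y1)))),
               stats::setNames(as.data.frame(prof$y2),
                               paste0("y2_", seq_len(ncol(prof$y2)))))
  utils::write.table(tab, file.path(run_dir, "profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(pp$report),
                       file.path(run_dir, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(run_dir, "preprocess", config,
                 c("pol2.bedGraph", "h3k4.bedGraph", "tss.tsv"),
                 c("profiles.tsv", "filter_report.json"))
}

load_profiles <- function(config, run_dir) {
  p <- need_artifact(run_dir, "profiles.tsv", "preprocess")
  tab <- utils::read.table(p, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  m <- 2L * config$half_bins + 1L
  structure(list(tss = tab[c("chrom", "pos", "strand", "gene_id")],
                 y1 = as.matrix(tab[paste0("y1_", seq_len(m))]),
                 y2 = as.matrix(tab[paste0("y2_", seq_len(m))]),
                 skipped = tab[0, c("chrom", "pos", "strand", "gene_id")],
                 bin_width = config$bin_width,
                 half_bins = config$half_bins),
            class = "tss_profiles")
}

stage_cluster <- function(config, run_dir) {
  prof <- load_profiles(config, run_dir)
  mat <- profile_matrix(prof)
  cl <- if (length(config$k_range) > 1)
    select_k(mat, config$k_range, seed = config$seed + 1L,
             n_init = config$n_init)
  else kmeans_correlation(mat, config$k_range, n_init = config$n_init,
                          seed = config$seed + 1L)
  jsonlite::write_json(list(k = cl$k, labels = cl$labels,
                            silhouette = cl$silhouette,
                            withinss = cl$withinss, seed = cl$seed,
                            silhouette_by_k = as.list(cl$silhouette_by_k)),
                       file.path(run_dir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(cl$centroids, file.path(run_dir, "centroids.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_manifest(run_dir, "cluster", config, "profiles.tsv",
                 c("clusters.json", "centroids.tsv"))
}

stage_fit <- function(config, run_dir) {
  prof <- load_profiles(config, run_dir)
  cj <- jsonlite::read_json(need_artifact(run_dir, "clusters.json", "cluster"),
                            simplifyVector = TRUE)
  assignment <- structure(list(labels = as.integer(cj$labels), k = cj$k,
                               centroids = NULL, withinss = cj$withinss,
                               silhouette = cj$silhouette, seed = cj$seed),
                          class = "signature_clusters")
  models <- fit_signature_models(assignment, prof, seed = config$seed + 2L,
                                 n_starts = config$n_starts,
                                 max_evals = config$max_evals,
                                 max_iters = config$max_iters,
                                 step_tol = config$step_tol,
                                 ftol = config$ftol)
  js <- lapply(models, function(m) list(
    cluster_id = m$cluster_id, n_members = m$n_members,
    degenerate = m$degenerate,
    pol2 = c(unclass(m$fit_pol2$params),
             list(objective = m$fit_pol2$objective,
                  stop_reason = m$fit_pol2$stop_reason,
                  n_evals = m$fit_pol2$n_evals)),
    h3k4 = c(unclass(m$fit_h3k4$params),
             list(objective = m$fit_h3k4$objective,
                  stop_reason = m$fit_h3k4$stop_reason,
                  n_evals = m$fit_h3k4$n_evals))))
  jsonlite::write_json(js, file.path(run_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tmpl <- do.call(rbind, lapply(models, function(m) m$template))
  utils::write.table(tmpl, file.path(run_dir, "templates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_manifest(run_dir, "fit", config, c("profiles.tsv", "clusters.json"),
                 c("models.json", "templates.tsv"))
}

load_models <- function(config, run_dir) {
  js <- jsonlite::read_json(need_artifact(run_dir, "models.json", "fit"),
                            simplifyVector = FALSE)
  grid <- -config$half_bins:config$half_bins
  lapply(js, function(rec) {
    mk <- function(side)
      mixture_params(pi = unlist(side$pi), mu = unlist(side$mu),
                     beta = unlist(side$beta), a = side$a, b = side$b)
    p1 <- mk(rec$pol2); p2 <- mk(rec$h3k4)
    s1 <- standardize_segment(mixture_grid_probs(p1, grid))
    s2 <- standardize_segment(mixture_grid_probs(p2, grid))
    structure(list(cluster_id = rec$cluster_id,
                   fit_pol2 = list(params = p1),
                   fit_h3k4 = list(params = p2),
                   template = c(as.numeric(s1), as.numeric(s2)),
                   n_members = rec$n_members,
                   degenerate = isTRUE(rec$degenerate), grid = grid),
              class = "signature_model")
  })
}

stage_scan <- function(config, run_dir) {
  # scanning runs on the raw binned counts: smoothing is a clustering aid,
  # and the permutation null is only calibrated for unsmoothed windows
  # (permuting a smoothed window would destroy its autocorrelation)
  tr <- load_binned_tracks(config, run_dir)
  prof <- load_profiles(config, run_dir)
  models <- load_models(config, run_dir)
  null <- permutation_null(prof, models, n_perm = config$n_perm,
                           seed = config$seed + 3L,
                           pct = config$threshold_pct,
                           scan_both_orientations = config$scan_both_orientations)
  cp <- scan_genome(tr$pol2, tr$h3k4, models, stride = config$stride,
                    scan_both_orientations = config$scan_both_orientations)
  regions <- call_regions(cp, null$threshold_z, merge_gap = config$merge_gap)
  jsonlite::write_json(list(threshold_z = null$threshold_z,
                            n_perm = null$n_perm, pct = null$pct,
                            seed = null$seed,
                            null_mean = mean(null$correlations),
                            null_sd = stats::sd(null$correlations)),
                       file.path(run_dir, "null.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_regions(regions, file.path(run_dir, "regions.bed"))
  write_manifest(run_dir, "scan", config,
                 c("pol2.bedGraph", "h3k4.bedGraph", "profiles.tsv",
                   "models.json"),
                 c("null.json", "regions.bed", "regions.bed.tsv"))
}

stage_annotate <- function(config, run_dir) {
  regions <- utils::read.table(need_artifact(run_dir, "regions.bed.tsv",
                                             "scan"),
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  tss <- read_tss_table(need_artifact(run_dir, "tss.tsv", "simulate"))
  cat_cfg <- list(RefSeq_promoter = tss)
  for (nm in c("EST", "CpG", "CTCF")) {
    p <- file.path(run_dir, paste0("annot_", nm, ".bed"))
    if (file.exists(p)) cat_cfg[[nm]] <- read_intervals(p, nm)
  }
  catalog <- suppressWarnings(build_catalog(cat_cfg))
  res <- annotate_hierarchical(regions, catalog)
  utils::write.table(res$regions, file.path(run_dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(hierarchical = as.list(res$hierarchical_counts),
                            independent = as.list(res$independent_counts)),
                       file.path(run_dir, "annotation_counts.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(run_dir, "annotate", config,
                 c("regions.bed.tsv", "tss.tsv"),
                 c("annotation.tsv", "annotation_counts.json"))
}
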