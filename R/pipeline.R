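#' Configuration for a full disparity analysis
#'
#' Collects every tunable of the pipeline with an explicit default. The
#' resolved configuration is serialised verbatim into the run manifest, so a
#' results bundle always records exactly how it was produced.
#'
#' @param matrix_path path to a NEXUS/CSV character matrix (`NULL` when
#'   using `preset`).
#' @param groups_path path to the taxon,group CSV.
#' @param groups_of_interest group labels the disparity stages compare
#'   (`NULL`: all groups in the assignment file).
#' @param preset name of a built-in synthetic dataset (`"study-shape"`,
#'   the 19-taxon stand-in from [synthetic_study_matrix()]); ignored when
#'   `matrix_path` is given.
#' @param method,polymorphism_rule dissimilarity settings
#'   (see [pairwise_dissimilarity()]).
#' @param outlier_threshold maximum unscored-cell fraction per taxon
#'   (see [filter_outliers()]).
#' @param correction PCoA negative-eigenvalue correction
#'   (see [pcoa_ordination()]).
#' @param axes number of ordination axes for all downstream stages (`NULL`:
#'   Broken-Stick retained count).
#' @param metric disparity metric (see [jackknife_disparity()]).
#' @param iterations jackknife and permutation iterations.
#' @param subsample_size jackknife subsample size (`NULL`: smallest group).
#' @param hv_samples,hv_quantile,hv_bandwidth,hv_random_points hypervolume
#'   settings (see [estimate_hypervolume()]).
#' @param kmeans_range candidate cluster counts.
#' @param dedup_tolerance merge threshold for duplicated taxa before
#'   neighbour joining.
#' @param seed master seed; each stochastic stage receives a deterministic
#'   child seed so stages can be re-run in isolation.
#' @param output_dir directory for the results bundle (`NULL`: keep results
#'   in memory only).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_path = NULL, groups_path = NULL,
                            groups_of_interest = NULL,
                            preset = "study-shape",
                            method = "mord", polymorphism_rule = "min",
                            outlier_threshold = 0.75,
                            correction = "none", axes = NULL,
                            metric = "ranges", iterations = 5000,
                            subsample_size = NULL,
                            hv_samples = 10000, hv_quantile = 0.05,
                            hv_bandwidth = NULL, hv_random_points = 1000,
                            kmeans_range = 2:6, dedup_tolerance = 0,
                            seed = 1, output_dir = NULL) {
  structure(
    list(matrix_path = matrix_path, groups_path = groups_path,
         groups_of_interest = groups_of_interest, preset = preset,
         method = method, polymorphism_rule = polymorphism_rule,
         outlier_threshold = outlier_threshold,
         correction = correction, axes = axes,
         metric = metric, iterations = iterations,
         subsample_size = subsample_size,
         hv_samples = hv_samples, hv_quantile = hv_quantile,
         hv_bandwidth = hv_bandwidth, hv_random_points = hv_random_points,
         kmeans_range = kmeans_range, dedup_tolerance = dedup_tolerance,
         seed = as.integer(seed), output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path a `.yaml`/`.yml` or `.json` file of configuration fields.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  fields <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(fields), names(formals(pipeline_config)))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, fields)
}

# deterministic child seeds so stages can be re-run in isolation
stage_seed <- function(config, stage_index) {
  (config$seed * 101L + stage_index * 7919L) %% 2147483647L
}

#' Run the full disparity pipeline
#'
#' Executes load -> outlier filter -> dissimilarity -> PCoA -> jackknife +
#' permutation disparity -> hypervolumes (volumes, Sorensen-Dice overlaps,
#' centroids, inclusion tests for ungrouped taxa) -> clustering
#' (neighbour-joining phenogram, k-means assessment), collecting a
#' machine-readable results bundle. Rerunning with the same configuration
#' and seed reproduces the bundle exactly. Any stage failure aborts with the
#' stage name; when `output_dir` is set, tables, the Newick tree and a JSON
#' manifest are written there (a partial manifest on failure).
#'
#' @param config a [pipeline_config()].
#' @return an object of class `disparity_pipeline`: list with `config`,
#'   `data` (matrix, grouping, removed outliers), `dissimilarity`,
#'   `ordination`, `disparity`, `hypervolume` (models, volumes, overlap
#'   table, centroids, centroid distances, inclusion tests, skipped groups),
#'   `clustering` (tree, merges, k-means) and `manifest`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(preset = "study-shape", iterations = 100,
#'                        hv_samples = 2000, seed = 1)
#' run <- run_pipeline(cfg)
#' run$ordination$n_retained
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  results <- list(config = config)
  log <- list()
  t_start <- Sys.time()

  run_stage <- function(name, idx, fun) {
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e) {
      log[[name]] <<- list(status = "error", message = conditionMessage(e))
      if (!is.null(config$output_dir)) {
        write_manifest(results, log, config, failed_stage = name)
      }
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log[[name]] <<- list(status = "ok",
                         elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
    out
  }

  # -- load ------------------------------------------------------------------
  results$data <- run_stage("load", 1L, function() {
    if (!is.null(config$matrix_path)) {
      mat <- read_matrix(config$matrix_path)
      if (is.null(config$groups_path)) {
        stop("a matrix file needs an accompanying groups file")
      }
      grouping <- read_groups(config$groups_path,
                              groups_of_interest = config$groups_of_interest)
      check_grouping_against(grouping, taxon_labels(mat))
      list(matrix = mat, grouping = grouping, preset = NULL)
    } else if (identical(config$preset, "study-shape")) {
      sim <- synthetic_study_matrix(seed = stage_seed(config, 1L))
      list(matrix = sim$matrix, grouping = sim$grouping, truth = sim$truth,
           preset = config$preset)
    } else {
      stop("no matrix_path and unknown preset: ", config$preset)
    }
  })

  # -- outlier filter --------------------------------------------------------
  results$data <- run_stage("filter", 2L, function() {
    d <- results$data
    flt <- filter_outliers(d$matrix, config$outlier_threshold)
    kept <- taxon_labels(flt$matrix)
    assignment <- d$grouping$assignment[names(d$grouping$assignment) %in% kept]
    d$grouping <- taxon_grouping(assignment,
                                 groups_of_interest = d$grouping$groups_of_interest)
    d$matrix <- flt$matrix
    d$removed <- flt$removed
    d
  })

  # -- dissimilarity ---------------------------------------------------------
  results$dissimilarity <- run_stage("dissimilarity", 3L, function() {
    D <- pairwise_dissimilarity(results$data$matrix, method = config$method,
                                polymorphism_rule = config$polymorphism_rule)
    require_complete(D, "the pipeline")
    D
  })

  # -- ordination ------------------------------------------------------------
  results$ordination <- run_stage("ordination", 4L, function() {
    suppressWarnings(pcoa_ordination(results$dissimilarity,
                                     correction = config$correction))
  })
  axes <- if (is.null(config$axes)) results$ordination$n_retained else config$axes

  # -- disparity -------------------------------------------------------------
  results$disparity <- run_stage("disparity", 5L, function() {
    jackknife_disparity(results$ordination, results$data$grouping,
                        metric = config$metric,
                        iterations = config$iterations,
                        subsample_size = config$subsample_size,
                        axes = axes, seed = stage_seed(config, 5L))
  })

  # -- hypervolume -----------------------------------------------------------
  results$hypervolume <- run_stage("hypervolume", 6L, function() {
    grouping <- results$data$grouping
    hv <- group_hypervolumes(results$ordination, grouping, axes = axes,
                             seed = stage_seed(config, 6L),
                             bandwidth = config$hv_bandwidth,
                             threshold_quantile = config$hv_quantile,
                             n_samples = config$hv_samples,
                             n_random_points = config$hv_random_points)
    overlaps <- if (length(hv$models) >= 2) overlap_table(hv$models) else NULL
    centroids <- group_centroids(results$ordination, grouping, axes = axes)
    cdist <- if (nrow(centroids) >= 2) centroid_distances(centroids) else NULL
    co <- ord_coordinates(results$ordination, axes)
    grouped <- names(grouping$assignment)[grouping$assignment %in%
                                            grouping$groups_of_interest]
    queries <- setdiff(rownames(co), grouped)
    inclusion <- NULL
    if (length(queries) && length(hv$models)) {
      inclusion <- vapply(hv$models, function(m) {
        inclusion_test(m, co[queries, , drop = FALSE])
      }, logical(length(queries)))
      inclusion <- matrix(inclusion, nrow = length(queries),
                          dimnames = list(queries, names(hv$models)))
    }
    list(models = hv$models, skipped = hv$skipped,
         volumes = vapply(hv$models, function(m) m$volume, numeric(1)),
         overlaps = overlaps, centroids = centroids,
         centroid_distances = cdist, inclusion = inclusion)
  })

  # -- clustering ------------------------------------------------------------
  results$clustering <- run_stage("clustering", 7L, function() {
    dd <- deduplicate(results$dissimilarity, tolerance = config$dedup_tolerance)
    tree <- if (nrow(dd$D$values) >= 3) neighbour_joining(dd$D) else NULL
    co <- ord_coordinates(results$ordination, axes)
    km <- NULL
    k_range <- config$kmeans_range[config$kmeans_range < nrow(co)]
    if (length(k_range)) {
      km <- kmeans_assessment(co, k_range = k_range,
                              seed = stage_seed(config, 7L))
    }
    list(tree = tree, merges = dd$merges, kmeans = km)
  })

  results$manifest <- list(
    package = "lobomorph",
    version = as.character(utils::packageVersion("lobomorph")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    axes_used = axes,
    started = format(t_start, "%Y-%m-%d %H:%M:%S"),
    stages = log
  )
  class(results) <- "disparity_pipeline"

  if (!is.null(config$output_dir)) write_bundle(results)
  results
}

#' @export
print.disparity_pipeline <- function(x, ...) {
  cat("Disparity pipeline run\n")
  cat(sprintf("  taxa: %d (after outlier filter), characters: %d\n",
              n_taxa(x$data$matrix), n_characters(x$data$matrix)))
  cat(sprintf("  dissimilarity: %s; Broken-Stick retained axes: %d; axes used: %d\n",
              x$dissimilarity$method, x$ordination$n_retained,
              x$manifest$axes_used))
  print(x$disparity$summary, digits = 4)
  if (!is.null(x$hypervolume$overlaps)) {
    cat("Sorensen-Dice overlaps:\n")
    print(x$hypervolume$overlaps, digits = 4)
  }
  if (!is.null(x$clustering$kmeans)) {
    cat(sprintf("k-means best k: %d\n", x$clustering$kmeans$best_k))
  }
  invisible(x)
}

write_manifest <- function(results, log, config, failed_stage = NULL) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- results$manifest
  if (is.null(manifest)) {
    manifest <- list(package = "lobomorph", seed = config$seed, stages = log)
  }
  if (!is.null(failed_stage)) manifest$failed_stage <- failed_stage
  manifest$config <- config_as_list(config)
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(NULL)
}

config_as_list <- function(config) {
  lapply(unclass(config), function(v) if (is.null(v)) NA else v)
}

write_bundle <- function(results) {
  config <- results$config
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_matrix(results$data$matrix, file.path(out, "matrix.nex"))
  write_groups(results$data$grouping, file.path(out, "groups.csv"))
  write_distances(results$dissimilarity, file.path(out, "dissimilarity.csv"))
  write_ordination(results$ordination, file.path(out, "ordination.csv"))
  write_eigenvalues(results$ordination, file.path(out, "eigenvalues.csv"))
  write_disparity(results$disparity, file.path(out, "disparity.csv"),
                  replicates_path = file.path(out, "disparity_replicates.csv"))
  if (length(results$hypervolume$models)) {
    write_hypervolumes(results$hypervolume$models,
                       file.path(out, "hypervolumes.csv"))
  }
  if (!is.null(results$hypervolume$overlaps)) {
    ov <- results$hypervolume$overlaps
    ov[, -(1:2)] <- signif(ov[, -(1:2)], 6)
    utils::write.csv(ov, file.path(out, "overlap.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(results$hypervolume$centroid_distances)) {
    cd <- data.frame(group = rownames(results$hypervolume$centroid_distances),
                     signif(results$hypervolume$centroid_distances, 6),
                     check.names = FALSE)
    utils::write.csv(cd, file.path(out, "centroid_distances.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(results$clustering$tree)) {
    write_newick(results$clustering$tree, file.path(out, "nj_tree.nwk"))
  }
  if (!is.null(results$clustering$kmeans)) {
    write_kmeans(results$clustering$kmeans, file.path(out, "kmeans.csv"))
  }
  write_manifest(results, results$manifest$stages, config)
  invisible(out)
}
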