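#' Benchmark configuration
#'
#' The full study grid: edge densities x sample sizes x estimators x
#' discretizations, with one ensemble of `n_datasets` datasets per
#' (density, sample size) cell. Defaults are the package's study
#' conditions; every knob is open.
#'
#' @param n_genes Genes per network.
#' @param edge_densities Numeric vector of ER edge densities.
#' @param sample_sizes Integer vector of dataset sample sizes.
#' @param n_datasets Ensemble size per cell.
#' @param estimators Subset of [mi_estimators()].
#' @param discretizations Subset of
#'   `c("equal_frequency", "equal_width", "global_equal_width")`.
#' @param noise_sd,interaction_strength Simulator settings.
#' @param alpha,correction,n_permutations C3NET significance settings.
#' @param d_max Chain/hub class boundary for the local error measure.
#' @param seed Base seed for the whole run.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(n_genes = 100,
                             edge_densities = c(0.005, 0.01, 0.02),
                             sample_sizes = c(50, 100, 200, 500),
                             n_datasets = 30,
                             estimators = mi_estimators(),
                             discretizations = c("equal_frequency",
                                                 "equal_width",
                                                 "global_equal_width"),
                             noise_sd = 0.05, interaction_strength = 1,
                             alpha = 0.05,
                             correction = "benjamini_hochberg",
                             n_permutations = 5000L, d_max = 4L,
                             seed = 1L) {
  if (length(estimators) == 0L || length(discretizations) == 0L ||
      length(edge_densities) == 0L || length(sample_sizes) == 0L) {
    stop("all grids must be nonempty", call. = FALSE)
  }
  estimators <- vapply(estimators, match.arg, character(1),
                       choices = mi_estimators())
  discretizations <- vapply(discretizations, match.arg, character(1),
                            choices = c("equal_frequency", "equal_width",
                                        "global_equal_width"))
  structure(list(n_genes = n_genes, edge_densities = edge_densities,
                 sample_sizes = as.integer(sample_sizes),
                 n_datasets = as.integer(n_datasets),
                 estimators = unname(estimators),
                 discretizations = unname(discretizations),
                 noise_sd = noise_sd,
                 interaction_strength = interaction_strength,
                 alpha = alpha, correction = correction,
                 n_permutations = as.integer(n_permutations),
                 d_max = as.integer(d_max), seed = as.integer(seed)),
            class = "benchmark_config")
}

#' Read a benchmark configuration from a flat YAML file
#'
#' Keys mirror the arguments of [benchmark_config()]; absent keys fall
#' back to the defaults. An example ships at
#' `system.file("extdata", "example_benchmark_config.yaml",
#' package = "mibench")`.
#'
#' @param path Path to the YAML file.
#' @return A [benchmark_config()].
#' @export
read_benchmark_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(benchmark_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(benchmark_config, raw)
}

cell_seed <- function(config, density, n_samples) {
  # distinct, stable seed per (density, n_samples) cell, independent of
  # grid ordering; kept well inside the 32-bit integer range
  di <- match(density, config$edge_densities)
  si <- match(n_samples, config$sample_sizes)
  config$seed + 10000L * di + 100L * si
}

#' Run the full benchmark grid
#'
#' One reference network is drawn per edge density and reused across all
#' sample sizes, so sample-size effects are paired on the same topology.
#' For every (density, sample size) cell an ensemble is simulated from
#' that network, and for every dataset and every
#' (estimator, discretization) combination the MI matrix is computed,
#' C3NET run, and the all-pairs MI ranking scored by AUC-PR. Ensemble
#' members are then aggregated per combination into a weighted network
#' and the reference edges' TPRs split by chain/hub class. Everything is
#' seeded from `config$seed`, so the same configuration reproduces the
#' records exactly.
#'
#' @param config A [benchmark_config()].
#' @param output_dir Optional directory; when given, per-dataset records
#'   (`records.tsv`), class TPRs (`class_tpr.tsv`) and a JSON manifest of
#'   seeds are written there, and cells already present in `records.tsv`
#'   are skipped on re-run (resumability by condition key).
#' @param verbose Print one progress line per cell.
#' @return List with `records` (tibble: density, n_samples, estimator,
#'   discretization, dataset, seed, auc_pr, n_edges_inferred) and
#'   `class_tpr` (tibble: density, n_samples, estimator, discretization,
#'   gene_a, gene_b, edge_class, tpr).
#' @export
run_benchmark <- function(config, output_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "benchmark_config"))
  rec_path <- if (!is.null(output_dir)) file.path(output_dir, "records.tsv")
  tpr_path <- if (!is.null(output_dir)) file.path(output_dir, "class_tpr.tsv")
  done <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(output_dir)) stop("cannot create output directory",
                                      call. = FALSE)
    if (file.exists(rec_path)) {
      done <- readr::read_tsv(rec_path, col_types = readr::cols())
    }
    if (file.exists(tpr_path)) {
      done_tpr <- readr::read_tsv(tpr_path, col_types = readr::cols())
    } else {
      done_tpr <- NULL
    }
  }
  grid <- tidyr::expand_grid(density = config$edge_densities,
                             n_samples = config$sample_sizes)
  records <- list()
  tprs <- list()
  for (g in seq_len(nrow(grid))) {
    density <- grid$density[g]
    n_samples <- grid$n_samples[g]
    seed_cell <- cell_seed(config, density, n_samples)
    if (!is.null(done) &&
        any(done$density == density & done$n_samples == n_samples)) {
      if (verbose) message(sprintf(
        "cell density=%g N=%d: found in %s, skipping", density, n_samples,
        rec_path))
      records[[g]] <- dplyr::filter(done, .data$density == !!density,
                                    .data$n_samples == !!n_samples)
      if (!is.null(done_tpr)) {
        tprs[[length(tprs) + 1L]] <- dplyr::filter(
          done_tpr, .data$density == !!density, .data$n_samples == !!n_samples)
      }
      next
    }
    if (verbose) message(sprintf(
      "cell density=%g N=%d (seed %d): simulating %d datasets",
      density, n_samples, seed_cell, config$n_datasets))
    # one network per density, shared by all sample sizes of that density
    net_seed <- config$seed + 10000L * match(density, config$edge_densities)
    network <- sample_er_network(config$n_genes, density, seed = net_seed)
    dnet <- orient_for_simulation(network, seed = net_seed)
    ens <- list(
      network = network,
      datasets = lapply(seq_len(config$n_datasets), function(i) {
        simulate_expression(dnet, n_samples, config$noise_sd,
                            config$interaction_strength,
                            seed = seed_cell + i)
      }))
    classes <- degree_scores_and_classes(ens$network, config$d_max)
    combos <- tidyr::expand_grid(estimator = config$estimators,
                                 discretization = config$discretizations)
    cell_rec <- list()
    for (ci in seq_len(nrow(combos))) {
      est <- combos$estimator[ci]
      disc <- combos$discretization[ci]
      scheme <- binning_scheme(disc)
      inferred <- vector("list", config$n_datasets)
      rr <- vector("list", config$n_datasets)
      for (k in seq_len(config$n_datasets)) {
        ds <- ens$datasets[[k]]
        mi <- mi_matrix(ds, est, scheme)
        null <- permutation_null(ds, est, scheme, config$n_permutations,
                                 seed = seed_cell + k)
        sig <- edge_significance(mi, null, config$alpha, config$correction)
        inferred[[k]] <- c3net_infer(mi, sig)
        scored <- dplyr::rename(tidy(mi), score = "mi")
        cell_auc <- if (nrow(ens$network$edges) > 0) {
          auc_pr(precision_recall_curve(scored, ens$network))
        } else NA_real_  # edgeless reference: recall undefined
        rr[[k]] <- tibble::tibble(
          density = density, n_samples = n_samples, estimator = est,
          discretization = disc, dataset = k, seed = seed_cell + k,
          auc_pr = cell_auc,
          n_edges_inferred = nrow(inferred[[k]]$edges))
      }
      cell_rec[[ci]] <- dplyr::bind_rows(rr)
      ct <- classwise_tpr(ensemble_network(inferred), ens$network, classes)
      tprs[[length(tprs) + 1L]] <- dplyr::mutate(
        ct, density = density, n_samples = n_samples, estimator = est,
        discretization = disc, .before = 1L)
    }
    records[[g]] <- dplyr::bind_rows(cell_rec)
  }
  records <- dplyr::bind_rows(records)
  class_tpr <- dplyr::bind_rows(tprs)
  if (!is.null(output_dir)) {
    readr::write_tsv(records, rec_path)
    if (nrow(class_tpr) > 0) readr::write_tsv(class_tpr, tpr_path)
    manifest <- list(
      package_version = as.character(utils::packageVersion("mibench")),
      base_seed = config$seed,
      cells = purrr::pmap(grid, function(density, n_samples) {
        list(density = density, n_samples = n_samples,
             seed = cell_seed(config, density, n_samples))
      }))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(records = records, class_tpr = class_tpr)
}

#' Summarize benchmark records per condition
#'
#' @param records The `records` tibble of [run_benchmark()] (per-dataset
#'   AUC-PR values).
#' @return Tibble with one row per (density, n_samples, estimator,
#'   discretization): median and interquartile range of AUC-PR, and the
#'   median inferred edge count.
#' @export
summarize_benchmark <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no records to summarize", call. = FALSE)
  }
  dplyr::summarise(
    dplyr::group_by(records, .data$density, .data$n_samples,
                    .data$estimator, .data$discretization),
    n_datasets = dplyr::n(),
    auc_pr_median = stats::median(.data$auc_pr),
    auc_pr_iqr = stats::IQR(.data$auc_pr),
    n_edges_median = stats::median(.data$n_edges_inferred),
    .groups = "drop")
}

#' Summarize class-wise TPRs per condition
#'
#' @param class_tpr The `class_tpr` tibble of [run_benchmark()].
#' @return Tibble with medians of the per-edge TPR for Class I and
#'   Class II edges per condition.
#' @export
summarize_class_tpr <- function(class_tpr) {
  if (is.null(class_tpr) || nrow(class_tpr) == 0L) {
    stop("no class TPR rows to summarize", call. = FALSE)
  }
  dplyr::summarise(
    dplyr::group_by(class_tpr, .data$density, .data$n_samples,
                    .data$estimator, .data$discretization,
                    .data$edge_class),
    n_edges = dplyr::n(),
    tpr_median = stats::median(.data$tpr),
    .groups = "drop")
}
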