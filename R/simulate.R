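#' Simulate steady-state expression data from a directed network
#'
#' Generates one dataset of steady-state expression values with known
#' ground truth. Per sample:
#'
#' * root genes (in-degree 0, including all unconnected genes) draw
#'   independent base activities from Uniform(0, 1) — bounded and
#'   non-Gaussian, so many simulated profiles reject normality, as real
#'   expression profiles do;
#' * every regulated gene is evaluated in topological order as a Hill-type
#'   saturating activation of its regulators' combined drive, plus
#'   additive Gaussian observation noise.
#'
#' Each arc carries an activator/repressor sign drawn once per arc with
#' probability 1/2. A repressing regulator contributes `1 - value`, an
#' activating one contributes `value`; the drive is the mean contribution,
#' optionally amplified around its midpoint by `interaction_strength` and
#' clipped to \[0, 1\], then passed through the Hill function
#' `h(u) = u^2 / (u^2 + 0.5^2)`. The map from a single activating
#' regulator to its target is therefore strictly increasing, which
#' downstream mutual-information estimation must detect despite its
#' nonlinearity.
#'
#' @param dnet A `directed_gene_network` from [orient_for_simulation()].
#' @param n_samples Number of samples (columns) to draw.
#' @param noise_sd Standard deviation of the additive Gaussian noise on the
#'   \[0, 1\] expression scale; default 0.05.
#' @param interaction_strength Linear gain on the regulator drive around
#'   0.5 before the Hill activation; 1 leaves the drive untouched.
#' @param seed Integer seed; the same call is bit-reproducible.
#' @return An `expression_dataset`: a numeric genes-by-samples matrix with
#'   gene ids as rownames, sample ids `s1..sN` as colnames, and attributes
#'   `seed` and `arc_signs`.
#' @examples
#' net <- sample_er_network(10, 0.05, seed = 3)
#' dnet <- orient_for_simulation(net, seed = 3)
#' x <- simulate_expression(dnet, n_samples = 20, seed = 3)
#' dim(x)
#' @export
simulate_expression <- function(dnet, n_samples, noise_sd = 0.05,
                                interaction_strength = 1, seed = 1L) {
  stopifnot(inherits(dnet, "directed_gene_network"))
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop("`n_samples` must be a positive count", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  n_samples <- as.integer(n_samples)
  ids <- dnet$gene_ids
  ord <- dnet$topo_order
  pos <- setNames(seq_along(ord), ord)
  if (nrow(dnet$arcs) > 0L && any(pos[dnet$arcs$regulator] >= pos[dnet$arcs$target])) {
    stop("`dnet` is not acyclic under its stored topological order",
         call. = FALSE)
  }
  regs <- split(dnet$arcs$regulator, dnet$arcs$target)

  values <- withr::with_seed(seed, {
    signs <- setNames(sample(c(1, -1), nrow(dnet$arcs), replace = TRUE),
                      paste(dnet$arcs$regulator, dnet$arcs$target))
    m <- matrix(NA_real_, length(ids), n_samples,
                dimnames = list(ids, paste0("s", seq_len(n_samples))))
    for (g in ord) {
      r <- regs[[g]]
      if (is.null(r)) {
        m[g, ] <- stats::runif(n_samples)
      } else {
        s <- signs[paste(r, g)]
        contrib <- m[r, , drop = FALSE]
        contrib[s < 0, ] <- 1 - contrib[s < 0, ]
        u <- colMeans(contrib)
        u <- pmin(1, pmax(0, 0.5 + interaction_strength * (u - 0.5)))
        m[g, ] <- hill_activation(u) + stats::rnorm(n_samples, sd = noise_sd)
      }
    }
    attr(m, "arc_signs") <- signs
    m
  })
  attr(values, "seed") <- seed
  class(values) <- c("expression_dataset", class(values))
  values
}

# saturating activation, exponent 2, half-saturation 0.5; maps [0,1] -> [0,0.8]
hill_activation <- function(u, m = 2, k = 0.5) u^m / (u^m + k^m)

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples (seed %s)\n",
              nrow(x), ncol(x), format(attr(x, "seed"))))
  invisible(x)
}

#' @rdname simulate_expression
#' @param x An `expression_dataset`.
#' @param ... Unused.
#' @method tidy expression_dataset
#' @export
tidy.expression_dataset <- function(x, ...) {
  tibble::as_tibble(as.data.frame(unclass(x)), rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "expression")
}

#' Simulation configuration
#'
#' Bundles the knobs of one simulation condition. Defaults are the
#' package's study conditions: 100 genes, sparse connectivity, observation
#' noise 0.05 on the \[0, 1\] scale and 30 datasets per network.
#'
#' @param n_genes Number of genes.
#' @param edge_density Edge probability of the Erdos-Renyi network.
#' @param n_samples Samples per dataset.
#' @param n_datasets Number of datasets in the ensemble.
#' @param noise_sd Gaussian observation noise SD.
#' @param interaction_strength Regulator drive gain (see
#'   [simulate_expression()]).
#' @param seed Base seed; dataset `i` of an ensemble uses `seed + i`.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 100, edge_density = 0.01,
                              n_samples = 100, n_datasets = 30,
                              noise_sd = 0.05, interaction_strength = 1,
                              seed = 1L) {
  stopifnot(n_genes >= 1, edge_density >= 0, edge_density <= 1,
            n_samples >= 1, n_datasets >= 1, noise_sd >= 0)
  structure(list(n_genes = as.integer(n_genes), edge_density = edge_density,
                 n_samples = as.integer(n_samples),
                 n_datasets = as.integer(n_datasets), noise_sd = noise_sd,
                 interaction_strength = interaction_strength,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate an ensemble of datasets from one network
#'
#' Draws a single reference network, orients it once, and simulates
#' `n_datasets` independent datasets from that same network — the ensemble
#' design that makes per-edge true-positive rates estimable. Dataset `i`
#' uses seed `config$seed + i`, so any member can be regenerated alone.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `network` (the [gene_network] ground
#'   truth), `dnet` (its simulation orientation) and `datasets` (list of
#'   `expression_dataset`).
#' @export
generate_ensemble <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  network <- sample_er_network(config$n_genes, config$edge_density,
                               seed = config$seed)
  dnet <- orient_for_simulation(network, seed = config$seed)
  datasets <- purrr::map(seq_len(config$n_datasets), function(i) {
    simulate_expression(dnet, config$n_samples, config$noise_sd,
                        config$interaction_strength,
                        seed = config$seed + i)
  })
  list(network = network, dnet = dnet, datasets = datasets)
}

#' Read and write expression matrices
#'
#' Tab-separated genes-by-samples matrix: first column `gene_id`, header
#' row of sample ids.
#'
#' @param dataset An `expression_dataset` or plain numeric matrix with
#'   gene rownames.
#' @param file Path of the TSV file.
#' @return `write_expression` returns its input invisibly;
#'   `read_expression` returns an `expression_dataset`.
#' @export
write_expression <- function(dataset, file) {
  df <- tibble::as_tibble(as.data.frame(unclass(dataset)),
                          rownames = "gene_id")
  readr::write_tsv(df, file)
  invisible(dataset)
}

#' @rdname write_expression
#' @export
read_expression <- function(file) {
  df <- readr::read_tsv(file, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()))
  m <- as.matrix(df[-1L])
  rownames(m) <- df$gene_id
  class(m) <- c("expression_dataset", class(m))
  m
}
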