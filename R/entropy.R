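#' Discrete entropy estimators
#'
#' Four plug-in style estimators of the Shannon entropy (in bits) of a
#' binned random variable, all operating on the same contingency table of
#' cell counts `n_k` with total `N`:
#'
#' * **empirical** — the maximum-likelihood estimate
#'   `H = -sum p_k log2 p_k` with `p_k = n_k / N`. Downward biased when
#'   cells are undersampled.
#' * **Miller-Madow** — adds the first-order bias correction
#'   `(Bhat - 1) / (2N)` nats, converted to bits, where `Bhat` is the
#'   number of occupied cells (set `nominal_bins = TRUE` to use the
#'   nominal cell count instead).
#' * **shrink** — James-Stein-type shrinkage of the cell probabilities
#'   toward the uniform target `t_k = 1/#cells` with data-driven
#'   intensity `lambda`, then the plug-in entropy of the regularized
#'   distribution.
#' * **Schurmann-Grassberger** — Bayesian posterior-mean cell
#'   probabilities under a Dirichlet prior with concentration
#'   `beta = 1/#cells` per cell, i.e. a single pseudocount spread over
#'   the table (`N + 1` total), then the plug-in entropy.
#'
#' Marginal entropies of a pair are computed from the row/column sums of
#' the joint table, never from a re-discretization, so
#' `I = H(X) + H(Y) - H(X, Y)` is internally consistent.
#'
#' @param table A `contingency_table` (or plain count matrix/vector).
#' @return Entropy in bits; `entropy_shrink` returns a list with elements
#'   `entropy` and `lambda`.
#' @examples
#' entropy_empirical(c(4, 4))        # 1 bit
#' entropy_miller_madow(c(4, 4))     # 1 + log2(e)/16
#' entropy_sg(c(8, 0))
#' entropy_shrink(c(9, 1))
#' @name entropy_estimators
NULL

#' @rdname entropy_estimators
#' @export
entropy_empirical <- function(table) {
  n <- ct_counts(table)
  total <- sum(n)
  if (total <= 0) stop("table total must be positive", call. = FALSE)
  p <- n[n > 0] / total
  -sum(p * log2(p))
}

#' @rdname entropy_estimators
#' @param nominal_bins Use the nominal number of cells instead of the
#'   occupied count in the Miller-Madow correction.
#' @export
entropy_miller_madow <- function(table, nominal_bins = FALSE) {
  n <- ct_counts(table)
  total <- sum(n)
  if (total <= 0) stop("table total must be positive", call. = FALSE)
  b_hat <- if (nominal_bins) length(n) else sum(n > 0)
  entropy_empirical(n) + (b_hat - 1) / (2 * total) * log2(exp(1))
}

#' @rdname entropy_estimators
#' @export
entropy_shrink <- function(table) {
  n <- ct_counts(table)
  total <- sum(n)
  if (total <= 1) stop("shrinkage needs a table total > 1", call. = FALSE)
  p_hat <- as.vector(n) / total
  target <- 1 / length(p_hat)
  denom <- (total - 1) * sum((target - p_hat)^2)
  lambda <- if (denom == 0) 1 else (1 - sum(p_hat^2)) / denom
  lambda <- min(1, max(0, lambda))
  p <- lambda * target + (1 - lambda) * p_hat
  p <- p[p > 0]
  list(entropy = -sum(p * log2(p)), lambda = lambda)
}

#' @rdname entropy_estimators
#' @export
entropy_sg <- function(table) {
  n <- ct_counts(table)
  total <- sum(n)
  if (total <= 0) stop("table total must be positive", call. = FALSE)
  beta <- 1 / length(n)
  p <- (as.vector(n) + beta) / (total + 1)
  -sum(p * log2(p))
}

#' Estimator registry
#'
#' @return Character vector of the four estimator names accepted wherever
#'   an `estimator` argument appears.
#' @export
mi_estimators <- function() {
  c("empirical", "miller_madow", "shrink", "schurmann_grassberger")
}

entropy_by_name <- function(table, estimator) {
  switch(estimator,
    empirical = entropy_empirical(table),
    miller_madow = entropy_miller_madow(table),
    shrink = entropy_shrink(table)$entropy,
    schurmann_grassberger = entropy_sg(table),
    stop("unknown estimator: ", estimator, call. = FALSE)
  )
}

mi_from_table <- function(table, estimator) {
  n <- ct_counts(table)
  entropy_by_name(rowSums(n), estimator) +
    entropy_by_name(colSums(n), estimator) -
    entropy_by_name(n, estimator)
}

#' Mutual information of two expression profiles
#'
#' Discretizes the pair under `scheme`, builds the joint contingency
#' table, and returns `I = H(X) + H(Y) - H(X, Y)` in bits with the chosen
#' entropy estimator applied to the joint table and its margins.
#' Bias-corrected estimators can return slightly negative values; these
#' are reported as computed (ranking downstream is unaffected).
#'
#' @param x,y Numeric vectors of equal length.
#' @param estimator One of [mi_estimators()].
#' @param scheme A [binning_scheme()].
#' @return Mutual information in bits.
#' @examples
#' x <- runif(200); y <- x + rnorm(200, sd = 0.1)
#' mutual_information(x, y, "miller_madow", binning_scheme("equal_width"))
#' @export
mutual_information <- function(x, y, estimator = "empirical",
                               scheme = binning_scheme()) {
  estimator <- match.arg(estimator, mi_estimators())
  d <- discretize_pair(x, y, scheme)
  mi_from_table(joint_counts(d$labels_x, d$labels_y, d$bins_x, d$bins_y),
                estimator)
}

#' Pairwise MI matrix of a dataset
#'
#' Computes mutual information for every unordered gene pair of a
#' genes-by-samples matrix. For the per-variable schemes each gene is
#' discretized once and labels reused across its pairs; the pooled-range
#' scheme is inherently pairwise. Diagonal is set to 0 by convention.
#'
#' @param dataset An `expression_dataset` or numeric matrix with gene
#'   rownames.
#' @inheritParams mutual_information
#' @return An `mi_matrix`: symmetric numeric matrix in bits with
#'   attributes `estimator` and `scheme`.
#' @export
mi_matrix <- function(dataset, estimator = "empirical",
                      scheme = binning_scheme()) {
  estimator <- match.arg(estimator, mi_estimators())
  m <- unclass(dataset)
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  ng <- nrow(m)
  ns <- ncol(m)
  b <- scheme_bins(scheme, ns)
  if (ns < b) stop("need at least B samples per gene", call. = FALSE)
  out <- matrix(0, ng, ng, dimnames = list(rownames(m), rownames(m)))
  if (scheme$method == "global_equal_width") {
    for (i in seq_len(ng - 1L)) {
      for (j in seq((i + 1L), ng)) {
        out[i, j] <- out[j, i] <-
          mutual_information(m[i, ], m[j, ], estimator, scheme)
      }
    }
  } else {
    labels <- matrix(0L, ng, ns)
    for (i in seq_len(ng)) {
      labels[i, ] <- if (scheme$method == "equal_frequency") {
        eqfreq_labels(m[i, ], b)
      } else {
        bin_by_breaks(m[i, ], seq(min(m[i, ]), max(m[i, ]),
                                  length.out = b + 1))
      }
    }
    for (i in seq_len(ng - 1L)) {
      for (j in seq((i + 1L), ng)) {
        tab <- joint_counts(labels[i, ], labels[j, ], b, b)
        out[i, j] <- out[j, i] <- mi_from_table(tab, estimator)
      }
    }
  }
  structure(out, estimator = estimator, scheme = scheme,
            class = c("mi_matrix", "matrix", "array"))
}

#' @export
print.mi_matrix <- function(x, ...) {
  cat(sprintf("<mi_matrix> %d genes, estimator = %s, method = %s\n",
              nrow(x), attr(x, "estimator"), attr(x, "scheme")$method))
  invisible(x)
}

#' Long tibble of the upper-triangle MI values
#'
#' @param x An `mi_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `gene_a`, `gene_b`, `mi` — one row per
#'   unordered gene pair, in canonical pair order.
#' @method tidy mi_matrix
#' @export
tidy.mi_matrix <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(gene_a = ids[idx[, 1L]], gene_b = ids[idx[, 2L]],
                 mi = unclass(x)[idx]) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Read and write MI matrices
#'
#' Square TSV with a `gene_id` first column and gene-id header row.
#'
#' @param mi An `mi_matrix` or named symmetric matrix.
#' @param file Path of the TSV file.
#' @export
write_mi_matrix <- function(mi, file) {
  df <- tibble::as_tibble(as.data.frame(unclass(mi)), rownames = "gene_id")
  readr::write_tsv(df, file)
  invisible(mi)
}

#' @rdname write_mi_matrix
#' @export
read_mi_matrix <- function(file) {
  df <- readr::read_tsv(file, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()))
  m <- as.matrix(df[-1L])
  rownames(m) <- df$gene_id
  structure(m, class = c("mi_matrix", "matrix", "array"))
}
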