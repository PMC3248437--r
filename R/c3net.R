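#' Pooled permutation null distribution of MI
#'
#' Builds a null sample of MI values under the hypothesis of no
#' association: repeatedly draw a random gene pair from the dataset,
#' permute the sample order of one profile (destroying any pairing while
#' preserving both marginals), and record the MI of the permuted pair.
#' The null values are pooled across pairs, which matches the pooled-null
#' spirit of the reference C3NET implementation and keeps the cost linear
#' in `n_permutations` rather than quadratic in genes.
#'
#' @param dataset An `expression_dataset` or numeric matrix with gene
#'   rownames.
#' @param estimator One of [mi_estimators()].
#' @param scheme A [binning_scheme()].
#' @param n_permutations Number of null draws (>= 100). The pooled null's
#'   smallest attainable p-value is `1/(n_permutations + 1)`, so after a
#'   multiple-testing correction over `n(n-1)/2` pairs the null must be
#'   large enough to resolve `alpha * k / m`-scale thresholds; the
#'   default suits networks up to a few hundred genes.
#' @param seed Integer seed; the same call returns the identical vector.
#' @return Numeric vector of `n_permutations` null MI values (bits).
#' @export
permutation_null <- function(dataset, estimator = "empirical",
                             scheme = binning_scheme(),
                             n_permutations = 5000L, seed = 1L) {
  estimator <- match.arg(estimator, mi_estimators())
  m <- unclass(dataset)
  stopifnot(is.matrix(m))
  if (n_permutations < 100L) {
    stop("`n_permutations` must be >= 100", call. = FALSE)
  }
  ns <- ncol(m)
  b <- scheme_bins(scheme, ns)
  if (ns < b) {
    stop("too few samples for the binning scheme", call. = FALSE)
  }
  ng <- nrow(m)
  if (ng < 2L) stop("need at least two genes", call. = FALSE)
  # permuting a profile's sample order permutes its bin labels (all three
  # schemes assign labels by value, and the pooled range of a pair is
  # permutation-invariant), so labels are computed once per gene/pair and
  # only the label vector is shuffled per draw
  pairwise <- scheme$method == "global_equal_width"
  labels <- if (!pairwise) {
    lapply(seq_len(ng), function(i) {
      d <- discretize_pair(m[i, ], m[i, ], scheme)
      d$labels_x
    })
  }
  withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(k) {
      ij <- sample.int(ng, 2L)
      if (pairwise) {
        d <- discretize_pair(m[ij[1L], ], m[ij[2L], ], scheme)
        lx <- d$labels_x
        ly <- d$labels_y
      } else {
        lx <- labels[[ij[1L]]]
        ly <- labels[[ij[2L]]]
      }
      mi_from_table(joint_counts(lx, ly[sample.int(ns)], b, b), estimator)
    }, numeric(1))
  })
}

#' Permutation p-values and significance mask for all gene pairs
#'
#' Each observed MI value is compared against the pooled null sample:
#' `p = (1 + #\{null >= observed\}) / (1 + n_null)` (the add-one
#' convention, so p is never 0). P-values are then adjusted over the
#' `n(n-1)/2` pairs and pairs with adjusted `p <= alpha` form the
#' significance mask.
#'
#' @param mi An `mi_matrix`.
#' @param null_samples Numeric vector from [permutation_null()].
#' @param alpha Significance level in (0, 1].
#' @param correction `"benjamini_hochberg"` (default), `"bonferroni"` or
#'   `"none"`.
#' @return A `significance_result` with symmetric matrices `p_values`
#'   (raw), `p_adjusted` and logical `mask`, plus the call settings.
#' @export
edge_significance <- function(mi, null_samples, alpha = 0.05,
                              correction = c("benjamini_hochberg",
                                             "bonferroni", "none")) {
  correction <- match.arg(correction)
  if (length(null_samples) == 0L) {
    stop("`null_samples` must be nonempty", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  }
  m <- unclass(mi)
  ids <- rownames(m)
  idx <- which(upper.tri(m))
  obs <- m[idx]
  null_sorted <- sort(null_samples)
  n_null <- length(null_sorted)
  # #{null >= obs} via binary search on the sorted null
  n_ge <- n_null - findInterval(obs, null_sorted, left.open = TRUE)
  p <- (1 + n_ge) / (1 + n_null)
  p_adj <- stats::p.adjust(p, method = switch(correction,
    benjamini_hochberg = "BH", bonferroni = "bonferroni", none = "none"))
  pm <- matrix(1, nrow(m), ncol(m), dimnames = dimnames(m))
  am <- pm
  pm[idx] <- p
  am[idx] <- p_adj
  pm[lower.tri(pm)] <- t(pm)[lower.tri(pm)]
  am[lower.tri(am)] <- t(am)[lower.tri(am)]
  mask <- am <= alpha
  diag(mask) <- FALSE
  structure(list(p_values = pm, p_adjusted = am, mask = mask,
                 alpha = alpha, correction = correction,
                 n_permutations = n_null),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf(
    "<significance_result> %d genes, %d significant pairs (%s, alpha = %g)\n",
    nrow(x$mask), sum(x$mask[upper.tri(x$mask)]), x$correction, x$alpha))
  invisible(x)
}

#' Conservative causal core (C3NET) network inference
#'
#' Step 2 and 3 of the C3NET algorithm: every gene nominates the single
#' pair with the highest MI among its *significant* pairs; the union of
#' nominations is the inferred network. A pair nominated by both
#' endpoints contributes one edge, so the network has at most as many
#' edges as genes. Genes with no significant pair contribute nothing.
#' Ties within a gene are broken toward the lexicographically smallest
#' partner id, making the result invariant under permutations of the
#' gene order.
#'
#' @param mi An `mi_matrix`.
#' @param sig A `significance_result` from [edge_significance()], or
#'   `NULL` to treat every pair as significant.
#' @return A [gene_network] of the inferred edges over the same gene
#'   universe.
#' @export
c3net_infer <- function(mi, sig = NULL) {
  m <- unclass(mi)
  ids <- rownames(m)
  mask <- if (is.null(sig)) {
    out <- matrix(TRUE, nrow(m), ncol(m))
    diag(out) <- FALSE
    out
  } else {
    stopifnot(identical(dim(sig$mask), dim(m)))
    sig$mask
  }
  # deterministic argmax: order partners lexicographically, pick first max
  ord <- order(ids)
  a <- character(0)
  b <- character(0)
  for (i in seq_along(ids)) {
    cand <- ord[mask[i, ord]]
    if (length(cand) == 0L) next
    j <- cand[which.max(m[i, cand])]
    a <- c(a, ids[i])
    b <- c(b, ids[j])
  }
  gene_network(ids, data.frame(gene_a = a, gene_b = b))
}
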