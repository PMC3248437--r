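#' Precision-recall curve against a reference network
#'
#' Sweeps a score threshold over candidate edges. For each distinct score
#' value theta (descending), pairs scoring `>= theta` are the predicted
#' edges; recall is `TP / (TP + FN)` with the denominator the full
#' reference edge count, precision is `TP / (TP + FP)`. One curve point
#' per distinct threshold. Candidate pairs missing from the reference
#' count as false positives when predicted; reference edges never scored
#' count as false negatives throughout.
#'
#' @param scored_pairs A data frame with columns `gene_a`, `gene_b`,
#'   `score` (one row per candidate pair; pair order within a row is
#'   irrelevant). [tidy.mi_matrix()] output with `mi` renamed to `score`,
#'   or any ranked edge list, fits.
#' @param reference A [gene_network] with at least one edge.
#' @return A `pr_curve`: tibble with columns `threshold`, `recall`,
#'   `precision`, carrying the reference edge count as attribute
#'   `n_positive`.
#' @examples
#' ref <- gene_network(c("a", "b", "c"),
#'                     data.frame(gene_a = "a", gene_b = "b"))
#' sc <- data.frame(gene_a = c("a", "a"), gene_b = c("b", "c"),
#'                  score = c(0.9, 0.2))
#' precision_recall_curve(sc, ref)
#' @export
precision_recall_curve <- function(scored_pairs, reference) {
  stopifnot(inherits(reference, "gene_network"))
  if (nrow(reference$edges) == 0L) {
    stop("`reference` must have at least one edge", call. = FALSE)
  }
  sp <- as.data.frame(scored_pairs)
  if (!all(c("gene_a", "gene_b", "score") %in% names(sp))) {
    stop("`scored_pairs` needs columns gene_a, gene_b, score",
         call. = FALSE)
  }
  if (!all(is.finite(sp$score))) stop("scores must be finite", call. = FALSE)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  truth_keys <- key(reference$edges$gene_a, reference$edges$gene_b)
  pair_keys <- key(sp$gene_a, sp$gene_b)
  if (anyDuplicated(pair_keys)) {
    stop("`scored_pairs` contains duplicate pairs", call. = FALSE)
  }
  n_pos <- length(truth_keys)
  o <- order(sp$score, decreasing = TRUE)
  scores <- sp$score[o]
  is_tp <- pair_keys[o] %in% truth_keys
  cum_tp <- cumsum(is_tp)
  cum_pred <- seq_along(scores)
  # last index of each distinct threshold block
  n <- length(scores)
  last <- c(which(scores[-n] != scores[-1L]), n)
  curve <- tibble::tibble(
    threshold = scores[last],
    recall = cum_tp[last] / n_pos,
    precision = cum_tp[last] / cum_pred[last]
  )
  structure(curve, n_positive = n_pos,
            class = c("pr_curve", class(curve)))
}

#' Area under a precision-recall curve
#'
#' Trapezoidal integration of precision over recall on the curve points
#' ordered by recall, anchored at recall 0 with the first point's
#' precision (avoiding the undefined 0/0 corner).
#'
#' @param curve A `pr_curve` from [precision_recall_curve()], or any data
#'   frame with `recall` and `precision` columns.
#' @return The area, in \[0, 1\].
#' @export
auc_pr <- function(curve) {
  cv <- as.data.frame(curve)
  stopifnot(nrow(cv) >= 1L, all(c("recall", "precision") %in% names(cv)))
  r <- c(0, cv$recall)
  p <- c(cv$precision[1L], cv$precision)
  sum(diff(r) * (p[-1L] + p[-length(p)]) / 2)
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> %d thresholds, AUC-PR = %.4f\n",
              nrow(x), auc_pr(x)))
  NextMethod()
}

#' @rdname precision_recall_curve
#' @param x A `pr_curve`.
#' @param ... Unused.
#' @method glance pr_curve
#' @export
glance.pr_curve <- function(x, ...) {
  tibble::tibble(n_thresholds = nrow(x),
                 n_positive = attr(x, "n_positive"),
                 auc_pr = auc_pr(x))
}

#' Aggregate an ensemble of inferred networks into a weighted network
#'
#' The weight of pair (i, j) is the fraction of ensemble members
#' containing that edge — the empirical probability that the edge is
#' present, i.e. the per-edge true positive rate when the members are
#' inferences on data from a known network.
#'
#' @param networks Nonempty list of [gene_network]s over the identical
#'   gene universe.
#' @return A `weighted_network`: tibble with columns `gene_a`, `gene_b`,
#'   `weight` for every pair seen in at least one member, plus attributes
#'   `gene_ids` and `ensemble_size`.
#' @export
ensemble_network <- function(networks) {
  if (length(networks) == 0L) stop("empty ensemble", call. = FALSE)
  ids <- networks[[1L]]$gene_ids
  ok <- vapply(networks, function(n) {
    inherits(n, "gene_network") && identical(n$gene_ids, ids)
  }, logical(1))
  if (!all(ok)) {
    stop("all networks must share the same gene universe", call. = FALSE)
  }
  k <- length(networks)
  counts <- purrr::map_dfr(networks, tidy) |>
    dplyr::count(.data$gene_a, .data$gene_b, name = "n_present")
  out <- dplyr::transmute(counts, .data$gene_a, .data$gene_b,
                          weight = .data$n_present / k) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  structure(out, gene_ids = ids, ensemble_size = k,
            class = c("weighted_network", class(out)))
}

#' Edge weight lookup including absent (weight-0) pairs
#'
#' @param weighted A `weighted_network`.
#' @param pairs Data frame with columns `gene_a`, `gene_b`.
#' @return Numeric vector of weights, 0 for pairs absent from every
#'   ensemble member.
#' @export
edge_weights <- function(weighted, pairs) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  w <- setNames(weighted$weight, key(weighted$gene_a, weighted$gene_b))
  out <- w[key(pairs$gene_a, pairs$gene_b)]
  out[is.na(out)] <- 0
  unname(out)
}

#' Degree score and chain/hub class of reference edges
#'
#' For each reference edge (i, j) the local score is
#' `D = deg(i) + deg(j)` in the reference network. Edges with
#' `D <= d_max` are Class I ("chain-like": both endpoints sparsely
#' connected), the rest Class II (attached to hubs). The minimum possible
#' D for a real edge is 2 (an isolated pair).
#'
#' @param reference A [gene_network].
#' @param d_max Class boundary; default 4, i.e. both endpoints of a
#'   Class I edge have degree at most 2 up to one spare.
#' @return An `edge_classification` tibble: `gene_a`, `gene_b`,
#'   `degree_score`, `edge_class` (factor `"I"`/`"II"`), with attribute
#'   `d_max`.
#' @export
degree_scores_and_classes <- function(reference, d_max = 4L) {
  stopifnot(inherits(reference, "gene_network"))
  e <- reference$edges
  deg <- table(factor(c(e$gene_a, e$gene_b), levels = reference$gene_ids))
  d <- as.vector(deg[e$gene_a] + deg[e$gene_b])
  out <- tibble::tibble(
    gene_a = e$gene_a, gene_b = e$gene_b,
    degree_score = as.integer(d),
    edge_class = factor(ifelse(d <= d_max, "I", "II"), levels = c("I", "II"))
  )
  structure(out, d_max = d_max,
            class = c("edge_classification", class(out)))
}

#' Per-class true positive rates of reference edges
#'
#' Splits the ensemble edge weights (per-edge TPRs) of the reference
#' edges by their chain/hub class.
#'
#' @param weighted A `weighted_network` aggregated from inferred networks.
#' @param reference The ground-truth [gene_network].
#' @param classes An `edge_classification` of `reference`; computed with
#'   default `d_max` when omitted.
#' @return Tibble with columns `gene_a`, `gene_b`, `edge_class`, `tpr` —
#'   one row per reference edge (an exact partition of the reference
#'   edge set).
#' @export
classwise_tpr <- function(weighted, reference, classes = NULL) {
  stopifnot(inherits(reference, "gene_network"))
  if (is.null(classes)) classes <- degree_scores_and_classes(reference)
  tibble::tibble(
    gene_a = classes$gene_a, gene_b = classes$gene_b,
    edge_class = classes$edge_class,
    tpr = edge_weights(weighted, classes)
  )
}

#' Write a weighted network as three-column TSV
#'
#' @param weighted A `weighted_network`.
#' @param file Output path.
#' @export
write_weighted_network <- function(weighted, file) {
  readr::write_tsv(tibble::as_tibble(weighted), file)
  invisible(weighted)
}
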