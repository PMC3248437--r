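#' Per-gene Anderson-Darling normality p-values
#'
#' Tests each gene's expression profile against the composite null of
#' normality with unknown mean and variance (Anderson-Darling test with
#' the small-sample p-value approximation). A constant profile has no
#' defined statistic; it is reported at the degenerate minimum p-value
#' with a warning, since a constant is as far from a normal sample as the
#' test can express.
#'
#' @param dataset An `expression_dataset` or numeric matrix with gene
#'   rownames; at least 8 samples.
#' @return Tibble with columns `gene_id`, `p_value`.
#' @export
gene_normality_pvalues <- function(dataset) {
  m <- unclass(dataset)
  stopifnot(is.matrix(m))
  if (ncol(m) < 8L) stop("need at least 8 samples", call. = FALSE)
  p <- vapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    if (stats::sd(v) == 0) {
      warning("constant profile for gene ", rownames(m)[i],
              "; degenerate minimum p-value reported", call. = FALSE)
      return(.Machine$double.xmin)
    }
    nortest::ad.test(v)$p.value
  }, numeric(1))
  tibble::tibble(gene_id = rownames(m), p_value = p)
}

#' Fraction of hypotheses rejected after multiplicity correction
#'
#' @param p_values Numeric vector of p-values (or a data frame with a
#'   `p_value` column, as returned by [gene_normality_pvalues()]).
#' @param alpha Significance level in (0, 1).
#' @param correction `"bonferroni"` (default here, following the
#'   normality audit), `"benjamini_hochberg"` or `"none"`.
#' @return The rejected fraction, in \[0, 1\].
#' @examples
#' rejection_fraction(c(0.001, rep(0.5, 9)), alpha = 0.05) # 0.1
#' @export
rejection_fraction <- function(p_values, alpha = 0.05,
                               correction = c("bonferroni",
                                              "benjamini_hochberg", "none")) {
  correction <- match.arg(correction)
  if (is.data.frame(p_values)) p_values <- p_values$p_value
  if (length(p_values) == 0L) stop("empty p-value vector", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  p_adj <- stats::p.adjust(p_values, method = switch(correction,
    bonferroni = "bonferroni", benjamini_hochberg = "BH", none = "none"))
  mean(p_adj <= alpha)
}

#' Stouffer combination of two p-values
#'
#' Transforms each p-value to a z-score, `z = qnorm(1 - p)`, averages
#' with weight `1/sqrt(2)` and maps back:
#' `p_comb = 1 - pnorm((z_i + z_j) / sqrt(2))`. One-sided so that two
#' small p-values (two strongly non-normal profiles) combine to a small
#' p-value. Vectorized over pairs. P-values of exactly 0 or 1 are clipped
#' into the open interval with a warning.
#'
#' @param p_i,p_j Numeric vectors of p-values in (0, 1).
#' @return Combined p-values.
#' @examples
#' combine_pair_pvalues(0.5, 0.5)    # 0.5
#' combine_pair_pvalues(0.05, 0.05)  # ~0.010
#' @export
combine_pair_pvalues <- function(p_i, p_j) {
  clip <- function(p) {
    if (any(p <= 0 | p >= 1)) {
      warning("p-values at 0 or 1 clipped into (0, 1)", call. = FALSE)
      p <- pmin(1 - 1e-15, pmax(1e-15, p))
    }
    p
  }
  z <- (stats::qnorm(1 - clip(p_i)) + stats::qnorm(1 - clip(p_j))) / sqrt(2)
  1 - stats::pnorm(z)
}

#' Two-sample Kolmogorov-Smirnov p-values for gene pairs
#'
#' Compares the expression distributions of the two genes of each pair,
#' without any distributional assumption — the generalization of the
#' normality audit. Ties (possible after discret-looking simulated
#' values) fall back on the asymptotic p-value silently.
#'
#' @param dataset An `expression_dataset` or numeric matrix.
#' @param pairs Data frame with columns `gene_a`, `gene_b`.
#' @return Tibble `gene_a`, `gene_b`, `p_value`.
#' @export
pair_distribution_pvalues <- function(dataset, pairs) {
  m <- unclass(dataset)
  stopifnot(is.matrix(m))
  pairs <- as.data.frame(pairs)
  if (!all(c(pairs$gene_a, pairs$gene_b) %in% rownames(m))) {
    stop("pair members must be dataset genes", call. = FALSE)
  }
  p <- vapply(seq_len(nrow(pairs)), function(k) {
    suppressWarnings(
      stats::ks.test(m[pairs$gene_a[k], ], m[pairs$gene_b[k], ])$p.value)
  }, numeric(1))
  tibble::tibble(gene_a = pairs$gene_a, gene_b = pairs$gene_b, p_value = p)
}

#' Accumulate TP and FP edge ranks over an ensemble
#'
#' For each dataset k the M pair p-values are ranked ascending (ties by
#' first occurrence in the canonical pair order, so ranks are a
#' permutation of 1..M). With `l_k = min(#TP_k, #FP_k)`, the `l_k`
#' best-ranked TP pairs and `l_k` best-ranked FP pairs each increment the
#' accumulator at their rank positions. Datasets with no TP or no FP
#' contribute nothing. By construction the two accumulators always hold
#' the same total mass, so their empirical CDFs are directly comparable.
#'
#' @param pvalue_list List (one element per dataset) of numeric vectors
#'   of length M — the combined pair p-values over all M pairs, in one
#'   fixed canonical pair order.
#' @param tp_list,fp_list Lists of integer index vectors into 1..M giving
#'   each dataset's TP and FP pairs (disjoint within a dataset).
#' @return A `rank_accumulation`: tibble with columns `rank` (1..M),
#'   `r_tp`, `r_fp`, with attribute `n_datasets`.
#' @export
tp_fp_rank_accumulate <- function(pvalue_list, tp_list, fp_list) {
  stopifnot(length(pvalue_list) == length(tp_list),
            length(pvalue_list) == length(fp_list))
  if (length(pvalue_list) == 0L) stop("empty ensemble", call. = FALSE)
  m_pairs <- length(pvalue_list[[1L]])
  r_tp <- integer(m_pairs)
  r_fp <- integer(m_pairs)
  for (k in seq_along(pvalue_list)) {
    pv <- pvalue_list[[k]]
    if (length(pv) != m_pairs) {
      stop("all p-value vectors must have length M", call. = FALSE)
    }
    tp <- tp_list[[k]]
    fp <- fp_list[[k]]
    if (length(intersect(tp, fp)) > 0L) {
      stop("TP and FP sets must be disjoint", call. = FALSE)
    }
    l_k <- min(length(tp), length(fp))
    if (l_k == 0L) next
    ranks <- rank(pv, ties.method = "first")
    tp_ranks <- sort(ranks[tp])[seq_len(l_k)]
    fp_ranks <- sort(ranks[fp])[seq_len(l_k)]
    r_tp[tp_ranks] <- r_tp[tp_ranks] + 1L
    r_fp[fp_ranks] <- r_fp[fp_ranks] + 1L
  }
  structure(tibble::tibble(rank = seq_len(m_pairs), r_tp = r_tp, r_fp = r_fp),
            n_datasets = length(pvalue_list),
            class = c("rank_accumulation", "tbl_df", "tbl", "data.frame"))
}

#' Empirical CDF over rank positions
#'
#' @param counts Integer vector of occurrence counts per rank position
#'   (a column of a `rank_accumulation`); total must be positive.
#' @return Tibble with columns `rank`, `cum_fraction`; non-decreasing,
#'   final value exactly 1.
#' @export
ecdf_points <- function(counts) {
  if (sum(counts) <= 0) stop("counts must have positive total",
                             call. = FALSE)
  tibble::tibble(rank = seq_along(counts),
                 cum_fraction = cumsum(counts) / sum(counts))
}

#' Heterogeneity analysis of one simulated ensemble
#'
#' Runs the full data-heterogeneity audit for an ensemble of datasets
#' with a known reference network:
#'
#' 1. per-gene Anderson-Darling normality p-values and the
#'    Bonferroni-corrected rejection fraction per dataset;
#' 2. Stouffer-combined pair p-values over all gene pairs;
#' 3. per-dataset C3NET inference; TP = inferred-and-true edges, FP =
#'    inferred-but-not-true edges;
#' 4. TP/FP rank accumulation of the combined p-values and the two rank
#'    ECDFs;
#' 5. pairwise Kolmogorov-Smirnov distribution comparison over all pairs
#'    of the first dataset and its Bonferroni-corrected rejection
#'    fraction (the homogeneity detector: i.i.d. genes from one
#'    distribution keep this fraction near the nominal level).
#'
#' @param ensemble Output of [generate_ensemble()] (or a list with
#'   `network` and `datasets`).
#' @param estimator,scheme MI settings for the C3NET stage.
#' @param alpha,correction Significance settings for the C3NET stage.
#' @param n_permutations Null sample size for [permutation_null()].
#' @param seed Seed for the permutation nulls.
#' @return A `heterogeneity_summary` list: `ad_rejection_fractions` (one
#'   per dataset), `ks_rejection_fraction`, `rank_accumulation`,
#'   `ecdf_tp`, `ecdf_fp`, `normality` (per-dataset p-value tibbles).
#' @export
heterogeneity_analysis <- function(ensemble, estimator = "miller_madow",
                                   scheme = binning_scheme("equal_width"),
                                   alpha = 0.05,
                                   correction = "benjamini_hochberg",
                                   n_permutations = 5000L, seed = 1L) {
  network <- ensemble$network
  datasets <- ensemble$datasets
  ids <- network$gene_ids
  all_pairs <- t(utils::combn(ids, 2L))
  pair_tbl <- tibble::tibble(gene_a = all_pairs[, 1L],
                             gene_b = all_pairs[, 2L])
  pair_key <- paste(pair_tbl$gene_a, pair_tbl$gene_b)
  true_key <- paste(network$edges$gene_a, network$edges$gene_b)

  normality <- purrr::map(datasets, gene_normality_pvalues)
  ad_fracs <- vapply(normality, rejection_fraction, numeric(1),
                     alpha = alpha, correction = "bonferroni")

  pvalue_list <- vector("list", length(datasets))
  tp_list <- vector("list", length(datasets))
  fp_list <- vector("list", length(datasets))
  for (k in seq_along(datasets)) {
    gp <- setNames(normality[[k]]$p_value, normality[[k]]$gene_id)
    pvalue_list[[k]] <- combine_pair_pvalues(gp[pair_tbl$gene_a],
                                             gp[pair_tbl$gene_b])
    mi <- mi_matrix(datasets[[k]], estimator, scheme)
    null <- permutation_null(datasets[[k]], estimator, scheme,
                             n_permutations, seed = seed + k)
    inferred <- c3net_infer(mi, edge_significance(mi, null, alpha, correction))
    inf_key <- paste(inferred$edges$gene_a, inferred$edges$gene_b)
    tp_list[[k]] <- which(pair_key %in% intersect(inf_key, true_key))
    fp_list[[k]] <- which(pair_key %in% setdiff(inf_key, true_key))
  }
  acc <- tp_fp_rank_accumulate(pvalue_list, tp_list, fp_list)

  ks <- pair_distribution_pvalues(datasets[[1L]], pair_tbl)
  structure(list(
    ad_rejection_fractions = ad_fracs,
    ks_rejection_fraction = rejection_fraction(ks, alpha = alpha,
                                               correction = "bonferroni"),
    rank_accumulation = acc,
    ecdf_tp = if (sum(acc$r_tp) > 0) ecdf_points(acc$r_tp) else NULL,
    ecdf_fp = if (sum(acc$r_fp) > 0) ecdf_points(acc$r_fp) else NULL,
    normality = normality
  ), class = "heterogeneity_summary")
}

#' @export
print.heterogeneity_summary <- function(x, ...) {
  cat("<heterogeneity_summary>\n")
  cat(sprintf("  mean AD rejection fraction (Bonferroni): %.3f\n",
              mean(x$ad_rejection_fractions)))
  cat(sprintf("  KS pair rejection fraction (Bonferroni): %.3f\n",
              x$ks_rejection_fraction))
  cat(sprintf("  rank mass accumulated: %d TP / %d FP\n",
              sum(x$rank_accumulation$r_tp), sum(x$rank_accumulation$r_fp)))
  invisible(x)
}
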