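#' Histogram bin-count rule
#'
#' Proportional k-interval discretization: the number of bins grows with
#' the sample size as `B = round(sqrt(N))`, floored at 2. With the joint
#' table then holding roughly N cells over N samples, the estimators'
#' undersampling regimes stay comparable across sample sizes.
#'
#' @param n_samples Number of samples (>= 4).
#' @return The bin count B.
#' @examples
#' choose_bin_count(100) # 10
#' @export
choose_bin_count <- function(n_samples) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 4) {
    stop("`n_samples` must be a count >= 4", call. = FALSE)
  }
  max(2L, as.integer(round(sqrt(n_samples))))
}

#' Binning scheme
#'
#' @param method One of `"equal_frequency"` (per-variable quantile bins),
#'   `"equal_width"` (per-variable equal-length intervals) or
#'   `"global_equal_width"` (equal-length intervals over the pooled range
#'   of both variables of a pair).
#' @param n_bins Number of bins B (>= 2), or `NULL` to apply
#'   [choose_bin_count()] to the data at hand.
#' @return A `binning_scheme` list.
#' @export
binning_scheme <- function(method = c("equal_frequency", "equal_width",
                                      "global_equal_width"),
                           n_bins = NULL) {
  method <- match.arg(method)
  if (!is.null(n_bins)) {
    stopifnot(is.numeric(n_bins), length(n_bins) == 1L, n_bins >= 2)
    n_bins <- as.integer(n_bins)
  }
  structure(list(method = method, n_bins = n_bins),
            class = "binning_scheme")
}

scheme_bins <- function(scheme, n_samples) {
  if (is.null(scheme$n_bins)) choose_bin_count(n_samples) else scheme$n_bins
}

#' Discretize a pair of expression profiles
#'
#' Maps two continuous vectors to bin labels `1..B`. Intervals are
#' left-open right-closed except the first, which is closed on both ends.
#' `equal_frequency` places boundaries at empirical quantiles of each
#' variable separately, so occupancies are balanced up to tie-induced
#' excess (tied values never split across a boundary — they fall in the
#' lower bin); `equal_width` splits each variable's own range into B equal
#' intervals; `global_equal_width` splits the pooled range of both
#' variables into B equal intervals used for both, so the two label sets
#' share one scale. A constant vector under a width-based scheme gets all
#' labels 1.
#'
#' @param x,y Numeric vectors of equal length with finite values.
#' @param scheme A [binning_scheme()].
#' @return A list with integer vectors `labels_x`, `labels_y` and counts
#'   `bins_x`, `bins_y`.
#' @export
discretize_pair <- function(x, y, scheme = binning_scheme()) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("values must be finite", call. = FALSE)
  }
  b <- scheme_bins(scheme, length(x))
  if (length(x) < b) stop("need at least B samples", call. = FALSE)
  switch(scheme$method,
    equal_frequency = {
      list(labels_x = eqfreq_labels(x, b), labels_y = eqfreq_labels(y, b),
           bins_x = b, bins_y = b)
    },
    equal_width = {
      lx <- bin_by_breaks(x, seq(min(x), max(x), length.out = b + 1))
      ly <- bin_by_breaks(y, seq(min(y), max(y), length.out = b + 1))
      list(labels_x = lx, labels_y = ly, bins_x = b, bins_y = b)
    },
    global_equal_width = {
      pooled <- range(c(x, y))
      breaks <- seq(pooled[1L], pooled[2L], length.out = b + 1)
      list(labels_x = bin_by_breaks(x, breaks),
           labels_y = bin_by_breaks(y, breaks),
           bins_x = b, bins_y = b)
    }
  )
}

# quantile bins assigned through ranks: the i-th order statistic gets label
# ceiling(i * B / N), so distinct values balance to within one count and a
# tie block inherits the label of its lowest member (never split upward)
eqfreq_labels <- function(v, b) {
  as.integer(ceiling(rank(v, ties.method = "min") * b / length(v)))
}

# labels via (a, b]-intervals, first interval closed; degenerate range -> 1
bin_by_breaks <- function(v, breaks) {
  breaks <- unique(breaks)
  if (length(breaks) < 2L) return(rep(1L, length(v)))
  .bincode(v, breaks, right = TRUE, include.lowest = TRUE)
}

#' Joint contingency table of two label vectors
#'
#' @param labels_x,labels_y Integer labels in `1..B_x` / `1..B_y`.
#' @param bins_x,bins_y Nominal bin counts.
#' @return A `contingency_table`: integer matrix of co-occurrence counts
#'   with attribute `total = N`.
#' @export
joint_counts <- function(labels_x, labels_y, bins_x, bins_y) {
  if (length(labels_x) != length(labels_y)) {
    stop("label vectors must have the same length", call. = FALSE)
  }
  if (any(labels_x < 1L | labels_x > bins_x) ||
      any(labels_y < 1L | labels_y > bins_y)) {
    stop("labels out of 1..B range", call. = FALSE)
  }
  counts <- matrix(tabulate((labels_y - 1L) * bins_x + labels_x,
                            nbins = bins_x * bins_y),
                   nrow = bins_x, ncol = bins_y)
  contingency_table(counts)
}

#' @rdname joint_counts
#' @param counts A nonnegative integer matrix (or vector, treated as a
#'   one-dimensional table) of bin counts.
#' @export
contingency_table <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(as.numeric(counts), nrow = 1L)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  structure(counts, total = sum(counts), class = "contingency_table")
}

ct_counts <- function(table) {
  if (inherits(table, "contingency_table")) unclass(table)
  else as.matrix(table)
}
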