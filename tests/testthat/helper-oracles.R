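# Independent oracles: literal transcriptions of the defining formulas,
# kept free of any package internals so they can arbitrate against the
# implementation.

oracle_entropy_empirical <- function(counts) {
  counts <- as.vector(counts)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p)) / log(2)
}

oracle_entropy_mm <- function(counts) {
  counts <- as.vector(counts)
  occupied <- sum(counts > 0)
  oracle_entropy_empirical(counts) +
    (occupied - 1) / (2 * sum(counts)) / log(2)
}

oracle_entropy_shrink <- function(counts) {
  counts <- as.vector(counts)
  n <- sum(counts)
  p_hat <- counts / n
  t_k <- rep(1 / length(counts), length(counts))
  denom <- (n - 1) * sum((t_k - p_hat)^2)
  lambda <- if (denom == 0) 1 else (1 - sum(p_hat^2)) / denom
  lambda <- max(0, min(1, lambda))
  p <- lambda * t_k + (1 - lambda) * p_hat
  p <- p[p > 0]
  list(entropy = -sum(p * log(p)) / log(2), lambda = lambda)
}

oracle_entropy_sg <- function(counts) {
  counts <- as.vector(counts)
  beta <- 1 / length(counts)
  p <- (counts + beta) / (sum(counts) + 1)
  -sum(p * log(p)) / log(2)
}

oracle_mi_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  oracle_entropy_empirical(rowSums(counts)) +
    oracle_entropy_empirical(colSums(counts)) -
    oracle_entropy_empirical(counts)
}

# literal trapezoid sum over (recall, precision) points anchored at recall 0
oracle_trapezoid_auc <- function(recall, precision) {
  r <- c(0, recall)
  p <- c(precision[1], precision)
  total <- 0
  for (i in seq_len(length(r) - 1)) {
    total <- total + (r[i + 1] - r[i]) * (p[i] + p[i + 1]) / 2
  }
  total
}

# brute-force C3NET re-selection: for every gene scan all partners,
# keep its significant-maximal pair, union the pairs
oracle_c3net <- function(mi, mask) {
  ids <- rownames(mi)
  chosen <- character(0)
  for (i in seq_along(ids)) {
    best <- NULL
    best_val <- -Inf
    for (j in order(ids)) {
      if (j == i || !mask[i, j]) next
      if (mi[i, j] > best_val) {
        best_val <- mi[i, j]
        best <- j
      }
    }
    if (!is.null(best)) {
      e <- sort(c(ids[i], ids[best]))
      chosen <- union(chosen, paste(e[1], e[2]))
    }
  }
  sort(chosen)
}

random_contingency_table <- function(max_bins = 10, max_total = 100) {
  bx <- sample(2:max_bins, 1)
  by <- sample(2:max_bins, 1)
  n <- sample(2:max_total, 1)
  cells <- sample.int(bx * by, n, replace = TRUE,
                      prob = stats::runif(bx * by)^2)
  matrix(tabulate(cells, bx * by), bx, by)
}

edge_key <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  sort(paste(pmin(edges$gene_a, edges$gene_b),
             pmax(edges$gene_a, edges$gene_b)))
}

# small labelled MI-like matrix with given gene ids
toy_mi_matrix <- function(values, ids) {
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (v in values) m[v[[1]], v[[2]]] <- m[v[[2]], v[[1]]] <- v[[3]]
  structure(m, class = c("mi_matrix", "matrix", "array"))
}
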