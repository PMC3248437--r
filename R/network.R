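#' Gene network objects
#'
#' A `gene_network` is an undirected, unweighted graph over a fixed gene
#' universe: a character vector of gene identifiers plus an edge table.
#' Unconnected genes are part of the universe (they model non-expressed
#' genes), so the gene list is carried explicitly rather than derived from
#' the edges. Edges are stored once in canonical order
#' (`gene_a < gene_b` lexicographically), which makes set operations on
#' edges plain joins on the edge tibble.
#'
#' @param gene_ids Character vector of gene identifiers (unique, non-empty).
#' @param edges A data frame with columns `gene_a` and `gene_b` (or a
#'   two-column data frame taken positionally). Self-pairs are rejected;
#'   duplicate and reversed duplicates collapse to one edge.
#' @return An object of class `gene_network` with fields `gene_ids` and
#'   `edges` (a tibble with columns `gene_a`, `gene_b`).
#' @examples
#' net <- gene_network(c("g1", "g2", "g3"),
#'                     data.frame(gene_a = "g2", gene_b = "g1"))
#' net$edges
#' @export
gene_network <- function(gene_ids, edges = NULL) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) < 1L || anyDuplicated(gene_ids) || anyNA(gene_ids)) {
    stop("`gene_ids` must be a non-empty vector of unique identifiers",
         call. = FALSE)
  }
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- tibble::tibble(gene_a = character(), gene_b = character())
  } else {
    edges <- as.data.frame(edges)
    a <- as.character(edges[[1L]])
    b <- as.character(edges[[2L]])
    if (any(a == b)) stop("self-pairs are not allowed", call. = FALSE)
    if (!all(c(a, b) %in% gene_ids)) {
      stop("edge endpoints must be listed in `gene_ids`", call. = FALSE)
    }
    edges <- canonical_edges(a, b)
  }
  structure(list(gene_ids = gene_ids, edges = edges),
            class = "gene_network")
}

# store each unordered pair once, gene_a < gene_b, sorted, deduplicated
canonical_edges <- function(a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  out <- tibble::tibble(gene_a = lo, gene_b = hi)
  out <- dplyr::distinct(out)
  dplyr::arrange(out, .data$gene_a, .data$gene_b)
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d genes, %d edges\n",
              length(x$gene_ids), nrow(x$edges)))
  invisible(x)
}

#' @rdname gene_network
#' @param x A `gene_network`.
#' @param ... Unused.
#' @method tidy gene_network
#' @export
tidy.gene_network <- function(x, ...) x$edges

#' @rdname gene_network
#' @method glance gene_network
#' @export
glance.gene_network <- function(x, ...) {
  n <- length(x$gene_ids)
  m <- nrow(x$edges)
  tibble::tibble(
    n_genes = n,
    n_edges = m,
    edge_density = if (n > 1) m / (n * (n - 1) / 2) else NA_real_,
    n_unconnected = sum(!x$gene_ids %in% c(x$edges$gene_a, x$edges$gene_b))
  )
}

#' Sample an Erdos-Renyi gene network
#'
#' Draws each of the `n(n-1)/2` unordered gene pairs as an edge
#' independently with probability `edge_density` (the Gilbert G(n, p)
#' model). Gene regulatory networks are sparse, so realistic densities are
#' on the order of 0.5-2%; genes left unconnected stay in the universe as
#' pure-noise genes.
#'
#' @param n_genes Number of genes (>= 1). Gene ids are `g001`, `g002`, ...
#' @param edge_density Probability of each potential edge, in \[0, 1\].
#' @param seed Integer seed; the same seed yields the identical network.
#' @return A [gene_network].
#' @examples
#' net <- sample_er_network(25, 0.02, seed = 1)
#' glance(net)
#' @export
sample_er_network <- function(n_genes, edge_density, seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1 ||
      n_genes != round(n_genes)) {
    stop("`n_genes` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(edge_density) || length(edge_density) != 1L ||
      edge_density < 0 || edge_density > 1) {
    stop("`edge_density` must lie in [0, 1]", call. = FALSE)
  }
  ids <- gene_labels(n_genes)
  if (n_genes == 1L) return(gene_network(ids))
  pairs <- utils::combn(ids, 2L)
  keep <- withr::with_seed(seed,
    stats::runif(ncol(pairs)) < edge_density)
  gene_network(ids, data.frame(gene_a = pairs[1L, keep],
                               gene_b = pairs[2L, keep]))
}

gene_labels <- function(n) {
  sprintf(paste0("g%0", max(3L, nchar(as.character(n))), "d"), seq_len(n))
}

#' Orient an undirected network for simulation
#'
#' Expression simulation needs a regulator-to-target direction even though
#' inference and evaluation are undirected. A uniformly random permutation
#' of the genes is drawn as a topological order and every edge is oriented
#' from the earlier to the later gene, so the result is acyclic by
#' construction and each undirected edge yields exactly one arc.
#'
#' @param network A [gene_network].
#' @param seed Integer seed for the permutation.
#' @return An object of class `directed_gene_network` with fields
#'   `gene_ids`, `arcs` (tibble with columns `regulator`, `target`) and
#'   `topo_order` (gene ids in topological order).
#' @export
orient_for_simulation <- function(network, seed = 1L) {
  stopifnot(inherits(network, "gene_network"))
  ord <- withr::with_seed(seed, sample(network$gene_ids))
  pos <- stats::setNames(seq_along(ord), ord)
  e <- network$edges
  if (nrow(e) == 0L) {
    arcs <- tibble::tibble(regulator = character(), target = character())
  } else {
    swap <- pos[e$gene_a] > pos[e$gene_b]
    arcs <- tibble::tibble(
      regulator = ifelse(swap, e$gene_b, e$gene_a),
      target    = ifelse(swap, e$gene_a, e$gene_b)
    )
  }
  structure(list(gene_ids = network$gene_ids, arcs = arcs, topo_order = ord),
            class = "directed_gene_network")
}

#' @export
print.directed_gene_network <- function(x, ...) {
  cat(sprintf("<directed_gene_network> %d genes, %d arcs\n",
              length(x$gene_ids), nrow(x$arcs)))
  invisible(x)
}

#' Read and write edge-list networks
#'
#' Networks travel as a two-column tab-separated edge list
#' (`gene_a TAB gene_b`, with header). Because unconnected genes carry
#' information (they are the pure-noise genes), the gene universe is
#' written alongside as a one-column file so a round-trip preserves it.
#'
#' @param network A [gene_network].
#' @param edges_file Path of the edge-list TSV.
#' @param genes_file Path of the one-column gene-universe file.
#' @return `write_network` returns `network` invisibly; `read_network`
#'   returns a [gene_network].
#' @export
write_network <- function(network, edges_file, genes_file) {
  stopifnot(inherits(network, "gene_network"))
  readr::write_tsv(network$edges, edges_file)
  readr::write_tsv(tibble::tibble(gene_id = network$gene_ids), genes_file)
  invisible(network)
}

#' @rdname write_network
#' @export
read_network <- function(edges_file, genes_file) {
  edges <- readr::read_tsv(edges_file, col_types = "cc")
  genes <- readr::read_tsv(genes_file, col_types = "c")
  gene_network(genes[[1L]], edges)
}
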