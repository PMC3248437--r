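test_that("ER sampling hits the degenerate densities exactly", {
  expect_equal(nrow(sample_er_network(100, 0, seed = 5)$edges), 0)
  expect_equal(nrow(sample_er_network(100, 1, seed = 5)$edges), 4950)
  expect_error(sample_er_network(100, 1.2), "0, 1")
  expect_error(sample_er_network(-3, 0.5), "positive")
})

test_that("ER edge counts follow Binomial(n(n-1)/2, p)", {
  # mean over many seeds against the binomial oracle, 3 SE band
  counts <- vapply(1:1000, function(s) {
    nrow(sample_er_network(100, 0.01, seed = s)$edges)
  }, numeric(1))
  mu <- 4950 * 0.01
  se <- sqrt(4950 * 0.01 * 0.99 / 1000)
  expect_lt(abs(mean(counts) - mu), 3 * se)

  # chi-square goodness of fit on a small network over 600 seeds
  n_pairs <- choose(6, 2)
  k <- vapply(1:600, function(s) {
    nrow(sample_er_network(6, 0.3, seed = 1000 + s)$edges)
  }, numeric(1))
  probs <- stats::dbinom(0:n_pairs, n_pairs, 0.3)
  obs <- tabulate(k + 1, n_pairs + 1)
  # pool the sparse tail so expected counts stay reasonable
  keep <- probs * 600 >= 5
  obs_p <- c(obs[keep], sum(obs[!keep]))
  probs_p <- c(probs[keep], sum(probs[!keep]))
  gof <- suppressWarnings(stats::chisq.test(obs_p, p = probs_p))
  expect_gt(gof$p.value, 0.001)
})

test_that("networks are reproducible and keep unconnected genes", {
  a <- sample_er_network(40, 0.02, seed = 11)
  b <- sample_er_network(40, 0.02, seed = 11)
  expect_identical(a, b)
  expect_length(a$gene_ids, 40)
  expect_true(nrow(a$edges) < 40 * 39 / 2)
  expect_gt(glance(a)$n_unconnected, 0)
})

test_that("orientation is acyclic and forced by the total order", {
  empty <- gene_network(c("a", "b"))
  expect_equal(nrow(orient_for_simulation(empty, 1)$arcs), 0)

  chain <- gene_network(c("a", "b", "c"),
                        data.frame(gene_a = c("a", "b"),
                                   gene_b = c("b", "c")))
  for (s in 1:10) {
    d <- orient_for_simulation(chain, seed = s)
    pos <- setNames(seq_along(d$topo_order), d$topo_order)
    expect_true(all(pos[d$arcs$regulator] < pos[d$arcs$target]))
    expect_equal(nrow(d$arcs), 2)
  }

  # arbitrary network: every arc goes forward in the stored order
  net <- sample_er_network(30, 0.2, seed = 3)
  d <- orient_for_simulation(net, seed = 9)
  pos <- setNames(seq_along(d$topo_order), d$topo_order)
  expect_true(all(pos[d$arcs$regulator] < pos[d$arcs$target]))
  expect_equal(nrow(d$arcs), nrow(net$edges))
})

test_that("expression simulation is seeded and respects the topology", {
  net <- sample_er_network(20, 0.05, seed = 2)
  dnet <- orient_for_simulation(net, seed = 2)
  x1 <- simulate_expression(dnet, 50, seed = 4)
  x2 <- simulate_expression(dnet, 50, seed = 4)
  expect_identical(unclass(x1), unclass(x2))
  expect_true(all(is.finite(x1)))
  expect_equal(dim(x1), c(20, 50))

  # unconnected gene stays uncorrelated with everything (null bound 3/sqrt(n))
  connected <- unique(c(net$edges$gene_a, net$edges$gene_b))
  lone <- setdiff(net$gene_ids, connected)[1]
  other <- setdiff(net$gene_ids, lone)[1]
  big <- simulate_expression(dnet, 10000, seed = 6)
  expect_lt(abs(stats::cor(big[lone, ], big[other, ])), 0.05)
})

test_that("a noise-free single-regulator target is a monotone map", {
  reg <- gene_network(c("a", "b"),
                      data.frame(gene_a = "a", gene_b = "b"))
  found <- FALSE
  for (s in 1:10) {
    d <- orient_for_simulation(reg, seed = s)
    x <- simulate_expression(d, 1000, noise_sd = 0,
                             interaction_strength = 1, seed = s)
    sgn <- attr(unclass(x), "arc_signs")[[1]]
    if (sgn > 0) {
      found <- TRUE
      expect_gt(stats::cor(x[d$arcs$regulator, ], x[d$arcs$target, ],
                           method = "spearman"), 0.99)
    } else {
      expect_lt(stats::cor(x[d$arcs$regulator, ], x[d$arcs$target, ],
                           method = "spearman"), -0.99)
    }
  }
  expect_true(found)
})

test_that("noise-free regulated genes are a deterministic function of roots", {
  net <- sample_er_network(15, 0.1, seed = 21)
  dnet <- orient_for_simulation(net, seed = 21)
  x <- simulate_expression(dnet, 30, noise_sd = 0, seed = 5)
  y <- simulate_expression(dnet, 30, noise_sd = 0, seed = 5)
  expect_identical(unclass(x), unclass(y))
})

test_that("coupled pairs correlate more than unconnected pairs", {
  stronger <- vapply(1:20, function(r) {
    net <- sample_er_network(20, 0.05, seed = 100 + r)
    if (nrow(net$edges) == 0) return(NA)
    dnet <- orient_for_simulation(net, seed = 100 + r)
    x <- simulate_expression(dnet, 200, seed = 100 + r)
    coupled <- apply(net$edges, 1, function(e) {
      abs(stats::cor(x[e[["gene_a"]], ], x[e[["gene_b"]], ]))
    })
    connected <- unique(c(net$edges$gene_a, net$edges$gene_b))
    lone <- setdiff(net$gene_ids, connected)
    if (length(lone) < 2) return(NA)
    prs <- utils::combn(lone, 2)
    loose <- vapply(seq_len(ncol(prs)), function(i) {
      abs(stats::cor(x[prs[1, i], ], x[prs[2, i], ]))
    }, numeric(1))
    stats::median(coupled) > stats::median(loose)
  }, logical(1))
  expect_gt(mean(stronger, na.rm = TRUE), 0.9)
})

test_that("ensembles reuse one network with per-dataset seeds", {
  cfg <- simulation_config(n_genes = 12, edge_density = 0.1, n_samples = 25,
                           n_datasets = 5, seed = 17)
  ens <- generate_ensemble(cfg)
  expect_length(ens$datasets, 5)
  shapes <- vapply(ens$datasets, function(d) paste(dim(d), collapse = "x"),
                   character(1))
  expect_true(all(shapes == "12x25"))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_false(identical(unclass(ens$datasets[[i]]),
                           unclass(ens$datasets[[j]])))
  }
  ens2 <- generate_ensemble(cfg)
  expect_identical(ens$network, ens2$network)
  expect_identical(lapply(ens$datasets, unclass),
                   lapply(ens2$datasets, unclass))

  one <- generate_ensemble(simulation_config(n_genes = 5, n_datasets = 1,
                                             n_samples = 10, seed = 2))
  expect_length(one$datasets, 1)
})

test_that("network and expression files round-trip", {
  net <- sample_er_network(15, 0.08, seed = 31)
  ef <- withr::local_tempfile(fileext = ".tsv")
  gf <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, ef, gf)
  back <- read_network(ef, gf)
  expect_identical(back$gene_ids, net$gene_ids)
  expect_equal(as.data.frame(back$edges), as.data.frame(net$edges))

  dnet <- orient_for_simulation(net, seed = 31)
  x <- simulate_expression(dnet, 12, seed = 31)
  xf <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, xf)
  xr <- read_expression(xf)
  expect_equal(unclass(xr)[, ], unclass(x)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(rownames(xr), rownames(x))
})
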