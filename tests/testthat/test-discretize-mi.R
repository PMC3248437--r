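test_that("bin count follows the square-root rule with floor 2", {
  expect_equal(choose_bin_count(100), 10)
  expect_equal(choose_bin_count(4), 2)
  expect_equal(choose_bin_count(50), 7)
  expect_error(choose_bin_count(3), ">= 4")
})

test_that("discretization matches hand-computed boundaries", {
  # quantile split of 8 distinct values
  x <- c(1, 2, 3, 4, 10, 11, 12, 13)
  d <- discretize_pair(x, x, binning_scheme("equal_frequency", 2))
  expect_equal(d$labels_x, c(1, 1, 1, 1, 2, 2, 2, 2))

  # equal width boundary at 0.45
  d <- discretize_pair(c(0, 0.2, 0.9), c(0, 0.2, 0.9),
                       binning_scheme("equal_width", 2))
  expect_equal(d$labels_x, c(1, 1, 2))

  # pooled range [0, 3], boundary 1.5 right-closed
  d <- discretize_pair(c(0, 0.5, 1), c(0, 1.5, 3),
                       binning_scheme("global_equal_width", 2))
  expect_equal(d$labels_x, c(1, 1, 1))
  expect_equal(d$labels_y, c(1, 1, 2))

  # constant vector under width binning: single bin, no error
  d <- discretize_pair(rep(2, 6), 1:6, binning_scheme("equal_width", 3))
  expect_equal(d$labels_x, rep(1, 6))

  expect_error(discretize_pair(1:4, 1:5, binning_scheme("equal_width", 2)),
               "same length")
})

test_that("equal-frequency occupancies are balanced for distinct values", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    b <- sample(2:10, 1)
    x <- sample(stats::rnorm(n))
    d <- discretize_pair(x, x, binning_scheme("equal_frequency", b))
    occ <- tabulate(d$labels_x, b)
    expect_lte(max(occ) - min(occ), 1)
  }
})

test_that("joint counts conserve the sample count", {
  ct <- joint_counts(c(1, 2, 1, 2), c(1, 2, 1, 2), 2, 2)
  expect_equal(unclass(ct)[, ], matrix(c(2, 0, 0, 2), 2),
               ignore_attr = TRUE)
  ct <- joint_counts(c(1, 1), c(2, 2), 2, 2)
  expect_equal(unclass(ct)[1, 2], 2)
  expect_equal(sum(unclass(ct)), 2)
  expect_error(joint_counts(c(1, 3), c(1, 1), 2, 2), "range")
  set.seed(1)
  lx <- sample(1:4, 50, replace = TRUE)
  ly <- sample(1:3, 50, replace = TRUE)
  expect_equal(sum(unclass(joint_counts(lx, ly, 4, 3))), 50)
})

test_that("entropy estimators reproduce hand-computed cases", {
  expect_equal(entropy_empirical(c(4, 4)), 1.0)
  expect_equal(entropy_empirical(c(8, 0)), 0.0)
  p <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(entropy_empirical(c(1, 2, 3, 4)), -sum(p * log2(p)),
               tolerance = 1e-12)

  expect_equal(entropy_miller_madow(c(8, 0)), 0.0)
  expect_equal(entropy_miller_madow(c(4, 4)), 1 + log2(exp(1)) / 16,
               tolerance = 1e-12)

  s <- entropy_shrink(c(4, 4))   # p_hat equals the uniform target
  expect_equal(s$lambda, 1)
  expect_equal(s$entropy, 1.0)
  s <- entropy_shrink(c(0, 10))  # numerator 1 - sum(p^2) = 0
  expect_equal(s$lambda, 0)
  expect_equal(s$entropy, 0.0)
  s <- entropy_shrink(c(9, 1))
  o <- oracle_entropy_shrink(c(9, 1))
  expect_equal(s$lambda, o$lambda, tolerance = 1e-12)
  expect_equal(s$entropy, o$entropy, tolerance = 1e-12)

  expect_equal(entropy_sg(c(4, 4)), 1.0)
  expect_equal(entropy_sg(c(8, 0)),
               -(8.5 / 9) * log2(8.5 / 9) - (0.5 / 9) * log2(0.5 / 9),
               tolerance = 1e-12)

  expect_error(entropy_empirical(c(0, 0)), "positive")
  expect_error(entropy_shrink(c(1, 0)), "> 1")
})

test_that("all four estimators match the literal-formula oracles", {
  set.seed(7)
  for (i in 1:100) {
    tab <- random_contingency_table()
    expect_equal(entropy_empirical(tab), oracle_entropy_empirical(tab),
                 tolerance = 1e-12)
    expect_equal(entropy_miller_madow(tab), oracle_entropy_mm(tab),
                 tolerance = 1e-12)
    if (sum(tab) > 1) {
      s <- entropy_shrink(tab)
      o <- oracle_entropy_shrink(tab)
      expect_equal(s$entropy, o$entropy, tolerance = 1e-12)
      expect_equal(s$lambda, o$lambda, tolerance = 1e-12)
      expect_gte(s$lambda, 0)
      expect_lte(s$lambda, 1)
    }
    expect_equal(entropy_sg(tab), oracle_entropy_sg(tab), tolerance = 1e-12)
    # order relations and normalization
    expect_gte(entropy_miller_madow(tab) - entropy_empirical(tab), 0)
    beta <- 1 / length(tab)
    p_sg <- (as.vector(tab) + beta) / (sum(tab) + 1)
    expect_true(all(p_sg > 0))
    expect_equal(sum(p_sg), 1, tolerance = 1e-12)
  }
})

test_that("bias-corrected entropies converge to the empirical entropy", {
  base <- c(1, 2, 3, 4)
  big <- base * 250000  # total 2.5e6 >> cells
  h_emp <- entropy_empirical(big)
  expect_lt(abs(entropy_shrink(big)$entropy - h_emp), 1e-3)
  expect_lt(abs(entropy_sg(big) - h_emp), 1e-3)
})

test_that("mutual information obeys its identities", {
  set.seed(11)
  x <- stats::runif(400)
  scheme <- binning_scheme("equal_width", 5)
  # identical vectors: I = H(X)
  d <- discretize_pair(x, x, scheme)
  hx <- entropy_empirical(tabulate(d$labels_x, 5))
  expect_equal(mutual_information(x, x, "empirical", scheme), hx,
               tolerance = 1e-12)
  # symmetry
  y <- stats::runif(400)
  for (est in mi_estimators()) {
    expect_equal(mutual_information(x, y, est, scheme),
                 mutual_information(y, x, est, scheme), tolerance = 1e-12)
  }
  # independence: small positive bias only, O(B^2/N)
  xl <- stats::runif(10000)
  yl <- stats::runif(10000)
  expect_lt(mutual_information(xl, yl, "empirical",
                               binning_scheme("equal_width", 10)), 0.05)
})

test_that("estimators are consistent for a known discrete joint", {
  # fixed 3x3 joint distribution with analytically computed I
  pj <- matrix(c(0.20, 0.05, 0.05,
                 0.05, 0.20, 0.05,
                 0.05, 0.05, 0.30), 3, 3, byrow = TRUE)
  px <- rowSums(pj); py <- colSums(pj)
  i_true <- sum(pj * log2(pj / outer(px, py)))
  scheme <- binning_scheme("equal_width", 3)
  for (r in 1:5) {
    set.seed(400 + r)
    cells <- sample.int(9, 1e5, replace = TRUE, prob = as.vector(pj))
    x <- (cells - 1) %% 3 + 1
    y <- (cells - 1) %/% 3 + 1
    # jitter within the bin so the width-based scheme recovers the support
    xc <- x + stats::runif(1e5, -0.2, 0.2)
    yc <- y + stats::runif(1e5, -0.2, 0.2)
    for (est in mi_estimators()) {
      expect_lt(abs(mutual_information(xc, yc, est, scheme) - i_true), 0.02)
    }
  }
})

test_that("the MI matrix is symmetric with zero diagonal", {
  net <- sample_er_network(8, 0.2, seed = 9)
  x <- simulate_expression(orient_for_simulation(net, 9), 60, seed = 9)
  for (method in c("equal_frequency", "equal_width", "global_equal_width")) {
    mi <- mi_matrix(x, "empirical", binning_scheme(method))
    m <- unclass(mi)
    expect_equal(m, t(m), tolerance = 1e-12)
    expect_equal(diag(m), setNames(rep(0, 8), rownames(m)))
    # entries agree with the pairwise entry point
    expect_equal(m[2, 5],
                 mutual_information(x[2, ], x[5, ], "empirical",
                                    binning_scheme(method)),
                 tolerance = 1e-12)
  }
})

test_that("a duplicated gene attains its row maximum at its twin", {
  set.seed(13)
  m <- rbind(g1 = stats::runif(80))
  m <- rbind(m, g2 = m["g1", ], g3 = stats::runif(80), g4 = stats::runif(80))
  mi <- mi_matrix(m, "empirical", binning_scheme("equal_width", 4))
  expect_equal(unname(unclass(mi)["g1", "g2"]),
               max(unclass(mi)["g1", -1]))
})

test_that("MI matrices round-trip through TSV", {
  net <- sample_er_network(6, 0.3, seed = 15)
  x <- simulate_expression(orient_for_simulation(net, 15), 40, seed = 15)
  mi <- mi_matrix(x, "miller_madow", binning_scheme("equal_width"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mi_matrix(mi, f)
  back <- read_mi_matrix(f)
  expect_equal(unclass(back)[, ], unclass(mi)[, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  # tidy view covers each unordered pair once
  expect_equal(nrow(tidy(mi)), choose(6, 2))
})
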