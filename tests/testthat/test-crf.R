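test_that("unary, pairwise and constrained potentials evaluate the defining formulas", {
  # pairwise: Iverson bracket, exp(0), and a hand-evaluated contrast case
  expect_identical(pairwise_term(0.3, 0.9, 1, 1, 1, 0.1), 0)
  expect_identical(pairwise_term(0.5, 0.5, 0, 1, 1, 0.1), 1)
  expect_equal(pairwise_term(0.2, 0.3, 0, 1, 1, 0.1), exp(-0.5))
  expect_equal(pairwise_term(0.2, 0.3, 0, 1, 2, 0.1), exp(-0.5) / 2)
  expect_error(pairwise_term(0, 0, 0, 1, 0, 0.1), "dij")
  # unary: clamped logs
  expect_lt(unary_term(1, 1), 1e-5)
  expect_equal(unary_term(0.5, 0), log(2))
  expect_equal(unary_term(0.5, 1), log(2))
  expect_equal(unary_term(0.9, 0), -log(0.1), tolerance = 1e-5)
  # constrained: scribble agreement is free, disagreement prohibitive
  scr <- scribble_set(fg = 1L, bg = 2L, shape = c(2, 2))
  expect_identical(constrained_unary(0.1, 1, scr, 1L), 0)
  expect_gte(constrained_unary(0.9, 1, scr, 2L), 1e3)
  expect_equal(constrained_unary(0.5, 0, scr, 3L), log(2))
})

test_that("at lambda = 0 the label update is per-pixel thresholding with ties to background", {
  p <- matrix(c(0.4, 0.5, 0.6, 0.1), 2, 2)
  y <- solve_labels(p, matrix(0, 2, 2), NULL, crf_params(lambda = 0))
  expect_identical(as.vector(y), c(0L, 0L, 1L, 0L))
})

test_that("one foreground scribble floods a flat region under strong smoothing", {
  p <- matrix(0.5, 3, 3)
  x <- matrix(0, 3, 3)
  scr <- scribble_set(fg = 5L, shape = c(3, 3))
  par <- crf_params(lambda = 50, sigma = 0.1)
  y <- solve_labels(p, x, scr, par)
  expect_true(all(y == 1L))
  expect_identical(y, brute_force_solve(p, x, scr, par))
})

test_that("graph-cut labelling attains the exhaustive minimum on random tiny instances", {
  set.seed(1234)
  for (k in 1:80) {
    ins <- random_crf_instance()
    y_gc <- solve_labels(ins$p, ins$x, ins$scr, ins$params)
    y_bf <- brute_force_solve(ins$p, ins$x, ins$scr, ins$params)
    e_gc <- crf_energy(y_gc, ins$p, ins$x, ins$scr, ins$params)
    e_bf <- crf_energy(y_bf, ins$p, ins$x, ins$scr, ins$params)
    expect_lte(e_gc, e_bf + 1e-6)
    if (!is.null(ins$scr)) {
      expect_true(all(y_gc[ins$scr$fg] == 1L))
      expect_true(all(y_gc[ins$scr$bg] == 0L))
      # scribble-violating labelings always cost strictly more
      y_bad <- y_bf
      flip <- c(ins$scr$fg, ins$scr$bg)[1]
      y_bad[flip] <- 1L - y_bad[flip]
      expect_gt(crf_energy(y_bad, ins$p, ins$x, ins$scr, ins$params), e_bf)
    }
  }
})

test_that("graph-cut labelling agrees with an independent max-flow implementation", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (k in 1:3) {
    d <- c(12L, 12L)
    p <- array(runif(prod(d)), d)
    x <- array(rnorm(prod(d)), d)
    par <- crf_params(lambda = c(1, 3, 10)[k], sigma = 0.2)
    y <- solve_labels(p, x, NULL, par)
    n <- prod(d)
    nb <- boxseg:::neighbor_pairs(x, par$sigma)
    large <- boxseg:::large_constant(p, par, length(nb$coef))
    u <- boxseg:::crf_unaries(p, NULL, large)
    g <- igraph::graph_from_edgelist(
      rbind(cbind(n + 1L, seq_len(n)), cbind(seq_len(n), n + 2L),
            cbind(nb$i, nb$j), cbind(nb$j, nb$i)), directed = TRUE)
    fl <- igraph::max_flow(g, source = n + 1L, target = n + 2L,
                           capacity = c(u$u0, u$u1, par$lambda * nb$coef,
                                        par$lambda * nb$coef))
    y_ig <- integer(n)
    side1 <- as.integer(fl$partition1)
    if ((n + 1L) %in% side1) y_ig[setdiff(side1, n + 1L)] <- 1L else
      y_ig[setdiff(as.integer(fl$partition2), n + 1L)] <- 1L
    expect_equal(crf_energy(y, p, x, NULL, par),
                 crf_energy(array(y_ig, d), p, x, NULL, par), tolerance = 1e-8)
  }
})

test_that("boundary length is non-increasing in the smoothing weight", {
  set.seed(7)
  p <- matrix(runif(64), 8, 8)
  x <- matrix(rnorm(64, sd = 0.5), 8, 8)
  lens <- vapply(c(0, 0.5, 1, 2, 5, 10), function(lam) {
    boundary_length(solve_labels(p, x, NULL, crf_params(lambda = lam, sigma = 0.3)))
  }, numeric(1))
  expect_true(all(diff(lens) <= 0))
})

test_that("energy evaluates unaries plus weighted pairwise over the neighbourhood", {
  # lambda = 0, labeling = argmax p with p in {0.1, 0.9}: sum of -log 0.9
  p <- matrix(c(0.9, 0.1, 0.9, 0.1), 2, 2)
  y <- array(as.integer(p > 0.5), dim(p))
  e <- crf_energy(y, p, matrix(0, 2, 2), NULL, crf_params(lambda = 0))
  expect_equal(e, -4 * log(0.9), tolerance = 1e-5)
  # constant labeling has zero pairwise contribution at any lambda
  y1 <- array(1L, c(3, 3))
  e1 <- crf_energy(y1, matrix(0.5, 3, 3), matrix(rnorm(9), 3, 3), NULL,
                   crf_params(lambda = 100))
  expect_equal(e1, 9 * log(2))
  # brute force on one pixel
  expect_identical(as.vector(brute_force_solve(array(0.9, c(1, 1)),
                                               array(0, c(1, 1)))), 1L)
  expect_error(brute_force_solve(array(0.5, c(5, 5)), array(0, c(5, 5))), "16")
})
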