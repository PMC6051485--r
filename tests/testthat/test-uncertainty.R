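test_that("network uncertainty uses strict thresholds and matches a pixel-scan oracle", {
  expect_true(network_uncertainty(array(0.5, c(1, 1)), 0.2, 0.7)[1])
  expect_false(network_uncertainty(array(0.2, c(1, 1)), 0.2, 0.7)[1])
  expect_false(network_uncertainty(array(0.7, c(1, 1)), 0.2, 0.7)[1])
  set.seed(3)
  p <- matrix(runif(120), 12, 10)
  up <- network_uncertainty(p, 0.2, 0.7)
  oracle <- apply(p, c(1, 2), function(v) v > 0.2 && v < 0.7)
  expect_identical(up, oracle)
  # the uncertain set shrinks as the band narrows
  expect_true(all(network_uncertainty(p, 0.3, 0.6) <= up))
})

test_that("geodesic distances match a Dijkstra reference and reduce to graph distance", {
  skip_if_not_installed("igraph")
  set.seed(11)
  for (k in 1:5) {
    img <- matrix(runif(64), 8, 8)
    seeds <- sample(64, sample(1:3, 1))
    g <- geodesic_distance(img, seeds, spacing = 1, gamma = 1)
    expect_true(all(g[seeds] == 0))
    d <- dim(img)
    idx <- array(seq_len(64), d)
    pi <- c(as.vector(idx[-8, ]), as.vector(idx[, -8]))
    pj <- c(as.vector(idx[-1, ]), as.vector(idx[, -1]))
    wt <- sqrt(1 + (img[pi] - img[pj])^2)
    gr <- igraph::graph_from_edgelist(cbind(pi, pj), directed = FALSE)
    D <- igraph::distances(gr, v = seeds, weights = wt)
    expect_equal(as.vector(g), apply(D, 2, min), tolerance = 1e-10)
    # neighbour consistency: distances differ by at most the step cost
    expect_true(all(abs(g[pi] - g[pj]) <= wt + 1e-10))
  }
  # constant image: pure spatial shortest-path (Manhattan) distance
  gc <- geodesic_distance(matrix(1, 8, 8), 1L)
  expect_equal(gc, outer(0:7, 0:7, `+`), ignore_attr = TRUE)
  expect_error(geodesic_distance(matrix(1, 4, 4), integer(0)), "seed")
})

test_that("scribble uncertainty flags opposite-labelled pixels geodesically close to scribbles", {
  x <- matrix(0, 9, 9)              # homogeneous region
  lab <- array(0L, c(9, 9))
  scr <- scribble_set(fg = 41L, shape = c(9, 9))   # centre pixel
  us <- scribble_uncertainty(x, scr, lab, epsilon = 0.2)
  # neighbours of the scribble are within epsilon (spacing 1/9) and wrongly
  # labelled background, hence scribble-uncertain; the scribble itself is not
  expect_true(us[5, 4] && us[4, 5] && us[6, 5] && us[5, 6])
  expect_false(us[41])
  # with the labels agreeing, nothing is uncertain
  expect_true(!any(scribble_uncertainty(x, scr, array(1L, c(9, 9)), 0.2)))
  # empty scribbles: unsupervised mode, empty set
  expect_true(!any(scribble_uncertainty(x, scribble_set(), lab, 0.2)))
})

test_that("scribble uncertainty equals direct evaluation of its defining predicates", {
  set.seed(21)
  for (k in 1:5) {
    x <- matrix(rnorm(100), 10, 10)
    lab <- array(as.integer(runif(100) < 0.5), c(10, 10))
    idx <- sample(100, 6)
    scr <- scribble_set(idx[1:3], idx[4:6], shape = c(10, 10))
    eps <- 0.25
    us <- scribble_uncertainty(x, scr, lab, epsilon = eps)
    sp <- 1 / 10
    gf <- geodesic_distance(x, scr$fg, spacing = sp)
    gb <- geodesic_distance(x, scr$bg, spacing = sp)
    oracle <- array(FALSE, c(10, 10))
    for (i in 1:100) {
      in_s <- i %in% c(scr$fg, scr$bg)
      oracle[i] <- (!in_s && gf[i] < eps && lab[i] == 0L) ||
                   (!in_s && gb[i] < eps && lab[i] == 1L)
    }
    expect_identical(us, oracle)
  }
})

test_that("the weight map partitions pixels into omega / zero / one with scribble precedence", {
  set.seed(8)
  p <- matrix(runif(144), 12, 12)
  x <- matrix(rnorm(144), 12, 12)
  lab <- array(as.integer(p > 0.5), dim(p))
  scr <- scribble_set(fg = c(1L, 2L), bg = c(100L, 101L), shape = dim(p))
  up <- network_uncertainty(p, 0.2, 0.7)
  us <- scribble_uncertainty(x, scr, lab, 0.2)
  w <- build_weight_map(scr, up, us, omega = 5.0)
  expect_setequal(unique(as.vector(w)), intersect(c(0, 1, 5), w))
  expect_true(all(w %in% c(0, 1, 5)))
  # precedence: scribbles keep omega even when uncertain
  expect_true(all(w[c(scr$fg, scr$bg)] == 5))
  # value histogram against a counting oracle
  s_idx <- c(scr$fg, scr$bg)
  unc <- which(up | us)
  expect_identical(sum(w == 5), length(s_idx))
  expect_identical(sum(w == 0), length(setdiff(unc, s_idx)))
  expect_identical(sum(w == 1), 144L - length(union(unc, s_idx)))
  # all sets empty: all-ones map
  expect_true(all(build_weight_map(NULL, array(FALSE, dim(p))) == 1))
  # unsupervised mode: no omega pixels
  w_u <- build_weight_map(NULL, up, NULL, omega = 5.0)
  expect_true(all(w_u %in% c(0, 1)))
})
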