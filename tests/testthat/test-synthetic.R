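test_that("scene generation is deterministic and honours the noise model", {
  sp <- small_scene_spec()
  s1 <- generate_scene(sp, seed = 19L)
  s2 <- generate_scene(sp, seed = 19L)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$labels, s2$labels)
  expect_false(identical(generate_scene(sp, seed = 20L)$labels, s1$labels))

  # zero noise, zero texture: object/background contrast equals the offset
  quiet <- scene_spec(shape = c(64L, 64L),
                      classes = lapply(default_catalog(2L), function(cl) {
                        cl$texture_sd <- 0; cl$size <- c(6, 10); cl
                      }),
                      background = list(noise_sd = 0))
  sq <- generate_scene(quiet, seed = 4L)
  for (ci in sort(unique(sq$labels[sq$labels > 0]))) {
    contrast <- unique(sq$image[sq$labels == ci]) - quiet$background$level
    expect_equal(contrast, quiet$classes[[ci]]$offset)
  }
  # base intensities stay in [0, 1] before noise
  expect_true(all(sq$image >= 0 & sq$image <= 1))
  # nonzero-offset invariant is enforced
  bad <- default_catalog(2L); bad[[1]]$offset <- 0
  expect_error(scene_spec(classes = bad), "nonzero")
})

test_that("per-class instance counts stay inside the catalog ranges (counting oracle)", {
  sp <- small_scene_spec()
  for (seed in 1:20) {
    sc <- generate_scene(sp, seed = seed)
    declared <- table(factor(vapply(sc$instances, `[[`, integer(1), "class"),
                             levels = seq_along(sp$classes)))
    for (ci in seq_along(sp$classes)) {
      # oracle: count connected components of each class in the label map
      vol <- array(sc$labels == ci, c(dim(sc$labels), 1L))
      ncomp <- max(boxseg:::.label_components_cpp(vol, dim(vol)))
      expect_identical(as.integer(declared[ci]), ncomp)
      expect_gte(ncomp, sp$classes[[ci]]$count[1])
      expect_lte(ncomp, sp$classes[[ci]]$count[2])
    }
  }
})

test_that("benchmark bundles have the requested sizes and class balance", {
  bm <- make_benchmark(n_train = 12L, n_test = 12L, seed = 8L,
                       spec = small_scene_spec(), prep = FALSE)
  expect_length(bm$train, 12L)
  expect_length(bm$test, 12L)
  tc <- table(vapply(bm$test, `[[`, character(1), "class_name"))
  expect_true(all(tc <= ceiling(12 / 4)))
  # reproducibility of the whole bundle
  bm2 <- make_benchmark(n_train = 12L, n_test = 12L, seed = 8L,
                        spec = small_scene_spec(), prep = FALSE)
  expect_identical(lapply(bm$train, `[[`, "region"),
                   lapply(bm2$train, `[[`, "region"))
  expect_error(make_benchmark(seen = c("ellipse"), unseen = c("ellipse")),
               "disjoint")
})

test_that("the benchmark exposes a seen/unseen gap that grows with network capacity", {
  classes <- lapply(default_catalog(2L), function(cl) { cl$size <- c(6, 11); cl })
  sp <- scene_spec(shape = c(64L, 64L), classes = classes)
  bm <- make_benchmark(n_train = 40L, n_test = 24L, seed = 29L, spec = sp,
                       target = 40L)
  tags <- vapply(bm$test, `[[`, logical(1), "seen")
  gap <- function(width) {
    spec <- network_spec(list(
      list(kernel = c(3L, 3L, 1L), dilation = c(1L, 1L, 1L), channels = width, layers = 2L),
      list(kernel = c(3L, 3L, 1L), dilation = c(2L, 2L, 1L), channels = width, layers = 2L),
      list(kernel = c(3L, 3L, 1L), dilation = c(4L, 4L, 1L), channels = width, layers = 2L)),
      dims = 2L)
    tr <- train_network(build_network(spec, seed = 5L), bm$train,
                        train_config(max_iterations = 300L, seed = 8L))
    ev <- evaluate_instances(tr$net, bm$test)
    mean(ev$dice[tags]) - mean(ev$dice[!tags])
  }
  gap_compact <- gap(4L)
  gap_wide <- gap(24L)   # deliberately over-parameterized for this data size
  expect_gt(gap_compact, 0)
  expect_gt(gap_wide, gap_compact)
})

test_that("robot scribbles fall only on mis-segmented pixels of the right kind", {
  set.seed(33)
  truth <- array(0L, c(20, 20)); truth[5:14, 6:15] <- 1L
  # a perfect prediction earns no scribbles
  expect_true(boxseg:::empty_scribbles(robot_scribbles(truth, truth)))
  # an inverted prediction earns both kinds
  scr <- robot_scribbles(1L - truth, truth)
  expect_gt(length(scr$fg), 0)
  expect_gt(length(scr$bg), 0)
  pol <- robot_user_policy(max_length = 6L)
  for (k in 1:10) {
    pred <- truth
    flip <- sample(400, 60)
    pred[flip] <- 1L - pred[flip]
    s <- robot_scribbles(pred, truth, pol)
    # foreground scribbles sit on false negatives, background on false positives
    expect_true(all(truth[s$fg] == 1L & pred[s$fg] == 0L))
    expect_true(all(truth[s$bg] == 0L & pred[s$bg] == 1L))
    expect_lte(length(s$fg), pol$max_length * pol$per_round)
    expect_lte(length(s$bg), pol$max_length * pol$per_round)
    # deterministic
    expect_identical(robot_scribbles(pred, truth, pol), s)
  }
})
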