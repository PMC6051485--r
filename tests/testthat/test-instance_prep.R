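test_that("instance extraction crops tight boxes with clipped random margins", {
  img <- matrix(0, 40, 40)
  lab <- matrix(0L, 40, 40)
  lab[11:20, 16:25] <- 1L
  # margins pinned to zero: tight 10x10 crop, all-ones mask
  inst <- extract_instances(img, lab, margin_sampler = function(n) rep(0L, n))
  expect_length(inst, 1)
  expect_identical(dim(inst[[1]]$mask), c(10L, 10L))
  expect_true(all(inst[[1]]$mask == 1L))
  expect_identical(inst[[1]]$box$lo, c(10L, 15L))
  # margins pinned to 10 near the image corner: box clipped at 0
  lab2 <- matrix(0L, 40, 40)
  lab2[1:5, 1:5] <- 1L
  inst2 <- extract_instances(img, lab2, margin_sampler = function(n) rep(10L, n))
  expect_identical(inst2[[1]]$box$lo, c(0L, 0L))
  expect_identical(inst2[[1]]$box$hi, c(15L, 15L))
  # all-background label map gives an empty list, not an error
  expect_length(extract_instances(img, matrix(0L, 40, 40)), 0)
})

test_that("per-instance foreground counts match an exhaustive pixel-scan oracle", {
  set.seed(31)
  img <- matrix(rnorm(48 * 48), 48, 48)
  lab <- matrix(0L, 48, 48)
  lab[5:12, 5:12] <- 1L      # class 1, instance a
  lab[30:35, 8:14] <- 1L     # class 1, instance b
  lab[20:27, 30:41] <- 2L    # class 2
  inst <- extract_instances(img, lab)
  expect_length(inst, 3)
  # oracle: exhaustive per-component pixel counts
  counts <- sort(vapply(inst, function(i) sum(i$mask), integer(1)))
  expect_identical(counts, sort(c(8L * 8L, 6L * 7L, 8L * 12L)))
  # every box contains its tight box with margins of at most 10 per side
  for (i in inst) {
    expect_true(all(i$box$lo <= i$tight_box$lo))
    expect_true(all(i$box$hi >= i$tight_box$hi))
    expect_true(all(i$tight_box$lo - i$box$lo <= 10L))
    expect_true(all(i$box$hi - i$tight_box$hi <= 10L))
  }
})

test_that("summed instance binarizations reconstruct the label map", {
  sc <- generate_scene(small_scene_spec(), seed = 77L)
  inst <- extract_instances(sc$image, sc$labels,
                            margin_sampler = function(n) rep(0L, n))
  canvas <- array(0, dim(sc$labels))
  for (i in inst) {
    reg <- crop_region(sc$labels * 0, i$box)  # reuse geometry records
    canvas <- canvas + restore_to_source(i$mask, reg, "mask") * i$label
  }
  expect_equal(canvas, array(as.numeric(sc$labels), dim(sc$labels)))
})

test_that("normalization standardizes, records its statistics and handles degenerate regions", {
  # constant region: all zeros, sd recorded as 1
  r <- normalize_region(matrix(3.7, 5, 5))
  expect_true(all(r$intensities == 0))
  expect_identical(r$normalization$sd, 1)
  # two-point region {0, 2} -> {-1, +1}
  r2 <- normalize_region(matrix(c(0, 2), 1, 2))
  expect_equal(as.vector(r2$intensities), c(-1, 1))
  # random region: mean ~ 0, sd ~ 1 by direct recomputation
  set.seed(5)
  r3 <- normalize_region(matrix(runif(200, 10, 40), 20, 10))
  expect_lt(abs(mean(r3$intensities)), 1e-5)
  expect_lt(abs(sqrt(mean(r3$intensities^2)) - 1), 1e-5)
  # invariance to affine intensity rescaling
  x <- matrix(rnorm(64), 8, 8)
  expect_equal(normalize_region(5 * x + 11)$intensities,
               normalize_region(x)$intensities, tolerance = 1e-10)
})

test_that("resizing fixes the controlling side and records an invertible scale", {
  r <- resize_for_network(matrix(0, 48, 96), target = 96)
  expect_identical(dim(r$intensities), c(96L, 192L))
  r3 <- resize_for_network(array(0, c(40, 100, 60)), target = 80)
  expect_identical(dim(r3$intensities), c(32L, 80L, 48L))
  # mask round trip through the pipeline's resize (min side to 96 in 2D,
  # max side to 80 in 3D) and back: Dice >= 0.95 on generated blobs
  set.seed(9)
  for (k in 1:5) {
    sc <- generate_scene(scene_spec(), seed = 100 + k)
    inst <- extract_instances(sc$image, sc$labels)
    if (length(inst) == 0) next
    m <- inst[[1]]$mask
    net_shape <- boxseg:::resized_shape(dim(m), "2d_min_side", 96L)
    up <- boxseg:::resample_array(m, net_shape, "nearest")
    back <- boxseg:::resample_array(up, dim(m), "nearest")
    expect_gte(dice_score(back, m), 0.95)
  }
})

test_that("restore_to_source inverts crop and resize", {
  img <- matrix(rnorm(30 * 24), 30, 24)
  box <- bounding_box(c(4, 6), c(14, 16))
  reg <- crop_region(img, box)
  # identity resize: placement only, pixels preserved exactly
  m <- matrix(rbinom(100, 1, 0.4), 10, 10)
  full <- restore_to_source(m, reg, "mask")
  expect_identical(dim(full), dim(img))
  expect_equal(full[5:14, 7:16], m)
  expect_true(all(full[-(5:14), ] == 0))
  # all-foreground crop: restored count equals box volume
  expect_equal(sum(restore_to_source(matrix(1, 10, 10), reg, "mask")), 100)
  # probability round trip at scale 2 stays within interpolation tolerance
  gx <- outer(seq(0, 1, length.out = 10), seq(0, 1, length.out = 10),
              function(a, b) 0.5 + 0.4 * sin(pi * a) * cos(pi * b))
  reg2 <- resize_for_network(reg, target = 20)
  up <- boxseg:::resample_array(gx, c(20, 20), "linear")
  restored <- restore_to_source(up, reg2, "prob")
  expect_lt(max(abs(restored[5:14, 7:16] - gx)), 0.05)
  # missing records are a state error
  expect_error(restore_to_source(m, normalize_region(matrix(0, 3, 3))), "record")
})
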