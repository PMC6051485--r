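test_that("weighted cross-entropy reduces correctly and matches hand evaluation", {
  p <- array(c(0.9, 0.2), c(1, 2))
  y <- array(c(1L, 0L), c(1, 2))
  # all weights zero: zero loss
  expect_identical(weighted_loss(p, y, array(0, c(1, 2))), 0)
  # all weights one: the plain cross-entropy sum
  expect_equal(weighted_loss(p, y, array(1, c(1, 2))), -log(0.9) - log(0.8))
  # hand-evaluated weighted case
  expect_equal(weighted_loss(p, y, array(c(5, 1), c(1, 2))),
               -5 * log(0.9) - log(0.8))
})

test_that("the network update trains only the classifier and descends the loss", {
  set.seed(12)
  net <- build_network(tiny_spec_2d(), seed = 12L)
  x <- matrix(rnorm(14 * 12), 14, 12)
  ca <- cache_features(net, x)
  lab <- array(as.integer(matrix(rnorm(14 * 12), 14, 12) > 0), c(14, 12))
  w <- array(1, c(14, 12))

  # all-zero weights: zero gradient, parameters unchanged
  net_z <- network_update(net, ca, lab, array(0, c(14, 12)))
  expect_identical(net_z$params, net$params)

  # vanishing learning rate: vanishing parameter change
  net_eps <- network_update(net, ca, lab, w, lr = 1e-12, steps = 1L)
  expect_lt(max(abs(net_eps$params$cls$W - net$params$cls$W)), 1e-9)

  # 20 steps at lr 1e-2 do not increase the loss
  before <- weighted_loss(classifier_forward(net, ca), lab, w)
  net_up <- network_update(net, ca, lab, w, lr = 1e-2, steps = 20L)
  after <- weighted_loss(classifier_forward(net_up, ca), lab, w)
  expect_lte(after, before)

  # every non-classifier parameter is bit-identical
  bk <- setdiff(names(net$params), "cls")
  expect_identical(net_up$params[bk], net$params[bk])
})

test_that("refine with rounds = 0 is the plain CNN + CRF baseline", {
  net <- build_network(tiny_spec_2d(), seed = 3L)
  reg <- normalize_region(matrix(rnorm(20 * 18), 20, 18))
  cfg <- finetune_config(rounds = 0L)
  st <- refine(net, reg, NULL, cfg)
  p0 <- forward_probability(net, reg)
  expect_identical(st$labeling, solve_labels(p0, reg, NULL, cfg$crf))
  expect_identical(nrow(st$history), 0L)
})

test_that("refinement honours scribbles every round, lowers energy and reproduces bit for bit", {
  set.seed(6)
  sc <- generate_scene(small_scene_spec(), seed = 41L)
  inst <- extract_instances(sc$image, sc$labels)[[1]]
  inst <- prep_instance(inst, target = 48L)
  net <- build_network(tiny_spec_2d(), seed = 5L)
  fg <- which(inst$mask == 1L)[1:3]
  bg <- which(inst$mask == 0L)[1:3]
  scr <- scribble_set(fg, bg, shape = dim(inst$mask))
  cfg <- finetune_config(rounds = 3L, crf = crf_params(lambda = 3, sigma = 0.1))
  st <- refine(net, inst$region, scr, cfg, reference = inst$mask)
  expect_identical(nrow(st$history), 3L)
  expect_true(all(st$history$scribbles_satisfied))
  expect_true(all(st$labeling[fg] == 1L))
  expect_true(all(st$labeling[bg] == 0L))
  # each label update may only lower the energy at fixed parameters
  expect_true(all(st$history$energy_after <= st$history$energy_before + 1e-8))
  # classifier-only adaptation
  expect_identical(boxseg:::backbone_checksum(st$net),
                   boxseg:::backbone_checksum(net))
  # bit-reproducible given identical inputs and seed
  st2 <- refine(net, inst$region, scr, cfg, reference = inst$mask)
  expect_identical(st2$labeling, st$labeling)
  expect_identical(st2$prob, st$prob)
  # scribbles outside the region are rejected
  expect_error(refine(net, inst$region,
                      scribble_set(fg = length(inst$mask) + 5L), cfg),
               "outside")
})

test_that("segment_box crops, refines and restores; scribbles must stay inside the box", {
  set.seed(14)
  sc <- generate_scene(small_scene_spec(), seed = 55L)
  inst <- extract_instances(sc$image, sc$labels)[[1]]
  net <- build_network(tiny_spec_2d(channels = 4L), seed = 10L)
  # quick training on this single instance so the net is better than chance
  tr <- train_network(net, list(prep_instance(inst, target = 48L)),
                      train_config(max_iterations = 400L, seed = 2L))
  box <- inst$box
  cfg <- finetune_config(rounds = 2L)
  out <- segment_box(tr$net, sc$image, box, cfg = cfg, target = 48L)
  expect_identical(dim(out), dim(sc$image))
  # nothing outside the box
  inside <- array(FALSE, dim(sc$image))
  inside[(box$lo[1] + 1):box$hi[1], (box$lo[2] + 1):box$hi[2]] <- TRUE
  expect_true(all(out[!inside] == 0L))
  # beats the box-as-segmentation baseline, and is good in absolute terms
  truth <- array(as.integer(sc$labels == inst$label), dim(sc$labels))
  baseline <- array(0L, dim(sc$image))
  baseline[inside] <- 1L
  expect_gt(dice_score(out, truth), dice_score(baseline, truth))
  expect_gt(dice_score(out, truth), 0.8)
  # identical seeds give identical outputs
  out2 <- segment_box(tr$net, sc$image, box, cfg = cfg, target = 48L)
  expect_identical(as.vector(out), as.vector(out2))
  # degenerate box and out-of-box scribbles are input errors
  expect_error(segment_box(tr$net, sc$image, bounding_box(c(0, 0), c(200, 5))),
               "bounds")
  bad_fg <- array(FALSE, dim(sc$image))
  bad_fg[1, 1] <- TRUE
  if (box$lo[1] > 0 || box$lo[2] > 0) {
    expect_error(segment_box(tr$net, sc$image, box,
                             scribbles = list(fg = bad_fg), cfg = cfg,
                             target = 48L),
                 "outside")
  }
})
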