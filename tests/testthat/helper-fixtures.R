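# Shared fixtures: small network specs and scene specs sized for fast tests.

# A two-block dilated spec, structurally like the default but tiny.
tiny_spec_2d <- function(channels = 3L) {
  network_spec(list(
    list(kernel = c(3L, 3L, 1L), dilation = c(1L, 1L, 1L),
         channels = channels, layers = 2L),
    list(kernel = c(3L, 3L, 1L), dilation = c(2L, 2L, 1L),
         channels = channels, layers = 1L)), dims = 2L)
}

tiny_spec_3d <- function(channels = 3L, compression = 2L) {
  network_spec(list(
    list(kernel = c(3L, 3L, 3L), dilation = c(1L, 1L, 1L),
         channels = channels, layers = 1L),
    list(kernel = c(3L, 3L, 1L), dilation = c(2L, 2L, 1L),
         channels = channels, layers = 1L)),
    dims = 3L, compression_channels = compression)
}

# Small scenes (64 x 64) with the default four-class catalog scaled down,
# for tests that train or refine and need speed over realism.
small_scene_spec <- function() {
  classes <- lapply(default_catalog(2L), function(cl) {
    cl$size <- c(6, 11)
    cl
  })
  scene_spec(shape = c(64L, 64L), classes = classes)
}

# Random tiny CRF instance (<= 12 pixels) for oracle-equivalence tests.
random_crf_instance <- function(allow_3d = TRUE) {
  d <- if (allow_3d && runif(1) < 0.3) c(2L, 2L, 3L) else sample(2:4, 2)
  n <- prod(d)
  p <- array(runif(n), d)
  x <- array(rnorm(n), d)
  scr <- NULL
  if (runif(1) < 0.5) {
    idx <- sample(n, sample(1:3, 1))
    half <- runif(length(idx)) < 0.5
    scr <- scribble_set(idx[half], idx[!half], shape = d)
  }
  list(p = p, x = x, scr = scr,
       params = crf_params(lambda = sample(c(0, 1, 10), 1), sigma = 0.3))
}

# Count of neighbouring pixel pairs with differing labels (boundary length).
boundary_length <- function(y) {
  nb <- boxseg:::neighbor_pairs(y * 1.0, sigma = 1)
  sum(y[nb$i] != y[nb$j])
}
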