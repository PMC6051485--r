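# Shared internal helpers.

# Coerce a 2D matrix / 3D array to the internal (nx, ny, nz) layout.
# 2D inputs travel with nz = 1; `dims` records the user-facing dimensionality.
as_volume <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array, got a bare vector", call. = FALSE)
  if (length(d) == 2L) {
    array(x, c(d, 1L))
  } else if (length(d) == 3L) {
    x
  } else {
    stop("expected a 2D or 3D array, got ", length(d), " dimensions", call. = FALSE)
  }
}

ndims_of <- function(x) if (length(dim(x)) == 2L) 2L else 3L

# Drop the trailing singleton z-axis for 2D results.
as_user_shape <- function(x, dims) {
  if (dims == 2L) {
    d <- dim(x)
    array(x, d[1:2])
  } else {
    x
  }
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

clamp01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# Deterministic numeric fingerprint of a nested parameter list; used only for
# cache-staleness and "classifier untouched" checks, not for security.
param_checksum <- function(params) {
  v <- unlist(params, use.names = FALSE)
  if (length(v) == 0L) return(c(0, 0, 0))
  c(sum(v), sum(v * seq_along(v)), sum(v * v))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a stream of child seeds from one integer seed, staying within R's
# 32-bit integer range.
child_seeds <- function(seed, n, salt = 0L) {
  (as.double(seed) * 1103L + salt * 7919L + seq_len(n) * 104729L) %% 2147483587
}
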