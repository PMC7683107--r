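# Small shared fixtures, built in code.

small_spec <- function(shape = c(160, 160), ...) {
  phantom_spec(image_shape = shape, ...)
}

quiet_spec <- function(shape = c(160, 160), ...) {
  phantom_spec(image_shape = shape, noise_sd = 0, asymmetry_jitter = 0, ...)
}

# Lesion population scaled to the 160 px test phantoms.
small_dist <- function(delta_hu = -6, smooth_sigma = 1.5) {
  list(radius_range = c(6, 10), irregularity = 0.3, delta_hu = delta_hu,
       smooth_sigma = smooth_sigma)
}

# A deterministic 24-pixel blob mask inside a blank grid.
tiny_mask <- function(nr = 32, nc = 32, r0 = 10, c0 = 12) {
  m <- matrix(FALSE, nr, nc)
  m[r0 + (-2:2), c0 + (-2:2)] <- TRUE
  m[r0 - 2, c0 - 2] <- FALSE
  m
}

# Fabricated feature table with known-informative columns.
toy_table <- function(n = 24, p_noise = 20, n_perfect = 3, seed = 99) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * p_noise), n, p_noise)
  perf <- matrix(rep(y, n_perfect), n, n_perfect) + 0
  tb <- as.data.frame(cbind(perf, X))
  names(tb) <- c(paste0("perfect", seq_len(n_perfect)),
                 paste0("noise", seq_len(p_noise)))
  attr(tb, "y") <- y
  attr(tb, "pairing_id") <- rep(seq_len(n / 2), each = 2)
  class(tb) <- c("labeled_feature_table", class(tb))
  tb
}
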