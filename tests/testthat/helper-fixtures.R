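# Shared fixtures: tiny slides, CNNs and oracles built in code.

# uniform-color slide of given dimensions (0-255 per channel)
solid_slide <- function(h, w, rgb = c(0, 0, 0)) {
  px <- array(0, dim = c(h, w, 3))
  for (k in 1:3) px[, , k] <- rgb[k]
  structure(list(slide_id = "solid", patient_id = "solid", pixels = px,
                 label = -1L), class = "duv_slide")
}

# brute-force tiling oracle: per-cell double loop over pixels
oracle_valid_count <- function(pixels, patch_size, fg_thr, bg_thr) {
  gray <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
  rows <- nrow(gray) %/% patch_size
  cols <- ncol(gray) %/% patch_size
  count <- 0L
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      n_fg <- 0L
      for (i in ((r - 1) * patch_size + 1):(r * patch_size)) {
        n_fg <- n_fg + sum(gray[i, ((cc - 1) * patch_size + 1):(cc * patch_size)] >= bg_thr)
      }
      if (n_fg / patch_size^2 >= fg_thr) count <- count + 1L
    }
  }
  count
}

# smooth fixture CNN: tanh over K channels, pooled, dense head
tanh_fixture_cnn <- function(K = 2, W = NULL) {
  if (is.null(W)) {
    set.seed(99)
    W <- matrix(rnorm(2 * K), 2, K)
  }
  cnn_sequential(list(layer_activation("tanh"), layer_global_pool(),
                      layer_dense(W)), input_size = 4L)
}

# piecewise-linear fixture CNN: relu head after the target activations
relu_fixture_cnn <- function(K = 3) {
  set.seed(77)
  W <- matrix(rnorm(2 * K), 2, K)
  cnn_sequential(list(layer_activation("relu"), layer_global_pool(),
                      layer_dense(W)), input_size = 4L)
}

# central finite differences of a scalar score function at one coordinate
fd_derivs <- function(Yfun, A, idx, h = 1e-3) {
  shift <- function(s) { B <- A; B[idx[1], idx[2], idx[3]] <- A[idx[1], idx[2], idx[3]] + s; B }
  y0 <- Yfun(A)
  yp <- Yfun(shift(h)); ym <- Yfun(shift(-h))
  yp2 <- Yfun(shift(2 * h)); ym2 <- Yfun(shift(-2 * h))
  list(d1 = (yp - ym) / (2 * h),
       d2 = (yp - 2 * y0 + ym) / h^2,
       d3 = (yp2 - 2 * yp + 2 * ym - ym2) / (2 * h^3))
}

# a small well-separated phantom cohort for integration-style tests
small_cohort <- function(seed = 5, nb = 4, nm = 6) {
  generate_cohort(nb, nm, seed = seed, dims = c(800L, 1200L))
}
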