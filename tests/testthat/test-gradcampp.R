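test_that("higher-order derivatives match hand calculus on toy heads", {
  A <- array(1, c(2, 2, 1))
  # linear head Y = sum(A): first derivative 1, higher orders vanish
  lin <- cnn_sequential(list(layer_global_pool(), layer_dense(matrix(4, 1, 1))),
                        input_size = 2L)
  d <- higher_order_grads(lin, A, class_c = 1, layer = 0, resize = FALSE)
  expect_equal(d$first, array(1, c(2, 2, 1)))
  expect_equal(d$second, array(0, c(2, 2, 1)))
  expect_equal(d$third, array(0, c(2, 2, 1)))
  expect_equal(d$method, "closed_form")

  # Y = (sum A)^2 on a 2x2 map of ones: d1 = 2*sum(A) = 8, d2 = 2, d3 = 0
  sq <- cnn_sequential(list(layer_global_pool(), layer_dense(matrix(4, 1, 1)),
                            layer_activation("square")), input_size = 2L)
  d <- higher_order_grads(sq, A, class_c = 1, layer = 0, resize = FALSE)
  expect_equal(d$first, array(8, c(2, 2, 1)))
  expect_equal(d$second, array(2, c(2, 2, 1)))
  expect_equal(d$third, array(0, c(2, 2, 1)))
  expect_equal(d$method, "jets")
})

test_that("derivatives match central finite differences on smooth fixtures", {
  mod <- tanh_fixture_cnn(K = 2)
  set.seed(8)
  A <- array(runif(4 * 4 * 2, -1.5, 1.5), c(4, 4, 2))
  for (transform in c("identity", "exp")) {
    d <- higher_order_grads(mod, A, class_c = 1, layer = 0, resize = FALSE,
                            transform = transform, method = "jets")
    Yfun <- function(B) {
      s <- cnn_forward(mod, B, resize = FALSE)$scores[1]
      if (transform == "exp") exp(s) else s
    }
    for (idx in list(c(1, 1, 1), c(2, 3, 1), c(4, 4, 2), c(3, 2, 2))) {
      fd <- fd_derivs(Yfun, A, idx, h = 1e-3)
      expect_equal(d$first[idx[1], idx[2], idx[3]], fd$d1, tolerance = 1e-3)
      expect_equal(d$second[idx[1], idx[2], idx[3]], fd$d2, tolerance = 1e-3)
      expect_equal(d$third[idx[1], idx[2], idx[3]], fd$d3, tolerance = 1e-2)
    }
  }
})

test_that("closed form and jets agree on piecewise-linear heads", {
  mod <- relu_fixture_cnn(K = 3)
  set.seed(12)
  A <- array(runif(4 * 4 * 3, -1, 1), c(4, 4, 3))
  for (transform in c("identity", "exp")) {
    d1 <- higher_order_grads(mod, A, class_c = 2, layer = 0, resize = FALSE,
                             transform = transform, method = "closed_form")
    d2 <- higher_order_grads(mod, A, class_c = 2, layer = 0, resize = FALSE,
                             transform = transform, method = "jets")
    expect_equal(d1$first, d2$first, tolerance = 1e-12)
    expect_equal(d1$second, d2$second, tolerance = 1e-12)
    expect_equal(d1$third, d2$third, tolerance = 1e-12)
  }
  # nested differentiation refuses unsupported (smooth) heads in closed form
  sm <- tanh_fixture_cnn(K = 2)
  expect_error(higher_order_grads(sm, array(0.1, c(4, 4, 2)), class_c = 1,
                                  layer = 0, resize = FALSE, method = "closed_form"),
               "tanh")
})

test_that("alpha coefficients follow the stated reductions and guards", {
  dims <- c(2, 2, 1)
  # d3 = 0, d2 != 0: alpha = 1/2 everywhere
  a <- alpha_coefficients(array(1, dims), acts = array(2, dims), third = array(0, dims))
  expect_equal(a, array(0.5, dims))
  # d2 = d3 = 0: guarded to 0
  a <- alpha_coefficients(array(0, dims), acts = array(1, dims), third = array(0, dims))
  expect_equal(a, array(0, dims))
  # hand evaluation: d2 = 1, d3 = 1, sum(A) = 2 -> alpha = 1/(2 + 2)
  dims2 <- c(1, 2, 1)
  a <- alpha_coefficients(array(1, dims2), acts = array(1, dims2), third = array(1, dims2))
  expect_equal(a, array(0.25, dims2))
})

test_that("channel weights rectify gradients and reduce to Grad-CAM", {
  # all first gradients negative: rectifier kills every channel weight
  g <- array(-abs(rnorm(8)), c(2, 2, 2))
  a <- array(0.3, c(2, 2, 2))
  expect_equal(channel_weights(a, g), c(0, 0))

  # hand sum: alpha = (.25, .25), grads = (2, -1) on a 2-pixel map
  a1 <- array(0.25, c(1, 2, 1)); g1 <- array(c(2, -1), c(1, 2, 1))
  expect_equal(channel_weights(a1, g1), 0.5)

  # alpha = 1/Z without the rectifier reproduces the pooled-gradient weights
  set.seed(21)
  g2 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  aZ <- array(1 / 16, c(4, 4, 3))
  expect_equal(channel_weights(aZ, g2, rectify = FALSE), gradcam_weights(g2))
})

test_that("regional importance composes the derivative steps exactly", {
  mod <- relu_fixture_cnn(K = 3)
  set.seed(33)
  img <- array(runif(4 * 4 * 3), c(4, 4, 3))
  map <- regional_importance(mod, img, class_c = 1, layer = 1,
                             out_h = 4, out_w = 4)
  # independent step-by-step composition from raw derivative arrays
  d <- higher_order_grads(mod, img, class_c = 1, layer = 1, transform = "exp",
                          resize = FALSE)
  A <- d$activations
  K <- dim(A)[3]
  alpha <- array(0, dim(A)); w <- numeric(K)
  for (k in seq_len(K)) {
    denom <- 2 * d$second[, , k] + sum(A[, , k] * d$third[, , k])
    ak <- ifelse(abs(denom) < 1e-12, 0, d$second[, , k] / denom)
    alpha[, , k] <- ak
    w[k] <- sum(ak * pmax(d$first[, , k], 0))
  }
  cam <- matrix(0, 4, 4)
  for (k in seq_len(K)) cam <- cam + w[k] * A[, , k]
  cam <- pmax(cam, 0)
  expected <- (cam - min(cam)) / (max(cam) - min(cam))
  expect_equal(map$values, expected, tolerance = 1e-10)
  expect_true(all(map$values >= 0 & map$values <= 1))
})

test_that("importance map invariants: range, zero map, scale covariance", {
  mod <- relu_fixture_cnn(K = 3)
  set.seed(44)
  img <- array(runif(4 * 4 * 3), c(4, 4, 3))
  map <- regional_importance(mod, img, class_c = 1, layer = 1)
  expect_equal(min(map$values), 0)
  expect_equal(max(map$values), 1)

  # all-zero input through relu head: zero map flagged, no error
  zmod <- cnn_sequential(list(layer_activation("relu"), layer_global_pool(),
                              layer_dense(matrix(1, 1, 3))), input_size = 4L)
  expect_warning(zmap <- regional_importance(zmod, array(0, c(4, 4, 3)),
                                             class_c = 1, layer = 1),
                 "zero")
  expect_true(zmap$all_zero)
  expect_equal(max(zmap$values), 0)

  # single positive channel with weight 1: normalized copy of the activation
  one <- cnn_sequential(list(layer_activation("identity"), layer_global_pool(),
                             layer_dense(matrix(1, 1, 1))), input_size = 4L)
  act <- array(runif(16, 0.1, 1), c(4, 4, 1))
  m1 <- regional_importance(one, act, class_c = 1, layer = 1, out_h = 4, out_w = 4)
  ref <- (act[, , 1] - min(act)) / (max(act) - min(act))
  expect_equal(m1$values, ref, tolerance = 1e-10)

  # scale covariance: scaling the input leaves the normalized map unchanged
  m2 <- regional_importance(one, act * 3.7, class_c = 1, layer = 1,
                            out_h = 4, out_w = 4)
  expect_equal(m2$values, m1$values, tolerance = 1e-10)
})

test_that("importance map export round-trips through the 16-bit encoding", {
  mod <- relu_fixture_cnn(K = 3)
  set.seed(55)
  img <- array(runif(4 * 4 * 3), c(4, 4, 3))
  map <- regional_importance(mod, img, class_c = 1, layer = 1, out_h = 32, out_w = 32)
  f <- withr::local_tempfile(fileext = ".png")
  write_importance_map(map, f)
  back <- read_importance_map(f)
  expect_equal(back$values, map$values, tolerance = 1 / 65535)
  expect_equal(back$class_index, map$class_index)
  expect_true(file.exists(paste0(f, ".json")))
})
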