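#' Higher-order score derivatives at a CAM target layer
#'
#' Computes the first, second and third partial derivatives of the class
#' score with respect to each activation of the target layer -- the
#' quantities from which Grad-CAM++ pixel-wise gradient weights are built.
#' Only diagonal partials (powers of one activation at a time) are needed.
#'
#' Two methods are available and the one used is recorded in the output:
#'
#' * `"closed_form"` -- for heads that are piecewise linear beyond the
#'   target layer (ReLU/identity activations, global pooling, dense).  The
#'   first gradient `g` comes from one reverse-mode pass; under the
#'   `"identity"` transform the higher orders vanish, and under the
#'   `"exp"` transform (score exponentiated before differentiation, the
#'   convention of reference Grad-CAM++ implementations) the n-th
#'   derivative is `exp(S) g^n`.
#' * `"jets"` -- exact nested forward-mode differentiation (third-order
#'   Taylor jets) for arbitrary smooth heads, e.g. tanh or square
#'   activations.  Cost grows with the number of target activations, so it
#'   is intended for compact fixture networks.
#'
#' @param model a [cnn_sequential()] network.
#' @param image input array (H x W x C, unit scale).
#' @param class_c 1-based class index; default: the model's top class.
#' @param layer 1-based index of the layer whose *output* is the target
#'   activation stack; default: the last spatial layer before global
#'   pooling.
#' @param transform `"identity"` (differentiate the raw score) or `"exp"`.
#' @param method `"auto"`, `"closed_form"` or `"jets"`.
#' @param resize resize `image` to the model's native input first.
#' @return object of class `duv_deriv_stack`: arrays `first`, `second`,
#'   `third` (same shape as the activations), `activations`, `score`,
#'   `class_index`, `layer`, `method`, `transform`.
#' @export
higher_order_grads <- function(model, image, class_c = NULL, layer = NULL,
                               transform = c("identity", "exp"),
                               method = c("auto", "closed_form", "jets"),
                               resize = TRUE) {
  transform <- match.arg(transform)
  method <- match.arg(method)
  fw <- cnn_forward(model, image, resize = resize)
  if (is.null(layer)) layer <- .default_target_layer(model)
  if (layer < 0 || layer > length(model$layers)) .duv_invalid("layer index out of range")
  A <- fw$activations[[layer + 1L]]
  if (length(dim(A)) != 3L) .duv_invalid("target layer output is not a spatial activation stack")
  if (is.null(class_c)) class_c <- which.max(fw$scores)
  if (class_c < 1 || class_c > length(fw$scores)) .duv_invalid("class index out of range")

  pw <- .head_piecewise_linear(model, layer)
  if (method == "auto") method <- if (pw) "closed_form" else "jets"
  if (method == "closed_form" && !pw) {
    bad <- .first_nonlinear_head_layer(model, layer)
    .duv_stop("closed-form derivatives require a piecewise-linear head; ",
              "layer ", bad$index, " (", bad$desc, ") is not supported -- use method = 'jets'")
  }
  if (method == "closed_form") {
    g <- .head_reverse_grad(model, fw$activations, layer, class_c)
    s <- fw$scores[class_c]
    if (transform == "identity") {
      d1 <- g; d2 <- array(0, dim(A)); d3 <- array(0, dim(A))
    } else {
      e <- exp(s)
      d1 <- e * g; d2 <- e * g^2; d3 <- e * g^3
    }
  } else {
    ds <- .head_jet_derivs(model, fw$activations, layer, class_c)
    s <- fw$scores[class_c]
    tf <- switch(transform,
                 identity = list(d1 = 1, d2 = 0, d3 = 0),
                 exp = list(d1 = exp(s), d2 = exp(s), d3 = exp(s)))
    d1 <- tf$d1 * ds$a1
    d2 <- tf$d2 * ds$a1^2 + tf$d1 * ds$a2
    d3 <- tf$d3 * ds$a1^3 + 3 * tf$d2 * ds$a1 * ds$a2 + tf$d1 * ds$a3
    dim(d1) <- dim(d2) <- dim(d3) <- dim(A)
  }
  structure(list(first = d1, second = d2, third = d3, activations = A,
                 score = fw$scores[class_c], scores = fw$scores,
                 class_index = class_c, layer = layer, method = method,
                 transform = transform),
            class = "duv_deriv_stack")
}

.first_nonlinear_head_layer <- function(model, layer) {
  for (i in (layer + 1L):length(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "conv") return(list(index = i, desc = "conv"))
    if (l$type == "activation" && !(l$fun %in% c("relu", "identity")))
      return(list(index = i, desc = paste0("activation:", l$fun)))
  }
  list(index = NA_integer_, desc = "none")
}

# reverse-mode gradient of score class_c wrt the target-layer output
.head_reverse_grad <- function(model, acts, layer, class_c) {
  n_layers <- length(model$layers)
  out <- acts[[n_layers + 1L]]
  grad <- rep(0, length(out))
  grad[class_c] <- 1
  if (layer == n_layers) {
    g <- grad; dim(g) <- dim(acts[[layer + 1L]]); return(g)
  }
  for (i in n_layers:(layer + 1L)) {
    l <- model$layers[[i]]
    inp <- acts[[i]]  # input to layer i
    grad <- switch(l$type,
      dense = as.vector(t(l$W) %*% grad),
      global_pool = {
        d <- dim(inp); z <- d[1] * d[2]
        as.vector(array(rep(grad / z, each = z), dim = d))
      },
      activation = {
        if (l$fun == "relu") as.vector(grad) * as.numeric(inp > 0)
        else as.vector(grad)
      },
      .duv_stop("unsupported layer in differentiation path: layer ", i, " (", l$type, ")"))
  }
  dim(grad) <- dim(acts[[layer + 1L]])
  grad
}

# third-order Taylor jets of the raw score wrt every target activation.
# Rows of D1..D3 index the perturbed activation; columns index the running
# state. Exact for the supported layer set.
.head_jet_derivs <- function(model, acts, layer, class_c, max_coords = 2048L) {
  A <- acts[[layer + 1L]]
  n <- length(A)
  if (n > max_coords)
    .duv_stop("jet differentiation over ", n, " activations exceeds the ",
              max_coords, " limit; use a closed-form-compatible head or a smaller fixture")
  v <- as.vector(A); vdim <- dim(A)
  D1 <- diag(n); D2 <- matrix(0, n, n); D3 <- matrix(0, n, n)
  n_layers <- length(model$layers)
  if (layer < n_layers) for (i in (layer + 1L):n_layers) {
    l <- model$layers[[i]]
    if (l$type == "dense") {
      v <- as.vector(l$W %*% v + l$b); vdim <- NULL
      D1 <- D1 %*% t(l$W); D2 <- D2 %*% t(l$W); D3 <- D3 %*% t(l$W)
    } else if (l$type == "global_pool") {
      d <- vdim; z <- d[1] * d[2]; k <- d[3]
      pool <- function(M) sapply(seq_len(k), function(j)
        rowMeans(M[, ((j - 1) * z + 1):(j * z), drop = FALSE]))
      vm <- matrix(v, nrow = 1)
      v <- as.vector(pool(vm)); vdim <- NULL
      D1 <- as.matrix(pool(D1)); D2 <- as.matrix(pool(D2)); D3 <- as.matrix(pool(D3))
    } else if (l$type == "activation") {
      af <- .act_fun(l$fun)
      f1 <- af$d1(v); f2 <- af$d2(v); f3 <- af$d3(v)
      D3n <- sweep(D3, 2, f1, `*`) + 3 * sweep(D1 * D2, 2, f2, `*`) +
        sweep(D1^3, 2, f3, `*`)
      D2n <- sweep(D2, 2, f1, `*`) + sweep(D1^2, 2, f2, `*`)
      D1 <- sweep(D1, 2, f1, `*`); D2 <- D2n; D3 <- D3n
      v <- af$f(v)
    } else if (l$type == "conv") {
      convrow <- function(row) as.vector(.conv2d_same(array(row, vdim), l$weights,
                                                      numeric(dim(l$weights)[4])))
      vout <- .conv2d_same(array(v, vdim), l$weights, l$bias)
      D1 <- t(apply(D1, 1, convrow)); D2 <- t(apply(D2, 1, convrow))
      D3 <- t(apply(D3, 1, convrow))
      v <- as.vector(vout); vdim <- dim(vout)
    } else .duv_stop("unsupported layer in differentiation path: layer ", i, " (", l$type, ")")
  }
  list(a1 = D1[, class_c], a2 = D2[, class_c], a3 = D3[, class_c])
}

#' Grad-CAM++ pixel-wise gradient weights (alpha)
#'
#' `alpha = d2 / (2 d2 + sum_l A_l d3_l)` per channel and pixel, where the
#' sum runs over the channel's pixels.  Vanishing denominators (including
#' the 0/0 case) are guarded to alpha = 0.
#'
#' @param derivs a [higher_order_grads()] stack, or an H x W x K array of
#'   second derivatives.
#' @param acts activation stack (H x W x K); taken from `derivs` if absent.
#' @param third third-derivative array when `derivs` is a bare array.
#' @return H x W x K array of alpha coefficients.
#' @export
alpha_coefficients <- function(derivs, acts = NULL, third = NULL) {
  if (inherits(derivs, "duv_deriv_stack")) {
    d2 <- derivs$second; d3 <- derivs$third
    if (is.null(acts)) acts <- derivs$activations
  } else {
    d2 <- derivs; d3 <- third
    if (is.null(acts) || is.null(d3)) .duv_invalid("acts and third are required with bare arrays")
  }
  if (!identical(dim(d2), dim(acts)) || !identical(dim(d3), dim(acts)))
    .duv_invalid("derivative and activation shapes must match")
  k <- dim(acts)[3]
  alpha <- array(0, dim(acts))
  for (j in seq_len(k)) {
    s3 <- sum(acts[, , j] * d3[, , j])
    denom <- 2 * d2[, , j] + s3
    a <- d2[, , j] / denom
    a[abs(denom) < 1e-12] <- 0
    alpha[, , j] <- a
  }
  alpha
}

#' Grad-CAM++ channel weights
#'
#' `w_k = sum_l alpha_l max(d1_l, 0)`: the alpha-weighted sum of rectified
#' first gradients over each channel's pixels.  With `rectify = FALSE` and
#' `alpha` forced to `1/Z` this reduces exactly to the plain Grad-CAM
#' global-average-pooled gradient (see [gradcam_weights()]).
#'
#' @param alpha H x W x K alpha array.
#' @param first_grads H x W x K first-derivative array.
#' @param rectify apply ReLU to the first gradients (default, as in the
#'   Grad-CAM++ weight formula).
#' @return numeric vector of K channel weights.
#' @export
channel_weights <- function(alpha, first_grads, rectify = TRUE) {
  if (inherits(first_grads, "duv_deriv_stack")) first_grads <- first_grads$first
  if (!identical(dim(alpha), dim(first_grads)))
    .duv_invalid("alpha and gradient shapes must match")
  g <- if (rectify) pmax(first_grads, 0) else first_grads
  apply(alpha * g, 3, sum)
}

#' Plain Grad-CAM channel weights (global-average-pooled gradients)
#'
#' @param first_grads H x W x K first-derivative array or a deriv stack.
#' @return numeric vector of K channel weights.
#' @export
gradcam_weights <- function(first_grads) {
  if (inherits(first_grads, "duv_deriv_stack")) first_grads <- first_grads$first
  apply(first_grads, 3, mean)
}

#' Regional importance map of a slide
#'
#' Runs Grad-CAM++ end to end: the slide is resized (bilinear) to the
#' model's native input, derivatives and channel weights are computed at
#' the target layer, the rectified weighted sum of activation maps is
#' bilinearly upsampled to the requested output size and min-max
#' normalized to `[0, 1]`.  An all-zero pre-normalization map is returned
#' as-is with `all_zero = TRUE` and a warning (no divide-by-zero).
#'
#' @param model a [cnn_sequential()] network.
#' @param slide_image H x W x 3 array, 0-255 or unit scale.
#' @param class_c target class; default: the model's top-predicted class
#'   for the slide.
#' @param layer target layer (see [higher_order_grads()]).
#' @param transform score transform for differentiation; `"exp"` by
#'   default, matching reference Grad-CAM++ practice (and required for
#'   non-degenerate alphas on piecewise-linear heads).
#' @param out_h,out_w output map dimensions; default: the input slide's.
#' @return object of class `duv_importance_map`: `values` (out_h x out_w
#'   in `[0, 1]`), `class_index`, `layer`, `norm_min`, `norm_max`,
#'   `all_zero`, `method`, `channel_weights`.
#' @export
regional_importance <- function(model, slide_image, class_c = NULL, layer = NULL,
                                transform = "exp", out_h = NULL, out_w = NULL) {
  d <- dim(slide_image)
  if (length(d) != 3L) .duv_invalid("slide_image must be an H x W x C array")
  if (max(slide_image) > 1.5) slide_image <- slide_image / 255
  if (is.null(out_h)) out_h <- d[1]
  if (is.null(out_w)) out_w <- d[2]
  derivs <- higher_order_grads(model, slide_image, class_c = class_c,
                               layer = layer, transform = transform)
  alpha <- alpha_coefficients(derivs)
  w <- channel_weights(alpha, derivs$first)
  A <- derivs$activations
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (j in seq_len(dim(A)[3])) cam <- cam + w[j] * A[, , j]
  cam <- pmax(cam, 0)
  up <- resize_bilinear(cam, out_h, out_w)
  up <- pmax(up, 0)  # bilinear can keep tiny negatives out; clamp for safety
  mn <- min(up); mx <- max(up)
  all_zero <- mx <= 0
  if (all_zero) {
    warning("regional importance map is identically zero")
    vals <- matrix(0, out_h, out_w)
  } else {
    vals <- (up - mn) / (mx - mn)
  }
  structure(list(values = vals, class_index = derivs$class_index,
                 layer = derivs$layer, norm_min = mn, norm_max = mx,
                 all_zero = all_zero, method = derivs$method,
                 channel_weights = w),
            class = "duv_importance_map")
}

#' Wrap a bare matrix as an importance map
#'
#' @param values numeric matrix with entries in `[0, 1]`.
#' @param class_index,layer metadata tags.
#' @return object of class `duv_importance_map`.
#' @export
importance_map <- function(values, class_index = NA_integer_, layer = NA_integer_) {
  if (any(values < 0 | values > 1)) .duv_invalid("importance values must lie in [0, 1]")
  structure(list(values = values, class_index = class_index, layer = layer,
                 norm_min = min(values), norm_max = max(values),
                 all_zero = max(values) == 0, method = "external",
                 channel_weights = NULL),
            class = "duv_importance_map")
}

#' Fixed hue-contrast CNN for phantom slides
#'
#' A frozen two-channel color-opponency network standing in for the large
#' pretrained dense-connectivity backbone that regional importance maps
#' are computed on in the original setting.  Channel 1 responds to
#' pink/yellow (malignant-like) hues, channel 2 to green (benign-like)
#' hues; a linear head yields two class scores (1 = malignant,
#' 2 = benign).  The head is piecewise linear, so Grad-CAM++ uses the
#' exponential closed form.
#'
#' @param input_size native spatial input edge (default 128).
#' @return a [cnn_sequential()] model.
#' @export
demo_color_cnn <- function(input_size = 128L) {
  wconv <- array(0, dim = c(1, 1, 3, 2))
  wconv[1, 1, , 1] <- c(1, -0.8, -0.2)   # R - 0.8 G - 0.2 B: pink/yellow detector
  wconv[1, 1, , 2] <- c(-0.8, 1, -0.2)   # G - 0.8 R - 0.2 B: green detector
  head <- matrix(c(3, -1,
                   -1, 3), nrow = 2, byrow = TRUE)
  cnn_sequential(list(
    layer_conv(wconv),
    layer_activation("relu"),
    layer_global_pool(),
    layer_dense(head)
  ), input_size = input_size, name = "hue-contrast-cnn")
}
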