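#' Minimal CNN layers for class-activation mapping
#'
#' A small sequential-CNN representation sufficient to compute class
#' scores and the higher-order activation derivatives that Grad-CAM++
#' needs.  Supported layers: 2-D convolution (`layer_conv`, same padding),
#' elementwise activations (`layer_activation`), global average pooling
#' (`layer_global_pool`) and dense heads (`layer_dense`).  This is not a
#' training framework -- weights are fixed, as in the frozen pretrained
#' networks the package models.
#'
#' @param weights convolution kernel, array kh x kw x c_in x c_out.
#' @param bias per-output-channel bias vector.
#' @return a layer object for [cnn_sequential()].
#' @export
layer_conv <- function(weights, bias = NULL) {
  d <- dim(weights)
  if (length(d) != 4L) .duv_invalid("conv weights must be kh x kw x c_in x c_out")
  if (is.null(bias)) bias <- numeric(d[4])
  structure(list(type = "conv", weights = weights, bias = bias),
            class = "duv_cnn_layer")
}

#' @rdname layer_conv
#' @param fun activation name: `"relu"`, `"tanh"`, `"identity"`,
#'   `"square"` or `"exp"`.
#' @export
layer_activation <- function(fun = c("relu", "tanh", "identity", "square", "exp")) {
  structure(list(type = "activation", fun = match.arg(fun)),
            class = "duv_cnn_layer")
}

#' @rdname layer_conv
#' @export
layer_global_pool <- function() {
  structure(list(type = "global_pool"), class = "duv_cnn_layer")
}

#' @rdname layer_conv
#' @param W dense weight matrix (out x in).
#' @param b bias vector (length out).
#' @export
layer_dense <- function(W, b = NULL) {
  W <- as.matrix(W)
  if (is.null(b)) b <- numeric(nrow(W))
  structure(list(type = "dense", W = W, b = b), class = "duv_cnn_layer")
}

#' Assemble a sequential CNN
#'
#' @param layers list of layers built with the `layer_*` constructors.
#' @param input_size native spatial input edge in pixels; images are
#'   resized to this before a forward pass.
#' @param name model tag recorded in derived artifacts.
#' @return object of class `duv_cnn`.
#' @export
cnn_sequential <- function(layers, input_size = 64L, name = "cnn") {
  for (l in layers) if (!inherits(l, "duv_cnn_layer"))
    .duv_invalid("all layers must be duv_cnn_layer objects")
  structure(list(layers = layers, input_size = as.integer(input_size),
                 name = name), class = "duv_cnn")
}

.conv2d_same <- function(x, weights, bias) {
  d <- dim(x); kd <- dim(weights)
  kh <- kd[1]; kw <- kd[2]; cin <- kd[3]; cout <- kd[4]
  if (d[3] != cin) .duv_invalid("conv input has ", d[3], " channels, kernel expects ", cin)
  h <- d[1]; w <- d[2]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  xp <- array(0, dim = c(h + kh - 1, w + kw - 1, cin))
  xp[(ph + 1):(ph + h), (pw + 1):(pw + w), ] <- x
  out <- array(0, dim = c(h, w, cout))
  for (o in seq_len(cout)) {
    acc <- matrix(bias[o], h, w)
    for (i in seq_len(cin)) for (a in seq_len(kh)) for (b in seq_len(kw)) {
      wgt <- weights[a, b, i, o]
      if (wgt != 0) acc <- acc + wgt * xp[(a):(a + h - 1), (b):(b + w - 1), i]
    }
    out[, , o] <- acc
  }
  out
}

.act_fun <- function(fun) {
  switch(fun,
    relu = list(f = function(v) pmax(v, 0),
                d1 = function(v) as.numeric(v > 0),
                d2 = function(v) 0 * v, d3 = function(v) 0 * v),
    tanh = list(f = tanh,
                d1 = function(v) 1 - tanh(v)^2,
                d2 = function(v) { t <- tanh(v); -2 * t * (1 - t^2) },
                d3 = function(v) { t <- tanh(v); -2 * (1 - t^2) * (1 - 3 * t^2) }),
    identity = list(f = identity, d1 = function(v) 1 + 0 * v,
                    d2 = function(v) 0 * v, d3 = function(v) 0 * v),
    square = list(f = function(v) v^2, d1 = function(v) 2 * v,
                  d2 = function(v) 2 + 0 * v, d3 = function(v) 0 * v),
    exp = list(f = exp, d1 = exp, d2 = exp, d3 = exp),
    .duv_invalid("unknown activation '", fun, "'"))
}

#' Forward pass through a CNN
#'
#' @param model a [cnn_sequential()] network.
#' @param x input array (H x W x C, unit scale); resized to the model's
#'   native input size when `resize = TRUE`.
#' @param resize resize the input to `model$input_size` first.
#' @return list with `scores` (final output vector) and `activations`
#'   (per-layer outputs, index 0 = the input, as list entry names
#'   `layer0..layerL`).
#' @export
cnn_forward <- function(model, x, resize = TRUE) {
  stopifnot(inherits(model, "duv_cnn"))
  if (resize && (dim(x)[1] != model$input_size || dim(x)[2] != model$input_size))
    x <- resize_bilinear(x, model$input_size, model$input_size)
  acts <- vector("list", length(model$layers) + 1L)
  names(acts) <- paste0("layer", seq_along(acts) - 1L)
  acts[[1]] <- x
  cur <- x
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    cur <- switch(l$type,
      conv = .conv2d_same(cur, l$weights, l$bias),
      activation = { af <- .act_fun(l$fun); a <- af$f(cur); dim(a) <- dim(cur); a },
      global_pool = apply(cur, 3, mean),
      dense = as.vector(l$W %*% as.vector(cur) + l$b),
      .duv_invalid("unknown layer type '", l$type, "'"))
    acts[[i + 1L]] <- cur
  }
  list(scores = as.vector(cur), activations = acts)
}

# index of the default CAM target layer: the last spatially-resolved
# activation before global pooling (the pre-pool normalization point)
.default_target_layer <- function(model) {
  pool_at <- which(vapply(model$layers, function(l) l$type == "global_pool", TRUE))
  if (length(pool_at) == 0) .duv_invalid("model has no global_pool layer; specify `layer`")
  pool_at[1] - 1L  # activations index (0-based layer count) feeding the pool
}

# is every head layer piecewise linear with reverse-mode support
# (dense/global_pool/relu/identity)?
.head_piecewise_linear <- function(model, layer) {
  if (layer >= length(model$layers)) return(TRUE)
  for (i in (layer + 1L):length(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "activation" && !(l$fun %in% c("relu", "identity"))) return(FALSE)
    if (l$type == "conv") return(FALSE)  # no reverse-mode conv implemented
  }
  TRUE
}
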