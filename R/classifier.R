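#' Flip/rotation augmentation of a square patch
#'
#' Returns the six-variant set used to boost training data: identity,
#' horizontal flip, vertical flip and the three 90-degree rotations.
#' Rotations are counter-clockwise: under `rot90` the pixel at (row 1,
#' col 1) moves to (row S, col 1).  Variants of a symmetric patch coincide
#' numerically but are never silently deduplicated.
#'
#' @param patch S x S matrix or S x S x C array.
#' @return named list of six arrays: `identity`, `hflip`, `vflip`,
#'   `rot90`, `rot180`, `rot270`.
#' @export
augment_patch <- function(patch) {
  d <- dim(patch)
  if (is.null(d) || d[1] != d[2]) .duv_invalid("augmentation requires a square patch")
  s <- d[1]
  per_channel <- function(f) {
    if (length(d) == 2L) return(f(patch))
    out <- array(patch[1], dim = c(s, s, d[3]))
    for (k in seq_len(d[3])) out[, , k] <- f(patch[, , k])
    out
  }
  rot90 <- function(m) t(m)[s:1, , drop = FALSE]          # counter-clockwise
  list(identity = patch,
       hflip = per_channel(function(m) m[, s:1, drop = FALSE]),
       vflip = per_channel(function(m) m[s:1, , drop = FALSE]),
       rot90 = per_channel(rot90),
       rot180 = per_channel(function(m) m[s:1, s:1, drop = FALSE]),
       rot270 = per_channel(function(m) rot90(rot90(rot90(m)))))
}

#' Default boosting hyperparameters
#'
#' The library-default settings of the bundled gradient-boosted tree
#' engine; the patch classifier is always trained at these defaults (no
#' tuning).
#'
#' @param nrounds,eta,max_depth,lambda,gamma,min_child_weight standard
#'   boosting controls (logistic loss, Newton boosting, exact greedy
#'   splits, no row/column subsampling -- training is fully deterministic).
#' @return a named list.
#' @export
gbt_params <- function(nrounds = 60L, eta = 0.3, max_depth = 3L, lambda = 1,
                       gamma = 0, min_child_weight = 1) {
  list(nrounds = as.integer(nrounds), eta = eta, max_depth = as.integer(max_depth),
       lambda = lambda, gamma = gamma, min_child_weight = min_child_weight)
}

#' Train the patch-level classifier
#'
#' Fits a gradient-boosted decision-tree ensemble (logistic loss) on
#' backbone feature vectors.  Labels use the +1 malignant / -1 benign
#' convention throughout.  Training is deterministic for fixed data.
#'
#' @param features numeric matrix, one row per (possibly augmented) patch.
#' @param labels vector in `{+1, -1}`, one per row.
#' @param params a [gbt_params()] list.
#' @return object of class `duv_patch_model`.
#' @export
train_patch_classifier <- function(features, labels, params = gbt_params()) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels)) .duv_invalid("features/labels length mismatch")
  if (!all(labels %in% c(-1, 1))) .duv_invalid("labels must be +1 (malignant) or -1 (benign)")
  if (length(unique(labels)) < 2L)
    .duv_stop("training requires both classes; got a single-class input")
  y <- as.numeric(labels == 1)
  base <- log(mean(y) / (1 - mean(y)))
  fit <- .gbt_train_cpp(features, y, params$nrounds, params$eta,
                        params$max_depth, params$lambda, params$gamma,
                        params$min_child_weight, base)
  structure(list(trees = fit$trees, base_margin = fit$base_margin,
                 eta = fit$eta, feature_dim = ncol(features), params = params),
            class = "duv_patch_model")
}

#' Predict patch labels and malignant scores
#'
#' One prediction per feature row; augmentation is never applied at
#' prediction time.  The decision point is score >= 0.5, with the boundary
#' mapped to +1 (malignant) -- ties favor sensitivity.
#'
#' @param model a [train_patch_classifier()] fit.
#' @param features numeric matrix with `model$feature_dim` columns; zero
#'   rows give a zero-row result.
#' @return data.frame with columns `label` (+1/-1) and `score` (malignant
#'   probability in `[0, 1]`).
#' @export
predict_patches <- function(model, features) {
  stopifnot(inherits(model, "duv_patch_model"))
  features <- as.matrix(features)
  if (nrow(features) == 0)
    return(data.frame(label = integer(0), score = numeric(0)))
  if (ncol(features) != model$feature_dim)
    .duv_invalid("feature dimension ", ncol(features),
                 " does not match training dimension ", model$feature_dim)
  margin <- .gbt_margin_cpp(model$trees, features, model$base_margin, model$eta)
  score <- 1 / (1 + exp(-margin))
  data.frame(label = ifelse(score >= 0.5, 1L, -1L), score = score)
}

#' Persist / restore a patch classifier
#'
#' The model is stored in the engine's native JSON format (per-tree node
#' tables plus hyperparameters).
#'
#' @param model a `duv_patch_model`.
#' @param path JSON file path.
#' @return `path` (save) or the restored model (load).
#' @export
save_patch_model <- function(model, path) {
  stopifnot(inherits(model, "duv_patch_model"))
  obj <- list(trees = lapply(model$trees, function(m) as.data.frame(m)),
              base_margin = model$base_margin, eta = model$eta,
              feature_dim = model$feature_dim, params = model$params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_patch_model
#' @export
load_patch_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trees <- lapply(obj$trees, function(df) as.matrix(df))
  structure(list(trees = trees, base_margin = obj$base_margin, eta = obj$eta,
                 feature_dim = obj$feature_dim,
                 params = as.list(obj$params)),
            class = "duv_patch_model")
}
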