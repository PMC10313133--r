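#' Feature-extraction backbone contract
#'
#' A backbone is a frozen convolutional network used purely as a feature
#' extractor: patches are preprocessed to the backbone's native input size
#' and the globally average-pooled final convolutional activations are
#' returned.  No weight update ever occurs.  Two specs ship:
#'
#' * `"resnet50"` — the 2048-dimensional contract of the standard
#'   ImageNet-pretrained ResNet50 (224 x 224 input, per-channel ImageNet
#'   normalization).  Pretrained weights are not bundled and cannot be
#'   downloaded in an offline install, so calling [extract_features()]
#'   with this spec raises an informative error unless an extractor
#'   function is attached via `extractor`.
#' * `"mock"` — a deterministic, download-free stand-in (see
#'   [mock_backbone()]) with identical plumbing; swapping it for a real
#'   backbone changes only the feature dimension.
#'
#' @param name `"mock"` or `"resnet50"`.
#' @param feature_dim output dimension D (mock only; resnet50 is fixed at
#'   2048).
#' @param extractor optional function(`unit_pixels`) -> numeric D-vector
#'   supplying a real backbone implementation.
#' @return object of class `duv_backbone`.
#' @export
backbone_spec <- function(name = c("mock", "resnet50"), feature_dim = 64L,
                          extractor = NULL) {
  name <- match.arg(name)
  if (name == "resnet50") {
    return(structure(list(
      name = "resnet50", input_size = 224L, feature_dim = 2048L,
      preprocessing = list(mean = c(0.485, 0.456, 0.406),
                           sd = c(0.229, 0.224, 0.225)),
      extractor = extractor
    ), class = "duv_backbone"))
  }
  mock_backbone(feature_dim = feature_dim)
}

#' Deterministic mock backbone
#'
#' Features are a pure function of the patch pixels: the three unit-scaled
#' channel means and standard deviations, followed by a fixed seeded random
#' projection of the bilinearly downsampled `grid x grid x 3` image.  The
#' downsampled block makes the features sensitive to spatial layout, so
#' flip/rotation augmentation produces genuinely distinct training rows.
#'
#' @param feature_dim total output dimension D (>= 7).
#' @param grid downsampling edge for the projected block.
#' @param seed seed fixing the projection matrix (part of the "weights").
#' @return object of class `duv_backbone`.
#' @export
mock_backbone <- function(feature_dim = 64L, grid = 8L, seed = 909090L) {
  if (feature_dim < 7L) .duv_invalid("mock backbone needs feature_dim >= 7")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  proj <- matrix(rnorm(3L * grid * grid * (feature_dim - 6L)),
                 nrow = feature_dim - 6L) / sqrt(3 * grid * grid)
  structure(list(name = "mock", input_size = as.integer(grid),
                 feature_dim = as.integer(feature_dim), grid = as.integer(grid),
                 preprocessing = list(mean = c(0, 0, 0), sd = c(1, 1, 1)),
                 projection = proj),
            class = "duv_backbone")
}

#' Extract a feature vector from one patch
#'
#' @param patch a `duv_patch`, or an H x W x 3 pixel array on the 0-255
#'   scale.
#' @param backbone a [backbone_spec()] / [mock_backbone()].
#' @return numeric vector of length `backbone$feature_dim` with attribute
#'   `backbone_id`.
#' @export
extract_features <- function(patch, backbone = mock_backbone()) {
  px <- if (inherits(patch, "duv_patch")) patch$pixels else patch
  d <- dim(px)
  if (length(d) != 3L || d[3] != 3L) .duv_invalid("patch must be an H x W x 3 array")
  unit <- px / 255
  if (backbone$name == "mock") {
    small <- resize_bilinear(unit, backbone$grid, backbone$grid)
    v <- c(apply(unit, 3, mean), apply(unit, 3, stats::sd),
           as.vector(backbone$projection %*% as.vector(small)))
  } else {
    if (is.null(backbone$extractor))
      .duv_stop("backbone '", backbone$name, "' has no bundled weights; ",
                "attach an extractor function or use mock_backbone()")
    unit <- resize_bilinear(unit, backbone$input_size, backbone$input_size)
    for (k in 1:3) unit[, , k] <- (unit[, , k] - backbone$preprocessing$mean[k]) /
        backbone$preprocessing$sd[k]
    v <- backbone$extractor(unit)
    if (length(v) != backbone$feature_dim)
      .duv_stop("extractor returned ", length(v), " values, expected ",
                backbone$feature_dim)
  }
  v <- as.numeric(v)
  attr(v, "backbone_id") <- backbone$name
  v
}

#' Extract features for a list of patches
#'
#' Order-stable: row i corresponds to `patches[[i]]`.  An empty list gives
#' an empty (0-row) table, not an error.
#'
#' @param patches list of patches (see [extract_features()]).
#' @param backbone a backbone spec.
#' @return numeric matrix, one row per patch, D columns.
#' @export
batch_extract <- function(patches, backbone = mock_backbone()) {
  out <- matrix(numeric(0), nrow = 0, ncol = backbone$feature_dim)
  if (length(patches) == 0) return(out)
  out <- matrix(0, nrow = length(patches), ncol = backbone$feature_dim)
  for (i in seq_along(patches)) out[i, ] <- extract_features(patches[[i]], backbone)
  out
}
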