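#' Mean regional importance over a patch footprint
#'
#' Averages the importance map over the pixels of the grid cell at
#' (`row`, `col`) (0-based indices; half-open pixel footprints
#' `[row * patch_size, (row + 1) * patch_size)`).
#'
#' @param map a `duv_importance_map` or a bare numeric matrix at slide
#'   resolution.
#' @param row,col 0-based grid indices of the patch.
#' @param patch_size patch edge in pixels.
#' @return scalar mean importance `r_ij` in `[0, 1]`.
#' @export
patch_importance <- function(map, row, col, patch_size = 400L) {
  vals <- if (inherits(map, "duv_importance_map")) map$values else map
  r0 <- row * patch_size + 1L; r1 <- (row + 1L) * patch_size
  c0 <- col * patch_size + 1L; c1 <- (col + 1L) * patch_size
  if (row < 0 || col < 0 || r1 > nrow(vals) || c1 > ncol(vals))
    .duv_invalid("patch footprint (", row, ",", col, ") lies outside the map")
  mean(vals[r0:r1, c0:c1])
}

#' Threshold a patch importance into a fusion weight
#'
#' `w_ij = 0` when `r_ij` falls strictly below the importance threshold,
#' otherwise `r_ij` itself (the boundary value is kept).  Low-importance
#' patches are thereby ignored in the fused slide decision.
#'
#' @param r mean patch importance, in `[0, 1]` (vectorized).
#' @param threshold importance cutoff (default 0.25).
#' @return weights with entries in `{0} U [threshold, 1]`.
#' @export
patch_weight <- function(r, threshold = 0.25) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1))
    .duv_invalid("patch importance must lie in [0, 1]")
  ifelse(r < threshold, 0, r)
}

#' Importance-weighted slide-level decision
#'
#' Multiplies each patch label by its importance weight
#' (`u_ij = w_ij y_ij`), counts the confidently-malignant patches
#' (`H_i = #\{u_ij > 0\}`) and calls the slide malignant when `H_i`
#' exceeds the fraction `q` of the `M_i` valid foreground patches:
#' `y_i = +1` iff `H_i > q M_i`.
#'
#' @param labels patch labels in `{+1, -1}`.
#' @param weights patch weights in `[0, 1]` (typically [patch_weight()]
#'   output), same length.
#' @param q decision fraction in `[0, 1]`; the default 0 flags a slide on
#'   any confidently-important malignant patch, favoring sensitivity.
#' @return object of class `duv_fusion_result`: `u`, `H`, `M`, `q`,
#'   `label` (+1/-1).
#' @export
slide_decision <- function(labels, weights, q = 0) {
  if (length(labels) == 0) .duv_stop("no valid patches: cannot fuse an empty slide")
  if (length(labels) != length(weights)) .duv_invalid("labels/weights length mismatch")
  if (!all(labels %in% c(-1, 1))) .duv_invalid("labels must be +1 or -1")
  if (any(weights < 0 | weights > 1)) .duv_invalid("weights must lie in [0, 1]")
  if (q < 0 || q > 1) .duv_invalid("q must lie in [0, 1]")
  u <- weights * labels
  H <- sum(u > 0)
  M <- length(labels)
  structure(list(u = u, H = H, M = M, q = q,
                 label = if (H > q * M) 1L else -1L),
            class = "duv_fusion_result")
}

#' Majority-vote slide baseline
#'
#' The unweighted comparison scheme: the slide is malignant when the
#' malignant patches reach at least half of the valid patches (ties go to
#' malignant).
#'
#' @param labels patch labels in `{+1, -1}`.
#' @return slide label +1 or -1.
#' @export
majority_vote <- function(labels) {
  if (length(labels) == 0) .duv_stop("no valid patches: cannot vote on an empty slide")
  if (!all(labels %in% c(-1, 1))) .duv_invalid("labels must be +1 or -1")
  if (2L * sum(labels == 1) >= length(labels)) 1L else -1L
}

#' Sweep the fusion fraction q over a slide
#'
#' Utility for choosing the operating point: evaluates [slide_decision()]
#' on a grid of q values.
#'
#' @param labels,weights as in [slide_decision()].
#' @param q_grid fractions to evaluate.
#' @return data.frame with columns `q` and `label`.
#' @export
sweep_q <- function(labels, weights, q_grid = seq(0, 1, by = 0.05)) {
  data.frame(q = q_grid,
             label = vapply(q_grid, function(q)
               slide_decision(labels, weights, q)$label, integer(1)))
}
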