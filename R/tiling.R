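#' Plan the non-overlapping patch grid for a slide
#'
#' Slides are resized to the closest dimensions evenly divisible into
#' non-overlapping `patch_size` x `patch_size` patches.  Ties halfway
#' between two multiples round up (preserving tissue); dimensions below
#' half a patch round up to a single patch.
#'
#' @param height,width slide dimensions in pixels, both >= 1.
#' @param patch_size patch edge in pixels (default 400).
#' @return object of class `duv_grid_plan`: `resized_h`, `resized_w`,
#'   `rows`, `cols`, `n_patches`, `patch_size`.
#' @export
plan_grid <- function(height, width, patch_size = 400L) {
  if (length(height) != 1 || length(width) != 1 || length(patch_size) != 1 ||
      !is.finite(height) || !is.finite(width) || !is.finite(patch_size) ||
      height < 1 || width < 1 || patch_size < 1)
    .duv_invalid("height, width and patch_size must be positive")
  rows <- max(1L, as.integer(floor(height / patch_size + 0.5)))
  cols <- max(1L, as.integer(floor(width / patch_size + 0.5)))
  structure(list(resized_h = rows * as.integer(patch_size),
                 resized_w = cols * as.integer(patch_size),
                 rows = rows, cols = cols, n_patches = rows * cols,
                 patch_size = as.integer(patch_size)),
            class = "duv_grid_plan")
}

#' Convert RGB pixels to grayscale luma
#'
#' ITU-R BT.601 luma: `0.299 R + 0.587 G + 0.114 B`, kept real-valued (no
#' rounding) so that thresholding is applied to exact values.
#'
#' @param pixels H x W x 3 numeric array on the 0-255 scale.
#' @return H x W numeric matrix.
#' @export
to_grayscale <- function(pixels) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) .duv_invalid("pixels must be an H x W x 3 array")
  g <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
  dim(g) <- d[1:2]
  g
}

#' Foreground fraction of a grayscale patch
#'
#' Fraction of pixels whose luma clears the background threshold
#' (`>= background_threshold`, default 5).  DUV backgrounds are near-black,
#' so this separates tissue from empty slide area.
#'
#' @param gray_patch numeric matrix of luma values.
#' @param background_threshold luma cutoff (default 5).
#' @return scalar in `[0, 1]`.
#' @export
foreground_fraction <- function(gray_patch, background_threshold = 5) {
  if (length(gray_patch) == 0) .duv_invalid("empty patch")
  mean(gray_patch >= background_threshold)
}

#' Default tiling/pipeline configuration
#'
#' @param patch_size patch edge in pixels.
#' @param foreground_threshold minimum foreground fraction for a patch to
#'   be kept (default 0.2, following the extraction pseudocode; the prose
#'   figure of 0.8 is available by configuration).
#' @param background_threshold luma cutoff separating tissue from
#'   background.
#' @return a named list.
#' @export
tiling_config <- function(patch_size = 400L, foreground_threshold = 0.2,
                          background_threshold = 5) {
  if (foreground_threshold < 0 || foreground_threshold > 1)
    .duv_invalid("foreground_threshold must lie in [0, 1]")
  list(patch_size = as.integer(patch_size),
       foreground_threshold = foreground_threshold,
       background_threshold = background_threshold)
}

#' Extract foreground-valid patches from a slide
#'
#' Resizes the slide to grid-aligned dimensions (bilinear), converts to
#' grayscale, computes every cell's foreground fraction and keeps exactly
#' the cells at or above `foreground_threshold`.  Patch footprints are
#' disjoint and tile the resized slide; grid indices are 0-based,
#' row-major.
#'
#' @param slide a `duv_slide` (list with `slide_id`, `patient_id`,
#'   `pixels`, `label`) or a bare H x W x 3 pixel array.
#' @param config a [tiling_config()].
#' @param keep_pixels if `FALSE`, per-patch pixel arrays are not stored
#'   (fractions and validity only), which bounds memory on large cohorts.
#' @return object of class `duv_patchset`: `grid` (the plan), `fractions`
#'   (rows x cols matrix), `cells` data.frame over all grid cells (`row`,
#'   `col`, 0-based; `foreground_fraction`; `valid`), `patches` (list of
#'   valid `duv_patch` records), `n_valid` (the count of valid foreground
#'   patches), and slide metadata.
#' @export
extract_valid_patches <- function(slide, config = tiling_config(),
                                  keep_pixels = TRUE) {
  if (is.array(slide) || is.matrix(slide)) {
    slide <- structure(list(slide_id = "slide", patient_id = "slide",
                            pixels = slide, label = NA_integer_),
                       class = "duv_slide")
  }
  px <- slide$pixels
  d <- dim(px)
  if (length(d) != 3L || d[3] != 3L) .duv_invalid("slide pixels must be H x W x 3")
  plan <- plan_grid(d[1], d[2], config$patch_size)
  if (d[1] != plan$resized_h || d[2] != plan$resized_w) {
    px <- resize_bilinear(px, plan$resized_h, plan$resized_w)
  }
  gray <- to_grayscale(px)
  p <- plan$patch_size
  fractions <- matrix(0, plan$rows, plan$cols)
  fg <- gray >= config$background_threshold
  for (r in seq_len(plan$rows)) {
    rs <- ((r - 1) * p + 1):(r * p)
    for (cc in seq_len(plan$cols)) {
      fractions[r, cc] <- mean(fg[rs, ((cc - 1) * p + 1):(cc * p)])
    }
  }
  valid <- fractions >= config$foreground_threshold
  cells <- data.frame(
    row = rep(seq_len(plan$rows) - 1L, times = plan$cols),
    col = rep(seq_len(plan$cols) - 1L, each = plan$rows),
    foreground_fraction = as.vector(fractions),
    valid = as.vector(valid)
  )
  cells <- cells[order(cells$row, cells$col), , drop = FALSE]
  rownames(cells) <- NULL
  patches <- list()
  vc <- cells[cells$valid, , drop = FALSE]
  for (i in seq_len(nrow(vc))) {
    r <- vc$row[i]; cc <- vc$col[i]
    patches[[i]] <- structure(list(
      row = r, col = cc,
      pixels = if (keep_pixels) px[(r * p + 1):((r + 1) * p),
                                   (cc * p + 1):((cc + 1) * p), , drop = FALSE] else NULL,
      foreground_fraction = vc$foreground_fraction[i], valid = TRUE
    ), class = "duv_patch")
  }
  structure(list(grid = plan, fractions = fractions, cells = cells,
                 patches = patches, n_valid = nrow(vc),
                 slide_id = slide$slide_id, patient_id = slide$patient_id,
                 label = slide$label, resized_pixels = if (keep_pixels) px else NULL),
            class = "duv_patchset")
}

#' Write extracted patches and their manifest
#'
#' Writes each valid patch as `{slide_id}_r{row}_c{col}.png` plus a
#' patch-manifest CSV with columns slide_id, patient_id, row, col,
#' foreground_fraction, label.
#'
#' @param patchset a [extract_valid_patches()] result with pixels kept.
#' @param out_dir output directory, created if missing.
#' @return the manifest path, invisibly.
#' @export
write_patchset <- function(patchset, out_dir) {
  stopifnot(inherits(patchset, "duv_patchset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (p in patchset$patches) {
    if (is.null(p$pixels)) .duv_invalid("patch pixels were not kept; re-extract with keep_pixels = TRUE")
    write_slide_image(p$pixels, file.path(
      out_dir, sprintf("%s_r%d_c%d.png", patchset$slide_id, p$row, p$col)))
  }
  vc <- patchset$cells[patchset$cells$valid, , drop = FALSE]
  manifest <- data.frame(slide_id = patchset$slide_id,
                         patient_id = patchset$patient_id,
                         row = vc$row, col = vc$col,
                         foreground_fraction = vc$foreground_fraction,
                         label = patchset$label)
  mp <- file.path(out_dir, sprintf("%s_patches.csv", patchset$slide_id))
  write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}
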