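#' Phantom slide specification
#'
#' Describes a synthetic DUV-like slide: overall dimensions, elliptical or
#' rectangular tissue regions with a tissue class, class color palettes and
#' texture parameters.  Phantoms emulate the statistical structure of
#' deep-UV fluorescence surface images: a near-black background (luma < 5),
#' benign tissue in light/dark green hues, malignant tissue in pink/yellow
#' hues with a higher density of bright "nuclei" spots.
#'
#' @param height,width slide dimensions in pixels.
#' @param regions list of regions, each created by [phantom_region()].
#' @param spot_density named numeric: expected bright spots per pixel for
#'   each class (`benign`, `malignant`); malignant defaults higher, a proxy
#'   for high cell density and infiltration.
#' @param noise_sd standard deviation of the additive Gaussian texture
#'   noise, on the 0-255 channel scale.
#' @param contrast class-color separation in `[0, 1]`: 1 keeps the full
#'   pink/yellow vs green hue gap, 0 collapses malignant colors onto the
#'   benign mean. Controls how separable the classes are by construction.
#' @return object of class `duv_phantom_spec`.
#' @export
phantom_spec <- function(height, width, regions = list(),
                         spot_density = c(benign = 2e-4, malignant = 8e-4),
                         noise_sd = 6, contrast = 1) {
  if (height < 1 || width < 1) .duv_invalid("phantom dimensions must be >= 1")
  if (contrast < 0 || contrast > 1) .duv_invalid("contrast must lie in [0, 1]")
  for (rg in regions) {
    if (!inherits(rg, "duv_phantom_region")) .duv_invalid("regions must be built by phantom_region()")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 regions = regions, spot_density = spot_density,
                 noise_sd = noise_sd, contrast = contrast),
            class = "duv_phantom_spec")
}

#' Define one tissue region of a phantom slide
#'
#' @param shape `"ellipse"` or `"rect"`.
#' @param cx,cy centre in pixels (column, row).
#' @param rx,ry half-axes (ellipse) or half-widths (rectangle) in pixels.
#' @param class `"malignant"` or `"benign"`.
#' @param shade palette entry: 1 = light variant, 2 = dark variant (benign
#'   light/dark green; malignant pink/yellow).
#' @return object of class `duv_phantom_region`.
#' @export
phantom_region <- function(shape = c("ellipse", "rect"), cx, cy, rx, ry,
                           class = c("benign", "malignant"), shade = 1L) {
  shape <- match.arg(shape)
  class <- match.arg(class)
  if (rx <= 0 || ry <= 0) .duv_invalid("degenerate region: half-axes must be positive")
  structure(list(shape = shape, cx = cx, cy = cy, rx = rx, ry = ry,
                 class = class, shade = as.integer(shade)),
            class = "duv_phantom_region")
}

# class palettes on the 0-255 scale (rows: light, dark variants)
.phantom_palette <- function(contrast = 1) {
  benign <- rbind(light = c(110, 190, 110), dark = c(45, 115, 55))
  malignant <- rbind(pink = c(235, 130, 170), yellow = c(230, 210, 90))
  benign_mean <- colMeans(benign)
  malignant <- contrast * malignant +
    (1 - contrast) * matrix(benign_mean, 2, 3, byrow = TRUE)
  list(benign = benign, malignant = malignant)
}

.region_mask <- function(rg, height, width) {
  row <- seq_len(height); col <- seq_len(width)
  if (rg$shape == "ellipse") {
    dy <- (row - rg$cy) / rg$ry
    dx <- (col - rg$cx) / rg$rx
    outer(dy^2, dx^2, `+`) <= 1
  } else {
    inr <- abs(row - rg$cy) <= rg$ry
    inc <- abs(col - rg$cx) <= rg$rx
    outer(inr, inc, `&`)
  }
}

#' Generate a phantom slide with ground truth
#'
#' Renders the regions of a [phantom_spec()] into an 8-bit RGB slide plus a
#' per-pixel tissue mask and a per-patch ground-truth grid.  Reproducible:
#' the same spec and seed give bit-identical output.  Background pixels are
#' clipped so their grayscale luma stays below 5; tissue pixels always
#' clear the foreground threshold.
#'
#' @param spec a [phantom_spec()].
#' @param slide_id,patient_id identifiers stored on the slide record.
#' @param seed integer seed for the texture noise and spot placement.
#' @param patch_size patch edge used for the ground-truth grid.
#' @return a list with elements `slide` (a `duv_slide`: `slide_id`,
#'   `patient_id`, `pixels` H x W x 3 in 0..255, `label` +1/-1), `mask`
#'   (integer matrix, 0 background / 1 benign / 2 malignant) and
#'   `patch_truth` (see [patch_truth_grid()]).
#' @export
generate_slide <- function(spec, slide_id = "phantom", patient_id = slide_id,
                           seed = 1L, patch_size = 400L) {
  stopifnot(inherits(spec, "duv_phantom_spec"))
  h <- spec$height; w <- spec$width
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  pal <- .phantom_palette(spec$contrast)
  mask <- matrix(0L, h, w)

  # background: dim near-black speckle in [0, 4] -- luma stays below 5.
  # one shared draw across channels keeps generation cheap at full slide size
  bg <- runif(h * w, 0, 4)
  dim(bg) <- c(h, w)
  ch <- list(bg, bg, bg)

  disc <- which(outer((-3):3, (-3):3, function(a, b) a^2 + b^2) <= 9, arr.ind = TRUE) - 4L
  for (rg in spec$regions) {
    inside <- .region_mask(rg, h, w)
    npix <- sum(inside)
    if (npix == 0) .duv_invalid("degenerate region: no pixels inside slide bounds")
    cls_code <- if (rg$class == "malignant") 2L else 1L
    mask[inside] <- cls_code
    base <- pal[[rg$class]][rg$shade, ]
    for (k in 1:3) {
      vals <- base[k] + rnorm(npix, 0, spec$noise_sd)
      ch[[k]][inside] <- vals
    }
    # bright nuclei spots: Poisson count at the class density
    nspot <- rpois(1, spec$spot_density[[rg$class]] * npix)
    if (nspot > 0) {
      idx <- which(inside)
      centres <- idx[sample.int(length(idx), nspot, replace = TRUE)]
      cr <- ((centres - 1L) %% h) + 1L
      cc <- ((centres - 1L) %/% h) + 1L
      pr <- rep(cr, each = nrow(disc)) + rep(disc[, 1], nspot)
      pc <- rep(cc, each = nrow(disc)) + rep(disc[, 2], nspot)
      keep <- pr >= 1 & pr <= h & pc >= 1 & pc <= w
      pr <- pr[keep]; pc <- pc[keep]
      lin <- (pc - 1L) * h + pr
      lin <- lin[inside[lin]]  # spots stay inside their region's tissue
      boost <- c(1.35, 1.35, 1.35)
      for (k in 1:3) ch[[k]][lin] <- pmin(ch[[k]][lin] * boost[k] + 25, 255)
    }
  }
  tissue <- which(mask > 0L)
  pixels <- array(0L, dim = c(h, w, 3L))
  for (k in 1:3) {
    ch[[k]][tissue] <- pmin(pmax(ch[[k]][tissue], 12), 255)  # tissue clears luma 5
    pixels[, , k] <- as.integer(ch[[k]] + 0.5)  # round: values are non-negative
  }

  label <- if (any(mask == 2L)) 1L else -1L
  slide <- structure(list(slide_id = slide_id, patient_id = patient_id,
                          pixels = pixels, label = label),
                     class = "duv_slide")
  list(slide = slide, mask = mask,
       patch_truth = patch_truth_grid(mask, patch_size))
}

# save/restore the global RNG state so generators are pure wrt the session
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Ground-truth patch-label grid from a pixel mask
#'
#' Tiles the mask with the same grid plan as the slide (nearest-neighbour
#' resampling when the dimensions are not patch multiples) and labels each
#' cell with its majority tissue class.  Ties between classes break toward
#' malignant (clinically conservative).
#'
#' @param mask integer matrix: 0 background, 1 benign, 2 malignant.
#' @param patch_size patch edge in pixels.
#' @return list with `majority` (rows x cols integer matrix of 0/1/2),
#'   `train_label` (+1 where malignant pixels outnumber benign, else -1)
#'   and the `grid` plan used.
#' @export
patch_truth_grid <- function(mask, patch_size = 400L) {
  plan <- plan_grid(nrow(mask), ncol(mask), patch_size)
  m <- mask
  if (nrow(m) != plan$resized_h || ncol(m) != plan$resized_w) {
    ri <- pmin(pmax(round((seq_len(plan$resized_h) - 0.5) * nrow(m) / plan$resized_h + 0.5), 1), nrow(m))
    ci <- pmin(pmax(round((seq_len(plan$resized_w) - 0.5) * ncol(m) / plan$resized_w + 0.5), 1), ncol(m))
    m <- m[ri, ci, drop = FALSE]
  }
  maj <- matrix(0L, plan$rows, plan$cols)
  trl <- matrix(-1L, plan$rows, plan$cols)
  p <- plan$patch_size
  for (r in seq_len(plan$rows)) {
    for (cc in seq_len(plan$cols)) {
      cell <- m[((r - 1) * p + 1):(r * p), ((cc - 1) * p + 1):(cc * p)]
      counts <- tabulate(cell + 1L, nbins = 3L)  # bg, benign, malignant
      top <- max(counts)
      maj[r, cc] <- if (counts[3] == top) 2L else if (counts[2] == top) 1L else 0L
      trl[r, cc] <- if (counts[3] >= counts[2] && counts[3] > 0L) 1L else -1L
    }
  }
  list(majority = maj, train_label = trl, grid = plan)
}

#' Generate a phantom cohort
#'
#' Builds a cohort of phantom slides mirroring the study composition the
#' package emulates (24 benign / 36 malignant by default).  Patients are
#' assigned so that roughly one in five contributes two or three slides,
#' exercising grouped cross-validation.  Slides are predominantly one
#' tissue class; malignant slides may carry a small benign satellite
#' region.  Slides are materialized lazily via [cohort_slide()] to keep
#' memory bounded.
#'
#' @param n_benign,n_malignant slide counts per class.
#' @param seed integer master seed; every slide derives its own sub-seed.
#' @param dims candidate slide edge lengths in pixels, sampled per slide.
#' @param contrast class-color separation passed to [phantom_spec()].
#' @param patch_size patch edge for ground-truth grids.
#' @return object of class `duv_cohort`: `manifest` data.frame (slide_id,
#'   patient_id, label), per-slide `specs`, `seeds`, and `patch_size`.
#' @export
generate_cohort <- function(n_benign = 24, n_malignant = 36, seed = 1L,
                            dims = c(1200L, 1600L, 2000L), contrast = 1,
                            patch_size = 400L) {
  if (n_benign < 0 || n_malignant < 0) .duv_invalid("counts must be >= 0")
  n <- n_benign + n_malignant
  if (n == 0) .duv_invalid("cohort must contain at least one slide")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  labels <- c(rep(-1L, n_benign), rep(1L, n_malignant))
  # patients: ~20% carry 2-3 slides of the same class
  patient_of <- integer(n); pid <- 0L
  for (cls in c(-1L, 1L)) {
    idx <- which(labels == cls)
    i <- 1L
    while (i <= length(idx)) {
      pid <- pid + 1L
      take <- if (runif(1) < 0.2) min(sample(2:3, 1), length(idx) - i + 1L) else 1L
      patient_of[idx[i:(i + take - 1L)]] <- pid
      i <- i + take
    }
  }
  specs <- vector("list", n)
  seeds <- integer(n)
  for (i in seq_len(n)) {
    h <- dims[sample.int(length(dims), 1)]
    w <- dims[sample.int(length(dims), 1)]
    cls <- if (labels[i] == 1L) "malignant" else "benign"
    # slides are predominantly one tissue class: regions are large enough
    # that tissue, not background, dominates the specimen surface
    nreg <- sample(1:3, 1)
    regions <- list()
    for (j in seq_len(nreg)) {
      rx <- runif(1, 0.22, 0.4) * w; ry <- runif(1, 0.22, 0.4) * h
      cx <- runif(1, rx + 10, w - rx - 10); cy <- runif(1, ry + 10, h - ry - 10)
      regions[[j]] <- phantom_region("ellipse", cx, cy, rx, ry, class = cls,
                                     shade = sample(1:2, 1))
    }
    if (cls == "malignant" && runif(1) < 0.4) {
      # small benign satellite, well under the tumor burden
      rx <- runif(1, 0.06, 0.1) * w; ry <- runif(1, 0.06, 0.1) * h
      cx <- runif(1, rx + 10, w - rx - 10); cy <- runif(1, ry + 10, h - ry - 10)
      regions[[nreg + 1L]] <- phantom_region("ellipse", cx, cy, rx, ry,
                                             class = "benign", shade = sample(1:2, 1))
    }
    specs[[i]] <- phantom_spec(h, w, regions, contrast = contrast)
    seeds[i] <- (seed %% 100000L) * 20000L + i  # < 2^31 for any small seed
  }
  ord <- sample.int(n)  # interleave classes in the manifest
  manifest <- data.frame(
    slide_id = sprintf("phantom_%03d", seq_len(n)),
    patient_id = sprintf("patient_%03d", patient_of[ord]),
    label = labels[ord], stringsAsFactors = FALSE
  )
  structure(list(manifest = manifest, specs = specs[ord], seeds = seeds[ord],
                 patch_size = as.integer(patch_size), seed = seed),
            class = "duv_cohort")
}

#' Materialize one slide of a phantom cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @param i slide index into the cohort manifest.
#' @return the [generate_slide()] result for slide `i`.
#' @export
cohort_slide <- function(cohort, i) {
  stopifnot(inherits(cohort, "duv_cohort"))
  if (i < 1 || i > nrow(cohort$manifest)) .duv_invalid("slide index out of range")
  generate_slide(cohort$specs[[i]],
                 slide_id = cohort$manifest$slide_id[i],
                 patient_id = cohort$manifest$patient_id[i],
                 seed = cohort$seeds[i], patch_size = cohort$patch_size)
}

#' Write a phantom cohort to disk
#'
#' Writes each slide as PNG, each truth mask as a compact run-length CSV,
#' and the cohort manifest CSV (slide_id, patient_id, label).
#'
#' @param cohort a [generate_cohort()] result.
#' @param out_dir output directory, created if missing.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "slides"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  for (i in seq_len(nrow(cohort$manifest))) {
    g <- cohort_slide(cohort, i)
    sid <- cohort$manifest$slide_id[i]
    write_slide_image(g$slide$pixels, file.path(out_dir, "slides", paste0(sid, ".png")))
    rle_df <- with(rle(as.integer(g$mask)), data.frame(lengths = lengths, values = values))
    rle_df$nrow <- c(nrow(g$mask), rep(NA, nrow(rle_df) - 1L))
    write.csv(rle_df, file.path(out_dir, "masks", paste0(sid, "_mask.csv")), row.names = FALSE)
  }
  mp <- file.path(out_dir, "manifest.csv")
  write.csv(cohort$manifest, mp, row.names = FALSE)
  invisible(mp)
}
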