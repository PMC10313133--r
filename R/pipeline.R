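#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline.  Defaults follow the
#' emulated protocol: 400-pixel patches, foreground fraction >= 0.2 at
#' luma threshold 5, six-variant flip/rotation augmentation, importance
#' threshold 0.25, fusion fraction q = 0 and grouped stratified 5-fold
#' cross-validation.
#'
#' @param patch_size patch edge in pixels.
#' @param foreground_threshold minimum foreground fraction for a valid
#'   patch.
#' @param background_threshold luma cutoff for foreground pixels.
#' @param backbone `"mock"` (deterministic, download-free) or
#'   `"resnet50"` (requires an attached extractor).
#' @param feature_dim mock backbone output dimension.
#' @param augment apply six-variant flip/rotation augmentation to
#'   training patches (never at prediction time).
#' @param importance_threshold cutoff below which a patch's importance
#'   weight is zeroed.
#' @param q fusion fraction: slide malignant iff `H_i > q M_i`.
#' @param k cross-validation folds.
#' @param seed master seed for cohort generation and fold assignment.
#' @param importance_class `"auto"` (model's top class per slide) or a
#'   fixed 1-based class index.
#' @param importance_transform score transform for Grad-CAM++
#'   differentiation.
#' @param importance_input spatial input edge of the importance CNN.
#' @param n_benign,n_malignant phantom cohort composition (defaults mirror
#'   the emulated 24/36 cohort).
#' @param phantom_contrast phantom class-color separation in `[0, 1]`.
#' @param phantom_dims candidate phantom slide edges in pixels.
#' @param gbt boosting hyperparameters ([gbt_params()]).
#' @param out_dir optional directory where artifacts are persisted.
#' @param save_maps also write per-slide importance maps (slower).
#' @return a named list of class `duv_pipeline_config`.
#' @export
pipeline_config <- function(patch_size = 400L, foreground_threshold = 0.2,
                            background_threshold = 5, backbone = "mock",
                            feature_dim = 64L, augment = TRUE,
                            importance_threshold = 0.25, q = 0, k = 5L,
                            seed = 1L, importance_class = "auto",
                            importance_transform = "exp",
                            importance_input = 128L, n_benign = 24L,
                            n_malignant = 36L, phantom_contrast = 1,
                            phantom_dims = c(1200L, 1600L, 2000L),
                            gbt = gbt_params(), out_dir = NULL,
                            save_maps = FALSE) {
  if (q < 0 || q > 1) .duv_invalid("q must lie in [0, 1]")
  if (importance_threshold < 0 || importance_threshold > 1)
    .duv_invalid("importance_threshold must lie in [0, 1]")
  structure(list(
    patch_size = as.integer(patch_size),
    foreground_threshold = foreground_threshold,
    background_threshold = background_threshold, backbone = backbone,
    feature_dim = as.integer(feature_dim), augment = isTRUE(augment),
    importance_threshold = importance_threshold, q = q, k = as.integer(k),
    seed = as.integer(seed), importance_class = importance_class,
    importance_transform = importance_transform,
    importance_input = as.integer(importance_input),
    n_benign = as.integer(n_benign), n_malignant = as.integer(n_malignant),
    phantom_contrast = phantom_contrast, phantom_dims = as.integer(phantom_dims),
    gbt = gbt, out_dir = out_dir, save_maps = isTRUE(save_maps)
  ), class = "duv_pipeline_config")
}

# mock-backbone feature rows for the six augmentation variants of a patch.
# Bilinear downsampling commutes exactly with flips and 90-degree
# rotations, so augmenting the downsampled block equals downsampling the
# augmented patch; channel means/sds are invariant under the group.
.mock_variant_features <- function(patch_px, backbone) {
  unit <- patch_px / 255
  base <- c(apply(unit, 3, mean), apply(unit, 3, stats::sd))
  small <- resize_bilinear(unit, backbone$grid, backbone$grid)
  vars <- augment_patch(small)
  t(vapply(vars, function(v)
    c(base, as.vector(backbone$projection %*% as.vector(v))),
    numeric(backbone$feature_dim)))
}

#' Run the end-to-end pipeline on a phantom cohort
#'
#' Executes tile -> features -> grouped-CV train/predict -> Grad-CAM++
#' importance -> fusion -> evaluation.  Per-slide work is streamed so
#' memory stays bounded; every threshold used is recorded in the result.
#' Slides with zero valid foreground patches are called benign with a
#' warning (no tissue evidence).
#'
#' @param config a [pipeline_config()].
#' @param cohort optional [generate_cohort()] result; generated from the
#'   config when absent.
#' @return object of class `duv_pipeline_result`: `config`, `manifest`
#'   (with fold, truth, fused and majority-vote predictions, `H`, `M`,
#'   `score`), `patch_table` (per-patch row/col, truth, importance `r`,
#'   weight `w`, predicted label and score), `report` (fused
#'   [eval_report()]), `majority_report`, `folds`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "duv_pipeline_config"))
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$n_benign, config$n_malignant,
                              seed = config$seed, dims = config$phantom_dims,
                              contrast = config$phantom_contrast,
                              patch_size = config$patch_size)
  }
  backbone <- if (identical(config$backbone, "mock"))
    mock_backbone(config$feature_dim) else backbone_spec(config$backbone)
  cnn <- demo_color_cnn(config$importance_input)
  tcfg <- tiling_config(config$patch_size, config$foreground_threshold,
                        config$background_threshold)
  n <- nrow(cohort$manifest)
  slide_rows <- vector("list", n)
  feat_id <- vector("list", n)     # identity features, per slide
  feat_aug <- vector("list", n)    # stacked 6-variant features (train only)
  maps <- if (config$save_maps) vector("list", n) else NULL

  for (i in seq_len(n)) {
    g <- cohort_slide(cohort, i)
    ps <- extract_valid_patches(g$slide, tcfg, keep_pixels = TRUE)
    if (ps$n_valid == 0) {
      slide_rows[i] <- list(NULL)
      feat_id[[i]] <- matrix(numeric(0), 0, backbone$feature_dim)
      feat_aug[[i]] <- matrix(numeric(0), 0, backbone$feature_dim)
      next
    }
    class_c <- if (identical(config$importance_class, "auto")) NULL
               else as.integer(config$importance_class)
    map <- regional_importance(cnn, ps$resized_pixels, class_c = class_c,
                               transform = config$importance_transform,
                               out_h = ps$grid$resized_h,
                               out_w = ps$grid$resized_w)
    if (config$save_maps) maps[[i]] <- map
    m <- ps$n_valid
    rows <- data.frame(
      slide_idx = i, slide_id = ps$slide_id,
      row = vapply(ps$patches, `[[`, 0L, "row"),
      col = vapply(ps$patches, `[[`, 0L, "col"),
      foreground_fraction = vapply(ps$patches, `[[`, 0, "foreground_fraction")
    )
    rows$truth <- g$patch_truth$train_label[cbind(rows$row + 1L, rows$col + 1L)]
    rows$r <- vapply(seq_len(m), function(j)
      patch_importance(map, rows$row[j], rows$col[j], config$patch_size), 0)
    rows$w <- patch_weight(rows$r, config$importance_threshold)
    fid <- matrix(0, m, backbone$feature_dim)
    faug <- vector("list", m)
    for (j in seq_len(m)) {
      if (backbone$name == "mock") {
        fv <- .mock_variant_features(ps$patches[[j]]$pixels, backbone)
      } else {
        vars <- augment_patch(ps$patches[[j]]$pixels)
        fv <- t(vapply(vars, function(v) extract_features(v, backbone),
                       numeric(backbone$feature_dim)))
      }
      fid[j, ] <- fv[1, ]
      faug[[j]] <- if (config$augment) fv else fv[1, , drop = FALSE]
    }
    slide_rows[[i]] <- rows
    feat_id[[i]] <- fid
    feat_aug[[i]] <- do.call(rbind, faug)
  }

  folds <- grouped_stratified_kfold(cohort$manifest, config$k, config$seed)
  manifest <- cohort$manifest
  manifest$fold <- folds
  manifest$predicted <- NA_integer_
  manifest$majority <- NA_integer_
  manifest$H <- NA_integer_; manifest$M <- 0L; manifest$score <- NA_real_

  patch_table <- NULL
  aug_factor <- if (config$augment) 6L else 1L
  for (f in sort(unique(folds))) {
    tr <- which(folds != f & !vapply(slide_rows, is.null, TRUE))
    te <- which(folds == f)
    Xtr <- do.call(rbind, feat_aug[tr])
    ytr <- unlist(lapply(tr, function(i) rep(slide_rows[[i]]$truth, each = aug_factor)))
    model <- train_patch_classifier(Xtr, ytr, config$gbt)
    for (i in te) {
      rows <- slide_rows[[i]]
      if (is.null(rows)) {
        warning("slide ", manifest$slide_id[i], " has no valid patches; calling benign")
        manifest$predicted[i] <- -1L; manifest$majority[i] <- -1L
        manifest$H[i] <- 0L; manifest$M[i] <- 0L; manifest$score[i] <- 0
        next
      }
      pred <- predict_patches(model, feat_id[[i]])
      rows$pred_label <- pred$label
      rows$pred_score <- pred$score
      fus <- slide_decision(rows$pred_label, rows$w, config$q)
      manifest$predicted[i] <- fus$label
      manifest$majority[i] <- majority_vote(rows$pred_label)
      manifest$H[i] <- fus$H; manifest$M[i] <- fus$M
      manifest$score[i] <- fus$H / fus$M
      rows$u <- fus$u
      patch_table <- rbind(patch_table, rows)
    }
  }
  report <- eval_report(manifest$label, manifest$predicted,
                        scores = manifest$score, folds = manifest$fold)
  majority_report <- eval_report(manifest$label, manifest$majority,
                                 folds = manifest$fold)
  res <- structure(list(config = config, manifest = manifest,
                        patch_table = patch_table, report = report,
                        majority_report = majority_report, folds = folds,
                        maps = maps),
                   class = "duv_pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(res, config$out_dir)
  res
}

#' Persist pipeline artifacts
#'
#' Writes the per-slide fusion report CSV, the per-patch table CSV, the
#' evaluation report JSON (confusion counts, rates, ROC points, AUC,
#' per-fold breakdown) and the full configuration JSON.
#'
#' @param res a [run_pipeline()] result.
#' @param out_dir output directory, created if missing.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(res, out_dir) {
  stopifnot(inherits(res, "duv_pipeline_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$manifest, file.path(out_dir, "fusion_slides.csv"), row.names = FALSE)
  if (!is.null(res$patch_table))
    write.csv(res$patch_table, file.path(out_dir, "fusion_patches.csv"), row.names = FALSE)
  rep <- res$report
  jsonlite::write_json(list(
    confusion = list(TP = rep$TP, TN = rep$TN, FP = rep$FP, FN = rep$FN),
    accuracy = rep$accuracy, sensitivity = rep$sensitivity,
    specificity = rep$specificity, auc = rep$auc,
    roc_points = rep$roc_points, per_fold = rep$per_fold,
    majority = list(accuracy = res$majority_report$accuracy,
                    sensitivity = res$majority_report$sensitivity,
                    specificity = res$majority_report$specificity)
  ), file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  cfg <- unclass(res$config)
  cfg$out_dir <- NULL
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(res$maps)) {
    md <- file.path(out_dir, "maps"); dir.create(md, showWarnings = FALSE)
    for (i in seq_along(res$maps)) if (!is.null(res$maps[[i]]))
      write_importance_map(res$maps[[i]], file.path(
        md, paste0(res$manifest$slide_id[i], "_importance.png")))
  }
  invisible(out_dir)
}

#' Render a classification overlay on a slide
#'
#' Draws the patch-grid decision boxes over the slide: red borders on
#' malignant-predicted patches with positive importance weight, green on
#' benign-predicted ones; zero-weight patches stay unboxed.  The result is
#' scaled down for viewing.
#'
#' @param slide a `duv_slide` or H x W x 3 pixel array (grid-aligned
#'   dimensions).
#' @param patches data.frame with columns `row`, `col` (0-based grid
#'   indices), `label` (+1/-1) and `w` (importance weight).
#' @param patch_size patch edge in pixels.
#' @param scale output scaling factor in (0, 1].
#' @return H*scale x W*scale x 3 pixel array (0-255).
#' @export
render_overlay <- function(slide, patches, patch_size = 400L, scale = 0.25) {
  px <- if (inherits(slide, "duv_slide")) slide$pixels else slide
  d <- dim(px)
  if (length(d) != 3L) .duv_invalid("slide must be an H x W x 3 array")
  rows_max <- d[1] %/% patch_size; cols_max <- d[2] %/% patch_size
  if (d[1] %% patch_size != 0 || d[2] %% patch_size != 0)
    .duv_invalid("slide dimensions are not grid-aligned; resize first")
  out <- px * 1.0
  th <- max(4L, as.integer(patch_size * 0.02))
  for (i in seq_len(NROW(patches))) {
    r <- patches$row[i]; cc <- patches$col[i]
    if (r < 0 || cc < 0 || r >= rows_max || cc >= cols_max)
      .duv_invalid("patch (", r, ",", cc, ") lies outside the slide grid")
    if (patches$w[i] <= 0) next
    color <- if (patches$label[i] == 1) c(255, 40, 40) else c(40, 255, 40)
    r0 <- r * patch_size + 1L; r1 <- (r + 1L) * patch_size
    c0 <- cc * patch_size + 1L; c1 <- (cc + 1L) * patch_size
    band_r <- c(r0:(r0 + th - 1L), (r1 - th + 1L):r1)
    band_c <- c(c0:(c0 + th - 1L), (c1 - th + 1L):c1)
    for (k in 1:3) {
      out[band_r, c0:c1, k] <- color[k]
      out[r0:r1, band_c, k] <- color[k]
    }
  }
  if (scale < 1) out <- resize_bilinear(out, round(d[1] * scale), round(d[2] * scale))
  out
}
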