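test_that("phantom slides are reproducible and respect the luma contract", {
  sp <- phantom_spec(800, 800, list(
    phantom_region("ellipse", 400, 400, 250, 220, class = "malignant")))
  g1 <- generate_slide(sp, seed = 42)
  g2 <- generate_slide(sp, seed = 42)
  expect_identical(g1$slide$pixels, g2$slide$pixels)
  expect_identical(g1$mask, g2$mask)
  g3 <- generate_slide(sp, seed = 43)
  expect_false(identical(g1$slide$pixels, g3$slide$pixels))

  # background luma strictly below 5, tissue luma at or above 5
  gray <- to_grayscale(g1$slide$pixels)
  expect_true(all(gray[g1$mask == 0L] < 5))
  expect_true(all(gray[g1$mask > 0L] >= 5))
})

test_that("all-background and degenerate specs behave as contracted", {
  empty <- phantom_spec(800, 800)
  g <- generate_slide(empty, seed = 1)
  expect_equal(g$slide$label, -1L)
  expect_equal(extract_valid_patches(g$slide)$n_valid, 0)
  expect_error(phantom_region("ellipse", 10, 10, 0, 5, class = "benign"),
               class = "duvmargin_invalid_input")
  # region fully outside the slide bounds has zero area
  off <- phantom_spec(400, 400, list(
    phantom_region("ellipse", 2000, 2000, 50, 50, class = "benign")))
  expect_error(generate_slide(off, seed = 1), "degenerate")
})

test_that("an 800x800 malignant square on 1200x1200 yields 4 of 9 malignant patches", {
  sp <- phantom_spec(1200, 1200, list(
    phantom_region("rect", 400.5, 400.5, 399.5, 399.5, class = "malignant")))
  g <- generate_slide(sp, seed = 3)
  expect_equal(dim(g$patch_truth$majority), c(3, 3))
  expect_equal(sum(g$patch_truth$majority == 2L), 4)
  expect_equal(g$patch_truth$majority[1:2, 1:2], matrix(2L, 2, 2))
  expect_equal(g$slide$label, 1L)
})

test_that("ground-truth patch labels agree with a pixel-counting oracle", {
  sp <- phantom_spec(900, 1300, list(
    phantom_region("ellipse", 300, 300, 280, 250, class = "malignant"),
    phantom_region("rect", 1000, 600, 250, 280, class = "benign")))
  g <- generate_slide(sp, seed = 8)
  pt <- g$patch_truth
  plan <- pt$grid
  # oracle: nearest-neighbour resample of the mask, then per-cell counts
  ri <- pmin(pmax(round((seq_len(plan$resized_h) - 0.5) * nrow(g$mask) / plan$resized_h + 0.5), 1), nrow(g$mask))
  ci <- pmin(pmax(round((seq_len(plan$resized_w) - 0.5) * ncol(g$mask) / plan$resized_w + 0.5), 1), ncol(g$mask))
  mres <- g$mask[ri, ci]
  for (r in seq_len(plan$rows)) for (cc in seq_len(plan$cols)) {
    cell <- mres[((r - 1) * 400 + 1):(r * 400), ((cc - 1) * 400 + 1):(cc * 400)]
    nb <- sum(cell == 1L); nm <- sum(cell == 2L); nbg <- sum(cell == 0L)
    top <- max(nb, nm, nbg)
    expected_major <- if (nm == top) 2L else if (nb == top) 1L else 0L
    expect_identical(pt$majority[r, cc], expected_major)
    expect_identical(pt$train_label[r, cc], if (nm >= nb && nm > 0) 1L else -1L)
  }
})

test_that("cohorts mirror the default 24/36 composition with grouped patients", {
  cohort <- generate_cohort(24, 36, seed = 2)
  expect_equal(nrow(cohort$manifest), 60)
  expect_equal(sum(cohort$manifest$label == -1), 24)
  expect_equal(sum(cohort$manifest$label == 1), 36)
  # some patients contribute multiple slides, all of one class
  tab <- table(cohort$manifest$patient_id)
  expect_true(any(tab > 1))
  for (p in names(tab[tab > 1]))
    expect_length(unique(cohort$manifest$label[cohort$manifest$patient_id == p]), 1)
  # single-slide cohort
  one <- generate_cohort(1, 0, seed = 1)
  expect_equal(nrow(one$manifest), 1)
  expect_equal(one$manifest$label, -1L)
  s <- cohort_slide(one, 1)
  expect_equal(s$slide$label, -1L)
  expect_error(generate_cohort(0, 0), class = "duvmargin_invalid_input")
})

test_that("phantom classes are separable in feature space by construction", {
  cohort <- small_cohort(seed = 19)
  bb <- mock_backbone()
  feats <- list(); labs <- integer(0)
  for (i in seq_len(nrow(cohort$manifest))) {
    g <- cohort_slide(cohort, i)
    ps <- extract_valid_patches(g$slide)
    if (ps$n_valid == 0) next
    f <- batch_extract(ps$patches, bb)
    tl <- vapply(ps$patches, function(p)
      g$patch_truth$train_label[p$row + 1, p$col + 1], 0L)
    feats[[length(feats) + 1]] <- f
    labs <- c(labs, tl)
  }
  X <- do.call(rbind, feats)
  # green-vs-pink channel contrast separates the classes linearly
  contrast <- X[, 1] - X[, 2]  # mean R - mean G
  expect_gt(min(contrast[labs == 1]), max(contrast[labs == -1]))
})
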