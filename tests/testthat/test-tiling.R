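test_that("plan_grid picks nearest patch multiples with upward ties", {
  # exact multiple: identity on dimensions
  p <- plan_grid(400, 400, 400)
  expect_equal(c(p$resized_h, p$resized_w, p$rows, p$cols), c(400, 400, 1, 1))

  # nearest multiples by hand: 1205 -> 1200, 810 -> 800
  p <- plan_grid(1205, 810, 400)
  expect_equal(c(p$resized_h, p$resized_w), c(1200, 800))
  expect_equal(c(p$rows, p$cols, p$n_patches), c(3, 2, 6))

  # halfway tie 600 (400 vs 800) breaks upward
  p <- plan_grid(600, 600, 400)
  expect_equal(c(p$resized_h, p$resized_w, p$rows, p$cols), c(800, 800, 2, 2))

  # tiny dimensions round up to one patch
  p <- plan_grid(120, 50, 400)
  expect_equal(c(p$rows, p$cols), c(1, 1))

  expect_error(plan_grid(0, 100, 400), class = "duvmargin_invalid_input")
  expect_error(plan_grid(100, -3, 400), class = "duvmargin_invalid_input")
})

test_that("to_grayscale is BT.601 luma on unrounded values", {
  black <- array(0, c(2, 2, 3))
  expect_equal(to_grayscale(black), matrix(0, 2, 2))
  gray10 <- array(10, c(1, 1, 3))
  expect_equal(to_grayscale(gray10)[1, 1], 10)
  blue <- array(rep(c(0, 0, 255), each = 1), c(1, 1, 3))
  expect_equal(to_grayscale(blue)[1, 1], 29.07)
  expect_error(to_grayscale(matrix(0, 2, 2)), class = "duvmargin_invalid_input")
})

test_that("foreground_fraction counts pixels at or above the threshold", {
  expect_equal(foreground_fraction(matrix(0, 400, 400)), 0)
  expect_equal(foreground_fraction(matrix(255, 400, 400)), 1)
  patch <- matrix(0, 400, 400); patch[1:100, ] <- 200
  expect_equal(foreground_fraction(patch), 0.25)
  # boundary: luma exactly at the threshold counts as foreground
  expect_equal(foreground_fraction(matrix(5, 10, 10)), 1)
  expect_equal(foreground_fraction(matrix(4.999, 10, 10)), 0)
  expect_error(foreground_fraction(matrix(0, 0, 0)), class = "duvmargin_invalid_input")
})

test_that("extract_valid_patches matches the naive pixel-counting oracle", {
  cfg <- tiling_config()
  # all-background slide: zero valid patches
  ps <- extract_valid_patches(solid_slide(800, 800, c(1, 1, 1)), cfg)
  expect_equal(ps$n_valid, 0)
  expect_equal(length(ps$patches), 0)

  # entirely-foreground 1200x800 slide: all 6 grid cells pass
  ps <- extract_valid_patches(solid_slide(1200, 800, c(120, 120, 120)), cfg)
  expect_equal(ps$n_valid, 6)

  # phantom slides with structured masks agree with the double-loop oracle
  for (seed in 1:4) {
    sp <- phantom_spec(800, 1200, list(
      phantom_region("ellipse", 300, 350, 240, 260, class = "malignant"),
      phantom_region("rect", 900, 500, 140 + 40 * seed, 200, class = "benign")))
    g <- generate_slide(sp, seed = seed)
    ps <- extract_valid_patches(g$slide, cfg)
    expect_equal(ps$n_valid,
                 oracle_valid_count(g$slide$pixels, 400, 0.2, 5))
  }
})

test_that("patch footprints partition the resized slide", {
  g <- generate_slide(phantom_spec(900, 1100, list(
    phantom_region("ellipse", 550, 450, 300, 280, class = "benign"))), seed = 2)
  ps <- extract_valid_patches(g$slide)
  cells <- ps$cells
  # every grid cell appears exactly once; footprints are disjoint by index
  expect_equal(nrow(cells), ps$grid$rows * ps$grid$cols)
  expect_false(any(duplicated(cells[, c("row", "col")])))
  expect_setequal(cells$row, 0:(ps$grid$rows - 1))
  expect_setequal(cells$col, 0:(ps$grid$cols - 1))
  # resized dims are multiples of the patch size
  expect_equal(ps$grid$resized_h %% 400, 0)
  expect_equal(ps$grid$resized_w %% 400, 0)
})

test_that("valid count is non-increasing in foreground_threshold", {
  g <- generate_slide(phantom_spec(1200, 1200, list(
    phantom_region("ellipse", 500, 600, 350, 300, class = "malignant"))), seed = 9)
  counts <- vapply(c(0, 0.1, 0.2, 0.5, 0.8, 1),
                   function(t) extract_valid_patches(
                     g$slide, tiling_config(foreground_threshold = t))$n_valid, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("patch PNG export and manifest round-trip", {
  g <- generate_slide(phantom_spec(800, 800, list(
    phantom_region("rect", 200, 200, 195, 195, class = "benign"))), seed = 1)
  ps <- extract_valid_patches(g$slide)
  td <- withr::local_tempdir()
  mp <- write_patchset(ps, td)
  man <- read.csv(mp)
  expect_equal(nrow(man), ps$n_valid)
  f <- file.path(td, sprintf("%s_r%d_c%d.png", ps$slide_id, man$row[1], man$col[1]))
  expect_true(file.exists(f))
  px <- read_slide_image(f)
  expect_equal(dim(px), c(400, 400, 3))
  expect_equal(px, ps$patches[[1]]$pixels, tolerance = 1e-8)
})
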