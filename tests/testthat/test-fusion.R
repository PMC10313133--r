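test_that("patch_importance averages the map over the patch footprint", {
  expect_equal(patch_importance(matrix(0.5, 800, 800), 0, 1, 400), 0.5)
  half <- rbind(matrix(0, 200, 400), matrix(1, 200, 400))
  expect_equal(patch_importance(half, 0, 0, 400), 0.5)
  # 4x4 toy map, values 0..15/15, 2x2 footprints: hand-computed means
  toy <- matrix(0:15, 4, 4, byrow = TRUE) / 15
  expect_equal(patch_importance(toy, 0, 0, 2), mean(c(0, 1, 4, 5) / 15))
  expect_equal(patch_importance(toy, 1, 1, 2), mean(c(10, 11, 14, 15) / 15))
  expect_error(patch_importance(toy, 2, 0, 2), class = "duvmargin_invalid_input")
  expect_error(patch_importance(toy, 0, -1, 2), class = "duvmargin_invalid_input")
})

test_that("patch_weight zeroes importances strictly below the threshold", {
  expect_equal(patch_weight(0.24), 0)
  expect_equal(patch_weight(0.25), 0.25)  # boundary kept
  expect_equal(patch_weight(0), 0)
  expect_equal(patch_weight(1), 1)
  expect_equal(patch_weight(c(0.1, 0.25, 0.9)), c(0, 0.25, 0.9))
  expect_error(patch_weight(1.2), class = "duvmargin_invalid_input")
  expect_error(patch_weight(-0.1), class = "duvmargin_invalid_input")
})

test_that("slide_decision reproduces the hand-worked examples", {
  # all benign: H = 0, slide benign for any q
  for (q in c(0, 0.3, 1)) {
    f <- slide_decision(c(-1, -1, -1), c(0.9, 0.5, 0.3), q)
    expect_equal(f$H, 0); expect_equal(f$label, -1L)
  }
  # one confident malignant patch at q = 0 flags the slide
  f <- slide_decision(c(1, -1, -1), c(0.5, 0.9, 0.9), 0)
  expect_equal(f$u, c(0.5, -0.9, -0.9))
  expect_equal(f$H, 1); expect_equal(f$M, 3)
  expect_equal(f$label, 1L)
  # a malignant patch with zero weight is ignored (low importance)
  f <- slide_decision(c(1), c(0), 0)
  expect_equal(f$H, 0); expect_equal(f$label, -1L)
  expect_error(slide_decision(integer(0), numeric(0)), "empty|no valid")
})

test_that("slide_decision agrees with exhaustive enumeration (small M)", {
  oracle <- function(labels, weights, q) {
    H <- 0L
    for (j in seq_along(labels)) if (weights[j] * labels[j] > 0) H <- H + 1L
    if (H > q * length(labels)) 1L else -1L
  }
  set.seed(14)
  wgrid <- seq(0, 1, by = 0.05)
  for (M in 1:6) {
    labs <- as.matrix(expand.grid(rep(list(c(-1, 1)), M)))
    for (i in seq_len(nrow(labs))) {
      w <- sample(wgrid, M, replace = TRUE)
      q <- sample(c(0, 0.25, 0.5, 1), 1)
      expect_identical(slide_decision(labs[i, ], w, q)$label,
                       oracle(labs[i, ], w, q))
    }
  }
})

test_that("fusion monotonicity properties hold", {
  set.seed(26)
  for (rep in 1:40) {
    M <- sample(2:8, 1)
    labels <- sample(c(-1, 1), M, replace = TRUE)
    weights <- sample(seq(0, 1, 0.05), M, replace = TRUE)
    q <- runif(1)
    y0 <- slide_decision(labels, weights, q)$label
    # flipping a benign patch to malignant never flips the slide to benign
    j <- sample(M, 1)
    labels2 <- labels; labels2[j] <- 1
    y1 <- slide_decision(labels2, weights, q)$label
    expect_true(y1 >= y0)
    # y_i is non-increasing in q
    qs <- sort(runif(5))
    ys <- vapply(qs, function(qq) slide_decision(labels, weights, qq)$label, 0L)
    expect_true(all(diff(ys) <= 0))
  }
})

test_that("majority_vote matches counting oracle and the fused special case", {
  expect_equal(majority_vote(c(1, 1, -1)), 1L)
  expect_equal(majority_vote(c(-1, -1, -1, 1)), -1L)
  expect_equal(majority_vote(c(1, -1)), 1L)  # tie goes malignant
  # exhaustive agreement with a counting oracle, lengths <= 10
  for (M in 1:10) {
    labs <- as.matrix(expand.grid(rep(list(c(-1, 1)), M)))
    for (i in seq_len(nrow(labs))) {
      v <- labs[i, ]
      expected <- if (sum(v == 1) >= length(v) / 2) 1L else -1L
      expect_identical(majority_vote(v), expected)
    }
  }
  # with all weights >= 0.25 and q = 0.5, fusion equals majority voting --
  # except at an exact even-count tie, where the vote's documented tie rule
  # (malignant) diverges from the fused strict inequality H > 0.5 M
  set.seed(5)
  for (rep in 1:30) {
    M <- sample(1:8, 1)
    labels <- sample(c(-1, 1), M, replace = TRUE)
    weights <- runif(M, 0.25, 1)
    if (sum(labels == 1) * 2L == M) next
    expect_identical(slide_decision(labels, weights, 0.5)$label,
                     majority_vote(labels))
  }
})

test_that("sweep_q traces the fusion operating curve", {
  sw <- sweep_q(c(1, 1, -1), c(0.5, 0.3, 0.9), q_grid = c(0, 0.5, 1))
  expect_equal(sw$label, c(1L, 1L, -1L))
})
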