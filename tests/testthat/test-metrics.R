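# Overlap metric, CSA morphometry, and group aggregation.

rootlets_spanning <- function(spans, shape = c(10L, 10L, 40L)) {
  # spans: named list level -> z slice indices (1-based)
  aff <- diag(c(0.5, 0.5, 0.5, 1))
  arr <- array(0L, shape)
  for (code in names(spans))
    for (k in spans[[code]])
      arr[5, 5, k] <- as.integer(code)
  sc_labels(arr, aff, "rootlets")
}

test_that("overlap is 100% for identical volumes and 0% when disjoint", {
  a <- rootlets_spanning(list(`2` = 30:35, `3` = 20:26))
  ov <- rootlet_overlap(a, a)
  expect_true(all(ov$percent == 100))
  expect_true(all(ov$dice1d == 100))
  b <- rootlets_spanning(list(`2` = 36:39, `3` = 10:15))
  ov2 <- rootlet_overlap(b, a)
  expect_true(all(ov2$percent == 0))
})

test_that("partial overlaps match brute-force slice-set intersection", {
  # subject spans [10, 20), template [15, 25): 5 shared slices, 50%
  tpl <- rootlets_spanning(list(`2` = 30:34, `3` = 15:24))
  sub <- rootlets_spanning(list(`2` = 30:34, `3` = 10:19))
  ov <- rootlet_overlap(sub, tpl)
  r3 <- ov[ov$level == 3, ]
  expect_identical(r3$length_overlap, 5L)
  expect_identical(r3$length_pam50, 10L)
  expect_identical(r3$length_sub, 10L)
  expect_equal(r3$percent, 50)
  expect_equal(r3$dice1d, 50)
})

test_that("overlap ignores in-plane position and flags absent levels", {
  tpl <- rootlets_spanning(list(`2` = 30:35, `3` = 20:25))
  sub <- rootlets_spanning(list(`2` = 30:35, `3` = 20:25))
  # scatter subject voxels to different in-plane locations
  arr <- array(0L, dim(sub$data))
  for (k in 30:35) arr[2, 8, k] <- 2L
  for (k in 20:25) arr[8, 2, k] <- 3L
  sub2 <- sc_labels(arr, sub$affine, "rootlets")
  expect_equal(rootlet_overlap(sub2, tpl)$percent,
               rootlet_overlap(sub, tpl)$percent)

  # level present in template, absent in subject: percent 0 with a flag
  arr[, , 20:25] <- 0L
  sub3 <- sc_labels(arr, sub$affine, "rootlets")
  ov <- rootlet_overlap(sub3, tpl)
  expect_equal(ov$percent[ov$level == 3], 0)
  expect_true(ov$missing_in_subject[ov$level == 3])
})

test_that("CSA of a digital cylinder approximates pi r^2", {
  shape <- c(50L, 50L, 20L)
  aff <- diag(c(0.5, 0.5, 0.5, 1))
  aff[1, 4] <- -(shape[1] - 1) / 4; aff[2, 4] <- -(shape[2] - 1) / 4
  xs <- aff[1, 1] * (seq_len(shape[1]) - 1) + aff[1, 4]
  ys <- aff[2, 2] * (seq_len(shape[2]) - 1) + aff[2, 4]
  X <- matrix(rep(xs, shape[2]), shape[1], shape[2])
  Y <- matrix(rep(ys, each = shape[1]), shape[1], shape[2])
  arr <- array(0L, shape)
  for (k in 3:18) arr[, , k] <- as.integer(X^2 + Y^2 <= 25)
  pr <- csa_profile(sc_labels(arr, aff, "cord-mask"))
  interior <- pr$slice %in% 4:17
  expect_true(all(abs(pr$csa_mm2[interior] - pi * 25) / (pi * 25) < 0.02))

  one <- array(0L, c(4L, 4L, 4L)); one[2, 2, 2] <- 1L
  # a second voxel two slices up keeps the support non-degenerate
  one[2, 2, 4] <- 1L
  pr1 <- csa_profile(sc_labels(one, diag(c(0.5, 0.5, 0.5, 1)),
                               "cord-mask"))
  expect_equal(pr1$csa_mm2[pr1$slice == 2], 0.25)
})

test_that("CSA normalization is scale-invariant and idempotent", {
  shape <- c(12L, 12L, 60L)
  aff <- diag(c(0.5, 0.5, 0.5, 1))
  arr <- array(0L, shape)
  arr[4:9, 4:9, 5:55] <- 1L
  cord <- sc_labels(arr, aff, "cord-mask")
  pr <- csa_profile(cord)
  n1 <- normalize_csa(pr, reference_z = 30)
  expect_true(all(abs(n1$csa_norm - 1) < 1e-12))

  # doubled profile normalizes identically
  arr2 <- array(0L, shape)
  arr2[3:10, 3:9, 5:55] <- 1L       # different but constant area
  n2 <- normalize_csa(csa_profile(sc_labels(arr2, aff, "cord-mask")), 30)
  expect_equal(n2$csa_norm, n1$csa_norm)

  # idempotent
  n11 <- normalize_csa(n1, reference_z = 30)
  expect_equal(n11$csa_norm, n1$csa_norm)

  expect_error(normalize_csa(pr, reference_z = 6), "window exceeds")
})

test_that("a linear ramp normalizes to unit mean over the window", {
  # build a ramp profile directly and check the windowed mean
  pr <- data.frame(slice = 1:50, z_mm = (1:50) * 0.5,
                   csa_mm2 = seq(40, 89, length.out = 50))
  attr(pr, "slice_thickness_mm") <- 0.5
  class(pr) <- c("csa_profile", "data.frame")
  n <- normalize_csa(pr, reference_z = 25)
  win <- 15:34                       # 20 slices centered at 25
  expect_equal(mean(n$csa_norm[n$slice %in% win]), 1, tolerance = 1e-9)
})

test_that("smoothing localizes maxima with the rostral tie rule", {
  mkprof <- function(y) {
    pr <- data.frame(slice = seq_along(y), z_mm = seq_along(y) * 0.5,
                     csa_mm2 = y)
    attr(pr, "slice_thickness_mm") <- 0.5
    class(pr) <- c("csa_profile", "data.frame")
    pr
  }
  # constant profile: unchanged, argmax at the most rostral slice
  cst <- smooth_and_localize(mkprof(rep(5, 80)))
  expect_equal(cst$csa_smooth, rep(5, 80), tolerance = 1e-6)
  expect_identical(attr(cst, "enlargement_slice"), 80L)

  # Gaussian bump: argmax within 1 slice of the brute-force argmax of the
  # analytically smoothed curve
  y <- 50 + 10 * exp(-((1:120) - 62)^2 / (2 * 15^2))
  sm <- smooth_and_localize(mkprof(y))
  w <- attr(sm, "smooth_window_slices")
  half <- (w - 1) / 2
  brute <- vapply(seq_along(y), function(i) {
    idx <- (i - half):(i + half)
    idx <- ifelse(idx < 1, 2 - idx, idx)
    idx <- ifelse(idx > length(y), 2 * length(y) - idx, idx)
    mean(y[idx])
  }, numeric(1))
  expect_lte(abs(attr(sm, "enlargement_slice") - which.max(brute)), 1)

  # two equal maxima: the more rostral wins
  y2 <- rep(1, 100); y2[30] <- 2; y2[70] <- 2
  sm2 <- smooth_and_localize(mkprof(y2))
  expect_gt(attr(sm2, "enlargement_slice"), 50)

  expect_error(smooth_and_localize(mkprof(rep(1, 10))), "shorter")
})

test_that("group aggregation matches brute-force recomputation", {
  a <- rootlets_spanning(list(`2` = 30:35, `3` = 20:25))
  one <- group_aggregate(list(rootlet_overlap(a, a)))
  expect_equal(one$mean_percent, rep(100, 3))
  expect_equal(one$sd_percent, rep(0, 3))

  # two subjects with overall percents 80 and 100 -> mean 90, SD 10
  tpl <- rootlets_spanning(list(`2` = 21:30, `3` = 6:15))
  s1 <- rootlets_spanning(list(`2` = 23:32, `3` = 8:17))   # 80% each
  agg <- group_aggregate(list(rootlet_overlap(s1, tpl),
                              rootlet_overlap(tpl, tpl)))
  ov <- agg[agg$level == "overall", ]
  expect_equal(ov$mean_percent, 90)
  expect_equal(ov$sd_percent, 10)

  # 10 random phantom-style results vs brute force
  set.seed(31)
  results <- lapply(1:10, function(i) {
    off <- sample(0:4, 1)
    sub <- rootlets_spanning(list(`2` = (21:30) + off, `3` = 6:15))
    rootlet_overlap(sub, tpl)
  })
  agg10 <- group_aggregate(results)
  p2 <- vapply(results, function(r) r$percent[r$level == 2], numeric(1))
  expect_equal(agg10$mean_percent[agg10$level == "2"], mean(p2))
  expect_equal(agg10$sd_percent[agg10$level == "2"],
               sqrt(mean((p2 - mean(p2))^2)))
})
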