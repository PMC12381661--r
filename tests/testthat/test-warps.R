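# Warp algebra: symmetrization, scaling, composition, inversion,
# pull-back resampling.

unit_grid <- function(shape = c(8L, 8L, 12L), res = 1) {
  aff <- diag(c(res, res, res, 1))
  grid_spec(shape, aff)
}

test_that("slice means exclude zeros and broadcast across the slice", {
  g <- unit_grid()
  w <- zero_field(g)
  w$vectors[1, 1, 5, 3] <- 2
  w$vectors[2, 1, 5, 3] <- 0
  w$vectors[3, 1, 5, 3] <- 4
  s <- symmetrize_slicewise(w)
  expect_true(all(s$vectors[, , 5, 3] == 3))
  expect_true(all(s$vectors[, , -5, 3] == 0))
})

test_that("symmetrization is idempotent and flip-invariant bit-exactly", {
  g <- unit_grid(c(9L, 9L, 15L))
  set.seed(13)
  w <- zero_field(g)
  v <- array(rnorm(prod(g$shape)), g$shape)
  v[v < 0] <- 0                        # leave genuine zeros in place
  w$vectors[, , , 3] <- v
  s1 <- symmetrize_slicewise(w)
  s2 <- symmetrize_slicewise(s1)
  expect_identical(s1$vectors, s2$vectors)

  wf <- w
  wf$vectors <- w$vectors[g$shape[1]:1, , , , drop = FALSE]
  sf <- symmetrize_slicewise(wf)
  expect_identical(sf$vectors, s1$vectors)

  w$vectors[1, 1, 1, 1] <- 1
  expect_error(symmetrize_slicewise(w), "zero x and y")
})

test_that("composition has the zero field as identity element", {
  g <- unit_grid()
  set.seed(4)
  w <- zero_field(g)
  w$vectors[] <- rnorm(length(w$vectors), 0, 0.5)
  z <- zero_field(g)
  expect_equal(compose_warps(z, w)$vectors, w$vectors, tolerance = 1e-12)
  expect_equal(compose_warps(w, z)$vectors, w$vectors, tolerance = 1e-12)
})

test_that("composing constant translations adds them", {
  g <- unit_grid()
  a <- zero_field(g); a$vectors[, , , 1] <- 1; a$vectors[, , , 3] <- 2
  b <- zero_field(g); b$vectors[, , , 2] <- 1; b$vectors[, , , 3] <- 1
  ab <- compose_warps(a, b)
  expect_equal(unique(as.vector(ab$vectors[, , , 1])), 1)
  expect_equal(unique(as.vector(ab$vectors[, , , 2])), 1)
  expect_equal(unique(as.vector(ab$vectors[, , , 3])), 3)
})

test_that("inversion inverts constants and smooth fields", {
  g <- unit_grid(c(12L, 12L, 24L))
  z <- zero_field(g)
  expect_equal(invert_warp(z)$vectors, z$vectors)
  ct <- zero_field(g)
  ct$vectors[, , , 1] <- 1.5; ct$vectors[, , , 3] <- -2
  inv <- invert_warp(ct)
  expect_equal(unique(as.vector(inv$vectors[, , , 1])), -1.5,
               tolerance = 1e-6)
  expect_equal(unique(as.vector(inv$vectors[, , , 3])), 2,
               tolerance = 1e-6)
  expect_identical(inv$direction, "backward")

  # smooth field of amplitude <= 5 mm: compose(w, invert(w)) ~ identity
  w <- random_smooth_zfield(grid_spec(c(10L, 10L, 80L),
                                      diag(c(1, 1, 1, 1))),
                            amplitude = 5, seed = 42)
  winv <- invert_warp(w, tol = 0.01)
  winv$direction <- w$direction       # chain the two as pull-back maps
  res <- compose_warps(w, winv)
  mag <- sqrt(rowSums(matrix(res$vectors, ncol = 3)^2))
  # interior only: the clamped field edge is not invertible information
  k <- rep(seq_len(80), each = 100)
  expect_lt(mean(mag[k > 10 & k < 70]), 0.5)
})

test_that("apply_warp is exact for zero fields and integer translations", {
  g <- unit_grid()
  set.seed(2)
  lab <- sc_labels(array(sample(c(0L, 2L, 3L), prod(g$shape), TRUE),
                         g$shape), g$affine, "rootlets")
  z <- zero_field(g)
  expect_identical(apply_warp(lab, z, "nearest")$data, lab$data)

  img <- sc_volume(array(rnorm(prod(g$shape)), g$shape), g$affine)
  expect_equal(apply_warp(img, z, "linear")$data, img$data,
               tolerance = 1e-12)

  tr <- zero_field(g)
  tr$vectors[, , , 3] <- 2           # pull from two voxels up (1 mm grid)
  moved <- apply_warp(lab, tr, "nearest")
  expect_identical(moved$data[, , 1:10], lab$data[, , 3:12])
  expect_true(all(moved$data[, , 11:12] == 0))
  # voxel counts conserved for labels that stay inside the grid
  inner <- lab$data[, , 3:12]
  expect_identical(sum(moved$data != 0), sum(inner != 0))

  expect_error(apply_warp(lab, z, "linear"), "refused")
})

test_that("warped label centers track an analytic sinusoidal transport", {
  tpl <- tiny_template()
  g <- grid_of(tpl$image)
  Z <- slice_z_world(g)
  w <- zero_field(g)
  w$vectors[, , , 3] <- rep(2 * sin(2 * pi * Z / 60),
                            each = g$shape[1] * g$shape[2])
  moved <- apply_warp(tpl$rootlets, w, "nearest")
  lc0 <- level_centers(tpl$rootlets)
  lc1 <- level_centers(moved)
  # pull-back by dz moves content to z* where z* + dz(z*) = z0: solve
  # the analytic fixed point per level
  for (lv in lc0$level) {
    z0 <- lc0$z[lc0$level == lv]
    zstar <- z0
    for (i in 1:50) zstar <- z0 - 2 * sin(2 * pi * zstar / 60)
    expect_lt(abs(lc1$z[lc1$level == lv] - zstar), 0.5 * 1.0)
  }
})

test_that("xy scaling matches analytic area ratios", {
  # subject disc radius 4 mm vs template radius 5 mm on every slice
  shape <- c(40L, 40L, 12L)
  aff <- diag(c(0.5, 0.5, 1, 1))
  aff[1, 4] <- -(shape[1] - 1) / 4; aff[2, 4] <- -(shape[2] - 1) / 4
  mk <- function(r) {
    xs <- aff[1, 1] * (seq_len(shape[1]) - 1) + aff[1, 4]
    ys <- aff[2, 2] * (seq_len(shape[2]) - 1) + aff[2, 4]
    X <- matrix(rep(xs, shape[2]), shape[1], shape[2])
    Y <- matrix(rep(ys, each = shape[1]), shape[1], shape[2])
    m <- array(0L, shape)
    for (k in 2:11) m[, , k] <- as.integer(X^2 + Y^2 <= r^2)
    sc_labels(m, aff, "cord-mask")
  }
  sub <- mk(4); tpl <- mk(5)

  idsc <- xy_scaling(tpl, tpl)
  expect_true(all(idsc$field$vectors == 0))

  sc <- xy_scaling(sub, tpl)
  s_expect <- sqrt(sum(tpl$data[, , 6]) / sum(sub$data[, , 6]))
  expect_equal(sc$profile$scale[6], s_expect, tolerance = 1e-9)
  expect_equal(s_expect, 1.25, tolerance = 0.02)

  # a point 2 mm right of center maps 2.5 mm right of center: the
  # pull-back field at x = 2.5 must reach back to x = 2
  i <- round((2.5 - aff[1, 4]) / aff[1, 1])
  j <- round((0 - aff[2, 4]) / aff[2, 2])
  x_here <- aff[1, 1] * i + aff[1, 4]
  expect_equal(x_here + sc$field$vectors[i + 1, j + 1, 6, 1],
               x_here / sc$profile$scale[6], tolerance = 1e-6)

  # after applying the field, subject CSA matches template CSA within 3%
  warped <- apply_warp(sub, sc$field, "nearest")
  for (k in 3:10) {
    csa_w <- sum(warped$data[, , k]) * 0.25
    csa_t <- sum(tpl$data[, , k]) * 0.25
    expect_lt(abs(csa_w - csa_t) / csa_t, 0.03)
  }
})

test_that("composition and direction contracts are enforced", {
  g <- unit_grid()
  a <- zero_field(g, direction = "forward")
  b <- zero_field(g, direction = "backward")
  expect_error(compose_warps(a, b), "direction mismatch")
})
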