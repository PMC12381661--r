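# Centerline extraction and straightening.

# tube mask around a parametric sagittal curve y = yc(z), x = 0
make_tube <- function(yc_fun, radius = 4, shape = c(40L, 40L, 100L),
                      res = 1, z_range = c(5, 95)) {
  aff <- diag(c(res, res, res, 1))
  aff[1, 4] <- -(shape[1] - 1) / 2 * res
  aff[2, 4] <- -(shape[2] - 1) / 2 * res
  xs <- aff[1, 1] * (seq_len(shape[1]) - 1) + aff[1, 4]
  ys <- aff[2, 2] * (seq_len(shape[2]) - 1) + aff[2, 4]
  X <- matrix(rep(xs, shape[2]), shape[1], shape[2])
  Y <- matrix(rep(ys, each = shape[1]), shape[1], shape[2])
  m <- array(0L, shape)
  for (k in seq_len(shape[3])) {
    z <- (k - 1) * res
    if (z < z_range[1] || z > z_range[2]) next
    m[, , k] <- as.integer(X^2 + (Y - yc_fun(z))^2 <= radius^2)
  }
  sc_labels(m, aff, "cord-mask")
}

test_that("a straight centered cylinder yields a (0, 0) centerline", {
  tube <- make_tube(function(z) 0)
  ctr <- extract_centerline(tube)
  ok <- !is.na(ctr$centers_x)
  expect_lt(max(abs(ctr$centers_x[ok])), 1e-9)
  expect_lt(max(abs(ctr$centers_y[ok])), 1e-9)
  d <- ctr$dense
  expect_lt(max(abs(d$x)), 1e-6)
  expect_lt(max(abs(d$y)), 1e-6)
})

test_that("raw per-slice centers equal brute-force voxel means", {
  set.seed(21)
  spec <- tiny_spec(curvature = "flexion")
  ph <- generate_phantom(spec)
  ctr <- extract_centerline(ph$cord)
  g <- grid_of(ph$cord)
  for (k in c(20, 50, 90)) {
    idx <- which(ph$cord$data[, , k] != 0, arr.ind = TRUE)
    w <- vox_to_world(g$affine, cbind(idx[, 1] - 1, idx[, 2] - 1, k - 1))
    expect_equal(ctr$centers_x[k], mean(w[, 1]), tolerance = 1e-6)
    expect_equal(ctr$centers_y[k], mean(w[, 2]), tolerance = 1e-6)
  }
})

test_that("a one-voxel-per-slice line x = 0.2 z is recovered", {
  shape <- c(40L, 40L, 80L)
  aff <- diag(c(1, 1, 1, 1)); aff[1, 4] <- -19.5; aff[2, 4] <- -19.5
  m <- array(0L, shape)
  for (k in seq_len(shape[3])) {
    z <- k - 1
    i <- round((0.2 * z - aff[1, 4]) / aff[1, 1]) + 1
    j <- round((0 - aff[2, 4]) / aff[2, 2]) + 1
    m[i, j, k] <- 1L
  }
  cord <- sc_labels(m, aff, "cord-mask")
  # heavy smoothing recovers the underlying line from the quantized
  # voxel-center staircase
  ctr <- extract_centerline(cord, smoothing = 10)
  interior <- ctr$dense$z >= 10 & ctr$dense$z <= 69
  err <- abs(ctr$dense$x[interior] - 0.2 * ctr$dense$z[interior])
  expect_lt(max(err), 0.1)
})

test_that("centerline errors on empty or too-sparse masks", {
  aff <- diag(c(1, 1, 1, 1))
  empty <- sc_labels(array(0L, c(8, 8, 8)), aff, "cord-mask")
  expect_error(extract_centerline(empty), "empty")
  sparse <- array(0L, c(8, 8, 8)); sparse[4, 4, 2:4] <- 1L
  expect_error(extract_centerline(sc_labels(sparse, aff, "cord-mask")),
               "fewer than 5")
})

test_that("straightening an already-straight phantom is the identity", {
  tpl <- tiny_template()
  ctr <- extract_centerline(tpl$cord)
  st <- straighten(tpl$image, ctr, target_grid = grid_of(tpl$image),
                   compute_inverse = FALSE)
  mag <- sqrt(rowSums(matrix(st$warp_straighten$vectors, ncol = 3)^2))
  expect_lt(max(mag), 0.5 * 1.0)   # < 0.5 voxel at 1 mm
  inside <- tpl$cord$data == 1
  err <- abs(st$straightened$data - tpl$image$data)
  expect_lt(mean(err[inside]), 0.02 * diff(range(tpl$image$data)))
})

test_that("a circular-arc cord straightens to the vertical axis", {
  R <- 200
  yc <- function(z) R - sqrt(R^2 - (z - 50)^2)
  tube <- make_tube(yc, z_range = c(5, 95))
  ctr <- extract_centerline(tube)
  st <- straighten(tube, ctr, compute_inverse = FALSE)
  cordw <- apply_warp(tube, st$warp_straighten, "nearest")
  ctr2 <- extract_centerline(cordw)
  # interior slices (full cross-sections; the end caps are partial)
  counts <- ctr2$counts
  interior <- which(counts >= stats::median(counts[counts > 0]))
  interior <- interior[interior > min(interior) + 2 &
                         interior < max(interior) - 2]
  expect_lt(max(abs(ctr2$centers_x[interior])), 1)
  expect_lt(max(abs(ctr2$centers_y[interior])), 1)
})

test_that("arc length between landmarks is preserved by straightening", {
  R <- 200
  yc <- function(z) R - sqrt(R^2 - (z - 50)^2)
  tube <- make_tube(yc, z_range = c(5, 95))
  ctr <- extract_centerline(tube)
  # analytic arc length of the circle between z = 20 and z = 80
  th <- function(z) asin((z - 50) / R)
  analytic <- R * (th(80) - th(20))
  p1 <- rootletreg:::straighten_points(ctr, c(0, yc(20), 20))
  p2 <- rootletreg:::straighten_points(ctr, c(0, yc(80), 80))
  measured <- p2[3] - p1[3]
  expect_lt(abs(measured - analytic) / analytic, 0.02)
})

test_that("straighten then unstraighten restores the image", {
  spec <- tiny_spec(curvature = "extension")
  ph <- generate_phantom(spec)
  ctr <- extract_centerline(ph$cord)
  st <- straighten(ph$image, ctr, compute_inverse = TRUE)
  back <- apply_warp(st$straightened, st$warp_unstraighten, "linear")
  inside <- ph$cord$data == 1
  err <- abs(back$data - ph$image$data)
  expect_lt(mean(err[inside]), 0.02 * diff(range(ph$image$data)))
})

test_that("straightening a straightened phantom is near-identity", {
  spec <- tiny_spec(curvature = "flexion")
  ph <- generate_phantom(spec)
  ctr <- extract_centerline(ph$cord)
  st <- straighten(ph$image, ctr, compute_inverse = FALSE)
  cordw <- apply_warp(ph$cord, st$warp_straighten, "nearest")
  ctr2 <- extract_centerline(cordw)
  st2 <- straighten(st$straightened, ctr2,
                    target_grid = grid_of(st$straightened),
                    compute_inverse = FALSE)
  mag <- sqrt(rowSums(matrix(st2$warp_straighten$vectors, ncol = 3)^2))
  # restrict to the cord region (the grid's far corners extrapolate)
  inside <- as.vector(cordw$data == 1)
  expect_lt(max(mag[inside]), 0.5 * 1.0)
})
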