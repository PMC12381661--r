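# Spinal-cord centerline extraction and straightening.
#
# The straightened space follows arc length along the smoothed centerline:
# each output slice samples the input on the plane orthogonal to the
# centerline tangent, with in-plane axes transported by minimal rotation
# (parallel transport) to avoid in-plane spinning. Arc length along the
# cord is preserved by construction.

#' Extract the spinal-cord centerline from a cord mask
#'
#' Computes the per-slice center of mass of the binary cord segmentation in
#' world mm, interpolates empty slices inside the segmented z-range, and
#' fits a cubic smoothing spline to x(z) and y(z). Beyond the segmented
#' range the curve extends linearly with the end tangent.
#'
#' @param cord an [sc_labels] cord mask with at least 5 non-empty axial
#'   slices.
#' @param smoothing positive smoothing-spline penalty (`lambda` of
#'   [stats::smooth.spline()]); default `1e-4` keeps sub-voxel fidelity
#'   while suppressing per-slice center jitter.
#' @return an object of class `sc_centerline`.
#' @export
extract_centerline <- function(cord, smoothing = 1e-4) {
  stopifnot(inherits(cord, "sc_labels"))
  if (all(cord$data == 0)) stop("empty cord mask")
  g <- grid_of(cord)
  nz <- g$shape[3]
  counts <- apply(cord$data != 0, 3L, sum)
  filled <- which(counts > 0)
  if (length(filled) < 5L)
    stop("cord mask has fewer than 5 non-empty axial slices")

  zs <- slice_z_world(g)
  cx <- rep(NA_real_, nz); cy <- rep(NA_real_, nz)
  for (k in filled) {
    idx <- which(cord$data[, , k] != 0, arr.ind = TRUE)
    w <- vox_to_world(g$affine, cbind(idx[, 1] - 1, idx[, 2] - 1, k - 1))
    cx[k] <- mean(w[, 1]); cy[k] <- mean(w[, 2])
  }
  krange <- range(filled)
  kin <- krange[1]:krange[2]
  # linear interpolation across empty interior slices
  cx[kin] <- approx(zs[filled], cx[filled], xout = zs[kin], rule = 2)$y
  cy[kin] <- approx(zs[filled], cy[filled], xout = zs[kin], rule = 2)$y

  # weight slices by voxel count: partial end-cap slices have biased,
  # noisy centers and should not bend the fit
  wts <- pmax(counts[kin], 1)
  wts <- wts / mean(wts)
  fit_x <- smooth.spline(zs[kin], cx[kin], w = wts, lambda = smoothing)
  fit_y <- smooth.spline(zs[kin], cy[kin], w = wts, lambda = smoothing)
  zr <- range(zs[kin])

  # dense sampling with linear end-tangent extension well beyond the mask
  dz <- min(voxel_size(g$affine)[3], 0.5)
  ext <- 50
  zd <- seq(zr[1] - ext, zr[2] + ext, by = dz)
  eval_curve <- function(fit, z) {
    z0 <- pmin(pmax(z, zr[1]), zr[2])
    v <- predict(fit, z0)$y
    d <- predict(fit, z0, deriv = 1)$y
    v + d * (z - z0)    # linear extension with end tangent
  }
  xd <- eval_curve(fit_x, zd)
  yd <- eval_curve(fit_y, zd)
  dxdz <- c(diff(xd) / dz, NA); dxdz[length(dxdz)] <- dxdz[length(dxdz) - 1]
  dydz <- c(diff(yd) / dz, NA); dydz[length(dydz)] <- dydz[length(dydz) - 1]
  # centered differences in the interior
  n <- length(zd)
  dxdz[2:(n - 1)] <- (xd[3:n] - xd[1:(n - 2)]) / (2 * dz)
  dydz[2:(n - 1)] <- (yd[3:n] - yd[1:(n - 2)]) / (2 * dz)
  seglen <- sqrt(1 + dxdz^2 + dydz^2) * dz
  s <- c(0, cumsum(seglen[-n]))
  s <- s - approx(zd, s, xout = zr[1])$y     # arc length 0 at the caudal end

  structure(list(
    z_slices = zs, centers_x = cx, centers_y = cy,
    counts = counts, z_range = zr,
    fit_x = fit_x, fit_y = fit_y, smoothing = smoothing,
    dense = data.frame(z = zd, x = xd, y = yd,
                       dxdz = dxdz, dydz = dydz, s = s),
    total_length = approx(zd, s, xout = zr[2])$y
  ), class = "sc_centerline")
}

#' @export
print.sc_centerline <- function(x, ...) {
  cat(sprintf(
    "<sc_centerline> z range [%.1f, %.1f] mm, arc length %.1f mm\n",
    x$z_range[1], x$z_range[2], x$total_length))
  invisible(x)
}

# curve point / unit tangent at arbitrary z (vectorized), from dense table
centerline_point <- function(ctr, z) {
  d <- ctr$dense
  x <- approx(d$z, d$x, xout = z, rule = 2)$y
  y <- approx(d$z, d$y, xout = z, rule = 2)$y
  cbind(x, y, z)
}

centerline_tangent <- function(ctr, z) {
  d <- ctr$dense
  tx <- approx(d$z, d$dxdz, xout = z, rule = 2)$y
  ty <- approx(d$z, d$dydz, xout = z, rule = 2)$y
  t <- cbind(tx, ty, 1)
  t / sqrt(rowSums(t^2))
}

# arc length <-> z lookup (monotone by construction)
arc_of_z <- function(ctr, z) approx(ctr$dense$z, ctr$dense$s, xout = z,
                                    rule = 2)$y
z_of_arc <- function(ctr, s) approx(ctr$dense$s, ctr$dense$z, xout = s,
                                    rule = 2)$y

# minimal-rotation (parallel transport) frames along a sequence of unit
# tangents; returns list(e1, e2) matrices aligned with the tangent rows
transport_frames <- function(tangents) {
  n <- nrow(tangents)
  e1 <- matrix(0, n, 3); e2 <- matrix(0, n, 3)
  t1 <- tangents[1, ]
  a <- c(1, 0, 0) - sum(c(1, 0, 0) * t1) * t1
  if (sqrt(sum(a^2)) < 1e-6) a <- c(0, 1, 0) - sum(c(0, 1, 0) * t1) * t1
  e1[1, ] <- a / sqrt(sum(a^2))
  e2[1, ] <- cross3(t1, e1[1, ])
  for (i in 2:n) {
    tp <- tangents[i - 1, ]; tn <- tangents[i, ]
    axis <- cross3(tp, tn)
    sa <- sqrt(sum(axis^2))
    ca <- sum(tp * tn)
    if (sa < 1e-12) {
      e1[i, ] <- e1[i - 1, ]
    } else {
      e1[i, ] <- rodrigues(e1[i - 1, ], axis / sa, ca, sa)
    }
    # re-orthogonalize against the tangent to stop drift
    v <- e1[i, ] - sum(e1[i, ] * tn) * tn
    e1[i, ] <- v / sqrt(sum(v^2))
    e2[i, ] <- cross3(tn, e1[i, ])
  }
  list(e1 = e1, e2 = e2)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rodrigues <- function(v, k, ca, sa) {
  v * ca + cross3(k, v) * sa + k * sum(k * v) * (1 - ca)
}

#' Straighten an image along its spinal-cord centerline
#'
#' Resamples the image on a grid whose vertical axis follows arc length
#' along the centerline: the output slice at arc length `s` samples the
#' input on the plane orthogonal to the centerline tangent at `s`, with
#' in-plane axes transported by minimal rotation between slices. The
#' centerline maps to the vertical line through `axis_xy`, and the arc
#' length origin maps to the native z of the caudal end of the
#' segmentation, so an already-straight centered cord maps to itself.
#'
#' @param image an [sc_volume] (or [sc_labels]) to straighten.
#' @param centerline an `sc_centerline` from [extract_centerline()].
#' @param target_grid optional [grid_spec] for the straightened space;
#'   defaults to the image's in-plane grid with the z-range extended by
#'   `pad_mm` above and below the cord.
#' @param pad_mm extra grid above/below the cord when `target_grid` is
#'   `NULL` (default 10 mm).
#' @param axis_xy world (x, y) of the straightened cord axis (default
#'   `c(0, 0)`, the template cord position).
#' @param compute_inverse also build the unstraightening field on the
#'   native grid (default `TRUE`).
#' @return list with `straightened` (warped input), `warp_straighten`
#'   (field on the straightened grid pulling native content into it) and
#'   `warp_unstraighten` (field on the native grid, the inverse mapping;
#'   `NULL` when `compute_inverse = FALSE`).
#' @export
straighten <- function(image, centerline, target_grid = NULL, pad_mm = 10,
                       axis_xy = c(0, 0), compute_inverse = TRUE) {
  ctr <- centerline
  stopifnot(inherits(ctr, "sc_centerline"))
  gin <- grid_of(image)
  vs <- voxel_size(gin$affine)
  z0 <- ctr$z_range[1]

  if (is.null(target_grid)) {
    nz <- ceiling((ctr$total_length + 2 * pad_mm) / vs[3]) + 1
    aff <- gin$affine
    aff[3, 4] <- z0 - pad_mm
    # keep in-plane origin but center the axis at axis_xy
    target_grid <- grid_spec(c(gin$shape[1:2], nz), aff)
  }
  g <- grid_of(target_grid)
  if (any(g$shape < 2L)) stop("target grid too small to contain the cord")

  # per output slice: arc length, curve point, tangent, transported frame
  Z <- slice_z_world(g)
  s <- Z - z0                     # straight z  <->  arc length anchored at z0
  zq <- z_of_arc(ctr, s)
  cpts <- centerline_point(ctr, zq)
  tang <- centerline_tangent(ctr, zq)
  if (any(!is.finite(tang))) stop("centerline tangent undefined")
  fr <- transport_frames(tang)

  d <- g$shape
  ij <- cbind(rep.int(seq_len(d[1]) - 1, d[2]),
              rep(seq_len(d[2]) - 1, each = d[1]))
  xy <- vox_to_world(g$affine, cbind(ij, 0))[, 1:2, drop = FALSE]
  u <- xy[, 1] - axis_xy[1]
  v <- xy[, 2] - axis_xy[2]

  vecs <- array(0, c(d, 3L))
  npl <- d[1] * d[2]
  for (k in seq_len(d[3])) {
    pt <- cpts[k, ]; e1 <- fr$e1[k, ]; e2 <- fr$e2[k, ]
    sx <- pt[1] + u * e1[1] + v * e2[1] - xy[, 1]
    sy <- pt[2] + u * e1[2] + v * e2[2] - xy[, 2]
    sz <- pt[3] + u * e1[3] + v * e2[3] - Z[k]
    vecs[, , k, 1] <- sx
    vecs[, , k, 2] <- sy
    vecs[, , k, 3] <- sz
  }
  w_straight <- warp_field(vecs, g$affine, "forward", "template")
  straightened <- apply_warp(image, w_straight)

  w_unstraight <- NULL
  if (compute_inverse)
    w_unstraight <- unstraighten_field(ctr, gin, z0, axis_xy)

  list(straightened = straightened,
       warp_straighten = w_straight,
       warp_unstraighten = w_unstraight)
}

# Map native-space points to their straightened coordinates by foot-point
# projection onto the centerline: a few Newton steps solve
# (p - c(t)) . T(t) = 0 for the curve parameter t (starting at t = native
# z), then the in-plane offsets are expressed in the transported frame and
# z becomes arc length anchored at z0.
straighten_points <- function(ctr, pts, z0 = ctr$z_range[1],
                              axis_xy = c(0, 0), frames = NULL) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L)
  den <- ctr$dense
  tden <- cbind(den$dxdz, den$dydz, 1)
  tden <- tden / sqrt(rowSums(tden^2))
  fr <- if (is.null(frames)) transport_frames(tden) else frames
  lookup <- function(tab, z) approx(den$z, tab, xout = z, rule = 2)$y

  px <- pts[, 1]; py <- pts[, 2]; pz <- pts[, 3]
  zc <- pz
  for (it in 1:4) {
    cx <- lookup(den$x, zc); cy <- lookup(den$y, zc)
    tx <- lookup(tden[, 1], zc)
    ty <- lookup(tden[, 2], zc)
    tz <- lookup(tden[, 3], zc)
    f <- (px - cx) * tx + (py - cy) * ty + (pz - zc) * tz
    zc <- zc + f * tz
  }
  cx <- lookup(den$x, zc); cy <- lookup(den$y, zc)
  dx <- px - cx; dy <- py - cy; dz <- pz - zc
  U <- dx * lookup(fr$e1[, 1], zc) + dy * lookup(fr$e1[, 2], zc) +
    dz * lookup(fr$e1[, 3], zc)
  V <- dx * lookup(fr$e2[, 1], zc) + dy * lookup(fr$e2[, 2], zc) +
    dz * lookup(fr$e2[, 3], zc)
  cbind(axis_xy[1] + U, axis_xy[2] + V, z0 + lookup(den$s, zc))
}

# Field on the native grid holding, at each native point p, the offset to
# its straightened coordinates (pull-back: resamples straightened content
# back to native space; the inverse of the straightening map).
unstraighten_field <- function(ctr, native_grid, z0, axis_xy) {
  g <- grid_of(native_grid)
  dgrid <- g$shape
  ij <- cbind(rep.int(seq_len(dgrid[1]) - 1, dgrid[2]),
              rep(seq_len(dgrid[2]) - 1, each = dgrid[1]))
  xy0 <- vox_to_world(g$affine, cbind(ij, 0))[, 1:2, drop = FALSE]
  Z <- slice_z_world(g)
  tden <- cbind(ctr$dense$dxdz, ctr$dense$dydz, 1)
  tden <- tden / sqrt(rowSums(tden^2))
  frames <- transport_frames(tden)
  vecs <- array(0, c(dgrid, 3L))
  for (k in seq_len(dgrid[3])) {
    pts <- cbind(xy0[, 1], xy0[, 2], Z[k])
    q <- straighten_points(ctr, pts, z0, axis_xy, frames = frames)
    vecs[, , k, 1] <- q[, 1] - pts[, 1]
    vecs[, , k, 2] <- q[, 2] - pts[, 2]
    vecs[, , k, 3] <- q[, 3] - pts[, 3]
  }
  warp_field(vecs, g$affine, "backward", "subject")
}
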