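# Displacement-field post-processing: slice-wise symmetrization, axial
# cord-size scaling, composition, inversion, and pull-back resampling.
# All fields hold world-mm offsets; application is pull-back throughout:
# the warped image at grid point p samples the input at p + field(p).

# evaluate a field's components at arbitrary world points (n x 3), with
# edge-clamped linear interpolation; fields are extended by clamping so
# z-only fields behave as constant beyond their support.
field_at_world <- function(field, xyz) {
  ijk <- world_to_vox(field$affine, xyz)
  cbind(
    interp3(field$vectors[, , , 1], ijk, "linear", oob = "clamp"),
    interp3(field$vectors[, , , 2], ijk, "linear", oob = "clamp"),
    interp3(field$vectors[, , , 3], ijk, "linear", oob = "clamp")
  )
}

#' Resample an image or label volume through a displacement field
#'
#' Pull-back resampling onto the field's reference grid: the output value at
#' grid point `p` is the input sampled at world point `p + field(p)`. Label
#' volumes must use nearest-neighbour; samples falling outside the input
#' grid are set to 0.
#'
#' @param image an [sc_volume] or [sc_labels].
#' @param field a [warp_field]; its grid is the output grid.
#' @param interpolation `"linear"` or `"nearest"`; defaults to `"nearest"`
#'   for label volumes and `"linear"` for images.
#' @return warped volume on the field's grid, same class as `image`.
#' @export
apply_warp <- function(image, field,
                       interpolation = if (inherits(image, "sc_labels"))
                         "nearest" else "linear") {
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  if (inherits(image, "sc_labels") && interpolation == "linear")
    stop("linear interpolation refused for label volumes; use nearest")
  g <- grid_of(field)
  ijk <- grid_index_matrix(g)
  p <- vox_to_world(g$affine, ijk)
  q <- p + matrix(field$vectors, ncol = 3L)
  src <- world_to_vox(image$affine, q)
  vals <- interp3(image$data, src, interpolation, oob = "zero")
  if (inherits(image, "sc_labels")) {
    sc_labels(array(as.integer(vals), g$shape), g$affine, image$semantics)
  } else {
    sc_volume(array(vals, g$shape), g$affine)
  }
}

#' Slice-wise symmetrization of a rostro-caudal displacement field
#'
#' For every axial slice the z-component is replaced by the mean of its
#' non-zero values (|dz| > 1e-9 mm), broadcast as a constant across the
#' whole slice; slices with no non-zero values stay zero. The result is
#' exactly left-right symmetric and the operation is idempotent.
#'
#' @param field a [warp_field] with zero x and y components.
#' @return symmetrized [warp_field].
#' @export
symmetrize_slicewise <- function(field) {
  if (any(field$vectors[, , , 1] != 0) || any(field$vectors[, , , 2] != 0))
    stop("symmetrize_slicewise expects zero x and y components")
  v <- field$vectors
  nz <- dim(v)[3]
  for (k in seq_len(nz)) {
    dz <- v[, , k, 3]
    rng <- range(dz)
    if (rng[1] == rng[2]) {
      # already constant: leave untouched (makes the op exactly idempotent)
      if (abs(rng[1]) <= 1e-9) v[, , k, 3] <- 0
      next
    }
    keep <- abs(dz) > 1e-9
    if (any(keep)) {
      # sort before summing so the mean is invariant to voxel order
      # (left-right flips permute voxels within the slice)
      v[, , k, 3] <- mean(sort(dz[keep]))
    } else {
      v[, , k, 3] <- 0
    }
  }
  warp_field(v, field$affine, field$direction, field$reference)
}

#' Per-slice axial scaling matching subject cord size to the template
#'
#' For each template slice the isotropic in-plane scale factor
#' `s(z) = sqrt(area_template / area_subject)` is computed from the two cord
#' masks, median-filtered along z (5-slice window), and expressed as a
#' pull-back displacement field about the template cord center of that
#' slice (zero z-component). Slices where either mask is empty get `s = 1`.
#'
#' @param subject_cord_warped subject cord mask already warped to the
#'   template grid ([sc_labels], cord-mask).
#' @param template_cord template cord mask ([sc_labels], cord-mask).
#' @return list with `field` (a [warp_field]) and `profile` (data frame of
#'   class `scale_profile`: slice, scale, center_x, center_y).
#' @export
xy_scaling <- function(subject_cord_warped, template_cord) {
  if (!check_same_grid(subject_cord_warped, template_cord))
    stop("cord masks must share the template grid")
  g <- grid_of(template_cord)
  nz <- g$shape[3]
  vs <- voxel_size(g$affine)
  area_sub <- apply(subject_cord_warped$data != 0, 3L, sum) * vs[1] * vs[2]
  area_tpl <- apply(template_cord$data != 0, 3L, sum) * vs[1] * vs[2]
  tpl_slices <- which(area_tpl > 0)
  if (length(tpl_slices) > 0 &&
      sum(area_sub[tpl_slices] == 0) > 0.5 * length(tpl_slices))
    stop("subject cord empty on more than half of template cord slices")

  s <- rep(1, nz)
  ok <- area_sub > 0 & area_tpl > 0
  s[ok] <- sqrt(area_tpl[ok] / area_sub[ok])
  s <- as.numeric(runmed(s, 5L, endrule = "keep"))
  s <- pmin(pmax(s, 0.2 + 1e-9), 5 - 1e-9)

  # per-slice template cord center (world mm); carried through empty slices
  cx <- rep(NA_real_, nz); cy <- rep(NA_real_, nz)
  for (k in tpl_slices) {
    idx <- which(template_cord$data[, , k] != 0, arr.ind = TRUE)
    w <- vox_to_world(g$affine, cbind(idx[, 1] - 1, idx[, 2] - 1, k - 1))
    cx[k] <- mean(w[, 1]); cy[k] <- mean(w[, 2])
  }
  if (all(is.na(cx))) { cx[] <- 0; cy[] <- 0 }
  ztab <- slice_z_world(g)
  cx <- approx(ztab, cx, xout = ztab, rule = 2)$y
  cy <- approx(ztab, cy, xout = ztab, rule = 2)$y

  # pull-back of forward map p -> c + s (p - c):  v(p) = (p - c) (1/s - 1)
  d <- g$shape
  ij <- cbind(
    rep.int(seq_len(d[1]) - 1, d[2]),
    rep(seq_len(d[2]) - 1, each = d[1])
  )
  xy <- vox_to_world(g$affine, cbind(ij, 0))[, 1:2, drop = FALSE]
  v <- array(0, c(d, 3L))
  for (k in seq_len(nz)) {
    f <- 1 / s[k] - 1
    if (f != 0) {
      v[, , k, 1] <- (xy[, 1] - cx[k]) * f
      v[, , k, 2] <- (xy[, 2] - cy[k]) * f
    }
  }
  profile <- data.frame(slice = seq_len(nz), scale = s,
                        center_x = cx, center_y = cy)
  class(profile) <- c("scale_profile", "data.frame")
  list(field = warp_field(v, g$affine, "forward", "template"),
       profile = profile)
}

#' Compose two displacement fields
#'
#' Pull-back chaining: `result(p) = inner(p + outer(p)) + outer(p)`, with
#' edge-clamped linear interpolation of `inner` off-grid. Under pull-back
#' application this is equivalent to applying `inner` first and `outer`
#' second, i.e. warping an image with `result` equals warping with `inner`
#' and then warping that result with `outer`. The output lives on the
#' `outer` grid and inherits its direction/reference; `inner` may live on a
#' different grid.
#'
#' @param outer,inner [warp_field]s; directions must agree.
#' @return composed [warp_field] on the `outer` grid.
#' @export
compose_warps <- function(outer, inner) {
  if (outer$direction != inner$direction)
    stop("direction mismatch: cannot compose ", outer$direction,
         " with ", inner$direction)
  g <- grid_of(outer)
  p <- vox_to_world(g$affine, grid_index_matrix(g))
  vout <- matrix(outer$vectors, ncol = 3L)
  vin <- field_at_world(inner, p + vout)
  warp_field(array(vout + vin, c(g$shape, 3L)), g$affine,
             outer$direction, outer$reference)
}

#' Invert a displacement field by fixed-point iteration
#'
#' Solves `v(p) = -field(p + v(p))` on the field's own grid (at most
#' `max_iter` iterations, stopping when the largest update falls below
#' `tol` mm). Requires a fold-over-free field; non-convergence is an error.
#'
#' @param field a [warp_field].
#' @param max_iter maximum fixed-point iterations (default 50).
#' @param tol convergence tolerance in mm (default 0.05).
#' @return the inverse [warp_field] (direction flipped).
#' @export
invert_warp <- function(field, max_iter = 50L, tol = 0.05) {
  g <- grid_of(field)
  p <- vox_to_world(g$affine, grid_index_matrix(g))
  v <- -matrix(field$vectors, ncol = 3L)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    vnew <- -field_at_world(field, p + v)
    delta <- max(abs(vnew - v))
    v <- vnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("displacement inversion did not converge (folded field?)")
  newdir <- if (field$direction == "forward") "backward" else "forward"
  warp_field(array(v, c(g$shape, 3L)), g$affine, newdir, field$reference)
}
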