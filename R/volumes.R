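# ---- affine / grid helpers --------------------------------------------------

#' Map 0-based voxel indices to world coordinates (mm)
#'
#' @param affine 4x4 voxel-index-to-world transform (NIfTI convention,
#'   0-based indices).
#' @param ijk numeric matrix with one row per point and columns (i, j, k),
#'   0-based; a length-3 vector is treated as a single point.
#' @return matrix of world coordinates (mm), one row per point.
#' @export
vox_to_world <- function(affine, ijk) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1L)
  xyz <- ijk %*% t(affine[1:3, 1:3, drop = FALSE])
  sweep(xyz, 2L, affine[1:3, 4], "+")
}

#' Map world coordinates (mm) to 0-based voxel indices
#'
#' @inheritParams vox_to_world
#' @param xyz world coordinates, one row per point.
#' @return matrix of fractional 0-based voxel indices.
#' @export
world_to_vox <- function(affine, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  inv <- solve(affine)
  ijk <- xyz %*% t(inv[1:3, 1:3, drop = FALSE])
  sweep(ijk, 2L, inv[1:3, 4], "+")
}

#' Voxel sizes (mm) of an affine
#' @param affine 4x4 voxel-to-world transform.
#' @return numeric length-3 vector (dx, dy, dz) in mm.
#' @export
voxel_size <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3, drop = FALSE]^2))
}

check_affine <- function(affine) {
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  if (!all(is.finite(affine))) stop("affine contains non-finite entries")
  d <- det(affine[1:3, 1:3])
  if (!is.finite(d) || abs(d) < 1e-12) stop("affine is not invertible")
  if (any(voxel_size(affine) <= 0)) stop("voxel sizes must be positive")
  invisible(affine)
}

#' Grid specification (shape + affine)
#'
#' A light container describing a sampling grid without data, used as the
#' reference-grid argument of alignment and registration operations.
#'
#' @param shape integer length-3 grid dimensions.
#' @param affine 4x4 voxel-to-world transform.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(shape, affine) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  check_affine(affine)
  structure(list(shape = shape, affine = affine), class = "grid_spec")
}

#' Extract the grid of a volume, label volume or displacement field
#' @param x an `sc_volume`, `sc_labels`, `warp_field` or `grid_spec`.
#' @return a `grid_spec`.
#' @export
grid_of <- function(x) {
  if (inherits(x, "grid_spec")) return(x)
  if (inherits(x, "warp_field")) {
    return(grid_spec(dim(x$vectors)[1:3], x$affine))
  }
  grid_spec(dim(x$data), x$affine)
}

# world z coordinate of every axial slice (canonical orientation assumed)
slice_z_world <- function(grid) {
  g <- grid_of(grid)
  k <- seq_len(g$shape[3L]) - 1
  as.numeric(g$affine[3, 3] * k + g$affine[3, 4])
}

# ---- volume classes ---------------------------------------------------------

#' Scalar image volume
#'
#' @param data 3D numeric array of intensities.
#' @param affine 4x4 voxel-index (0-based) to world-mm transform.
#' @return an object of class `sc_volume` with fields `data` and `affine`.
#' @export
sc_volume <- function(data, affine) {
  stopifnot(length(dim(data)) == 3L)
  check_affine(affine)
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  structure(list(data = data, affine = affine), class = "sc_volume")
}

#' Integer-labeled volume
#'
#' Label semantics follow the host convention for cervical rootlet level
#' labels: in a `"rootlets"` volume, label 2 marks the C2 rootlets, 3 the C3
#' rootlets, and so on up to 8 for C8. Cord masks are binary (0/1), and
#' disc-point volumes hold isolated voxels carrying level codes.
#'
#' @param labels 3D integer array.
#' @param affine 4x4 voxel-to-world transform.
#' @param semantics one of `"cord-mask"`, `"rootlets"`, `"disc-points"`.
#' @return an object of class `sc_labels`.
#' @export
sc_labels <- function(labels, affine,
                      semantics = c("rootlets", "cord-mask", "disc-points")) {
  semantics <- match.arg(semantics)
  stopifnot(length(dim(labels)) == 3L)
  check_affine(affine)
  storage.mode(labels) <- "integer"
  u <- sort(unique(as.vector(labels)))
  if (semantics == "cord-mask" && !all(u %in% c(0L, 1L)))
    stop("cord-mask labels must be in {0, 1}")
  if (semantics == "rootlets" && !all(u %in% c(0L, 2:8)))
    stop("rootlet labels must be in {0, 2..8}")
  structure(list(data = labels, affine = affine, semantics = semantics),
            class = "sc_labels")
}

#' Displacement field
#'
#' Per-voxel world-mm offsets on a stated reference grid. Directions are
#' named from the template's viewpoint: a `"forward"` field lives on the
#' template grid and its value at a template point is the offset to the
#' corresponding subject-space point (pull-back sampling); `"backward"` is
#' the converse. A zero field is the identity.
#'
#' @param vectors 4D numeric array `(nx, ny, nz, 3)` of offsets in mm.
#' @param affine 4x4 voxel-to-world transform of the reference grid.
#' @param direction `"forward"` or `"backward"`.
#' @param reference `"template"` or `"subject"` — which space the grid lies in.
#' @return an object of class `warp_field`.
#' @export
warp_field <- function(vectors, affine,
                       direction = c("forward", "backward"),
                       reference = c("template", "subject")) {
  direction <- match.arg(direction)
  reference <- match.arg(reference)
  d <- dim(vectors)
  stopifnot(length(d) == 4L, d[4L] == 3L)
  check_affine(affine)
  if (!all(is.finite(vectors))) stop("displacement components must be finite")
  structure(list(vectors = vectors, affine = affine,
                 direction = direction, reference = reference),
            class = "warp_field")
}

#' Zero (identity) displacement field on a grid
#' @param grid a `grid_spec` or gridded object.
#' @inheritParams warp_field
#' @return a `warp_field` of zeros.
#' @export
zero_field <- function(grid, direction = "forward", reference = "template") {
  g <- grid_of(grid)
  warp_field(array(0, c(g$shape, 3L)), g$affine, direction, reference)
}

#' Test whether two gridded objects share shape and affine
#'
#' @param a,b volumes, label volumes, fields or grid specs.
#' @param tol affine agreement tolerance in mm (default 1e-5).
#' @return `TRUE` iff shapes are equal and affines agree within `tol`.
#' @export
check_same_grid <- function(a, b, tol = 1e-5) {
  ga <- grid_of(a); gb <- grid_of(b)
  identical(ga$shape, gb$shape) && all(abs(ga$affine - gb$affine) <= tol)
}

#' @export
print.sc_volume <- function(x, ...) {
  d <- dim(x$data); vs <- voxel_size(x$affine)
  cat(sprintf("<sc_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.sc_labels <- function(x, ...) {
  d <- dim(x$data)
  u <- setdiff(sort(unique(as.vector(x$data))), 0L)
  cat(sprintf("<sc_labels:%s> %d x %d x %d voxels, labels {%s}\n",
              x$semantics, d[1], d[2], d[3], paste(u, collapse = ",")))
  invisible(x)
}

#' @export
print.warp_field <- function(x, ...) {
  d <- dim(x$vectors)
  mag <- sqrt(rowSums(matrix(x$vectors, ncol = 3L)^2))
  cat(sprintf(
    "<warp_field:%s/%s> %d x %d x %d, |v| mean %.3g mm, max %.3g mm\n",
    x$direction, x$reference, d[1], d[2], d[3], mean(mag), max(mag)))
  invisible(x)
}

# ---- interpolation ----------------------------------------------------------

# Trilinear / nearest sampling of a 3D array at fractional 0-based indices.
# oob = "zero": samples outside the grid return 0 (pull-back convention);
# oob = "clamp": indices are clamped to the edge (used for field lookup).
interp3 <- function(arr, ijk, method = c("linear", "nearest"),
                    oob = c("zero", "clamp")) {
  method <- match.arg(method)
  oob <- match.arg(oob)
  d <- dim(arr)
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1L)
  n <- nrow(ijk)

  if (method == "nearest") {
    idx <- round(ijk)
    inside <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
      idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
      idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
    if (oob == "clamp") {
      idx[, 1] <- pmin(pmax(idx[, 1], 0), d[1] - 1)
      idx[, 2] <- pmin(pmax(idx[, 2], 0), d[2] - 1)
      idx[, 3] <- pmin(pmax(idx[, 3], 0), d[3] - 1)
      inside <- rep(TRUE, n)
    }
    out <- numeric(n)
    if (any(inside)) {
      ii <- idx[inside, , drop = FALSE] + 1
      out[inside] <- arr[cbind(ii[, 1], ii[, 2], ii[, 3])]
    }
    return(out)
  }

  if (oob == "clamp") {
    ijk[, 1] <- pmin(pmax(ijk[, 1], 0), d[1] - 1)
    ijk[, 2] <- pmin(pmax(ijk[, 2], 0), d[2] - 1)
    ijk[, 3] <- pmin(pmax(ijk[, 3], 0), d[3] - 1)
    inside <- rep(TRUE, n)
  } else {
    inside <- ijk[, 1] >= 0 & ijk[, 1] <= d[1] - 1 &
      ijk[, 2] >= 0 & ijk[, 2] <= d[2] - 1 &
      ijk[, 3] >= 0 & ijk[, 3] <= d[3] - 1
  }
  out <- numeric(n)
  if (!any(inside)) return(out)
  p <- ijk[inside, , drop = FALSE]
  f0 <- floor(p)
  w <- p - f0
  # upper corner clamped so that exact-edge samples stay valid
  i0 <- pmin(f0[, 1], d[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(f0[, 2], d[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(f0[, 3], d[3] - 2); k0 <- pmax(k0, 0)
  wx <- p[, 1] - i0; wy <- p[, 2] - j0; wz <- p[, 3] - k0
  i0 <- i0 + 1; j0 <- j0 + 1; k0 <- k0 + 1
  v000 <- arr[cbind(i0,     j0,     k0)]
  v100 <- arr[cbind(i0 + 1, j0,     k0)]
  v010 <- arr[cbind(i0,     j0 + 1, k0)]
  v110 <- arr[cbind(i0 + 1, j0 + 1, k0)]
  v001 <- arr[cbind(i0,     j0,     k0 + 1)]
  v101 <- arr[cbind(i0 + 1, j0,     k0 + 1)]
  v011 <- arr[cbind(i0,     j0 + 1, k0 + 1)]
  v111 <- arr[cbind(i0 + 1, j0 + 1, k0 + 1)]
  out[inside] <-
    v000 * (1 - wx) * (1 - wy) * (1 - wz) +
    v100 * wx       * (1 - wy) * (1 - wz) +
    v010 * (1 - wx) * wy       * (1 - wz) +
    v110 * wx       * wy       * (1 - wz) +
    v001 * (1 - wx) * (1 - wy) * wz +
    v101 * wx       * (1 - wy) * wz +
    v011 * (1 - wx) * wy       * wz +
    v111 * wx       * wy       * wz
  out
}

# 0-based index grid of all voxels of a grid_spec, as an n x 3 matrix
grid_index_matrix <- function(grid) {
  g <- grid_of(grid)
  d <- g$shape
  cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  )
}
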