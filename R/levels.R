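# Per-level landmark centers of mass and the 1D non-linear rostro-caudal
# alignment of subject landmarks to the template. Levels follow the host
# label convention (2 = C2 rootlets ... 8 = C8 rootlets; disc points carry
# their own level codes). More caudal levels sit at lower z in the
# canonical orientation, so level z must strictly decrease with level code.

#' Per-level centers of mass of a labeled volume
#'
#' For each non-zero label code, the unweighted mean of the world
#' coordinates of its voxels.
#'
#' @param labels an [sc_labels] volume (rootlets or disc points).
#' @return object of class `level_centers`: a data frame with columns
#'   `level`, `x`, `y`, `z` (mm) and `n_voxels`, ordered by level code.
#' @export
level_centers <- function(labels) {
  stopifnot(inherits(labels, "sc_labels"))
  codes <- setdiff(sort(unique(as.vector(labels$data))), 0L)
  if (length(codes) < 2L)
    stop("fewer than 2 labeled levels present; alignment impossible")
  g <- grid_of(labels)
  rows <- lapply(codes, function(code) {
    idx <- which(labels$data == code, arr.ind = TRUE) - 1
    w <- vox_to_world(g$affine, idx)
    data.frame(level = code, x = mean(w[, 1]), y = mean(w[, 2]),
               z = mean(w[, 3]), n_voxels = nrow(idx))
  })
  out <- do.call(rbind, rows)
  if (any(diff(out$z) >= 0))
    stop("non-monotone level ordering in z: more caudal levels must be ",
         "more inferior (corrupt segmentation?)")
  class(out) <- c("level_centers", "data.frame")
  out
}

# Monotone 1D mapping built from matched landmark z positions.
# Returns a vectorized function mapping z in `from`-space to z in
# `to`-space; between landmarks a shape-preserving monotone cubic
# (Fritsch-Carlson) interpolant, beyond the outermost landmarks a constant
# shift (clamped extension).
level_map_fun <- function(from_z, to_z, interp = c("pchip", "linear")) {
  interp <- match.arg(interp)
  o <- order(from_z)
  from_z <- from_z[o]; to_z <- to_z[o]
  if (any(diff(from_z) <= 0) || any(diff(to_z) <= 0))
    stop("landmark mapping is non-monotone (crossing landmarks)")
  f <- if (interp == "pchip" && length(from_z) >= 3L) {
    splinefun(from_z, to_z, method = "monoH.FC")
  } else {
    function(z) approx(from_z, to_z, xout = z, rule = 2)$y
  }
  lo <- from_z[1]; hi <- from_z[length(from_z)]
  shift_lo <- to_z[1] - lo
  shift_hi <- to_z[length(to_z)] - hi
  function(z) {
    out <- f(pmin(pmax(z, lo), hi))
    out[z < lo] <- z[z < lo] + shift_lo
    out[z > hi] <- z[z > hi] + shift_hi
    out
  }
}

match_levels <- function(subject, template) {
  common <- intersect(subject$level, template$level)
  if (length(common) < 2L)
    stop("fewer than 2 common levels between subject and template")
  missing_mid <- setdiff(
    template$level[template$level > min(common) &
                     template$level < max(common)], common)
  if (length(missing_mid) > 0)
    warning("missing intermediate level(s) ",
            paste(missing_mid, collapse = ", "),
            "; interpolating across the gap")
  list(sub_z = subject$z[match(common, subject$level)],
       tpl_z = template$z[match(common, template$level)],
       levels = common)
}

#' Non-linear rostro-caudal alignment of level landmarks to the template
#'
#' Builds a z-only displacement field on the reference (template) grid that
#' sends each subject level z to the matching template level z: the field's
#' z-component at template z equals `m(z) - z`, where `m` is the monotone
#' map from template landmark z to subject landmark z. Interpolation
#' between landmarks is shape-preserving monotone cubic; beyond the
#' outermost landmarks the shift is held constant. x and y components are
#' zero.
#'
#' @param subject [level_centers] in straightened-subject space.
#' @param template [level_centers] of the template.
#' @param reference_grid [grid_spec] (or gridded object) of the template.
#' @param interp `"pchip"` (monotone cubic, default) or `"linear"`.
#' @return a z-only [warp_field] on the reference grid (forward direction).
#' @export
build_level_alignment <- function(subject, template, reference_grid,
                                  interp = c("pchip", "linear")) {
  interp <- match.arg(interp)
  m <- match_levels(subject, template)
  # pull-back: at template z we need the subject z to sample from
  map_t2s <- level_map_fun(m$tpl_z, m$sub_z, interp)
  g <- grid_of(reference_grid)
  Z <- slice_z_world(g)
  dz <- map_t2s(Z) - Z
  v <- array(0, c(g$shape, 3L))
  v[, , , 3] <- rep(dz, each = g$shape[1] * g$shape[2])
  warp_field(v, g$affine, "forward", "template")
}

#' Disc-landmark baseline alignment
#'
#' The traditional comparator: identical machinery to
#' [build_level_alignment()] but driven by intervertebral-disc point labels
#' instead of rootlet levels.
#'
#' @inheritParams build_level_alignment
#' @param subject_discs,template_discs [level_centers] of disc point labels.
#' @return a z-only [warp_field] on the reference grid.
#' @export
disc_baseline_alignment <- function(subject_discs, template_discs,
                                    reference_grid,
                                    interp = c("pchip", "linear")) {
  build_level_alignment(subject_discs, template_discs, reference_grid,
                        interp = match.arg(interp))
}

#' Subject-to-template landmark z mapping
#'
#' The monotone 1D map sending subject level z to template level z (the
#' inverse direction of the pull-back field built by
#' [build_level_alignment()]); useful for diagnostics and tests.
#'
#' @inheritParams build_level_alignment
#' @return a vectorized function z_subject -> z_template.
#' @export
level_map <- function(subject, template, interp = c("pchip", "linear")) {
  m <- match_levels(subject, template)
  level_map_fun(m$sub_z, m$tpl_z, match.arg(interp))
}
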