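# Validation metrics: per-level rostro-caudal overlap against the template
# rootlets, slice-wise cross-sectional area (CSA) morphometry with
# normalization, moving-average smoothing, and localization of the
# cervical enlargement.

#' Per-level rostro-caudal overlap with the template rootlets
#'
#' For each level the set of axial slices containing that label is computed
#' in both volumes; `length_overlap` is the size of the intersection and
#' the primary percentage normalizes by the template level's slice count,
#' so 100 describes a perfect overlap with the template rootlets. A 1D Dice
#' variant `200 * overlap / (length_pam50 + length_sub)` is reported
#' alongside. Only z-extents matter: the metric ignores in-plane position.
#'
#' @param subject_warped subject rootlet labels warped to the template grid
#'   ([sc_labels]).
#' @param template_rootlets template rootlet labels ([sc_labels]).
#' @return object of class `overlap_result`: data frame with columns
#'   `level`, `length_overlap`, `length_pam50`, `length_sub`, `percent`,
#'   `dice1d`, `missing_in_subject`; attributes `mean` and `sd`
#'   (population SD) of the primary percentage.
#' @export
rootlet_overlap <- function(subject_warped, template_rootlets) {
  if (!check_same_grid(subject_warped, template_rootlets))
    stop("both volumes must be on the template grid")
  levels <- setdiff(sort(unique(as.vector(template_rootlets$data))), 0L)
  rows <- lapply(levels, function(lv) {
    zt <- which(apply(template_rootlets$data == lv, 3L, any))
    zs <- which(apply(subject_warped$data == lv, 3L, any))
    ov <- length(intersect(zt, zs))
    data.frame(level = lv,
               length_overlap = ov,
               length_pam50 = length(zt),
               length_sub = length(zs),
               percent = 100 * ov / length(zt),
               dice1d = if (length(zt) + length(zs) > 0)
                 200 * ov / (length(zt) + length(zs)) else 0,
               missing_in_subject = length(zs) == 0L)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean") <- mean(out$percent)
  attr(out, "sd") <- pop_sd(out$percent)
  class(out) <- c("overlap_result", "data.frame")
  out
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
print.overlap_result <- function(x, ...) {
  cat("Per-level rostro-caudal overlap with template rootlets\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("mean %.2f%%, SD %.2f%% (population)\n",
              attr(x, "mean"), attr(x, "sd")))
  invisible(x)
}

#' Slice-wise cross-sectional area profile of a cord mask
#'
#' CSA per axial slice = voxel count x in-plane voxel area, over the slices
#' within the mask support.
#'
#' @param cord an [sc_labels] cord mask.
#' @return object of class `csa_profile`: data frame with columns `slice`
#'   (1-based index), `z_mm`, `csa_mm2`; attribute `slice_thickness_mm`.
#' @export
csa_profile <- function(cord) {
  stopifnot(inherits(cord, "sc_labels"))
  if (all(cord$data == 0)) stop("empty cord mask")
  g <- grid_of(cord)
  vs <- voxel_size(g$affine)
  counts <- apply(cord$data != 0, 3L, sum)
  support <- which(counts > 0)
  ks <- support[1]:support[length(support)]
  out <- data.frame(slice = ks, z_mm = slice_z_world(g)[ks],
                    csa_mm2 = counts[ks] * vs[1] * vs[2])
  attr(out, "slice_thickness_mm") <- vs[3]
  class(out) <- c("csa_profile", "data.frame")
  out
}

#' Normalize a CSA profile at a reference slice
#'
#' Divides the profile by its mean over a window of `window_slices` slices
#' centered at `reference_z` (by default 20 slices, i.e. 10 mm at 0.5 mm
#' slice thickness, centered at the C2-C3 intervertebral disc), adding a
#' `csa_norm` column. Normalizing twice is idempotent.
#'
#' @param profile a [csa_profile()] data frame.
#' @param reference_z slice index at the center of the window.
#' @param window_slices window length in slices (default 20).
#' @return the profile with `csa_norm` added/replaced.
#' @export
normalize_csa <- function(profile, reference_z, window_slices = 20L) {
  stopifnot(inherits(profile, "csa_profile"))
  half_lo <- floor(window_slices / 2)
  win <- seq(reference_z - half_lo, length.out = window_slices)
  if (min(win) < min(profile$slice) || max(win) > max(profile$slice))
    stop("normalization window exceeds the profile support")
  ref <- mean(profile$csa_mm2[match(win, profile$slice)])
  profile$csa_norm <- profile$csa_mm2 / ref
  attr(profile, "norm_reference") <- ref
  profile
}

#' Smooth a CSA profile and localize the cervical enlargement
#'
#' Applies a centered moving average of physical width `window_mm`
#' (converted to an odd number of slices) with reflected boundaries to the
#' normalized profile when present (raw CSA otherwise), then takes the
#' argmax of the smoothed curve as the center of the cervical enlargement.
#' Ties are broken toward the more rostral (superior) slice.
#'
#' @param profile a [csa_profile()] data frame.
#' @param window_mm moving-average window in mm (default 22.5).
#' @return the profile with a `csa_smooth` column and attributes
#'   `enlargement_slice` (slice index), `enlargement_z_mm` and
#'   `smooth_window_slices`.
#' @export
smooth_and_localize <- function(profile, window_mm = 22.5) {
  stopifnot(inherits(profile, "csa_profile"))
  dz <- attr(profile, "slice_thickness_mm")
  w <- round(window_mm / dz)
  if (w %% 2 == 0) w <- w + 1L
  y <- if ("csa_norm" %in% names(profile)) profile$csa_norm
       else profile$csa_mm2
  n <- length(y)
  if (n < w) stop("profile shorter than the smoothing window")
  half <- (w - 1L) / 2L
  ypad <- c(rev(y[2:(half + 1L)]), y, rev(y[(n - half):(n - 1L)]))
  ys <- as.numeric(stats::filter(ypad, rep(1 / w, w), sides = 2L))
  ys <- ys[(half + 1L):(half + n)]
  profile$csa_smooth <- ys
  best <- max(ys)
  # rostral = superior = larger z: among ties take the largest slice index
  kbest <- max(which(ys >= best - 1e-12))
  attr(profile, "enlargement_slice") <- profile$slice[kbest]
  attr(profile, "enlargement_z_mm") <- profile$z_mm[kbest]
  attr(profile, "smooth_window_slices") <- w
  profile
}

#' Aggregate overlap or CSA results across subjects
#'
#' Means and population SDs per level (for overlap results) or of the
#' enlargement location (for localized CSA profiles), plus the overall
#' summary.
#'
#' @param results non-empty list of [rootlet_overlap()] results or of
#'   localized [csa_profile()]s.
#' @return a data frame summary; for overlap input one row per level plus
#'   an `overall` row (mean/SD of per-subject means), for CSA input a
#'   one-row summary of the enlargement slice.
#' @export
group_aggregate <- function(results) {
  stopifnot(length(results) >= 1L)
  if (inherits(results[[1]], "overlap_result")) {
    levels <- sort(unique(unlist(lapply(results, function(r) r$level))))
    per_level <- do.call(rbind, lapply(levels, function(lv) {
      p <- unlist(lapply(results, function(r) r$percent[r$level == lv]))
      data.frame(level = as.character(lv), n = length(p),
                 mean_percent = mean(p), sd_percent = pop_sd(p))
    }))
    subj_means <- vapply(results, function(r) attr(r, "mean"), numeric(1))
    rbind(per_level,
          data.frame(level = "overall", n = length(subj_means),
                     mean_percent = mean(subj_means),
                     sd_percent = pop_sd(subj_means)))
  } else if (inherits(results[[1]], "csa_profile")) {
    ez <- vapply(results, function(r) {
      v <- attr(r, "enlargement_slice")
      if (is.null(v)) stop("CSA profiles must be localized first")
      as.numeric(v)
    }, numeric(1))
    ezmm <- vapply(results, function(r)
      as.numeric(attr(r, "enlargement_z_mm")), numeric(1))
    data.frame(n = length(ez),
               mean_enlargement_slice = mean(ez),
               sd_enlargement_slice = pop_sd(ez),
               mean_enlargement_z_mm = mean(ezmm),
               sd_enlargement_z_mm = pop_sd(ezmm))
  } else {
    stop("unsupported result type")
  }
}
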