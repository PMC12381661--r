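# Full registration pipeline: (1) per-level centers of mass, (2) cord
# straightening, (3) non-linear level alignment, (4) masked B-spline
# refinement along the rostro-caudal axis, (5) slice-wise warp
# symmetrization, (6) axial cord-size scaling, (7) concatenation into
# forward and backward warps.

run_stage <- function(name, expr, verbose = FALSE) {
  if (verbose) message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

as_template_bundle <- function(template) {
  if (is.character(template) && length(template) == 1L)
    return(read_template_bundle(template))
  if (inherits(template, "sc_phantom"))
    return(list(t2 = template$image, cord = template$cord,
                rootlets = template$rootlets, discs = template$discs))
  stopifnot(is.list(template),
            all(c("t2", "cord", "rootlets") %in% names(template)))
  template
}

#' Register a subject image to the straightened template
#'
#' Runs the seven-step rootlet-based registration: per-level rootlet
#' center-of-mass landmarks, cord straightening onto the template grid,
#' non-linear rostro-caudal alignment of the landmarks, masked B-spline
#' refinement along z (rootlet segmentations dilated by
#' `zreg$dilation` voxels mask both images), slice-wise symmetrization of
#' the refinement field, per-slice axial scaling of the cord to the
#' template cord size, and concatenation of all fields into the forward
#' (subject-to-template) and backward (template-to-subject) warps.
#' With `landmarks = "discs"` the intervertebral-disc point labels drive
#' steps 1 and 3 instead (the traditional baseline); all downstream
#' machinery is identical.
#'
#' @param image subject T2w [sc_volume].
#' @param cord subject binary cord segmentation ([sc_labels], cord-mask).
#' @param rootlets subject level-labeled dorsal-rootlet segmentation
#'   ([sc_labels], labels 2-8 = C2-C8).
#' @param template template bundle: an `sc_phantom`, a list with elements
#'   `t2`, `cord`, `rootlets` (and `discs`), or a directory path holding
#'   `template.nii.gz`, `cord.nii.gz`, `rootlets.nii.gz`, `discs.nii.gz`.
#' @param discs subject disc point labels ([sc_labels]); required when
#'   `landmarks = "discs"`.
#' @param landmarks `"rootlets"` (default) or `"discs"` (baseline).
#' @param no_xy_scaling skip the axial cord-size scaling step (used for
#'   morphometric analyses that must preserve native cord size).
#' @param compute_inverse also build the backward (template-to-subject)
#'   warp (default `TRUE`).
#' @param zreg a [zreg_params()] object for the refinement step.
#' @param straighten_smoothing centerline smoothing-spline penalty.
#' @param verbose print stage progress.
#' @return an object of class `rootlet_registration` with elements
#'   `warp_subject2template`, `warp_template2subject`, `warped_image`,
#'   `warped_cord`, `warped_rootlets`, and `diagnostics` (per-level
#'   residuals in mm, the registration metric trace, the scale profile).
#' @export
register_to_template <- function(image, cord, rootlets, template,
                                 discs = NULL,
                                 landmarks = c("rootlets", "discs"),
                                 no_xy_scaling = FALSE,
                                 compute_inverse = TRUE,
                                 zreg = zreg_params(),
                                 straighten_smoothing = 1e-4,
                                 verbose = FALSE) {
  landmarks <- match.arg(landmarks)
  tpl <- as_template_bundle(template)
  if (!check_same_grid(image, cord) || !check_same_grid(image, rootlets))
    stop("subject image, cord and rootlets must share one grid")
  if (landmarks == "discs" && is.null(discs))
    stop("landmarks = 'discs' requires subject disc labels")
  tgrid <- grid_of(tpl$t2)

  sub_marks <- if (landmarks == "rootlets") rootlets else discs
  tpl_marks <- if (landmarks == "rootlets") tpl$rootlets else tpl$discs
  if (is.null(tpl_marks)) stop("template bundle lacks ", landmarks)

  # (1) per-level centers of mass
  tpl_centers <- run_stage("level_centers",
                           level_centers(tpl_marks), verbose)
  sub_centers <- run_stage("level_centers",
                           level_centers(sub_marks), verbose)

  # (2) straightening onto the template grid
  ctr <- run_stage("centerline",
                   extract_centerline(cord,
                                      smoothing = straighten_smoothing),
                   verbose)
  st <- run_stage("straighten",
                  straighten(image, ctr, target_grid = tgrid,
                             compute_inverse = compute_inverse),
                  verbose)
  w1 <- st$warp_straighten

  # (3) non-linear level alignment; subject landmark centers are carried
  # into straightened space geometrically (exact foot-point transport)
  w2 <- run_stage("level_alignment", {
    q <- straighten_points(ctr,
                           as.matrix(sub_centers[, c("x", "y", "z")]))
    sub_centers_st <- sub_centers
    sub_centers_st$x <- q[, 1]; sub_centers_st$y <- q[, 2]
    sub_centers_st$z <- q[, 3]
    build_level_alignment(sub_centers_st, tpl_centers, tgrid)
  }, verbose)
  w12 <- compose_warps(w2, w1)

  # (4) masked B-spline refinement along the rostro-caudal axis
  zres <- run_stage("register_z", {
    rl_aligned <- apply_warp(rootlets, w12, "nearest")
    sub_mask <- dilate_labels(rl_aligned, zreg$dilation)
    tpl_mask <- dilate_labels(tpl$rootlets, zreg$dilation)
    img_aligned <- apply_warp(image, w12, "linear")
    sub_masked <- sc_volume(img_aligned$data * sub_mask$data,
                            tgrid$affine)
    tpl_masked <- sc_volume(tpl$t2$data * tpl_mask$data, tgrid$affine)
    register_z(sub_masked, tpl_masked, zreg)
  }, verbose)

  # (5) slice-wise symmetrization
  w3 <- run_stage("symmetrize", symmetrize_slicewise(zres), verbose)
  w123 <- compose_warps(w3, w12)

  # (6) axial cord-size scaling
  scale_profile <- NULL
  if (no_xy_scaling) {
    W <- w123
  } else {
    sc <- run_stage("xy_scaling", {
      cord_warped <- apply_warp(cord, w123, "nearest")
      xy_scaling(cord_warped, tpl$cord)
    }, verbose)
    scale_profile <- sc$profile
    W <- compose_warps(sc$field, w123)
  }

  # (7) concatenated outputs
  warped_image <- apply_warp(image, W, "linear")
  warped_cord <- apply_warp(cord, W, "nearest")
  warped_rootlets <- apply_warp(rootlets, W, "nearest")

  Winv <- NULL
  if (compute_inverse) {
    Winv <- run_stage("invert", {
      C <- st$warp_unstraighten
      C <- compose_warps(C, invert_warp(w2))
      C <- compose_warps(C, invert_warp(w3))
      if (!no_xy_scaling) C <- compose_warps(C, invert_warp(sc$field))
      warp_field(C$vectors, C$affine, "backward", "subject")
    }, verbose)
  }

  # diagnostics: per-level residuals of warped rootlet centers vs template
  resid <- tryCatch({
    wc <- level_centers(warped_rootlets)
    tc <- level_centers(tpl$rootlets)
    common <- intersect(wc$level, tc$level)
    data.frame(level = common,
               dz_mm = wc$z[match(common, wc$level)] -
                 tc$z[match(common, tc$level)])
  }, error = function(e) NULL)

  structure(list(
    warp_subject2template = W,
    warp_template2subject = Winv,
    warped_image = warped_image,
    warped_cord = warped_cord,
    warped_rootlets = warped_rootlets,
    template_grid = tgrid,
    landmarks = landmarks,
    no_xy_scaling = no_xy_scaling,
    fields = list(straighten = w1, level_alignment = w2,
                  zreg_symmetrized = w3,
                  xy_scaling = if (no_xy_scaling) NULL else sc$field),
    diagnostics = list(
      level_residuals = resid,
      zreg_trace = attr(zres, "trace"),
      scale_profile = scale_profile,
      template_centers = tpl_centers
    )
  ), class = "rootlet_registration")
}

#' @export
print.rootlet_registration <- function(x, ...) {
  mag <- sqrt(rowSums(matrix(x$warp_subject2template$vectors,
                             ncol = 3L)^2))
  cat(sprintf(
    "<rootlet_registration> landmarks=%s%s\n", x$landmarks,
    if (x$no_xy_scaling) ", xy scaling omitted" else ""))
  cat(sprintf("  forward warp |v|: mean %.3f mm, max %.3f mm\n",
              mean(mag), max(mag)))
  if (!is.null(x$diagnostics$level_residuals)) {
    r <- x$diagnostics$level_residuals
    cat(sprintf("  level residuals (mm): %s\n",
                paste(sprintf("C%d %+0.2f", r$level, r$dz_mm),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.rootlet_registration <- function(object, ...) {
  tr <- object$diagnostics$zreg_trace
  out <- list(
    landmarks = object$landmarks,
    level_residuals = object$diagnostics$level_residuals,
    final_metric = if (!is.null(tr)) tr$metric[nrow(tr)] else NA_real_,
    scale_range = if (!is.null(object$diagnostics$scale_profile))
      range(object$diagnostics$scale_profile$scale) else NULL,
    has_inverse = !is.null(object$warp_template2subject)
  )
  class(out) <- "summary.rootlet_registration"
  out
}

#' @export
print.summary.rootlet_registration <- function(x, ...) {
  cat("Rootlet-based template registration (", x$landmarks,
      " landmarks)\n", sep = "")
  if (!is.null(x$level_residuals)) {
    cat("Per-level rostro-caudal residuals (mm):\n")
    print(x$level_residuals, row.names = FALSE, digits = 3)
  }
  cat(sprintf("Final similarity metric: %.4f\n", x$final_metric))
  if (!is.null(x$scale_range))
    cat(sprintf("Axial scale factors in [%.3f, %.3f]\n",
                x$scale_range[1], x$scale_range[2]))
  cat("Backward warp available:", x$has_inverse, "\n")
  invisible(x)
}

#' @export
plot.rootlet_registration <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  r <- x$diagnostics$level_residuals
  if (!is.null(r)) {
    plot(r$level, r$dz_mm, type = "h", lwd = 3,
         xlab = "level code", ylab = "z residual (mm)",
         main = "Level residuals", ...)
    abline(h = 0, lty = 3)
  }
  tr <- x$diagnostics$zreg_trace
  if (!is.null(tr)) {
    plot(seq_len(nrow(tr)), tr$metric, type = "b", pch = 16, cex = 0.6,
         xlab = "accepted step", ylab = "similarity",
         main = "z-registration trace")
  }
  invisible(x)
}

#' Read a template bundle directory
#'
#' Expects `template.nii.gz`, `cord.nii.gz`, `rootlets.nii.gz` and
#' optionally `discs.nii.gz` (a `manifest.json` is read when present).
#'
#' @param dir directory path.
#' @return list with `t2`, `cord`, `rootlets`, `discs`.
#' @export
read_template_bundle <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("template bundle missing ", f)
    p
  }
  out <- list(
    t2 = read_volume(need("template.nii.gz")),
    cord = read_volume(need("cord.nii.gz"), labels = TRUE,
                       semantics = "cord-mask"),
    rootlets = read_volume(need("rootlets.nii.gz"), labels = TRUE,
                           semantics = "rootlets")
  )
  pd <- file.path(dir, "discs.nii.gz")
  if (file.exists(pd))
    out$discs <- read_volume(pd, labels = TRUE, semantics = "disc-points")
  out
}

#' Write a template bundle directory
#' @param bundle list with `t2`, `cord`, `rootlets` and optionally `discs`
#'   (an `sc_phantom` is accepted).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_template_bundle <- function(bundle, dir) {
  bundle <- as_template_bundle(bundle)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(bundle$t2, file.path(dir, "template.nii.gz"))
  write_volume(bundle$cord, file.path(dir, "cord.nii.gz"))
  write_volume(bundle$rootlets, file.path(dir, "rootlets.nii.gz"))
  if (!is.null(bundle$discs))
    write_volume(bundle$discs, file.path(dir, "discs.nii.gz"))
  jsonlite::write_json(
    list(files = list(t2 = "template.nii.gz", cord = "cord.nii.gz",
                      rootlets = "rootlets.nii.gz",
                      discs = "discs.nii.gz"),
         orientation = "canonical (L-R, P-A, I-S)", units = "mm"),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
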