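# Synthetic cervical spinal-cord phantom with known ground truth.
#
# The phantom emulates the inputs of the registration pipeline at the
# acquisition conditions of a typical cervical T2w protocol (0.8 mm
# isotropic images covering the cervical spine): a cord modeled as a tube
# along a smooth centerline with a Gaussian cervical-enlargement bulge,
# paired dorsal rootlet blobs per level (labels 2-8 = C2-C8), single-voxel
# intervertebral-disc point labels, and a T2w-like intensity image
# (bright CSF, intermediate cord, hypointense rootlets) with smoothing and
# seeded Gaussian noise. Curvature modes emulate neck positions: neutral
# is straight, flexion/extension bow the cord with opposite signs.

#' Specification of a synthetic cervical-cord phantom
#'
#' Defaults describe a neutral-position cervical acquisition: 0.8 mm
#' isotropic grid covering ~154 mm of cervical spine, a 4 mm cord radius
#' with a 1 mm Gaussian enlargement bulge centered between the C5 and C6
#' spinal levels, rootlet levels C2-C8 at anatomically spaced z positions,
#' and disc points offset caudally from the corresponding spinal levels.
#'
#' @param shape grid dimensions (default `c(48, 48, 192)`).
#' @param resolution isotropic voxel size in mm (default 0.8).
#' @param cord_radius baseline cord radius in mm (default 4).
#' @param enlargement_z center of the cervical enlargement in mm
#'   (default 75, between the C5 and C6 levels).
#' @param enlargement_amplitude bulge amplitude in mm added to the radius
#'   (default 1).
#' @param enlargement_width Gaussian sigma of the bulge in mm (default 10).
#' @param rootlet_z named numeric vector of per-level rootlet z positions
#'   (mm), strictly decreasing from C2 to C8.
#' @param rootlet_blob_radius in-plane radius of each rootlet blob in mm
#'   (default 1.6).
#' @param rootlet_blob_halflength half-extent of each blob along z in mm
#'   (default 3).
#' @param disc_z named numeric vector of disc-point z positions (mm),
#'   labels 3-8 (host convention: label 3 = C2-C3 disc), strictly
#'   decreasing.
#' @param curvature `"neutral"`, `"flexion"` or `"extension"`.
#' @param curvature_amplitude sagittal bow amplitude in mm (default 8).
#' @param cord_z_range z extent of the cord in mm (default `c(10, 145)`).
#' @param intensities named vector of tissue intensities
#'   (background/csf/cord/rootlet).
#' @param canal_margin CSF canal margin beyond the cord radius in mm
#'   (default 3).
#' @param smooth_sigma Gaussian smoothing of the intensity image in mm
#'   (default 0.8).
#' @param noise_sd Gaussian noise SD in intensity units (default 2).
#' @param seed RNG seed for the noise (default 1).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 192L),
                         resolution = 0.8,
                         cord_radius = 4,
                         enlargement_z = 75,
                         enlargement_amplitude = 1,
                         enlargement_width = 10,
                         rootlet_z = c(`2` = 132, `3` = 117, `4` = 102,
                                       `5` = 88, `6` = 74, `7` = 60,
                                       `8` = 47),
                         rootlet_blob_radius = 1.6,
                         rootlet_blob_halflength = 3,
                         disc_z = c(`3` = 125, `4` = 110, `5` = 95,
                                    `6` = 81, `7` = 67, `8` = 53),
                         curvature = c("neutral", "flexion", "extension"),
                         curvature_amplitude = 8,
                         cord_z_range = c(10, 145),
                         intensities = c(background = 10, csf = 90,
                                         cord = 50, rootlet = 30),
                         canal_margin = 3,
                         smooth_sigma = 0.8,
                         noise_sd = 2,
                         seed = 1L) {
  curvature <- match.arg(curvature)
  stopifnot(resolution > 0, cord_radius > 0, enlargement_width > 0,
            rootlet_blob_radius > 0, rootlet_blob_halflength > 0,
            all(diff(rootlet_z) < 0), all(diff(disc_z) < 0))
  spec <- list(shape = as.integer(shape), resolution = resolution,
               cord_radius = cord_radius,
               enlargement_z = enlargement_z,
               enlargement_amplitude = enlargement_amplitude,
               enlargement_width = enlargement_width,
               rootlet_z = rootlet_z,
               rootlet_blob_radius = rootlet_blob_radius,
               rootlet_blob_halflength = rootlet_blob_halflength,
               disc_z = disc_z,
               curvature = curvature,
               curvature_amplitude = curvature_amplitude,
               cord_z_range = cord_z_range,
               intensities = intensities,
               canal_margin = canal_margin,
               smooth_sigma = smooth_sigma,
               noise_sd = noise_sd,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

phantom_affine <- function(spec) {
  r <- spec$resolution
  aff <- diag(c(r, r, r, 1))
  aff[1, 4] <- -(spec$shape[1] - 1) / 2 * r
  aff[2, 4] <- -(spec$shape[2] - 1) / 2 * r
  aff[3, 4] <- 0
  aff
}

# sagittal centerline of the phantom cord: x = 0 always; y bows in the
# anterior-posterior plane for flexion/extension
phantom_centerline_y <- function(spec, z) {
  if (spec$curvature == "neutral") return(rep(0, length(z)))
  zr <- spec$cord_z_range
  amp <- spec$curvature_amplitude *
    switch(spec$curvature, flexion = 1, extension = -1)
  u <- (pmin(pmax(z, zr[1]), zr[2]) - zr[1]) / (zr[2] - zr[1])
  amp * sin(pi * u)^2
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# separable Gaussian smoothing of a 3D array (voxel units)
gauss_smooth3 <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma_vox))
  kern <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  kern <- kern / sum(kern)
  d <- dim(arr)
  for (ax in 1:3) {
    out <- array(0, d)
    for (o in seq(-r, r)) {
      w <- kern[o + r + 1]
      src <- pmin(pmax(seq_len(d[ax]) + o, 1L), d[ax])
      out <- out + w * switch(ax,
        arr[src, , , drop = FALSE],
        arr[, src, , drop = FALSE],
        arr[, , src, drop = FALSE])
    }
    arr <- out
  }
  arr
}

#' Generate a synthetic cervical-cord phantom
#'
#' Builds the full input set of the registration pipeline with known
#' ground truth: T2w-like image, binary cord mask, level-labeled rootlet
#' blobs (2-8), disc point labels, and a truth record holding every
#' ground-truth coordinate in world mm.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `sc_phantom`: list with elements `image`
#'   ([sc_volume]), `cord`, `rootlets`, `discs` ([sc_labels]) and `truth`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  lz <- spec$rootlet_z
  if (any(abs(diff(lz)) < 2 * spec$rootlet_blob_halflength))
    stop("rootlet blobs overlapping between adjacent levels; ",
         "spec too dense")
  aff <- phantom_affine(spec)
  d <- spec$shape
  g <- grid_spec(d, aff)

  # world coordinates of the whole grid, organized per slice
  xs <- aff[1, 1] * (seq_len(d[1]) - 1) + aff[1, 4]
  ys <- aff[2, 2] * (seq_len(d[2]) - 1) + aff[2, 4]
  zs <- slice_z_world(g)
  X <- matrix(rep(xs, d[2]), d[1], d[2])
  Y <- matrix(rep(ys, each = d[1]), d[1], d[2])

  radius_at <- function(z) {
    spec$cord_radius + spec$enlargement_amplitude *
      exp(-(z - spec$enlargement_z)^2 / (2 * spec$enlargement_width^2))
  }

  cord <- array(0L, d)
  canal <- array(FALSE, d)
  zr <- spec$cord_z_range
  yc_all <- phantom_centerline_y(spec, zs)
  for (k in seq_len(d[3])) {
    z <- zs[k]
    if (z < zr[1] || z > zr[2]) next
    rc <- radius_at(z)
    r2 <- (X - 0)^2 + (Y - yc_all[k])^2
    cord[, , k] <- as.integer(r2 <= rc^2)
    canal[, , k] <- r2 <= (rc + spec$canal_margin)^2
  }

  rootlets <- array(0L, d)
  rb <- spec$rootlet_blob_radius
  hl <- spec$rootlet_blob_halflength
  for (code in names(lz)) {
    zl <- lz[[code]]
    kset <- which(abs(zs - zl) <= hl)
    rcl <- radius_at(zl)
    ycl <- phantom_centerline_y(spec, zl)
    for (k in kset) {
      fz <- 1 - ((zs[k] - zl) / hl)^2
      if (fz <= 0) next
      rk <- rb * sqrt(fz)
      for (sgn in c(-1, 1)) {
        cx <- sgn * (spec$cord_radius * 0.8)
        cy <- ycl - (rcl + 2)
        hit <- (X - cx)^2 + (Y - cy)^2 <= rk^2
        sl <- rootlets[, , k]
        sl[hit] <- as.integer(code)
        rootlets[, , k] <- sl
      }
    }
  }

  discs <- array(0L, d)
  disc_xyz <- list()
  for (code in names(spec$disc_z)) {
    zd <- spec$disc_z[[code]]
    yd <- phantom_centerline_y(spec, zd) -
      (spec$cord_radius + spec$canal_margin + 3)
    ijk <- round(world_to_vox(aff, c(0, yd, zd)))
    ijk <- pmin(pmax(ijk, 0), d - 1)
    discs[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1] <- as.integer(code)
    disc_xyz[[code]] <- as.numeric(vox_to_world(aff, ijk))
  }

  ints <- spec$intensities
  img <- array(ints[["background"]], d)
  img[canal] <- ints[["csf"]]
  img[cord == 1L] <- ints[["cord"]]
  img[rootlets != 0L] <- ints[["rootlet"]]
  img <- gauss_smooth3(img, spec$smooth_sigma / spec$resolution)
  if (spec$noise_sd > 0) {
    img <- img + with_seed(spec$seed,
                           array(rnorm(prod(d), 0, spec$noise_sd), d))
  }

  truth <- list(
    rootlet_z = lz,
    disc_z = spec$disc_z,
    disc_xyz = disc_xyz,
    enlargement_z = spec$enlargement_z,
    cord_z_range = zr,
    centerline = data.frame(z = zs, x = 0, y = yc_all),
    radius = data.frame(z = zs, r = radius_at(zs)),
    spec = spec
  )
  structure(list(
    image = sc_volume(img, aff),
    cord = sc_labels(cord, aff, "cord-mask"),
    rootlets = sc_labels(rootlets, aff, "rootlets"),
    discs = sc_labels(discs, aff, "disc-points"),
    truth = truth
  ), class = "sc_phantom")
}

#' @export
print.sc_phantom <- function(x, ...) {
  s <- x$truth$spec
  cat(sprintf(
    "<sc_phantom> %s, %d levels, grid %s @ %.2g mm, seed %d\n",
    s$curvature, length(s$rootlet_z),
    paste(s$shape, collapse = "x"), s$resolution, s$seed))
  invisible(x)
}

#' Template bundle from a phantom specification
#'
#' The template of the synthetic study: a straight (neutral), noise-free
#' phantom playing the role of the straightened population template, with
#' the image, cord mask, rootlet levels and disc labels of a template
#' bundle.
#'
#' @param spec a [phantom_spec()]; curvature and noise are overridden to
#'   neutral/0.
#' @return an `sc_phantom` (fields `image`, `cord`, `rootlets`, `discs`,
#'   `truth`).
#' @export
phantom_template <- function(spec = phantom_spec()) {
  spec$curvature <- "neutral"
  spec$noise_sd <- 0
  generate_phantom(spec)
}

#' Seeded synthetic cohort with rootlet-disc decoupling
#'
#' One template phantom plus `n` subjects whose rootlet z positions are the
#' template positions plus seeded Gaussian jitter whose SD grows linearly
#' from x1 at C2 to x2 at C8 (spinal-vs-vertebral discrepancies grow
#' caudally), and whose disc positions carry an additional per-subject
#' constant offset (SD `rootlet_disc_offset_sd`) decoupling vertebral
#' landmarks from spinal levels. Each subject's cervical enlargement moves
#' with its C5/C6 levels. Jitter draws producing non-monotone levels are
#' resampled up to 10 times, then error.
#'
#' @param n number of subjects (>= 1).
#' @param template_spec [phantom_spec()] of the template (and base of all
#'   subjects).
#' @param level_jitter_sd rootlet-level jitter SD in mm at C2 (default 2).
#' @param rootlet_disc_offset_sd SD in mm of the per-subject disc offset
#'   (default 4).
#' @param seed RNG seed.
#' @return list with `template` (an `sc_phantom`) and `subjects` (list of
#'   `sc_phantom`s, each with `truth$jitter` and `truth$disc_offset`).
#' @export
generate_cohort <- function(n, template_spec = phantom_spec(),
                            level_jitter_sd = 2,
                            rootlet_disc_offset_sd = 4,
                            seed = 1L) {
  stopifnot(n >= 1L)
  template <- phantom_template(template_spec)
  nlev <- length(template_spec$rootlet_z)
  scale <- seq(1, 2, length.out = nlev)    # caudal levels jitter more
  subjects <- with_seed(seed, lapply(seq_len(n), function(i) {
    hl <- template_spec$rootlet_blob_halflength
    for (try in 1:10) {
      jit <- rnorm(nlev, 0, level_jitter_sd) * scale
      rz <- template_spec$rootlet_z + jit
      # valid draws keep levels ordered with non-touching rootlet blobs
      if (all(diff(rz) <= -2 * hl)) break
      jit <- NULL
    }
    if (is.null(jit))
      stop("jitter produced non-monotone levels 10 times; reduce SD")
    b <- rnorm(1, 0, rootlet_disc_offset_sd)
    sp <- template_spec
    sp$rootlet_z <- template_spec$rootlet_z + jit
    sp$disc_z <- template_spec$disc_z + b
    # the enlargement sits at spinal levels C5-C6 and moves with them
    i56 <- match(c("5", "6"), names(template_spec$rootlet_z))
    sp$enlargement_z <- template_spec$enlargement_z + mean(jit[i56])
    sp$seed <- template_spec$seed + i
    ph <- generate_phantom(sp)
    ph$truth$jitter <- jit
    ph$truth$disc_offset <- b
    ph
  }))
  list(template = template, subjects = subjects)
}

#' Neck-position phantom set for one synthetic subject
#'
#' Three phantoms of the same subject in flexion, neutral and extension.
#' Curvature bows the cord with opposite signs, and the cord (with its
#' rootlet levels and enlargement) slides along the canal by `slide_mm`
#' rostrally in flexion and caudally in extension while the vertebral disc
#' positions stay fixed — emulating the neck-position dependence of the
#' spinal-vs-vertebral level correspondence.
#'
#' @param spec base [phantom_spec()] (neutral).
#' @param slide_mm cord slide per position in mm (default 3).
#' @return named list of three `sc_phantom`s
#'   (`flexion`, `neutral`, `extension`).
#' @export
neck_position_set <- function(spec = phantom_spec(), slide_mm = 3) {
  positions <- c(flexion = 1, neutral = 0, extension = -1)
  out <- lapply(names(positions), function(pos) {
    sp <- spec
    sp$curvature <- pos
    shift <- positions[[pos]] * slide_mm
    sp$rootlet_z <- spec$rootlet_z + shift
    sp$enlargement_z <- spec$enlargement_z + shift
    sp$seed <- spec$seed + match(pos, names(positions))
    ph <- generate_phantom(sp)
    ph$truth$slide <- shift
    ph
  })
  names(out) <- names(positions)
  out
}
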