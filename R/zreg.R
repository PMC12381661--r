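# Masked non-linear refinement along the rostro-caudal axis.
#
# The transform is a single 1D cubic B-spline displacement profile dz(z)
# shared across the axial plane (the subsequent slice-wise symmetrization
# collapses any in-plane variation anyway), optimized greedily with a
# monotone backtracking line search against a similarity metric evaluated
# over the non-zero (rootlet-masked) region.

#' Parameters of the rostro-caudal B-spline registration
#'
#' @param spacing_mm control-point spacing along z in mm (default 10).
#' @param pyramid integer shrink factors along z, coarse to fine
#'   (default `c(4, 2, 1)`).
#' @param metric `"ncc"` (normalized cross-correlation, default) or
#'   `"msq"` (negative mean squares).
#' @param iterations maximum accepted optimizer steps per pyramid level
#'   (default 50).
#' @param step_mm initial line-search step in mm (default 1).
#' @param tol convergence tolerance on the metric gain (default 1e-6).
#' @param cap_mm hard bound on |dz| in mm (default 10).
#' @param dilation mask dilation radius in voxels used by the pipeline
#'   (default 3).
#' @return an object of class `zreg_params`.
#' @export
zreg_params <- function(spacing_mm = 10, pyramid = c(4L, 2L, 1L),
                        metric = c("ncc", "msq"), iterations = 50L,
                        step_mm = 1, tol = 1e-6, cap_mm = 10,
                        dilation = 3L) {
  metric <- match.arg(metric)
  stopifnot(spacing_mm > 0, iterations >= 1L, dilation >= 0L,
            all(pyramid >= 1L), step_mm > 0, cap_mm > 0)
  structure(list(spacing_mm = spacing_mm, pyramid = as.integer(pyramid),
                 metric = metric, iterations = as.integer(iterations),
                 step_mm = step_mm, tol = tol, cap_mm = cap_mm,
                 dilation = as.integer(dilation)),
            class = "zreg_params")
}

#' Binary dilation of the union of all labels
#'
#' Binarizes the non-zero labels and applies `radius` iterations of a
#' 6-connected structuring element, so a single voxel grows into the
#' L1-ball of the given radius.
#'
#' @param labels an [sc_labels].
#' @param radius non-negative integer dilation radius (voxels).
#' @return an [sc_labels] cord-mask-style binary volume (0/1).
#' @export
dilate_labels <- function(labels, radius) {
  stopifnot(inherits(labels, "sc_labels"), radius >= 0)
  b <- labels$data != 0
  d <- dim(b)
  for (r in seq_len(radius)) {
    nb <- b
    nb[-1, , ] <- nb[-1, , ] | b[-d[1], , ]
    nb[-d[1], , ] <- nb[-d[1], , ] | b[-1, , ]
    nb[, -1, ] <- nb[, -1, ] | b[, -d[2], ]
    nb[, -d[2], ] <- nb[, -d[2], ] | b[, -1, ]
    nb[, , -1] <- nb[, , -1] | b[, , -d[3]]
    nb[, , -d[3]] <- nb[, , -d[3]] | b[, , -1]
    b <- nb
  }
  sc_labels(array(as.integer(b), d), labels$affine, "cord-mask")
}

# cubic B-spline basis value for scaled distance u = (z - knot)/h
bspline3 <- function(u) {
  au <- abs(u)
  ifelse(au < 1, 2 / 3 - au^2 + au^3 / 2,
         ifelse(au < 2, (2 - au)^3 / 6, 0))
}

# design matrix: rows = z positions, cols = control points
bspline_design <- function(z, knots, h) {
  outer(z, knots, function(zz, kk) bspline3((zz - kk) / h))
}

ncc_metric <- function(f, m) {
  fd <- f - mean(f); md <- m - mean(m)
  den <- sqrt(sum(fd^2) * sum(md^2))
  if (den < 1e-12) return(0)
  sum(fd * md) / den
}

#' Masked B-spline registration along the rostro-caudal axis
#'
#' Estimates a smooth z-only displacement profile `dz(z)` (cubic B-spline,
#' shared across the axial plane) that maximizes the similarity between the
#' masked template image and the masked subject image sampled at
#' `z + dz(z)`, using a multi-resolution pyramid along z and a greedy
#' gradient ascent with a monotone backtracking line search. The output
#' field has exactly zero x and y components, and |dz| is capped at
#' `params$cap_mm`.
#'
#' @param subject_masked subject image on the template grid, already
#'   straightened and level-aligned, zero outside the rootlet mask
#'   ([sc_volume]).
#' @param template_masked template image masked the same way ([sc_volume]).
#' @param params a [zreg_params()] object.
#' @return a z-only [warp_field] on the template grid (forward direction)
#'   with attribute `"trace"`: a data frame of accepted metric values per
#'   pyramid level.
#' @export
register_z <- function(subject_masked, template_masked,
                       params = zreg_params()) {
  if (!check_same_grid(subject_masked, template_masked))
    stop("subject and template must share the template grid")
  g <- grid_of(template_masked)
  vs <- voxel_size(g$affine)
  if (params$spacing_mm <= vs[3])
    stop("control-point spacing must exceed the voxel size")

  tmpl <- template_masked$data
  subj <- subject_masked$data
  mask_idx <- which(tmpl != 0, arr.ind = TRUE)
  if (nrow(mask_idx) == 0L) stop("empty template mask")
  if (all(subj == 0)) stop("empty mask overlap")

  Z <- slice_z_world(g)
  kz <- range(mask_idx[, 3])
  zr <- Z[kz] + c(-2, 2) * params$spacing_mm
  knots <- seq(zr[1], zr[2], by = params$spacing_mm)
  ncoef <- length(knots)
  coef <- rep(0, ncoef)

  trace <- list()
  for (shrink in sort(params$pyramid, decreasing = TRUE)) {
    lev <- pyramid_level(subj, tmpl, shrink)
    midx <- which(lev$tmpl != 0, arr.ind = TRUE)
    if (nrow(midx) == 0L) next
    fvals <- lev$tmpl[midx]
    zslice <- Z[lev$kmap]                     # world z of each level slice
    B <- bspline_design(zslice, knots, params$spacing_mm)

    lev_dz_mm <- vs[3] * shrink               # slice spacing at this level
    moving_at <- function(coef) {
      dz <- as.numeric(B %*% coef)
      dz <- pmin(pmax(dz, -params$cap_mm), params$cap_mm)
      kf <- midx[, 3] + dz[midx[, 3]] / lev_dz_mm
      interp_columns(lev$subj, midx, kf)
    }
    objective <- function(coef) {
      m <- moving_at(coef)
      if (params$metric == "ncc") ncc_metric(fvals, m)
      else -mean((fvals - m)^2)
    }

    cur <- objective(coef)
    if (!is.finite(cur)) stop("non-finite similarity metric")
    step <- params$step_mm
    accepted <- cur
    eps <- 0.05
    for (it in seq_len(params$iterations)) {
      grad <- vapply(seq_len(ncoef), function(j) {
        cp <- coef; cp[j] <- cp[j] + eps
        cm <- coef; cm[j] <- cm[j] - eps
        (objective(cp) - objective(cm)) / (2 * eps)
      }, numeric(1))
      gn <- sqrt(sum(grad^2))
      if (gn < 1e-10) break
      dir <- grad / gn
      improved <- FALSE
      st <- step
      for (ls in 1:8) {                       # monotone backtracking search
        cand <- pmin(pmax(coef + st * dir, -params$cap_mm), params$cap_mm)
        val <- objective(cand)
        if (is.finite(val) && val > cur) {
          coef <- cand; cur <- val; improved <- TRUE
          step <- st * 1.5
          break
        }
        st <- st / 2
      }
      accepted <- c(accepted, cur)
      if (!improved) break
      if (length(accepted) > 1 &&
          diff(utils::tail(accepted, 2)) < params$tol) break
    }
    trace[[length(trace) + 1L]] <-
      data.frame(shrink = shrink, iter = seq_along(accepted) - 1L,
                 metric = accepted)
  }

  dz_full <- as.numeric(bspline_design(Z, knots, params$spacing_mm) %*% coef)
  dz_full <- pmin(pmax(dz_full, -params$cap_mm), params$cap_mm)
  v <- array(0, c(g$shape, 3L))
  v[, , , 3] <- rep(dz_full, each = g$shape[1] * g$shape[2])
  out <- warp_field(v, g$affine, "forward", "template")
  attr(out, "trace") <- do.call(rbind, trace)
  attr(out, "coefficients") <- coef
  out
}

# shrink both arrays along z (Gaussian smoothing + subsampling); kmap maps
# level slices back to full-resolution slice indices
pyramid_level <- function(subj, tmpl, shrink) {
  d <- dim(tmpl)
  if (shrink == 1L) {
    return(list(subj = subj, tmpl = tmpl, kmap = seq_len(d[3]),
                shrink = 1L))
  }
  sm_s <- smooth_z(subj, sigma = shrink / 2)
  sm_t <- smooth_z(tmpl, sigma = shrink / 2)
  keep <- seq(1L, d[3], by = shrink)
  list(subj = sm_s[, , keep, drop = FALSE],
       tmpl = sm_t[, , keep, drop = FALSE],
       kmap = keep, shrink = shrink)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian smoothing along the 3rd array dimension
smooth_z <- function(arr, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  kx <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  kx <- kx / sum(kx)
  d <- dim(arr)
  out <- array(0, d)
  for (o in seq(-r, r)) {
    w <- kx[o + r + 1]
    src <- pmin(pmax(seq_len(d[3]) + o, 1L), d[3])
    out <- out + arr[, , src, drop = FALSE] * w
  }
  out
}

# linear interpolation of arr along z at fractional slice index kf for the
# in-plane positions given by idx (1-based rows i,j); out-of-range -> 0
interp_columns <- function(arr, idx, kf) {
  d <- dim(arr)
  out <- numeric(length(kf))
  inside <- kf >= 1 & kf <= d[3]
  if (!any(inside)) return(out)
  kfi <- kf[inside]
  k0 <- pmin(floor(kfi), d[3] - 1)
  w <- kfi - k0
  i <- idx[inside, 1]; j <- idx[inside, 2]
  out[inside] <- arr[cbind(i, j, k0)] * (1 - w) +
    arr[cbind(i, j, k0 + 1)] * w
  out
}
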