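# NIfTI reading/writing and canonical orientation.
#
# Internal canonical orientation after load: axis 1 = left-to-right,
# axis 2 = posterior-to-anterior, axis 3 = inferior-to-superior (RAS+),
# so the rostro-caudal axis is always the array's third dimension.

# Determine the permutation/flip bringing an affine to approximately
# diagonal-positive (RAS). Returns list(perm, flip) where perm[w] is the
# voxel axis dominant along world axis w and flip[w] says that axis runs
# in the negative world direction.
orientation_plan <- function(affine) {
  M <- affine[1:3, 1:3]
  C <- abs(sweep(M, 2L, sqrt(colSums(M^2)), "/"))
  perm <- integer(3)
  flip <- logical(3)
  for (step in 1:3) {
    best <- which(C == max(C), arr.ind = TRUE)[1, ]
    w <- best[1]; v <- best[2]
    perm[w] <- v
    flip[w] <- M[w, v] < 0
    C[w, ] <- -Inf
    C[, v] <- -Inf
  }
  list(perm = perm, flip = flip)
}

# Apply an orientation plan to (data, affine); preserves world coordinates.
apply_orientation <- function(data, affine, plan) {
  d <- dim(data)
  data <- aperm(data, plan$perm)
  # new affine: columns permuted, then flips re-anchor the origin
  A <- affine
  A[1:3, 1:3] <- affine[1:3, plan$perm]
  newd <- d[plan$perm]
  idx <- lapply(seq_len(3L), function(w) {
    if (plan$flip[w]) rev(seq_len(newd[w])) else seq_len(newd[w])
  })
  data <- data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  for (w in 1:3) {
    if (plan$flip[w]) {
      A[1:3, 4] <- A[1:3, 4] + A[1:3, w] * (newd[w] - 1)
      A[1:3, w] <- -A[1:3, w]
    }
  }
  list(data = data, affine = A)
}

reorient_canonical <- function(data, affine) {
  plan <- orientation_plan(affine)
  out <- apply_orientation(data, affine, plan)
  out$plan <- plan
  out
}

#' Read a 3D NIfTI volume in canonical orientation
#'
#' Loads a NIfTI-1 file (optionally gzipped) and reorients it so that array
#' axes run left-to-right, posterior-to-anterior and inferior-to-superior.
#' The original on-disk orientation string is recorded in attribute
#' `"orig_orientation"` for round-tripping.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param labels if `TRUE`, return an [sc_labels] volume with the given
#'   `semantics`; otherwise an [sc_volume].
#' @param semantics label semantics, see [sc_labels].
#' @return an [sc_volume] or [sc_labels].
#' @export
read_volume <- function(path, labels = FALSE, semantics = "rootlets") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected 3D volume, got ", length(d), "D")
  affine <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  affine <- matrix(as.numeric(affine), 4L, 4L)
  check_affine(affine)
  orig <- RNifti::orientation(img)
  arr <- array(as.numeric(img), dim = d)
  can <- reorient_canonical(arr, affine)
  out <- if (labels) {
    sc_labels(array(as.integer(round(can$data)), dim(can$data)),
              can$affine, semantics)
  } else {
    sc_volume(can$data, can$affine)
  }
  attr(out, "orig_orientation") <- orig
  out
}

nifti_with_affine <- function(arr, affine, datatype) {
  img <- RNifti::asNifti(arr, datatype = datatype)
  aff <- structure(affine, code = 2L)
  RNifti::`sform<-`(img, aff)
}

#' Write a volume or label volume to NIfTI
#'
#' Scalar volumes are stored as float64 so read/write round-trips are
#' bit-exact; label volumes as int16.
#'
#' @param x an [sc_volume] or [sc_labels].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, c("sc_volume", "sc_labels")))
  datatype <- if (inherits(x, "sc_labels")) "int16" else "double"
  img <- nifti_with_affine(x$data, x$affine, datatype)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a displacement field to NIfTI with a JSON sidecar
#'
#' The field is stored as a 4D NIfTI (4th dimension = x/y/z world-mm
#' components, float64) plus a small JSON sidecar recording `direction`
#' (`forward`/`backward`), `reference` (`template`/`subject`) and `units`
#' (`mm`). [read_displacement_field()] inverts it bit-exactly.
#'
#' @param field a [warp_field].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_displacement_field <- function(field, path) {
  stopifnot(inherits(field, "warp_field"))
  img <- nifti_with_affine(field$vectors, field$affine, "double")
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(
    list(direction = field$direction, reference = field$reference,
         units = "mm"),
    sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a displacement field written by [write_displacement_field()]
#' @param path path to the 4D NIfTI; the sidecar is looked up next to it.
#' @return a [warp_field].
#' @export
read_displacement_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing displacement sidecar: ", sc)
  meta <- jsonlite::read_json(sc)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4L] != 3L)
    stop("expected a 4D displacement NIfTI with 3 components")
  affine <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  warp_field(array(as.numeric(img), dim = d), affine,
             direction = meta$direction, reference = meta$reference)
}
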