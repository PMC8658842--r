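#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation (3x3 orthonormal matrix with
#' determinant +1) followed by a translation, mapping coordinates of one
#' pharmacophore frame onto another. No scaling and no reflection is ever
#' allowed: pharmacophore alignment must preserve chirality and all internal
#' distances.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation numeric length-3 translation vector (Angstrom).
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' tr <- rigid_transform(diag(3), c(1, 2, 3))
#' transform_points(tr, matrix(0, 1, 3))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation matrix is not orthonormal (R'R != I within 1e-9)")
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation matrix is not a proper rotation (det != +1): reflections are not rigid transforms")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param x object to test.
#' @export
is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Apply a rigid transform to 3D points
#'
#' @param transform a [rigid_transform()].
#' @param points n x 3 numeric matrix (or length-3 vector) of coordinates.
#' @return n x 3 matrix of transformed coordinates.
#' @export
transform_points <- function(transform, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  if (nrow(points) == 0L) return(points)
  sweep(points %*% t(transform$rotation), 2L, transform$translation, "+")
}

#' Compose two rigid transforms
#'
#' `compose_transforms(f, g)` returns the transform equivalent to applying
#' `g` first and `f` second (function composition `f o g`).
#'
#' @param f,g [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
compose_transforms <- function(f, g) {
  rigid_transform(f$rotation %*% g$rotation,
                  as.numeric(f$rotation %*% g$translation) + f$translation)
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  rinv <- t(transform$rotation)
  rigid_transform(rinv, as.numeric(-rinv %*% transform$translation))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (rotation + translation)\n")
  cat("  translation:", sprintf("%.4f", x$translation), "\n")
  print(round(x$rotation, 6))
  invisible(x)
}

# Shift a transform by a pure translation delta (applied after the transform).
shift_transform <- function(transform, delta) {
  rigid_transform(transform$rotation, transform$translation + as.numeric(delta))
}
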