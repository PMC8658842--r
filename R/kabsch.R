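#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Computes the proper rotation and translation minimizing the RMSD of the
#' points `pointsB` superposed onto `pointsA`, via SVD of the centred
#' cross-covariance matrix. A reflection in the raw SVD solution is
#' corrected by flipping the sign of the smallest singular direction, so
#' the returned rotation always has determinant +1.
#'
#' @param pointsA,pointsB n x 3 matrices of paired coordinates (row k of B
#'   corresponds to row k of A); n >= 3.
#' @param check if `TRUE` (default), raise an error for underdetermined
#'   (n < 3) or geometrically degenerate (collinear/coincident) point sets,
#'   for which the rotation is not unique. With `check = FALSE` only n < 3
#'   errors; degenerate inputs return the (non-unique) SVD solution, which
#'   is still RMSD-optimal.
#' @return a [rigid_transform()] `t` such that `transform_points(t, pointsB)`
#'   best superposes onto `pointsA`.
#' @examples
#' A <- matrix(rnorm(15), 5, 3)
#' tr <- kabsch(A, A)
#' max(abs(tr$rotation - diag(3)))
#' @export
kabsch <- function(pointsA, pointsB, check = TRUE) {
  pointsA <- as.matrix(pointsA); pointsB <- as.matrix(pointsB)
  n <- nrow(pointsA)
  if (n != nrow(pointsB)) stop("point sets must have equal size")
  if (n < 3L) {
    stop(g3ps_error("g3ps_underdetermined_error",
                    "at least 3 point pairs are required for an unambiguous rigid superposition"))
  }
  ca <- colMeans(pointsA); cb <- colMeans(pointsB)
  Ac <- sweep(pointsA, 2L, ca); Bc <- sweep(pointsB, 2L, cb)
  if (check) {
    # collinear or coincident points leave a rotation about an axis free
    for (M in list(Ac, Bc)) {
      s <- svd(M, nu = 0, nv = 0)$d
      if (s[2L] <= 1e-7 * max(s[1L], 1)) {
        stop_degenerate("point set is (nearly) collinear or coincident: rotation is not uniquely determined")
      }
    }
  }
  H <- crossprod(Bc, Ac)                      # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ca - as.numeric(R %*% cb))
}
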