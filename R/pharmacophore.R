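#' Construct a pharmacophore model
#'
#' A pharmacophore is an ordered collection of labelled 3D feature points.
#' Each feature carries a type code (by convention `H` hydrophobic, `AR`
#' aromatic, `HBA`/`HBD` hydrogen-bond acceptor/donor, `PI`/`NI`
#' positive/negative ionizable; arbitrary custom codes are allowed), a
#' positional tolerance radius in Angstrom bounding how far the centre of a
#' matching feature may lie, and optionally a unit direction vector.
#' A model may additionally carry exclusion-volume spheres ("anti-features"
#' no atom of an aligned molecule may penetrate) and the atom coordinates
#' of its underlying molecule, against which exclusion volumes of a query
#' are checked.
#'
#' The reserved type code `XV` denotes exclusion volumes in file formats and
#' never participates in feature matching; it cannot be used as a feature
#' type.
#'
#' @param name model name (molecule identifier in screening).
#' @param types character vector of feature type codes, one per feature.
#' @param positions n x 3 numeric matrix of feature centres (Angstrom).
#' @param tolerances numeric vector of positive tolerance radii (Angstrom).
#' @param directions optional n x 3 matrix of unit direction vectors; rows of
#'   `NA` mark undirected features. A plain `NULL` means no feature is
#'   directed.
#' @param optional logical vector flagging user-designated optional features
#'   (stored verbatim; matching itself treats all features equally and
#'   omission is governed by the global omitted-feature budget).
#' @param exclusions `NULL` or a list with `centers` (m x 3 matrix) and
#'   `radii` (positive numeric vector), the exclusion spheres.
#' @param atoms optional k x 3 matrix of molecule atom coordinates.
#' @param conformer optional conformer identifier (string), used by
#'   [screen()] to group conformers of one molecule.
#' @return An object of class `pharmacophore`.
#' @examples
#' p <- pharmacophore("toy",
#'   types = c("H", "AR", "HBA"),
#'   positions = rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
#'   tolerances = c(1.5, 1.5, 1.5))
#' n_features(p)
#' @export
pharmacophore <- function(name = "", types = character(),
                          positions = matrix(numeric(), 0L, 3L),
                          tolerances = numeric(),
                          directions = NULL, optional = NULL,
                          exclusions = NULL, atoms = NULL,
                          conformer = NA_character_) {
  types <- as.character(types)
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3L, byrow = TRUE)
  positions <- matrix(as.numeric(positions), ncol = 3L)
  tolerances <- as.numeric(tolerances)
  n <- length(types)
  stopifnot(nrow(positions) == n, length(tolerances) == n)
  if (any(types == "XV")) {
    stop("'XV' is reserved for exclusion volumes and cannot label a feature")
  }
  if (any(!is.finite(positions))) stop("feature positions must be finite")
  if (n > 0L && any(!(tolerances > 0))) {
    stop("feature tolerances must be strictly positive")
  }
  if (is.null(directions)) {
    directions <- matrix(NA_real_, n, 3L)
  } else {
    directions <- matrix(as.numeric(directions), ncol = 3L)
    stopifnot(nrow(directions) == n)
    has_dir <- stats::complete.cases(directions)
    if (any(has_dir)) {
      nrm <- sqrt(rowSums(directions[has_dir, , drop = FALSE]^2))
      if (any(abs(nrm - 1) > 1e-9)) {
        stop("direction vectors must be unit length (|norm - 1| <= 1e-9)")
      }
    }
  }
  if (is.null(optional)) optional <- rep(FALSE, n)
  stopifnot(length(optional) == n)
  if (!is.null(exclusions)) {
    exclusions$centers <- matrix(as.numeric(exclusions$centers), ncol = 3L)
    exclusions$radii <- as.numeric(exclusions$radii)
    stopifnot(nrow(exclusions$centers) == length(exclusions$radii))
    if (any(!(exclusions$radii > 0))) stop("exclusion radii must be positive")
  }
  if (!is.null(atoms)) {
    if (is.null(dim(atoms))) atoms <- matrix(atoms, ncol = 3L, byrow = TRUE)
    atoms <- matrix(as.numeric(atoms), ncol = 3L)
  }
  structure(list(name = as.character(name), types = types,
                 positions = positions, tolerances = tolerances,
                 directions = directions, optional = as.logical(optional),
                 exclusions = exclusions, atoms = atoms,
                 conformer = as.character(conformer)),
            class = "pharmacophore")
}

#' @rdname pharmacophore
#' @param x object to test or print.
#' @export
is_pharmacophore <- function(x) inherits(x, "pharmacophore")

#' Number of features in a pharmacophore
#' @param p a [pharmacophore()].
#' @return integer feature count.
#' @export
n_features <- function(p) length(p$types)

#' @export
print.pharmacophore <- function(x, ...) {
  cat(sprintf("Pharmacophore '%s': %d feature(s)", x$name, n_features(x)))
  if (!is.na(x$conformer)) cat(sprintf(" [conformer %s]", x$conformer))
  cat("\n")
  if (n_features(x) > 0L) {
    tab <- table(x$types)
    cat("  types:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  nx <- if (is.null(x$exclusions)) 0L else length(x$exclusions$radii)
  na <- if (is.null(x$atoms)) 0L else nrow(x$atoms)
  cat(sprintf("  exclusion spheres: %d, molecule atoms: %d\n", nx, na))
  invisible(x)
}

#' Apply a rigid transform to a whole pharmacophore
#'
#' Transforms feature positions, direction vectors (rotation only),
#' exclusion-sphere centres and atom coordinates.
#'
#' @param p a [pharmacophore()].
#' @param transform a [rigid_transform()].
#' @return the transformed [pharmacophore()].
#' @export
transform_pharmacophore <- function(p, transform) {
  p$positions <- transform_points(transform, p$positions)
  has_dir <- stats::complete.cases(p$directions)
  if (any(has_dir)) {
    p$directions[has_dir, ] <- p$directions[has_dir, , drop = FALSE] %*%
      t(transform$rotation)
  }
  if (!is.null(p$exclusions)) {
    p$exclusions$centers <- transform_points(transform, p$exclusions$centers)
  }
  if (!is.null(p$atoms)) p$atoms <- transform_points(transform, p$atoms)
  p
}

#' Do two features match under a transform?
#'
#' Two features match when their type codes are equal and the distance
#' between the query feature centre and the transformed target feature
#' centre is strictly smaller than the larger of the two tolerance radii.
#' Both inequality directions are strict by definition: a centre exactly on
#' the tolerance boundary does not match.
#'
#' @param a query feature: a list with `type`, `position`, `tolerance`
#'   (as returned by [get_feature()]).
#' @param b target feature, transformed by `transform` before evaluation.
#' @param transform [rigid_transform()] mapping the target frame onto the
#'   query frame.
#' @return `TRUE` or `FALSE`.
#' @export
features_match <- function(a, b, transform = rigid_transform()) {
  if (!identical(a$type, b$type)) return(FALSE)
  pb <- as.numeric(transform_points(transform, b$position))
  sqrt(sum((a$position - pb)^2)) < max(a$tolerance, b$tolerance)
}

#' Extract one feature of a pharmacophore
#'
#' @param p a [pharmacophore()].
#' @param i feature index (1-based).
#' @return list with `type`, `position`, `tolerance`, `direction` (or `NULL`),
#'   `optional`.
#' @export
get_feature <- function(p, i) {
  i <- as.integer(i)
  stopifnot(i >= 1L, i <= n_features(p))
  dir <- p$directions[i, ]
  list(type = p$types[[i]], position = p$positions[i, ],
       tolerance = p$tolerances[[i]],
       direction = if (all(is.finite(dir))) dir else NULL,
       optional = p$optional[[i]])
}

# Vectorised match predicate for a set of (i, j) pairs: distances between
# query features i and transformed target features j, strictly below the
# per-pair max tolerance. Types are checked too (defensive; callers pair
# like types only).
pairs_satisfied <- function(A, B, pairs, transform) {
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2L)
  if (nrow(pairs) == 0L) return(logical(0))
  i <- pairs[, 1L]; j <- pairs[, 2L]
  tb <- transform_points(transform, B$positions[j, , drop = FALSE])
  d <- sqrt(rowSums((A$positions[i, , drop = FALSE] - tb)^2))
  (A$types[i] == B$types[j]) & (d < pmax(A$tolerances[i], B$tolerances[j]))
}

pair_rmsd <- function(A, B, pairs, transform) {
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2L)
  if (nrow(pairs) == 0L) return(NA_real_)
  tb <- transform_points(transform, B$positions[pairs[, 2L], , drop = FALSE])
  sqrt(mean(rowSums((A$positions[pairs[, 1L], , drop = FALSE] - tb)^2)))
}

#' Check exclusion-volume clearance
#'
#' An alignment is sterically admissible when every atom of the transformed
#' molecule lies strictly outside every exclusion sphere of the query:
#' `dist(t(a), center) > radius` for all atom/sphere combinations. An atom
#' exactly on a sphere surface counts as a clash (the clearance inequality
#' is strict). An empty atom list is vacuously admissible.
#'
#' @param atoms k x 3 matrix of atom coordinates (target frame), or `NULL`.
#' @param exclusions `NULL` or list with `centers` (m x 3) and `radii`.
#' @param transform [rigid_transform()] applied to the atoms.
#' @return `TRUE` if no atom penetrates any sphere.
#' @export
exclusion_ok <- function(atoms, exclusions, transform = rigid_transform()) {
  if (is.null(atoms) || nrow(atoms) == 0L) return(TRUE)
  if (is.null(exclusions) || length(exclusions$radii) == 0L) return(TRUE)
  ta <- transform_points(transform, atoms)
  for (s in seq_along(exclusions$radii)) {
    d2 <- rowSums(sweep(ta, 2L, exclusions$centers[s, ], "-")^2)
    if (any(d2 <= exclusions$radii[s]^2)) return(FALSE)
  }
  TRUE
}

#' Classify the fit of an alignment
#'
#' Fit classes follow the standard pharmacophore-screening vocabulary:
#' `full` — every feature of both models is paired; `maximum` — every query
#' feature is paired into a larger target model; `partial` — at least
#' `|A| - omitted` query features are paired; `none` otherwise.
#'
#' @param A query [pharmacophore()].
#' @param B target [pharmacophore()].
#' @param result an alignment result (anything with a `match_count`).
#' @param omitted non-negative integer, allowed omitted query features.
#' @return one of `"full"`, `"maximum"`, `"partial"`, `"none"`.
#' @export
classify_fit <- function(A, B, result, omitted = 0L) {
  stopifnot(omitted >= 0L)
  mc <- result$match_count
  na <- n_features(A); nb <- n_features(B)
  if (mc == na && na == nb) return("full")
  if (mc == na && na < nb) return("maximum")
  if (mc >= na - omitted && mc < na) return("partial")
  "none"
}

#' Alignment result container
#'
#' Bundles the rigid transform applied to the target model, the matched
#' feature pairs (rows of `(i, j)` indices into query and target), the
#' match count, the RMSD over matched pairs after transformation, and a
#' validity verdict updated by post-processing.
#'
#' @param transform [rigid_transform()] applied to the target.
#' @param pairs integer matrix with columns `i` (query) and `j` (target);
#'   all `i` distinct, all `j` distinct, types equal per pair.
#' @param match_count number of matched pairs.
#' @param rmsd RMSD (Angstrom) over the matched pairs.
#' @param valid logical verdict.
#' @param ... further fields stored verbatim (e.g. `collected`, diagnostics).
#' @return object of class `pharm_alignment`.
#' @export
alignment_result <- function(transform, pairs, match_count = nrow(pairs),
                             rmsd = NA_real_, valid = FALSE, ...) {
  if (is.null(dim(pairs))) pairs <- matrix(as.integer(pairs), ncol = 2L)
  colnames(pairs) <- c("i", "j")
  if (anyDuplicated(pairs[, 1L]) || anyDuplicated(pairs[, 2L])) {
    stop("matched pairs must map one-to-one (distinct i, distinct j)")
  }
  structure(list(transform = transform, pairs = pairs,
                 match_count = as.integer(match_count), rmsd = rmsd,
                 valid = isTRUE(valid), ...),
            class = "pharm_alignment")
}

no_alignment <- function(reason = "no feasible seed") {
  alignment_result(rigid_transform(), matrix(integer(), 0L, 2L),
                   match_count = 0L, rmsd = NA_real_, valid = FALSE,
                   reason = reason)
}

#' @export
print.pharm_alignment <- function(x, ...) {
  cat(sprintf("Pharmacophore alignment: %d matched pair(s), RMSD %s, %s\n",
              x$match_count,
              if (is.na(x$rmsd)) "NA" else sprintf("%.4f A", x$rmsd),
              if (x$valid) "valid" else "not valid"))
  if (nrow(x$pairs) > 0L) {
    cat("  pairs (query -> target):",
        paste(sprintf("%d->%d", x$pairs[, 1L], x$pairs[, 2L]), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# ---- condition constructors ----------------------------------------------

g3ps_error <- function(class, message, ...) {
  structure(class = c(class, "g3ps_error", "error", "condition"),
            list(message = message, call = sys.call(-1), ...))
}

stop_ambiguous <- function(n, omitted) {
  stop(g3ps_error("g3ps_ambiguous_error", sprintf(
    "query has %d feature(s) with %d omitted: fewer than 3 features would remain, so no unambiguous 3D alignment exists",
    n, omitted)))
}

stop_degenerate <- function(msg) stop(g3ps_error("g3ps_degenerate_error", msg))

stop_no_seed <- function(msg) stop(g3ps_error("g3ps_no_seed_error", msg))
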