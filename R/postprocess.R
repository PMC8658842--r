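# Post-processing of raw alignments: steric admissibility against the
# query's exclusion volumes (with small "dodging" translations that can
# save an alignment with only a shallow clash) and direction-vector
# agreement for directed features.

#' Post-filter configuration
#'
#' @param max_dodge_translations maximum number of dodging translations
#'   attempted to clear exclusion-volume clashes (default 3).
#' @param direction_angle_tolerance largest allowed angle, in degrees,
#'   between the query direction and the rotated target direction of a
#'   matched directed feature pair (default 45).
#' @param enforce_exclusions if `FALSE`, exclusion volumes are ignored and
#'   results pass through untouched.
#' @param plane_normal_types feature type codes whose direction is a plane
#'   normal (aromatic rings), for which the angle is taken modulo
#'   orientation: normal and anti-normal are equivalent.
#' @return list of class `post_filter_config`.
#' @export
post_filter_config <- function(max_dodge_translations = 3L,
                               direction_angle_tolerance = 45,
                               enforce_exclusions = TRUE,
                               plane_normal_types = "AR") {
  stopifnot(max_dodge_translations >= 0L,
            direction_angle_tolerance > 0, direction_angle_tolerance <= 180)
  structure(list(max_dodge_translations = as.integer(max_dodge_translations),
                 direction_angle_tolerance = direction_angle_tolerance,
                 enforce_exclusions = enforce_exclusions,
                 plane_normal_types = plane_normal_types),
            class = "post_filter_config")
}

# Minimum-displacement translation clearing the given clashing
# (atom, sphere) pairs to radius + eps. The deepest-penetration objective
# alone is unbounded below (any huge shift clears a finite clash set), so
# the search minimizes |delta| under a feasibility penalty, started from
# the resultant of the per-clash outward pushes, and finally shrinks the
# shift to the smallest clearing scale along its direction. Returns NULL
# when no clearing translation was found.
dodge_translation <- function(atoms_t, centers, radii, eps = 1e-3) {
  penetration <- function(delta) {
    at <- sweep(atoms_t, 2L, delta, "+")
    max(radii + eps - sqrt(rowSums((at - centers)^2)))
  }
  out <- atoms_t - centers
  nrm <- sqrt(rowSums(out^2))
  dirs <- out / ifelse(nrm > 1e-12, nrm, 1)
  bad <- nrm <= 1e-12
  if (any(bad)) dirs[bad, ] <- matrix(c(0, 0, 1), sum(bad), 3L, byrow = TRUE)
  depth <- radii + eps - nrm
  push <- colSums(dirs * depth)
  cand <- NULL
  if (penetration(push) <= 0) {
    cand <- push
  } else {
    penalized <- function(d) sqrt(sum(d^2)) + 100 * max(0, penetration(d))
    for (s in list(push, 2 * push, c(0, 0, max(radii + eps)))) {
      opt <- stats::optim(s, penalized, method = "Nelder-Mead",
                          control = list(reltol = 1e-10, maxit = 1000L))
      if (penetration(opt$par) <= 0) { cand <- opt$par; break }
    }
  }
  if (is.null(cand)) return(NULL)
  # shrink along the found direction to the minimal clearing norm
  lo <- 0; hi <- 1
  for (k in 1:40) {
    mid <- (lo + hi) / 2
    if (penetration(cand * mid) <= 0) hi <- mid else lo <- mid
  }
  cand * hi
}

#' Resolve exclusion-volume clashes by dodging translations
#'
#' If the aligned molecule's atoms clash with the query's exclusion
#' spheres, up to `max_dodge_translations` small translations are applied,
#' each the minimum-displacement shift clearing all currently clashing
#' atoms. If a clash-free pose is reached, every matched pair's tolerance
#' is re-checked under the shifted transform; pairs now violating are
#' dropped. The result stays valid when the surviving match count still
#' reaches `min_required`; persistent clashes invalidate it.
#'
#' @param result a `pharm_alignment` from [align()] or [refine()].
#' @param A query [pharmacophore()] (owner of the exclusion spheres).
#' @param B target [pharmacophore()] (owner of the molecule atoms).
#' @param config a [post_filter_config()].
#' @param min_required minimum surviving match count (`|A| - omitted` in
#'   screening; defaults to 3).
#' @return the (possibly adjusted) `pharm_alignment`.
#' @export
dodge_exclusions <- function(result, A, B, config = post_filter_config(),
                             min_required = 3L) {
  if (!config$enforce_exclusions) return(result)
  if (is.null(B$atoms) || nrow(B$atoms) == 0L) return(result)
  if (is.null(A$exclusions) || length(A$exclusions$radii) == 0L) return(result)
  tr <- result$transform
  cleared <- exclusion_ok(B$atoms, A$exclusions, tr)
  if (!cleared) {
    for (attempt in seq_len(config$max_dodge_translations)) {
      ta <- transform_points(tr, B$atoms)
      # enumerate clashing (atom, sphere) pairs
      idx <- NULL
      for (s in seq_along(A$exclusions$radii)) {
        d <- sqrt(rowSums(sweep(ta, 2L, A$exclusions$centers[s, ], "-")^2))
        hit <- which(d <= A$exclusions$radii[s])
        if (length(hit)) idx <- rbind(idx, cbind(atom = hit, sphere = s))
      }
      if (is.null(idx)) { cleared <- TRUE; break }
      delta <- dodge_translation(ta[idx[, 1L], , drop = FALSE],
                                 A$exclusions$centers[idx[, 2L], , drop = FALSE],
                                 A$exclusions$radii[idx[, 2L]])
      if (is.null(delta)) break
      tr <- shift_transform(tr, delta)
      if (exclusion_ok(B$atoms, A$exclusions, tr)) { cleared <- TRUE; break }
    }
  }
  if (!cleared) {
    result$valid <- FALSE
    return(result)
  }
  if (!identical(tr, result$transform)) {
    sat <- pairs_satisfied(A, B, result$pairs, tr)
    result$transform <- tr
    result$pairs <- result$pairs[sat, , drop = FALSE]
    result$match_count <- nrow(result$pairs)
    result$rmsd <- pair_rmsd(A, B, result$pairs, tr)
    result$valid <- result$match_count >= max(min_required, 3L)
  }
  result
}

#' Filter matched pairs by direction-vector agreement
#'
#' For each matched pair where both features carry direction vectors, the
#' angle between the query direction and the rotated target direction must
#' not exceed the configured tolerance; otherwise the pair is considered
#' unmatched and removed. For plane-normal feature types the angle is
#' evaluated orientation-free. Pairs lacking a direction on either side
#' pass. If the surviving count falls below `min_required`, the solution
#' is discarded (`valid = FALSE`).
#'
#' @inheritParams dodge_exclusions
#' @return the filtered `pharm_alignment`.
#' @export
check_directions <- function(result, A, B, config = post_filter_config(),
                             min_required = 3L) {
  if (nrow(result$pairs) == 0L) return(result)
  R <- result$transform$rotation
  keep <- rep(TRUE, nrow(result$pairs))
  for (k in seq_len(nrow(result$pairs))) {
    i <- result$pairs[k, 1L]; j <- result$pairs[k, 2L]
    da <- A$directions[i, ]; db <- B$directions[j, ]
    if (any(!is.finite(da)) || any(!is.finite(db))) next
    dbr <- as.numeric(R %*% db)
    cosang <- max(-1, min(1, sum(da * dbr)))
    ang <- acos(cosang) * 180 / pi
    if (A$types[[i]] %in% config$plane_normal_types) ang <- min(ang, 180 - ang)
    if (ang > config$direction_angle_tolerance) keep[k] <- FALSE
  }
  if (!all(keep)) {
    result$pairs <- result$pairs[keep, , drop = FALSE]
    result$match_count <- nrow(result$pairs)
    result$rmsd <- pair_rmsd(A, B, result$pairs, result$transform)
    if (result$match_count < max(min_required, 3L)) result$valid <- FALSE
  }
  result
}

#' Apply all post-filters to an alignment
#'
#' Convenience wrapper running [dodge_exclusions()] then
#' [check_directions()], as done per screening hit.
#'
#' @inheritParams dodge_exclusions
#' @return the filtered `pharm_alignment`.
#' @export
post_process <- function(result, A, B, config = post_filter_config(),
                         min_required = 3L) {
  result <- dodge_exclusions(result, A, B, config, min_required)
  if (!result$valid) return(result)
  check_directions(result, A, B, config, min_required)
}
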