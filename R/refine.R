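# Greedy refinement: grow a matched pair set from a three-pair seed while
# keeping every collected pair inside its tolerance under the current
# Kabsch superposition. A boolean "forbidden" matrix F over all (i, j)
# feature pairs guarantees termination: every loop iteration marks at
# least one new entry, so the loop runs at most |A| * |B| times.

#' Alignment configuration
#'
#' @param guesses number of three-pair seed guesses to refine (ignored when
#'   `exhaustive = TRUE`). The presets of practical interest are
#'   `preset = "fast"` (20 guesses) and `preset = "accurate"` (300 guesses).
#' @param preset `"fast"`, `"accurate"`, or `NULL` to use `guesses` as given.
#' @param exhaustive refine every label-compatible three-pair combination.
#' @param omitted allowed number of unmatched query features (`#o`) for a
#'   solution to count as sufficient.
#' @param early_exit stop as soon as a solution with at least
#'   `|query| - omitted` matched features is found, instead of searching
#'   for the maximal match across all guesses.
#' @return list of class `align_config`.
#' @export
align_config <- function(guesses = 20L, preset = NULL, exhaustive = FALSE,
                         omitted = 0L, early_exit = FALSE) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("fast", "accurate"))
    guesses <- c(fast = 20L, accurate = 300L)[[preset]]
  }
  stopifnot(guesses >= 1L, omitted >= 0L)
  structure(list(guesses = as.integer(guesses), exhaustive = exhaustive,
                 omitted = as.integer(omitted), early_exit = early_exit),
            class = "align_config")
}

# Counter environment shared through one align()/screen() run; hardware
# independent effort proxies.
new_counters <- function() {
  e <- new.env(parent = emptyenv())
  e$refine_calls <- 0L
  e$kabsch_calls <- 0L
  e
}

#' Seek a rescuing translation for a violated pair set
#'
#' When adding a pair breaks the tolerance of some collected pair under the
#' freshly computed superposition, a pure translation may still bring every
#' pair inside its tolerance sphere simultaneously. Feasibility is a
#' ball-intersection problem: minimize over the shift `delta` the largest
#' excess `dist(A_i, t(B_j) + delta) - max(tol_i, tol_j)`. The objective is
#' convex (a max of Euclidean norms), so a deterministic Nelder--Mead
#' descent from the zero shift and from the most-violated pair's residual
#' finds the minimum reliably; success requires a strictly negative
#' minimax excess.
#'
#' @param A,B [pharmacophore()] query and target.
#' @param pairs integer matrix of `(i, j)` pairs.
#' @param transform current [rigid_transform()] for `B`.
#' @return the rescued [rigid_transform()], or `NULL` when no pure
#'   translation can satisfy every pair.
#' @export
translation_rescue <- function(A, B, pairs, transform) {
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2L)
  tb <- transform_points(transform, B$positions[pairs[, 2L], , drop = FALSE])
  resid <- A$positions[pairs[, 1L], , drop = FALSE] - tb
  rho <- pmax(A$tolerances[pairs[, 1L]], B$tolerances[pairs[, 2L]])
  excess <- function(delta) {
    max(sqrt(rowSums(sweep(resid, 2L, delta, "-")^2)) - rho)
  }
  if (excess(c(0, 0, 0)) < 0) return(transform)
  # necessary condition: a common interior point requires every two
  # tolerance balls around the residuals to overlap (triangle inequality);
  # rejects hopeless cases without invoking the optimizer
  if (nrow(resid) > 1L) {
    dd <- as.matrix(stats::dist(resid))
    if (any(dd >= outer(rho, rho, "+"))) return(NULL)
  }
  starts <- list(colMeans(resid),
                 resid[which.max(sqrt(rowSums(resid^2)) - rho), ])
  best <- NULL; best_val <- Inf
  for (s in starts) {
    opt <- stats::optim(s, excess, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 500L))
    if (opt$value < best_val) { best_val <- opt$value; best <- opt$par }
    if (best_val < 0) break
  }
  if (best_val < 0) shift_transform(transform, best) else NULL
}

#' Grow an alignment from a three-pair seed
#'
#' Implements the greedy collection loop. The seed is superposed by
#' [kabsch()]; the forbidden matrix starts with all type-incompatible
#' pairs and the rows/columns of the seed pairs marked. Each iteration
#' picks the unforbidden pair with the smallest centre distance under the
#' current transform, tentatively adds it, re-superposes, and keeps the
#' addition only if every collected pair still satisfies its tolerance
#' (directly or after a [translation_rescue()]); otherwise the single pair
#' is forbidden and the previous transform restored. Accepted pairs forbid
#' their whole row and column. The loop ends when no unforbidden entry
#' remains, when every query feature is matched, or (with
#' `config$early_exit`) when `|A| - omitted` features are matched.
#'
#' @param A,B [pharmacophore()] query and target.
#' @param seed a `seed_guess` (or bare 3 x 2 index matrix).
#' @param config an [align_config()].
#' @param counters internal effort counters (environment), optional.
#' @return a `pharm_alignment`; `valid` is `FALSE` when some collected pair
#'   (necessarily a seed pair) ends outside its tolerance, in which case
#'   `match_count` counts only the satisfied pairs. The full collected set
#'   is kept in field `collected`, and field `iterations` reports the loop
#'   length.
#' @export
refine <- function(A, B, seed, config = align_config(),
                   counters = new_counters()) {
  pairs <- if (is.list(seed)) seed$pairs else seed
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  stopifnot(nrow(pairs) == 3L)
  counters$refine_calls <- counters$refine_calls + 1L
  na <- n_features(A); nb <- n_features(B)
  tr <- kabsch(A$positions[pairs[, 1L], , drop = FALSE],
               B$positions[pairs[, 2L], , drop = FALSE], check = TRUE)
  counters$kabsch_calls <- counters$kabsch_calls + 1L
  FB <- outer(A$types, B$types, "!=")       # type-mismatched pairs forbidden
  FB[pairs[, 1L], ] <- TRUE                 # rows/columns of seed features
  FB[, pairs[, 2L]] <- TRUE
  P <- pairs
  iterations <- 0L
  f_trace <- sum(FB)
  repeat {
    if (!any(!FB)) break                    # forbidden matrix exhausted
    if (nrow(P) >= na) break                # every query feature collected
    if (config$early_exit && nrow(P) >= na - config$omitted) break
    iterations <- iterations + 1L
    open <- which(!FB, arr.ind = TRUE)
    open <- open[order(open[, 1L], open[, 2L]), , drop = FALSE]
    tb <- transform_points(tr, B$positions[open[, 2L], , drop = FALSE])
    d <- sqrt(rowSums((A$positions[open[, 1L], , drop = FALSE] - tb)^2))
    k <- which.min(d)                       # first minimum = lexicographic tie-break
    ij <- open[k, ]
    Ptest <- rbind(P, ij)
    tr_test <- kabsch(A$positions[Ptest[, 1L], , drop = FALSE],
                      B$positions[Ptest[, 2L], , drop = FALSE], check = FALSE)
    counters$kabsch_calls <- counters$kabsch_calls + 1L
    ok <- all(pairs_satisfied(A, B, Ptest, tr_test))
    if (!ok) {
      rescued <- translation_rescue(A, B, Ptest, tr_test)
      if (!is.null(rescued)) { tr_test <- rescued; ok <- TRUE }
    }
    if (ok) {
      P <- Ptest
      tr <- tr_test
      FB[ij[1L], ] <- TRUE
      FB[, ij[2L]] <- TRUE
    } else {
      FB[ij[1L], ij[2L]] <- TRUE            # previous transform kept
    }
    f_trace <- c(f_trace, sum(FB))
  }
  sat <- pairs_satisfied(A, B, P, tr)
  matched <- P[sat, , drop = FALSE]
  alignment_result(tr, matched, match_count = nrow(matched),
                   rmsd = pair_rmsd(A, B, matched, tr),
                   valid = all(sat) && nrow(matched) >= 3L,
                   collected = P, iterations = iterations,
                   f_trace = f_trace)
}

#' Align two pharmacophore models
#'
#' Full greedy 3-point search: generate ranked three-pair seed guesses
#' (single best, top-m from the dissimilarity matrix, or exhaustive
#' enumeration), refine each with [refine()], and return the result with
#' the largest matched-pair count; equal counts are tie-broken by smaller
#' RMSD, then by guess rank. A guess whose three pairs are all contained
#' in the collected pair set of an earlier refinement is skipped, since it
#' would converge to the same solution. Seeds with degenerate (collinear)
#' geometry are skipped as well.
#'
#' @param A query [pharmacophore()].
#' @param B target [pharmacophore()].
#' @param config an [align_config()].
#' @param counters internal effort counters (environment), optional;
#'   exposed so screening can aggregate hardware-independent work proxies.
#' @return a `pharm_alignment` with extra fields `guesses_generated`,
#'   `guesses_skipped`, `refine_calls`, `kabsch_calls`; `valid` is `TRUE`
#'   when at least `max(3, |A| - omitted)` features matched. When no
#'   feasible seed exists a zero-match invalid result is returned.
#' @examples
#' spec <- fixture_spec(n_features = 6, seed = 7)
#' A <- random_pharmacophore(spec)
#' cp <- perturbed_copy(A, seed = 8)
#' align(A, cp$pharmacophore, align_config(preset = "fast"))
#' @export
align <- function(A, B, config = align_config(), counters = new_counters()) {
  na <- n_features(A)
  if (na - config$omitted < 3L) stop_ambiguous(na, config$omitted)
  if (n_features(B) < 3L) {
    res <- no_alignment("target has fewer than 3 features")
    res$guesses_generated <- 0L; res$guesses_skipped <- 0L
    res$refine_calls <- counters$refine_calls
    res$kabsch_calls <- counters$kabsch_calls
    return(res)
  }
  guesses <- if (config$exhaustive) {
    all_guesses(A, B)
  } else {
    top_m_guesses(build_dissimilarity_matrix(A, B), config$guesses)
  }
  best <- NULL
  prev_collected <- list()
  skipped <- 0L
  min_needed <- max(na - config$omitted, 3L)
  for (g in guesses) {
    key <- paste(g$pairs[, 1L], g$pairs[, 2L], sep = "-")
    contained <- any(vapply(prev_collected, function(pc) all(key %in% pc),
                            logical(1)))
    if (contained) { skipped <- skipped + 1L; next }
    res <- tryCatch(refine(A, B, g, config, counters),
                    g3ps_degenerate_error = function(e) NULL)
    if (is.null(res)) { skipped <- skipped + 1L; next }
    prev_collected[[length(prev_collected) + 1L]] <-
      paste(res$collected[, 1L], res$collected[, 2L], sep = "-")
    if (is.null(best) ||
        res$match_count > best$match_count ||
        (res$match_count == best$match_count &&
         !is.na(res$rmsd) && !is.na(best$rmsd) && res$rmsd < best$rmsd)) {
      best <- res
    }
    if (best$match_count >= na) break       # every query feature matched
    if (config$early_exit && best$match_count >= min_needed) break
  }
  if (is.null(best)) best <- no_alignment()
  best$valid <- best$match_count >= min_needed
  best$guesses_generated <- length(guesses)
  best$guesses_skipped <- skipped
  best$refine_calls <- counters$refine_calls
  best$kabsch_calls <- counters$kabsch_calls
  best
}
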