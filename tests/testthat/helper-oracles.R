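# Independent oracles used across the test suite. These deliberately use
# brute force (full enumeration) rather than the package's search
# machinery, so they can certify results of the fast paths.

# Exhaustive minimum-cost assignment by permutation enumeration (n <= 7).
perm_assignment_oracle <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost), n <= 7L)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (k in seq_along(v)) {
      for (r in perms(v[-k])) out[[length(out) + 1L]] <- c(v[k], r)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    best <- min(best, sum(cost[cbind(seq_len(n), p)]))
  }
  best
}

# All injective label-consistent mappings of >= 3 query features into the
# target, by recursive extension. Returns a list of 2-column matrices.
enumerate_mappings <- function(A, B, min_size = 3L) {
  na <- g3ps::n_features(A); nb <- g3ps::n_features(B)
  out <- list()
  recurse <- function(i, pairs, used_j) {
    if (i > na) {
      if (nrow(pairs) >= min_size) out[[length(out) + 1L]] <<- pairs
      return(invisible())
    }
    recurse(i + 1L, pairs, used_j)                    # leave feature i out
    for (j in seq_len(nb)) {
      if (!used_j[j] && A$types[i] == B$types[j]) {
        recurse(i + 1L, rbind(pairs, c(i, j)), replace(used_j, j, TRUE))
      }
    }
  }
  recurse(1L, matrix(integer(), 0L, 2L), rep(FALSE, nb))
  out
}

# Brute-force alignment oracle: for every label-consistent one-to-one
# mapping of size >= 3, superpose by Kabsch, and if some mapped pair ends
# outside its tolerance, additionally test whether a pure translation can
# bring every mapped pair inside (the same transform family the greedy
# refinement searches: rotation from Kabsch, translation polished).
# Returns the maximum satisfied count over all mappings.
subset_superposition_oracle <- function(A, B) {
  best <- 0L
  for (m in enumerate_mappings(A, B)) {
    if (nrow(m) <= best) next              # cannot improve
    tr <- tryCatch(g3ps::kabsch(A$positions[m[, 1L], , drop = FALSE],
                                B$positions[m[, 2L], , drop = FALSE],
                                check = FALSE),
                   error = function(e) NULL)
    if (is.null(tr)) next
    sat <- sum(g3ps:::pairs_satisfied(A, B, m, tr))
    if (sat < nrow(m) && oracle_translation_feasible(A, B, m, tr)) {
      sat <- nrow(m)
    }
    if (sat > best) best <- sat
  }
  best
}

# Independent feasibility check: does a pure shift delta exist bringing
# every mapped pair strictly inside its tolerance? Convex minimax solved
# by Nelder-Mead from two deterministic starts.
oracle_translation_feasible <- function(A, B, m, tr) {
  tb <- g3ps::transform_points(tr, B$positions[m[, 2L], , drop = FALSE])
  resid <- A$positions[m[, 1L], , drop = FALSE] - tb
  rho <- pmax(A$tolerances[m[, 1L]], B$tolerances[m[, 2L]])
  f <- function(d) max(sqrt(rowSums(sweep(resid, 2L, d, "-")^2)) - rho)
  for (s in list(colMeans(resid),
                 resid[which.max(sqrt(rowSums(resid^2)) - rho), ])) {
    if (stats::optim(s, f, method = "Nelder-Mead",
                     control = list(reltol = 1e-10,
                                    maxit = 800L))$value < 0) {
      return(TRUE)
    }
  }
  FALSE
}

# Grid-search feasibility check for a pure rescuing translation: is there
# a shift delta on the grid bringing every pair strictly inside its
# tolerance?
grid_rescue_oracle <- function(A, B, pairs, transform,
                               extent = 2, step = 0.05) {
  tb <- g3ps::transform_points(transform,
                               B$positions[pairs[, 2L], , drop = FALSE])
  resid <- A$positions[pairs[, 1L], , drop = FALSE] - tb
  rho <- pmax(A$tolerances[pairs[, 1L]], B$tolerances[pairs[, 2L]])
  g <- seq(-extent, extent, by = step)
  for (dx in g) for (dy in g) for (dz in g) {
    d <- sqrt(rowSums(sweep(resid, 2L, c(dx, dy, dz), "-")^2))
    if (all(d < rho)) return(TRUE)
  }
  FALSE
}

# Small deterministic test model used in several files.
toy_pharmacophore <- function() {
  g3ps::pharmacophore(
    "toy",
    types = c("H", "AR", "HBA", "HBD"),
    positions = rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0), c(1, 1, 3)),
    tolerances = c(1.5, 1.2, 1.0, 2.0),
    directions = rbind(c(NA, NA, NA), c(0, 0, 1), c(1, 0, 0), c(NA, NA, NA)))
}

random_rigid <- function(seed) {
  withr::with_seed(seed, {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                  2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                  2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
                3, 3, byrow = TRUE)
    g3ps::rigid_transform(R, stats::runif(3, -5, 5))
  })
}
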