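# Seed-guess generation: every alignment starts from exactly three feature
# pairs, the minimum fixing an unambiguous rigid transform. Guesses are
# ranked by the sum of their three dissimilarity entries (smaller = better)
# and everything is deterministic: ties break lexicographically on the
# sorted (i, j) index pairs.

# Enumerate all feasible three-pair combinations over the finite cells of a
# matrix: distinct rows, distinct columns, no sentinel entry. Returns a
# list of guesses ordered by (score, lexicographic pair indices).
enumerate_triples <- function(M, m = Inf) {
  cells <- which(!is.na(M), arr.ind = TRUE)
  if (nrow(cells) < 3L) return(list())
  ord <- order(cells[, 1L], cells[, 2L])
  cells <- cells[ord, , drop = FALSE]
  K <- nrow(cells)
  cmb <- utils::combn(K, 3L)
  i1 <- cells[cmb[1L, ], 1L]; j1 <- cells[cmb[1L, ], 2L]
  i2 <- cells[cmb[2L, ], 1L]; j2 <- cells[cmb[2L, ], 2L]
  i3 <- cells[cmb[3L, ], 1L]; j3 <- cells[cmb[3L, ], 2L]
  ok <- i1 != i2 & i1 != i3 & i2 != i3 & j1 != j2 & j1 != j3 & j2 != j3
  if (!any(ok)) return(list())
  sc <- M[cbind(i1, j1)] + M[cbind(i2, j2)] + M[cbind(i3, j3)]
  keep <- which(ok)
  keep <- keep[order(sc[keep])]          # stable: ties stay lexicographic
  if (is.finite(m)) keep <- utils::head(keep, m)
  lapply(keep, function(k) {
    structure(list(pairs = cbind(i = c(i1[k], i2[k], i3[k]),
                                 j = c(j1[k], j2[k], j3[k])),
                   score = sc[k]),
              class = "seed_guess")
  })
}

#' @export
print.seed_guess <- function(x, ...) {
  cat(sprintf("Seed guess (score %.4f): %s\n", x$score,
              paste(sprintf("%d->%d", x$pairs[, 1L], x$pairs[, 2L]),
                    collapse = ", ")))
  invisible(x)
}

#' Single best three-pair seed from the dissimilarity matrix
#'
#' Solves the optimal assignment over the full dissimilarity matrix
#' (sentinel entries carry a prohibitive penalty) and keeps the three
#' assigned pairs with the smallest dissimilarity, the combination most
#' likely to seed the globally optimal refinement.
#'
#' @param M matrix from [build_dissimilarity_matrix()].
#' @return a `seed_guess`: list with `pairs` (3 x 2 matrix) and `score`.
#' @export
single_best_guess <- function(M) {
  BIG <- 1e6
  n <- nrow(M); m <- ncol(M)
  k <- max(n, m)
  cost <- matrix(BIG, k, k)
  cost[seq_len(n), seq_len(m)] <- ifelse(is.na(M), BIG, M)
  sol <- solve_assignment(cost)
  i <- seq_len(n)
  j <- sol$assignment[i]
  real <- j <= m & !is.na(M[cbind(i, pmin(j, m))])
  i <- i[real]; j <- j[real]
  if (length(i) < 3L) {
    stop_no_seed("fewer than 3 label-compatible assigned pairs: alignment impossible")
  }
  cst <- M[cbind(i, j)]
  ord <- order(cst, i, j)[1:3]
  structure(list(pairs = cbind(i = i[ord], j = j[ord]), score = sum(cst[ord])),
            class = "seed_guess")
}

#' Best m three-pair seeds
#'
#' Enumerates every feasible combination of three pairs (distinct query
#' features, distinct target features, no type-incompatible entry) and
#' returns the `m` lowest-scoring ones, ascending by score. The
#' enumeration is O(n^6) in the feature count but cheap in practice since
#' sentinel cells are skipped and unordered combinations are counted once.
#'
#' @param M matrix from [build_dissimilarity_matrix()].
#' @param m positive integer budget.
#' @return list of `seed_guess` objects (possibly fewer than `m`; empty if
#'   no feasible combination exists).
#' @export
top_m_guesses <- function(M, m) {
  stopifnot(m >= 1)
  enumerate_triples(M, m)
}

#' All label-compatible three-pair seeds
#'
#' Exhaustive seeding needs no dissimilarity matrix: every combination of
#' three pairs with matching feature types, distinct query features and
#' distinct target features is produced exactly once (scores all 0,
#' lexicographic order).
#'
#' @param A,B [pharmacophore()] objects.
#' @return list of `seed_guess` objects.
#' @export
all_guesses <- function(A, B) {
  if (n_features(A) == 0L || n_features(B) == 0L) return(list())
  compat <- outer(A$types, B$types, "==")
  M <- ifelse(compat, 0, NA_real_)
  enumerate_triples(M, Inf)
}
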