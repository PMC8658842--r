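#' Encode features by their labelled neighbourhood-distance profile
#'
#' The encoding of feature `i` records, for every other feature `p != i` of
#' the same pharmacophore, the pair `(type(p), dist(i, p))`. Because only
#' internal distances enter, the encoding is invariant under rigid motion
#' of the whole model, which is what makes it usable for seeding an
#' alignment before any transform is known.
#'
#' @param P a [pharmacophore()] with at least one feature.
#' @return list of encodings, one per feature; each is a list with
#'   `owner_type`, `owner_tolerance`, `neighbour_types`,
#'   `neighbour_distances`, `neighbour_tolerances` (neighbours in feature
#'   index order).
#' @export
encode_features <- function(P) {
  n <- n_features(P)
  stopifnot(n >= 1L)
  D <- as.matrix(stats::dist(P$positions))
  lapply(seq_len(n), function(i) {
    nb <- setdiff(seq_len(n), i)
    list(owner_type = P$types[[i]], owner_tolerance = P$tolerances[[i]],
         neighbour_types = P$types[nb],
         neighbour_distances = if (n > 1L) D[i, nb] else numeric(),
         neighbour_tolerances = P$tolerances[nb])
  })
}

#' Dissimilarity between two feature encodings
#'
#' Encodings of different owner types are incomparable and yield the
#' invalid sentinel `NA`. Otherwise the neighbour lists are matched by an
#' optimal assignment: a neighbour pair `(p, q)` with different labels
#' costs 1; with equal labels it costs the absolute difference of encoded
#' distances divided by the larger of the two summed positional tolerances
#' `max(tol(i) + tol(p), tol(j) + tol(q))`, clamped at exactly 1 (beyond
#' that the pair is incompatible and further differences carry no
#' discriminative value). Unequal-length neighbour lists are squared with
#' dummy entries at the maximal cost 1. The minimal total assignment cost
#' divided by `normalizer` (the feature count of the larger pharmacophore)
#' is returned, always in `[0, 1]`.
#'
#' @param ea,eb encodings from [encode_features()].
#' @param normalizer positive integer, `max(|A|, |B|)`.
#' @return numeric cost in `[0, 1]`, or `NA` for incompatible owner types.
#' @export
encoding_dissimilarity <- function(ea, eb, normalizer) {
  if (normalizer <= 0) stop("normalizer must be a positive feature count")
  if (!identical(ea$owner_type, eb$owner_type)) return(NA_real_)
  na <- length(ea$neighbour_distances)
  nb <- length(eb$neighbour_distances)
  k <- max(na, nb)
  if (k == 0L) return(0)
  grid <- matrix(1, k, k)
  if (na > 0L && nb > 0L) {
    dd <- abs(outer(ea$neighbour_distances, eb$neighbour_distances, "-"))
    tol <- pmax(outer(ea$owner_tolerance + ea$neighbour_tolerances,
                      rep(1, nb)),
                outer(rep(1, na),
                      eb$owner_tolerance + eb$neighbour_tolerances))
    cost <- pmin(1, dd / tol)
    cost[outer(ea$neighbour_types, eb$neighbour_types, "!=")] <- 1
    grid[seq_len(na), seq_len(nb)] <- cost
  }
  solve_assignment(grid)$cost / normalizer
}

#' Build the feature dissimilarity matrix of two pharmacophores
#'
#' Entry `(i, j)` measures how dissimilar the neighbourhood of query
#' feature `i` is to that of target feature `j`; type-incompatible pairs
#' hold the sentinel `NA` and are never eligible for seeding. All finite
#' entries lie in `[0, 1]`.
#'
#' @param A,B [pharmacophore()] objects with at least one feature each.
#' @return numeric `|A| x |B|` matrix of class `dissimilarity_matrix`,
#'   `NA` marking invalid (type-mismatched) pairs.
#' @export
build_dissimilarity_matrix <- function(A, B) {
  stopifnot(n_features(A) >= 1L, n_features(B) >= 1L)
  ea <- encode_features(A); eb <- encode_features(B)
  normalizer <- max(n_features(A), n_features(B))
  M <- matrix(NA_real_, n_features(A), n_features(B))
  for (i in seq_len(n_features(A))) {
    for (j in seq_len(n_features(B))) {
      if (identical(A$types[[i]], B$types[[j]])) {
        M[i, j] <- encoding_dissimilarity(ea[[i]], eb[[j]], normalizer)
      }
    }
  }
  structure(M, class = c("dissimilarity_matrix", class(M)))
}

#' Write a dissimilarity matrix to CSV (debugging aid)
#'
#' @param M matrix from [build_dissimilarity_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dump_dissimilarity_matrix <- function(M, path) {
  utils::write.csv(unclass(M), path, row.names = FALSE)
  invisible(path)
}
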