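# Reference implementation of the classic histogram/Hungarian/Kabsch
# alignment scheme ("RM" method) used as the comparison baseline. Features
# are encoded as per-neighbour-type binned distance histograms; a single
# optimal assignment fixes candidate pairs; Kabsch superposition with
# iterative removal of tolerance-violating pairs follows; omitted features
# are handled by combinatorial enumeration of query feature subsets, which
# is exactly what makes its cost grow with the omitted budget.

#' RM baseline configuration
#'
#' @param bin_width histogram bin width in Angstrom (default 1).
#' @param range distance range covered by the histograms (default 0--20 A;
#'   larger distances are clamped into the last bin).
#' @param kernel symmetric smoothing kernel applied to each histogram
#'   (default triangular `c(0.25, 0.5, 0.25)`); must sum to 1. Smoothing
#'   makes histograms of features whose neighbour distances straddle a bin
#'   boundary more similar. Mass is conserved via edge-mirrored boundaries.
#' @return list of class `rmm_config`.
#' @export
rmm_config <- function(bin_width = 1, range = c(0, 20),
                       kernel = c(0.25, 0.5, 0.25)) {
  stopifnot(bin_width > 0, length(range) == 2L, range[2L] > range[1L],
            length(kernel) %% 2L == 1L, abs(sum(kernel) - 1) < 1e-9)
  structure(list(bin_width = bin_width, range = range, kernel = kernel),
            class = "rmm_config")
}

smooth_histogram <- function(h, kernel) {
  k <- (length(kernel) - 1L) %/% 2L
  if (k == 0L || length(h) == 0L) return(h)
  n <- length(h)
  pad <- c(h[seq_len(k)][k:1], h, h[seq.int(n, n - k + 1L)])
  out <- numeric(n)
  for (b in seq_len(n)) out[b] <- sum(pad[b:(b + 2L * k)] * kernel)
  out
}

#' Distance-histogram feature encoding (RM baseline)
#'
#' For each feature, one histogram of centre distances per neighbour
#' feature type, binned at `config$bin_width` over `config$range` and
#' smoothed with the configured kernel.
#'
#' @param P a [pharmacophore()].
#' @param config an [rmm_config()].
#' @param smooth apply the smoothing kernel (default `TRUE`).
#' @return list (one element per feature) of lists with `owner_type` and
#'   `histograms` (named list, neighbour type -> numeric bin counts).
#' @export
rmm_encode <- function(P, config = rmm_config(), smooth = TRUE) {
  n <- n_features(P)
  stopifnot(n >= 1L)
  breaks <- seq(config$range[1L], config$range[2L], by = config$bin_width)
  if (breaks[length(breaks)] < config$range[2L]) {
    breaks <- c(breaks, config$range[2L])
  }
  nb_bins <- length(breaks) - 1L
  D <- as.matrix(stats::dist(P$positions))
  lapply(seq_len(n), function(i) {
    nb <- setdiff(seq_len(n), i)
    hmap <- list()
    for (ty in unique(P$types[nb])) {
      dd <- D[i, nb[P$types[nb] == ty]]
      dd <- pmin(pmax(dd, config$range[1L]), config$range[2L] - 1e-9)
      bins <- pmin(floor((dd - config$range[1L]) / config$bin_width) + 1L,
                   nb_bins)
      h <- tabulate(bins, nbins = nb_bins)
      hmap[[ty]] <- if (smooth) smooth_histogram(h, config$kernel) else h
    }
    list(owner_type = P$types[[i]], histograms = hmap)
  })
}

# Histogram-overlap dissimilarity between two encodings of equal owner
# type: 1 - mean over the union of neighbour types of
# sum(pmin(h1, h2)) / max(sum(h1), sum(h2), 1). Monotone in overlap,
# bounded in [0, 1]; a type present on one side only contributes zero
# overlap.
rmm_cost <- function(ea, eb) {
  tys <- union(names(ea$histograms), names(eb$histograms))
  if (length(tys) == 0L) return(0)
  ov <- vapply(tys, function(ty) {
    h1 <- ea$histograms[[ty]]; h2 <- eb$histograms[[ty]]
    if (is.null(h1) || is.null(h2)) return(0)
    sum(pmin(h1, h2)) / max(sum(h1), sum(h2), 1)
  }, numeric(1))
  1 - mean(ov)
}

rmm_cost_matrix <- function(encA, typesA, encB, typesB) {
  BIG <- 1e6
  M <- matrix(BIG, length(encA), length(encB))
  for (i in seq_along(encA)) {
    for (j in seq_along(encB)) {
      if (identical(typesA[[i]], typesB[[j]])) M[i, j] <- rmm_cost(encA[[i]], encB[[j]])
    }
  }
  M
}

# One Hungarian/Kabsch fixed-point pass for a fixed query feature subset.
# Returns a pharm_alignment (possibly invalid) or NULL when no alignment
# with >= 3 pairs survives.
rmm_align_subset <- function(Asub, subset_idx, B, config, counters) {
  BIG <- 1e6
  encA <- rmm_encode(Asub, config)
  encB <- rmm_encode(B, config)
  cost <- rmm_cost_matrix(encA, Asub$types, encB, B$types)
  na <- nrow(cost); nb <- ncol(cost)
  k <- max(na, nb)
  repeat {
    sq <- matrix(BIG, k, k)
    sq[seq_len(na), seq_len(nb)] <- cost
    sol <- solve_assignment(sq)
    i <- seq_len(na)
    j <- sol$assignment[i]
    real <- j <= nb
    real[real] <- cost[cbind(i[real], j[real])] < BIG
    pairs <- cbind(i[real], j[real])
    if (nrow(pairs) < 3L) return(NULL)
    tr <- tryCatch(kabsch(Asub$positions[pairs[, 1L], , drop = FALSE],
                          B$positions[pairs[, 2L], , drop = FALSE],
                          check = TRUE),
                   g3ps_degenerate_error = function(e) NULL)
    if (is.null(tr)) return(NULL)
    counters$kabsch_calls <- counters$kabsch_calls + 1L
    sat <- pairs_satisfied(Asub, B, pairs, tr)
    if (all(sat)) {
      full_pairs <- cbind(subset_idx[pairs[, 1L]], pairs[, 2L])
      return(alignment_result(tr, full_pairs, match_count = nrow(full_pairs),
                              rmsd = pair_rmsd(Asub, B, pairs, tr),
                              valid = TRUE))
    }
    cost[pairs[!sat, , drop = FALSE]] <- BIG  # forbid violating pairs, repeat
  }
}

#' Align with the RM baseline algorithm
#'
#' Enumerates query feature subsets from largest (`|A|`) down to
#' `|A| - omitted`, and for each subset runs the histogram-encoding /
#' Hungarian-assignment / Kabsch pipeline with iterative removal of
#' tolerance-violating pairs until a stable, fully tolerance-satisfying
#' assignment remains (or fewer than 3 pairs survive). The first subset
#' producing a valid alignment that also passes the post-filters wins.
#' The number of Kabsch invocations is reported as a hardware-independent
#' effort proxy; it grows combinatorially with the omitted budget, in
#' contrast to the greedy search.
#'
#' @param A query [pharmacophore()].
#' @param B target [pharmacophore()].
#' @param omitted allowed omitted query features (`#o`).
#' @param config an [rmm_config()].
#' @param post a [post_filter_config()].
#' @param counters internal effort counters (environment), optional.
#' @return a `pharm_alignment` with fields `kabsch_calls` and
#'   `combinations_tried`; a zero-match invalid result when no combination
#'   aligns.
#' @export
rmm_align <- function(A, B, omitted = 0L, config = rmm_config(),
                      post = post_filter_config(),
                      counters = new_counters()) {
  na <- n_features(A)
  if (na - omitted < 3L) stop_ambiguous(na, omitted)
  min_needed <- na - omitted
  combos_tried <- 0L
  if (n_features(B) >= 3L) {
    for (k in 0:omitted) {
      subsets <- utils::combn(na, na - k)
      for (s in seq_len(ncol(subsets))) {
        idx <- subsets[, s]
        combos_tried <- combos_tried + 1L
        Asub <- pharmacophore(A$name, A$types[idx],
                              A$positions[idx, , drop = FALSE],
                              A$tolerances[idx],
                              directions = A$directions[idx, , drop = FALSE],
                              optional = A$optional[idx],
                              exclusions = A$exclusions)
        res <- rmm_align_subset(Asub, idx, B, config, counters)
        if (is.null(res)) next
        res <- post_process(res, A, B, post, min_required = min_needed)
        if (res$valid && res$match_count >= min_needed) {
          res$kabsch_calls <- counters$kabsch_calls
          res$combinations_tried <- combos_tried
          return(res)
        }
      }
    }
  }
  res <- no_alignment("no query feature subset aligned")
  res$kabsch_calls <- counters$kabsch_calls
  res$combinations_tried <- combos_tried
  res
}
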