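#' Solve a minimum-cost linear assignment problem
#'
#' Shortest-augmenting-path solver with dual potentials (the
#' Jonker--Volgenant scheme, O(n^3)) for square cost matrices. Returns the
#' optimal one-to-one assignment of rows to columns minimizing total cost.
#' Ties between equally cheap assignments are resolved deterministically
#' (lowest column index is augmented first), so repeated calls on identical
#' input yield identical assignments.
#'
#' Pharmacophore cost matrices are small (one row per feature), so a plain
#' R implementation is entirely adequate.
#'
#' @param cost square numeric matrix; finite entries only (encode forbidden
#'   pairs with a large finite penalty such as `1e6`).
#' @return list with `assignment` (integer vector, `assignment[i]` = column
#'   assigned to row `i`) and `cost` (total).
#' @examples
#' solve_assignment(rbind(c(1, 2), c(2, 1)))
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0L) return(list(assignment = integer(), cost = 0))
  if (any(!is.finite(cost))) {
    stop("cost matrix must be finite; use a large penalty for forbidden pairs")
  }
  u <- numeric(n)            # row potentials
  v <- numeric(n + 1L)       # column potentials; n+1 is the virtual column
  p <- integer(n + 1L)       # p[j]: row currently assigned to column j (0 = free)
  way <- integer(n)          # predecessor column on the alternating path
  cols <- seq_len(n)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      cur <- cost[i0, ] - u[i0] - v[cols]
      upd <- !used[cols] & cur < minv
      if (any(upd)) {
        minv[upd] <- cur[upd]
        way[upd] <- j0
      }
      free <- which(!used[cols])
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      used_cols <- which(used)
      rows_used <- p[used_cols]          # all assigned (virtual column holds i)
      u[rows_used] <- u[rows_used] + delta
      v[used_cols] <- v[used_cols] - delta
      notused <- !used[cols]
      minv[notused] <- minv[notused] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assignment <- integer(n)
  assignment[p[cols]] <- cols
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}
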