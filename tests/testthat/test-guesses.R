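test_that("single best guess returns three zero-cost identity pairs for identical models", {
  A <- random_pharmacophore(fixture_spec(6, seed = 51))
  M <- build_dissimilarity_matrix(A, A)
  g <- single_best_guess(M)
  expect_identical(nrow(g$pairs), 3L)
  expect_equal(g$score, 0, tolerance = 1e-12)
  expect_identical(g$pairs[, 1L], g$pairs[, 2L])
})

test_that("single best guess errors when fewer than 3 compatible pairs exist", {
  M <- matrix(NA_real_, 4, 4)
  expect_error(single_best_guess(structure(M, class = "dissimilarity_matrix")),
               class = "g3ps_no_seed_error")
  M2 <- matrix(NA_real_, 3, 3); M2[1, 1] <- 0; M2[2, 2] <- 0
  expect_error(single_best_guess(M2), class = "g3ps_no_seed_error")
})

test_that("top-m guesses enumerate feasible three-pair combinations exactly", {
  # 3x3 all-finite matrix: the 6 one-to-one triples, regardless of m
  M <- matrix(stats::runif(9, 0, 1), 3, 3)
  gs <- top_m_guesses(M, 100)
  expect_length(gs, 6L)
  scores <- vapply(gs, `[[`, numeric(1), "score")
  expect_true(!is.unsorted(scores))
  # m truncates; requesting more than exists returns all
  expect_length(top_m_guesses(M, 2), 2L)
  # the global minimum is at least as good as the assignment-based guess
  g1 <- single_best_guess(M)
  expect_gte(g1$score, gs[[1]]$score - 1e-12)
})

test_that("guess enumeration matches a brute-force count and respects sentinels", {
  withr::local_seed(52)
  for (rep in 1:6) {
    na <- sample(3:5, 1); nb <- sample(3:5, 1)
    M <- matrix(stats::runif(na * nb), na, nb)
    M[sample(length(M), floor(length(M) / 3))] <- NA
    gs <- top_m_guesses(M, Inf)
    # brute force over all cell triples
    cells <- which(!is.na(M), arr.ind = TRUE)
    count <- 0L
    if (nrow(cells) >= 3) {
      cmb <- utils::combn(nrow(cells), 3)
      for (k in seq_len(ncol(cmb))) {
        tri <- cells[cmb[, k], , drop = FALSE]
        if (!anyDuplicated(tri[, 1]) && !anyDuplicated(tri[, 2])) {
          count <- count + 1L
        }
      }
    }
    expect_length(gs, count)
    for (g in gs) {
      expect_false(anyDuplicated(g$pairs[, 1]) > 0)
      expect_false(anyDuplicated(g$pairs[, 2]) > 0)
      expect_false(anyNA(M[g$pairs]))
    }
  }
})

test_that("all_guesses yields every label-compatible combination once, without a matrix", {
  # three distinct types matching one-to-one: a single combination
  A <- pharmacophore("a", c("H", "AR", "HBA"),
                     rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)), rep(1.5, 3))
  expect_length(all_guesses(A, A), 1L)
  # all same type: 3! = 6 one-to-one maps
  B <- pharmacophore("b", rep("H", 3),
                     rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)), rep(1.5, 3))
  expect_length(all_guesses(B, B), 6L)
  # no shared types: empty
  C <- pharmacophore("c", rep("NI", 3),
                     rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)), rep(1.5, 3))
  expect_length(all_guesses(A, C), 0L)
})

test_that("guess lists are invariant under rigid motion of either model", {
  A <- random_pharmacophore(fixture_spec(5, seed = 53))
  B <- random_pharmacophore(fixture_spec(5, seed = 54))
  Bt <- transform_pharmacophore(B, random_rigid(55))
  g0 <- top_m_guesses(build_dissimilarity_matrix(A, B), 10)
  g1 <- top_m_guesses(build_dissimilarity_matrix(A, Bt), 10)
  expect_identical(lapply(g0, `[[`, "pairs"), lapply(g1, `[[`, "pairs"))
  expect_equal(vapply(g0, `[[`, numeric(1), "score"),
               vapply(g1, `[[`, numeric(1), "score"), tolerance = 1e-9)
})
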