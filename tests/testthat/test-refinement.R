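test_that("kabsch recovers exact rigid maps and refuses degenerate input", {
  A <- matrix(stats::rnorm(15, sd = 3), 5, 3)
  tr0 <- kabsch(A, A)
  expect_equal(tr0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tr0$translation, c(0, 0, 0), tolerance = 1e-9)

  # B = A rotated 90 degrees about z and shifted: kabsch inverts it exactly
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  g <- rigid_transform(Rz, c(1, 2, 3))
  B <- transform_points(g, A)
  tr <- kabsch(A, B)
  expect_equal(transform_points(tr, B), A, tolerance = 1e-9)
  inv <- invert_transform(g)
  expect_equal(tr$rotation, inv$rotation, tolerance = 1e-9)
  expect_equal(tr$translation, inv$translation, tolerance = 1e-9)

  expect_error(kabsch(A[1:2, ], A[1:2, ]),
               class = "g3ps_underdetermined_error")
  line <- cbind(1:4, 0, 0)
  expect_error(kabsch(line, line), class = "g3ps_degenerate_error")
})

test_that("kabsch beats random rigid transforms on noisy point clouds", {
  withr::local_seed(61)
  A <- matrix(stats::rnorm(15, sd = 3), 5, 3)
  B <- transform_points(random_rigid(62), A) +
    matrix(stats::rnorm(15, sd = 0.1), 5, 3)
  tr <- kabsch(A, B)
  rmsd <- function(t) sqrt(mean(rowSums((A - transform_points(t, B))^2)))
  best <- rmsd(tr)
  for (s in 1:1000) expect_lte(best, rmsd(random_rigid(s)) + 1e-12)
})

test_that("kabsch never returns a reflection even for mirrored geometry", {
  A <- matrix(stats::rnorm(18, sd = 3), 6, 3)
  B <- A; B[, 3] <- -B[, 3]                 # mirror image
  tr <- kabsch(A, B)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
})

test_that("refinement collects all pairs of an exact rigid copy from any correct seed", {
  A <- random_pharmacophore(fixture_spec(6, seed = 63))
  cp <- perturbed_copy(A, seed = 64)
  B <- cp$pharmacophore
  gt <- cp$ground_truth
  seed <- gt[1:3, , drop = FALSE]
  res <- refine(A, B, seed)
  expect_identical(res$match_count, 6L)
  expect_lt(res$rmsd, 1e-6)
  expect_true(res$valid)
  expect_false(anyDuplicated(res$pairs[, 1]) > 0)
  expect_false(anyDuplicated(res$pairs[, 2]) > 0)
})

test_that("refinement matches everything when noise stays below half the smallest tolerance", {
  withr::local_seed(65)
  for (rep in 1:5) {
    A <- random_pharmacophore(fixture_spec(6, seed = sample.int(1e6, 1)))
    sigma <- min(A$tolerances) / 10
    cp <- perturbed_copy(A, noise_sigma = sigma, seed = sample.int(1e6, 1))
    # verify the construction honestly: every ground-truth pair satisfies
    # the predicate under the inverse of the applied transform
    inv <- invert_transform(cp$transform)
    stopifnot(all(g3ps:::pairs_satisfied(A, cp$pharmacophore,
                                         cp$ground_truth, inv)))
    res <- align(A, cp$pharmacophore, align_config(preset = "fast"))
    expect_identical(res$match_count, 6L)
  }
})

test_that("forbidden-matrix markings strictly increase each iteration", {
  A <- random_pharmacophore(fixture_spec(6, type_alphabet = c("H", "AR"),
                                         seed = 66))
  B <- random_pharmacophore(fixture_spec(6, type_alphabet = c("H", "AR"),
                                         seed = 67))
  gs <- all_guesses(A, B)
  tried <- 0L
  for (g in utils::head(gs, 10)) {
    res <- tryCatch(refine(A, B, g), g3ps_degenerate_error = function(e) NULL)
    if (is.null(res)) next
    tried <- tried + 1L
    expect_true(all(diff(res$f_trace) >= 1))
  }
  expect_gte(tried, 1L)
})

test_that("translation rescue agrees with a grid-search feasibility oracle", {
  # one violated pair with slack elsewhere: rescue must succeed
  A <- pharmacophore("a", c("H", "AR", "HBA", "HBD"),
                     rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4)),
                     tolerances = c(1, 1, 1, 1))
  B <- A
  B$positions[4, ] <- B$positions[4, ] + c(0, 0, 1.2)  # 1.2 > tol 1
  pairs <- cbind(1:4, 1:4)
  tr <- rigid_transform()                  # identity leaves pair 4 violated
  expect_false(all(g3ps:::pairs_satisfied(A, B, pairs, tr)))
  resc <- translation_rescue(A, B, pairs, tr)
  oracle <- grid_rescue_oracle(A, B, pairs, tr)
  expect_true(oracle)
  expect_false(is.null(resc))
  expect_true(all(g3ps:::pairs_satisfied(A, B, pairs, resc)))

  # two pairs violated in opposite directions beyond combined slack: fail
  B2 <- A
  B2$positions[1, ] <- B2$positions[1, ] + c(0, 0, 2.5)
  B2$positions[4, ] <- B2$positions[4, ] - c(0, 0, 2.5)
  expect_null(translation_rescue(A, B2, pairs, tr))
  expect_false(grid_rescue_oracle(A, B2, pairs, tr, extent = 3, step = 0.1))

  # no violation: the transform passes through unchanged
  expect_identical(translation_rescue(A, A, pairs, tr), tr)
})

test_that("align recovers full matches on rigid copies and guards degenerate queries", {
  A <- random_pharmacophore(fixture_spec(7, seed = 68))
  cp <- perturbed_copy(A, seed = 69)
  res <- align(A, cp$pharmacophore, align_config(preset = "fast"))
  expect_identical(res$match_count, 7L)
  expect_lt(res$rmsd, 1e-6)
  expect_identical(classify_fit(A, cp$pharmacophore, res), "full")

  A5 <- random_pharmacophore(fixture_spec(5, seed = 70))
  expect_error(align(A5, cp$pharmacophore, align_config(omitted = 3)),
               class = "g3ps_ambiguous_error")
  # no shared types: clean no-alignment result, not an error
  C <- pharmacophore("c", rep("NI", 4),
                     rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3)),
                     rep(1.5, 4))
  A_noNI <- random_pharmacophore(fixture_spec(5, type_alphabet = c("H", "AR"),
                                              seed = 71))
  res0 <- align(A_noNI, C, align_config(preset = "fast"))
  expect_identical(res0$match_count, 0L)
  expect_false(res0$valid)
})

test_that("align is deterministic and rigid-invariant in match count", {
  A <- random_pharmacophore(fixture_spec(5, seed = 72))
  B <- random_pharmacophore(fixture_spec(5, seed = 73))
  r1 <- align(A, B, align_config(exhaustive = TRUE))
  r2 <- align(A, B, align_config(exhaustive = TRUE))
  expect_identical(r1$pairs, r2$pairs)
  expect_identical(r1$rmsd, r2$rmsd)
  for (s in c(74, 75)) {
    Bt <- transform_pharmacophore(B, random_rigid(s))
    rt <- align(A, Bt, align_config(exhaustive = TRUE))
    expect_identical(rt$match_count, r1$match_count)
  }
})

test_that("exhaustive match count dominates the fast preset and the no-RNG core is pure", {
  withr::local_seed(76)
  for (rep in 1:4) {
    A <- random_pharmacophore(fixture_spec(5, seed = sample.int(1e6, 1)))
    B <- random_pharmacophore(fixture_spec(6, seed = sample.int(1e6, 1)))
    rng_before <- .Random.seed
    fast <- align(A, B, align_config(preset = "fast"))
    exh <- align(A, B, align_config(exhaustive = TRUE))
    expect_identical(.Random.seed, rng_before)  # aligners never touch the RNG
    expect_gte(exh$match_count, fast$match_count)
    expect_true(fast$match_count == 0L || fast$match_count >= 3L)
  }
})
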