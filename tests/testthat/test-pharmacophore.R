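test_that("feature matching uses type equality and the strict larger-tolerance rule", {
  a <- list(type = "H", position = c(0, 0, 0), tolerance = 1.5)
  expect_true(features_match(a, a))
  b <- list(type = "H", position = c(1.4, 0, 0), tolerance = 1.0)
  expect_true(features_match(a, b))                     # 1.4 < max(1.5, 1.0)
  expect_false(features_match(list(type = "AR", position = c(0, 0, 0),
                                   tolerance = 1.5), b = a))
  # boundary equality fails: distance exactly max tolerance
  c <- list(type = "H", position = c(1.5, 0, 0), tolerance = 1.0)
  expect_false(features_match(a, c))
  # symmetry: max() makes the predicate symmetric under a shared frame
  expect_identical(features_match(a, b), features_match(b, a))
})

test_that("exclusion clearance is a strict inequality and vacuous without atoms", {
  exc <- list(centers = rbind(c(0, 0, 0)), radii = 2)
  expect_true(exclusion_ok(NULL, exc))
  expect_true(exclusion_ok(matrix(numeric(), 0, 3), exc))
  expect_false(exclusion_ok(rbind(c(2, 0, 0)), exc))    # exactly on surface
  expect_true(exclusion_ok(rbind(c(2.1, 0, 0)), exc))
  expect_false(exclusion_ok(rbind(c(0, 0, 0)), exc))
})

test_that("fit classification distinguishes full, maximum, partial and none", {
  A5 <- random_pharmacophore(fixture_spec(5, seed = 11))
  B5 <- random_pharmacophore(fixture_spec(5, seed = 12))
  B8 <- random_pharmacophore(fixture_spec(8, seed = 13))
  res <- function(mc) list(match_count = mc)
  expect_identical(classify_fit(A5, B5, res(5)), "full")
  expect_identical(classify_fit(A5, B8, res(5)), "maximum")
  A6 <- random_pharmacophore(fixture_spec(6, seed = 14))
  expect_identical(classify_fit(A6, B8, res(4), omitted = 2), "partial")
  expect_identical(classify_fit(A6, B8, res(3), omitted = 2), "none")
})

test_that("pharmacophore constructor enforces invariants", {
  expect_error(pharmacophore("x", "H", c(0, 0, 0), tolerances = 0),
               "positive")
  expect_error(pharmacophore("x", "XV", c(0, 0, 0), tolerances = 1),
               "reserved")
  expect_error(pharmacophore("x", "H", c(0, 0, 0), tolerances = 1,
                             directions = rbind(c(2, 0, 0))),
               "unit length")
  expect_error(alignment_result(rigid_transform(),
                                rbind(c(1L, 1L), c(1L, 2L))),
               "one-to-one")
})

test_that("rigid transforms compose, invert, and preserve internal distances", {
  pts <- matrix(stats::rnorm(30), 10, 3)
  for (s in 1:5) {
    f <- random_rigid(s); g <- random_rigid(s + 100)
    fg <- compose_transforms(f, g)
    expect_equal(transform_points(fg, pts),
                 transform_points(f, transform_points(g, pts)),
                 tolerance = 1e-12)
    roundtrip <- transform_points(invert_transform(f),
                                  transform_points(f, pts))
    expect_equal(roundtrip, pts, tolerance = 1e-9)
    d0 <- dist(pts); d1 <- dist(transform_points(fg, pts))
    expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  }
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper rotation")
  expect_error(rigid_transform(diag(c(2, 1, 1))), "orthonormal")
})

test_that("transform_pharmacophore moves features, directions, exclusions and atoms", {
  p <- toy_pharmacophore()
  p$exclusions <- list(centers = rbind(c(5, 5, 5)), radii = 1)
  p$atoms <- rbind(c(1, 2, 3))
  tr <- random_rigid(7)
  q <- transform_pharmacophore(p, tr)
  expect_equal(q$positions, transform_points(tr, p$positions))
  expect_equal(q$atoms, transform_points(tr, p$atoms))
  expect_equal(q$exclusions$centers, transform_points(tr, p$exclusions$centers))
  # directions rotate without translation and stay unit length
  expect_equal(as.numeric(q$directions[2, ]),
               as.numeric(tr$rotation %*% p$directions[2, ]))
  expect_equal(sqrt(sum(q$directions[2, ]^2)), 1, tolerance = 1e-12)
})
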