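test_that("feature encodings list every other feature with its label and distance", {
  single <- pharmacophore("s", "H", c(0, 0, 0), 1.5)
  enc <- encode_features(single)
  expect_length(enc, 1L)
  expect_length(enc[[1]]$neighbour_distances, 0L)

  two <- pharmacophore("t", c("H", "AR"), rbind(c(0, 0, 0), c(3, 0, 0)),
                       c(1.5, 1.5))
  enc <- encode_features(two)
  expect_equal(as.numeric(enc[[1]]$neighbour_distances), 3)
  expect_identical(enc[[1]]$neighbour_types, "AR")
  expect_equal(as.numeric(enc[[2]]$neighbour_distances), 3)

  four <- random_pharmacophore(fixture_spec(4, seed = 41))
  expect_true(all(lengths(lapply(encode_features(four),
                                 `[[`, "neighbour_distances")) == 3L))
})

test_that("encoding dissimilarity: identical surroundings cost 0, type clash is invalid, large gaps clamp at 1", {
  p <- random_pharmacophore(fixture_spec(5, seed = 42))
  enc <- encode_features(p)
  for (i in seq_len(5)) {
    expect_equal(encoding_dissimilarity(enc[[i]], enc[[i]], 5), 0)
  }
  ar <- list(owner_type = "AR", owner_tolerance = 1, neighbour_types = "H",
             neighbour_distances = 1, neighbour_tolerances = 1)
  h <- list(owner_type = "H", owner_tolerance = 1, neighbour_types = "H",
            neighbour_distances = 1, neighbour_tolerances = 1)
  expect_true(is.na(encoding_dissimilarity(ar, h, 2)))
  # one neighbour 10 A off with tolerance sums 3: per-pair cost clamps at 1
  far <- list(owner_type = "H", owner_tolerance = 1.5, neighbour_types = "H",
              neighbour_distances = 11, neighbour_tolerances = 1.5)
  near <- list(owner_type = "H", owner_tolerance = 1.5, neighbour_types = "H",
               neighbour_distances = 1, neighbour_tolerances = 1.5)
  expect_equal(encoding_dissimilarity(far, near, 2), 1 / 2)
  expect_error(encoding_dissimilarity(h, h, 0), "positive")
})

test_that("dissimilarity matrix: sentinel iff type mismatch, entries in [0,1], zero diagonal against rigid copies", {
  withr::local_seed(43)
  for (rep in 1:8) {
    A <- random_pharmacophore(fixture_spec(sample(3:6, 1),
                                           seed = sample.int(1e6, 1)))
    B <- random_pharmacophore(fixture_spec(sample(3:6, 1),
                                           seed = sample.int(1e6, 1)))
    M <- build_dissimilarity_matrix(A, B)
    mismatch <- outer(A$types, B$types, "!=")
    expect_identical(is.na(unclass(M)), mismatch)
    expect_true(all(M[!is.na(M)] >= 0 & M[!is.na(M)] <= 1))
  }
  # rigid motion leaves internal distances, hence the encoding, unchanged
  A <- random_pharmacophore(fixture_spec(6, seed = 44))
  Bt <- transform_pharmacophore(A, random_rigid(45))
  M <- build_dissimilarity_matrix(A, Bt)
  expect_equal(unname(diag(unclass(M))), rep(0, 6), tolerance = 1e-9)
})

test_that("matrix entries agree with a brute-force neighbour-assignment enumerator", {
  A <- random_pharmacophore(fixture_spec(4, seed = 46))
  B <- random_pharmacophore(fixture_spec(5, seed = 47))
  M <- build_dissimilarity_matrix(A, B)
  encA <- encode_features(A); encB <- encode_features(B)
  normalizer <- 5
  for (i in 1:4) for (j in 1:5) {
    if (A$types[i] != B$types[j]) next
    # rebuild the padded neighbour-cost grid and minimize by enumeration
    da <- encA[[i]]$neighbour_distances; db <- encB[[j]]$neighbour_distances
    k <- max(length(da), length(db))
    grid <- matrix(1, k, k)
    for (p in seq_along(da)) for (q in seq_along(db)) {
      if (encA[[i]]$neighbour_types[p] == encB[[j]]$neighbour_types[q]) {
        D <- max(A$tolerances[i] + encA[[i]]$neighbour_tolerances[p],
                 B$tolerances[j] + encB[[j]]$neighbour_tolerances[q])
        grid[p, q] <- min(1, abs(da[p] - db[q]) / D)
      }
    }
    expect_equal(M[i, j], perm_assignment_oracle(grid) / normalizer,
                 tolerance = 1e-12)
  }
})
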