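# Synthetic pharmacophore generators. All randomness is locally seeded:
# identical specs produce identical fixtures and the caller's RNG state is
# never disturbed. The alignment algorithms themselves are deterministic
# and RNG-free; only fixture generation draws random numbers.

#' Specification for a random synthetic pharmacophore
#'
#' Defaults emulate structure-based screening models: a handful of
#' features drawn from the six standard interaction types, spread over a
#' binding-site-sized box with at least bonded-atom separation, and
#' tolerance radii in the range typical of screening queries (1--2 A).
#'
#' @param n_features number of features (>= 1).
#' @param type_alphabet feature type codes to draw from, uniformly.
#' @param bbox cubic box edge length in Angstrom (default 10).
#' @param tolerance_range two-element range for uniform tolerance radii
#'   (default `c(1, 2)` A).
#' @param noise_sigma default positional noise (A) used by consumers.
#' @param seed integer RNG seed; identical specs give identical fixtures.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_features,
                         type_alphabet = c("H", "AR", "HBA", "HBD", "PI", "NI"),
                         bbox = 10, tolerance_range = c(1, 2),
                         noise_sigma = 0, seed = 1L) {
  stopifnot(n_features >= 1L, bbox > 0, length(tolerance_range) == 2L,
            tolerance_range[1L] > 0,
            tolerance_range[2L] >= tolerance_range[1L])
  structure(list(n_features = as.integer(n_features),
                 type_alphabet = type_alphabet, bbox = bbox,
                 tolerance_range = tolerance_range,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a random pharmacophore
#'
#' Feature positions are sampled uniformly in the box with a minimum
#' inter-feature separation of 1.5 A (rejection sampling), types uniformly
#' from the alphabet, tolerances uniformly from the configured range.
#'
#' @param spec a [fixture_spec()].
#' @param name model name (default derived from the seed).
#' @return a [pharmacophore()].
#' @export
random_pharmacophore <- function(spec, name = sprintf("rand-%d", spec$seed)) {
  withr::with_seed(spec$seed, random_pharmacophore_impl(spec, name))
}

random_pharmacophore_impl <- function(spec, name) {
  n <- spec$n_features
  pos <- matrix(NA_real_, n, 3L)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > 1e4) {
      stop(g3ps_error("g3ps_fixture_error", sprintf(
        "could not place %d features at 1.5 A separation in a %g A box after 1e4 attempts",
        n, spec$bbox)))
    }
    cand <- stats::runif(3L, 0, spec$bbox)
    if (placed == 0L ||
        min(sqrt(rowSums(sweep(pos[seq_len(placed), , drop = FALSE],
                               2L, cand, "-")^2))) >= 1.5) {
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
  }
  pharmacophore(
    name = name,
    types = sample(spec$type_alphabet, n, replace = TRUE),
    positions = pos,
    tolerances = stats::runif(n, spec$tolerance_range[1L],
                              spec$tolerance_range[2L]))
}

# Uniform random rotation from a normalized Gaussian quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

#' Rigidly transformed, noisy, feature-dropped copy with ground truth
#'
#' Produces a screening "active": the input model moved by a random rigid
#' transform, optionally with isotropic Gaussian positional noise, with
#' `drop_k` randomly deleted features, and with the surviving features
#' randomly reordered. The returned ground truth maps original feature
#' indices to their indices in the copy, enabling recovery tests.
#'
#' @param P source [pharmacophore()].
#' @param rigid apply a random rotation + translation (default `TRUE`).
#' @param noise_sigma isotropic positional noise s.d. in Angstrom.
#' @param drop_k number of features to delete (< `|P|`).
#' @param seed integer RNG seed.
#' @param name name for the copy.
#' @return list with `pharmacophore`, `ground_truth` (matrix with columns
#'   `i` = original index, `j` = index in the copy), and `transform` (the
#'   applied [rigid_transform()]).
#' @export
perturbed_copy <- function(P, rigid = TRUE, noise_sigma = 0, drop_k = 0L,
                           seed = 1L, name = paste0(P$name, "-copy")) {
  stopifnot(drop_k < n_features(P))
  withr::with_seed(seed,
                   perturbed_copy_impl(P, rigid, noise_sigma, drop_k, name))
}

perturbed_copy_impl <- function(P, rigid, noise_sigma, drop_k, name) {
  n <- n_features(P)
  keep <- sort(sample(n, n - drop_k))
  perm <- sample(length(keep))              # position of each kept feature
  tr <- if (rigid) {
    rigid_transform(random_rotation(), stats::runif(3L, -5, 5))
  } else {
    rigid_transform()
  }
  pos <- transform_points(tr, P$positions[keep, , drop = FALSE])
  if (noise_sigma > 0) {
    pos <- pos + matrix(stats::rnorm(length(pos), 0, noise_sigma), ncol = 3L)
  }
  ord <- order(perm)
  dirs <- P$directions[keep, , drop = FALSE]
  has_dir <- stats::complete.cases(dirs)
  if (any(has_dir)) {
    dirs[has_dir, ] <- dirs[has_dir, , drop = FALSE] %*% t(tr$rotation)
  }
  copy <- pharmacophore(
    name = name,
    types = P$types[keep][ord],
    positions = pos[ord, , drop = FALSE],
    tolerances = P$tolerances[keep][ord],
    directions = dirs[ord, , drop = FALSE],
    optional = P$optional[keep][ord])
  list(pharmacophore = copy,
       ground_truth = cbind(i = keep, j = perm),
       transform = tr)
}

#' Deterministic exclusion-volume clash scenarios
#'
#' Constructs a query with one exclusion sphere and a target (an exact
#' copy of the query features, carrying molecule atoms) whose pose under
#' the identity alignment clashes with that sphere. With
#' `fixable = TRUE` the clash is 0.1 A deep while every matched pair has
#' over 1 A of tolerance slack, so a small dodging translation resolves
#' it; with `fixable = FALSE` the atom sits at the feature centroid deep
#' inside a large sphere, so any clearing translation breaks the feature
#' tolerances.
#'
#' @param fixable logical.
#' @return list with `query` and `target` [pharmacophore()] objects.
#' @export
clash_scenario <- function(fixable = TRUE) {
  types <- c("H", "AR", "HBA", "HBD")
  pos <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4))
  tol <- rep(1.5, 4L)
  if (fixable) {
    centre <- c(8, 8, 8)
    radius <- 2
    atom <- centre + c(0, 0, radius - 0.1)  # 0.1 A inside the sphere
  } else {
    centre <- colMeans(pos)
    radius <- 5
    atom <- centre                          # 5 A deep: unclearable
  }
  query <- pharmacophore("clash-query", types, pos, tol,
                         exclusions = list(centers = rbind(centre),
                                           radii = radius))
  target <- pharmacophore("clash-target", types, pos, tol,
                          atoms = rbind(atom))
  list(query = query, target = target)
}

#' Build a synthetic screening library with known hit labels
#'
#' Emulates a conformer-ensemble actives/decoys screen: for each "active"
#' molecule, conformer entries are perturbed copies of the query (rigid
#' motion + positional noise); "decoy" molecules are unrelated random
#' pharmacophores of the same size. Ground-truth activity is the
#' construction label, not a guarantee that an alignment exists under the
#' chosen noise.
#'
#' @param query query [pharmacophore()].
#' @param n_active number of active molecules.
#' @param n_decoy number of decoy molecules.
#' @param conformers conformer entries per molecule.
#' @param noise_sigma positional noise for active conformers (A).
#' @param seed integer RNG seed.
#' @return list with `library` (list of [pharmacophore()]) and `truth`
#'   (data frame: `molecule`, `active`).
#' @export
synthetic_library <- function(query, n_active = 20L, n_decoy = 80L,
                              conformers = 1L, noise_sigma = 0.1,
                              seed = 1L) {
  lib <- list()
  truth <- list()
  for (a in seq_len(n_active)) {
    mol <- sprintf("active-%03d", a)
    for (cf in seq_len(conformers)) {
      cp <- perturbed_copy(query, noise_sigma = noise_sigma,
                           seed = seed + 7919L * a + cf, name = mol)
      p <- cp$pharmacophore
      p$conformer <- as.character(cf)
      lib[[length(lib) + 1L]] <- p
    }
    truth[[length(truth) + 1L]] <- data.frame(molecule = mol, active = TRUE)
  }
  for (d in seq_len(n_decoy)) {
    mol <- sprintf("decoy-%03d", d)
    spec <- fixture_spec(n_features = n_features(query),
                         seed = seed + 104729L + d)
    for (cf in seq_len(conformers)) {
      p <- random_pharmacophore(
        fixture_spec(n_features = spec$n_features, seed = spec$seed + cf),
        name = mol)
      p$conformer <- as.character(cf)
      lib[[length(lib) + 1L]] <- p
    }
    truth[[length(truth) + 1L]] <- data.frame(molecule = mol, active = FALSE)
  }
  list(library = lib, truth = do.call(rbind, truth))
}
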