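#' Screen a pharmacophore library against a query
#'
#' Aligns every library entry to the query and classifies hits. A library
#' entry is typically one conformer pharmacophore; entries sharing a
#' `name` are treated as conformers of one molecule, and a molecule counts
#' as a hit when any of its conformers yields a valid alignment matching
#' at least `|query| - omitted` features after post-filters. The full
#' guess budget is refined for every entry regardless of the omitted
#' budget, so the greedy search's effort (refinement and Kabsch call
#' counts, reported per entry) depends only on the guess budget — the
#' omitted budget enters hit classification alone.
#'
#' @param query query [pharmacophore()].
#' @param library list of target [pharmacophore()] objects.
#' @param config an [align_config()] (guess budget / preset, omitted
#'   budget, exhaustive flag).
#' @param algorithm `"g3ps"` (greedy 3-point search) or `"rmm"` (baseline).
#' @param post a [post_filter_config()] applied to every alignment.
#' @param rmm an [rmm_config()] (used when `algorithm = "rmm"`).
#' @return object of class `screen_result`: list with
#'   \describe{
#'     \item{hits}{data frame, one row per hit molecule: `molecule`,
#'       `conformer` (best), `match_count`, `rmsd`.}
#'     \item{per_entry}{data frame, one row per library entry: `molecule`,
#'       `conformer`, `match_count`, `rmsd`, `valid`, `hit`,
#'       `refine_calls`, `kabsch_calls`.}
#'     \item{alignments}{list of the per-entry `pharm_alignment` objects.}
#'     \item{metrics}{totals: `refine_calls`, `kabsch_calls`, `n_entries`,
#'       `n_hits`.}
#'   }
#' @examples
#' q <- random_pharmacophore(fixture_spec(n_features = 5, seed = 1))
#' lib <- list(perturbed_copy(q, seed = 2)$pharmacophore,
#'             random_pharmacophore(fixture_spec(n_features = 5, seed = 3)))
#' screen(q, lib, align_config(preset = "fast"))
#' @export
screen <- function(query, library, config = align_config(),
                   algorithm = c("g3ps", "rmm"),
                   post = post_filter_config(), rmm = rmm_config()) {
  algorithm <- match.arg(algorithm)
  nq <- n_features(query)
  if (nq - config$omitted < 3L) stop_ambiguous(nq, config$omitted)
  min_needed <- nq - config$omitted
  rows <- vector("list", length(library))
  aligns <- vector("list", length(library))
  for (e in seq_along(library)) {
    entry <- library[[e]]
    counters <- new_counters()
    res <- if (algorithm == "g3ps") {
      r <- align(query, entry, config, counters)
      post_process(r, query, entry, post, min_required = min_needed)
    } else {
      rmm_align(query, entry, omitted = config$omitted, config = rmm,
                post = post, counters = counters)
    }
    hit <- res$valid && res$match_count >= min_needed
    aligns[[e]] <- res
    rows[[e]] <- data.frame(
      molecule = entry$name,
      conformer = entry$conformer,
      match_count = res$match_count,
      rmsd = res$rmsd,
      valid = res$valid,
      hit = hit,
      refine_calls = counters$refine_calls,
      kabsch_calls = counters$kabsch_calls,
      stringsAsFactors = FALSE)
  }
  per_entry <- do.call(rbind, rows)
  if (is.null(per_entry)) {
    per_entry <- data.frame(molecule = character(), conformer = character(),
                            match_count = integer(), rmsd = numeric(),
                            valid = logical(), hit = logical(),
                            refine_calls = integer(), kabsch_calls = integer(),
                            stringsAsFactors = FALSE)
  }
  hit_rows <- per_entry[per_entry$hit, , drop = FALSE]
  hits <- if (nrow(hit_rows) > 0L) {
    # best conformer per molecule: most matches, then smallest RMSD
    ord <- order(hit_rows$molecule, -hit_rows$match_count, hit_rows$rmsd)
    hit_rows <- hit_rows[ord, , drop = FALSE]
    hit_rows[!duplicated(hit_rows$molecule),
             c("molecule", "conformer", "match_count", "rmsd"), drop = FALSE]
  } else {
    data.frame(molecule = character(), conformer = character(),
               match_count = integer(), rmsd = numeric(),
               stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  structure(list(hits = hits, per_entry = per_entry, alignments = aligns,
                 metrics = list(refine_calls = sum(per_entry$refine_calls),
                                kabsch_calls = sum(per_entry$kabsch_calls),
                                n_entries = nrow(per_entry),
                                n_hits = nrow(hits))),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Pharmacophore screen: %d entr%s, %d hit molecule(s)\n",
              x$metrics$n_entries,
              if (x$metrics$n_entries == 1L) "y" else "ies",
              x$metrics$n_hits))
  cat(sprintf("  effort: %d refinement call(s), %d Kabsch call(s)\n",
              x$metrics$refine_calls, x$metrics$kabsch_calls))
  if (nrow(x$hits) > 0L) print(utils::head(x$hits, 10L))
  invisible(x)
}

#' Write a screening hit table to TSV
#'
#' Columns: molecule, conformer, match_count, rmsd, and the flattened 3x4
#' transform matrix (rotation columns then translation, 4 decimals).
#'
#' @param result a `screen_result` from [screen()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(result, path) {
  pe <- result$per_entry
  hit_idx <- which(pe$hit)
  mat <- vapply(hit_idx, function(e) {
    tr <- result$alignments[[e]]$transform
    paste(sprintf("%.4f", c(tr$rotation, tr$translation)), collapse = ",")
  }, character(1))
  out <- cbind(pe[hit_idx, c("molecule", "conformer", "match_count", "rmsd"),
                  drop = FALSE],
               matrix = mat)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
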