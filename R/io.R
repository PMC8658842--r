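# File formats. Two representations are supported:
#
# * Native JSON: a single object with "name", "features" (list of
#   {type, position, tolerance, direction?, optional?}), "exclusions"
#   (list of {center, radius}), "atoms" (list of [x,y,z]) and "conformer".
#   Numbers are written at full precision, so JSON round-trips are
#   lossless.
#
# * phar dialect: a minimal line-oriented text format, one record per
#   line, models terminated by "$$$$". Records:
#       NAME <name>                         (optional, first line)
#       CONF <conformer id>                 (optional)
#       <CODE> x y z tolerance hasDir nx ny nz
#       EXCL x y z radius
#       ATOM x y z
#   Coordinates are written with 4 decimals, so phar round-trips are exact
#   to 1e-4 A. Multiple concatenated models form a library file.

phar_num <- function(x) sprintf("%.4f", x)

pharmacophore_to_phar <- function(p) {
  lines <- character()
  if (nzchar(p$name)) lines <- c(lines, paste("NAME", p$name))
  if (!is.na(p$conformer)) lines <- c(lines, paste("CONF", p$conformer))
  for (i in seq_len(n_features(p))) {
    dir <- p$directions[i, ]
    has_dir <- all(is.finite(dir))
    if (!has_dir) dir <- c(0, 0, 0)
    lines <- c(lines, paste(p$types[[i]],
                            paste(phar_num(p$positions[i, ]), collapse = " "),
                            phar_num(p$tolerances[[i]]),
                            if (has_dir) 1L else 0L,
                            paste(phar_num(dir), collapse = " ")))
  }
  if (!is.null(p$exclusions)) {
    for (s in seq_along(p$exclusions$radii)) {
      lines <- c(lines, paste("EXCL",
                              paste(phar_num(p$exclusions$centers[s, ]),
                                    collapse = " "),
                              phar_num(p$exclusions$radii[s])))
    }
  }
  if (!is.null(p$atoms)) {
    for (a in seq_len(nrow(p$atoms))) {
      lines <- c(lines, paste("ATOM",
                              paste(phar_num(p$atoms[a, ]), collapse = " ")))
    }
  }
  c(lines, "$$$$")
}

parse_error <- function(line_no, line, why) {
  stop(g3ps_error("g3ps_parse_error",
                  sprintf("parse error at line %d (%s): %s", line_no, why,
                          line),
                  line = line_no))
}

parse_num <- function(tok, line_no, line) {
  v <- suppressWarnings(as.numeric(tok))
  if (any(is.na(v))) parse_error(line_no, line, "non-numeric field")
  v
}

# Parse one model from lines[from..]; returns list(pharmacophore, next_line)
# or NULL at end of input. line offset is for error reporting.
parse_phar_model <- function(lines, from, known_types, strict) {
  name <- ""; conformer <- NA_character_
  types <- character(); pos <- NULL; tol <- numeric(); dirs <- NULL
  exc_c <- NULL; exc_r <- numeric(); atoms <- NULL
  i <- from
  seen_any <- FALSE
  while (i <= length(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) { i <- i + 1L; next }
    seen_any <- TRUE
    if (ln == "$$$$") {
      i <- i + 1L
      p <- pharmacophore(name, types,
                         if (is.null(pos)) matrix(numeric(), 0L, 3L) else pos,
                         tol,
                         directions = dirs,
                         exclusions = if (length(exc_r)) {
                           list(centers = exc_c, radii = exc_r)
                         },
                         atoms = atoms, conformer = conformer)
      return(list(pharmacophore = p, next_line = i))
    }
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    rec <- tok[[1L]]
    if (rec == "NAME") {
      name <- paste(tok[-1L], collapse = " ")
    } else if (rec == "CONF") {
      conformer <- paste(tok[-1L], collapse = " ")
    } else if (rec == "EXCL") {
      if (length(tok) != 5L) parse_error(i, ln, "EXCL needs x y z radius")
      v <- parse_num(tok[2:5], i, ln)
      if (v[4L] <= 0) parse_error(i, ln, "exclusion radius must be positive")
      exc_c <- rbind(exc_c, v[1:3]); exc_r <- c(exc_r, v[4L])
    } else if (rec == "ATOM") {
      if (length(tok) != 4L) parse_error(i, ln, "ATOM needs x y z")
      atoms <- rbind(atoms, parse_num(tok[2:4], i, ln))
    } else {
      if (strict && !(rec %in% known_types)) {
        parse_error(i, ln, sprintf("unknown feature code '%s'", rec))
      }
      if (length(tok) != 9L) {
        parse_error(i, ln, "feature record needs CODE x y z tol hasDir nx ny nz")
      }
      v <- parse_num(tok[2:9], i, ln)
      if (v[4L] <= 0) parse_error(i, ln, "tolerance must be positive")
      types <- c(types, rec)
      pos <- rbind(pos, v[1:3]); tol <- c(tol, v[4L])
      d <- if (v[5L] != 0) {
        u <- v[6:8]
        nu <- sqrt(sum(u^2))
        if (nu == 0) parse_error(i, ln, "directed feature with zero vector")
        u / nu
      } else {
        c(NA_real_, NA_real_, NA_real_)
      }
      dirs <- rbind(dirs, d)
    }
    i <- i + 1L
  }
  if (!seen_any) return(NULL)
  parse_error(length(lines), "<end of file>", "missing $$$$ terminator")
}

default_feature_codes <- c("H", "AR", "HBA", "HBD", "PI", "NI")

pharmacophore_from_json_obj <- function(obj) {
  feats <- obj$features
  n <- length(feats)
  types <- vapply(feats, function(f) f$type, character(1))
  pos <- if (n) t(vapply(feats, function(f) as.numeric(f$position),
                         numeric(3))) else matrix(numeric(), 0L, 3L)
  tol <- vapply(feats, function(f) as.numeric(f$tolerance), numeric(1))
  dirs <- if (n) t(vapply(feats, function(f) {
    if (is.null(f$direction)) c(NA_real_, NA_real_, NA_real_)
    else as.numeric(f$direction)
  }, numeric(3))) else NULL
  optional <- vapply(feats, function(f) isTRUE(f$optional), logical(1))
  exc <- NULL
  if (length(obj$exclusions)) {
    exc <- list(centers = t(vapply(obj$exclusions,
                                   function(s) as.numeric(s$center),
                                   numeric(3))),
                radii = vapply(obj$exclusions,
                               function(s) as.numeric(s$radius), numeric(1)))
  }
  atoms <- if (length(obj$atoms)) {
    t(vapply(obj$atoms, as.numeric, numeric(3)))
  }
  pharmacophore(name = if (is.null(obj$name)) "" else obj$name,
                types = types, positions = pos, tolerances = tol,
                directions = dirs, optional = optional,
                exclusions = exc, atoms = atoms,
                conformer = if (is.null(obj$conformer)) NA_character_
                            else obj$conformer)
}

pharmacophore_to_json_obj <- function(p) {
  feats <- lapply(seq_len(n_features(p)), function(i) {
    f <- list(type = p$types[[i]],
              position = p$positions[i, ],
              tolerance = p$tolerances[[i]])
    if (all(is.finite(p$directions[i, ]))) f$direction <- p$directions[i, ]
    if (isTRUE(p$optional[[i]])) f$optional <- TRUE
    f
  })
  obj <- list(name = p$name, features = feats)
  if (!is.null(p$exclusions) && length(p$exclusions$radii)) {
    obj$exclusions <- lapply(seq_along(p$exclusions$radii), function(s) {
      list(center = p$exclusions$centers[s, ],
           radius = p$exclusions$radii[s])
    })
  }
  if (!is.null(p$atoms) && nrow(p$atoms)) {
    obj$atoms <- lapply(seq_len(nrow(p$atoms)), function(a) p$atoms[a, ])
  }
  if (!is.na(p$conformer)) obj$conformer <- p$conformer
  obj
}

#' Read and write pharmacophore files
#'
#' Two formats are supported: the native JSON schema (lossless) and the
#' line-oriented phar dialect (4-decimal fixed precision, exact to
#' 1e-4 A). The format is inferred from the file extension (`.json` /
#' anything else = phar) unless given explicitly.
#'
#' @param path file path.
#' @param format `"json"` or `"phar"`; `NULL` to infer from the extension.
#' @param strict reject unknown feature type codes instead of passing them
#'   through as custom types (default `FALSE`).
#' @return [read_pharmacophore()] returns a [pharmacophore()];
#'   [write_pharmacophore()] returns `path` invisibly.
#' @export
read_pharmacophore <- function(path, format = NULL, strict = FALSE) {
  format <- infer_format(path, format)
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    p <- pharmacophore_from_json_obj(obj)
    if (strict) check_known_codes(p)
    p
  } else {
    lines <- readLines(path)
    parsed <- parse_phar_model(lines, 1L, default_feature_codes, strict)
    if (is.null(parsed)) {
      pharmacophore()
    } else {
      parsed$pharmacophore
    }
  }
}

#' @rdname read_pharmacophore
#' @param p a [pharmacophore()] to write.
#' @export
write_pharmacophore <- function(p, path, format = NULL) {
  format <- infer_format(path, format)
  if (format == "json") {
    jsonlite::write_json(pharmacophore_to_json_obj(p), path,
                         auto_unbox = TRUE, digits = I(17))
  } else {
    writeLines(pharmacophore_to_phar(p), path)
  }
  invisible(path)
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("json", "phar")))
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "phar"
}

check_known_codes <- function(p) {
  bad <- setdiff(unique(p$types), default_feature_codes)
  if (length(bad)) {
    stop(g3ps_error("g3ps_parse_error",
                    sprintf("unknown feature code(s): %s",
                            paste(bad, collapse = ", "))))
  }
  invisible(p)
}

#' Read and write pharmacophore libraries
#'
#' A library is either a concatenation of phar models (each terminated by
#' `$$$$`) or a JSON-lines file (`.jsonl`, one JSON model per line).
#'
#' @param path file path (`.jsonl` = JSON lines, otherwise phar).
#' @param strict reject unknown feature codes.
#' @return [read_pharmacophore_library()] returns a list of
#'   [pharmacophore()]; [write_pharmacophore_library()] returns `path`
#'   invisibly.
#' @export
read_pharmacophore_library <- function(path, strict = FALSE) {
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    lapply(lines, function(ln) {
      pharmacophore_from_json_obj(jsonlite::fromJSON(ln,
                                                     simplifyVector = FALSE))
    })
  } else {
    lines <- readLines(path)
    out <- list()
    i <- 1L
    repeat {
      parsed <- parse_phar_model(lines, i, default_feature_codes, strict)
      if (is.null(parsed)) break
      out[[length(out) + 1L]] <- parsed$pharmacophore
      i <- parsed$next_line
    }
    out
  }
}

#' @rdname read_pharmacophore_library
#' @param library list of [pharmacophore()] objects.
#' @export
write_pharmacophore_library <- function(library, path) {
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) {
    lines <- vapply(library, function(p) {
      as.character(jsonlite::toJSON(pharmacophore_to_json_obj(p),
                                    auto_unbox = TRUE, digits = I(17)))
    }, character(1))
    writeLines(lines, path)
  } else {
    writeLines(unlist(lapply(library, pharmacophore_to_phar)), path)
  }
  invisible(path)
}
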