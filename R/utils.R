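# Shared internal helpers.

#' The five localizer categories, in canonical order
#'
#' Canonical category order used throughout: faces, bodies, pseudowords,
#' places, objects. Partition names and similarity-matrix rows always follow
#' this order.
#'
#' @return Character vector of length 5.
#' @export
rsa_categories <- function() {
  c("faces", "bodies", "pseudowords", "places", "objects")
}

#' The ten localizer subcategories
#'
#' Each category has two subcategories (e.g. child and adult faces), shown
#' in separate stimulus blocks but combined within one contrast.
#'
#' @return Named character vector: names are subcategory condition labels
#'   (`"faces.child"`, ...), values the parent category.
#' @export
rsa_subcategories <- function() {
  subs <- c(
    faces.child = "faces", faces.adult = "faces",
    bodies.whole = "bodies", bodies.limbs = "bodies",
    pseudowords.words = "pseudowords", pseudowords.numbers = "pseudowords",
    places.corridors = "places", places.houses = "places",
    objects.cars = "objects", objects.guitars = "objects"
  )
  subs
}

# single-letter initials used in canonical partition names
category_initials <- function(categories) {
  std <- c(
    faces = "F", bodies = "B", pseudowords = "W", places = "P", objects = "O"
  )
  ifelse(categories %in% names(std), std[categories],
    toupper(substr(categories, 1, 1))
  )
}

check_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  ok <- if (strict_min) x > min else x >= min
  if (!ok) {
    abort(sprintf(
      "`%s` must be %s %s (got %g).", name,
      if (strict_min) ">" else ">=", format(min), x
    ))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    abort(sprintf("`%s` must be a single whole number.", name))
  }
  if (x < min) {
    abort(sprintf("`%s` must be >= %d (got %d).", name, min, as.integer(x)))
  }
  invisible(as.integer(x))
}

# Parse "run<r>_<condition>" column names of a pattern matrix.
parse_pattern_columns <- function(x) {
  cn <- colnames(x)
  if (is.null(cn)) {
    abort("Pattern matrix must have `run<r>_<condition>` column names.")
  }
  m <- regmatches(cn, regexec("^run([0-9]+)_(.+)$", cn))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    abort(sprintf(
      "Malformed pattern column name(s): %s",
      paste(cn[bad], collapse = ", ")
    ))
  }
  tibble(
    column = cn,
    run = as.integer(vapply(m, `[`, character(1), 2L)),
    condition = vapply(m, `[`, character(1), 3L)
  )
}

# Category of each condition label ("faces.child" -> "faces").
condition_category <- function(condition) {
  sub("\\..*$", "", condition)
}

#' Collapse subcategory patterns to category level
#'
#' Averages the two subcategory columns of each category within each run,
#' returning a matrix with columns `run<r>_<category>`.
#'
#' @param x Pattern matrix, vertices x (run x condition), with
#'   `run<r>_<condition>` column names.
#' @return Matrix with one column per run x category.
#' @export
collapse_subcategories <- function(x) {
  info <- parse_pattern_columns(x)
  info$category <- condition_category(info$condition)
  if (all(info$condition == info$category)) {
    return(x)
  }
  keys <- unique(info[, c("run", "category")])
  keys <- keys[order(keys$run, match(keys$category, unique(info$category))), ]
  out <- vapply(seq_len(nrow(keys)), function(i) {
    cols <- info$column[info$run == keys$run[i] &
      info$category == keys$category[i]]
    rowMeans(x[, cols, drop = FALSE])
  }, numeric(nrow(x)))
  colnames(out) <- sprintf("run%d_%s", keys$run, keys$category)
  out
}

# Deterministic per-stream seed derived from a master seed (< 2^31).
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 2654435761 + stream * 97) %% 2147483647
}
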