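# Binary partition models: enumeration, scoring against similarity
# matrices, and ranking.

#' Build a binary partition model
#'
#' A partition model assigns categories to two labeled groups (possibly
#' leaving some categories out) and encodes the assignment as a symmetric
#' binary model matrix: entry (i, j) = 1 when i and j belong to the same
#' group, and (i, i) = 1 when category i belongs to either group.
#'
#' @param group_a,group_b Disjoint, non-empty character vectors of
#'   categories.
#' @param categories All categories, in canonical order (defaults to the
#'   five localizer categories).
#' @return A `partition_model`: list with `name` (canonical label such as
#'   `"FB_WPO"`), `group_a`, `group_b`, `model_matrix`.
#' @export
partition_model <- function(group_a, group_b, categories = rsa_categories()) {
  group_a <- as.character(group_a)
  group_b <- as.character(group_b)
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("Both groups must be non-empty.")
  }
  if (length(intersect(group_a, group_b)) > 0) {
    abort("Groups must be disjoint.")
  }
  if (!all(c(group_a, group_b) %in% categories)) {
    abort("All group members must be known categories.")
  }
  group_a <- categories[categories %in% group_a]
  group_b <- categories[categories %in% group_b]
  # group containing the earliest canonical category listed first
  if (match(group_b[1], categories) < match(group_a[1], categories)) {
    tmp <- group_a
    group_a <- group_b
    group_b <- tmp
  }
  k <- length(categories)
  mm <- matrix(0, k, k, dimnames = list(categories, categories))
  for (g in list(group_a, group_b)) {
    mm[g, g] <- 1
  }
  name <- paste(
    paste(category_initials(group_a), collapse = ""),
    paste(category_initials(group_b), collapse = ""),
    sep = "_"
  )
  structure(
    list(
      name = name, group_a = group_a, group_b = group_b,
      model_matrix = mm, categories = categories
    ),
    class = "partition_model"
  )
}

#' @export
print.partition_model <- function(x, ...) {
  cat(sprintf(
    "<partition_model> %s: {%s} vs {%s}\n", x$name,
    paste(x$group_a, collapse = ", "), paste(x$group_b, collapse = ", ")
  ))
  invisible(x)
}

#' Enumerate candidate partition models
#'
#' Three enumeration families over two-group divisions of the categories,
#' all deduplicated under group swap and returned in a deterministic
#' canonical order:
#' * `"full_bipartition"`: both groups non-empty, every category assigned
#'   (15 models for five categories).
#' * `"disjoint_pairs"`: both groups non-empty, categories may be left out
#'   (90 models).
#' * `"disjoint_pairs_partial"`: as `"disjoint_pairs"` but with at least one
#'   category left out (75 models) — the disjoint pairs that are not full
#'   bipartitions.
#'
#' @param categories Character vector, >= 2 categories.
#' @param mode Enumeration family.
#' @return List of [partition_model()] objects.
#' @examples
#' length(enumerate_partitions(mode = "full_bipartition")) # 15
#' length(enumerate_partitions(mode = "disjoint_pairs")) # 90
#' length(enumerate_partitions(mode = "disjoint_pairs_partial")) # 75
#' @export
enumerate_partitions <- function(categories = rsa_categories(),
                                 mode = c(
                                   "full_bipartition", "disjoint_pairs",
                                   "disjoint_pairs_partial"
                                 )) {
  mode <- match.arg(mode)
  categories <- as.character(categories)
  k <- length(categories)
  if (k < 2) abort("Need >= 2 categories to partition.")
  assign_grid <- expand.grid(rep(list(0:2), k))
  keep <- apply(assign_grid, 1, function(a) any(a == 1) && any(a == 2))
  assign_grid <- assign_grid[keep, , drop = FALSE]
  if (mode == "full_bipartition") {
    assign_grid <- assign_grid[apply(assign_grid, 1, function(a) all(a != 0)), ,
      drop = FALSE
    ]
  } else if (mode == "disjoint_pairs_partial") {
    assign_grid <- assign_grid[apply(assign_grid, 1, function(a) any(a == 0)), ,
      drop = FALSE
    ]
  }
  seen <- character(0)
  models <- list()
  for (i in seq_len(nrow(assign_grid))) {
    a <- as.integer(assign_grid[i, ])
    mod <- partition_model(
      categories[a == 1], categories[a == 2],
      categories
    )
    key <- paste(mod$name)
    if (!key %in% seen) {
      seen <- c(seen, key)
      models[[length(models) + 1L]] <- mod
    }
  }
  # canonical order: larger first group size, then name
  ord <- order(
    -lengths(lapply(models, `[[`, "group_a")),
    vapply(models, `[[`, character(1), "name")
  )
  models[ord]
}

#' Score a partition model against a similarity matrix
#'
#' Pearson correlation between the vectorized unique cells of the
#' (symmetrized) similarity matrix and the corresponding cells of the binary
#' model matrix. With five categories these are the 5 diagonal plus 10
#' unique off-diagonal cells; categories outside both groups contribute
#' cells with model value 0.
#'
#' @param model A [partition_model()].
#' @param sm An `rsa_simmat` (or symmetric matrix) over the model's
#'   categories.
#' @param cells `"all"` (default: diagonal included) or `"offdiag"`
#'   (off-diagonal cells only).
#' @return Correlation (length-1 numeric).
#' @export
score_partition <- function(model, sm, cells = c("all", "offdiag")) {
  cells <- match.arg(cells)
  if (!inherits(model, "partition_model")) {
    abort("`model` must be a partition_model().")
  }
  m <- as_square_matrix(sm)
  if (nrow(m) != length(model$categories)) {
    abort("Similarity matrix and model cover different numbers of categories.")
  }
  include_diag <- cells == "all"
  v_sm <- sim_cells(m, include_diag)
  v_mod <- sim_cells(model$model_matrix, include_diag)
  if (sd(v_sm) == 0 || sd(v_mod) == 0) {
    abort("Degenerate model or matrix: zero variance over scored cells.")
  }
  cor(v_sm, v_mod)
}

#' Rank partition models against a similarity matrix
#'
#' Scores every model with [score_partition()], sorts descending (ties
#' broken by the models' input order) and assigns ranks 1..N and
#' percentiles rank / N.
#'
#' @param models List of [partition_model()] objects (e.g. from
#'   [enumerate_partitions()]).
#' @param sm Similarity matrix to score against.
#' @param cells Passed to [score_partition()].
#' @return A `partition_ranking` tibble: `name`, `group_a`, `group_b`,
#'   `score`, `rank`, `percentile`, ordered by rank.
#' @export
rank_partitions <- function(models, sm, cells = "all") {
  if (length(models) < 2) abort("Need >= 2 models to rank.")
  scores <- vapply(models, score_partition, numeric(1), sm = sm, cells = cells)
  ord <- order(-scores, seq_along(scores))
  n <- length(models)
  out <- tibble(
    name = vapply(models, `[[`, character(1), "name")[ord],
    group_a = vapply(
      models,
      function(m) paste(m$group_a, collapse = ","), character(1)
    )[ord],
    group_b = vapply(
      models,
      function(m) paste(m$group_b, collapse = ","), character(1)
    )[ord],
    score = scores[ord],
    rank = seq_len(n),
    percentile = seq_len(n) / n
  )
  class(out) <- c("partition_ranking", class(out))
  out
}
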