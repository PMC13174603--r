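# Leave-one-run-out cross-validated representational similarity matrices
# and within/between-category and within/between-block statistics.

new_simmat <- function(values, categories, fold_scheme, symmetrized,
                       folds = NULL) {
  dimnames(values) <- list(categories, categories)
  structure(
    values,
    categories = categories, fold_scheme = fold_scheme,
    symmetrized = symmetrized, folds = folds,
    class = c("rsa_simmat", "matrix", "array")
  )
}

#' @export
print.rsa_simmat <- function(x, ...) {
  cat(sprintf(
    "<rsa_simmat> %d x %d, folds: %s%s\n",
    nrow(x), ncol(x), attr(x, "fold_scheme"),
    if (isTRUE(attr(x, "symmetrized"))) ", symmetrized" else ""
  ))
  print(round(unclass(x)[, , drop = FALSE], 3))
  invisible(x)
}

#' Leave-one-run-out cross-validated similarity matrix
#'
#' For each cross-validation fold, the held-out run's pattern for category i
#' is Pearson-correlated with the mean over the remaining runs of category
#' j's pattern; entries are averaged over folds and the matrix is
#' symmetrized by `(M + t(M)) / 2`. The diagonal is within-category
#' cross-run reliability; off-diagonal entries are between-category
#' similarity.
#'
#' @param x Pattern matrix, vertices x (run x condition), with
#'   `run<r>_<condition>` column names (as produced by [generate_cohort()]).
#' @param level `"category"` (default; subcategory columns averaged within
#'   category first) or `"subcategory"`.
#' @param method `"holdout_vs_mean"` (held-out run vs mean of remaining
#'   runs, the default) or `"run_vs_run"` (average over all ordered run
#'   pairs, a sensitivity-check mode).
#' @param fisher If `TRUE`, fold correlations are Fisher-transformed before
#'   averaging and back-transformed afterwards. Default `FALSE`: raw
#'   correlations are averaged.
#' @param keep_folds If `TRUE`, the per-fold symmetrized matrices are kept
#'   in the `folds` attribute (used by the stability/coupling analyses).
#' @return An `rsa_simmat`: a symmetric condition x condition correlation
#'   matrix with metadata attributes.
#' @examples
#' cohort <- generate_cohort(cohort_spec(
#'   n_children = 1, n_adults = 0,
#'   n_vertices = 60, seed = 1
#' ))
#' loro_similarity(cohort$data[[1]])
#' @export
loro_similarity <- function(x, level = c("category", "subcategory"),
                            method = c("holdout_vs_mean", "run_vs_run"),
                            fisher = FALSE, keep_folds = FALSE) {
  level <- match.arg(level)
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) < 3) abort("Need >= 3 vertices to correlate patterns.")
  if (anyNA(x)) abort("Pattern matrix contains missing values.")
  if (level == "category") x <- collapse_subcategories(x)
  info <- parse_pattern_columns(x)
  runs <- sort(unique(info$run))
  conds <- unique(info$condition)
  if (length(runs) < 2) {
    abort("Cross-validation requires >= 2 runs; found a single run.")
  }
  tab <- table(info$run, info$condition)
  if (any(tab != 1)) {
    abort("Every (run, condition) pair must appear exactly once in the columns.")
  }
  col_of <- function(r, cc) info$column[info$run == r & info$condition == cc]
  for (i in seq_len(nrow(info))) {
    if (sd(x[, info$column[i]]) == 0) {
      abort(sprintf(
        "Zero-variance pattern for run %d, condition '%s'.",
        info$run[i], info$condition[i]
      ))
    }
  }
  k <- length(conds)
  avg <- function(m) if (fisher) tanh(mean(atanh(pmin(pmax(m, -1 + 1e-12), 1 - 1e-12)))) else mean(m)

  fold_mats <- lapply(runs, function(r) {
    test <- x[, vapply(conds, function(cc) col_of(r, cc), character(1)),
      drop = FALSE
    ]
    if (method == "holdout_vs_mean") {
      train <- vapply(conds, function(cc) {
        rowMeans(x[, vapply(
          setdiff(runs, r),
          function(r2) col_of(r2, cc), character(1)
        ), drop = FALSE])
      }, numeric(nrow(x)))
      m <- cor(test, train)
    } else {
      per_pair <- lapply(setdiff(runs, r), function(r2) {
        other <- x[, vapply(conds, function(cc) col_of(r2, cc), character(1)),
          drop = FALSE
        ]
        cor(test, other)
      })
      m <- Reduce(`+`, per_pair) / length(per_pair)
    }
    (m + t(m)) / 2
  })

  vals <- array(unlist(fold_mats), dim = c(k, k, length(fold_mats)))
  out <- apply(vals, c(1, 2), avg)
  scheme <- sprintf(
    "LORO over %d runs (%s%s)", length(runs), method,
    if (fisher) ", fisher-averaged" else ""
  )
  new_simmat(
    out, conds, scheme,
    symmetrized = TRUE,
    folds = if (keep_folds) {
      lapply(fold_mats, new_simmat,
        categories = conds,
        fold_scheme = "single fold", symmetrized = TRUE
      )
    } else {
      NULL
    }
  )
}

#' Similarity matrices for every archive in a cohort
#'
#' Maps [loro_similarity()] over the rows of a cohort tibble.
#'
#' @param cohort An `rsa_cohort` tibble (see [generate_cohort()]).
#' @param ... Passed to [loro_similarity()].
#' @return The cohort tibble with the `data`/`roi` columns replaced by a
#'   `sim` list-column of `rsa_simmat` objects.
#' @export
cohort_similarity <- function(cohort, ...) {
  out <- cohort |>
    dplyr::mutate(sim = purrr::map(.data$data, loro_similarity, ...)) |>
    dplyr::select(-dplyr::any_of(c("data", "roi")))
  out
}

#' Within- and between-category similarity summary
#'
#' @param sm An `rsa_simmat` (or plain square matrix).
#' @return One-row tibble: `within_mean` (mean diagonal), `between_mean`
#'   (mean over unique off-diagonal pairs), `difference`.
#' @export
within_between_category <- function(sm) {
  sm <- as_square_matrix(sm)
  off <- sm[upper.tri(sm)]
  tibble(
    within_mean = mean(diag(sm)),
    between_mean = mean(off),
    difference = mean(diag(sm)) - mean(off)
  )
}

as_square_matrix <- function(sm) {
  m <- unclass(sm)
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort("Expected a square similarity matrix.")
  }
  if (any(abs(m) > 1 + 1e-8, na.rm = TRUE)) {
    abort("Similarity entries must lie in [-1, 1].")
  }
  m
}

#' Block schemes over the five categories
#'
#' `block_scheme("animate_inanimate")` groups faces+bodies vs
#' pseudowords+places+objects; `block_scheme("tripartite")` divides
#' animate (faces, bodies), language (pseudowords) and spatial (places,
#' objects) categories. Custom schemes pass `blocks` directly.
#'
#' @param name Scheme name, or any label when `blocks` is supplied.
#' @param blocks Optional named list of category vectors; must be disjoint
#'   and cover all five categories.
#' @return A `block_scheme` object.
#' @export
block_scheme <- function(name = c("animate_inanimate", "tripartite"),
                         blocks = NULL) {
  if (is.null(blocks)) {
    name <- match.arg(name)
    blocks <- switch(name,
      animate_inanimate = list(
        animate = c("faces", "bodies"),
        inanimate = c("pseudowords", "places", "objects")
      ),
      tripartite = list(
        animate = c("faces", "bodies"),
        language = "pseudowords",
        spatial = c("places", "objects")
      )
    )
  }
  cats <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(cats)) abort("Blocks must be disjoint.")
  if (!setequal(cats, rsa_categories())) {
    abort("Blocks must cover exactly the five categories.")
  }
  structure(list(name = name[1], blocks = blocks), class = "block_scheme")
}

#' Within- vs between-block similarity contrast
#'
#' Averages the off-diagonal similarity entries whose two categories share a
#' block versus those that cross blocks. The diagonal (within-category
#' reliability) is excluded.
#'
#' @param sm An `rsa_simmat` over the five categories.
#' @param scheme A [block_scheme()].
#' @return One-row tibble: `within_block_mean`, `between_block_mean`,
#'   `contrast`.
#' @export
block_contrast <- function(sm, scheme) {
  if (!inherits(scheme, "block_scheme")) {
    abort("`scheme` must be a block_scheme().")
  }
  m <- as_square_matrix(sm)
  cats <- rownames(m) %||% rsa_categories()
  block_of <- setNames(
    rep(names(scheme$blocks), lengths(scheme$blocks)),
    unlist(scheme$blocks, use.names = FALSE)
  )
  pairs <- combn(cats, 2)
  same <- block_of[pairs[1, ]] == block_of[pairs[2, ]]
  if (!any(same)) {
    abort("No within-block pairs: every block is a singleton.")
  }
  vals <- m[cbind(pairs[1, ], pairs[2, ])]
  tibble(
    within_block_mean = mean(vals[same]),
    between_block_mean = mean(vals[!same]),
    contrast = mean(vals[same]) - mean(vals[!same])
  )
}

# Vectorize the unique cells of a symmetric k x k similarity or model
# matrix: k diagonal cells then the upper-triangle pairs, in a fixed order.
sim_cells <- function(m, include_diag = TRUE) {
  m <- unclass(m)
  ut <- m[upper.tri(m)]
  if (include_diag) c(diag(m), ut) else ut
}
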