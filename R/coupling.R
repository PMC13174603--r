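# Stability-versus-coupling coordinates: split-half reliability of a
# region's similarity structure (stability) vs its cross-split correlation
# with another region's similarity structure (coupling), the signed
# distance from the identity line, and developmental displacement vectors.

simmat_list_cells <- function(splits) {
  if (length(splits) < 1) abort("Need at least one split matrix.")
  lapply(splits, function(s) {
    v <- sim_cells(as_square_matrix(s))
    if (sd(v) == 0) abort("Constant similarity matrix: correlation undefined.")
    v
  })
}

#' Split-half stability of a region's similarity structure
#'
#' Mean Pearson correlation between the vectorized unique cells of each
#' unordered pair of per-fold similarity matrices from the same region.
#'
#' @param splits List of per-fold `rsa_simmat`s (>= 2), e.g. the `folds`
#'   attribute of `loro_similarity(..., keep_folds = TRUE)`.
#' @return Correlation (length-1 numeric).
#' @export
split_stability <- function(splits) {
  if (length(splits) < 2) abort("Stability needs >= 2 split matrices.")
  cells <- simmat_list_cells(splits)
  pairs <- combn(length(cells), 2)
  mean(vapply(
    seq_len(ncol(pairs)),
    function(j) cor(cells[[pairs[1, j]]], cells[[pairs[2, j]]]),
    numeric(1)
  ))
}

#' Cross-region coupling of similarity structures
#'
#' Mean Pearson correlation over all cross-region split pairs (every split
#' of one region against every split of the other), on vectorized unique
#' cells.
#'
#' @param splits_a,splits_b Lists of per-fold `rsa_simmat`s from the two
#'   regions.
#' @return Correlation (length-1 numeric).
#' @export
cross_coupling <- function(splits_a, splits_b) {
  ca <- simmat_list_cells(splits_a)
  cb <- simmat_list_cells(splits_b)
  mean(vapply(ca, function(va) {
    mean(vapply(cb, function(vb) cor(va, vb), numeric(1)))
  }, numeric(1)))
}

#' Signed distance from the identity line
#'
#' Perpendicular distance of a (coupling, stability) point from the
#' identity line, `(stability - coupling) / sqrt(2)`. Positive values
#' indicate dominance of internal stability over cross-region coupling.
#'
#' @param stability,coupling Numeric vectors.
#' @return Numeric vector.
#' @export
signed_identity_distance <- function(stability, coupling) {
  (stability - coupling) / sqrt(2)
}

#' Per-subject stability-coupling coordinates
#'
#' For every subject x hemisphere, computes the split-half stability of the
#' prefrontal region's leave-one-run-out similarity structure and its
#' cross-split coupling with the posterior region, yielding one
#' (coupling, stability) coordinate per subject and hemisphere plus the
#' signed identity-line distance.
#'
#' @param cohort `rsa_cohort` tibble containing both regions.
#' @param pfc_region,vtc_region Region labels (defaults `"VLPFC"`,
#'   `"VTC"`).
#' @param ... Passed to [loro_similarity()].
#' @return Tibble: `subject_id`, `group`, `hemisphere`, `coupling`,
#'   `stability`, `signed_distance`.
#' @export
coupling_points <- function(cohort, pfc_region = "VLPFC",
                            vtc_region = "VTC", ...) {
  need <- c(pfc_region, vtc_region)
  if (!all(need %in% cohort$region)) {
    abort(sprintf(
      "Cohort must contain both regions (%s).", paste(need, collapse = ", ")
    ))
  }
  cells <- cohort |>
    dplyr::filter(.data$region %in% need) |>
    dplyr::group_by(.data$subject_id, .data$group, .data$hemisphere)
  keys <- dplyr::group_keys(cells)
  splits <- dplyr::group_split(cells)
  purrr::map2(splits, seq_len(nrow(keys)), function(df, i) {
    pfc <- df$data[df$region == pfc_region]
    vtc <- df$data[df$region == vtc_region]
    if (length(pfc) != 1 || length(vtc) != 1) {
      abort("Expected exactly one archive per subject x hemisphere x region.")
    }
    pf <- attr(loro_similarity(pfc[[1]], keep_folds = TRUE, ...), "folds")
    vf <- attr(loro_similarity(vtc[[1]], keep_folds = TRUE, ...), "folds")
    st <- split_stability(pf)
    cp <- cross_coupling(pf, vf)
    dplyr::bind_cols(
      keys[i, ],
      tibble(
        coupling = cp, stability = st,
        signed_distance = signed_identity_distance(st, cp)
      )
    )
  }) |> dplyr::bind_rows()
}

#' Category-level stability-coupling coordinates
#'
#' As [split_stability()] / [cross_coupling()] but restricted, per category,
#' to the cells of that category's row of the similarity matrix (its
#' diagonal cell plus its four between-category cells).
#'
#' @param pfc_splits,vtc_splits Lists of per-fold `rsa_simmat`s.
#' @return Tibble: `category`, `stability`, `coupling`.
#' @export
category_coordinates <- function(pfc_splits, vtc_splits) {
  if (length(pfc_splits) < 2) abort("Stability needs >= 2 split matrices.")
  m1 <- as_square_matrix(pfc_splits[[1]])
  cats <- rownames(m1) %||% rsa_categories()
  row_cells <- function(m, cc) {
    m <- as_square_matrix(m)
    m[cc, ]
  }
  purrr::map(cats, function(cc) {
    pf <- lapply(pfc_splits, row_cells, cc = cc)
    vf <- lapply(vtc_splits, row_cells, cc = cc)
    if (any(vapply(c(pf, vf), sd, numeric(1)) == 0)) {
      abort(sprintf("Constant similarity row for category '%s'.", cc))
    }
    pairs <- combn(length(pf), 2)
    st <- mean(vapply(
      seq_len(ncol(pairs)),
      function(j) cor(pf[[pairs[1, j]]], pf[[pairs[2, j]]]),
      numeric(1)
    ))
    cp <- mean(vapply(pf, function(va) {
      mean(vapply(vf, function(vb) cor(va, vb), numeric(1)))
    }, numeric(1)))
    tibble(category = cc, stability = st, coupling = cp)
  }) |> dplyr::bind_rows()
}

#' Developmental displacement vectors in stability-coupling space
#'
#' Per category, the vector from the child group mean to the adult group
#' mean in (coupling, stability) coordinates, with a group-label permutation
#' test of the displacement magnitude (labels shuffled across subjects,
#' add-one p value).
#'
#' @param points Tibble of per-subject, per-category coordinates with
#'   columns `subject_id`, `group` (`"child"`/`"adult"`), `category`,
#'   `coupling`, `stability`.
#' @param n_permutations Number of group-label permutations (0 = skip the
#'   test).
#' @param seed Integer seed.
#' @return Tibble: `category`, `delta_coupling`, `delta_stability`,
#'   `magnitude`, `p_value`.
#' @export
displacement <- function(points, n_permutations = 1000, seed = 1L) {
  need <- c("subject_id", "group", "category", "coupling", "stability")
  if (!all(need %in% names(points))) {
    abort(sprintf(
      "`points` needs columns %s.", paste(need, collapse = ", ")
    ))
  }
  groups <- points |>
    dplyr::distinct(.data$subject_id, .data$group)
  if (!setequal(unique(groups$group), c("child", "adult"))) {
    abort("`points$group` must contain exactly the groups child and adult.")
  }
  if (n_permutations > 0 && any(table(groups$group) < 2)) {
    abort("Permutation test needs >= 2 subjects per group.")
  }
  vecs_for <- function(grp_of) {
    points |>
      dplyr::mutate(g = grp_of[.data$subject_id]) |>
      dplyr::group_by(.data$category, .data$g) |>
      dplyr::summarise(
        coupling = mean(.data$coupling),
        stability = mean(.data$stability), .groups = "drop"
      ) |>
      tidyr::pivot_wider(
        names_from = "g",
        values_from = c("coupling", "stability")
      ) |>
      dplyr::mutate(
        delta_coupling = .data$coupling_adult - .data$coupling_child,
        delta_stability = .data$stability_adult - .data$stability_child,
        magnitude = sqrt(.data$delta_coupling^2 + .data$delta_stability^2)
      ) |>
      dplyr::select(
        "category", "delta_coupling", "delta_stability", "magnitude"
      )
  }
  grp_of <- setNames(groups$group, groups$subject_id)
  obs <- vecs_for(grp_of)
  if (n_permutations == 0) {
    obs$p_value <- NA_real_
    return(obs)
  }
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  null_mags <- replicate(n_permutations, {
    perm <- setNames(sample(groups$group), groups$subject_id)
    vecs_for(perm)$magnitude
  })
  null_mags <- matrix(null_mags, nrow = nrow(obs))
  obs$p_value <- vapply(seq_len(nrow(obs)), function(i) {
    (1 + sum(null_mags[i, ] >= obs$magnitude[i])) / (1 + n_permutations)
  }, numeric(1))
  obs
}
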