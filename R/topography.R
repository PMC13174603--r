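# Topography summaries: suprathreshold vertex counts, surface-area shares,
# laterality indices, and per-ROI response-profile correlations.

#' Count suprathreshold vertices
#'
#' Number of vertices whose selectivity t-value strictly exceeds the
#' threshold.
#'
#' @param t_values Numeric vector of per-vertex t-values.
#' @param threshold Selectivity threshold (default 2.5, strict inequality).
#' @return Integer count.
#' @export
suprathreshold_count <- function(t_values, threshold = 2.5) {
  check_number(threshold, "threshold", min = 0, strict_min = TRUE)
  if (any(!is.finite(t_values))) abort("t-values must be finite.")
  sum(t_values > threshold)
}

#' Laterality index
#'
#' Proportion of suprathreshold activity in the right hemisphere relative
#' to both hemispheres: `LI = RH / (RH + LH)`. 0.5 is symmetric; values
#' above 0.5 indicate right-hemisphere dominance.
#'
#' @param rh_count,lh_count Suprathreshold vertex counts (vectorized).
#' @return Numeric in `[0, 1]`.
#' @export
laterality_index <- function(rh_count, lh_count) {
  if (any(rh_count < 0 | lh_count < 0)) abort("Counts must be >= 0.")
  if (any(rh_count + lh_count == 0)) {
    abort("No suprathreshold activity in either hemisphere; LI undefined.")
  }
  rh_count / (rh_count + lh_count)
}

#' Per-category shares of suprathreshold territory
#'
#' Each category's share of the summed suprathreshold vertex counts
#' (vertices may be suprathreshold for several category contrasts; counts
#' are per contrast, not a winner-take-all partition).
#'
#' @param counts Named numeric vector of per-category suprathreshold
#'   counts.
#' @return Tibble: `category`, `count`, `share`. Shares sum to 1.
#' @export
area_share <- function(counts) {
  if (sum(counts) == 0) {
    abort("No suprathreshold vertices in any category; shares undefined.")
  }
  tibble(
    category = names(counts) %||% as.character(seq_along(counts)),
    count = as.numeric(counts),
    share = as.numeric(counts) / sum(counts)
  )
}

#' Percent change in territory share between groups
#'
#' `(share_adult - share_child) / share_child * 100`.
#'
#' @param child_share,adult_share Shares (fractions).
#' @return Percent change.
#' @export
share_change <- function(child_share, adult_share) {
  if (any(child_share == 0)) abort("Child share of 0: percent change undefined.")
  (adult_share - child_share) / child_share * 100
}

#' Per-vertex category selectivity maps for an archive
#'
#' The selectivity t-map of a category is its condition pattern averaged
#' across runs (patterns are already preferred-vs-others contrasts).
#'
#' @param x Pattern matrix with `run<r>_<condition>` columns.
#' @return Matrix vertices x categories of mean t-values.
#' @export
selectivity_maps <- function(x) {
  m <- collapse_subcategories(as.matrix(x))
  info <- parse_pattern_columns(m)
  cats <- unique(info$condition)
  out <- vapply(cats, function(cc) {
    rowMeans(m[, info$column[info$condition == cc], drop = FALSE])
  }, numeric(nrow(m)))
  colnames(out) <- cats
  out
}

#' Suprathreshold counts and laterality for a cohort
#'
#' Counts suprathreshold vertices per subject x region x category and
#' hemisphere, and joins hemispheres into laterality indices.
#'
#' @param cohort An `rsa_cohort` tibble with both hemispheres.
#' @param threshold Selectivity threshold.
#' @return List of two tibbles: `counts` (subject, group, hemisphere,
#'   region, category, n_suprathreshold) and `laterality` (subject, group,
#'   region, category, li; rows where both hemisphere counts are zero are
#'   dropped).
#' @export
cohort_topography <- function(cohort, threshold = 2.5) {
  counts <- purrr::map(seq_len(nrow(cohort)), function(i) {
    maps <- selectivity_maps(cohort$data[[i]])
    tibble(
      subject_id = cohort$subject_id[i], group = cohort$group[i],
      hemisphere = cohort$hemisphere[i], region = cohort$region[i],
      category = colnames(maps),
      n_suprathreshold = apply(maps, 2, suprathreshold_count,
        threshold = threshold
      )
    )
  }) |> dplyr::bind_rows()
  lat <- counts |>
    tidyr::pivot_wider(
      names_from = "hemisphere", values_from = "n_suprathreshold"
    )
  if (all(c("LH", "RH") %in% names(lat))) {
    lat <- lat |>
      dplyr::filter(.data$LH + .data$RH > 0) |>
      dplyr::mutate(li = laterality_index(.data$RH, .data$LH))
  } else {
    lat <- lat[0, ]
  }
  list(counts = counts, laterality = lat)
}

#' Per-ROI category response profile
#'
#' Mean t-value of each category contrast within each ROI, concatenated
#' into one ordered vector (ROI-major order).
#'
#' @param x Pattern matrix with `run<r>_<condition>` columns.
#' @param roi_labels Per-vertex ROI labels (length = rows of `x`).
#' @return A `profile_vector`: list with `values`, `roi_order`,
#'   `category_order`.
#' @export
profile_vector <- function(x, roi_labels) {
  maps <- selectivity_maps(x)
  if (length(roi_labels) != nrow(maps)) {
    abort("`roi_labels` must have one label per vertex.")
  }
  rois <- sort(unique(roi_labels))
  cats <- colnames(maps)
  vals <- as.vector(vapply(rois, function(rr) {
    colMeans(maps[roi_labels == rr, , drop = FALSE])
  }, numeric(length(cats))))
  structure(
    list(
      values = vals, roi_order = rois, category_order = cats
    ),
    class = "profile_vector"
  )
}

#' Correlate two response profiles
#'
#' Pearson correlation of two per-ROI category response vectors. The two
#' profiles must record identical ROI and category orderings; mismatches
#' are an error, never silently reordered.
#'
#' @param a,b `profile_vector` objects.
#' @return Correlation (length-1 numeric).
#' @export
profile_correlation <- function(a, b) {
  if (!inherits(a, "profile_vector") || !inherits(b, "profile_vector")) {
    abort("Both arguments must be profile_vector objects.")
  }
  if (!identical(a$roi_order, b$roi_order) ||
    !identical(a$category_order, b$category_order)) {
    abort("Profile orderings differ; refusing to correlate misaligned vectors.")
  }
  cor(a$values, b$values)
}
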