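# Quantitative-MRI tissue trajectories and gene-set normalization.

#' Assign developmental age groups
#'
#' Bins ages into the four developmental groups: kids (5-10), teens
#' (11-17), young_adults (18-24), adults (25-54); the bins are disjoint
#' and exhaustive over [5, 54]. Ages outside [5, 54] are an error (older
#' adults are excluded because aging is distinct from development).
#'
#' @param age Numeric vector of ages in years.
#' @return Factor with levels kids, teens, young_adults, adults.
#' @export
assign_age_group <- function(age) {
  if (any(!is.finite(age)) || any(age < 5 | age > 54)) {
    abort("Ages must lie within [5, 54]; older adults are excluded.")
  }
  cut(age,
    breaks = c(5, 11, 18, 25, 54),
    labels = c("kids", "teens", "young_adults", "adults"),
    include.lowest = TRUE, right = FALSE
  )
}

#' ROI-mean tissue metric per subject
#'
#' Arithmetic mean of the per-voxel metric within each subject x
#' hemisphere x lobe cell.
#'
#' @param tissue A `tissue_tbl` (long tibble with `subject_id`, `age`,
#'   `hemisphere`, `lobe`, `r1`, `mtv`).
#' @param metric `"r1"` or `"mtv"`.
#' @return Tibble: `subject_id`, `age`, `age_group`, `hemisphere`, `lobe`,
#'   `value`.
#' @export
roi_mean <- function(tissue, metric = c("r1", "mtv")) {
  metric <- match.arg(metric)
  if (nrow(tissue) == 0) abort("Empty voxel set: ROI mean undefined.")
  tissue |>
    dplyr::group_by(
      .data$subject_id, .data$age, .data$hemisphere, .data$lobe
    ) |>
    dplyr::summarise(value = mean(.data[[metric]]), .groups = "drop") |>
    dplyr::mutate(age_group = assign_age_group(.data$age)) |>
    dplyr::relocate("age_group", .after = "age")
}

#' Per-subject R1 vs inverse water volume fraction fit
#'
#' Ordinary least-squares fit of voxelwise R1 on 1/WVF = 1/(1 - MTV) within
#' each subject. Deviations of the R1-MTV relation from linearity index
#' hydrophobic (myelin-like) tissue composition; the per-subject slopes are
#' the inputs to the child/adult slope contrast.
#'
#' @param tissue A `tissue_tbl`; each subject needs >= 3 voxels and
#'   non-constant MTV.
#' @return Tibble: `subject_id`, `age`, `age_group`, `slope`, `intercept`,
#'   `r_squared`.
#' @export
r1_vs_invwvf_fit <- function(tissue) {
  if (any(tissue$mtv <= 0 | tissue$mtv >= 1)) {
    abort("MTV must lie strictly in (0, 1) so that WVF = 1 - MTV > 0.")
  }
  tissue |>
    dplyr::group_by(.data$subject_id, .data$age) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 3) abort("Each subject needs >= 3 voxels for the fit.")
      x <- 1 / (1 - df$mtv)
      if (var(x) == 0) {
        abort("Zero variance in 1/WVF; slope undefined.")
      }
      fit <- lm(df$r1 ~ x)
      tss <- sum((df$r1 - mean(df$r1))^2)
      rss <- sum(fit$residuals^2)
      tibble(
        slope = unname(coef(fit)[2]),
        intercept = unname(coef(fit)[1]),
        r_squared = if (tss == 0) 1 else 1 - rss / tss
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(age_group = assign_age_group(.data$age)) |>
    dplyr::relocate("age_group", .after = "age")
}

#' Contrast R1-MTV slopes between two age groups
#'
#' Welch two-sample t-test on per-subject slopes.
#'
#' @param fits Output of [r1_vs_invwvf_fit()].
#' @param groups Length-2 character: the `age_group` levels to contrast
#'   (first minus second).
#' @return One-row tibble from [welch_t()] plus the group means.
#' @export
slope_contrast <- function(fits, groups = c("kids", "adults")) {
  a <- fits$slope[fits$age_group == groups[1]]
  b <- fits$slope[fits$age_group == groups[2]]
  res <- welch_t(a, b)
  res$mean_a <- mean(a)
  res$mean_b <- mean(b)
  res
}

#' Inter-voxel R1 heterogeneity vs age
#'
#' Computes each subject's inter-voxel R1 standard deviation and regresses
#' it on age by ordinary least squares.
#'
#' @param tissue A `tissue_tbl` with >= 3 subjects at distinct ages.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `slope_se`, with the per-subject SDs in the `per_subject` list-column.
#' @export
heterogeneity_vs_age <- function(tissue) {
  per <- tissue |>
    dplyr::group_by(.data$subject_id, .data$age) |>
    dplyr::summarise(r1_sd = sd(.data$r1), .groups = "drop")
  if (nrow(per) < 3 || length(unique(per$age)) < 2) {
    abort("Need >= 3 subjects with at least two distinct ages.")
  }
  fit <- lm(r1_sd ~ age, data = per)
  sm <- summary(fit)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients["age", "Pr(>|t|)"],
    slope_se = sm$coefficients["age", "Std. Error"],
    per_subject = list(per)
  )
}

#' Normalize gene expression to the adolescence window
#'
#' Divides each gene's expression by its mean over the adolescence window
#' (open interval, default 11 < age < 20), then averages the normalized
#' curves across the genes of each set. By construction every gene's mean
#' over the window maps to 1.
#'
#' @param expr Long tibble: `gene`, `set`, `age`, `expression` (>= 0).
#' @param window Length-2 numeric, open interval of ages.
#' @return Tibble: `set`, `age`, `value` (mean normalized expression).
#' @export
normalize_gene_sets <- function(expr, window = c(11, 20)) {
  need <- c("gene", "set", "age", "expression")
  if (!all(need %in% names(expr))) {
    abort(sprintf("`expr` needs columns %s.", paste(need, collapse = ", ")))
  }
  in_win <- expr$age > window[1] & expr$age < window[2]
  if (!any(in_win)) abort("No ages fall inside the adolescence window.")
  win_means <- expr[in_win, ] |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(win_mean = mean(.data$expression), .groups = "drop")
  missing <- setdiff(unique(expr$gene), win_means$gene)
  if (length(missing) > 0) {
    abort(sprintf(
      "Gene(s) with no expression values inside the window: %s",
      paste(missing, collapse = ", ")
    ))
  }
  zero <- win_means$gene[win_means$win_mean == 0]
  if (length(zero) > 0) {
    abort(sprintf(
      "Gene(s) with window mean 0 (normalization undefined): %s",
      paste(zero, collapse = ", ")
    ))
  }
  expr |>
    dplyr::left_join(win_means, by = "gene") |>
    dplyr::mutate(norm = .data$expression / .data$win_mean) |>
    dplyr::group_by(.data$set, .data$age) |>
    dplyr::summarise(value = mean(.data$norm), .groups = "drop")
}

#' Lobe x age-group ANOVA on ROI-mean tissue metrics
#'
#' Balanced two-way factorial ANOVA of ROI-mean values on cortical lobe and
#' developmental age group (see [factorial_anova()]).
#'
#' @param roi_means Output of [roi_mean()] for two or more lobes.
#' @param factor_b Second factor column (default `"age_group"`).
#' @return Tibble from [factorial_anova()].
#' @export
trajectory_anova <- function(roi_means, factor_b = "age_group") {
  factorial_anova(
    roi_means$value, roi_means$lobe, roi_means[[factor_b]]
  )
}
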