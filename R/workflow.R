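# End-to-end orchestration of the analysis graph on a (synthetic) cohort.

#' Run the full analysis pipeline on a cohort
#'
#' Generates (or accepts) a cohort and runs the requested analysis stages
#' in dependency order: similarity (`rsm`), partition ranking
#' (`partitions`), representational geometry (`geometry`), cross-subject
#' decoding (`decoding`), stability-coupling (`coupling`) and topography
#' summaries (`topography`). All randomness flows from the cohort spec's
#' seed; re-running with an identical config reproduces all outputs.
#'
#' @param spec A [cohort_spec()], or an already-generated `rsa_cohort`.
#' @param stages Character subset of
#'   `c("rsm", "partitions", "geometry", "decoding", "coupling",
#'   "topography")`.
#' @param out_dir Optional directory; when given, per-stage TSV/JSON result
#'   files plus a provenance record are written under it.
#' @param n_permutations Permutations for the decoding null.
#' @param threshold Suprathreshold selectivity threshold for topography.
#' @return Named list of stage result tibbles plus `provenance`.
#' @export
run_pipeline <- function(spec = cohort_spec(),
                         stages = c(
                           "rsm", "partitions", "geometry", "decoding",
                           "coupling", "topography"
                         ),
                         out_dir = NULL, n_permutations = 200,
                         threshold = 2.5) {
  known <- c(
    "rsm", "partitions", "geometry", "decoding", "coupling", "topography"
  )
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  cohort <- if (inherits(spec, "rsa_cohort")) spec else generate_cohort(spec)
  cfg <- attr(cohort, "spec")
  seed <- if (!is.null(cfg)) cfg$seed else 1L
  results <- list()

  cells <- cohort |>
    dplyr::group_by(.data$group, .data$hemisphere, .data$region)
  keys <- dplyr::group_keys(cells)
  parts <- dplyr::group_split(cells)

  sims <- NULL
  if (any(c("rsm", "partitions", "coupling") %in% stages)) {
    sims <- cohort_similarity(cohort)
  }
  if ("rsm" %in% stages) {
    results$rsm <- sims |>
      dplyr::mutate(stats = purrr::map(.data$sim, function(s) {
        dplyr::bind_cols(
          within_between_category(s),
          block_contrast(s, block_scheme("animate_inanimate")) |>
            dplyr::rename_with(~ paste0("ai_", .x))
        )
      })) |>
      tidyr::unnest("stats") |>
      dplyr::select(-"sim")
  }
  if ("partitions" %in% stages) {
    models <- enumerate_partitions(mode = "full_bipartition")
    results$partitions <- purrr::map2(parts, seq_len(nrow(keys)), function(df, i) {
      sm_mean <- Reduce(`+`, lapply(df$data, function(d) {
        unclass(loro_similarity(d))
      })) / nrow(df)
      top <- rank_partitions(models, sm_mean)
      dplyr::bind_cols(keys[i, ], top)
    }) |> dplyr::bind_rows()
  }
  if ("geometry" %in% stages) {
    results$geometry <- purrr::map2(parts, seq_len(nrow(keys)), function(df, i) {
      cfgs <- purrr::map2(
        df$data, df$subject_id,
        ~ embed_patterns(.x, owner = .y)
      )
      templ <- group_template(cfgs)
      disp <- dispersion(cfgs, templ)
      sims_t <- vapply(cfgs, function(cfg) {
        procrustes_align(cfg, templ)$report$template_similarity
      }, numeric(1))
      group_cfg <- embed_patterns(
        Reduce(`+`, df$data) / nrow(df),
        owner = "group_mean"
      )
      dplyr::bind_cols(
        keys[i, ],
        tibble(
          dispersion = disp$dispersion,
          template_similarity = mean(sims_t),
          hull_area = convex_hull_area(group_cfg)
        )
      )
    }) |> dplyr::bind_rows()
  }
  if ("decoding" %in% stages) {
    results$decoding <- purrr::map2(parts, seq_len(nrow(keys)), function(df, i) {
      res <- permutation_null(df,
        n_permutations = n_permutations,
        seed = derive_seed(seed, i)
      )
      dplyr::bind_cols(keys[i, ], glance(res))
    }) |> dplyr::bind_rows()
  }
  if ("coupling" %in% stages) {
    if (!all(c("VLPFC", "VTC") %in% cohort$region)) {
      abort("Stage `coupling` needs both VLPFC and VTC in the cohort.")
    }
    results$coupling <- coupling_points(cohort)
  }
  if ("topography" %in% stages) {
    topo <- cohort_topography(cohort, threshold = threshold)
    results$topography <- topo$counts
    results$laterality <- topo$laterality
  }
  results$provenance <- tibble(
    seed = seed,
    n_subjects = length(unique(cohort$subject_id)),
    stages = paste(stages, collapse = ","),
    config_hash = rlang::hash(list(cfg, stages, n_permutations, threshold)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(results), "provenance")) {
      df <- results[[nm]]
      df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
      readr::write_tsv(df, file.path(out_dir, paste0(nm, ".tsv")),
        progress = FALSE
      )
    }
    jsonlite::write_json(
      as.list(results$provenance),
      file.path(out_dir, "provenance.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  results
}
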