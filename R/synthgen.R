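# Synthetic cohort generator.
#
# Emulates the statistical structure of a developmental category-localizer
# fMRI study: two groups (children, adults), three runs, five categories
# (two subcategories each), two hemispheres x two regions (VLPFC, VTC).
# Patterns are "t-values" over vertices: a region-level category signal
# (block-structured: shared animate component for faces+bodies, shared
# inanimate component for pseudowords+places+objects with half weight on
# pseudowords, plus a pseudoword-private word axis), mean-centered across
# categories (contrast semantics: preferred > all others), plus a
# subject-idiosyncratic component constant across runs, plus independent
# run noise.

#' Default signal strengths per group x hemisphere x region
#'
#' Unitless scales of the animate-inanimate block signal and the
#' pseudoword-selective axis relative to unit run noise. Defaults encode the
#' structure the pipeline is designed to detect: strong bilateral animacy in
#' VTC at all ages; right-VLPFC animacy present in children and stronger in
#' adults; a left-lateralized word axis established early in both VLPFC and
#' VTC.
#'
#' @return Tibble with columns `group`, `hemisphere`, `region`, `animacy`,
#'   `word_axis`.
#' @export
default_strengths <- function() {
  tidyr::expand_grid(
    group = c("child", "adult"),
    hemisphere = c("LH", "RH"),
    region = c("VLPFC", "VTC")
  ) |>
    dplyr::mutate(
      animacy = dplyr::case_when(
        .data$region == "VTC" ~ 1.2,
        .data$hemisphere == "RH" & .data$group == "child" ~ 0.5,
        .data$hemisphere == "RH" & .data$group == "adult" ~ 1.0,
        .data$group == "child" ~ 0.3,
        TRUE ~ 0.4
      ),
      word_axis = dplyr::case_when(
        .data$hemisphere == "LH" ~ 0.8,
        .data$region == "VTC" ~ 0.3,
        TRUE ~ 0.2
      )
    )
}

#' Specify a synthetic cohort
#'
#' Bundles and validates all generator parameters. Defaults are the study
#' conditions emulated throughout the package: 30 children + 30 adults,
#' 3 localizer runs, the five fixed categories with two subcategories each,
#' 500 vertices per region, both hemispheres, VLPFC and VTC.
#'
#' @param n_children,n_adults Subjects per group.
#' @param n_runs Localizer runs per subject (>= 2; cross-validation needs at
#'   least two folds).
#' @param n_vertices Vertices per region.
#' @param regions,hemispheres Region / hemisphere labels to simulate.
#' @param strengths Data frame like [default_strengths()]: per group x
#'   hemisphere x region `animacy` and `word_axis` scales (>= 0). A single
#'   number recycles one value to every cell of both columns.
#' @param run_noise_sd SD of independent per-run noise (> 0).
#' @param subject_noise_sd SD of the subject-idiosyncratic pattern component
#'   shared across runs (>= 0).
#' @param subcat_perturbation Subcategory templates are the parent category
#'   template plus a perturbation with SD equal to this fraction of the
#'   template SD.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec including this seed.
#' @return A `cohort_spec` (validated list).
#' @export
cohort_spec <- function(n_children = 30, n_adults = 30, n_runs = 3,
                        n_vertices = 500,
                        regions = c("VLPFC", "VTC"),
                        hemispheres = c("LH", "RH"),
                        strengths = default_strengths(),
                        run_noise_sd = 1,
                        subject_noise_sd = 0.5,
                        subcat_perturbation = 0.25,
                        seed = 1L) {
  n_children <- check_count(n_children, "n_children", min = 0L)
  n_adults <- check_count(n_adults, "n_adults", min = 0L)
  if (n_children + n_adults < 1) abort("`n_children` + `n_adults` must be >= 1.")
  n_runs <- check_count(n_runs, "n_runs", min = 2L)
  n_vertices <- check_count(n_vertices, "n_vertices", min = 3L)
  check_number(run_noise_sd, "run_noise_sd", min = 0, strict_min = TRUE)
  check_number(subject_noise_sd, "subject_noise_sd", min = 0)
  check_number(subcat_perturbation, "subcat_perturbation", min = 0)
  seed <- check_count(seed, "seed", min = 0L)
  regions <- as.character(regions)
  hemispheres <- as.character(hemispheres)
  if (length(regions) < 1 || length(hemispheres) < 1) {
    abort("Need at least one region and one hemisphere.")
  }
  if (is.numeric(strengths) && length(strengths) == 1L) {
    check_number(strengths, "strengths", min = 0)
    strengths <- tidyr::expand_grid(
      group = c("child", "adult"), hemisphere = hemispheres, region = regions
    ) |>
      dplyr::mutate(animacy = !!strengths, word_axis = !!strengths)
  }
  strengths <- as_tibble(strengths)
  need <- c("group", "hemisphere", "region", "animacy", "word_axis")
  if (!all(need %in% names(strengths))) {
    abort(sprintf(
      "`strengths` must have columns %s.", paste(need, collapse = ", ")
    ))
  }
  if (any(!is.finite(strengths$animacy)) || any(strengths$animacy < 0)) {
    abort("`strengths$animacy` values must be finite and >= 0.")
  }
  if (any(!is.finite(strengths$word_axis)) || any(strengths$word_axis < 0)) {
    abort("`strengths$word_axis` values must be finite and >= 0.")
  }
  cells <- tidyr::expand_grid(
    group = c("child", "adult"), hemisphere = hemispheres, region = regions
  )
  merged <- dplyr::left_join(cells, strengths,
    by = c("group", "hemisphere", "region")
  )
  if (anyNA(merged$animacy) || anyNA(merged$word_axis)) {
    abort("`strengths` is missing rows for some group x hemisphere x region cell.")
  }
  structure(
    list(
      n_children = n_children, n_adults = n_adults, n_runs = n_runs,
      categories = rsa_categories(), subcats_per_category = 2L,
      n_vertices = n_vertices, regions = regions, hemispheres = hemispheres,
      strengths = merged, run_noise_sd = run_noise_sd,
      subject_noise_sd = subject_noise_sd,
      subcat_perturbation = subcat_perturbation, seed = seed
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d children + %d adults, %d runs, %d vertices, seed %d\n",
    x$n_children, x$n_adults, x$n_runs, x$n_vertices, x$seed
  ))
  cat("regions:", paste(x$regions, collapse = ", "),
    "| hemispheres:", paste(x$hemispheres, collapse = ", "), "\n")
  invisible(x)
}

# Category signal templates for one hemisphere x region, at subcategory
# level, already contrast-centered across the five categories.
# components: a list with animate, inanimate, word, private (5 cols),
# perturb (10 cols) standard-normal vertex patterns.
build_templates <- function(components, animacy, word_axis,
                            subcat_perturbation) {
  cats <- rsa_categories()
  lambda <- 0.7 # within-block category distinctness
  sig <- sapply(cats, function(cc) {
    switch(cc,
      faces = animacy * (components$animate + lambda * components$private[, "faces"]),
      bodies = animacy * (components$animate + lambda * components$private[, "bodies"]),
      pseudowords = 0.5 * animacy * components$inanimate +
        word_axis * components$word,
      places = animacy * (components$inanimate + lambda * components$private[, "places"]),
      objects = animacy * (components$inanimate + lambda * components$private[, "objects"])
    )
  })
  sig <- sig - rowMeans(sig) # preferred > all others contrast
  subs <- rsa_subcategories()
  out <- sapply(names(subs), function(sc) {
    parent <- sig[, subs[[sc]]]
    s <- sd(parent)
    parent + subcat_perturbation * s * components$perturb[, sc]
  })
  colnames(out) <- names(subs)
  out
}

#' Generate a synthetic cohort of category-pattern archives
#'
#' Deterministically (given the spec's seed) simulates per-subject,
#' per-hemisphere, per-region pattern matrices of "t-values" over vertices,
#' one column per run x subcategory condition. See the package vignette for
#' the signal model. Expected within-category cross-run correlation exceeds
#' between-category correlation whenever any structure strength is positive;
#' with all strengths zero the patterns are exchangeable noise.
#'
#' @param spec A [cohort_spec()].
#' @return A `rsa_cohort` tibble: one row per subject x hemisphere x region,
#'   with columns `subject_id`, `group`, `age`, `hemisphere`, `region`,
#'   `roi` (list of per-vertex ROI labels) and `data` (list of vertices x
#'   (run x condition) matrices).
#' @examples
#' cohort <- generate_cohort(cohort_spec(
#'   n_children = 2, n_adults = 2,
#'   n_vertices = 40, seed = 7
#' ))
#' cohort
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be created with cohort_spec().")
  }
  set.seed(spec$seed)
  nv <- spec$n_vertices
  cats <- spec$categories
  subs <- rsa_subcategories()
  n_cond <- length(subs)

  # region-level components, drawn once per hemisphere x region
  comps <- list()
  for (hemi in spec$hemispheres) {
    for (reg in spec$regions) {
      key <- paste(hemi, reg, sep = ".")
      comps[[key]] <- list(
        animate = rnorm(nv), inanimate = rnorm(nv), word = rnorm(nv),
        private = matrix(rnorm(nv * 5), nv,
          dimnames = list(NULL, cats)
        ),
        perturb = matrix(rnorm(nv * n_cond), nv,
          dimnames = list(NULL, names(subs))
        )
      )
    }
  }

  n_total <- spec$n_children + spec$n_adults
  groups <- rep(c("child", "adult"), c(spec$n_children, spec$n_adults))
  ids <- sprintf("sub-%03d", seq_len(n_total))
  ages <- numeric(n_total)
  ages[groups == "child"] <- round(runif(spec$n_children, 5, 12), 1)
  ages[groups == "adult"] <- round(runif(spec$n_adults, 20, 29), 1)

  n_rois <- c(VLPFC = 10L, VTC = 8L)
  rows <- list()
  idx <- 1L
  for (s in seq_len(n_total)) {
    for (hemi in spec$hemispheres) {
      for (reg in spec$regions) {
        key <- paste(hemi, reg, sep = ".")
        st <- spec$strengths[
          spec$strengths$group == groups[s] &
            spec$strengths$hemisphere == hemi &
            spec$strengths$region == reg,
        ]
        templ <- build_templates(
          comps[[key]], st$animacy, st$word_axis, spec$subcat_perturbation
        )
        subj_eff <- matrix(
          rnorm(nv * n_cond, sd = spec$subject_noise_sd), nv, n_cond
        )
        mats <- lapply(seq_len(spec$n_runs), function(r) {
          templ + subj_eff +
            matrix(rnorm(nv * n_cond, sd = spec$run_noise_sd), nv, n_cond)
        })
        data <- do.call(cbind, mats)
        colnames(data) <- as.vector(vapply(
          seq_len(spec$n_runs),
          function(r) sprintf("run%d_%s", r, names(subs)),
          character(n_cond)
        ))
        k <- if (reg %in% names(n_rois)) n_rois[[reg]] else 5L
        roi <- sprintf("ROI%02d", rep(seq_len(k), length.out = nv)[
          order(rep(seq_len(k), length.out = nv))
        ])
        rows[[idx]] <- tibble(
          subject_id = ids[s], group = groups[s], age = ages[s],
          hemisphere = hemi, region = reg,
          roi = list(roi), data = list(data)
        )
        idx <- idx + 1L
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rsa_cohort", class(out))
  attr(out, "spec") <- spec
  out
}

#' Write / read a cohort as plain-text archives
#'
#' `write_cohort()` writes one wide TSV per subject x hemisphere x region
#' (rows = vertices, columns = `run<r>_<condition>`, plus a leading `roi`
#' column), a `manifest.tsv` and a `spec.json` sidecar recording the full
#' generator spec and seed. `read_cohort()` reads the directory back into an
#' `rsa_cohort` tibble.
#'
#' @param cohort An `rsa_cohort` tibble.
#' @param dir Directory to write into (created if missing).
#' @return `write_cohort()`: the manifest tibble, invisibly.
#'   `read_cohort()`: an `rsa_cohort` tibble.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort |>
    dplyr::mutate(
      path = sprintf(
        "%s_%s_%s.tsv", .data$subject_id, .data$hemisphere, .data$region
      )
    ) |>
    dplyr::select(
      "subject_id", "group", "age", "hemisphere", "region", "path"
    )
  for (i in seq_len(nrow(cohort))) {
    df <- as.data.frame(cohort$data[[i]])
    df <- cbind(roi = cohort$roi[[i]], df)
    readr::write_tsv(df, file.path(dir, manifest$path[i]), progress = FALSE)
  }
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
  spec <- attr(cohort, "spec")
  if (!is.null(spec)) {
    jsonlite::write_json(
      unclass(spec), file.path(dir, "spec.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(manifest)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- readr::read_tsv(
    file.path(dir, "manifest.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
  rows <- purrr::pmap(manifest, function(subject_id, group, age, hemisphere,
                                         region, path) {
    df <- readr::read_tsv(file.path(dir, path),
      show_col_types = FALSE, progress = FALSE
    )
    roi <- df$roi
    mat <- as.matrix(df[setdiff(names(df), "roi")])
    tibble(
      subject_id = subject_id, group = group, age = age,
      hemisphere = hemisphere, region = region,
      roi = list(roi), data = list(mat)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rsa_cohort", class(out))
  spec_path <- file.path(dir, "spec.json")
  if (file.exists(spec_path)) {
    attr(out, "spec") <- jsonlite::read_json(spec_path, simplifyVector = TRUE)
  }
  out
}

#' Generate synthetic quantitative-MRI tissue samples
#'
#' Simulates per-voxel R1 (1/s) and MTV (fraction of non-water tissue)
#' values around a developmental age trajectory for one ROI. `"linear"`
#' gives a monotone increase with age (VTC-like continuous macromolecular
#' proliferation); `"dip"` gives a rise-dip-recover shape (right-VLPFC-like
#' adolescent dip, a Gaussian trough centered at `dip_age`). Inter-voxel R1
#' SD grows linearly with age (`r1_noise_base + r1_noise_slope * age`), and
#' per voxel R1 follows a linear relation to inverse water volume fraction
#' 1/(1 - MTV) whose slope declines with age (`slope_child -
#' slope_decline * (age - 5)`), so children show the steeper, more
#' constrained R1-MTV relation.
#'
#' @param n_subjects Number of subjects.
#' @param age_range Length-2 numeric inside [5, 54].
#' @param trajectory `"linear"` or `"dip"`.
#' @param n_voxels Voxels per subject (>= 10).
#' @param seed Integer seed.
#' @param hemisphere,lobe Labels attached to every sample.
#' @param r1_base,r1_age_slope Mean R1 trajectory: `r1_base + r1_age_slope *
#'   age` (1/s and 1/s/year).
#' @param dip_age,dip_depth,dip_width Gaussian dip parameters (years, 1/s,
#'   years), used when `trajectory = "dip"`.
#' @param mtv_base,mtv_age_slope Logit-scale MTV trajectory; MTV stays in
#'   (0, 1) by construction.
#' @param mtv_noise_sd Logit-scale per-voxel MTV noise SD.
#' @param r1_noise_base,r1_noise_slope Inter-voxel R1 noise SD at age 0 and
#'   its increase per year.
#' @param slope_child,slope_decline R1 vs 1/WVF slope at age 5 and its
#'   decline per year.
#' @return A `tissue_tbl` tibble: `subject_id`, `age`, `age_group`,
#'   `hemisphere`, `lobe`, `voxel`, `r1`, `mtv`.
#' @export
generate_tissue <- function(n_subjects, age_range = c(5, 54),
                            trajectory = c("linear", "dip"),
                            n_voxels = 200, seed = 1L,
                            hemisphere = "RH", lobe = "VLPFC",
                            r1_base = 0.85, r1_age_slope = 0.0015,
                            dip_age = 17, dip_depth = 0.08, dip_width = 3,
                            mtv_base = qlogis(0.28), mtv_age_slope = 0.008,
                            mtv_noise_sd = 0.05,
                            r1_noise_base = 0.02, r1_noise_slope = 0.0008,
                            slope_child = 0.35, slope_decline = 0.004) {
  trajectory <- match.arg(trajectory)
  n_subjects <- check_count(n_subjects, "n_subjects", min = 1L)
  n_voxels <- check_count(n_voxels, "n_voxels", min = 10L)
  if (length(age_range) != 2 || !all(is.finite(age_range)) ||
    age_range[1] > age_range[2]) {
    abort("`age_range` must be two finite numbers, low <= high.")
  }
  if (age_range[1] < 5 || age_range[2] > 54) {
    abort("`age_range` must lie within [5, 54] (older adults excluded).")
  }
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  ages <- sort(round(runif(n_subjects, age_range[1], age_range[2]), 1))
  r1_mean <- r1_base + r1_age_slope * ages
  if (trajectory == "dip") {
    r1_mean <- r1_mean - dip_depth * exp(-(ages - dip_age)^2 / (2 * dip_width^2))
  }
  rows <- lapply(seq_len(n_subjects), function(s) {
    age <- ages[s]
    mtv <- plogis(
      mtv_base + mtv_age_slope * (age - 20) + rnorm(n_voxels, 0, mtv_noise_sd)
    )
    inv_wvf <- 1 / (1 - mtv)
    beta <- max(slope_child - slope_decline * (age - 5), 0)
    eps_sd <- r1_noise_base + r1_noise_slope * age
    r1 <- r1_mean[s] + beta * (inv_wvf - mean(inv_wvf)) +
      rnorm(n_voxels, 0, eps_sd)
    r1 <- pmax(r1, 0.01)
    tibble(
      subject_id = sprintf("tissue-%03d", s), age = age,
      hemisphere = hemisphere, lobe = lobe,
      voxel = seq_len(n_voxels), r1 = r1, mtv = mtv
    )
  })
  out <- dplyr::bind_rows(rows)
  out$age_group <- assign_age_group(out$age)
  out <- dplyr::relocate(out, "age_group", .after = "age")
  class(out) <- c("tissue_tbl", class(out))
  out
}

#' Generate synthetic developmental gene-expression curves
#'
#' Emulates gene x age expression tables (RPKM-like units) for gene sets
#' that all decline during adolescence; sets flagged `recovery = TRUE` rise
#' again after the adolescence window while the others stay at the declined
#' level. Each gene carries a log-normal baseline scale.
#'
#' @param sets Named list of character vectors: gene symbols per set. Every
#'   gene must belong to exactly one set.
#' @param ages Numeric vector of ages (years) spanning the adolescence
#'   window (11, 20).
#' @param recovery Named logical, one flag per set (post-window recovery).
#' @param seed Integer seed.
#' @param noise_sd SD of multiplicative log-normal noise (0 = noiseless).
#' @param window Adolescence window, open interval.
#' @return Tibble: `gene`, `set`, `age`, `expression`.
#' @export
generate_expression <- function(sets, ages, recovery, seed = 1L,
                                noise_sd = 0, window = c(11, 20)) {
  genes <- unlist(sets, use.names = FALSE)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    abort(sprintf(
      "Gene(s) in more than one set: %s", paste(dup, collapse = ", ")
    ))
  }
  if (length(genes) == 0) abort("`sets` contains no genes.")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a named list.")
  }
  if (!all(names(sets) %in% names(recovery))) {
    abort("`recovery` needs one named flag per set.")
  }
  if (!any(ages > window[1] & ages < window[2])) {
    abort("`ages` must include at least one age inside the adolescence window.")
  }
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  shape <- function(age, rec) {
    pre <- 1.3
    low <- 0.7
    post <- if (rec) 1.1 else low
    ifelse(age <= window[1], pre,
      ifelse(age < window[2],
        pre + (low - pre) * (age - window[1]) / (window[2] - window[1]),
        post
      )
    )
  }
  rows <- purrr::imap(sets, function(gs, set_name) {
    rec <- isTRUE(recovery[[set_name]])
    purrr::map(gs, function(g) {
      base <- 10 * exp(rnorm(1, 0, 0.3))
      noise <- exp(rnorm(length(ages), 0, noise_sd))
      tibble(
        gene = g, set = set_name, age = ages,
        expression = base * shape(ages, rec) * noise
      )
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

#' Myelin-sheath gene set
#'
#' Genes directly involved in the structure and maintenance of the human
#' myelin sheath, as used in the developmental expression analysis
#' (duplicates removed).
#'
#' @return Character vector of gene symbols.
#' @export
myelin_genes <- function() {
  c("PLP1", "PLLP", "MAG", "MBP", "CA2", "PMP22", "MAL", "ERMN", "OMG")
}
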