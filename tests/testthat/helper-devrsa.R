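# Shared fixtures and independent mini-oracles, all built in code.

# Independent Pearson correlation (direct sums, no stats::cor).
brute_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Uniform strengths table for a single-cell spec.
flat_strengths <- function(hemispheres, regions, animacy, word_axis) {
  expand.grid(
    group = c("child", "adult"), hemisphere = hemispheres,
    region = regions, stringsAsFactors = FALSE
  ) |>
    transform(animacy = animacy, word_axis = word_axis)
}

# Small single-cell cohort used across tests.
small_cohort <- function(n_children = 5, n_adults = 5, n_vertices = 40,
                         animacy = 1, word_axis = 0.3,
                         run_noise_sd = 1, subject_noise_sd = 0.3,
                         hemispheres = "RH", regions = "VLPFC",
                         n_runs = 3, seed = 1) {
  generate_cohort(cohort_spec(
    n_children = n_children, n_adults = n_adults, n_runs = n_runs,
    n_vertices = n_vertices, regions = regions, hemispheres = hemispheres,
    strengths = flat_strengths(hemispheres, regions, animacy, word_axis),
    run_noise_sd = run_noise_sd, subject_noise_sd = subject_noise_sd,
    seed = seed
  ))
}

# Random symmetric 5x5 "similarity" matrix with entries in [-1, 1].
random_simmat <- function(seed = 1, categories = rsa_categories()) {
  set.seed(seed)
  k <- length(categories)
  m <- matrix(runif(k * k, -0.6, 0.9), k, k)
  m <- (m + t(m)) / 2
  dimnames(m) <- list(categories, categories)
  m
}

# A noiseless pattern matrix whose runs are identical: five exactly
# orthogonal zero-mean category templates over 2k vertices.
orthogonal_archive <- function(n_runs = 3) {
  base <- diag(5)
  templ <- rbind(base, -base) # zero-mean, mutually orthogonal columns
  cols <- list()
  for (r in seq_len(n_runs)) {
    m <- templ
    colnames(m) <- sprintf("run%d_%s", r, rsa_categories())
    cols[[r]] <- m
  }
  do.call(cbind, cols)
}

# Hand-rolled average-linkage agglomeration on a distance matrix:
# returns the k-cluster labels (clusters numbered by first member).
brute_average_linkage <- function(d, k) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  ord <- order(vapply(clusters, min, integer(1)))
  for (g in seq_along(ord)) labels[clusters[[ord[g]]]] <- g
  labels
}

# Balanced tissue sample: n_per subjects in each developmental age bin.
balanced_tissue <- function(n_per, trajectory, lobe, seed, n_voxels = 60,
                            ...) {
  bins <- list(c(5, 10), c(11, 17), c(18, 24), c(25, 54))
  out <- lapply(seq_along(bins), function(i) {
    tt <- generate_tissue(
      n_subjects = n_per, age_range = bins[[i]], trajectory = trajectory,
      n_voxels = n_voxels, seed = seed + i, lobe = lobe, ...
    )
    tt$subject_id <- sprintf("%s-%s", lobe, paste0(tt$subject_id, "-", i))
    tt
  })
  dplyr::bind_rows(out)
}
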