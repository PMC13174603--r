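# Cross-subject decoding: hierarchical category clustering,
# leave-one-subject-out linear classification, and label-permutation nulls.

#' Hierarchically cluster category patterns
#'
#' Agglomerative clustering of the category mean patterns on correlation
#' distance (1 - Pearson) with average linkage, cut at k clusters. Cluster
#' labels are deterministic: clusters are numbered by the canonical order of
#' their first member category.
#'
#' @param patterns Category x vertex matrix (rownames = categories).
#' @param k Number of clusters, between 2 and the number of categories.
#' @return A `cluster_solution`: list with `k`, `labels` (named integer
#'   vector category -> cluster) and `tree` (the `hclust` merge history).
#' @export
cluster_categories <- function(patterns, k) {
  patterns <- as.matrix(patterns)
  if (is.null(rownames(patterns))) {
    abort("`patterns` needs category rownames.")
  }
  k <- check_count(k, "k", min = 2L)
  if (k > nrow(patterns)) {
    abort("`k` cannot exceed the number of categories.")
  }
  sds <- apply(patterns, 1, sd)
  if (any(sds == 0)) {
    abort(sprintf(
      "Constant pattern for category '%s'; correlation distance undefined.",
      rownames(patterns)[which(sds == 0)[1]]
    ))
  }
  d <- as.dist(1 - cor(t(patterns)))
  tree <- hclust(d, method = "average")
  raw <- cutree(tree, k = k)
  # renumber clusters by first appearance in category (input) order
  first <- vapply(unique(raw), function(g) which(raw == g)[1], integer(1))
  relabel <- setNames(rank(first), unique(raw))
  labels <- setNames(as.integer(relabel[as.character(raw)]), names(raw))
  structure(
    list(k = k, labels = labels, tree = tree),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d\n", x$k))
  print(x$labels)
  invisible(x)
}

# Per-subject category-level mean patterns for one analysis cell.
# Returns list: features (obs x vertex matrix), subject (chr), category (chr).
cohort_observations <- function(cohort) {
  if (nrow(cohort) < 1) abort("Empty cohort.")
  if (anyDuplicated(cohort$subject_id)) {
    abort(paste(
      "Multiple archives per subject: filter the cohort to one",
      "hemisphere x region before decoding."
    ))
  }
  obs <- purrr::map(seq_len(nrow(cohort)), function(i) {
    m <- collapse_subcategories(cohort$data[[i]])
    info <- parse_pattern_columns(m)
    cats <- unique(info$condition)
    feat <- t(vapply(cats, function(cc) {
      rowMeans(m[, info$column[info$condition == cc], drop = FALSE])
    }, numeric(nrow(m))))
    list(
      features = feat, subject = rep(cohort$subject_id[i], length(cats)),
      category = cats
    )
  })
  list(
    features = do.call(rbind, purrr::map(obs, "features")),
    subject = unlist(purrr::map(obs, "subject")),
    category = unlist(purrr::map(obs, "category"))
  )
}

#' Leave-one-subject-out linear decoding
#'
#' For each held-out subject, a linear maximum-margin classifier (linear
#' support-vector classifier, cost 1) is trained on all other subjects'
#' per-category mean patterns — one observation per subject x category —
#' and evaluated on the held-out subject's patterns. Features are
#' standardized with training-fold statistics only. Accuracy is the average
#' over folds.
#'
#' The optional `train_targets` map lets the training labels differ from
#' the evaluation labels; the label-permutation null ([permutation_null()])
#' uses it to break the pattern-label association while test folds keep the
#' true targets.
#'
#' @param cohort `rsa_cohort` tibble filtered to one hemisphere x region
#'   (one archive per subject), >= 3 subjects.
#' @param targets Named vector mapping each category to a label (e.g.
#'   category identity, or a cluster label from [cluster_categories()]).
#'   Defaults to 5-way category identity.
#' @param train_targets Category -> label map used for training
#'   observations; defaults to `targets`.
#' @param cost Soft-margin cost of the linear classifier.
#' @return One-row tibble: `accuracy`, `n_subjects`, `n_classes`, plus a
#'   `fold_accuracy` list-column of per-fold accuracies.
#' @export
loso_decode <- function(cohort, targets = NULL, train_targets = NULL,
                        cost = 1) {
  obs <- cohort_observations(cohort)
  cats <- unique(obs$category)
  if (is.null(targets)) targets <- setNames(cats, cats)
  targets <- as_target_map(targets, cats)
  train_targets <- if (is.null(train_targets)) {
    targets
  } else {
    as_target_map(train_targets, cats)
  }
  subjects <- unique(obs$subject)
  if (length(subjects) < 3) {
    abort("Leave-one-subject-out decoding needs >= 3 subjects.")
  }
  if (length(unique(targets)) == 1) {
    warn("degenerate single-class targets: accuracy is trivially 1")
    return(tibble(
      accuracy = 1, n_subjects = length(subjects), n_classes = 1L,
      fold_accuracy = list(rep(1, length(subjects)))
    ))
  }
  y_true <- factor(unname(targets[obs$category]))
  y_train_all <- factor(unname(train_targets[obs$category]),
    levels = levels(y_true)
  )
  fold_acc <- vapply(subjects, function(s) {
    tr <- obs$subject != s
    te <- !tr
    if (length(unique(y_train_all[tr])) < length(levels(y_true))) {
      abort(sprintf(
        "Training fold for held-out subject %s is missing a target label.", s
      ))
    }
    mu <- colMeans(obs$features[tr, , drop = FALSE])
    sg <- apply(obs$features[tr, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    xtr <- sweep(sweep(obs$features[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    xte <- sweep(sweep(obs$features[te, , drop = FALSE], 2, mu), 2, sg, "/")
    fit <- e1071::svm(xtr, droplevels(y_train_all[tr]),
      kernel = "linear",
      cost = cost, scale = FALSE
    )
    pred <- predict(fit, xte)
    mean(as.character(pred) == as.character(y_true[te]))
  }, numeric(1))
  tibble(
    accuracy = mean(fold_acc),
    n_subjects = length(subjects),
    n_classes = length(unique(targets)),
    fold_accuracy = list(unname(fold_acc))
  )
}

as_target_map <- function(targets, cats) {
  if (inherits(targets, "cluster_solution")) targets <- targets$labels
  if (is.null(names(targets))) {
    if (length(targets) != length(cats)) {
      abort("Unnamed `targets` must have one label per category.")
    }
    names(targets) <- cats
  }
  if (!all(cats %in% names(targets))) {
    abort("`targets` must name every category present in the cohort.")
  }
  setNames(as.character(targets[cats]), cats)
}

#' Label-permutation null for leave-one-subject-out decoding
#'
#' Repeatedly permutes the category-to-label assignment across categories
#' (the same permutation applied to every subject's training observations),
#' re-runs [loso_decode()] with the permuted training map, and collects the
#' null accuracies; test folds are always evaluated against the true
#' targets, so the permutation breaks the pattern-label association.
#' Because the decoder is deterministic in the training map and at most
#' `factorial(n categories)` distinct permuted maps exist, accuracies are
#' cached per distinct map.
#'
#' The p value uses the add-one convention:
#' `(1 + #(null >= true)) / (1 + n_permutations)`.
#'
#' @param cohort,targets,cost As in [loso_decode()].
#' @param n_permutations Number of label permutations (>= 1).
#' @param seed Integer seed for the permutation draws.
#' @return A `decoding_result`: list with `granularity`, `true_accuracy`,
#'   `shuffled_accuracies`, `true_minus_shuffled`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
permutation_null <- function(cohort, targets = NULL, n_permutations = 1000,
                             seed = 1L, cost = 1) {
  n_permutations <- check_count(n_permutations, "n_permutations", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  obs_cats <- unique(cohort_observations(cohort)$category)
  if (is.null(targets)) targets <- setNames(obs_cats, obs_cats)
  targets <- as_target_map(targets, obs_cats)
  true_res <- loso_decode(cohort, targets, cost = cost)
  set.seed(seed)
  cache <- new.env(parent = emptyenv())
  null_acc <- vapply(seq_len(n_permutations), function(i) {
    perm <- sample(length(obs_cats))
    permuted <- setNames(unname(targets)[perm], obs_cats)
    key <- paste(permuted, collapse = "|")
    if (exists(key, envir = cache, inherits = FALSE)) {
      return(get(key, envir = cache))
    }
    acc <- loso_decode(cohort, targets,
      train_targets = permuted,
      cost = cost
    )$accuracy
    assign(key, acc, envir = cache)
    acc
  }, numeric(1))
  structure(
    list(
      granularity = sprintf("%d-way", length(unique(targets))),
      true_accuracy = true_res$accuracy,
      shuffled_accuracies = null_acc,
      true_minus_shuffled = true_res$accuracy - mean(null_acc),
      p_value = (1 + sum(null_acc >= true_res$accuracy)) /
        (1 + n_permutations),
      n_permutations = n_permutations,
      seed = seed
    ),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "<decoding_result> %s: true %.3f, shuffled %.3f +- %.3f, p = %.4g\n",
    x$granularity, x$true_accuracy, mean(x$shuffled_accuracies),
    sd(x$shuffled_accuracies), x$p_value
  ))
  invisible(x)
}

#' @method glance decoding_result
#' @export
glance.decoding_result <- function(x, ...) {
  tibble(
    granularity = x$granularity,
    true_accuracy = x$true_accuracy,
    null_mean = mean(x$shuffled_accuracies),
    null_sd = sd(x$shuffled_accuracies),
    true_minus_shuffled = x$true_minus_shuffled,
    p_value = x$p_value,
    n_permutations = x$n_permutations,
    seed = x$seed
  )
}

#' Leave-one-subject-out cluster decoding (k = 2..5)
#'
#' For each fold, the category clustering is derived from the training
#' subjects' group-mean patterns only (no peeking at the held-out subject),
#' and the held-out subject's category patterns are classified into those
#' cluster labels.
#'
#' @param cohort `rsa_cohort` tibble filtered to one hemisphere x region.
#' @param k Number of clusters.
#' @param cost Classifier cost.
#' @return One-row tibble: `k`, `accuracy`, `n_subjects`, with per-fold
#'   accuracies in `fold_accuracy`.
#' @export
loso_cluster_decode <- function(cohort, k, cost = 1) {
  obs <- cohort_observations(cohort)
  subjects <- unique(obs$subject)
  if (length(subjects) < 3) {
    abort("Leave-one-subject-out decoding needs >= 3 subjects.")
  }
  cats <- unique(obs$category)
  fold_acc <- vapply(subjects, function(s) {
    tr <- obs$subject != s
    group_mean <- t(vapply(cats, function(cc) {
      colMeans(obs$features[tr & obs$category == cc, , drop = FALSE])
    }, numeric(ncol(obs$features))))
    sol <- cluster_categories(group_mean, k)
    targets <- setNames(as.character(sol$labels[cats]), cats)
    y <- factor(unname(targets[obs$category]))
    mu <- colMeans(obs$features[tr, , drop = FALSE])
    sg <- apply(obs$features[tr, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    xtr <- sweep(sweep(obs$features[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    xte <- sweep(sweep(obs$features[!tr, , drop = FALSE], 2, mu), 2, sg, "/")
    if (length(unique(y[tr])) == 1) {
      return(mean(as.character(y[!tr]) == unique(as.character(y[tr]))))
    }
    fit <- e1071::svm(xtr, droplevels(y[tr]),
      kernel = "linear", cost = cost,
      scale = FALSE
    )
    mean(as.character(predict(fit, xte)) == as.character(y[!tr]))
  }, numeric(1))
  tibble(
    k = k, accuracy = mean(fold_acc), n_subjects = length(subjects),
    fold_accuracy = list(unname(fold_acc))
  )
}
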