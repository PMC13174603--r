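# Representational geometry: PCA embeddings of category patterns, pairwise
# distances, Procrustes alignment, generalized-Procrustes group templates,
# dispersion, and convex-hull spread.

new_embedding <- function(points, items, owner = NA_character_,
                          sdev = NULL) {
  rownames(points) <- items
  colnames(points) <- paste0("pc", seq_len(ncol(points)))
  structure(
    list(points = points, items = items, owner = owner, sdev = sdev,
      n_components = ncol(points)),
    class = "embedding"
  )
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf(
    "<embedding> %d items x %d components (owner: %s)\n",
    nrow(x$points), ncol(x$points), x$owner
  ))
  print(round(x$points, 3))
  invisible(x)
}

#' @method tidy embedding
#' @export
tidy.embedding <- function(x, ...) {
  dplyr::bind_cols(
    tibble(owner = x$owner, item = x$items),
    as_tibble(x$points)
  )
}

#' Embed category patterns in principal-component space
#'
#' Averages each condition's pattern across runs, z-scores every item
#' pattern across vertices, and projects the item x vertex matrix (items
#' centered) onto its leading principal components. Components are ordered
#' by explained variance with a deterministic sign convention: the
#' largest-magnitude vertex loading of each component is made positive.
#'
#' @param x Pattern matrix (vertices x run-condition columns) or an
#'   `rsa_cohort` row's `data` entry.
#' @param n_components Number of components (default 2; a single component
#'   is allowed for two-item configurations).
#' @param level `"subcategory"` (default, 10 items) or `"category"`
#'   (5 items).
#' @param owner Label stored on the configuration.
#' @return An `embedding`: item coordinates in component space.
#' @export
embed_patterns <- function(x, n_components = 2,
                           level = c("subcategory", "category"),
                           owner = NA_character_) {
  level <- match.arg(level)
  n_components <- check_count(n_components, "n_components", min = 1L)
  x <- as.matrix(x)
  if (level == "category") x <- collapse_subcategories(x)
  info <- parse_pattern_columns(x)
  items <- unique(info$condition)
  if (length(items) < n_components + 1) {
    abort("Need at least n_components + 1 items.")
  }
  item_mat <- t(vapply(items, function(cc) {
    rowMeans(x[, info$column[info$condition == cc], drop = FALSE])
  }, numeric(nrow(x))))
  # z-score each item pattern across vertices
  item_mat <- t(apply(item_mat, 1, function(v) {
    s <- sd(v)
    if (s == 0) abort("An item pattern has zero variance across vertices.")
    (v - mean(v)) / s
  }))
  centered <- scale(item_mat, center = TRUE, scale = FALSE)
  sv <- svd(centered)
  pos <- sum(sv$d > max(sv$d) * 1e-10)
  if (pos < n_components) {
    abort(sprintf(
      "Input is rank %d; cannot extract %d components.", pos, n_components
    ))
  }
  flip <- vapply(seq_len(n_components), function(j) {
    load <- sv$v[, j]
    sign(load[which.max(abs(load))])
  }, numeric(1))
  scores <- sweep(
    sv$u[, seq_len(n_components), drop = FALSE] %*%
      diag(sv$d[seq_len(n_components)], n_components),
    2, flip, `*`
  )
  new_embedding(
    scores, items, owner,
    sdev = sv$d / sqrt(max(1, nrow(item_mat) - 1))
  )
}

#' Pairwise Euclidean distances between embedded items
#'
#' @param cfg An `embedding`.
#' @return Tibble of unordered item pairs: `item_a`, `item_b`, `distance`.
#' @export
pairwise_distances <- function(cfg) {
  pts <- embedding_points(cfg)
  if (nrow(pts) < 2) abort("Need >= 2 items.")
  d <- as.matrix(dist(pts))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  tibble(
    item_a = rownames(d)[pairs[, 1]],
    item_b = rownames(d)[pairs[, 2]],
    distance = d[pairs]
  )
}

embedding_points <- function(cfg) {
  if (inherits(cfg, "embedding")) {
    return(cfg$points)
  }
  m <- as.matrix(cfg)
  if (is.null(rownames(m))) rownames(m) <- paste0("item", seq_len(nrow(m)))
  m
}

#' Within-cluster spread vs between-centroid distance
#'
#' `within_cluster_mean` is the mean Euclidean distance among items sharing
#' a cluster (singleton clusters contribute nothing); the between statistic
#' is the Euclidean distance between cluster centroids computed in the
#' embedding space (averaged over centroid pairs when there are more than
#' two clusters).
#'
#' @param cfg An `embedding`.
#' @param clusters Either a [block_scheme()] (items mapped to blocks by
#'   their category prefix) or a named vector mapping each item to a
#'   cluster.
#' @return One-row tibble: `within_cluster_mean`, `between_centroid_distance`.
#' @export
axis_contrast <- function(cfg, clusters) {
  pts <- embedding_points(cfg)
  items <- rownames(pts)
  if (inherits(clusters, "block_scheme")) {
    block_of <- setNames(
      rep(names(clusters$blocks), lengths(clusters$blocks)),
      unlist(clusters$blocks, use.names = FALSE)
    )
    cl <- block_of[condition_category(items)]
  } else {
    cl <- clusters[items]
  }
  if (anyNA(cl)) abort("Every item must map to a cluster.")
  within <- c()
  for (g in unique(cl)) {
    idx <- which(cl == g)
    if (length(idx) >= 2) {
      within <- c(within, as.vector(dist(pts[idx, , drop = FALSE])))
    }
  }
  if (length(within) == 0) {
    abort("Within-cluster spread undefined: all clusters are singletons.")
  }
  cents <- t(vapply(
    unique(cl),
    function(g) colMeans(pts[cl == g, , drop = FALSE]),
    numeric(ncol(pts))
  ))
  if (nrow(cents) < 2) abort("Between-centroid distance needs >= 2 clusters.")
  tibble(
    within_cluster_mean = mean(within),
    between_centroid_distance = mean(dist(cents))
  )
}

#' Full Procrustes alignment of one configuration onto another
#'
#' Translates, uniformly scales and orthogonally rotates (reflection
#' permitted) the source configuration to minimize the summed squared
#' distance to the target. The Procrustes distance is the residual sum of
#' squares normalized by the centered target's sum of squares; template
#' similarity is the Pearson correlation between the flattened aligned
#' source and target coordinates.
#'
#' @param source,target `embedding`s (or item x component matrices) with the
#'   same items and number of components.
#' @param scale Allow uniform scaling (default `TRUE`).
#' @param reflection Allow reflections (default `TRUE`).
#' @return List with `aligned` (an `embedding`) and `report` (one-row
#'   tibble: `procrustes_distance`, `template_similarity`, `scale`,
#'   `reflection_used`).
#' @export
procrustes_align <- function(source, target, scale = TRUE,
                             reflection = TRUE) {
  xs <- embedding_points(source)
  xt <- embedding_points(target)
  if (!identical(dim(xs), dim(xt))) {
    abort("Source and target must have the same items and components.")
  }
  if (!is.null(rownames(xs)) && !is.null(rownames(xt)) &&
    !identical(rownames(xs), rownames(xt))) {
    abort("Source and target item labels differ.")
  }
  cs <- colMeans(xs)
  ct <- colMeans(xt)
  xsc <- sweep(xs, 2, cs)
  xtc <- sweep(xt, 2, ct)
  ss_s <- sum(xsc^2)
  ss_t <- sum(xtc^2)
  if (ss_s == 0 || ss_t == 0) {
    abort("Degenerate configuration: all points coincident.")
  }
  sv <- svd(crossprod(xsc, xtc))
  d <- sv$d
  u <- sv$u
  v <- sv$v
  refl <- det(u %*% t(v)) < 0
  if (!reflection && refl) {
    j <- ncol(u)
    u[, j] <- -u[, j]
    d[j] <- -d[j]
    refl <- FALSE
  }
  rot <- u %*% t(v)
  s <- if (scale) sum(d) / ss_s else 1
  aligned <- sweep(s * xsc %*% rot, 2, ct, `+`)
  rss <- sum((xtc - s * xsc %*% rot)^2)
  report <- tibble(
    procrustes_distance = rss / ss_t,
    template_similarity = cor(as.vector(aligned), as.vector(xt)),
    scale = s,
    reflection_used = refl
  )
  items <- rownames(xt) %||% paste0("item", seq_len(nrow(xt)))
  list(
    aligned = new_embedding(aligned, items,
      owner = if (inherits(source, "embedding")) source$owner else NA_character_
    ),
    report = report
  )
}

#' Generalized-Procrustes group template
#'
#' Iteratively aligns every configuration to the current mean shape and
#' re-averages (the mean re-normalized to unit centroid size each round)
#' until the mean moves less than `tol` or `max_iter` rounds.
#'
#' @param cfgs List of `embedding`s with identical items.
#' @param tol Convergence threshold on mean movement (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return An `embedding` (owner `"template"`), with the iteration count in
#'   attribute `iterations`.
#' @export
group_template <- function(cfgs, tol = 1e-8, max_iter = 100) {
  if (length(cfgs) < 2) abort("Need >= 2 configurations.")
  pts <- lapply(cfgs, embedding_points)
  items <- rownames(pts[[1]])
  for (p in pts) {
    if (!identical(rownames(p), items)) {
      abort("All configurations must share the same item set and order.")
    }
  }
  normalize <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  mean_shape <- normalize(pts[[1]])
  iter <- 0L
  repeat {
    iter <- iter + 1L
    aligned <- lapply(pts, function(p) {
      procrustes_align(p, mean_shape)$aligned$points
    })
    new_mean <- normalize(Reduce(`+`, aligned) / length(aligned))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol || iter >= max_iter) break
  }
  out <- new_embedding(mean_shape, items, owner = "template")
  attr(out, "iterations") <- iter
  out
}

#' Dispersion of configurations around a template
#'
#' Mean Procrustes distance from each configuration to the (group) template.
#'
#' @param cfgs List of `embedding`s.
#' @param template Template `embedding`; defaults to [group_template()] of
#'   `cfgs`.
#' @return One-row tibble: `dispersion` (mean), `n`, plus per-configuration
#'   distances in the `distances` list-column.
#' @export
dispersion <- function(cfgs, template = NULL) {
  if (is.null(template)) template <- group_template(cfgs)
  d <- vapply(cfgs, function(cfg) {
    procrustes_align(cfg, template)$report$procrustes_distance
  }, numeric(1))
  tibble(dispersion = mean(d), n = length(d), distances = list(d))
}

#' Convex hull area of a 2-D configuration
#'
#' Area of the minimal polygon enclosing all items in the first two
#' components (shoelace formula over the hull vertices).
#'
#' @param cfg An `embedding` (or points matrix) with >= 3 non-collinear
#'   points.
#' @return Area (component units squared).
#' @export
convex_hull_area <- function(cfg) {
  pts <- embedding_points(cfg)[, 1:2, drop = FALSE]
  if (nrow(pts) < 3) abort("Convex hull area needs >= 3 points.")
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[hull, 1]
  hy <- pts[hull, 2]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (area <= .Machine$double.eps * max(1, sum(pts^2))) {
    abort("Zero-area hull: points are collinear or coincident.")
  }
  area
}
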