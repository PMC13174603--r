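# Build a pattern matrix whose item patterns are prescribed rows (one run).
rows_as_archive <- function(rows, items = rsa_categories()) {
  m <- t(rows)
  out <- cbind(m, m) # two identical "runs"
  colnames(out) <- c(
    sprintf("run1_%s", items), sprintf("run2_%s", items)
  )
  out
}

test_that("two items embed symmetrically about the origin on PC1", {
  set.seed(1)
  rows <- rbind(rnorm(30), rnorm(30))
  x <- rows_as_archive(rows, items = c("faces", "bodies"))
  emb <- embed_patterns(x, n_components = 1, level = "category")
  expect_equal(emb$points[1, 1], -emb$points[2, 1], tolerance = 1e-10)
})

test_that("exactly planar item sets are embedded without distortion", {
  set.seed(2)
  nv <- 60
  u <- rnorm(nv); u <- u - mean(u); u <- u / sqrt(sum(u^2))
  v <- rnorm(nv); v <- v - mean(v); v <- v - u * sum(u * v)
  v <- v / sqrt(sum(v^2))
  coords <- cbind(c(3, -1, 0, 2, -4), c(1, 2, -2, 0, 3))
  rows <- coords %*% rbind(u, v)
  x <- rows_as_archive(rows)
  emb <- embed_patterns(x, n_components = 2, level = "category")
  # z-scoring rescales each item pattern; distances must match the
  # z-scored planar configuration computed independently
  zrows <- t(apply(rows, 1, function(r) (r - mean(r)) / sd(r)))
  expect_equal(
    as.matrix(dist(emb$points)), as.matrix(dist(zrows)),
    ignore_attr = TRUE, tolerance = 1e-9
  )
})

test_that("component variances equal an independent eigendecomposition", {
  set.seed(3)
  rows <- matrix(rnorm(5 * 100), 5)
  x <- rows_as_archive(rows)
  emb <- embed_patterns(x, n_components = 4, level = "category")
  zrows <- t(apply(rows, 1, function(r) (r - mean(r)) / sd(r)))
  centered <- scale(zrows, center = TRUE, scale = FALSE)
  ev <- eigen(centered %*% t(centered) / 4, symmetric = TRUE)$values
  expect_equal(emb$sdev[1:4]^2, ev[1:4], tolerance = 1e-9)
  expect_error(embed_patterns(x, n_components = 5), "items")
})

test_that("pairwise distances match the direct Euclidean formula", {
  pts <- rbind(a = c(0, 0), b = c(3, 4), c = c(3, 4))
  d <- pairwise_distances(structure(
    list(points = pts, items = rownames(pts), owner = "x", n_components = 2),
    class = "embedding"
  ))
  expect_equal(d$distance[d$item_a == "a" & d$item_b == "b"], 5)
  expect_equal(d$distance[d$item_a == "b" & d$item_b == "c"], 0)
  set.seed(4)
  rnd <- matrix(rnorm(12), 6, 2,
    dimnames = list(paste0("i", 1:6), NULL)
  )
  dd <- pairwise_distances(rnd)
  for (r in seq_len(nrow(dd))) {
    expect_equal(
      dd$distance[r],
      sqrt(sum((rnd[dd$item_a[r], ] - rnd[dd$item_b[r], ])^2))
    )
  }
})

test_that("within-cluster spread and centroid separation are computed in space", {
  pts <- rbind(
    f = c(-1, 0), b = c(1, 0),
    p = c(3, 0), o = c(5, 0)
  )
  res <- axis_contrast(pts, c(f = "an", b = "an", p = "in", o = "in"))
  expect_equal(res$within_cluster_mean, 2.0)
  expect_equal(res$between_centroid_distance, 4.0)

  res2 <- axis_contrast(
    rbind(a = c(0, 0), b = c(0, 0), c = c(1, 0), d = c(1, 0)),
    c(a = "g1", b = "g1", c = "g2", d = "g2")
  )
  expect_equal(res2$within_cluster_mean, 0)
  expect_equal(res2$between_centroid_distance, 1)

  expect_error(
    axis_contrast(pts, c(f = "w", b = "x", p = "y", o = "z")),
    "singleton"
  )
})

test_that("Procrustes alignment is exact under similarity transforms", {
  set.seed(5)
  target <- matrix(rnorm(20), 10, 2,
    dimnames = list(paste0("i", 1:10), NULL)
  )
  self <- procrustes_align(target, target)$report
  expect_equal(self$procrustes_distance, 0, tolerance = 1e-12)
  expect_equal(self$template_similarity, 1, tolerance = 1e-12)

  th <- pi / 2
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  source <- 3 * target %*% rot + 2
  rownames(source) <- rownames(target)
  rep2 <- procrustes_align(source, target)$report
  expect_lt(rep2$procrustes_distance, 1e-9)
  expect_equal(rep2$template_similarity, 1, tolerance = 1e-9)

  flat <- matrix(1, 10, 2, dimnames = list(rownames(target), NULL))
  expect_error(procrustes_align(flat, target), "coincident")
})

test_that("Procrustes residual matches the independent SVD oracle", {
  skip_if_not_installed("vegan")
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rnorm(16), 8, 2, dimnames = list(paste0("i", 1:8), NULL))
    y <- matrix(rnorm(16), 8, 2, dimnames = list(paste0("i", 1:8), NULL))
    mine <- procrustes_align(x, y)$report$procrustes_distance
    oracle <- vegan::procrustes(y, x, symmetric = TRUE)$ss
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
})

test_that("group templates reproduce shared shapes and ignore input order", {
  set.seed(6)
  shape <- matrix(rnorm(10), 5, 2, dimnames = list(letters[1:5], NULL))
  same <- lapply(1:4, function(i) shape)
  templ <- group_template(same)
  expect_equal(dispersion(same, templ)$dispersion, 0, tolerance = 1e-12)

  th <- runif(1, 0, 2 * pi)
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pair <- list(shape, shape %*% rot)
  rownames(pair[[2]]) <- rownames(shape)
  templ2 <- group_template(pair)
  expect_lt(procrustes_align(shape, templ2)$report$procrustes_distance, 1e-9)

  cfgs <- lapply(1:5, function(i) {
    m <- shape + matrix(rnorm(10, sd = 0.3), 5, 2)
    rownames(m) <- rownames(shape)
    m
  })
  t_fwd <- group_template(cfgs)
  t_rev <- group_template(rev(cfgs))
  expect_lt(
    procrustes_align(t_fwd, t_rev)$report$procrustes_distance, 1e-6
  )
})

test_that("convex hull areas match shoelace values and a brute-force oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  rownames(sq) <- paste0("i", 1:4)
  expect_equal(convex_hull_area(sq), 1.0)
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  rownames(tri) <- paste0("i", 1:3)
  expect_equal(convex_hull_area(tri), 0.5)
  coll <- cbind(1:4, 2 * (1:4))
  rownames(coll) <- paste0("i", 1:4)
  expect_error(convex_hull_area(coll), "hull")

  # brute-force oracle: hull points are those not strictly inside any
  # triangle of other points; shoelace over the angular ordering
  set.seed(7)
  pts <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("i", 1:20), NULL))
  in_triangle <- function(p, a, b, c) {
    s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
    s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
    (s1 > 1e-12 & s2 > 1e-12 & s3 > 1e-12) |
      (s1 < -1e-12 & s2 < -1e-12 & s3 < -1e-12)
  }
  n <- nrow(pts)
  interior <- vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    any(apply(combn(others, 3), 2, function(tr) {
      in_triangle(pts[i, ], pts[tr[1], ], pts[tr[2], ], pts[tr[3], ])
    }))
  }, logical(1))
  hull <- pts[!interior, , drop = FALSE]
  ctr <- colMeans(hull)
  ord <- order(atan2(hull[, 2] - ctr[2], hull[, 1] - ctr[1]))
  hx <- hull[ord, 1]; hy <- hull[ord, 2]
  oracle <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  expect_equal(convex_hull_area(pts), oracle, tolerance = 1e-10)
})

test_that("dispersion grows with subject idiosyncrasy", {
  # one seed across the grid: identical templates and noise realizations,
  # so only the idiosyncrasy scale differs between points
  grid <- c(0, 0.3, 0.7, 1.2, 2)
  disp <- vapply(seq_along(grid), function(i) {
    co <- small_cohort(
      n_children = 12, n_adults = 0, n_vertices = 40,
      animacy = 1.2, word_axis = 0.3, subject_noise_sd = grid[i],
      run_noise_sd = 0.3, seed = 500
    )
    cfgs <- lapply(co$data, embed_patterns)
    dispersion(cfgs)$dispersion
  }, numeric(1))
  expect_gt(cor(grid, disp, method = "spearman"), 0.9)
})
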