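make_splits <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) random_simmat(seed = seed * 10 + i))
}

test_that("stability and coupling behave on identical and negated splits", {
  m <- random_simmat(seed = 2)
  expect_equal(split_stability(list(m, m, m)), 1.0)
  expect_equal(split_stability(list(m, -m)), -1.0)
  expect_equal(cross_coupling(list(m, m), list(m)), 1.0)
  expect_equal(cross_coupling(list(m), list(-m)), -1.0)
  # identical everything: stability = coupling, signed distance 0
  st <- split_stability(list(m, m))
  cp <- cross_coupling(list(m, m), list(m, m))
  expect_equal(signed_identity_distance(st, cp), 0)
  flat <- matrix(0.2, 5, 5)
  expect_error(split_stability(list(flat, m)), "[Cc]onstant")
})

test_that("stability and coupling match brute-force pair enumeration", {
  pf <- make_splits(3, seed = 4)
  vt <- make_splits(2, seed = 9)
  cells <- function(m) c(diag(m), m[upper.tri(m)])
  st_oracle <- mean(c(
    brute_pearson(cells(pf[[1]]), cells(pf[[2]])),
    brute_pearson(cells(pf[[1]]), cells(pf[[3]])),
    brute_pearson(cells(pf[[2]]), cells(pf[[3]]))
  ))
  expect_equal(split_stability(pf), st_oracle, tolerance = 1e-12)

  cp_oracle <- mean(vapply(pf, function(a) {
    mean(vapply(vt, function(b) brute_pearson(cells(a), cells(b)), numeric(1)))
  }, numeric(1)))
  expect_equal(cross_coupling(pf, vt), cp_oracle, tolerance = 1e-12)
})

test_that("signed identity-line distance is antisymmetric in its axes", {
  s <- runif(10, -1, 1)
  c2 <- runif(10, -1, 1)
  expect_identical(
    signed_identity_distance(s, c2),
    -signed_identity_distance(c2, s)
  )
})

test_that("category coordinates restrict to the category's row cells", {
  m <- random_simmat(seed = 6)
  res <- category_coordinates(list(m, m), list(m, m))
  expect_equal(res$stability, rep(1, 5))
  expect_equal(res$coupling, rep(1, 5))

  pf <- make_splits(2, seed = 11)
  vt <- make_splits(2, seed = 13)
  res2 <- category_coordinates(pf, vt)
  for (i in seq_along(rsa_categories())) {
    cc <- rsa_categories()[i]
    st_o <- brute_pearson(pf[[1]][cc, ], pf[[2]][cc, ])
    cp_o <- mean(c(
      brute_pearson(pf[[1]][cc, ], vt[[1]][cc, ]),
      brute_pearson(pf[[1]][cc, ], vt[[2]][cc, ]),
      brute_pearson(pf[[2]][cc, ], vt[[1]][cc, ]),
      brute_pearson(pf[[2]][cc, ], vt[[2]][cc, ])
    ))
    expect_equal(res2$stability[res2$category == cc], st_o, tolerance = 1e-12)
    expect_equal(res2$coupling[res2$category == cc], cp_o, tolerance = 1e-12)
  }
})

test_that("per-subject coupling points agree with the underlying fold statistics", {
  co <- generate_cohort(cohort_spec(
    n_children = 2, n_adults = 2, n_vertices = 40,
    regions = c("VLPFC", "VTC"), hemispheres = "RH", seed = 14
  ))
  pts <- coupling_points(co)
  expect_equal(nrow(pts), 4)
  expect_true(all(abs(pts$coupling) <= 1 & abs(pts$stability) <= 1))
  s1 <- pts$subject_id[1]
  pfc <- co$data[co$subject_id == s1 & co$region == "VLPFC"][[1]]
  vtc <- co$data[co$subject_id == s1 & co$region == "VTC"][[1]]
  pf <- attr(loro_similarity(pfc, keep_folds = TRUE), "folds")
  vf <- attr(loro_similarity(vtc, keep_folds = TRUE), "folds")
  expect_equal(pts$stability[1], split_stability(pf))
  expect_equal(pts$coupling[1], cross_coupling(pf, vf))
  expect_equal(
    pts$signed_distance,
    (pts$stability - pts$coupling) / sqrt(2)
  )
})

test_that("matched region structure equalizes stability and coupling", {
  # Both regions carry the same realized category templates with
  # independent noise, and the splits compared are built from disjoint run
  # pairs (so no split shares measurement noise with another): expected
  # stability then equals expected coupling. LORO folds from the same
  # region share training runs and would inflate stability; the disjoint
  # construction isolates the invariant itself.
  set.seed(15)
  nv <- 40
  cats <- rsa_categories()
  templ <- matrix(rnorm(nv * 5), nv, dimnames = list(NULL, cats))
  half_archive <- function() {
    mats <- lapply(1:2, function(r) {
      m <- templ + matrix(rnorm(nv * 5), nv)
      colnames(m) <- sprintf("run%d_%s", r, cats)
      m
    })
    do.call(cbind, mats)
  }
  diffs <- vapply(1:100, function(s) {
    pf <- list(
      loro_similarity(half_archive()),
      loro_similarity(half_archive())
    )
    vt <- list(
      loro_similarity(half_archive()),
      loro_similarity(half_archive())
    )
    split_stability(pf) - cross_coupling(pf, vt)
  }, numeric(1))
  tt <- paired_t(diffs)
  expect_lt(abs(tt$statistic), 3)
})

test_that("displacement vectors and their permutation test behave", {
  pts <- tidyr::expand_grid(
    subject_id = sprintf("s%02d", 1:8),
    category = rsa_categories()
  ) |>
    dplyr::mutate(
      group = ifelse(subject_id <= "s04", "child", "adult"),
      coupling = 0.2, stability = 0.3
    )
  same <- displacement(pts, n_permutations = 0)
  expect_equal(same$magnitude, rep(0, 5))

  shifted <- pts |>
    dplyr::mutate(
      coupling = coupling + ifelse(group == "adult", 0.3, 0),
      stability = stability + ifelse(group == "adult", 0.4, 0)
    )
  res <- displacement(shifted, n_permutations = 0)
  expect_equal(res$magnitude, rep(0.5, 5), tolerance = 1e-12)
  expect_equal(res$delta_coupling, rep(0.3, 5), tolerance = 1e-12)

  one_group <- dplyr::mutate(pts, group = "child")
  expect_error(displacement(one_group), "child and adult")
})
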