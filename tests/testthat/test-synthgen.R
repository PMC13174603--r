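test_that("identical spec and seed reproduce cohorts byte-identically", {
  sp <- cohort_spec(
    n_children = 2, n_adults = 2, n_vertices = 30,
    regions = "VLPFC", hemispheres = c("LH", "RH"), seed = 42
  )
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a$data, b$data)
  expect_identical(a$age, b$age)

  t1 <- generate_tissue(5, c(5, 30), "dip", n_voxels = 20, seed = 7)
  t2 <- generate_tissue(5, c(5, 30), "dip", n_voxels = 20, seed = 7)
  expect_identical(t1, t2)

  sets <- list(myelin = c("PLP1", "MAG"), synapse = c("SYN1", "DLG4"))
  e1 <- generate_expression(sets, 5:40, c(myelin = TRUE, synapse = FALSE),
    seed = 3, noise_sd = 0.1
  )
  e2 <- generate_expression(sets, 5:40, c(myelin = TRUE, synapse = FALSE),
    seed = 3, noise_sd = 0.1
  )
  expect_identical(e1, e2)
})

test_that("invalid cohort specs fail naming the offending field", {
  expect_error(cohort_spec(n_runs = 1), "n_runs")
  expect_error(cohort_spec(run_noise_sd = 0), "run_noise_sd")
  expect_error(cohort_spec(subject_noise_sd = -1), "subject_noise_sd")
  expect_error(cohort_spec(n_vertices = 2), "n_vertices")
  expect_error(
    cohort_spec(strengths = data.frame(
      group = "child", hemisphere = "LH", region = "VLPFC",
      animacy = -1, word_axis = 0
    )),
    "animacy"
  )
})

test_that("structureless patterns yield no cross-run category structure", {
  co <- small_cohort(
    n_children = 200, n_adults = 0, n_vertices = 40,
    animacy = 0, word_axis = 0, subject_noise_sd = 0, n_runs = 2,
    seed = 21
  )
  diffs <- vapply(co$data, function(d) {
    within_between_category(loro_similarity(d))$difference
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("any positive structure strength makes within exceed between", {
  for (st in list(c(1.5, 0), c(0, 1.5))) {
    co <- small_cohort(
      n_children = 40, n_adults = 0, n_vertices = 50,
      animacy = st[1], word_axis = st[2], subject_noise_sd = 0, seed = 8
    )
    diffs <- vapply(co$data, function(d) {
      within_between_category(loro_similarity(d))$difference
    }, numeric(1))
    expect_gt(mean(diffs) / (sd(diffs) / sqrt(length(diffs))), 3)
  }
})

test_that("within-minus-between grows monotonically with animacy strength", {
  grid <- c(0.2, 0.5, 0.9, 1.4, 2)
  means <- vapply(seq_along(grid), function(i) {
    co <- small_cohort(
      n_children = 100, n_adults = 0, n_vertices = 40,
      animacy = grid[i], word_axis = 0, seed = 100 + i
    )
    mean(vapply(co$data, function(d) {
      within_between_category(loro_similarity(d))$difference
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(grid, means, method = "spearman"), 0.9)
})

test_that("tissue trajectories have the configured shapes", {
  noiseless <- function(traj) {
    generate_tissue(30, c(5, 54), traj,
      n_voxels = 10, seed = 5,
      mtv_noise_sd = 0, r1_noise_base = 0, r1_noise_slope = 0
    )
  }
  lin <- roi_mean(noiseless("linear"), "r1") |> dplyr::arrange(age)
  expect_true(all(diff(lin$value) > 0))

  dip <- noiseless("dip")
  m <- roi_mean(dip, "r1")
  dip_val <- m$value[which.min(abs(m$age - 17))]
  young <- m$value[which.min(abs(m$age - 10))]
  old <- m$value[which.min(abs(m$age - 30))]
  expect_lt(dip_val, young)
  expect_lt(dip_val, old)

  noisy <- generate_tissue(10, c(5, 54), "linear", n_voxels = 50, seed = 2)
  expect_true(all(noisy$mtv > 0 & noisy$mtv < 1))
  expect_true(all(noisy$r1 > 0))
})

test_that("tissue generation validates its age range", {
  expect_error(generate_tissue(5, c(3, 30), "linear"), "\\[5, 54\\]")
  expect_error(generate_tissue(5, c(30, 10), "linear"), "age_range")
})

test_that("expression curves decline in adolescence and recover only when flagged", {
  sets <- list(myelin = myelin_genes(), synapse = c("SYN1", "DLG4", "SHANK3"))
  expr <- generate_expression(sets, 5:40,
    recovery = c(myelin = TRUE, synapse = FALSE), seed = 1, noise_sd = 0
  )
  win <- function(df) mean(df$expression[df$age > 11 & df$age < 20])
  post <- function(df) mean(df$expression[df$age >= 20])
  pre <- function(df) mean(df$expression[df$age <= 11])
  for (s in names(sets)) {
    df <- expr[expr$set == s, ]
    expect_gt(pre(df), win(df)) # adolescent decline in both sets
  }
  expect_gt(post(expr[expr$set == "myelin", ]), win(expr[expr$set == "myelin", ]))
  expect_lte(
    post(expr[expr$set == "synapse", ]),
    win(expr[expr$set == "synapse", ])
  )
})

test_that("a gene in zero or two sets is rejected", {
  expect_error(
    generate_expression(
      list(a = c("G1", "G2"), b = c("G2", "G3")), 5:30,
      recovery = c(a = TRUE, b = FALSE)
    ),
    "G2"
  )
})

test_that("cohort archives round-trip through TSV unchanged", {
  co <- small_cohort(n_children = 2, n_adults = 1, n_vertices = 20, seed = 6)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "spec.json")))
  back <- read_cohort(dir)
  expect_equal(nrow(back), nrow(co))
  for (i in seq_len(nrow(co))) {
    expect_equal(back$data[[i]], co$data[[i]], tolerance = 1e-12)
  }
  expect_equal(back$group, co$group)
})
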