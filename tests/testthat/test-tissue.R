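test_that("age groups use the inclusive developmental bins", {
  expect_equal(as.character(assign_age_group(10)), "kids")
  expect_equal(as.character(assign_age_group(11)), "teens")
  expect_equal(as.character(assign_age_group(17.9)), "teens")
  expect_equal(as.character(assign_age_group(18)), "young_adults")
  expect_equal(as.character(assign_age_group(25)), "adults")
  expect_equal(as.character(assign_age_group(54)), "adults")
  expect_error(assign_age_group(60), "excluded")
  expect_error(assign_age_group(4), "excluded")
})

test_that("ROI means are plain voxel averages", {
  tt <- tibble::tibble(
    subject_id = "s1", age = 20, hemisphere = "RH", lobe = "VLPFC",
    voxel = 1:2, r1 = c(1, 3), mtv = c(0.2, 0.4)
  )
  expect_equal(roi_mean(tt, "r1")$value, 2)
  expect_equal(roi_mean(tt, "mtv")$value, 0.3)
  expect_error(roi_mean(tt[0, ], "r1"), "Empty")
  set.seed(1)
  tt2 <- generate_tissue(3, c(10, 30), "linear", n_voxels = 25, seed = 2)
  m <- roi_mean(tt2, "r1")
  for (i in seq_len(nrow(m))) {
    expect_equal(
      m$value[i],
      mean(tt2$r1[tt2$subject_id == m$subject_id[i]])
    )
  }
})

test_that("R1 vs 1/WVF fits recover exact and noisy linear relations", {
  expect_equal(1 / (1 - 0.3), 1.4286, tolerance = 1e-4)
  mtv <- seq(0.2, 0.4, length.out = 20)
  tt <- tibble::tibble(
    subject_id = "s1", age = 25, hemisphere = "RH", lobe = "VLPFC",
    voxel = 1:20, mtv = mtv, r1 = 0.4 + 0.9 / (1 - mtv)
  )
  fit <- r1_vs_invwvf_fit(tt)
  expect_equal(fit$slope, 0.9, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.4, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # noisy line vs closed-form normal equations
  set.seed(4)
  x <- 1 / (1 - mtv)
  y <- 0.5 + 0.7 * x + rnorm(20, sd = 0.05)
  tt2 <- dplyr::mutate(tt, r1 = y)
  fit2 <- r1_vs_invwvf_fit(tt2)
  slope_oracle <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
  expect_equal(fit2$slope, slope_oracle, tolerance = 1e-10)

  bad <- dplyr::mutate(tt, mtv = 0.3)
  expect_error(r1_vs_invwvf_fit(bad), "Zero variance")
})

test_that("children show steeper generated R1-MTV slopes than adults", {
  tt <- dplyr::bind_rows(
    generate_tissue(12, c(5, 10), "linear", n_voxels = 80, seed = 5),
    dplyr::mutate(
      generate_tissue(12, c(25, 54), "linear", n_voxels = 80, seed = 6),
      subject_id = paste0(subject_id, "-a")
    )
  )
  fits <- r1_vs_invwvf_fit(tt)
  res <- slope_contrast(fits, c("kids", "adults"))
  expect_gt(res$mean_a, res$mean_b)
})

test_that("heterogeneity regression recovers exact and constant slopes", {
  per_sd <- function(sds, ages) {
    dplyr::bind_rows(lapply(seq_along(sds), function(i) {
      tibble::tibble(
        subject_id = sprintf("s%d", i), age = ages[i], hemisphere = "RH",
        lobe = "VLPFC", voxel = 1:4,
        r1 = 1 + sds[i] * c(-1.5, -0.5, 0.5, 1.5) /
          stats::sd(c(-1.5, -0.5, 0.5, 1.5)),
        mtv = 0.3
      )
    }))
  }
  ages <- c(10, 20, 30, 40)
  flat <- suppressWarnings(heterogeneity_vs_age(per_sd(rep(0.05, 4), ages)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  line <- suppressWarnings(heterogeneity_vs_age(per_sd(0.01 + 0.002 * ages, ages)))
  expect_equal(line$slope, 0.002, tolerance = 1e-9)
  expect_error(
    heterogeneity_vs_age(per_sd(rep(0.05, 4), rep(20, 4))),
    "distinct ages"
  )
})

test_that("gene-set normalization anchors the adolescence window at 1", {
  expr1 <- tibble::tibble(
    gene = "G1", set = "s", age = 5:30, expression = 4
  )
  out <- normalize_gene_sets(expr1)
  expect_equal(out$value, rep(1, nrow(out)))

  expr2 <- tibble::tibble(
    gene = "G2", set = "s", age = 5:30,
    expression = ifelse(5:30 >= 20, 6, 3)
  )
  out2 <- normalize_gene_sets(expr2)
  expect_equal(out2$value[out2$age >= 20], rep(2, 11))

  # two-gene set, hand-computed normalization
  expr3 <- dplyr::bind_rows(
    tibble::tibble(gene = "A", set = "s", age = c(12, 15, 25),
      expression = c(2, 4, 9)),
    tibble::tibble(gene = "B", set = "s", age = c(12, 15, 25),
      expression = c(10, 10, 5))
  )
  out3 <- normalize_gene_sets(expr3)
  # window means: A = 3, B = 10; at age 25: mean(9/3, 5/10) = 1.75
  expect_equal(out3$value[out3$age == 25], 1.75)
  expect_equal(out3$value[out3$age == 12], mean(c(2 / 3, 1)))

  # per-gene window mean maps to exactly 1
  sets <- list(m = myelin_genes())
  expr4 <- generate_expression(sets, 5:40, c(m = TRUE),
    seed = 2,
    noise_sd = 0.2
  )
  win <- expr4$age > 11 & expr4$age < 20
  win_means <- tapply(expr4$expression[win], expr4$gene[win], mean)
  norm_means <- tapply(
    expr4$expression[win] / win_means[expr4$gene[win]],
    expr4$gene[win], mean
  )
  expect_equal(as.numeric(norm_means), rep(1, length(norm_means)),
    tolerance = 1e-12
  )

  zero <- tibble::tibble(
    gene = "GZ", set = "s", age = c(12, 25), expression = c(0, 1)
  )
  expect_error(normalize_gene_sets(zero), "GZ")
})

test_that("dip trajectories produce a lobe x age-group interaction", {
  hits <- vapply(1:12, function(r) {
    tt <- dplyr::bind_rows(
      balanced_tissue(6, "dip", "VLPFC", seed = 1000 + 10 * r),
      balanced_tissue(6, "linear", "VTC", seed = 2000 + 10 * r)
    )
    rm <- roi_mean(tt, "r1")
    res <- trajectory_anova(rm)
    res$p_value[res$term == "A:B"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
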