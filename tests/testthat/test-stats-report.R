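ct <- cohort_tables()

test_that("group summaries reproduce the published site means", {
  gs_den <- group_summary(ct$gross, "lacunar_density_per_mm3")
  expect_equal(round(gs_den$mean[gs_den$site == "AB"]), 22874)
  expect_equal(round(gs_den$mean[gs_den$site == "FB"]), 19376)
  expect_equal(gs_den$min[gs_den$site == "AB"], 20228)
  expect_equal(gs_den$max[gs_den$site == "AB"], 24108)
  gs_por <- group_summary(ct$gross, "vessel_porosity_pct")
  expect_equal(round(gs_por$mean[gs_por$site == "AB"], 1), 8.3)
  expect_equal(round(gs_por$mean[gs_por$site == "FB"], 1), 6.9)
  single <- data.frame(sample_id = c("a", "b"), patient_id = c("1", "1"),
                       site = c("AB", "FB"), m = c(5, 7))
  gs <- group_summary(single, "m")
  expect_equal(gs$mean, gs$min)
  expect_equal(gs$mean, gs$max)
  expect_error(group_summary(ct$gross, "no_such_metric"), "no_such_metric")
})

test_that("paired t statistic matches the hand formula and t CDF oracle", {
  x <- c(2, 4, 6, 8)
  y <- x - c(1, 2, 3, 4)                     # differences 1, 2, 3, 4
  res <- paired_t_test(x, y)
  d <- x - y
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * pt(-abs(t_oracle), length(d) - 1)
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$t, 3.873, tolerance = 1e-3)
  expect_equal(res$df, 3)
  expect_equal(res$p, p_oracle, tolerance = 1e-9)
  expect_equal(res$p, 0.0305, tolerance = 2e-3)
})

test_that("paired test on cohort lacunar densities gives p = 0.038", {
  pv <- cortmorph:::paired_values(ct$gross, "lacunar_density_per_mm3")
  res <- paired_t_test(pv$ab, pv$fb)
  expect_equal(round(res$p, 3), 0.038)
})

test_that("paired test is antisymmetric and rejects degenerate input", {
  x <- c(1, 3, 5, 9); y <- c(2, 2, 7, 4)
  a <- paired_t_test(x, y); b <- paired_t_test(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_error(paired_t_test(x, x), "zero variance")
  expect_error(paired_t_test(1, 2), "at least 2")
})

test_that("unpaired pooled t matches the hand computation oracle", {
  x <- c(0, 0, 1, 1); y <- c(10, 10, 11, 11)
  res <- unpaired_t_test(x, y, "pooled")
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$t, -24.49, tolerance = 1e-3)
  expect_lt(res$p, 1e-5)
  same <- unpaired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(unpaired_t_test(c(1, 1), c(1, 1)), "degenerate")
})

test_that("unpaired pooled test on the 640 nm densities gives p = 0.0049", {
  res <- unpaired_t_test(
    ct$shape$lacunar_density_per_mm3[ct$shape$site == "AB"],
    ct$shape$lacunar_density_per_mm3[ct$shape$site == "FB"], "pooled")
  expect_equal(round(res$p, 4), 0.0049)
})

test_that("build_paper_tables regenerates ratios and means from row values", {
  tabs <- build_paper_tables(ct$resolution)
  expect_equal(round(tabs$resolution$ratio, 3),
               c(1.037, 1.063, 1.139, 1.153, 1.048, 0.959))
  tabs2 <- build_paper_tables(ct$gross)
  s <- tabs2$summary
  den <- s[s$metric == "lacunar_density_per_mm3", ]
  expect_equal(round(den$mean_AB), 22874)
  expect_equal(round(den$mean_FB), 19376)
  expect_equal(round(den$p_paired, 3), 0.038)
  md <- s[s$metric == "mineral_dist50_um", ]
  expect_equal(round(md$mean_AB), 96)
  expect_equal(round(md$mean_FB), 76)
  expect_error(build_paper_tables(ct$gross[0, ]), "empty")
  orphan <- ct$gross[-2, ]
  expect_error(cortmorph:::paired_values(orphan, "vessel_porosity_pct"),
               "unpaired")
})

test_that("orientation and permeability tables derive LOA and inverts", {
  tabs <- build_paper_tables(ct$orientation)
  o <- tabs$orientation
  expect_equal(round(o$LOA[o$sample_id == "54A"] * 1e5, 2), 5.32)
  expect_equal(round(o$loa_ratio_fb_ab[o$sample_id == "54A"], 2), 0.13)
  # recomputation from the printed variances lands within one unit of the
  # last printed digit (the reference ratios used unrounded LOA values)
  expect_lt(abs(o$loa_ratio_fb_ab[o$sample_id == "57A"] - 2.71), 0.015)
  tabs2 <- build_paper_tables(ct$permeability)
  pm <- tabs2$permeability
  expect_equal(round(pm$invert[pm$sample_id == "55A"], 1), 13.0)
  expect_equal(round(pm$invert[pm$sample_id == "57F"], 1), 8.1)
})

test_that("a phantom cohort with a 3-sigma effect is detected at alpha 0.05", {
  # simulated paired cohort: per-patient densities with between-sample sd
  # ~600 and an AB-FB offset of 3 x sd
  set.seed(42)
  detected <- replicate(20, {
    ab <- rnorm(4, 22800, 600)
    fb <- ab - 1800 + rnorm(4, 0, 600)
    paired_t_test(ab, fb)$p < 0.05
  })
  expect_gte(mean(detected), 0.8)
})
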