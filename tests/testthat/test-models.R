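linear_samples <- function(n, slope = 2, intercept = 1, noise = 0, seed = 1,
                           xname = "Minor") {
  withr::with_seed(seed, {
    x <- stats::runif(n, 2.5, 3.3)
    df <- data.frame(sample_id = seq_len(n), x = x,
                     MGW = slope * x + intercept + stats::rnorm(n, 0, noise))
    names(df)[2] <- xname
    df
  })
}

test_that("sample aggregation averages grains and derives MGW", {
  grains <- data.frame(Label = 1:410,
                       Area = withr::with_seed(2, stats::runif(410, 500, 800)),
                       Minor = withr::with_seed(3, stats::runif(410, 17, 22)))
  s <- aggregate_sample(grains, sample_weight = 16400, sample_id = "plot-1")
  expect_equal(s$grain_count, 410)
  expect_equal(s$mgw, 40)
  expect_equal(s$means$Area, mean(grains$Area))
  expect_equal(s$means$Minor, mean(grains$Minor))
  expect_false("Label" %in% names(s$means))

  one <- aggregate_sample(grains[7, ], sample_weight = 41)
  expect_equal(one$means$Area, grains$Area[7])
  expect_equal(one$mgw, 41)

  no_w <- aggregate_sample(grains)
  expect_true(is.na(no_w$mgw))
  expect_error(aggregate_sample(grains[0, ]), "at least one grain")
})

test_that("linear fits recover exact laws and match closed-form OLS", {
  df <- linear_samples(25)
  m <- fit_linear(df, "Minor")
  expect_equal(m$slope, 2, tolerance = 1e-9)
  expect_equal(m$intercept, 1, tolerance = 1e-9)
  expect_equal(m$rmse, 0, tolerance = 1e-9)
  expect_equal(m$r2, 1, tolerance = 1e-9)

  noisy <- linear_samples(40, noise = 1.3, seed = 11)
  m2 <- fit_linear(noisy, "Minor")
  x <- noisy$Minor; y <- noisy$MGW
  slope_ref <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(m2$slope, slope_ref, tolerance = 1e-10)
  expect_equal(m2$intercept, mean(y) - slope_ref * mean(x), tolerance = 1e-10)
  expect_equal(m2$rmse,
               sqrt(mean((y - m2$intercept - m2$slope * x)^2)),
               tolerance = 1e-10)

  const <- df; const$Minor <- 3
  expect_error(fit_linear(const, "Minor"), "zero variance")
  expect_error(fit_linear(df[1:2, ], "Minor"), ">= 3 samples")
})

test_that("k-fold cross-validation splits evenly and is seed-reproducible", {
  df <- linear_samples(180, noise = 0)
  cv <- kfold_cv(df, "Minor", k = 10, seed = 4)
  expect_equal(cv$fold_sizes, rep(18, 10))
  expect_lte(cv$rmse_mean, 1e-9)

  noisy <- linear_samples(60, noise = 1.1, seed = 21)
  cv1 <- kfold_cv(noisy, "Minor", k = 5, seed = 7)
  cv2 <- kfold_cv(noisy, "Minor", k = 5, seed = 7)
  expect_identical(cv1$fold_rmse, cv2$fold_rmse)
  cv3 <- kfold_cv(noisy, "Minor", k = 5, seed = 8)
  expect_false(identical(cv1$fold_rmse, cv3$fold_rmse))

  expect_error(kfold_cv(noisy, "Minor", k = 61), "exceeds")
  expect_error(kfold_cv(noisy, "Minor", k = 1), ">= 2")
})

test_that("in-sample RMSE does not exceed CV RMSE in expectation", {
  ins <- cvs <- numeric(20)
  for (r in 1:20) {
    df <- linear_samples(40, noise = 1.1, seed = 100 + r)
    ins[r] <- fit_linear(df, "Minor")$rmse
    cvs[r] <- kfold_cv(df, "Minor", k = 10, seed = r)$rmse_mean
  }
  expect_lt(mean(ins), mean(cvs))
})

test_that("published coefficients are complete and reproduce worked examples", {
  co <- published_coefficients()
  expect_equal(nrow(co), 36)  # 12 indices x 3 unit systems
  expect_setequal(unique(co$index), catalogue_names(selected = TRUE))
  expect_setequal(unique(co$unit_system),
                  c("original-pixel", "enhanced-pixel", "SI"))

  expect_equal(predict_published(15, "Area", "SI"),
               3.4546529 * 15 - 10.50562, tolerance = 1e-9)
  expect_equal(predict_published(15, "Area", "SI"), 41.314, tolerance = 1e-3)
  expect_equal(predict_published(2.897, "Minor", "SI"), 38.534,
               tolerance = 1e-3)
  # index value of zero returns the intercept exactly
  expect_equal(predict_published(0, "Minor", "SI"), -37.43548)
  expect_error(predict_published(1, "Banana", "SI"), "available")
})

test_that("published-style prediction round-trips through a fitted model", {
  df <- linear_samples(30, noise = 0.9, seed = 5)
  m <- fit_linear(df, "Minor", unit_system = "SI")
  co <- data.frame(index = "Minor", unit_system = "SI",
                   slope = m$slope, intercept = m$intercept)
  pred1 <- predict_published(df$Minor, "Minor", "SI", coeffs = co)
  pred2 <- predict(m, df)
  expect_equal(pred1, pred2, tolerance = 1e-12)
})

test_that("unit rescaling transforms the slope and preserves the fit", {
  s <- 0.15
  df <- linear_samples(40, noise = 0.7, seed = 9, xname = "Minor")
  df$Minor_px <- df$Minor / s
  m_mm <- fit_linear(df, "Minor")
  m_px <- fit_linear(df, "Minor_px")
  expect_equal(m_mm$slope, m_px$slope / s, tolerance = 1e-9)
  expect_equal(m_mm$intercept, m_px$intercept, tolerance = 1e-9)
  expect_equal(m_mm$r2, m_px$r2, tolerance = 1e-9)
  expect_equal(m_mm$rmse, m_px$rmse, tolerance = 1e-9)
})

test_that("correlation reports mirror the per-group layout", {
  df <- linear_samples(24, noise = 0, xname = "Minor")
  df$Area <- withr::with_seed(14, df$Minor * stats::runif(24, 0.9, 1.1) * 5)
  rep1 <- correlation_report(df, indices = c("Minor", "Area"))
  expect_equal(rep1$Overall[rep1$index == "Minor"], 1, tolerance = 1e-12)

  # constant grouping column reproduces the overall column
  df$grp <- "all"
  rep2 <- correlation_report(df, group_cols = "grp",
                             indices = c("Minor", "Area"))
  expect_equal(rep2$all, rep2$Overall)

  # 2 x 2 design: per-group values equal direct recomputation
  df$year <- rep(1:2, each = 12)
  df$irr <- rep(c("WI", "DI"), 12)
  rep3 <- correlation_report(df, group_cols = c("year", "irr"),
                             indices = c("Minor", "Area"))
  sub <- df[df$year == 2 & df$irr == "DI", ]
  expect_equal(rep3$"2:DI"[rep3$index == "Area"], cor(sub$Area, sub$MGW))

  # undersized groups are skipped with a warning
  df_small <- df[c(1:10, 11), ]
  df_small$g2 <- c(rep("a", 10), "b")
  expect_warning(rep4 <- correlation_report(df_small, group_cols = "g2",
                                            indices = "Minor"), "fewer than 3")
  expect_false("b" %in% names(rep4))
})

test_that("percent differences reproduce the reported treatment effects", {
  expect_equal(percent_difference(39.139, 36.566), 6.574, tolerance = 5e-4)
  expect_equal(percent_difference(39.561, 36.143), 8.640, tolerance = 5e-4)
  expect_equal(percent_difference(10, 10), 0)
})
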