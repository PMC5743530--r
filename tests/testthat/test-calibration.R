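test_that("paired difference summary reports mean, SD, ratio and test", {
  s <- paired_difference_summary(c(0.3, 0.5), c(0.2, 0.4))
  expect_equal(s$mean_diff, 0.1)
  expect_equal(s$sd_diff, 0)
  expect_equal(s$n, 2)
  a <- runif(20)
  ident <- paired_difference_summary(a, a)
  expect_equal(ident$mean_diff, 0)
  expect_equal(ident$mean_ratio_percent, 100)
  expect_error(paired_difference_summary(0.4, 0.2), "insufficient")
  # ratio uses only pairs with positive denominator
  s2 <- paired_difference_summary(c(0.2, 0.3), c(0, 0.2))
  expect_equal(s2$mean_ratio_percent, 150)
})

test_that("noiseless linear structures are recovered exactly", {
  set.seed(8)
  df <- data.frame(x = runif(40, 0.05, 0.6))
  df$y <- 0.05 + 0.6 * df$x
  fit <- fit_linear_structure(df, "y", "x", "y~x")
  expect_equal(unname(fit$coefficients), c(0.05, 0.6), tolerance = 1e-10)
  df$y <- df$x
  fit_id <- fit_linear_structure(df, "y", "x", "y~x")
  expect_equal(unname(fit_id$coefficients), c(0, 1), tolerance = 1e-10)
  expect_equal(predict_circular_equivalent(fit_id, c(0.12, 0.7)),
               c(0.12, 0.7), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("overstory interaction structures reproduce per-species slopes", {
  set.seed(12)
  ovs <- c("broadleaves", "douglas", "sitka", "larch", "pine")
  df <- data.frame(OV = rep(ovs, each = 30), x = runif(150, 0.05, 0.6))
  offsets <- c(broadleaves = 0, douglas = 0.197, sitka = 0.228,
               larch = 0.398, pine = 0.267)
  df$y <- 0.025 + (0.275 + offsets[df$OV]) * df$x
  fit <- fit_linear_structure(df, "y", "x", "y~x+x:OV")
  # the larch-specific prediction follows the fitted linear form by hand
  pred <- predict_circular_equivalent(fit, 0.5, OV = "larch")
  expect_equal(as.numeric(pred), 0.025 + (0.275 + 0.398) * 0.5,
               tolerance = 1e-8)
  expect_equal(as.numeric(pred), 0.3615, tolerance = 1e-8)
  expect_error(predict_circular_equivalent(fit, 0.5, OV = "spruce"),
               "missing level|unknown OV")
  expect_error(predict_circular_equivalent(fit, 0.5), "requires 'OV'")
  # clipping: a negative linear prediction is floored at zero and flagged
  df$y2 <- -0.2 + 0.1 * df$x
  fit_neg <- fit_linear_structure(df, "y2", "x", "y~x")
  out <- predict_circular_equivalent(fit_neg, 0.1)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "clipped"))
})

test_that("per-overstory slope ordering is recovered under realistic noise", {
  set.seed(91)
  hits <- 0L
  for (r in 1:100) {
    df <- hemicanopy:::simulate_calibration_records(
      200, 0.025, 0.275,
      c(douglas = 0.197, sitka = 0.228, larch = 0.398, pine = 0.267),
      noise_sd = 0.03)
    fit <- fit_linear_structure(df, "y", "x", "y~x+x:OV")
    cf <- fit$coefficients
    lar <- cf[grep("larch", names(cf))]
    pin <- cf[grep("pine", names(cf))]
    if (lar > 0 && pin > 0) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("degenerate designs are rejected but the base structure still fits", {
  df <- data.frame(OV = "pine", x = runif(20), y = runif(20))
  expect_error(fit_linear_structure(df, "y", "x", "y~x+x:OV"),
               "degenerate")
  expect_s3_class(fit_linear_structure(df, "y", "x", "y~x"),
                  "calibration_model")
  tab <- compare_structures_aic(df, "y", "x")
  expect_true("y~x" %in% tab$structure)
  expect_false(any(grepl("OV", tab$structure)))
  expect_true(length(attr(tab, "skipped")) >= 1)
  # far too few records for the coefficient count
  tiny <- data.frame(x = c(0.1, 0.2), y = c(0.1, 0.3))
  expect_error(fit_linear_structure(tiny, "y", "x", "y~x"), "insufficient")
})

test_that("a useless added term is penalised by up to two AIC points", {
  # one inert binary covariate: AIC difference is 2 - chi2(1), so it is
  # bounded above by the 2-point penalty and positive for typical draws
  set.seed(7)
  diffs <- replicate(100, {
    df <- data.frame(x = runif(100, 0.05, 0.6),
                     camera_type = sample(rep(c("N990", "N4500"), 50)))
    df$y <- 0.04 + 0.5 * df$x + rnorm(100, 0, 0.03)
    f1 <- fit_linear_structure(df, "y", "x", "y~x")
    fit2 <- stats::lm(y ~ x + camera_type, data = df)
    rss2 <- sum(residuals(fit2)^2)
    aic2 <- 100 * log(rss2 / 100) + 2 * (3 + 1)
    aic2 - f1$AIC
  })
  expect_true(all(diffs <= 2 + 1e-9))
  expect_gt(mean(diffs), 0)           # the penalty dominates on average
  expect_gt(max(diffs), 1.8)          # and approaches the full 2 points
})

test_that("AIC ranking agrees with the stats::AIC ordering", {
  set.seed(18)
  df <- hemicanopy:::simulate_calibration_records(
    150, 0.025, 0.275,
    c(douglas = 0.2, sitka = 0.2, larch = 0.4, pine = 0.3), noise_sd = 0.03)
  tab <- compare_structures_aic(df, "y", "x")
  models <- attr(tab, "models")
  ours <- vapply(models, `[[`, numeric(1), "AIC")
  theirs <- vapply(models, function(m) stats::AIC(m$fit), numeric(1))
  expect_identical(order(ours), order(theirs))
})

test_that("calibration models serialize to JSON and records validate on read", {
  set.seed(3)
  df <- data.frame(x = runif(30), y = runif(30))
  fit <- fit_linear_structure(df, "y", "x", "y~x")
  path <- tempfile(fileext = ".json")
  write_calibration_json(fit, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$structure, "y~x")
  expect_equal(parsed$coefficients[["x"]], unname(fit$coefficients["x"]),
               tolerance = 1e-12)
  unlink(path)

  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(point_id = 1:3, OV = "pine",
                       CO = c(0.2, 0.4, 0.6), COsm = c(0.3, 0.5, 0.7)),
            csv, row.names = FALSE)
  rec <- read_paired_records(csv)
  expect_equal(nrow(rec), 3)
  write.csv(data.frame(point_id = 1, CO = 1.4), csv, row.names = FALSE)
  expect_error(read_paired_records(csv), "outside")
  unlink(csv)
})
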