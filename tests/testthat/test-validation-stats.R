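# Hearing-loss dataset, 1248 averaging and regression machinery.

test_that("the packaged hair-cell-loss dataset loads intact", {
  df <- load_hearing_loss_data()
  expect_equal(nrow(df), 22)
  expect_equal(df$laeq[df$group == "G44"], 100.6)
  expect_equal(df$ohc_500[df$group == "G44"], 20.8)
  expect_equal(df$ohc_500[df$group == "G61"], 7.9)
  expect_equal(df$ihc_1000[df$group == "G61"], 0.2)
  expect_equal(df$laeq[df$group == "G57"], 94.2)
  expect_equal(df$ihc_16000[df$group == "G57"], 11.6)
  expect_error(load_hearing_loss_data(tempfile()), "checksum|file|exist")
})

test_that("1248 band averaging is the arithmetic mean of the four bands", {
  expect_equal(band_average_1248(c(10, 20, 30, 40)), 25)
  expect_equal(band_average_1248(c(7, 7, 7, 7)), 7)
  g44 <- c("1000" = 38.1, "2000" = 67.9, "4000" = 67.5, "8000" = 62.7)
  expect_equal(band_average_1248(g44), mean(c(38.1, 67.9, 67.5, 62.7)))
  expect_error(band_average_1248(c("1000" = 1, "2000" = 2)), "missing")
})

test_that("linear regression matches exact fits and the normal-equations oracle", {
  x <- 1:10
  fit <- linear_regression(x, 2 * x + 1)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)

  fit0 <- linear_regression(x, rep(5, 10))
  expect_equal(fit0$r_squared, 0)

  set.seed(31)
  for (i in 1:20) {
    xx <- stats::rnorm(20); yy <- 1.5 * xx + stats::rnorm(20)
    mine <- linear_regression(xx, yy)
    orc <- oracle_ols(xx, yy)
    expect_equal(mine$intercept, unname(orc$intercept), tolerance = 1e-10)
    expect_equal(mine$slope, unname(orc$slope), tolerance = 1e-10)
    expect_equal(mine$r_squared, orc$r_squared, tolerance = 1e-10)
    expect_equal(mine$p_value, unname(orc$p_value), tolerance = 1e-10)
  }
  expect_error(linear_regression(rep(1, 5), 1:5), "degenerate")
})

test_that("regression is affine-equivariant in the metric (r2 and p invariant)", {
  set.seed(8)
  x <- stats::rnorm(22); y <- x + stats::rnorm(22, sd = 0.5)
  f1 <- linear_regression(x, y)
  f2 <- linear_regression(10 * x + 3, y)   # V0/H0 choice shifts/scales x
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-12)
  expect_equal(f2$slope, f1$slope / 10, tolerance = 1e-12)
  # r2 equals the squared Pearson correlation
  expect_equal(f1$r_squared, stats::cor(x, y)^2, tolerance = 1e-12)
})

test_that("correlate_metrics joins groups, self-regresses to r2=1, warns on mismatch", {
  records <- load_hearing_loss_data()
  metrics <- do.call(rbind, lapply(records$group, function(g) {
    data.frame(group = g, band_hz = c(1000, 2000, 4000, 8000),
               level_db = as.numeric(records[records$group == g,
                                             c("ohc_1000", "ohc_2000",
                                               "ohc_4000", "ohc_8000")]))
  }))
  out <- correlate_metrics(metrics, records, index = "OHC",
                           bands = c(1000, 4000))
  expect_equal(out$r2, c(1, 1), tolerance = 1e-12)
  expect_equal(out$n, c(22, 22))

  out1248 <- correlate_metrics(metrics, records, index = "OHC", bands = "1248")
  expect_equal(out1248$r2, 1, tolerance = 1e-12)

  bad <- metrics
  bad$group[bad$group == "G44"] <- "G99"
  expect_warning(outb <- correlate_metrics(bad, records, index = "OHC",
                                           bands = 1000), "excluded")
  expect_equal(outb$n, 21)
})

test_that("noisy synthetic metrics recover the population r2", {
  # index + Gaussian noise with sigma set for population r2 = 0.8
  records <- load_hearing_loss_data()
  y <- vapply(seq_len(nrow(records)), function(i)
    band_average_1248(as.numeric(records[i, c("ohc_1000", "ohc_2000",
                                              "ohc_4000", "ohc_8000")])),
    numeric(1))
  sd_noise <- stats::sd(y) * sqrt(1 / 0.8 - 1)
  set.seed(77)
  r2s <- replicate(200, {
    x <- y + stats::rnorm(length(y), sd = sd_noise)
    linear_regression(x, y)$r_squared
  })
  expect_lt(abs(mean(r2s) - 0.8), 0.15)
})
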