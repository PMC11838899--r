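test_that("y variation orthogonal to x gives a zero slope and the mean as intercept", {
  x <- c(-2, -1, 0, 1, 2)
  y <- 3 + c(0.1, -0.1, 0, -0.1, 0.1)  # Sxy = 0 but nonzero residuals
  f <- fit_ols(x, y)
  expect_equal(f$m, 0, tolerance = 1e-12)
  expect_equal(f$c, 3, tolerance = 1e-12)
})

test_that("shifting y translates the intercept and leaves slope and tau", {
  set.seed(1)
  x <- runif(20)
  y <- 2 * x + rnorm(20, 0, 0.3)
  f1 <- fit_ols(x, y)
  f2 <- fit_ols(x, y + 5)
  expect_equal(f2$m, f1$m)
  expect_equal(f2$c, f1$c + 5)
  expect_equal(f2$tau, f1$tau)
})

test_that("fit matches the normal equations solved by matrix algebra", {
  x <- c(0.3, 1.2, 2.7, 3.1, 4.9)
  y <- c(0.7, 1.9, 3.1, 3.0, 5.6)
  f <- fit_ols(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  expect_equal(f$c, beta[1], tolerance = 1e-10)
  expect_equal(f$m, beta[2], tolerance = 1e-10)
  expect_equal(f$tau, (5 - 2) / sum(resid^2), tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  expect_error(fit_ols(rep(1, 5), 1:5), "all x values are equal")
  expect_error(fit_ols(1:5, 2 * (1:5) + 1), "zero residual")
  expect_error(fit_ols(1:2, 1:2), "at least 3")
})

test_that("prediction interval is symmetric, narrowest at x_bar, and matches lm", {
  set.seed(2)
  x <- runif(40, 0, 10)
  y <- 1.5 * x + 2 + rnorm(40)
  f <- fit_ols(x, y)
  grid <- seq(-5, 15, length.out = 41)
  pi_tbl <- prediction_interval(f, grid, 0.95)
  expect_equal(pi_tbl$upper - pi_tbl$fit, pi_tbl$fit - pi_tbl$lower)
  widths <- pi_tbl$upper - pi_tbl$lower
  expect_equal(grid[which.min(widths)],
               grid[which.min(abs(grid - f$x_bar))])
  # independent oracle: R's own out-of-sample interval
  lmfit <- lm(y ~ x)
  oracle <- predict(lmfit, newdata = data.frame(x = grid),
                    interval = "prediction", level = 0.95)
  expect_equal(pi_tbl$lower, unname(oracle[, "lwr"]), tolerance = 1e-8)
  expect_equal(pi_tbl$upper, unname(oracle[, "upr"]), tolerance = 1e-8)
  expect_error(prediction_interval(f, 1, level = 1.2), "between 0 and 1")
})

test_that("fibres on the pooled line are never flagged; 10-sigma ones always", {
  set.seed(3)
  n <- 200
  df <- tibble::tibble(
    subject_id = "C01", subject_type = "control",
    fibre_id = sprintf("c%03d", 1:n), x = runif(n, 1, 3))
  df$y <- 1.2 * df$x + 0.5 + rnorm(n, 0, 0.2)
  pooled <- fit_ols(df$x, df$y)
  pat <- tibble::tibble(
    subject_id = "P01", subject_type = "patient",
    fibre_id = c("p1", "p2"), x = c(1.5, 2.5))
  pat$y <- pooled$m * pat$x + pooled$c + c(0, 10 * pooled$sigma)
  d <- mito_data_from_log(dplyr::bind_rows(df, pat), patient_id = "P01")
  cls <- classify_frequentist(d)
  expect_equal(cls$fibres$z, c(0L, 1L))
  expect_equal(cls$fibres$side, c("within", "above"))
})

test_that("the pooled fit equals an OLS on the concatenated control arrays", {
  d <- tiny_mito()
  cls <- classify_frequentist(d)
  ctrl <- d[d$subject_type == "control", ]
  direct <- fit_ols(ctrl$x, ctrl$y)
  expect_identical(cls$fit$m, direct$m)
  expect_identical(cls$fit$c, direct$c)
  expect_identical(cls$fit$tau, direct$tau)
})

test_that("rescaling the response leaves classifications unchanged", {
  d <- tiny_mito()
  a <- 3.7
  df <- tibble::as_tibble(d)[, c("subject_id", "subject_type", "fibre_id",
                                 "x", "y")]
  df$y <- df$y * a
  d2 <- mito_data_from_log(df, patient_id = "P01")
  c1 <- classify_frequentist(d)
  c2 <- classify_frequentist(d2)
  expect_identical(c1$fibres$z, c2$fibres$z)
  expect_equal(c2$fit$c, a * c1$fit$c)
  expect_equal(c2$fibres$lower, a * c1$fibres$lower)
})

test_that("fibres simulated from the pooled control model are flagged at ~5%", {
  set.seed(11)
  n_ctrl <- 1155
  xc <- runif(n_ctrl, 1, 3)
  yc <- 1.1 * xc + 0.3 + rnorm(n_ctrl, 0, 0.2)
  n_p <- 2000
  xp <- runif(n_p, 1, 3)
  yp <- 1.1 * xp + 0.3 + rnorm(n_p, 0, 0.2)
  df <- dplyr::bind_rows(
    tibble::tibble(subject_id = "C01", subject_type = "control",
                   fibre_id = sprintf("c%04d", 1:n_ctrl), x = xc, y = yc),
    tibble::tibble(subject_id = "P01", subject_type = "patient",
                   fibre_id = sprintf("p%04d", 1:n_p), x = xp, y = yp))
  cls <- classify_frequentist(mito_data_from_log(df, patient_id = "P01"))
  flagged <- mean(cls$fibres$z)
  expect_gte(flagged, 0.03)
  expect_lte(flagged, 0.07)
})
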