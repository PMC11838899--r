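test_that("ground truth and datasets are bitwise reproducible from the seed", {
  t1 <- sample_ground_truth(seed = 91)
  t2 <- sample_ground_truth(seed = 91)
  expect_identical(unclass(t1), unclass(t2))
  s1 <- generate_dataset(t1, n_per_subject = c(30, 30, 30, 30, 50),
                         seed = 92)
  s2 <- generate_dataset(t1, n_per_subject = c(30, 30, 30, 30, 50),
                         seed = 92)
  expect_identical(s1$data$x, s2$data$x)
  expect_identical(s1$data$y, s2$data$y)
  expect_identical(s1$labels, s2$labels)
})

test_that("explicit configuration is echoed exactly and slopes obey truncation", {
  tr <- sample_ground_truth(
    config = list(mu_m = 0.9, tau = 30, pi = 0.22, delta = -1.5,
                  tau_def = 3, m = c(1, 1.1, 0.95, 1.2, 0.8),
                  c = rep(0.2, 5)),
    seed = 93)
  expect_equal(tr$mu_m, 0.9)
  expect_equal(tr$tau, 30)
  expect_equal(tr$pi, 0.22)
  expect_equal(tr$m, c(1, 1.1, 0.95, 1.2, 0.8))
  expect_equal(tr$c, rep(0.2, 5))

  slopes <- unlist(lapply(1:2000, function(s) {
    sample_ground_truth(config = list(tau_m = 2), seed = s)$m
  }))
  expect_gte(min(slopes), 0.1)
  expect_length(slopes, 10000)
})

test_that("degenerate deficiency configurations are rejected", {
  expect_error(sample_ground_truth(config = list(pi = 0.7), seed = 1),
               "\\[0, 0.5\\]")
  expect_error(sample_ground_truth(config = list(delta = 0.5), seed = 1),
               "below the like-control line")
  expect_error(sample_ground_truth(config = list(tau_def = 30), seed = 1),
               "smaller than tau")
})

test_that("patient labels follow the deficiency proportion", {
  tr0 <- sample_ground_truth(config = list(pi = 0), seed = 94)
  s0 <- generate_dataset(tr0, n_per_subject = c(20, 20, 20, 20, 200),
                         seed = 95)
  expect_equal(sum(s0$labels$label), 0)

  tr <- sample_ground_truth(config = list(pi = 0.3), seed = 96)
  s <- generate_dataset(tr, n_per_subject = c(20, 20, 20, 20, 10000),
                        seed = 97)
  frac <- mean(s$labels$label)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("generated moments match the ground truth", {
  tr <- sample_ground_truth(config = list(pi = 0.5 * 0), seed = 98)
  s <- generate_dataset(tr, n_per_subject = c(20, 20, 20, 20, 10000),
                        seed = 99)
  pat <- s$data[s$data$subject_type == "patient", ]
  resid <- pat$y - (tr$m[5] * pat$x + tr$c[5])
  expect_lt(abs(sd(resid) - 1 / sqrt(tr$tau)) / (1 / sqrt(tr$tau)), 0.02)
  # deficient fibres sit strictly below the like-control line on average
  tr2 <- sample_ground_truth(config = list(pi = 0.4), seed = 100)
  s2 <- generate_dataset(tr2, n_per_subject = c(20, 20, 20, 20, 5000),
                         seed = 101)
  pat2 <- s2$data[s2$data$subject_type == "patient", ]
  resid2 <- pat2$y - (tr2$m[5] * pat2$x + tr2$c[5])
  expect_lt(mean(resid2[s2$labels$label == 1]), -1)
})

test_that("the IF-like variant transforms the covariate and subject spread", {
  tr <- sample_ground_truth(seed = 102)
  expect_identical(unclass(make_d02_variant(tr, 1, 0, 1)), unclass(tr))

  shifted <- make_d02_variant(tr, scale = 1.5, shift = 2)
  s_base <- generate_dataset(tr, n_per_subject = rep(200, 5), seed = 103)
  s_shift <- generate_dataset(shifted, n_per_subject = rep(200, 5),
                              seed = 103)
  expect_gt(mean(s_shift$data$x), mean(s_base$data$x))

  base_slopes <- unlist(lapply(1:1000, function(s) {
    sample_ground_truth(seed = 5000 + s)$m
  }))
  wide_slopes <- unlist(lapply(1:1000, function(s) {
    make_d02_variant(sample_ground_truth(seed = 5000 + s),
                     subject_sd_factor = 2, seed = 6000 + s)$m
  }))
  ratio <- sd(wide_slopes) / sd(base_slopes)
  expect_lt(abs(ratio - 2), 0.2)
})

test_that("synthetic bundles write their three artefacts", {
  tr <- sample_ground_truth(config = list(k = 3L), seed = 104)
  s <- generate_dataset(tr, n_per_subject = c(10, 10, 15), seed = 105)
  dir <- withr::local_tempdir()
  write_synthetic(s, dir, stem = "toy")
  expect_true(file.exists(file.path(dir, "toy_fibres.csv")))
  labels <- readr::read_csv(file.path(dir, "toy_labels.csv"),
                            show_col_types = FALSE)
  expect_equal(labels$label, s$labels$label)
  truth <- jsonlite::fromJSON(file.path(dir, "toy_truth.json"))
  expect_equal(truth$pi, tr$pi)
})
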