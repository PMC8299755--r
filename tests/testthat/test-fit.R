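make_signal_matrix <- function(n = 60, p = 20, seed = 1, beta = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", 1:p)))
  if (is.null(beta)) beta <- c(2, -1.5, 1, rep(0, p - 3))
  score <- drop(x %*% beta)
  y <- as.integer(score + rnorm(n, sd = 0.3) > 0)
  list(x = x, y = y, score = score)
}

test_that("prediction is the hand-computed normalised dot product", {
  fnames <- c("a", "b", "c", "d")
  fit <- make_linear_fit(fnames, selected = c(1, 3, 4),
                         weights = c(0.2, -0.4, 0.1), bias = 0.3,
                         center = c(1, 2, 0), scale = c(2, 1, 4))
  x <- matrix(c(3, 9, 4, -2), 1, 4, dimnames = list(NULL, fnames))
  manual <- 0.2 * (3 - 1) / 2 - 0.4 * (4 - 2) / 1 + 0.1 * (-2 - 0) / 4 + 0.3
  expect_equal(predict(fit, x, type = "raw")[1], manual, tolerance = 1e-12)
  expect_equal(predict(fit, x, type = "risk")[1],
               min(1, max(0, manual)), tolerance = 1e-12)
  expect_error(predict(fit, x[, 1:3, drop = FALSE]), "mismatch")
})

test_that("risk is monotone in a positively weighted feature and w=0 gives b", {
  fnames <- c("a", "b")
  fit <- make_linear_fit(fnames, 1:2, c(0.5, 0), bias = 0.4)
  xs <- cbind(a = seq(-2, 2, by = 0.5), b = 0)
  risk <- predict(fit, xs, type = "risk")
  expect_true(all(diff(risk) >= 0))
  fit0 <- make_linear_fit(fnames, 1:2, c(0, 0), bias = 1.7)
  expect_equal(unique(predict(fit0, xs, type = "risk")), 1)  # clipped bias
})

test_that("classification threshold matches the reported per-patient calls", {
  expect_equal(as.character(classify_risk(c(0.651, 0.235, 0.431, 0.617))),
               c("AVB", "no-AVB", "no-AVB", "AVB"))
  expect_error(classify_risk(1.2), "risk")
  expect_error(classify_risk(0.5, tau = 1), "tau")
})

test_that("the full fit recovers a planted linear signal end-to-end", {
  sim <- make_signal_matrix()
  coh <- make_matrix_cohort(sim$x, sim$y)
  x <- with_meta(sim$x, 10)
  cfg <- tavr_config()
  fit <- tavr_fit(coh, features = x, config = cfg, lambda = 1e-6,
                  n_select = 3)
  expect_setequal(names(fit$weights), c("f01", "f02", "f03"))
  expect_gt(cosine(predict(fit, x, "raw"), sim$score), 0.9)
  expect_s3_class(summary(fit), "summary.tavr_fit")
  expect_equal(residuals(fit), fit$y - fitted(fit))
  expect_output(print(fit), "risk model")
})

test_that("lambda cross-validation is deterministic and grid-bound", {
  sim <- make_signal_matrix(seed = 3)
  coh <- make_matrix_cohort(sim$x, sim$y)
  x <- with_meta(sim$x, 10)
  f1 <- tavr_fit(coh, features = x)
  f2 <- tavr_fit(coh, features = x)
  expect_identical(f1$lambda, f2$lambda)
  expect_true(f1$lambda %in% tavr_config()$model$lambda_grid)
  expect_identical(f1$weights, f2$weights)
})

test_that("degenerate cohorts are rejected", {
  sim <- make_signal_matrix(n = 20)
  coh <- make_matrix_cohort(sim$x[1:6, ], sim$y[1:6])
  expect_error(tavr_fit(coh, features = sim$x[1:6, ]), "at least 8")
  coh2 <- make_matrix_cohort(sim$x, rep(1L, 20))
  expect_error(tavr_fit(coh2, features = sim$x), "single-class")
})

test_that("simulate draws labels at the fitted risks", {
  sim <- make_signal_matrix()
  coh <- make_matrix_cohort(sim$x, sim$y)
  fit <- tavr_fit(coh, features = with_meta(sim$x, 10))
  s1 <- simulate(fit, nsim = 3, seed = 1)
  s2 <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(s1, s2)
  expect_true(all(unlist(s1) %in% 0:1))
  expect_equal(dim(s1), c(60L, 3L))
})
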