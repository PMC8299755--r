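separable_cohort <- function(n = 24, p = 8, gap = 6, seed = 2) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", 1:p)))
  x[, 1] <- x[, 1] + gap * y
  x[, 2] <- x[, 2] - gap * y
  list(x = with_meta(x, 4), y = y)
}

test_that("ROC/AUC agree with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(5)
  for (i in 1:5) {
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- rnorm(40) + y
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_trapezoid(s, y), ref, tolerance = 1e-12)
  }
  expect_equal(auc_trapezoid(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc_trapezoid(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  expect_equal(auc_trapezoid(rep(1, 4), c(0, 0, 1, 1)), 0.5)  # all tied
})

test_that("a perfectly separable cohort reaches 100% LOO accuracy", {
  sep <- separable_cohort()
  coh <- make_matrix_cohort(sep$x, sep$y)
  ev <- loo_cv(coh, features = sep$x, lambda = 0.1)
  expect_equal(ev$accuracy, 100)
  expect_equal(ev$accuracy_no_avb, 100)
  expect_equal(ev$accuracy_avb, 100)
  expect_equal(ev$auc, 1)
  expect_equal(nrow(ev$predictions), 24)  # one fold per patient
})

test_that("risk scores shuffled against labels give a null AUC of one half", {
  set.seed(7)
  n <- 200
  scores <- runif(n)
  labels <- rbinom(n, 1, 0.4)
  aucs <- replicate(100, auc_trapezoid(scores, sample(labels)))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("baseline comparator table has four deterministic methods", {
  sep <- separable_cohort()
  coh <- make_matrix_cohort(sep$x, sep$y)
  t1 <- run_baselines(coh, features = sep$x, lambda = 0.1, seed = 1)
  expect_equal(nrow(t1), 4)
  expect_setequal(t1$method, c("svr", "logistic", "tree", "nnet"))
  # separable limit; complete separation makes the glm MLE diverge, so the
  # logistic baseline is allowed a small margin below the other three
  expect_true(all(t1$accuracy[t1$method != "logistic"] == 100))
  expect_gte(t1$accuracy[t1$method == "logistic"], 90)
  t2 <- run_baselines(coh, features = sep$x, lambda = 0.1, seed = 1)
  expect_identical(t1, t2)
})

test_that("ablation separates stress-driven from clinical-driven signal", {
  set.seed(11)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  stress <- matrix(rnorm(n * 6), n, 6,
                   dimnames = list(NULL, sprintf("stress_%03d", 1:6)))
  stress[, 1:3] <- stress[, 1:3] + 4 * y   # labels depend on stress only
  clin <- matrix(rnorm(n * 4), n, 4,
                 dimnames = list(NULL, c("calcified_volume", "bmi",
                                         "lvef", "male")))
  x <- with_meta(cbind(stress, clin), 6)
  coh <- make_matrix_cohort(x, y)
  tab <- ablation(coh, features = x, lambda = 0.1)
  expect_setequal(tab$regime, c("combined", "biomechanical", "clinical"))
  expect_equal(tab$accuracy[tab$regime == "biomechanical"], 100)
  # clinical-only cannot beat chance on stress-driven labels
  expect_lt(tab$accuracy[tab$regime == "clinical"], 75)
  expect_gte(tab$auc[tab$regime == "combined"],
             max(tab$auc[tab$regime != "combined"]) - 0.05)
})

test_that("degenerate training folds fall back with a warning", {
  sep <- separable_cohort(n = 10)
  y <- c(rep(0L, 8), 1L, 1L)
  coh <- make_matrix_cohort(sep$x[1:10, ], y)
  expect_warning(loo_cv(coh, features = sep$x[1:10, , drop = FALSE],
                        lambda = 0.1),
                 "degenerate")
})
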