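cfg_fast <- tiny_cfg()

test_that("quota sampling reproduces the reference class and sex split", {
  coh <- simulate_cohort(48, seed = 7, config = cfg_fast, physics = FALSE)
  expect_equal(sum(coh$patients$sex == "male"), 28)
  expect_equal(sum(coh$patients$sex == "female"), 20)
  expect_equal(sum(coh$patients$avb_label == 1), 20)
  expect_equal(sum(coh$patients$avb_label == 0), 28)
  expect_equal(nrow(coh$patients), 48)
})

test_that("identical seeds give byte-identical cohorts", {
  c1 <- simulate_cohort(20, seed = 3, config = cfg_fast)
  c2 <- simulate_cohort(20, seed = 3, config = cfg_fast)
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$deposits, c2$deposits)
  expect_identical(attr(c1, "truth")$score, attr(c2, "truth")$score)
  c3 <- simulate_cohort(20, seed = 4, config = cfg_fast)
  expect_false(identical(c1$patients, c3$patients))
})

test_that("a minimal cohort carries one patient per class", {
  coh <- simulate_cohort(2, seed = 1, config = cfg_fast, physics = FALSE)
  expect_equal(sort(coh$patients$avb_label), c(0L, 1L))
  expect_error(simulate_cohort(1, seed = 1, config = cfg_fast),
               "two outcome classes")
})

test_that("invalid distribution bounds are rejected", {
  bad <- tiny_cfg(generator = list(age = list(min = 90, max = 80)))
  expect_error(simulate_cohort(10, seed = 1, config = bad), "age")
  bad2 <- tiny_cfg(generator = list(thickness = list(sd = -1)))
  expect_error(simulate_cohort(10, seed = 1, config = bad2), "thickness")
})

test_that("record-level invariants hold on a generated cohort", {
  coh <- simulate_cohort(30, seed = 9, config = cfg_fast, physics = FALSE)
  p <- tavr_config()$generator
  pt <- coh$patients
  expect_true(all(pt$age >= p$age$min & pt$age <= p$age$max))
  expect_true(all(pt$bmi >= p$bmi$min & pt$bmi <= p$bmi$max))
  expect_true(all(pt$avb_label %in% c(0L, 1L)))
  expect_true(all(pt$applied_valve_size %in% c(23, 26, 29, 31)))
  dep <- coh$deposits
  expect_true(all(dep$thickness > 0 & dep$thickness <= p$thickness$max))
  # calcified volume equals the deposit sum to 1e-6 relative
  v <- tapply(dep$volume, dep$patient_id, sum)
  expect_equal(as.numeric(v[as.character(pt$id)]), pt$calcified_volume,
               tolerance = 1e-9)
  rng <- p$total_volume_range
  expect_true(all(pt$calcified_volume >= rng[1] - 1e-9 &
                    pt$calcified_volume <= rng[2] + 1e-9))
})

test_that("generated marginals track the configured cohort statistics", {
  reps <- vapply(1:40, function(s) {
    coh <- simulate_cohort(48, seed = 100 + s, config = cfg_fast,
                           physics = FALSE)
    c(mean(coh$patients$age), mean(coh$patients$bmi))
  }, numeric(2))
  expect_lt(abs(mean(reps[1, ]) - 79), 2)
  expect_lt(abs(mean(reps[2, ]) - 29.3), 2)
})

test_that("thickness draws match the truncated-normal they come from", {
  d <- sample_deposit_thickness(5000, seed = 1)
  expect_lt(abs(mean(d) - 3.2), 0.1)
  expect_true(all(d > 0.5 & d <= 6.8))
})

test_that("label probabilities follow the logistic truth link", {
  expect_equal(avb_label_prob(c(-3, 0, 2), 0), c(0, 0, 1))  # 0 at the tie
  expect_equal(avb_label_prob(0.5, 1), plogis(0.5))
  expect_equal(avb_label_prob(1e3, 1e-9), 1)
  set.seed(2)
  score <- qlogis(0.3)  # noise 1: p = 0.3
  draws <- draw_avb_label(rep(score, 10000), 1)
  expect_lt(abs(mean(draws) - 0.3), 0.02)
  expect_error(avb_label_prob(1, -1), "noise")
})

test_that("cohorts round-trip exactly through the CSV pair", {
  coh <- simulate_cohort(12, seed = 5, config = cfg_fast, physics = FALSE)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_identical(back$patients, coh$patients)
  expect_identical(back$deposits, coh$deposits)
})

test_that("an empty cohort round-trips to header-only files", {
  empty <- structure(list(
    patients = simulate_cohort(2, 1, cfg_fast, physics = FALSE)$patients[0, ],
    deposits = empty_deposits()), class = "tavr_cohort")
  dir <- withr::local_tempdir()
  write_cohort(empty, dir)
  expect_identical(length(readLines(file.path(dir, "cohort.csv"))), 1L)
  back <- read_cohort(dir)
  expect_equal(nrow(back$patients), 0)
  expect_equal(nrow(back$deposits), 0)
})

test_that("parse errors name the offending file and line", {
  coh <- simulate_cohort(5, seed = 2, config = cfg_fast, physics = FALSE)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  # orphan deposit row
  dep <- readLines(file.path(dir, "deposits.csv"))
  row <- strsplit(dep[2], ",")[[1]]; row[1] <- "999"
  writeLines(c(dep, paste(row, collapse = ",")),
             file.path(dir, "deposits.csv"))
  expect_error(read_cohort(dir), "unknown patient id 999")
  # non-numeric field
  write_cohort(coh, dir)
  pt <- readLines(file.path(dir, "cohort.csv"))
  f3 <- strsplit(pt[3], ",")[[1]]; f3[3] <- "abc"
  pt[3] <- paste(f3, collapse = ",")
  writeLines(pt, file.path(dir, "cohort.csv"))
  expect_error(read_cohort(dir), "non-numeric.*line 3")
  # malformed header
  write_cohort(coh, dir)
  pt <- readLines(file.path(dir, "cohort.csv"))
  pt[1] <- sub("id", "identifier", pt[1])
  writeLines(pt, file.path(dir, "cohort.csv"))
  expect_error(read_cohort(dir), "malformed header")
})
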