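test_that("cumulative curves count events right-continuously", {
  ev <- division_events(numeric(0))
  expect_true(all(cumulative_curve(ev, 10, 100)$count == 0))

  ev <- division_events(c(10, 20, 30))
  cc <- cumulative_curve(ev, 10)
  expect_equal(cc$count[cc$time %in% c(10, 20, 30)], c(1, 2, 3))
  expect_equal(cc$count[cc$time == 0], 0)
  expect_error(cumulative_curve(ev, 0), "grid_step")
  expect_error(division_events(c(-5, 3)), ">= 0")
})

test_that("uniform event times stay inside a Kolmogorov band of the line", {
  set.seed(3)
  n <- 1000
  ev <- division_events(runif(n, 0, 1000))
  cc <- cumulative_curve(ev, 10, 1000)
  dev <- max(abs(cc$count / n - cc$time / 1000))
  expect_lt(dev, 1.95 / sqrt(n))  # 99% KS band
})

test_that("linear_rate solves the normal equations", {
  cc <- data.frame(time = seq(0, 100, 10), count = 0.1 * seq(0, 100, 10))
  fit <- linear_rate(cc)
  expect_equal(unname(coef(fit)[["slope"]]), 0.1)
  expect_true(all(abs(residuals(fit)) < 1e-12))

  # hand-solved normal equations: t=(0,10,20,30), y=(0,1,1,3) -> slope 0.09
  fit2 <- linear_rate(data.frame(time = c(0, 10, 20, 30),
                                 count = c(0, 1, 1, 3)))
  expect_equal(coef(fit2)[["slope"]], 0.09)

  # slope invariant to adding a constant to counts
  fit3 <- linear_rate(data.frame(time = c(0, 10, 20, 30),
                                 count = c(0, 1, 1, 3) + 7))
  expect_equal(coef(fit3)[["slope"]], 0.09)
  expect_error(linear_rate(cc[1:2, ]), ">= 3 grid points")
})

test_that("closed-form OLS matches lm on random curves to 1e-10", {
  set.seed(19)
  for (i in 1:20) {
    cc <- data.frame(time = seq(0, 500, 10))
    cc$count <- runif(1, 0.01, 0.5) * cc$time + rnorm(nrow(cc), sd = 3)
    fit <- linear_rate(cc)
    ref <- coef(lm(count ~ time, data = cc))
    expect_lt(abs(coef(fit)[["slope"]] - ref[["time"]]), 1e-10)
    expect_lt(abs(coef(fit)[["intercept"]] - ref[["(Intercept)"]]), 1e-10)
  }
})

test_that("fold changes are antisymmetric and direction-flagged", {
  f1 <- linear_rate(data.frame(time = 0:10, count = 0.2 * (0:10)))
  f2 <- linear_rate(data.frame(time = 0:10, count = 0.05 * (0:10)))
  expect_equal(rate_fold_change(f1, f1)$ratio, 1)
  fc <- rate_fold_change(f1, f2)
  expect_equal(fc$ratio, 4)
  expect_equal(fc$direction, "a_faster")
  expect_equal(fc$ratio * rate_fold_change(f2, f1)$ratio, 1)
  f0 <- linear_rate(data.frame(time = 0:10, count = rep(0, 11)))
  expect_error(rate_fold_change(f1, f0), "> 0")
})

test_that("breakpoint detection finds a slope drop and skips pure lines", {
  t <- seq(0, 1000, 10)
  expect_true(is.na(linearity_breakpoint(
    data.frame(time = t, count = 0.1 * t))))
  expect_true(is.na(linearity_breakpoint(
    data.frame(time = t, count = rep(2, length(t))))))
  expect_error(linearity_breakpoint(
    data.frame(time = 0:20, count = 0:20), min_segment = 150), "span")

  set.seed(29)
  y <- ifelse(t <= 500, 0.10 * t, 50 + 0.05 * (t - 500)) +
    rnorm(length(t), sd = 0.5)
  b <- linearity_breakpoint(data.frame(time = t, count = y))
  expect_false(is.na(b))
  expect_lt(abs(b - 500), 30)

  # a slope increase is not a (negative-deviation) breakpoint
  y_up <- ifelse(t <= 500, 0.05 * t, 25 + 0.10 * (t - 500))
  expect_true(is.na(linearity_breakpoint(data.frame(time = t,
                                                    count = y_up))))
})

test_that("breakpoint false-positive rate stays below 5%", {
  set.seed(11)
  fp <- 0
  n_curves <- 200
  for (i in seq_len(n_curves)) {
    t <- seq(0, 1000, 10)
    y <- 0.1 * t + rnorm(length(t), sd = 2)
    if (!is.na(linearity_breakpoint(data.frame(time = t, count = y))))
      fp <- fp + 1
  }
  expect_lte(fp / n_curves, 0.05)
})

test_that("event streams round-trip through CSV", {
  ev <- division_events(c(5, 17, 90), cell_id = c(2, 1, 3),
                        condition = "ctl")
  path <- withr::local_tempfile(fileext = ".csv")
  write_division_events(ev, path)
  back <- read_division_events(path, condition = "ctl")
  expect_equal(back$time, ev$time)
})
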