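test_that("pearson_r2 matches hand cases and the textbook formula", {
  x <- 1:10
  expect_equal(pearson_r2(x, 2 * x + 1), 1)
  expect_equal(pearson_r2(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
  xa <- c(1, 2, 3, 4); ya <- c(1.1, 1.9, 3.2, 3.8)
  expect_equal(pearson_r2(xa, ya), bf_r2(xa, ya), tolerance = 1e-12)
  expect_true(is.na(pearson_r2(rep(2, 5), 1:5)))
  expect_error(pearson_r2(1:2, 1:2), "3")
})

test_that("rmse matches hand arithmetic", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(4:8, 1:5), 3)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(round(rmse(c(0, 0), c(3, 4)), 4), 3.5355)
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("bland_altman matches hand computation and trivial cases", {
  ba0 <- bland_altman(1:5, 1:5)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high, ba0$rpc), c(0, 0, 0))

  ba2 <- bland_altman(c(3, 4, 5), c(1, 2, 3))
  expect_equal(ba2$bias, 2)
  expect_equal(ba2$sd_diff, 0)
  expect_equal(c(ba2$loa_low, ba2$loa_high), c(2, 2))

  x <- c(10, 12, 14); y <- c(9, 13, 12)
  ba <- bland_altman(x, y)
  ref <- bf_ba(x, y)
  expect_equal(ba$bias, ref$bias, tolerance = 1e-12)
  expect_equal(ba$sd_diff, ref$sd, tolerance = 1e-12)
  expect_equal(ba$loa_low, ref$lo, tolerance = 1e-12)
  expect_equal(ba$loa_high, ref$hi, tolerance = 1e-12)
  expect_equal(ba$cv_pct, ref$cv, tolerance = 1e-12)
  expect_true(is.na(bland_altman(c(-1, 0, 1), c(1, 0, -1))$cv_pct))
})

test_that("the statistics agree with brute force on random paired data", {
  set.seed(101)
  for (rep in 1:20) {
    x <- rnorm(50, 100, 15)
    y <- x + rnorm(50, 2, 5)
    expect_equal(pearson_r2(x, y), bf_r2(x, y), tolerance = 1e-9)
    expect_equal(rmse(x, y), bf_rmse(x, y), tolerance = 1e-9)
    ba <- bland_altman(x, y); ref <- bf_ba(x, y)
    expect_equal(ba$bias, ref$bias, tolerance = 1e-9)
    expect_equal(ba$rpc, ref$rpc, tolerance = 1e-9)
    expect_equal(ba$cv_pct, ref$cv, tolerance = 1e-9)
  }
})

test_that("agreement properties hold under random inputs", {
  set.seed(202)
  for (rep in 1:25) {
    x <- rnorm(30, 50, 10); y <- rnorm(30, 48, 12)
    ba <- bland_altman(x, y); ba_sw <- bland_altman(y, x)
    expect_equal(ba_sw$bias, -ba$bias, tolerance = 1e-12)
    expect_equal(ba_sw$loa_low, -ba$loa_high, tolerance = 1e-12)
    expect_equal(ba_sw$loa_high, -ba$loa_low, tolerance = 1e-12)
    expect_equal(ba_sw$rpc, ba$rpc, tolerance = 1e-12)
    expect_equal(ba_sw$cv_pct, ba$cv_pct, tolerance = 1e-12)
    expect_equal(ba$loa_high - ba$loa_low, 2 * ba$rpc, tolerance = 1e-12)
    expect_gte(rmse(x, y), abs(ba$bias))
    # r2 invariant under positive affine maps of either argument
    expect_equal(pearson_r2(3 * x + 7, y), pearson_r2(x, y),
                 tolerance = 1e-12)
  }
})

test_that("tidy, glance and autoplot expose the Bland-Altman results", {
  ba <- bland_altman(c(10, 12, 14, 16), c(9, 13, 12, 17))
  td <- tidy(ba)
  gl <- glance(ba)
  expect_equal(td$estimate[td$term == "bias"], ba$bias)
  expect_equal(gl$rpc, ba$rpc)
  expect_equal(gl$n, 4L)
  expect_s3_class(autoplot(ba), "ggplot")
})

test_that("agreement_report joins tables and quantifies noise", {
  ref <- tibble::tibble(beat = 1:200, lvet = rnorm(200, 310, 20))
  same <- agreement_report(ref, ref)
  expect_equal(same$r2, 1)
  expect_equal(same$rmse, 0)

  set.seed(7)
  meas <- ref
  meas$lvet <- meas$lvet + rnorm(200, 0, 5)
  rep5 <- agreement_report(ref, meas)
  expect_equal(rep5$rmse, 5, tolerance = 0.2 * 5)

  other <- tibble::tibble(beat = 500:520, lvet = rnorm(21))
  expect_error(agreement_report(ref, other), "Empty join")
})
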