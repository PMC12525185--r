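set.seed(101)
obs_r <- rnorm(40)
pred_r <- 0.8 * obs_r + rnorm(40, sd = 0.5)

test_that("r2 equals the textbook squared-correlation formula", {
  expect_equal(stat_r2(obs_r, obs_r), 1)
  expect_equal(stat_r2(obs_r, -obs_r), 1)
  oracle <- (sum((obs_r - mean(obs_r)) * (pred_r - mean(pred_r))))^2 /
    (sum((obs_r - mean(obs_r))^2) * sum((pred_r - mean(pred_r))^2))
  expect_equal(stat_r2(obs_r, pred_r), oracle, tolerance = 1e-12)
  expect_error(stat_r2(rep(1, 5), 1:5), "zero variance")
})

test_that("ccc matches its closed form and shift behaviour", {
  expect_equal(stat_ccc(obs_r, obs_r), 1)
  s2 <- stats::var(obs_r)
  expect_equal(stat_ccc(obs_r, obs_r + 2), 2 * s2 / (2 * s2 + 4),
               tolerance = 1e-12)
  oracle <- 2 * stats::cov(obs_r, pred_r) /
    (stats::var(obs_r) + stats::var(pred_r) +
       (mean(obs_r) - mean(pred_r))^2)
  expect_equal(stat_ccc(obs_r, pred_r), oracle, tolerance = 1e-12)
  expect_error(stat_ccc(rep(1, 4), rep(2, 4)), "constant")
})

test_that("iic reproduces the hand-computed example and conventions", {
  expect_equal(stat_iic(c(0, 1, 3), c(1, 1, 2)), (15 / sqrt(252)) * 0.5,
               tolerance = 1e-12)
  # symmetric one-sided errors: iic equals r exactly
  o <- c(1, 2, 3, 4); p <- c(1.5, 1.5, 3.5, 3.5)
  expect_equal(stat_iic(o, p), stats::cor(o, p), tolerance = 1e-12)
  # perfect agreement: ratio convention 1
  expect_equal(stat_iic(o, o), 1)
  # one empty residual class: ratio convention 0
  expect_equal(stat_iic(o, o - 1), 0)
})

test_that("iic magnitude never exceeds the correlation magnitude", {
  set.seed(7)
  for (i in 1:50) {
    o <- rnorm(12); p <- rnorm(12)
    iic <- stat_iic(o, p)
    r <- stats::cor(o, p)
    expect_lte(abs(iic), abs(r) + 1e-12)
    # formula oracle
    d <- o - p
    mn <- mean(abs(d[d < 0])); mp <- mean(abs(d[d >= 0]))
    expect_equal(iic, r * min(mn, mp) / max(mn, mp), tolerance = 1e-10)
  }
})

test_that("q2 matches an explicit leave-one-out refit oracle", {
  expect_equal(stat_q2_loo(1:6, 2 * (1:6) + 1), 1)
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(5); y <- x + rnorm(5)
    press <- sum(vapply(1:5, function(j) {
      fit <- stats::lm(y[-j] ~ x[-j])
      (y[j] - (coef(fit)[1] + coef(fit)[2] * x[j]))^2
    }, numeric(1)))
    oracle <- 1 - press / sum((y - mean(y))^2)
    expect_equal(stat_q2_loo(x, y), oracle, tolerance = 1e-10)
    expect_lte(stat_q2_loo(x, y), stat_r2(y, x + 0) + 1e-12)
  }
  expect_error(stat_q2_loo(rep(1, 5), rnorm(5)), "degenerate")
})

test_that("the F-ratio reproduces every published integer F value", {
  expect_equal(round(f_from_r2(0.4791, 63)), 56)
  expect_equal(round(f_from_r2(0.6803, 65)), 134)
  expect_equal(f_from_r2(0.5, 4), 2.0)
  has_f <- !is.na(published_stats$f)
  expect_identical(
    round(f_from_r2(published_stats$r2[has_f], published_stats$n[has_f])),
    published_stats$f[has_f])
  # strictly increasing in r2 at fixed n
  r2s <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(f_from_r2(r2s, 50)) > 0))
  expect_error(f_from_r2(1, 10), "infinite")
})

test_that("rmse and mae follow their definitions", {
  expect_equal(stat_rmse_mae(1:4, 1:4), c(rmse = 0, mae = 0))
  expect_equal(stat_rmse_mae(c(1, -1), c(0, 0)), c(rmse = 1, mae = 1))
  e <- obs_r - pred_r
  expect_equal(stat_rmse_mae(obs_r, pred_r),
               c(rmse = sqrt(mean(e^2)), mae = mean(abs(e))),
               tolerance = 1e-12)
  expect_gte(stat_rmse_mae(obs_r, pred_r)[["rmse"]],
             stat_rmse_mae(obs_r, pred_r)[["mae"]])
})

test_that("residual-sign clusters are assigned and scored correctly", {
  o <- c(1, 2, 3, 4); p <- c(0.5, 1.5, 2.5, 3.5)
  rep_ <- cluster_r2(o, p)
  expect_equal(rep_$n_low, 0L)
  expect_equal(rep_$n_high, 4L)
  expect_true(is.na(rep_$low_cluster_r2))
  # ties (obs == pred) go to the high cluster
  rep0 <- cluster_r2(o, o)
  expect_equal(rep0$n_high, 4)
  # two parallel bands around the diagonal: per-cluster R2 beats overall
  set.seed(3)
  x <- rnorm(60)
  band <- rep(c(-1, 1), 30)
  obs <- x + band
  rep2 <- cluster_r2(obs, x)
  expect_gt(rep2$low_cluster_r2, rep2$overall_r2)
  expect_gt(rep2$high_cluster_r2, rep2$overall_r2)
  expect_equal(rep2$n_low + rep2$n_high, 60)
})

test_that("stat_bundle collects consistent per-set statistics", {
  b <- stat_bundle(obs_r, pred_r)
  expect_equal(b$n, 40)
  expect_equal(b$r2, stat_r2(obs_r, pred_r))
  expect_lte(b$q2, b$r2)
  expect_gte(b$rmse, b$mae)
  expect_equal(b$f, f_from_r2(b$r2, 40))
})
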