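test_that("the ex-Gaussian density is a proper density with the stated mean", {
  f <- function(x) dexgauss(x, mu = 100, sigma = 15, tau = 40)
  expect_equal(integrate(f, -Inf, Inf)$value, 1, tolerance = 1e-6)
  m <- integrate(function(x) x * f(x), -Inf, Inf)$value
  expect_equal(m, 140, tolerance = 1e-4)  # mean = mu + tau
  expect_error(dexgauss(1, 0, -1, 1))
})

test_that("maximum-likelihood fitting recovers known parameters", {
  grid <- list(c(120, 10, 45), c(150, 25, 10), c(90, 8, 60))
  set.seed(99)
  for (g in grid) {
    x <- rexgauss(5000, g[1], g[2], g[3])
    fit <- fit_exgaussian(x)
    expect_equal(fit$mu, g[1], tolerance = 0.1)
    expect_equal(fit$sigma, g[2], tolerance = 0.1)
    expect_equal(fit$tau, g[3], tolerance = 0.1)
  }
})

test_that("fitting degrades gracefully at the edges", {
  set.seed(7)
  # nearly pure Gaussian data: tau collapses relative to sigma
  x <- rnorm(3000, 100, 10)
  fit <- fit_exgaussian(x)
  expect_lt(fit$tau, fit$sigma)
  expect_error(fit_exgaussian(rep(100, 50)), "degenerate")
  expect_error(fit_exgaussian(rnorm(5)), "at least")
  # censored values are dropped, not propagated
  fit2 <- fit_exgaussian(c(x, rep(NA, 100)))
  expect_equal(fit2$n, 3000)
})

test_that("cumulative history accumulates per target channel", {
  cs <- cumulative_history(c(1, -1, 0.1), c(1, 1, 2))
  expect_equal(cs[1, ], c(1, 0, 0))
  expect_equal(cs[2, ], c(0, 0, 0.1))
  expect_equal(cs[3, ], c(0, 0, 0))
  # all-zero history: all-zero cumsum
  expect_true(all(cumulative_history(rep(0, 10), rep(1:2, 5)) == 0))
  # one channel rewarded on each of its 250 presentations sums to 250
  cs2 <- cumulative_history(rep(1, 250), rep(1L, 250))
  expect_equal(cs2[1, 250], 250)
  # linearity in the history values
  set.seed(3)
  tgt <- sample(1:4, 50, replace = TRUE)
  h1 <- runif(50); h2 <- runif(50)
  expect_equal(cumulative_history(h1 + h2, tgt),
               cumulative_history(h1, tgt) + cumulative_history(h2, tgt))
})

test_that("the weighted history statistic matches hand computation", {
  # two epochs, hand-computable: channels (1,2) then (1,-1) on ch 3/4
  cs <- cumulative_history(c(1, 1, 1, -1), c(1, 2, 3, 4))
  # epoch 4 cumsums: (1,1,1,-1), mean 0.5, sq devs (.25,.25,.25,2.25)
  w <- weighted_std_history(cs)
  n <- ncol(cs)
  manual_std <- sum(sqrt(colSums((cs - rep(colMeans(cs), each = 4))^2))) / n
  expect_equal(w$std_history, manual_std)
  expect_equal(w$ratio, (sum(cs < 0) / n) / sum(cs > 0))
  expect_equal(w$weighted, w$ratio * w$std_history)
  # the prose variant uses magnitudes
  ws <- weighted_std_history(cs, method = "sum")
  expect_equal(ws$ratio, -sum(cs[cs < 0]) / sum(cs[cs > 0]))
  # identical channels at every epoch: zero spread, zero weighted statistic
  cs_eq <- matrix(1, 4, 8)
  expect_equal(weighted_std_history(cs_eq)$std_history, 0)
  expect_equal(weighted_std_history(cs_eq)$weighted, 0)
  # all-negative history: ratio undefined
  cs_neg <- cumulative_history(rep(-1, 4), 1:4)
  expect_error(weighted_std_history(cs_neg), "positive")
})

test_that("group regressions report exact fits and affine-invariant R2", {
  x <- 1:6
  # suppressWarnings: summary.lm flags the deliberately perfect fits
  lin <- suppressWarnings(group_regression(x, 2 * x + 3, "linear"))
  expect_equal(lin$r_squared, 1)
  quad <- suppressWarnings(group_regression(x, x^2 - x + 1, "quadratic"))
  expect_equal(quad$r_squared, 1)
  set.seed(11)
  y <- 2 * x + rnorm(6)
  r1 <- group_regression(x, y, "linear")$r_squared
  r2 <- group_regression(10 * x - 7, y, "linear")$r_squared
  expect_equal(r1, r2)
  expect_error(group_regression(1:2, 1:2, "linear"), "at least")
})

test_that("subgroup labels follow the severity profile", {
  s <- data.frame(pct_success = c(100, 75, 60),
                  mu = c(120, 115, 190),
                  sigma = c(8, 9, 40),
                  tau = c(5, 80, 45))
  expect_equal(unname(classify_subgroups(s)), c("a", "b", "c"))
})
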