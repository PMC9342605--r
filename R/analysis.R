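#' Ex-Gaussian density
#'
#' Density of the exponentially-modified Gaussian distribution: the sum of
#' a normal variate (mean `mu`, sd `sigma`) and an independent exponential
#' variate (mean `tau`).  Computed on the log scale for numerical
#' stability in the far tail.
#'
#' @param x quantiles.
#' @param mu,sigma,tau distribution parameters (`sigma`, `tau` > 0).
#' @param log return log-density.
#' @return density values.
#' @examples
#' dexgauss(150, mu = 120, sigma = 10, tau = 45)
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  stopifnot(sigma > 0, tau > 0)
  z <- (x - mu) / sigma
  s_t <- sigma / tau
  # log f = -log tau + s_t^2/2 - z*s_t + log Phi(z - s_t)
  lf <- -base::log(tau) + s_t^2 / 2 - z * s_t +
    pnorm(z - s_t, log.p = TRUE)
  if (log) lf else exp(lf)
}

#' Draw ex-Gaussian random variates
#'
#' @param n sample size.
#' @param mu,sigma,tau distribution parameters.
#' @return numeric vector.
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
}

#' Fit an ex-Gaussian distribution to reaction times
#'
#' Maximum-likelihood fit of the exponentially-modified Gaussian, the
#' standard decomposition of reaction-time distributions: `mu` and `sigma`
#' describe the Gaussian body, `tau` the exponential slow tail (the
#' component that is characteristically inflated in attention-deficit
#' response patterns).  Initial values come from the method of moments and
#' the likelihood is maximised with `optim` (Nelder-Mead on log-scale
#' `sigma`, `tau`).
#'
#' @param rts numeric reaction times (any unit; typically ms); `NA`s
#'   (censored trials) are dropped.
#' @param min_n minimum number of finite observations required.
#' @return object of class `"exgauss_fit"`: list with `mu`, `sigma`,
#'   `tau`, `loglik`, `n`.  The fitted distribution mean is `mu + tau`.
#' @examples
#' set.seed(1)
#' x <- rexgauss(2000, mu = 120, sigma = 10, tau = 45)
#' fit_exgaussian(x)
#' @export
fit_exgaussian <- function(rts, min_n = 20) {
  x <- rts[is.finite(rts)]
  if (length(x) < min_n)
    stop("need at least ", min_n, " finite reaction times")
  if (sd(x) == 0) stop("degenerate sample: zero variance")
  m <- mean(x); s <- sd(x)
  skew <- mean((x - m)^3) / s^3
  # moment-based start: tau^3 = skew * s^3 / 2
  tau0 <- s * (max(skew, 0.01) / 2)^(1 / 3)
  tau0 <- min(max(tau0, s / 20), 2 * s)
  mu0 <- m - tau0
  sig0 <- sqrt(max(s^2 - tau0^2, (s / 10)^2))
  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2]); tau <- exp(par[3])
    -sum(dexgauss(x, mu, sigma, tau, log = TRUE))
  }
  # box constraints keep the optimum in the identifiable region (a huge
  # sigma with tau -> 0 can dominate the likelihood for strongly bimodal
  # samples without describing the tail)
  lower <- c(min(x) - 3 * s, base::log(s / 100), base::log(s / 100))
  upper <- c(max(x), base::log(2 * s), base::log(5 * s))
  fit <- optim(c(mu0, base::log(sig0), base::log(tau0)), nll,
               method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = 500))
  out <- list(mu = fit$par[1], sigma = exp(fit$par[2]),
              tau = exp(fit$par[3]), loglik = -fit$value, n = length(x))
  class(out) <- "exgauss_fit"
  out
}

#' @export
print.exgauss_fit <- function(x, ...) {
  cat(sprintf("ex-Gaussian fit (n = %d): mu = %.2f, sigma = %.2f, tau = %.2f\n",
              x$n, x$mu, x$sigma, x$tau))
  invisible(x)
}

#' Per-channel cumulative reinforcement history
#'
#' Running sum of the reinforcement history codes, attributed to the
#' action channel that was the target of each epoch's stimulus.  Channels
#' carry their value forward over epochs in which they were not presented,
#' so the result is a 4 x epochs matrix of step functions.
#'
#' @param history numeric epoch codes (+1, +0.1, -1, 0).
#' @param target integer target channel (1-4) per epoch.
#' @return 4 x length(history) matrix of cumulative sums.
#' @examples
#' cumulative_history(c(1, -1, 0.1), c(1, 1, 2))
#' @export
cumulative_history <- function(history, target) {
  stopifnot(length(history) == length(target),
            all(target %in% 1:4))
  n <- length(history)
  cs <- matrix(0, 4, n)
  cur <- numeric(4)
  for (i in seq_len(n)) {
    cur[target[i]] <- cur[target[i]] + history[i]
    cs[, i] <- cur
  }
  cs
}

#' History-variability statistic
#'
#' Quantifies how unevenly the four actions were reinforced during
#' training.  From the 4 x epochs cumulative-history matrix it computes:
#' `std_history`, the epoch-averaged across-channel spread
#' `(1/epochs) * sum_i sqrt(sum_j (cumsum_j(i) - mean(i))^2)`;
#' `ratio`, a penalty for predominantly negative histories; and their
#' product `weighted = ratio * std_history`.  With `method = "count"`
#' (the default) the ratio is the number of (epoch, channel) cells with a
#' negative cumulative sum, scaled by `1/epochs`, divided by the number of
#' cells with a positive one; with `method = "sum"` it is the total
#' negative magnitude divided by the total positive magnitude.  Both
#' variants grow when failures dominate successes.
#'
#' @param cs 4 x epochs matrix from [cumulative_history()].
#' @param method `"count"` or `"sum"` (see above).
#' @return list with `ratio`, `std_history` and `weighted`.
#' @examples
#' cs <- cumulative_history(c(1, 1, -1, -1), c(1, 2, 3, 3))
#' weighted_std_history(cs)
#' @export
weighted_std_history <- function(cs, method = c("count", "sum")) {
  method <- match.arg(method)
  stopifnot(is.matrix(cs), nrow(cs) == 4)
  n <- ncol(cs)
  mean_i <- colMeans(cs)
  std_history <- sum(sqrt(colSums((cs - rep(mean_i, each = 4))^2))) / n
  if (method == "count") {
    npos <- sum(cs > 0)
    if (npos == 0)
      stop("no positive cumulative-history cells; ratio undefined ",
           "(no action was ever successfully reinforced)")
    ratio <- (sum(cs < 0) / n) / npos
  } else {
    pos <- sum(cs[cs > 0])
    if (pos == 0)
      stop("no positive cumulative history; ratio undefined ",
           "(no action was ever successfully reinforced)")
    ratio <- -sum(cs[cs < 0]) / pos
  }
  list(ratio = ratio, std_history = std_history,
       weighted = ratio * std_history)
}

#' History metrics for a trained subject
#'
#' Convenience wrapper combining [cumulative_history()] and
#' [weighted_std_history()] for a training record.
#'
#' @param rec a record from [train_subject()].
#' @param method passed to [weighted_std_history()].
#' @return list with `cumsum` (4 x epochs matrix), `ratio`,
#'   `std_history`, `weighted`.
#' @export
history_metrics <- function(rec, method = "count") {
  cs <- cumulative_history(rec$history, rec$target)
  c(list(cumsum = cs), weighted_std_history(cs, method))
}

#' Group regression of reaction-time variability on history variability
#'
#' Least-squares fit of the per-subject reaction-time standard deviation
#' against the weighted history-variability statistic, linear or
#' quadratic.
#'
#' @param weighted predictor values (one per subject).
#' @param rt_sd response values.
#' @param model `"linear"` or `"quadratic"`.
#' @return list with `model`, `coefficients`, `r_squared` and the `lm`
#'   `fit` object.
#' @examples
#' group_regression(1:5, (1:5) * 2 + 3, "linear")$r_squared  # 1
#' @export
group_regression <- function(weighted, rt_sd,
                             model = c("linear", "quadratic")) {
  model <- match.arg(model)
  need <- if (model == "linear") 3 else 4
  ok <- is.finite(weighted) & is.finite(rt_sd)
  if (sum(ok) < need)
    stop("need at least ", need, " complete points for a ", model, " fit")
  d <- data.frame(x = weighted[ok], y = rt_sd[ok])
  fit <- if (model == "linear") lm(y ~ x, data = d)
         else lm(y ~ x + I(x^2), data = d)
  list(model = model, coefficients = coef(fit),
       r_squared = summary(fit)$r.squared, fit = fit)
}

#' Classify imbalance subjects into severity subgroups
#'
#' Splits subjects into three profiles along increasing history
#' variability: `a` - perfect test accuracy (variability may already be
#' elevated, but performance is intact); `b` - impaired accuracy with an
#' exponential-dominated reaction-time distribution (`tau` much larger
#' than `sigma`: a mixture of fast and very slow responses); `c` - the
#' poorest accuracy with a slow, broadly Gaussian distribution (large
#' `mu`, `sigma` and `tau` comparable).  Thresholds are explicit
#' arguments, not fitted quantities.
#'
#' @param summaries data.frame with one row per subject and columns
#'   `pct_success`, `mu`, `sigma`, `tau`.
#' @param perfect success percentage counted as perfect.
#' @param tau_dominance `tau/sigma` ratio above which the distribution is
#'   considered exponential-dominated (group `b`).
#' @return character vector of labels `"a"`, `"b"`, `"c"`.
#' @examples
#' s <- data.frame(pct_success = c(100, 75, 60),
#'                 mu = c(120, 115, 190), sigma = c(8, 9, 40),
#'                 tau = c(5, 80, 45))
#' classify_subgroups(s)
#' @export
classify_subgroups <- function(summaries, perfect = 100,
                               tau_dominance = 3) {
  stopifnot(all(c("pct_success", "mu", "sigma", "tau") %in%
                names(summaries)))
  apply(summaries, 1, function(r) {
    if (r[["pct_success"]] >= perfect) "a"
    else if (r[["tau"]] >= tau_dominance * r[["sigma"]]) "b"
    else "c"
  })
}
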