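#' Canonical training stimulus set
#'
#' The four stimulus vectors of the forced-choice task.  Each vector has
#' one strong channel (value 1, the target), one intermediate channel
#' (0.2) and two weak channels (0.1); each action channel is the target of
#' exactly one vector.
#'
#' @return a 4x4 matrix, one stimulus vector per row.
#' @examples
#' stimulus_set()
#' @export
stimulus_set <- function() {
  rbind(c(1.0, 0.2, 0.1, 0.1),
        c(0.2, 1.0, 0.1, 0.1),
        c(0.1, 0.1, 0.2, 1.0),
        c(0.1, 0.1, 1.0, 0.2))
}

#' Build a paired virtual cohort
#'
#' Creates the specifications of `n_per_group` control and `n_per_group`
#' dopamine-imbalance subjects.  Subject *k* of the two groups shares the
#' same noise seed - they experience identical noise streams and stimulus
#' orders - and the groups differ only in the maximal reuptake rate
#' `Vmax` of their dopamine parameters.  Per-subject seeds are drawn once
#' from `base_seed`, so the same `base_seed` always reproduces the same
#' cohort and extending the cohort preserves existing subjects.
#'
#' @param n_per_group subjects per group.
#' @param base_seed integer master seed.
#' @param net [network_params()] shared by all subjects.
#' @param lp [learning_params()] shared by all subjects.
#' @return list of subject specs; each spec is a list with fields `group`,
#'   `subject_id`, `noise_seed`, `da_params`, `net`, `lp`.
#' @examples
#' specs <- build_cohort(2, base_seed = 1)
#' sapply(specs, function(s) s$group)
#' @export
build_cohort <- function(n_per_group = 10, base_seed = 1,
                         net = network_params(), lp = learning_params()) {
  stopifnot(n_per_group >= 1)
  set.seed(base_seed)
  seeds <- sample.int(2147483646L, n_per_group)
  specs <- list()
  for (k in seq_len(n_per_group)) {
    for (grp in c("control", "imbalance")) {
      specs[[length(specs) + 1L]] <- list(
        group = grp, subject_id = k, noise_seed = seeds[k],
        da_params = da_params(grp), net = net, lp = lp)
    }
  }
  specs
}

#' Train one virtual subject
#'
#' Runs the training protocol: `epochs / 4` blocks, each presenting the
#' four canonical stimuli in random order for 800 ms apiece, with uniform
#' cortical noise.  After each responded trial the earned dopamine event
#' (large/small reward burst or punishment clamp) unfolds and the Hebb rule
#' updates the plastic weights once.  The reinforcement history is coded
#' +1 (large reward), +0.1 (small reward), -1 (punishment), 0 (no
#' response), and each epoch is attributed to the target channel of the
#' stimulus presented.
#'
#' @param spec one subject spec from [build_cohort()].
#' @param epochs number of training trials (a multiple of 4).
#' @param duration stimulus presentation time (s).
#' @param threshold response threshold.
#' @param dt integration step (s).
#' @param keep_weight_trajectory if `TRUE`, snapshot the weights once per
#'   block.
#' @return a subject record: list with `spec`, `history` (epoch codes),
#'   `target` (target channel per epoch), `chosen`, `rt`, `weights`
#'   (final), `ratio` (the subject's dopamine ratio),
#'   `trials_to_criterion`, and optionally `weight_trajectory`.
#' @examples
#' \donttest{
#' rec <- train_subject(build_cohort(1, 1)[[1]], epochs = 40)
#' table(rec$history)
#' }
#' @export
train_subject <- function(spec, epochs = 1000, duration = 0.8,
                          threshold = 0.9, dt = 1e-3,
                          keep_weight_trajectory = FALSE) {
  stopifnot(epochs %% 4 == 0)
  da <- spec$da_params; net <- spec$net; lp <- spec$lp
  ratio <- da_ratio(da, dt = dt)
  occ_traces <- window_occupancy_traces(da, lp, dt)
  stim <- stimulus_set()
  W <- naive_weights()
  history <- numeric(epochs); target <- integer(epochs)
  chosen <- integer(epochs); rts <- rep(NA_real_, epochs)
  wtraj <- if (keep_weight_trajectory) vector("list", epochs / 4) else NULL

  set.seed(spec$noise_seed)
  ep <- 0L
  for (b in seq_len(epochs / 4)) {
    for (s_idx in sample.int(4L)) {
      ep <- ep + 1L
      S <- stim[s_idx, ]
      trial <- run_trial(S, W, net = net, da = da, duration = duration,
                         threshold = threshold, dt = dt)
      out <- assign_outcome(S, trial$chosen, lp)
      history[ep] <- out$code
      target[ep] <- which.max(S)
      chosen[ep] <- trial$chosen
      rts[ep] <- trial$rt
      W <- apply_learning_event(trial, out, W, ratio, da = da, net = net,
                                lp = lp, occ_traces = occ_traces, dt = dt)
    }
    if (keep_weight_trajectory) wtraj[[b]] <- W
  }
  rec <- list(spec = spec, history = history, target = target,
              chosen = chosen, rt = rts, weights = W, ratio = ratio,
              trials_to_criterion = trials_to_criterion(history))
  if (keep_weight_trajectory) rec$weight_trajectory <- wtraj
  rec
}

#' Trials to the learning criterion
#'
#' The criterion is 5 successful responses within 10 successive trials,
#' where a success is a large-reward outcome (history code +1).  Returns
#' the index of the last trial of the first such window, or `NA`
#' (censored) if the criterion is never met.
#'
#' @param history numeric vector of epoch history codes.
#' @param successes,window criterion definition (5 of 10 by default).
#' @return integer trial count, or `NA_integer_` if censored.
#' @examples
#' trials_to_criterion(rep(1, 20))   # 5
#' trials_to_criterion(rep(-1, 20))  # NA (censored)
#' @export
trials_to_criterion <- function(history, successes = 5, window = 10) {
  succ <- as.integer(history == 1)
  n <- length(succ)
  run <- cumsum(succ)
  for (t in seq_len(n)) {
    lo <- max(t - window + 1L, 1L)
    cnt <- run[t] - if (lo > 1L) run[lo - 1L] else 0L
    if (cnt >= successes) return(t)
  }
  NA_integer_
}

#' Test phase for a trained subject
#'
#' Freezes the weights and presents `n_stimuli` four-choice reaction-time
#' trials.  Each trial targets a random channel: the stimulus in the
#' target channel has value 1 (plus normal noise with standard deviation
#' `stim_sd` when a noise sweep is requested), while every channel
#' receives the background cortical noise.  A trial ends at the first
#' threshold crossing (1,800 ms limit); a crossing in the target channel
#' is a success.  Trials with no crossing are failures with censored
#' reaction time.
#'
#' @param spec subject spec.
#' @param W trained weights.
#' @param n_stimuli number of test trials.
#' @param duration per-stimulus presentation limit (s).
#' @param threshold response threshold.
#' @param dt integration step (s).
#' @param stim_sd standard deviation of the sweep noise on the target
#'   channel; 0 (the default) presents a clean unit stimulus.  When
#'   positive, normal noise with mean 1 and this standard deviation is
#'   added on top of the unit stimulus ([noise_sweep()] raises this);
#'   negative total drives are clipped to 0.
#' @return list with per-trial vectors `target`, `chosen`, `rt` (s, `NA`
#'   censored), `success`, and summary fields `pct_success`, `mean_rt`,
#'   `sd_rt` (reaction-time stats over responded trials, in s).
#' @examples
#' \donttest{
#' spec <- build_cohort(1, 1)[[1]]
#' rec <- train_subject(spec, epochs = 40)
#' test_subject(spec, rec$weights, n_stimuli = 10)$pct_success
#' }
#' @export
test_subject <- function(spec, W, n_stimuli = 100, duration = 1.8,
                         threshold = 0.9, dt = 1e-3, stim_sd = 0) {
  da <- spec$da_params; net <- spec$net
  set.seed(spec$noise_seed + 1L)
  target <- sample.int(4L, n_stimuli, replace = TRUE)
  chosen <- integer(n_stimuli); rts <- rep(NA_real_, n_stimuli)
  for (i in seq_len(n_stimuli)) {
    S <- numeric(4)
    S[target[i]] <- if (stim_sd > 0) max(1 + rnorm(1, 1, stim_sd), 0) else 1
    trial <- run_trial(S, W, net = net, da = da, duration = duration,
                       threshold = threshold, dt = dt)
    chosen[i] <- trial$chosen
    rts[i] <- trial$rt
  }
  success <- chosen == target
  ok <- !is.na(rts)
  list(target = target, chosen = chosen, rt = rts, success = success,
       pct_success = 100 * mean(success),
       mean_rt = if (any(ok)) mean(rts[ok]) else NA_real_,
       sd_rt = if (sum(ok) > 1) sd(rts[ok]) else NA_real_)
}

#' Success curve under increasing stimulus noise
#'
#' Repeats the test phase while adding normal noise (mean 1, standard
#' deviation swept from 0 upward) to the target-channel stimulus, and
#' records the percentage of successes at each noise level.  Increasing
#' the spread raises the probability of weak total drives that fail to
#' ignite the correct channel.
#'
#' @param spec subject spec.
#' @param W trained weights.
#' @param sd_grid standard deviations to sweep.
#' @param n_stimuli trials per noise level.
#' @param ... passed to [test_subject()].
#' @return data.frame with columns `sd` and `pct_success`.
#' @export
noise_sweep <- function(spec, W, sd_grid = seq(0, 1, by = 0.1),
                        n_stimuli = 100, ...) {
  stopifnot(all(sd_grid >= 0))
  pct <- vapply(sd_grid, function(s)
    test_subject(spec, W, n_stimuli = n_stimuli, stim_sd = s, ...)$pct_success,
    numeric(1))
  data.frame(sd = sd_grid, pct_success = pct)
}

#' Input-output gain curve of the basal ganglia loop
#'
#' Presents stimuli of increasing amplitude in the first action channel
#' (the other channels receive only background cortical noise) and records
#' the maximum cortical output activity in that channel, summarised over
#' repeated presentations.
#'
#' @param spec subject spec.
#' @param W trained weights.
#' @param amplitudes stimulus amplitudes to probe.
#' @param n_rep repetitions per amplitude.
#' @param duration trial length (s).
#' @param dt integration step (s).
#' @return data.frame with columns `amplitude`, `mean`, `p5`, `p95` of the
#'   channel-1 cortical output.
#' @export
io_gain_curve <- function(spec, W, amplitudes = seq(0.1, 1, by = 0.1),
                          n_rep = 10, duration = 1.8, dt = 1e-3) {
  stopifnot(all(amplitudes >= 0 & amplitudes <= 1.5))
  da <- spec$da_params; net <- spec$net
  set.seed(spec$noise_seed + 2L)
  out <- lapply(amplitudes, function(a) {
    y <- vapply(seq_len(n_rep), function(i) {
      trial <- run_trial(c(a, 0, 0, 0), W, net = net, da = da,
                         duration = duration, dt = dt)
      trial$max_cortex[1]
    }, numeric(1))
    c(mean = mean(y), p5 = unname(quantile(y, 0.05)),
      p95 = unname(quantile(y, 0.95)))
  })
  res <- do.call(rbind, out)
  data.frame(amplitude = amplitudes, mean = res[, 1],
             p5 = res[, 2], p95 = res[, 3])
}

#' Run the full two-group virtual-cohort experiment
#'
#' Trains and tests paired control / dopamine-imbalance cohorts and
#' assembles the group-level summaries: trials to criterion, test-phase
#' success and reaction-time statistics, ex-Gaussian fits of the pooled
#' reaction times, and the history-variability statistic with its group
#' regressions.
#'
#' @param n_per_group subjects per group.
#' @param base_seed master seed.
#' @param epochs training epochs per subject.
#' @param n_test test-phase stimuli per subject.
#' @param net,lp shared [network_params()] and [learning_params()].
#' @param progress print one line per subject.
#' @return list with `subjects` (per-subject records, each containing the
#'   training record, test results and history metrics) and `summary`
#'   (per-group statistics).
#' @examples
#' \donttest{
#' ex <- run_experiment(n_per_group = 2, base_seed = 1, epochs = 100,
#'                      n_test = 20)
#' ex$summary
#' }
#' @export
run_experiment <- function(n_per_group = 10, base_seed = 1, epochs = 1000,
                           n_test = 100, net = network_params(),
                           lp = learning_params(), progress = FALSE) {
  specs <- build_cohort(n_per_group, base_seed, net = net, lp = lp)
  subjects <- lapply(specs, function(spec) {
    rec <- train_subject(spec, epochs = epochs)
    tst <- test_subject(spec, rec$weights, n_stimuli = n_test)
    hm <- history_metrics(rec)
    if (progress)
      message(sprintf("%s #%d: criterion %s, success %.0f%%",
                      spec$group, spec$subject_id,
                      ifelse(is.na(rec$trials_to_criterion), "censored",
                             rec$trials_to_criterion), tst$pct_success))
    list(spec = spec, train = rec, test = tst, history = hm)
  })
  list(subjects = subjects,
       summary = summarize_experiment(subjects))
}

#' Summarise an experiment by group
#'
#' @param subjects the `subjects` element of [run_experiment()] output.
#' @return data.frame with one row per group: mean/SD of trials to
#'   criterion (censored excluded), number censored, mean/SD of the
#'   per-subject success percentage, mean/SD of reaction times (ms, pooled
#'   over responded trials), and the pooled ex-Gaussian parameters
#'   (mu, sigma, tau, ms).
#' @export
summarize_experiment <- function(subjects) {
  grp <- vapply(subjects, function(s) s$spec$group, "")
  rows <- lapply(c("control", "imbalance"), function(g) {
    sub <- subjects[grp == g]
    if (!length(sub)) return(NULL)
    ttc <- vapply(sub, function(s)
      as.numeric(s$train$trials_to_criterion), numeric(1))
    succ <- vapply(sub, function(s) s$test$pct_success, numeric(1))
    rts <- unlist(lapply(sub, function(s) s$test$rt))
    rts <- rts[!is.na(rts)] * 1000
    fit <- tryCatch(fit_exgaussian(rts), error = function(e) NULL)
    data.frame(group = g,
               n = length(sub),
               mean_trials_to_criterion = mean(ttc, na.rm = TRUE),
               sd_trials_to_criterion = sd(ttc, na.rm = TRUE),
               n_censored = sum(is.na(ttc)),
               mean_pct_success = mean(succ),
               sd_pct_success = sd(succ),
               mean_rt_ms = mean(rts),
               sd_rt_ms = sd(rts),
               exg_mu = if (is.null(fit)) NA_real_ else fit$mu,
               exg_sigma = if (is.null(fit)) NA_real_ else fit$sigma,
               exg_tau = if (is.null(fit)) NA_real_ else fit$tau)
  })
  do.call(rbind, rows)
}
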