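#' Naive cortico-striatal weights
#'
#' The four plastic weight matrices in their naive state: all active
#' entries at 0.5, with no differentiation between action channels.
#' `wGS` and `wNS` (stimulus to Go / NoGo) are full 4x4 matrices; `wGC` and
#' `wNC` (cortex to Go / NoGo) are diagonal, and only their diagonals are
#' ever trained.
#'
#' @return object of class `"plastic_weights"`: list with fields `wGS`,
#'   `wNS`, `wGC`, `wNC`, each a 4x4 matrix.
#' @examples
#' W <- naive_weights()
#' W$wGC
#' @export
naive_weights <- function() {
  structure(list(wGS = matrix(0.5, 4, 4), wNS = matrix(0.5, 4, 4),
                 wGC = diag(0.5, 4), wNC = diag(0.5, 4)),
            class = "plastic_weights")
}

check_weights <- function(W) {
  if (!is.list(W) || !all(c("wGS", "wNS", "wGC", "wNC") %in% names(W)))
    stop("W must contain matrices wGS, wNS, wGC, wNC")
  for (nm in c("wGS", "wNS", "wGC", "wNC")) {
    m <- W[[nm]]
    if (!is.matrix(m) || !all(dim(m) == c(4L, 4L)))
      stop(nm, " must be a 4x4 matrix")
  }
  for (nm in c("wGC", "wNC"))
    if (any(W[[nm]][row(W[[nm]]) != col(W[[nm]])] != 0))
      stop(nm, " must be diagonal")
  invisible(W)
}

#' Learning-rule parameters
#'
#' @param phi_base base gain coefficient of the Hebb rule.
#' @param theta_pre,theta_post pre- and postsynaptic activity thresholds
#'   (midpoint of the normalised activity range by default).
#' @param latency delay from the response to the dopamine/learning window (s).
#' @param window duration of the dopamine/learning window (s).
#' @param rpe_large,rpe_small reward-prediction-error magnitudes for
#'   choosing the strongest (value 1) and second-strongest (value 0.2)
#'   stimulus channel.
#' @return object of class `"learning_params"`.
#' @examples
#' learning_params()
#' @export
learning_params <- function(phi_base = 0.0013, theta_pre = 0.5,
                            theta_post = 0.5, latency = 0.1,
                            window = 0.05, rpe_large = 1, rpe_small = 0.1) {
  if (phi_base <= 0) stop("phi_base must be > 0")
  if (theta_pre < 0 || theta_pre > 1 || theta_post < 0 || theta_post > 1)
    stop("thresholds must lie in [0, 1]")
  if (latency <= 0 || window <= 0) stop("latency and window must be > 0")
  structure(list(phi_base = phi_base, theta_pre = theta_pre,
                 theta_post = theta_post, latency = latency,
                 window = window, rpe_large = rpe_large,
                 rpe_small = rpe_small),
            class = "learning_params")
}

#' Outcome of a trial given the canonical stimulus
#'
#' Maps the chosen channel to the reinforcement outcome.  The stimulus must
#' be in canonical form (one value 1, one 0.2, two 0.1, before any noise).
#' Choosing the strongest channel yields a large reward-prediction error
#' (+1), the second-strongest a small one (+0.1), either of the weak
#' channels a punishment (history code -1), and no response codes 0.
#'
#' @param S canonical stimulus vector.
#' @param chosen chosen channel index in 1..4, or 0 / `NA` for no response.
#' @param lp [learning_params()].
#' @return list with `kind` (`"reward"`, `"punishment"` or `"none"`),
#'   `magnitude` (RPE magnitude, 0 if none) and `code` (history code:
#'   +1, +0.1, -1 or 0).
#' @examples
#' assign_outcome(c(1, 0.2, 0.1, 0.1), 1)$code   # +1
#' assign_outcome(c(1, 0.2, 0.1, 0.1), 2)$code   # +0.1
#' @export
assign_outcome <- function(S, chosen, lp = learning_params()) {
  sv <- sort(S, decreasing = TRUE)
  if (!isTRUE(all.equal(sv, c(1, 0.2, 0.1, 0.1))))
    stop("S is not canonical (expected one 1, one 0.2, two 0.1)")
  if (is.na(chosen) || chosen == 0)
    return(list(kind = "none", magnitude = 0, code = 0))
  stopifnot(chosen %in% 1:4)
  if (S[chosen] == 1)
    list(kind = "reward", magnitude = lp$rpe_large, code = 1)
  else if (S[chosen] == 0.2)
    list(kind = "reward", magnitude = lp$rpe_small, code = 0.1)
  else
    list(kind = "punishment", magnitude = lp$rpe_large, code = -1)
}

#' Hebbian learning gain
#'
#' `phi = phi_base * |RPE| * DA-ratio`.  The phasic/tonic dopamine ratio is
#' precomputed per subject ([da_ratio()]) and treated as a constant, so a
#' dopamine-imbalance subject (ratio ~8.3) updates its synapses roughly
#' 2.8x faster than a control (ratio ~3) for the same prediction error.
#'
#' @param rpe reward-prediction-error magnitude.
#' @param ratio the subject's phasic/tonic dopamine ratio.
#' @param lp [learning_params()].
#' @return the gain `phi`.
#' @examples
#' gain_phi(1, 3)  # ~0.0039
#' @export
gain_phi <- function(rpe, ratio, lp = learning_params()) {
  if (ratio < 0) stop("ratio must be >= 0")
  lp$phi_base * abs(rpe) * ratio
}

#' Apply the Hebb rule to the plastic weights
#'
#' Thresholded Hebbian update
#' `dw_ij = phi * max(y_pre_j - theta_pre, 0) * (y_post_i - theta_post)`.
#' The positive-part gate on the presynaptic term means silent presynaptic
#' units never drive learning; the ungated postsynaptic term lets
#' sub-threshold postsynaptic activity *depress* the synapse.  Presynaptic
#' activities are the stimulus vector (for `wGS`, `wNS`) and the cortical
#' activities (for the diagonals of `wGC`, `wNC`); postsynaptic activities
#' are the Go and NoGo unit activities.  All entries of the full matrices
#' and only the diagonals of the cortical matrices are updated, and the
#' result is clipped to \[0, 1\].
#'
#' @param W [naive_weights()]-shaped weight list.
#' @param y_S stimulus vector (presynaptic activities for `wGS`/`wNS`).
#' @param y_C cortical activities (presynaptic for `wGC`/`wNC` diagonals).
#' @param y_G,y_N Go and NoGo activities (postsynaptic).
#' @param phi learning gain from [gain_phi()].
#' @param lp [learning_params()].
#' @return the updated weights.
#' @examples
#' W <- naive_weights()
#' W2 <- hebb_update(W, c(1, .2, .1, .1), c(.95, 0, 0, 0),
#'                   c(.9, .3, .3, .3), c(.1, .1, .1, .1), phi = 0.0039)
#' @export
hebb_update <- function(W, y_S, y_C, y_G, y_N, phi,
                        lp = learning_params()) {
  check_weights(W)
  stopifnot(length(y_S) == 4, length(y_C) == 4,
            length(y_G) == 4, length(y_N) == 4)
  pre_S <- pmax(y_S - lp$theta_pre, 0)
  pre_C <- pmax(y_C - lp$theta_pre, 0)
  post_G <- y_G - lp$theta_post
  post_N <- y_N - lp$theta_post
  clip01 <- function(m) pmin(pmax(m, 0), 1)
  W$wGS <- clip01(W$wGS + phi * outer(post_G, pre_S))
  W$wNS <- clip01(W$wNS + phi * outer(post_N, pre_S))
  W$wGC <- diag(clip01(diag(W$wGC) + phi * pre_C * post_G), 4)
  W$wNC <- diag(clip01(diag(W$wNC) + phi * pre_C * post_N), 4)
  W
}

# Per-step D1/D2 occupancy traces across the learning window for each
# event kind, precomputed once per subject (the transient always starts
# from the tonic steady state).
window_occupancy_traces <- function(da, lp = learning_params(), dt = 1e-3) {
  nwin <- round(lp$window / dt)
  mk <- function(rpe) {
    tr <- phasic_transient(da, rpe = rpe, dt = dt,
                           t_end = lp$latency + lp$window,
                           latency = lp$latency, duration = lp$window)$trace
    idx <- which(tr$t > lp$latency - dt / 2 &
                 tr$t <= lp$latency + lp$window + dt / 2)[seq_len(nwin)]
    list(D1 = tr$D1[idx], D2 = tr$D2[idx])
  }
  list(reward_large = mk(1), reward_small = mk(0.1),
       punishment = list(D1 = rep(0, nwin), D2 = rep(0, nwin)))
}

#' Apply one learning event after a trial
#'
#' Once a response has occurred, the dopamine event it earned (reward burst
#' or punishment clamp) unfolds 0.1 s later and lasts 0.05 s.  This
#' function continues the network integration from the response through the
#' event window (with D1/D2 following the dopamine transient: a burst
#' raises D1 drive to the Go pathway, the punishment clamp removes all
#' dopamine tone and disinhibits NoGo), time-averages the activities across
#' the window, and applies [hebb_update()] once.  No-response trials change
#' nothing.
#'
#' @param trial result of [run_trial()] (needs the saved `state`).
#' @param outcome result of [assign_outcome()] for this trial.
#' @param W current weights.
#' @param ratio the subject's [da_ratio()].
#' @param da,net,lp model parameter objects.
#' @param occ_traces optional precomputed per-event D1/D2 occupancy traces
#'   across the window; supplied by [train_subject()] so the transient is
#'   not re-integrated every epoch.
#' @param dt integration step (s).
#' @param noise logical; keep cortical noise on during the window.
#' @return the updated weights.
#' @export
apply_learning_event <- function(trial, outcome, W, ratio,
                                 da = da_params(), net = network_params(),
                                 lp = learning_params(), occ_traces = NULL,
                                 dt = 1e-3, noise = TRUE) {
  if (outcome$kind == "none" || !trial$responded) return(W)
  if (is.null(occ_traces)) occ_traces <- window_occupancy_traces(da, lp, dt)
  tr <- switch(outcome$kind,
    reward = if (outcome$magnitude >= lp$rpe_large) occ_traces$reward_large
             else occ_traces$reward_small,
    punishment = occ_traces$punishment)
  ss <- da_steady_state(da)
  occ <- receptor_occupancy(ss$C_tonic, da)
  win <- .run_window_cpp(trial$state, as.numeric(trial$S),
                         W$wGS, W$wNS, diag(W$wGC), diag(W$wNC),
                         unclass(net), occ$D1, occ$D2,
                         tr$D1, tr$D2, dt,
                         lat_steps = round(lp$latency / dt),
                         noise_on = noise)
  phi <- gain_phi(outcome$magnitude, ratio, lp)
  hebb_update(W, trial$S, win$y_cortex, win$y_go, win$y_nogo, phi, lp)
}
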