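#' Tonic dopamine release rate
#'
#' Sustained release from background firing,
#' `rho * Pr_tonic * n0 / (alpha_vf * NA) * nu_tonic`, converted to uM/L/s.
#' Tonic release is independent of autoreceptor occupancy.
#'
#' @param p a [da_params()] object.
#' @return release rate (uM/L/s).
#' @examples
#' tonic_release_rate(da_params("control"))  # ~0.1423 uM/L/s
#' @export
tonic_release_rate <- function(p) {
  stopifnot(inherits(p, "da_params"))
  p$rho * p$Pr_tonic * p$n0 / (p$alpha_vf * p$avogadro) * p$nu_tonic * 1e6
}

#' Phasic dopamine release rate
#'
#' Burst release during a reward-prediction-error signal.  Both the vesicle
#' release probability and the burst firing rate are scaled inversely with
#' autoreceptor occupancy (normalised so the scaling is 1 at the control
#' occupancy `AR_norm` = 0.334), so the release rate carries an
#' `(AR_norm / AR)^2` autoregulation factor: low autoreceptor occupancy
#' (low tonic dopamine) *amplifies* phasic release.
#'
#' @param p a [da_params()] object.
#' @param AR autoreceptor occupancy in (0, 1]; `AR = 0` is an error
#'   (uncalibrated state).
#' @param rpe reward-prediction-error magnitude (absolute value is used).
#' @return release rate (uM/L/s).
#' @examples
#' p <- da_params("control")
#' # at AR = AR_norm and RPE = 1 this is (nu_phasic/nu_tonic) x tonic rate
#' phasic_release_rate(p, AR = 0.334, rpe = 1) / tonic_release_rate(p)
#' @export
phasic_release_rate <- function(p, AR, rpe) {
  stopifnot(inherits(p, "da_params"))
  if (any(AR <= 0)) stop("AR must be > 0 (AR = 0 signals an uncalibrated state)")
  if (any(AR > 1)) stop("AR must be <= 1")
  p$rho * (p$Pr_phasic * p$AR_norm / AR) * p$n0 * abs(rpe) /
    (p$alpha_vf * p$avogadro) * (p$nu_phasic * p$AR_norm / AR) * 1e6
}

#' D1/D2 receptor occupancy
#'
#' Equilibrium receptor binding `D_i = Bmax_i * C / (kD_i + C)` for the two
#' postsynaptic receptor families.  D1 occupancy excites the direct (Go)
#' pathway, D2 occupancy inhibits the indirect (NoGo) pathway in the
#' basal-ganglia network.
#'
#' @param C dopamine concentration (uM/L), scalar or vector.
#' @param p a [da_params()] object.
#' @return list with numeric fields `D1` and `D2` (bound receptor
#'   concentration, uM/L), same length as `C`.
#' @examples
#' receptor_occupancy(0.02, da_params("control"))
#' @export
receptor_occupancy <- function(C, p) {
  stopifnot(inherits(p, "da_params"))
  if (any(C < 0)) stop("C must be >= 0")
  list(D1 = p$Bmax_D1 * C / (p$kD_D1 + C),
       D2 = p$Bmax_D2 * C / (p$kD_D2 + C))
}

# time-derivatives of (C_DA, AR) given an instantaneous release rate
da_deriv <- function(C, AR, p, release) {
  c(release - p$Vmax * C / (p$km + C) - p$krem * C,
    C * p$kon * (1 - AR) - p$koff * AR)
}

#' Advance the dopamine state by one time step
#'
#' One fixed-step RK4 update of the concentration/occupancy pair.  Outside
#' any event window the terminal releases tonically.  Inside a reward
#' window the phasic term [phasic_release_rate()] is added (with the
#' occupancy tracked continuously through the burst).  Inside a punishment
#' window the concentration is clamped to zero for the whole window (the
#' firing-pause simplification); the occupancy keeps evolving by pure
#' unbinding.
#'
#' @param state list with fields `C_DA` (uM/L), `AR` (fraction) and `t` (s).
#' @param p a [da_params()] object.
#' @param events list of [rpe_event()] objects (possibly empty).
#' @param dt step size (s); must be positive and at most 1 ms so the burst
#'   and clamp windows are resolved.
#' @return the updated state list (with `t` advanced by `dt`).
#' @examples
#' p <- da_params()
#' ss <- da_steady_state(p)
#' st <- list(C_DA = ss$C_tonic, AR = ss$AR, t = 0)
#' da_step(st, p, list(), dt = 1e-3)
#' @export
da_step <- function(state, p, events = list(), dt = 1e-3) {
  stopifnot(inherits(p, "da_params"))
  if (dt <= 0) stop("dt must be > 0")
  if (dt > 1e-3 + 1e-12) stop("dt must be <= 1 ms")
  if (inherits(events, "rpe_event")) events <- list(events)
  C <- state$C_DA; AR <- state$AR; t <- state$t
  if (C < 0) stop("C_DA must be >= 0")
  if (AR < 0 || AR > 1) stop("AR must lie in [0, 1]")

  punish <- any(vapply(events, function(ev)
    ev$kind == "punishment" && in_event_window(ev, t), logical(1)))
  if (punish) {
    # hard clamp: C = 0 across the window, AR unbinds with C = 0
    AR2 <- rk4_scalar(function(a) -p$koff * a, AR, dt)
    return(list(C_DA = 0, AR = AR2, t = t + dt))
  }
  release <- function(Ct, ARt) {
    r <- tonic_release_rate(p)
    for (ev in events)
      if (ev$kind == "reward" && in_event_window(ev, t))
        r <- r + phasic_release_rate(p, ARt, ev$magnitude)
    r
  }
  f <- function(x) da_deriv(x[1], x[2], p, release(x[1], x[2]))
  x <- c(C, AR)
  k1 <- f(x); k2 <- f(x + dt / 2 * k1); k3 <- f(x + dt / 2 * k2)
  k4 <- f(x + dt * k3)
  x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  list(C_DA = max(x[1], 0), AR = min(max(x[2], 0), 1), t = t + dt)
}

rk4_scalar <- function(f, x, dt) {
  k1 <- f(x); k2 <- f(x + dt / 2 * k1); k3 <- f(x + dt / 2 * k2)
  k4 <- f(x + dt * k3)
  x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Tonic steady state of the dopamine terminal
#'
#' Solves `tonic_release = Vmax*C/(km + C) + krem*C` for the unique positive
#' root (closed-form quadratic) and the corresponding autoreceptor
#' occupancy `AR = kon*C / (kon*C + koff)`.
#'
#' @param p a [da_params()] object.
#' @return list with `C_tonic` (uM/L) and `AR` (fraction).
#' @examples
#' da_steady_state(da_params("control"))    # C ~ 0.02, AR ~ 0.334
#' da_steady_state(da_params("imbalance"))  # C ~ 0.0128
#' @export
da_steady_state <- function(p) {
  stopifnot(inherits(p, "da_params"))
  I <- tonic_release_rate(p)
  # krem C^2 + (Vmax + krem*km - I) C - I*km = 0
  a <- p$krem; b <- p$Vmax + p$krem * p$km - I; cc <- -I * p$km
  C <- if (a > 0) (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a) else -cc / b
  list(C_tonic = C, AR = p$kon * C / (p$kon * C + p$koff))
}

#' Single-burst phasic dopamine transient
#'
#' Integrates the terminal model from its tonic steady state through one
#' reward burst (latency 0.1 s, duration 0.05 s by default) and returns the
#' trajectory and its peak concentration.
#'
#' @param p a [da_params()] object.
#' @param rpe reward-prediction-error magnitude of the burst.
#' @param dt integration step (s).
#' @param t_end end of the simulated interval (s); must cover the burst.
#' @param latency,duration burst window geometry (s).
#' @return list with `trace` (data.frame `t`, `C_DA`, `AR`, `D1`, `D2`),
#'   `C_peak` (uM/L) and `C_tonic` (uM/L).
#' @examples
#' tr <- phasic_transient(da_params("control"), rpe = 1)
#' tr$C_peak
#' @export
phasic_transient <- function(p, rpe = 1, dt = 1e-3, t_end = 0.3,
                             latency = 0.1, duration = 0.05) {
  stopifnot(inherits(p, "da_params"))
  ss <- da_steady_state(p)
  ev <- if (rpe > 0)
    list(rpe_event("reward", magnitude = rpe, onset = 0,
                   latency = latency, duration = duration)) else list()
  n <- ceiling(t_end / dt)
  out <- matrix(NA_real_, n + 1L, 3L)
  st <- list(C_DA = ss$C_tonic, AR = ss$AR, t = 0)
  out[1L, ] <- c(0, st$C_DA, st$AR)
  for (i in seq_len(n)) {
    st <- da_step(st, p, ev, dt)
    out[i + 1L, ] <- c(st$t, st$C_DA, st$AR)
  }
  occ <- receptor_occupancy(out[, 2L], p)
  trace <- data.frame(t = out[, 1L], C_DA = out[, 2L], AR = out[, 3L],
                      D1 = occ$D1, D2 = occ$D2)
  list(trace = trace, C_peak = max(out[, 2L]), C_tonic = ss$C_tonic)
}

#' Phasic/tonic dopamine ratio
#'
#' The learning-gain constant `(C_peak - C_tonic) / C_tonic`, with `C_peak`
#' the maximum concentration of a single unit-RPE burst starting from the
#' tonic steady state.  It is computed once per parameter set and treated
#' as a per-subject constant.  Typical values: ~3 for the control preset,
#' ~8.3 for the imbalance preset - raising reuptake lowers tonic dopamine
#' and autoreceptor occupancy, which amplifies the burst.
#'
#' @param p a [da_params()] object.
#' @param dt integration step (s) passed to [phasic_transient()].
#' @return dimensionless ratio.
#' @examples
#' da_ratio(da_params("control"))
#' @export
da_ratio <- function(p, dt = 1e-3) {
  tr <- phasic_transient(p, rpe = 1, dt = dt)
  if (tr$C_tonic <= 0) stop("C_tonic is zero; ratio undefined")
  (tr$C_peak - tr$C_tonic) / tr$C_tonic
}

#' Dopamine decay time under a firing pause
#'
#' Integrates the concentration equation with all release switched off
#' (the punishment/pause condition) from the tonic steady state, and
#' returns the first time the concentration falls below
#' `threshold_frac * C_tonic`.  With control parameters this takes roughly
#' 500 ms, which motivates applying the punishment clamp instantaneously in
#' the trial simulations.  In the small-concentration limit the decay is
#' exponential with rate `Vmax/km + krem`.
#'
#' @param p a [da_params()] object.
#' @param threshold_frac fraction of the initial concentration in (0, 1).
#' @param dt integration step (s).
#' @return time (s).
#' @examples
#' punishment_decay_time(da_params("control"))  # ~0.5-0.6 s
#' @export
punishment_decay_time <- function(p, threshold_frac = 0.01, dt = 1e-3) {
  stopifnot(inherits(p, "da_params"))
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must lie in (0, 1)")
  C0 <- da_steady_state(p)$C_tonic
  C <- C0; t <- 0
  f <- function(C) -p$Vmax * C / (p$km + C) - p$krem * C
  while (C >= threshold_frac * C0) {
    C <- rk4_scalar(f, C, dt)
    t <- t + dt
    if (t > 60) stop("decay did not reach threshold within 60 s")
  }
  t
}

#' Simulate a dopamine trajectory with arbitrary events
#'
#' Convenience wrapper integrating the terminal model from its steady state
#' under a list of reward/punishment events, returning a tidy trajectory
#' suitable for CSV export.
#'
#' @param p a [da_params()] object.
#' @param events list of [rpe_event()] objects.
#' @param t_end simulated duration (s).
#' @param dt integration step (s).
#' @return data.frame with columns `t`, `C_DA`, `AR`, `D1`, `D2`.
#' @examples
#' ev <- list(rpe_event("reward", 1, onset = 0.2),
#'            rpe_event("punishment", onset = 1))
#' tr <- da_simulate(da_params(), ev, t_end = 2)
#' @export
da_simulate <- function(p, events = list(), t_end = 1, dt = 1e-3) {
  stopifnot(inherits(p, "da_params"))
  ss <- da_steady_state(p)
  n <- ceiling(t_end / dt)
  out <- matrix(NA_real_, n + 1L, 3L)
  st <- list(C_DA = ss$C_tonic, AR = ss$AR, t = 0)
  out[1L, ] <- c(0, st$C_DA, st$AR)
  for (i in seq_len(n)) {
    st <- da_step(st, p, events, dt)
    out[i + 1L, ] <- c(st$t, st$C_DA, st$AR)
  }
  occ <- receptor_occupancy(out[, 2L], p)
  data.frame(t = out[, 1L], C_DA = out[, 2L], AR = out[, 3L],
             D1 = occ$D1, D2 = occ$D2)
}
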