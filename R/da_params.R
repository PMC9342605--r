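#' Dopamine terminal parameters
#'
#' Parameter set for the dopamine terminal model: release, reuptake,
#' removal, autoreceptor binding and postsynaptic D1/D2 receptor binding.
#' Two named presets are provided.  The `"control"` preset uses the maximal
#' DAT reuptake rate `Vmax = 1.2` uM/L/s and is calibrated so that the tonic
#' steady-state dopamine concentration is 0.02 uM/L; the `"imbalance"`
#' preset raises reuptake to `Vmax = 1.8` uM/L/s, which lowers tonic
#' dopamine, lowers autoreceptor occupancy and thereby *increases* phasic
#' release (the phasic/tonic imbalance mechanism).
#'
#' Units: concentrations in uM/L, times in s, `rho` in terminals/L,
#' `n0` in molecules per vesicle fusion, `avogadro` in 1/mol.  Release
#' rates computed from these are expressed in uM/L/s (the molar rate is
#' scaled by 1e6).
#'
#' @param group `"control"` or `"imbalance"`; selects the preset `Vmax`.
#' @param ... named overrides for any parameter field.
#'
#' @return An object of class `"da_params"`: a named list with fields
#'   `Vmax`, `km`, `krem` (removal rate, 1/s), `kon`, `koff` (autoreceptor
#'   on/off rates), `rho`, `alpha_vf` (extracellular volume fraction),
#'   `n0`, `avogadro`, `Pr_tonic`, `Pr_phasic` (vesicle release
#'   probabilities), `nu_tonic`, `nu_phasic` (firing rates, 1/s),
#'   `Bmax_D1`, `kD_D1`, `Bmax_D2`, `kD_D2` (receptor densities and
#'   dissociation constants, uM/L), and `AR_norm` (the autoregulation
#'   normalisation constant, 0.334 = control autoreceptor occupancy).
#'
#' @examples
#' p <- da_params("control")
#' da_steady_state(p)$C_tonic  # ~0.02 uM/L
#' @export
da_params <- function(group = c("control", "imbalance"), ...) {
  group <- match.arg(group)
  p <- list(
    Vmax      = if (group == "control") 1.2 else 1.8,
    km        = 0.15,
    krem      = 0.04,
    kon       = 10,
    koff      = 0.4,
    rho       = 0.025e15,
    alpha_vf  = 0.21,
    n0        = 3000,
    avogadro  = 6.02214076e23,
    Pr_tonic  = 0.06,
    Pr_phasic = 0.06,
    nu_tonic  = 4,
    nu_phasic = 40,
    Bmax_D1   = 1.6,
    kD_D1     = 1,
    Bmax_D2   = 0.08,
    kD_D2     = 0.01,
    AR_norm   = 0.334
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad))
      stop("unknown da_params field(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  p$group <- group
  class(p) <- "da_params"
  validate_da_params(p)
  p
}

validate_da_params <- function(p) {
  num <- setdiff(names(unclass(p)), "group")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("da_params field '", f, "' must be a finite numeric scalar")
    if (v < 0) stop("da_params field '", f, "' must be >= 0")
  }
  if (p$km <= 0) stop("km must be > 0")
  if (p$koff <= 0) stop("koff must be > 0")
  if (p$alpha_vf <= 0 || p$alpha_vf >= 1)
    stop("alpha_vf must lie in (0, 1)")
  if (p$AR_norm <= 0 || p$AR_norm >= 1)
    stop("AR_norm must lie in (0, 1)")
  invisible(p)
}

#' @export
print.da_params <- function(x, ...) {
  cat("<da_params> preset:", x$group, "\n")
  flds <- setdiff(names(unclass(x)), "group")
  cat(paste0("  ", flds, " = ", vapply(flds, function(f) format(x[[f]]), "")),
      sep = "\n")
  invisible(x)
}

#' Reward / punishment prediction-error event
#'
#' Describes one phasic dopamine event.  A reward event adds a burst of
#' phasic release proportional to `|RPE|` inside the window
#' `[onset + latency, onset + latency + duration]`; a punishment event
#' clamps the dopamine concentration to zero over the same window
#' (the firing pause is applied as an instantaneous clamp).
#'
#' @param kind `"reward"` or `"punishment"`.
#' @param magnitude absolute reward-prediction-error value (dimensionless);
#'   ignored for punishments.
#' @param onset event time (s), e.g. the response time of the trial.
#' @param latency delay from onset to the start of the dopamine window (s).
#' @param duration length of the dopamine window (s).
#' @return An object of class `"rpe_event"`.
#' @examples
#' rpe_event("reward", magnitude = 1, onset = 0)
#' @export
rpe_event <- function(kind = c("reward", "punishment"), magnitude = 1,
                      onset = 0, latency = 0.1, duration = 0.05) {
  kind <- match.arg(kind)
  if (kind == "reward" && magnitude < 0)
    stop("reward magnitude must be >= 0")
  if (latency <= 0 || duration <= 0)
    stop("latency and duration must be > 0")
  structure(list(kind = kind, magnitude = magnitude, onset = onset,
                 latency = latency, duration = duration),
            class = "rpe_event")
}

# TRUE if time t falls inside the event's dopamine window
in_event_window <- function(ev, t) {
  t >= ev$onset + ev$latency && t < ev$onset + ev$latency + ev$duration
}
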