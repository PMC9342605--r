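#' Basal-ganglia network parameters
#'
#' Parameters of the four-action-channel cortico-basal-ganglia-thalamic
#' network.  Every unit is a first-order leaky integrator with a sigmoidal
#' output normalised to \[0, 1\].  The wiring follows the classical
#' direct / indirect / hyperdirect scheme: striatal Go units inhibit the
#' internal pallidum (GPi) channel-wise (direct, movement-promoting);
#' NoGo units inhibit the external pallidum (GPe), which in turn inhibits
#' GPi and the subthalamic nucleus (indirect, movement-suppressing);
#' cortex excites the STN, which diffusely excites GPi across all channels
#' (hyperdirect, global "hold").  GPi tonically inhibits the thalamus;
#' thalamic disinhibition ignites the corresponding cortical channel, and
#' cortical self-excitation plus cross-channel lateral inhibition implement
#' winner-takes-all selection.  D1 receptor occupancy multiplies the Go
#' pathway gain up, D2 occupancy multiplies the NoGo gain down, and a
#' constant cholinergic factor `chi` potentiates both striatal pathways.
#'
#' Defaults are calibrated so that (i) a naive network (all plastic weights
#' at 0.5) responds within an 800 ms trial with an essentially
#' noise-driven choice among the four channels, and (ii) a trained control
#' subject responds in roughly 150 ms with winner-takes-all exclusivity
#' (selected channel above 0.9, others near zero).
#'
#' @param ... named overrides of any default.
#' @return object of class `"network_params"` (named list).
#' @examples
#' np <- network_params(noise_amp = 0.1)
#' @export
network_params <- function(...) {
  p <- list(
    # time constants (s); common value calibrated so a trained control
    # subject responds in ~150 ms
    tau_cortex = 0.033, tau_go = 0.033, tau_nogo = 0.033,
    tau_gpe = 0.033, tau_gpi = 0.033, tau_thal = 0.033, tau_stn = 0.033,
    # sigmoid slopes and centers per region; the steep cortical sigmoid
    # sharpens the winner-takes-all commitment, the shallow pallidal /
    # thalamic sigmoids keep selection graded
    slope_cortex = 12, center_cortex = 0.8,
    slope_striatum = 5, center_go = 0.80, center_nogo = 0.64,
    slope_gpe = 4, center_gpe = 0.4,
    slope_gpi = 4, center_gpi = 0.5,
    slope_thal = 4, center_thal = 0.3,
    slope_stn = 4, center_stn = 0.3,
    # cortex: self-excitation, lateral inhibition, thalamo-cortical loop
    w_cortex_self = 1.0, w_cortex_lateral = 1.2,
    w_thal_cortex = 1.2, w_cortex_thal = 0.4,
    w_gpi_thal = 1.0, drive_thal = 0.8,
    # indirect pathway
    w_nogo_gpe = 1.0, drive_gpe = 0.9,
    # GPi afferents
    w_go_gpi = 1.2, w_gpe_gpi = 0.8, w_stn_gpi = 0.4, drive_gpi = 1.28,
    # hyperdirect
    w_cortex_stn = 0.25, w_gpe_stn = 0.3, drive_stn = 0.5,
    # striatal NoGo -> Go collateral inhibition (carries the
    # punishment-window depression of the Go pathway)
    w_nogo_go = 1.015,
    # structural gains on the stimulus-> and cortex->striatum projections
    w_stim_striatum = 1.3, w_cortex_striatum = 0.45,
    # dopamine and cholinergic gains
    gain_d1 = 6, gain_d2 = 9, chi = 1,
    # cortical input noise: uniform on [0, noise_amp], redrawn per step
    noise_amp = 0.2
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad))
      stop("unknown network_params field(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_network_params(p)
  class(p) <- "network_params"
  p
}

validate_network_params <- function(p) {
  taus <- grep("^tau_", names(p), value = TRUE)
  for (f in taus) if (p[[f]] <= 0) stop(f, " must be > 0")
  slopes <- grep("^slope_", names(p), value = TRUE)
  for (f in slopes) if (p[[f]] <= 0) stop(f, " must be > 0")
  if (p$w_cortex_lateral <= 0)
    stop("w_cortex_lateral must be > 0 (it enters with a negative sign)")
  if (p$w_cortex_self < 0) stop("w_cortex_self must be >= 0")
  if (p$noise_amp < 0) stop("noise_amp must be >= 0")
  invisible(p)
}

#' Run one trial of the action-selection network
#'
#' Integrates the network (Euler, fixed step `dt`) from its settled resting
#' state under stimulus `S`, with uniform cortical noise redrawn per step
#' from the current R random stream, until one cortical channel crosses
#' `threshold` or `duration` elapses.  D1/D2 receptor occupancies are held
#' at their tonic values during the decision period (dopamine transients
#' only occur later, in the post-response learning window; see
#' [apply_learning_event()]).
#'
#' The chosen channel is the first to cross the threshold; if two channels
#' cross within the same step, the one with the larger activity wins and
#' exact ties go to the lowest channel index.  "No response" (`chosen = 0`)
#' is a valid outcome.
#'
#' @param S numeric stimulus vector of length 4.
#' @param W a [naive_weights()]-shaped list of plastic weights.
#' @param net [network_params()].
#' @param da [da_params()]; sets the tonic D1/D2 occupancies.
#' @param duration trial length after stimulus onset (s).
#' @param threshold response threshold on cortical activity, in (0, 1).
#' @param dt integration step (s).
#' @param noise logical; draw cortical noise (disable for deterministic
#'   symmetry checks).
#' @param trace logical; also return the cortical activity trace.
#' @return list with `chosen` (1-4, or 0 for none), `rt` (s, `NA` if no
#'   response), `responded`, `y_cortex` (activities at stopping time),
#'   `max_cortex` (per-channel maximum over the trial), `state` (internal
#'   state for window continuation) and, if requested, `trace` (steps x 25
#'   matrix: activities of the 4 channels of cortex, Go, NoGo, GPe, GPi
#'   and thalamus, then the STN unit).
#' @examples
#' W <- naive_weights()
#' set.seed(1)
#' run_trial(c(1, 0.2, 0.1, 0.1), W)$chosen
#' @export
run_trial <- function(S, W, net = network_params(), da = da_params(),
                      duration = 0.8, threshold = 0.9, dt = 1e-3,
                      noise = TRUE, trace = FALSE) {
  stopifnot(length(S) == 4, is.numeric(S))
  if (duration <= 0) stop("duration must be > 0")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  check_weights(W)
  ss <- da_steady_state(da)
  occ <- receptor_occupancy(ss$C_tonic, da)
  res <- .run_trial_cpp(as.numeric(S), W$wGS, W$wNS,
                        diag(W$wGC), diag(W$wNC),
                        unclass(net), occ$D1, occ$D2,
                        dt, settle = 0.3, duration = duration,
                        threshold = threshold, noise_on = noise,
                        trace = trace)
  res$responded <- res$chosen > 0
  res$S <- S
  res
}
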