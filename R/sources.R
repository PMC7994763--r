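#' Cortical source specification
#'
#' A source is a noisy phase oscillator at a fixed scalp-projected location.
#' Between pulses its phase follows a Wiener-perturbed rotation at the natural
#' frequency f0; at each effective pulse it receives the circle-map update
#' `phi <- phi + kappa * sin(psi_p - phi)` toward the fixed pulse-target phase
#' `psi_p = 0`. `kappa = 1` is a full deterministic phase reset, `0 < kappa < 1`
#' partial (progressive) entrainment, `kappa = 0` no pulse effect.
#'
#' @param location channel label (resolved against the montage) or a length-3
#'   unit vector on the head sphere.
#' @param natural_freq_hz intrinsic oscillation frequency f0 in Hz.
#' @param amplitude_uv oscillation amplitude at the source, microvolts.
#' @param phase_noise_sd standard deviation of the Wiener phase increments,
#'   rad/sqrt(s); larger values mean faster phase diffusion (shorter intrinsic
#'   coherence time, roughly 1/phase_noise_sd^2 seconds).
#' @param coupling_kappa pulse phase-coupling strength in `[0, 1]`.
#' @param propagation list of `list(target =, gain =, lag_s =)` entries: the
#'   pulse update is forwarded to the target source (index into the source
#'   list) scaled by `gain` after `lag_s` seconds, but only if the two natural
#'   frequencies differ by at most 3 Hz (frequency-specific networks).
#' @return an object of class `source_spec`.
#' @export
source_spec <- function(location, natural_freq_hz, amplitude_uv = 20,
                        phase_noise_sd = 1.5, coupling_kappa = 0.4,
                        propagation = list()) {
  stopifnot(natural_freq_hz > 0, coupling_kappa >= 0, coupling_kappa <= 1,
            amplitude_uv >= 0, phase_noise_sd >= 0)
  for (pr in propagation) {
    stopifnot(pr$gain >= 0, pr$gain <= 1, pr$lag_s >= 0)
  }
  structure(list(location = location, natural_freq_hz = natural_freq_hz,
                 amplitude_uv = amplitude_uv, phase_noise_sd = phase_noise_sd,
                 coupling_kappa = coupling_kappa, propagation = propagation),
            class = "source_spec")
}

#' Default source configurations for the two stimulation sites
#'
#' The visual source sits at Oz with a natural frequency of 10.5 Hz (alpha),
#' the motor source at C3 at 21 Hz (low beta). Each local source propagates
#' pulse updates to one frequency-matched remote source, giving the simulated
#' data a frequency-specific long-range network with known ground truth.
#'
#' @param site `"motor"`, `"visual"` or `"sham"`; sham uses the visual layout
#'   (the coil is off-scalp, so no source is ever stimulated).
#' @return list of [source_spec()] objects.
#' @export
default_sources <- function(site = c("visual", "motor", "sham")) {
  site <- match.arg(site)
  if (site == "motor") {
    list(
      source_spec("C3", 21, amplitude_uv = 15,
                  propagation = list(list(target = 2L, gain = 0.5, lag_s = 0.01))),
      source_spec("C4", 21, amplitude_uv = 12),
      source_spec("Oz", 10.5, amplitude_uv = 18)
    )
  } else {
    list(
      source_spec("Oz", 10.5, amplitude_uv = 20,
                  propagation = list(list(target = 2L, gain = 0.5, lag_s = 0.01))),
      source_spec("AFz", 10.5, amplitude_uv = 14),
      source_spec("C3", 21, amplitude_uv = 12)
    )
  }
}

#' Noise, artifact and evoked-component configuration
#'
#' @param pink_sd_uv standard deviation of the 1/f background noise per
#'   channel, microvolts.
#' @param artifact_scale pulse decay-artifact amplitude as a multiple of the
#'   largest source amplitude (10x by default).
#' @param artifact_tau_ms decay time constant of the pulse artifact (ms); with
#'   2 ms the artifact is confined to the first ~8 ms after each pulse.
#' @param evoked logical: add a pulse-evoked damped sinusoid with fixed
#'   latency and polarity (a deliberate "spurious phase locking" component).
#' @param evoked_amp_uv,evoked_freq_hz,evoked_decay_ms,evoked_latency_ms
#'   evoked kernel amplitude, carrier frequency, decay constant and latency.
#' @param evoked_attenuation per-pulse multiplicative attenuation of the
#'   evoked amplitude over the train (1 = constant, the default).
#' @return a list of class `noise_config`.
#' @export
noise_config <- function(pink_sd_uv = 10, artifact_scale = 10,
                         artifact_tau_ms = 2, evoked = FALSE,
                         evoked_amp_uv = 8, evoked_freq_hz = 10,
                         evoked_decay_ms = 100, evoked_latency_ms = 15,
                         evoked_attenuation = 1) {
  structure(list(pink_sd_uv = pink_sd_uv, artifact_scale = artifact_scale,
                 artifact_tau_ms = artifact_tau_ms, evoked = evoked,
                 evoked_amp_uv = evoked_amp_uv, evoked_freq_hz = evoked_freq_hz,
                 evoked_decay_ms = evoked_decay_ms,
                 evoked_latency_ms = evoked_latency_ms,
                 evoked_attenuation = evoked_attenuation),
            class = "noise_config")
}
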