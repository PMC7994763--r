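#' Simulate a multi-trial rTMS-EEG dataset
#'
#' Generates seeded synthetic TMS-EEG epochs realizing three regimes with
#' known ground truth: no pulse effect (sham site), single-pulse phase reset,
#' and progressive entrainment over a 5-pulse train. Each cortical source is a
#' noisy phase oscillator; at each pulse the directly stimulated source (the
#' one under the coil) receives the circle-map update
#' `phi <- phi + kappa * sin(-phi)`, and propagation entries forward the
#' update (scaled by their gain, after their lag) to frequency-matched remote
#' sources (natural frequencies within 3 Hz). Sensor signals are a smooth
#' Gaussian-leadfield projection of `amplitude * cos(phi)` plus 1/f background
#' noise, an optional pulse-evoked damped sinusoid, and a large exponentially
#' decaying pulse artifact confined to the first ~8 ms after each pulse
#' (real-stimulation sites only).
#'
#' @param protocol a [stim_protocol()]; `site = "sham"` applies no phase
#'   update and no decay artifact (the coil is off the scalp).
#' @param sources list of [source_spec()]; default [default_sources()] for the
#'   protocol's site.
#' @param montage a [make_montage()] montage.
#' @param noise a [noise_config()].
#' @param fs_hz native sampling rate (must exceed 4x the highest natural
#'   frequency; the experimental recordings this emulates used 5000 Hz).
#' @param seed integer seed; identical arguments and seed give identical data.
#' @return a [trialset()].
#' @export
simulate_trialset <- function(protocol, sources = default_sources(protocol$site),
                              montage = make_montage(), noise = noise_config(),
                              fs_hz = 5000, seed = 1) {
  if (length(sources) == 0) stop("empty source list")
  f0 <- vapply(sources, function(s) s$natural_freq_hz, 0)
  if (fs_hz < 4 * max(f0)) {
    stop("fs_hz must be at least 4x the highest natural frequency")
  }
  n_src <- length(sources)
  n_ch <- length(montage$labels)
  dur <- protocol$epoch_pre_s + train_duration(protocol) + protocol$epoch_post_s
  n_t <- round(dur * fs_hz)
  ptimes <- pulse_times(protocol)
  psamp <- round((protocol$epoch_pre_s + ptimes) * fs_hz) + 1L

  src_pos <- t(vapply(sources, function(s) resolve_location(s$location, montage),
                      numeric(3)))
  lead <- leadfield_gaussian(montage$pos, src_pos)        # n_ch x n_src
  stim_idx <- stimulated_sources(protocol$site, src_pos, montage)
  updates <- pulse_update_schedule(sources, stim_idx, psamp, fs_hz, n_t)

  coil <- coil_position(protocol$site, montage)
  coil_w <- exp(-(arc_dist(montage$pos, coil))^2 / (2 * (0.445)^2))
  smooth_k <- spatial_smoother(montage$pos)

  set.seed(seed)
  amp <- vapply(sources, function(s) s$amplitude_uv, 0)
  data <- array(0, dim = c(protocol$n_trials, n_ch, n_t))
  for (tr in seq_len(protocol$n_trials)) {
    phi <- matrix(0, n_t, n_src)
    for (s in seq_len(n_src)) {
      phi[, s] <- sim_phase_path(sources[[s]], n_t, fs_hz)
    }
    # pulse updates, in sample order (lags can interleave pulses)
    for (u in updates) {
      ph <- phi[u$sample, u$source]
      delta <- u$strength * wrap_pi(-ph)
      phi[u$sample:n_t, u$source] <- phi[u$sample:n_t, u$source] + delta
    }
    x <- lead %*% (t(cos(phi)) * amp)                     # n_ch x n_t
    x <- x + t(pink_noise(n_t, n_ch, noise$pink_sd_uv) %*% smooth_k)
    if (noise$evoked) {
      x <- x + outer(coil_w, evoked_waveform(n_t, fs_hz, psamp, noise))
    }
    if (protocol$site != "sham" && noise$artifact_scale > 0) {
      x <- x + outer(coil_w, artifact_waveform(n_t, fs_hz, psamp, noise,
                                               noise$artifact_scale * max(amp)))
    }
    data[tr, , ] <- x
  }
  dimnames(data) <- list(NULL, montage$labels, NULL)
  trialset(data, fs_hz, montage, rep(list(psamp), protocol$n_trials), protocol,
           condition = condition_label(protocol))
}

condition_label <- function(protocol) {
  if (protocol$n_pulses == 1) sprintf("sp-%s", protocol$site)
  else sprintf("rtms%g-%s", protocol$train_freq_hz, protocol$site)
}

resolve_location <- function(loc, montage) {
  if (is.character(loc)) montage$pos[channel_index(montage, loc), ]
  else { v <- as.numeric(loc); v / sqrt(sum(v^2)) }
}

arc_dist <- function(pos, v) {
  d <- pos %*% v
  d[d > 1] <- 1; d[d < -1] <- -1
  acos(drop(d))
}

# Gaussian falloff on the sphere, FWHM ~ 60 deg of arc
leadfield_gaussian <- function(ch_pos, src_pos, fwhm_rad = 60 * pi / 180) {
  sigma <- fwhm_rad / (2 * sqrt(2 * log(2)))
  w <- matrix(0, nrow(ch_pos), nrow(src_pos))
  for (s in seq_len(nrow(src_pos))) {
    w[, s] <- exp(-arc_dist(ch_pos, src_pos[s, ])^2 / (2 * sigma^2))
  }
  w
}

coil_position <- function(site, montage) {
  v <- switch(site,
    motor = montage$pos[channel_index(montage, "C3"), ],
    visual = colMeans(montage$pos[channel_index(montage, c("Oz", "O2")), ]),
    sham = c(0, 0, 1))
  v / sqrt(sum(v^2))
}

stimulated_sources <- function(site, src_pos, montage, max_arc = 0.5) {
  if (site == "sham") return(integer(0))
  coil <- coil_position(site, montage)
  which(arc_dist(src_pos, coil) < max_arc)
}

# Flatten direct + propagated pulse updates into (source, sample, strength),
# ordered by sample so lagged updates interleave correctly.
pulse_update_schedule <- function(sources, stim_idx, psamp, fs_hz, n_t) {
  ups <- list()
  for (s in stim_idx) {
    kap <- sources[[s]]$coupling_kappa
    for (p in psamp) {
      ups[[length(ups) + 1L]] <- list(source = s, sample = p, strength = kap)
    }
    for (pr in sources[[s]]$propagation) {
      tgt <- pr$target
      if (abs(sources[[tgt]]$natural_freq_hz - sources[[s]]$natural_freq_hz) > 3) next
      lag <- round(pr$lag_s * fs_hz)
      for (p in psamp) {
        sm <- p + lag
        if (sm <= n_t) {
          ups[[length(ups) + 1L]] <- list(source = tgt, sample = sm,
                                          strength = kap * pr$gain)
        }
      }
    }
  }
  ups[order(vapply(ups, `[[`, 0, "sample"))]
}

wrap_pi <- function(x) atan2(sin(x), cos(x))

sim_phase_path <- function(src, n_t, fs_hz) {
  dt <- 1 / fs_hz
  inc <- 2 * pi * src$natural_freq_hz * dt
  if (src$phase_noise_sd > 0) {
    inc <- inc + stats::rnorm(n_t, 0, src$phase_noise_sd * sqrt(dt))
  }
  stats::runif(1, -pi, pi) + cumsum(inc)
}

# Background EEG noise is itself volume-conducted, so adjacent channels see
# correlated activity: mix channel noise with a Gaussian kernel on the sphere
# (FWHM ~ 40 deg), unit row norm so the per-channel SD is preserved.
spatial_smoother <- function(pos, fwhm_rad = 40 * pi / 180) {
  sigma <- fwhm_rad / (2 * sqrt(2 * log(2)))
  d <- tcrossprod(pos)
  d[d > 1] <- 1; d[d < -1] <- -1
  K <- exp(-acos(d)^2 / (2 * sigma^2))
  K / sqrt(rowSums(K^2))
}

# 1/f (power) background noise, exact target SD per channel
pink_noise <- function(n_t, n_ch, sd_uv) {
  if (sd_uv <= 0) return(matrix(0, n_t, n_ch))
  w <- matrix(stats::rnorm(n_t * n_ch), n_t, n_ch)
  f <- c(1, seq_len(n_t - 1))
  f <- pmin(f, n_t - f + 1)                     # two-sided frequency index
  g <- 1 / sqrt(f)
  x <- Re(stats::mvfft(stats::mvfft(w) * g, inverse = TRUE)) / n_t
  x <- sweep(x, 2, apply(x, 2, stats::sd), "/") * sd_uv
  x
}

evoked_waveform <- function(n_t, fs_hz, psamp, noise) {
  tau <- seq_len(n_t)
  out <- numeric(n_t)
  lat <- round(noise$evoked_latency_ms / 1000 * fs_hz)
  dec <- noise$evoked_decay_ms / 1000
  amp <- noise$evoked_amp_uv
  for (k in seq_along(psamp)) {
    t0 <- psamp[k] + lat
    if (t0 > n_t) next
    tt <- (seq.int(t0, n_t) - t0) / fs_hz
    out[t0:n_t] <- out[t0:n_t] +
      amp * noise$evoked_attenuation^(k - 1) * exp(-tt / dec) *
      sin(2 * pi * noise$evoked_freq_hz * tt)
  }
  out
}

# the onset sample itself is the trigger time and stays clean; the decaying
# artifact occupies the samples after it (the downstream interpolation window)
artifact_waveform <- function(n_t, fs_hz, psamp, noise, amp_uv) {
  out <- numeric(n_t)
  tau <- noise$artifact_tau_ms / 1000
  for (p in psamp) {
    if (p + 1 > n_t) next
    tt <- (seq.int(p + 1, n_t) - p - 1) / fs_hz
    out[(p + 1):n_t] <- out[(p + 1):n_t] + amp_uv * exp(-tt / tau)
  }
  out
}

#' Entrainment map over coupling strength and detuning (Arnold tongue)
#'
#' Runs the pulse-train phase recursion (no sensor layer) over a grid of
#' coupling strengths kappa and detunings (stimulation frequency minus natural
#' frequency) and returns the across-trial phase-locking factor immediately
#' after the last pulse, averaged over repetitions. With increasing kappa the
#' range of detunings that entrain widens — the synchronization region.
#'
#' @param kappa_grid coupling strengths in `[0, 1]`.
#' @param detuning_grid detunings in Hz (`f_stim = f0 + detuning`).
#' @param base a [source_spec()] supplying f0 and phase noise.
#' @param protocol a [stim_protocol()] supplying pulse count and trial count.
#' @param n_rep repetitions averaged per grid cell (>= 10).
#' @param seed integer seed.
#' @return data.frame with columns `kappa`, `detuning_hz`, `plf`.
#' @export
arnold_map <- function(kappa_grid, detuning_grid, base = source_spec("Oz", 10.5),
                       protocol = stim_protocol("visual"), n_rep = 20, seed = 1) {
  if (length(kappa_grid) == 0 || length(detuning_grid) == 0) {
    stop("empty grids")
  }
  stopifnot(n_rep >= 10)
  set.seed(seed)
  out <- expand.grid(kappa = kappa_grid, detuning_hz = detuning_grid)
  out$plf <- NA_real_
  for (i in seq_len(nrow(out))) {
    f_stim <- base$natural_freq_hz + out$detuning_hz[i]
    if (f_stim <= 0) stop("detuning pushes stimulation frequency below 0")
    plfs <- vapply(seq_len(n_rep), function(r) {
      ph <- train_end_phases(out$kappa[i], base$natural_freq_hz, f_stim,
                             base$phase_noise_sd, protocol$n_pulses,
                             protocol$n_trials)
      abs(mean(exp(1i * ph)))
    }, 0)
    out$plf[i] <- mean(plfs)
  }
  attr(out, "seed") <- seed
  out
}

# phases of all trials right after the last pulse, pulse-to-pulse recursion
train_end_phases <- function(kappa, f0, f_stim, noise_sd, n_pulses, n_trials) {
  dt <- 1 / f_stim
  phi <- stats::runif(n_trials, -pi, pi)
  phi <- phi + kappa * wrap_pi(-phi)
  if (n_pulses > 1) {
    for (k in seq_len(n_pulses - 1)) {
      phi <- phi + 2 * pi * f0 * dt + stats::rnorm(n_trials, 0, noise_sd * sqrt(dt))
      phi <- phi + kappa * wrap_pi(-phi)
    }
  }
  phi
}
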