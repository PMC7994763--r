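#' Inter-trial phase-locking factor
#'
#' PLF at a (channel, frequency, time) point is the modulus of the
#' across-trial mean unit phasor of the instantaneous phase: 0 for uniform
#' phases, 1 for identical phases. Samples flagged invalid in the TFR edge
#' mask propagate as NA, never as zero.
#'
#' @param tfr a [morlet_transform()] result with at least 2 trials.
#' @return an object of class `plf_map`: numeric array channel x frequency x
#'   time in `[0, 1]` with attributes `n_trials`, `freqs_hz`, `times`,
#'   `channels`, `protocol`.
#' @export
plf <- function(tfr) {
  stopifnot(inherits(tfr, "tfr_stack"))
  if (tfr$n_trials < 2) stop("need at least 2 trials")
  d <- dim(tfr$coeffs)
  ph <- tfr$coeffs / Mod(tfr$coeffs)           # unit phasors
  dim(ph) <- c(d[1], prod(d[2:4]))
  v <- Mod(colMeans(ph))                       # across-trial mean phasor
  dim(v) <- d[2:4]
  v[v > 1] <- 1
  mask <- !tfr$valid                           # freq x time
  for (ch in seq_len(dim(v)[1])) v[ch, , ][mask] <- NA_real_
  structure(v, class = "plf_map", n_trials = tfr$n_trials,
            freqs_hz = tfr$freqs_hz, times = tfr$times,
            channels = tfr$channels, protocol = tfr$protocol)
}

#' Rayleigh-Z bias-corrected phase locking (ZPLF)
#'
#' `ZPLF = N * PLF^2`. Under uniform (unlocked) phase its expectation is ~1
#' for every trial count N, so conditions that kept different numbers of
#' trials after artifact rejection remain comparable.
#'
#' @param plf_map a [plf()] result.
#' @return a `zplf_map`: array channel x frequency x time, >= 0, same
#'   attributes as the input.
#' @export
zplf <- function(plf_map) {
  stopifnot(inherits(plf_map, "plf_map"))
  v <- unclass(plf_map)^2 * attr(plf_map, "n_trials")
  a <- attributes(plf_map)
  a$class <- "zplf_map"
  attributes(v) <- a
  v
}

#' Standardize ZPLF across the frequency axis
#'
#' Per (channel, time) slice, subtracts the mean and divides by the SD taken
#' over frequencies — the ZPLF_norm used for per-pulse frequency profiles.
#' Slices with zero SD are masked with a warning.
#'
#' @param zplf_map a [zplf()] result with >= 3 frequencies.
#' @return a `zplf_map` standardized over frequencies.
#' @export
zplf_norm_freq <- function(zplf_map) {
  stopifnot(inherits(zplf_map, "zplf_map"), dim(zplf_map)[2] >= 3)
  v <- unclass(zplf_map)
  mu <- apply(v, c(1, 3), mean)
  sd <- apply(v, c(1, 3), stats::sd)
  if (any(sd == 0, na.rm = TRUE)) {
    warning("zero-SD slice(s) masked in frequency standardization")
    sd[sd == 0] <- NA_real_
  }
  out <- sweep(sweep(v, c(1, 3), mu, "-"), c(1, 3), sd, "/")
  attributes(out) <- attributes(zplf_map)
  attr(out, "standardized") <- "frequency"
  out
}

#' Standardize ZPLF across the time axis
#'
#' Per (channel, frequency) slice, subtracts the mean and divides by the SD
#' over all (valid) time points of the epoch — the normalization used for the
#' individual-alpha-frequency analyses.
#'
#' @param zplf_map a [zplf()] result with >= 3 time points.
#' @return a `zplf_map` standardized over time.
#' @export
zplf_norm_time <- function(zplf_map) {
  stopifnot(inherits(zplf_map, "zplf_map"), dim(zplf_map)[3] >= 3)
  v <- unclass(zplf_map)
  mu <- apply(v, c(1, 2), mean, na.rm = TRUE)
  sd <- apply(v, c(1, 2), stats::sd, na.rm = TRUE)
  if (any(sd == 0, na.rm = TRUE)) {
    warning("zero-SD slice(s) masked in time standardization")
    sd[sd == 0] <- NA_real_
  }
  out <- sweep(sweep(v, c(1, 2), mu, "-"), c(1, 2), sd, "/")
  attributes(out) <- attributes(zplf_map)
  attr(out, "standardized") <- "time"
  out
}

#' Per-pulse frequency profile of normalized phase locking
#'
#' For each pulse k (at time t_k) and each analysis frequency f, averages the
#' frequency-standardized ZPLF over `t_k +/- 0.5/f` (half a cycle of that
#' frequency on each side). The baseline `ctrl` is the mean over the window
#' from 5 to 2 stimulation-frequency cycles before the first pulse; the
#' window is defined in stimulation-frequency cycles for every profiled
#' frequency.
#'
#' @param zplf_norm a [zplf_norm_freq()] result.
#' @param protocol the [stim_protocol()] of the data.
#' @param channel channel label to profile (the stimulated electrode).
#' @return an object of class `pulse_profile`: list with `profile` (pulse x
#'   frequency matrix), `ctrl` (baseline per frequency), `freqs_hz`,
#'   `stim_freq_hz`.
#' @export
pulse_profile <- function(zplf_norm, protocol, channel) {
  stopifnot(inherits(zplf_norm, "zplf_map"))
  times <- attr(zplf_norm, "times")
  freqs <- attr(zplf_norm, "freqs_hz")
  chi <- match(channel, attr(zplf_norm, "channels"))
  if (is.na(chi)) stop("channel not present in map: ", channel)
  f_stim <- if (protocol$n_pulses > 1) protocol$train_freq_hz else NA_real_
  pt <- pulse_times(protocol)
  v <- unclass(zplf_norm)[chi, , , drop = TRUE]      # freq x time
  prof <- matrix(NA_real_, protocol$n_pulses, length(freqs))
  for (k in seq_len(protocol$n_pulses)) {
    for (fi in seq_along(freqs)) {
      w <- which(times >= pt[k] - 0.5 / freqs[fi] &
                 times <= pt[k] + 0.5 / freqs[fi])
      if (length(w) == 0 || anyNA(v[fi, w])) {
        stop(sprintf("pulse %d window at %g Hz exceeds the valid region",
                     k, freqs[fi]))
      }
      prof[k, fi] <- mean(v[fi, w])
    }
  }
  fb <- if (is.na(f_stim)) 10 else f_stim            # sp-TMS: alpha-cycle baseline
  bw <- which(times >= -5 / fb & times <= -2 / fb)
  if (length(bw) == 0) stop("baseline window outside the epoch")
  ctrl <- apply(v[, bw, drop = FALSE], 1, mean)
  structure(list(profile = prof, ctrl = ctrl, freqs_hz = freqs,
                 stim_freq_hz = f_stim, channel = channel),
            class = "pulse_profile")
}

#' @export
print.pulse_profile <- function(x, ...) {
  cat(sprintf("<pulse_profile> channel %s, %d pulse(s), %d frequencies\n",
              x$channel, nrow(x$profile), length(x$freqs_hz)))
  if (!is.na(x$stim_freq_hz)) {
    fi <- which.min(abs(x$freqs_hz - x$stim_freq_hz))
    cat(sprintf("  at %g Hz: ctrl %.2f, pulses %s\n", x$freqs_hz[fi],
                x$ctrl[fi], paste(sprintf("%.2f", x$profile[, fi]), collapse = " ")))
  }
  invisible(x)
}

#' Post-train persistence of phase locking, in stimulation cycles
#'
#' Length of the longest criterion-satisfying run starting at the last pulse,
#' expressed in units of the stimulation period. The criterion is either a
#' logical significance mask over time or `zplf_map > threshold` at the given
#' channel and frequency.
#'
#' @param x a `zplf_map`, or a logical vector over the map's time axis (e.g.
#'   a cluster-significance mask), in which case `times` must be supplied.
#' @param protocol the [stim_protocol()].
#' @param channel,freq channel label and frequency (Hz) selecting the slice
#'   when `x` is a map.
#' @param threshold ZPLF criterion when `x` is a map.
#' @param times time axis for a logical-vector `x`.
#' @return persistence in stimulation-frequency cycles (0 when the criterion
#'   fails at the last pulse).
#' @export
persistence_cycles <- function(x, protocol, channel = NULL, freq = NULL,
                               threshold = 1, times = NULL) {
  f_stim <- protocol$train_freq_hz
  t_last <- train_duration(protocol)
  if (is.logical(x)) {
    mask <- x
    stopifnot(!is.null(times), length(times) == length(mask))
  } else {
    stopifnot(inherits(x, "zplf_map"))
    times <- attr(x, "times")
    chi <- match(channel, attr(x, "channels"))
    fi <- which.min(abs(attr(x, "freqs_hz") - freq))
    mask <- unclass(x)[chi, fi, ] > threshold
  }
  post <- which(times >= t_last)
  if (length(post) == 0) return(0)
  m <- mask[post]
  m[is.na(m)] <- FALSE
  n_run <- if (!m[1]) 0L else (which(!c(m, FALSE))[1] - 1L)
  dt <- stats::median(diff(times))
  n_run * dt * f_stim
}

#' Individual alpha frequency from pre-stimulus spectra
#'
#' Estimates the participant's alpha peak (8-13 Hz) from the trial-averaged
#' amplitude spectrum of the pre-stimulus interval. The peak is accepted only
#' if its amplitude exceeds the log-linear 1/f trend (fit on the flanking 3-30
#' Hz range, alpha band excluded) by at least `prominence`; otherwise
#' `NA` ("no peak") is returned. Ties resolve toward the lower frequency.
#'
#' @param trials a [trialset()] with >= 2 s of data before the first pulse.
#' @param channels channel labels averaged for the spectrum (e.g. occipital
#'   electrodes).
#' @param band alpha search band in Hz.
#' @param prominence required fractional elevation above the 1/f trend (0.2 =
#'   20 percent).
#' @return list with `iaf_hz` (NA if no prominent peak), `freqs_hz`,
#'   `amplitude`, `trend`.
#' @export
estimate_iaf <- function(trials, channels = c("Oz", "O1", "O2"),
                         band = c(8, 13), prominence = 0.2) {
  ci <- channel_index(trials$montage, channels)
  p1 <- min(trials$pulse_samples[[1]])
  n_pre <- p1 - 1L
  if (n_pre < 2 * trials$fs_hz) stop("need >= 2 s of pre-stimulus data")
  n_trial <- dim(trials$data)[1]
  amp <- NULL
  for (tr in seq_len(n_trial)) {
    X <- matrix(trials$data[tr, ci, seq_len(n_pre)], ncol = length(ci),
                byrow = TRUE)
    a <- rowMeans(Mod(stats::mvfft(X)))                # amplitude spectrum
    amp <- if (is.null(amp)) a else amp + a
  }
  amp <- amp / n_trial
  amp <- stats::filter(amp, rep(1 / 5, 5), sides = 2)   # smooth bin noise
  amp <- as.numeric(amp)
  freqs <- (seq_len(n_pre) - 1) * trials$fs_hz / n_pre
  sel <- freqs >= 3 & freqs <= 30
  fit_sel <- sel & !(freqs >= band[1] - 1 & freqs <= band[2] + 1)
  fit <- stats::lm(log(amp[fit_sel]) ~ log(freqs[fit_sel]))
  trend <- exp(cbind(1, log(freqs[sel])) %*% stats::coef(fit))
  in_band <- which(freqs[sel] >= band[1] & freqs[sel] <= band[2])
  rel <- amp[sel][in_band] / trend[in_band]
  pk <- in_band[which.max(rel)]
  iaf <- if (max(rel) > 1 + prominence) freqs[sel][pk] else NA_real_
  list(iaf_hz = iaf, freqs_hz = freqs[sel], amplitude = amp[sel],
       trend = drop(trend))
}
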