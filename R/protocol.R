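#' Stimulation protocol
#'
#' Describes one TMS block: stimulation site, number of pulses, train
#' frequency, trial count, inter-train interval and epoch padding. The default
#' epoch runs from 2 s before the first pulse to 3 s after the last pulse.
#'
#' @param site one of `"motor"`, `"visual"`, `"sham"`.
#' @param n_pulses pulses per train (1 = single-pulse TMS, 5 = rTMS train).
#' @param train_freq_hz train frequency in Hz (ignored when `n_pulses == 1`).
#' @param n_trials trains (= trials) per block.
#' @param iti_s inter-train interval mean and jitter, seconds (bookkeeping
#'   only; epochs are simulated independently).
#' @param epoch_pre_s seconds of epoch before the first pulse.
#' @param epoch_post_s seconds of epoch after the last pulse.
#' @return an object of class `stim_protocol`.
#' @examples
#' pulse_times(stim_protocol("motor", n_pulses = 5, train_freq_hz = 5))
#' @export
stim_protocol <- function(site = c("motor", "visual", "sham"),
                          n_pulses = 5, train_freq_hz = 11, n_trials = 30,
                          iti_s = c(10, 1.5), epoch_pre_s = 2, epoch_post_s = 3) {
  site <- match.arg(site)
  stopifnot(n_pulses >= 1, n_trials >= 1, epoch_pre_s > 0, epoch_post_s > 0)
  if (n_pulses > 1 && (!is.finite(train_freq_hz) || train_freq_hz <= 0)) {
    stop("train_freq_hz must be > 0 for multi-pulse trains")
  }
  structure(list(site = site, n_pulses = as.integer(n_pulses),
                 train_freq_hz = train_freq_hz, n_trials = as.integer(n_trials),
                 iti_s = iti_s, epoch_pre_s = epoch_pre_s,
                 epoch_post_s = epoch_post_s),
            class = "stim_protocol")
}

#' Pulse onset times of a train
#'
#' @param protocol a [stim_protocol()].
#' @return pulse onset times in seconds relative to the first pulse:
#'   `0, 1/f, ..., (n_pulses - 1)/f`. The last element is the train duration
#'   (800 ms for 5 pulses at 5 Hz, ~364 ms at 11 Hz, ~174 ms at 23 Hz).
#' @export
pulse_times <- function(protocol) {
  if (protocol$n_pulses == 1) return(0)
  (seq_len(protocol$n_pulses) - 1) / protocol$train_freq_hz
}

train_duration <- function(protocol) {
  (protocol$n_pulses - 1) / ifelse(protocol$n_pulses > 1, protocol$train_freq_hz, 1)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> %s site, %d pulse(s)%s, %d trials, epoch -%g..+%g s\n",
              x$site, x$n_pulses,
              if (x$n_pulses > 1) sprintf(" at %g Hz", x$train_freq_hz) else "",
              x$n_trials, x$epoch_pre_s,
              train_duration(x) + x$epoch_post_s))
  invisible(x)
}
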