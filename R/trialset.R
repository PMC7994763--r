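#' Multi-trial EEG epoch container
#'
#' @param data numeric array trial x channel x time, microvolts.
#' @param fs_hz sampling rate.
#' @param montage a [make_montage()] object whose channel count matches
#'   `dim(data)[2]`.
#' @param pulse_samples list (one element per trial) of integer pulse onset
#'   sample indices (1-based).
#' @param protocol the [stim_protocol()] that produced the epochs.
#' @param condition,participant_id free-form labels.
#' @return an object of class `trialset`.
#' @export
trialset <- function(data, fs_hz, montage, pulse_samples, protocol,
                     condition = "", participant_id = "") {
  stopifnot(length(dim(data)) == 3,
            dim(data)[2] == length(montage$labels),
            length(pulse_samples) == dim(data)[1])
  n_t <- dim(data)[3]
  for (ps in pulse_samples) {
    if (length(ps) != protocol$n_pulses) {
      stop("pulse count per trial must equal protocol$n_pulses")
    }
    if (any(ps < 1 | ps > n_t)) stop("pulse sample index outside the epoch")
  }
  structure(list(data = data, fs_hz = fs_hz, montage = montage,
                 pulse_samples = pulse_samples, protocol = protocol,
                 condition = condition, participant_id = participant_id),
            class = "trialset")
}

#' @export
print.trialset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trialset> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs_hz))
  cat(sprintf("  site %s, %d pulse(s), condition '%s'\n",
              x$protocol$site, x$protocol$n_pulses, x$condition))
  invisible(x)
}

#' Epoch time axis
#'
#' @param trials a [trialset()].
#' @return time in seconds per sample, 0 at the first pulse of the train.
#' @export
trial_times <- function(trials) {
  p1 <- trials$pulse_samples[[1]][1]
  (seq_len(dim(trials$data)[3]) - p1) / trials$fs_hz
}

#' Read/write a trialset container
#'
#' Round-trip persistence of a trialset (arrays plus attributes) via R
#' serialization. Binary runtime artifact; not a data-exchange format.
#'
#' @param trials a [trialset()].
#' @param path file path.
#' @return `read_trialset` returns the trialset; `write_trialset` the path,
#'   invisibly.
#' @export
write_trialset <- function(trials, path) {
  stopifnot(inherits(trials, "trialset"))
  saveRDS(trials, path)
  invisible(path)
}

#' @rdname write_trialset
#' @export
read_trialset <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "trialset")) stop("file does not contain a trialset")
  x
}
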