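# Shared fixture builders. Everything is generated in code at test time.

# minimal montage-like object with arbitrary channel count (chain adjacency);
# positions are spread along an arc so CSD/leadfield style code stays usable
toy_montage <- function(n_ch, labels = paste0("ch", seq_len(n_ch)),
                        scalp = rep(TRUE, n_ch)) {
  th <- seq(-1.2, 1.2, length.out = n_ch)
  pos <- cbind(sin(th), 0, cos(th))
  adj <- matrix(FALSE, n_ch, n_ch, dimnames = list(labels, labels))
  if (n_ch > 1) {
    idx <- cbind(seq_len(n_ch - 1), seq_len(n_ch - 1) + 1)
    adj[idx] <- TRUE
    adj[idx[, 2:1, drop = FALSE]] <- TRUE
  }
  structure(list(labels = labels, pos = pos, scalp = scalp, adjacency = adj,
                 head_radius_mm = 92), class = "montage")
}

# trialset with externally supplied data and evenly spaced pulses
toy_trialset <- function(data, fs_hz, montage, n_pulses = 1,
                         train_freq_hz = 10, epoch_pre_s = NULL) {
  n_t <- dim(data)[3]
  if (is.null(epoch_pre_s)) epoch_pre_s <- (n_t / fs_hz) / 2
  prot <- stim_protocol("visual", n_pulses = n_pulses,
                        train_freq_hz = train_freq_hz,
                        n_trials = dim(data)[1], epoch_pre_s = epoch_pre_s,
                        epoch_post_s = n_t / fs_hz - epoch_pre_s)
  ps <- round((epoch_pre_s + pulse_times(prot)) * fs_hz) + 1L
  trialset(data, fs_hz, montage, rep(list(ps), dim(data)[1]), prot)
}

# tfr_stack carrying prescribed phases (unit amplitude), for direct PLF tests
toy_tfr <- function(phases) {                 # trial x channel x freq x time
  d <- dim(phases)
  structure(list(coeffs = array(exp(1i * phases), d),
                 valid = matrix(TRUE, d[3], d[4]),
                 times = seq_len(d[4]) / 100, freqs_hz = seq_len(d[3]),
                 fs_hz = 100, channels = paste0("ch", seq_len(d[2])),
                 n_trials = d[1], protocol = NULL),
            class = "tfr_stack")
}

# zplf_map from a plain channel x freq x time array
toy_zplf <- function(v, n_trials = 10, times = NULL, freqs = NULL,
                     channels = NULL) {
  d <- dim(v)
  structure(v, class = "zplf_map", n_trials = n_trials,
            freqs_hz = if (is.null(freqs)) seq_len(d[2]) else freqs,
            times = if (is.null(times)) seq_len(d[3]) / 100 else times,
            channels = if (is.null(channels)) paste0("ch", seq_len(d[1]))
                       else channels,
            protocol = NULL)
}
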