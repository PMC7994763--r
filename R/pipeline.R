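#' Cohort run configuration
#'
#' Bundles every knob of an end-to-end synthetic cohort run: how many
#' participants to simulate, which stimulation conditions (each real condition
#' is paired with a site-matched sham block at the same train frequency),
#' preprocessing, wavelet and statistical settings, and the problem-size
#' reductions (trials per block, native rate, map channels, map time grid).
#'
#' @param n_participants simulated participants (14 in the emulated design).
#' @param conditions list of [stim_protocol()] objects for the real blocks.
#' @param n_trials trials per block.
#' @param fs_hz native simulation rate.
#' @param noise a [noise_config()].
#' @param preproc a [preproc_config()].
#' @param wavelet a [wavelet_spec()].
#' @param map_channels channel labels entering the cluster-level maps
#'   (default: all scalp channels).
#' @param map_time_range,map_time_decim analysis window (s, 0 = first pulse)
#'   and decimation step of the stored phase-locking maps.
#' @param n_perm cluster-permutation count.
#' @param ica logical, run the ICA stage (disable for data simulated without
#'   decay artifacts).
#' @param seed master seed; participant p's condition c uses seed
#'   `seed + 1000 * p + c`.
#' @return a list of class `run_config`.
#' @export
run_config <- function(n_participants = 14,
                       conditions = list(stim_protocol("visual", 5, 11)),
                       n_trials = 12, fs_hz = 1000, noise = noise_config(),
                       preproc = preproc_config(), wavelet = wavelet_spec(),
                       map_channels = NULL, map_time_range = c(-0.5, 1.5),
                       map_time_decim = 10, n_perm = 500, ica = TRUE,
                       seed = 1) {
  structure(list(n_participants = n_participants, conditions = conditions,
                 n_trials = n_trials, fs_hz = fs_hz, noise = noise,
                 preproc = preproc, wavelet = wavelet,
                 map_channels = map_channels,
                 map_time_range = map_time_range,
                 map_time_decim = map_time_decim, n_perm = n_perm,
                 ica = ica, seed = seed),
            class = "run_config")
}

#' Run an end-to-end synthetic cohort analysis
#'
#' For every participant and every configured condition (plus its site-matched
#' sham partner) the pipeline simulates raw epochs, preprocesses them
#' (re-reference, pulse-window interpolation, optional ICA, trial rejection,
#' CSD, downsampling), computes Morlet phase-locking (ZPLF) maps on the
#' configured channel/time grid, and then runs the cohort-level statistics per
#' condition: real-vs-sham cluster permutation over (channel, frequency,
#' time), significant-electrode counts, the per-pulse normalized-ZPLF profile
#' at the stimulated electrode with one-way ANOVA, Dunnett comparisons against
#' baseline and the Pearson pulse trend, and the peak response frequency.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory: per-condition summary tables are written
#'   as tab-separated text and listed (with MD5 checksums) in the manifest.
#' @return list of class `cohort_result` with `conditions` (per real
#'   condition: `zplf_maps`, `sham_maps`, `cluster`, `sig_counts`,
#'   `profile_tab`, `anova`, `dunnett`, `pearson`, `peak_freq_hz`,
#'   `profiles`), `config`, `manifest`.
#' @export
run_cohort <- function(config = run_config(), out_dir = NULL) {
  mon <- make_montage()
  stim_ch <- c(motor = "C3", visual = "Oz", sham = "Oz")
  res <- list()
  for (cc in seq_along(config$conditions)) {
    prot <- config$conditions[[cc]]
    prot$n_trials <- config$n_trials
    sham <- prot
    sham$site <- "sham"
    chan <- stim_ch[[prot$site]]
    maps_real <- vector("list", config$n_participants)
    maps_sham <- vector("list", config$n_participants)
    prof_real <- vector("list", config$n_participants)
    prof_sham <- vector("list", config$n_participants)
    for (p in seq_len(config$n_participants)) {
      sd_p <- config$seed + 1000 * p + cc
      maps_real[[p]] <- participant_zplf(prot, prot$site, mon, config, sd_p, chan)
      maps_sham[[p]] <- participant_zplf(sham, prot$site, mon, config, sd_p + 500, chan)
      prof_real[[p]] <- attr(maps_real[[p]], "profile")
      prof_sham[[p]] <- attr(maps_sham[[p]], "profile")
    }
    adj <- mon$adjacency[attr(maps_real[[1]], "channels"),
                         attr(maps_real[[1]], "channels"), drop = FALSE]
    clus <- cluster_permutation(lapply(maps_real, strip_zplf),
                                lapply(maps_sham, strip_zplf),
                                adj, n_perm = config$n_perm,
                                seed = config$seed + cc)
    counts <- count_significant_electrodes(clus)
    fstim <- if (prot$n_pulses > 1) prot$train_freq_hz else NA
    ptab <- profile_table(prof_real, fstim)
    if (prot$n_pulses > 1) {
      an <- anova_pulse(ptab)
      du <- dunnett_vs_ctrl(ptab)
      pe <- pearson_trend(rep(seq_len(prot$n_pulses), each = config$n_participants),
                          as.numeric(ptab[, -1]))
    } else {
      an <- du <- pe <- NULL
    }
    pk <- mean_map_peak(maps_real, chan,
                        c(0, train_duration(prot) + ifelse(is.na(fstim), 0.3,
                                                           2 / fstim)))
    res[[condition_label(prot)]] <-
      list(protocol = prot, channel = chan, cluster = clus,
           sig_counts = counts, profile_tab = ptab, anova = an, dunnett = du,
           pearson = pe, peak_freq_hz = pk,
           sham_profile_tab = profile_table(prof_sham, fstim),
           zplf_maps = maps_real, sham_maps = maps_sham)
  }
  manifest <- write_cohort_tables(res, out_dir)
  structure(list(conditions = res, config = config, manifest = manifest),
            class = "cohort_result")
}

# simulate + preprocess + phase-locking maps for one participant/condition;
# the per-pulse profile at the stimulated electrode rides along as attribute
participant_zplf <- function(prot, real_site, mon, config, seed, stim_chan) {
  src <- default_sources(real_site)
  ts <- simulate_trialset(prot, sources = src, montage = mon,
                          noise = config$noise, fs_hz = config$fs_hz,
                          seed = seed)
  pp <- preprocess(ts, config$preproc, seed = seed, ica = config$ica)
  chans <- config$map_channels
  if (is.null(chans)) chans <- pp$trials$montage$labels[pp$trials$montage$scalp]
  tf <- morlet_transform(pp$trials, config$wavelet, channels = chans,
                         time_range = config$map_time_range,
                         time_decim = config$map_time_decim)
  zm <- zplf(plf(tf))
  prof <- pulse_profile(zplf_norm_freq(zm), prot, stim_chan)
  attr(zm, "profile") <- prof
  zm
}

strip_zplf <- function(zm) {
  v <- unclass(zm)
  v[is.na(v)] <- 0
  attributes(v) <- list(dim = dim(v))
  v
}

# participants x (ctrl, p1..pk) table of profile values at the stimulation
# frequency (nearest profiled frequency)
profile_table <- function(profiles, f_stim) {
  f <- profiles[[1]]$freqs_hz
  fi <- if (is.na(f_stim)) which.max(f == f[1]) else which.min(abs(f - f_stim))
  tab <- t(vapply(profiles,
                  function(pr) c(pr$ctrl[fi], pr$profile[, fi]),
                  numeric(nrow(profiles[[1]]$profile) + 1)))
  colnames(tab) <- c("ctrl", paste0("p", seq_len(ncol(tab) - 1)))
  tab
}

mean_map_peak <- function(maps, channel, window) {
  m <- Reduce(`+`, lapply(maps, unclass)) / length(maps)
  attributes(m) <- attributes(maps[[1]])
  peak_response_frequency(m, window, channel)
}

write_cohort_tables <- function(res, out_dir) {
  if (is.null(out_dir)) return(NULL)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(res)) {
    r <- res[[nm]]
    p1 <- file.path(out_dir, paste0(nm, "_clusters.tsv"))
    utils::write.table(r$cluster$clusters, p1, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    p2 <- file.path(out_dir, paste0(nm, "_profile.tsv"))
    utils::write.table(cbind(participant = seq_len(nrow(r$profile_tab)),
                             r$profile_tab), p2, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    p3 <- file.path(out_dir, paste0(nm, "_sig_counts.tsv"))
    utils::write.table(unclass(r$sig_counts), p3, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    paths <- c(paths, p1, p2, p3)
  }
  data.frame(path = paths, md5 = unname(tools::md5sum(paths)),
             stringsAsFactors = FALSE)
}

#' Contrast two real conditions of a cohort run
#'
#' Runs the same cluster-permutation machinery between the ZPLF maps of two
#' real conditions (e.g. beta-rTMS vs theta-rTMS), the comparison behind the
#' between-frequency topography contrasts. Swapping the contrast order flips
#' every cluster sign.
#'
#' @param cohort a [run_cohort()] result.
#' @param contrast character vector of two condition labels present in the
#'   cohort.
#' @param n_perm,seed permutation settings (defaults from the cohort config).
#' @return a [cluster_permutation()] result.
#' @export
compare_conditions <- function(cohort, contrast, n_perm = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "cohort_result"), length(contrast) == 2)
  miss <- setdiff(contrast, names(cohort$conditions))
  if (length(miss)) stop("condition(s) not in cohort: ", paste(miss, collapse = ", "))
  a <- cohort$conditions[[contrast[1]]]$zplf_maps
  b <- cohort$conditions[[contrast[2]]]$zplf_maps
  chans <- attr(a[[1]], "channels")
  mon <- make_montage()
  adj <- mon$adjacency[chans, chans, drop = FALSE]
  cluster_permutation(lapply(a, strip_zplf), lapply(b, strip_zplf), adj,
                      n_perm = if (is.null(n_perm)) cohort$config$n_perm else n_perm,
                      seed = if (is.null(seed)) cohort$config$seed + 77 else seed)
}
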