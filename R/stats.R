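#' Elementwise paired t map over participants
#'
#' Computes the paired t statistic between two conditions at every (channel,
#' frequency, time) element, over participants, plus the uncorrected
#' two-tailed threshold mask at p < 0.05 with n - 1 degrees of freedom.
#' Elements with zero-variance differences are masked (NA) with a warning.
#'
#' @param cond_a,cond_b lists (one element per participant, same order) of
#'   numeric arrays with identical dimensions (channel x frequency x time).
#' @param alpha uncorrected two-tailed threshold.
#' @return list with `t` (array), `df`, `crit` (critical |t|), `mask`
#'   (logical array, |t| > crit).
#' @export
paired_t_map <- function(cond_a, cond_b, alpha = 0.05) {
  if (length(cond_a) != length(cond_b)) stop("participant mismatch")
  n <- length(cond_a)
  if (n < 3) stop("need >= 3 participants")
  dm <- dim(cond_a[[1]])
  for (p in seq_len(n)) {
    if (!identical(dim(cond_a[[p]]), dm) || !identical(dim(cond_b[[p]]), dm)) {
      stop("participant maps have mismatched dimensions")
    }
  }
  D <- vapply(seq_len(n), function(p) as.numeric(cond_a[[p]] - cond_b[[p]]),
              numeric(prod(dm)))
  mu <- rowMeans(D)
  sd <- sqrt((rowSums(D^2) - n * mu^2) / (n - 1))
  t <- mu / (sd / sqrt(n))
  if (any(sd == 0)) {
    warning("zero-variance element(s) masked in paired t map")
    t[sd == 0] <- NA_real_
  }
  dim(t) <- dm
  crit <- stats::qt(1 - alpha / 2, n - 1)
  list(t = t, df = n - 1, crit = crit, mask = !is.na(t) & abs(t) > crit)
}

#' Cluster-based permutation test over (channel, frequency, time) maps
#'
#' Nonparametric family-wise control for paired condition comparisons:
#' elementwise paired t maps are thresholded at uncorrected two-tailed
#' p < 0.05, suprathreshold elements of equal sign are clustered (connected
#' over montage-adjacent channels at the same bin and over +/- 1 frequency
#' and time bins), and each cluster is scored by its summed t. The null
#' distribution of the maximum (positive) and minimum (negative) cluster
#' score is built by flipping the condition labels within participants (sign
#' flips of the paired differences); a cluster is significant when it exceeds
#' the 97.5th percentile of its signed null (two-tailed 5 percent). When
#' `2^n <= n_perm` the sign patterns are enumerated exhaustively (with a
#' warning).
#'
#' @param cond_a,cond_b per-participant arrays as in [paired_t_map()].
#' @param adjacency symmetric logical channel adjacency matrix (e.g.
#'   `montage$adjacency` subset to the map's channels); a 1 x 1 matrix for
#'   single-channel maps.
#' @param n_perm number of permutations (>= 100; 500 by default).
#' @param seed integer seed.
#' @param alpha cluster-forming (elementwise) threshold.
#' @return object of class `cluster_result`: `t_map`, `clusters` (data.frame:
#'   id, sign, size, sum_t, p, significant), `cluster_id` (integer array, 0
#'   outside clusters), `null_pos`, `null_neg`, `crit_pos`, `crit_neg`,
#'   `masked_t_map`, `df`, `n_perm`, `exhaustive`.
#' @export
cluster_permutation <- function(cond_a, cond_b, adjacency, n_perm = 500,
                                seed = 1, alpha = 0.05) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  n <- length(cond_a)
  tm <- paired_t_map(cond_a, cond_b, alpha)
  dm <- dim(tm$t)
  D <- vapply(seq_len(n), function(p) as.numeric(cond_a[[p]] - cond_b[[p]]),
              numeric(prod(dm)))                      # nvox x n
  ssq <- rowSums(D^2)

  exhaustive <- 2^n <= n_perm
  if (exhaustive) {
    warning(sprintf("2^%d = %d sign patterns <= n_perm; enumerating exhaustively",
                    n, 2^n))
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    set.seed(seed)
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  }
  M <- tcrossprod(D, S) / n                           # nvox x n_perm means
  SD <- sqrt(pmax((ssq - n * M^2) / (n - 1), 0))
  Tm <- M / (SD / sqrt(n))
  Tm[SD == 0] <- 0

  null_pos <- numeric(ncol(Tm))
  null_neg <- numeric(ncol(Tm))
  for (i in seq_len(ncol(Tm))) {
    tmap <- Tm[, i]
    dim(tmap) <- dm
    cl <- t_clusters(tmap, tm$crit, adjacency)$clusters
    null_pos[i] <- if (any(cl$sum_t > 0)) max(cl$sum_t) else 0
    null_neg[i] <- if (any(cl$sum_t < 0)) min(cl$sum_t) else 0
  }
  crit_pos <- stats::quantile(null_pos, 0.975, names = FALSE)
  crit_neg <- stats::quantile(null_neg, 0.025, names = FALSE)

  obs <- t_clusters(tm$t, tm$crit, adjacency)
  if (nrow(obs$clusters)) {
    pos <- obs$clusters$sum_t > 0
    obs$clusters$p <- NA_real_
    obs$clusters$p[pos] <- (1 + vapply(obs$clusters$sum_t[pos],
      function(s) sum(null_pos >= s), 0L)) / (length(null_pos) + 1)
    obs$clusters$p[!pos] <- (1 + vapply(obs$clusters$sum_t[!pos],
      function(s) sum(null_neg <= s), 0L)) / (length(null_neg) + 1)
    # p <= 0.025 per sign with the add-one Monte-Carlo convention: the
    # calibrated equivalent of exceeding the 97.5th percentile of the
    # signed null, robust to quantile interpolation at small n_perm
    obs$clusters$significant <- obs$clusters$p <= 0.025
  } else {
    obs$clusters$p <- numeric(0)
    obs$clusters$significant <- logical(0)
  }
  masked <- tm$t
  masked[is.na(masked)] <- 0
  sig_ids <- obs$clusters$id[obs$clusters$significant]
  masked[!(obs$id_map %in% sig_ids)] <- 0
  structure(list(t_map = tm$t, df = tm$df, clusters = obs$clusters,
                 cluster_id = obs$id_map, null_pos = null_pos,
                 null_neg = null_neg, crit_pos = crit_pos, crit_neg = crit_neg,
                 masked_t_map = masked, n_perm = ncol(Tm),
                 exhaustive = exhaustive),
            class = "cluster_result")
}

# connected components of same-sign suprathreshold elements of a
# channel x freq x time t map. Returns sum-t per cluster and an id array.
t_clusters <- function(tmap, crit, adjacency) {
  dm <- dim(tmap)
  if (length(dm) != 3) stop("t map must be channel x frequency x time")
  id_map <- array(0L, dm)
  clusters <- data.frame(id = integer(0), sign = integer(0), size = integer(0),
                         sum_t = numeric(0))
  next_id <- 0L
  for (sgn in c(1, -1)) {
    mask <- !is.na(tmap) & (sgn * tmap > crit)
    if (!any(mask)) next
    edges <- mask_edges(mask, adjacency)
    vox <- which(mask)
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
      directed = FALSE, vertices = data.frame(name = as.character(vox)))
    comp <- igraph::components(g)
    memb <- comp$membership[as.character(vox)]
    sums <- tapply(tmap[vox], memb, sum)
    sizes <- tapply(vox, memb, length)
    ids <- next_id + seq_along(sums)
    id_map[vox] <- ids[match(memb, as.integer(names(sums)))]
    clusters <- rbind(clusters,
                      data.frame(id = ids, sign = sgn,
                                 size = as.integer(sizes),
                                 sum_t = as.numeric(sums)))
    next_id <- next_id + length(sums)
  }
  list(clusters = clusters, id_map = id_map)
}

# edge list (pairs of linear indices) of a logical channel x freq x time mask
# under +/-1 freq, +/-1 time, and channel-adjacency connectivity
mask_edges <- function(mask, adjacency) {
  dm <- dim(mask)
  idx <- array(seq_len(prod(dm)), dm)
  from <- integer(0); to <- integer(0)
  if (dm[3] > 1) {
    m <- mask[, , -dm[3], drop = FALSE] & mask[, , -1, drop = FALSE]
    f <- idx[, , -dm[3], drop = FALSE][m]
    from <- c(from, f); to <- c(to, idx[, , -1, drop = FALSE][m])
  }
  if (dm[2] > 1) {
    m <- mask[, -dm[2], , drop = FALSE] & mask[, -1, , drop = FALSE]
    f <- idx[, -dm[2], , drop = FALSE][m]
    from <- c(from, f); to <- c(to, idx[, -1, , drop = FALSE][m])
  }
  if (dm[1] > 1) {
    pairs <- which(adjacency & upper.tri(adjacency), arr.ind = TRUE)
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      m <- mask[a, , , drop = FALSE] & mask[b, , , drop = FALSE]
      from <- c(from, idx[a, , , drop = FALSE][m])
      to <- c(to, idx[b, , , drop = FALSE][m])
    }
  }
  cbind(from, to)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d significant (%d permutations%s)\n",
              nrow(x$clusters), sum(x$clusters$significant), x$n_perm,
              if (x$exhaustive) ", exhaustive" else ""))
  if (nrow(x$clusters)) print(x$clusters[order(x$clusters$p), ], row.names = FALSE)
  invisible(x)
}

#' Count electrodes inside significant clusters
#'
#' @param result a [cluster_permutation()] result.
#' @return object of class `sig_count_map`: integer matrix frequency x time of
#'   the number of channels covered by any significant cluster at each bin.
#' @export
count_significant_electrodes <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  sig_ids <- result$clusters$id[result$clusters$significant]
  covered <- array(result$cluster_id %in% sig_ids, dim(result$cluster_id))
  counts <- apply(covered, c(2, 3), sum)
  structure(counts, class = "sig_count_map")
}

#' Exact binomial comparison of significant-electrode counts
#'
#' Two-sided exact binomial test of the count at the stimulation frequency
#' against the count at another frequency, under the null that a significant
#' electrode is equally likely to come from either (p0 = 0.5). Two-sided by
#' the minimum-likelihood rule (all outcomes at most as probable as the
#' observed one), which at p0 = 0.5 coincides with doubling the smaller tail.
#'
#' @param count_at_stim_f,count_at_other_f non-negative electrode counts.
#' @return two-sided p value (NA when both counts are zero).
#' @export
binomial_freq_test <- function(count_at_stim_f, count_at_other_f) {
  stopifnot(count_at_stim_f >= 0, count_at_other_f >= 0)
  n <- count_at_stim_f + count_at_other_f
  if (n == 0) return(NA_real_)
  stats::binom.test(round(count_at_stim_f), round(n), p = 0.5)$p.value
}

#' One-way ANOVA over pulse levels
#'
#' Fixed-effects one-way ANOVA of a complete participant x level table with
#' levels (ctrl, pulse 1, ..., pulse 5): with n participants per level the
#' degrees of freedom are (5, 6 (n - 1)).
#'
#' @param tab numeric matrix, participants x levels (first column = ctrl).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
anova_pulse <- function(tab) {
  tab <- as.matrix(tab)
  if (anyNA(tab)) stop("missing cells in the pulse table")
  if (nrow(tab) < 2) stop("need >= 2 participants")
  y <- as.numeric(tab)
  g <- factor(rep(seq_len(ncol(tab)), each = nrow(tab)))
  if (stats::var(y) == 0) {
    warning("zero within- and between-level variance; F undefined")
    return(list(F = NaN, df1 = ncol(tab) - 1,
                df2 = length(y) - ncol(tab), p = NA_real_))
  }
  a <- stats::anova(stats::lm(y ~ g))
  list(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2], p = a$`Pr(>F)`[1])
}

#' Dunnett many-to-one comparisons against the control level
#'
#' Compares each pulse level against the first (ctrl) column, two-sided, with
#' family-wise adjustment over the k - 1 comparisons via the many-to-one
#' multivariate t distribution (correlation 1/2 in the balanced case),
#' integrated by seeded quasi-Monte-Carlo.
#'
#' @param tab numeric matrix, participants x levels; column 1 is ctrl.
#' @return data.frame with `level`, `estimate`, `t`, `p_adj`.
#' @export
dunnett_vs_ctrl <- function(tab) {
  tab <- as.matrix(tab)
  if (anyNA(tab)) stop("missing cells in the pulse table")
  n <- nrow(tab); k <- ncol(tab)
  if (n < 2) stop("need >= 2 participants")
  mu <- colMeans(tab)
  df <- k * (n - 1)
  s2 <- sum(sweep(tab, 2, mu)^2) / df
  est <- mu[-1] - mu[1]
  tt <- est / sqrt(2 * s2 / n)
  R <- matrix(0.5, k - 1, k - 1); diag(R) <- 1
  p_adj <- vapply(abs(tt), function(q) {
    if (!is.finite(q)) return(NA_real_)
    1 - local_seed_pmvt(q, R, df)
  }, 0)
  data.frame(level = if (!is.null(colnames(tab))) colnames(tab)[-1]
             else paste0("p", seq_len(k - 1)),
             estimate = unname(est), t = unname(tt),
             p_adj = pmin(pmax(unname(p_adj), 0), 1))
}

# P(max |T_j| <= q) for the many-to-one multivariate t; RNG state is saved
# and restored so the quasi-Monte-Carlo integration is reproducible without
# disturbing the caller's random stream.
local_seed_pmvt <- function(q, R, df) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(20260924)
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  as.numeric(mvtnorm::pmvt(lower = rep(-q, nrow(R)), upper = rep(q, nrow(R)),
                           df = df, corr = R,
                           algorithm = mvtnorm::GenzBretz(abseps = 1e-4,
                                                          maxpts = 25000)))
}

#' Pearson trend of phase locking over pulses
#'
#' Correlates the pulse index with the phase-locking value over all
#' (participant, pulse) points, testing for a linearly increasing trend over
#' the train.
#'
#' @param pulse_idx integer pulse index per observation.
#' @param value phase-locking value per observation.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_trend <- function(pulse_idx, value) {
  stopifnot(length(pulse_idx) == length(value))
  if (length(value) < 3) stop("need >= 3 points")
  if (stats::var(pulse_idx) == 0 || stats::var(value) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(value)))
  }
  ct <- stats::cor.test(pulse_idx, value)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(value))
}

#' Frequency of the peak time-averaged response
#'
#' @param map a `zplf_map` or the `masked_t_map` of a [cluster_permutation()]
#'   (then supply `freqs_hz`, `times`, `channels` explicitly).
#' @param window `c(t0, t1)` seconds over which to average.
#' @param channel channel label.
#' @param freqs_hz,times,channels axis metadata; defaults taken from the map's
#'   attributes.
#' @return peak frequency in Hz (ties resolve toward the lowest frequency).
#' @export
peak_response_frequency <- function(map, window, channel,
                                    freqs_hz = attr(map, "freqs_hz"),
                                    times = attr(map, "times"),
                                    channels = attr(map, "channels")) {
  chi <- match(channel, channels)
  if (is.na(chi)) stop("channel not present in map: ", channel)
  w <- which(times >= window[1] & times <= window[2])
  v <- unclass(map)[chi, , w, drop = FALSE]
  prof <- apply(v, 2, mean, na.rm = TRUE)
  if (all(is.na(prof))) stop("window is fully masked")
  freqs_hz[which.max(prof)]
}
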