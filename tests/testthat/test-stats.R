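test_that("paired t maps agree with the direct t-test and mask degeneracies", {
  set.seed(41)
  dm <- c(3, 4, 5)
  n <- 14
  a <- lapply(1:n, function(i) array(rnorm(prod(dm)), dm))
  b <- lapply(1:n, function(i) array(rnorm(prod(dm)), dm))
  tm <- paired_t_map(a, b)
  expect_equal(tm$df, 13)
  # recomputation oracle: stats::t.test on a handful of elements
  for (idx in list(c(1, 1, 1), c(2, 3, 4), c(3, 4, 5))) {
    av <- vapply(a, function(x) x[idx[1], idx[2], idx[3]], 0)
    bv <- vapply(b, function(x) x[idx[1], idx[2], idx[3]], 0)
    expect_equal(tm$t[idx[1], idx[2], idx[3]],
                 unname(t.test(av, bv, paired = TRUE)$statistic),
                 tolerance = 1e-10)
  }
  # identical conditions give all-zero t
  tz <- suppressWarnings(paired_t_map(a, a))
  expect_true(all(is.na(tz$t)))               # 0/0: masked as degenerate
  # constant unit difference with zero variance is masked with a warning
  ac <- lapply(1:4, function(i) array(1, c(2, 2, 2)))
  bc <- lapply(1:4, function(i) array(0, c(2, 2, 2)))
  expect_warning(tc <- paired_t_map(ac, bc), "zero-variance")
  expect_true(all(is.na(tc$t)))
  expect_error(paired_t_map(a[1:3], b[1:4]), "mismatch")
})

test_that("clusters are connected under the declared adjacency and scored by summed t", {
  mon <- toy_montage(4)
  tmap <- array(0, c(4, 3, 5))
  # one positive cluster: channels 1-2 (adjacent), freq 1, times 1-2
  tmap[1, 1, 1:2] <- 3
  tmap[2, 1, 1] <- 4
  # a separate positive island at channel 4 (not adjacent to 1-2)
  tmap[4, 3, 5] <- 5
  # a negative cluster
  tmap[3, 2, 3:4] <- -6
  cl <- entrainlock:::t_clusters(tmap, crit = 2, adjacency = mon$adjacency)
  expect_equal(nrow(cl$clusters), 3)
  sums <- sort(cl$clusters$sum_t)
  expect_equal(sums, c(-12, 5, 10))
  # mask/id consistency
  expect_equal(sum(cl$id_map > 0), 6)
})

test_that("the permutation test is exact for few participants and calibrated overall", {
  set.seed(7)
  dm <- c(2, 4, 6)
  mon <- toy_montage(2)
  a <- lapply(1:4, function(i) array(rnorm(prod(dm)), dm))
  b <- lapply(1:4, function(i) array(rnorm(prod(dm)), dm))
  expect_warning(r1 <- cluster_permutation(a, b, mon$adjacency, n_perm = 100,
                                           seed = 1),
                 "exhaustively")
  expect_warning(r2 <- cluster_permutation(a, b, mon$adjacency, n_perm = 100,
                                           seed = 99),
                 "exhaustively")
  expect_equal(r1$n_perm, 16)                  # 2^4 sign patterns
  expect_identical(r1$clusters$p, r2$clusters$p)   # seed-independent when exact
  expect_true(all(r1$clusters$p >= 1 / 17 & r1$clusters$p <= 1))
  # a strong inserted effect is detected
  a2 <- lapply(1:10, function(i) {
    x <- array(rnorm(prod(dm)), dm)
    x[1:2, 1:2, 1:3] <- x[1:2, 1:2, 1:3] + 4
    x
  })
  b2 <- lapply(1:10, function(i) array(rnorm(prod(dm)), dm))
  r3 <- cluster_permutation(a2, b2, mon$adjacency, n_perm = 200, seed = 3)
  expect_true(any(r3$clusters$significant & r3$clusters$sum_t > 0))
  # masked map is zero outside significant clusters
  expect_true(all(r3$masked_t_map[r3$cluster_id == 0] == 0))
  expect_error(cluster_permutation(a, b, mon$adjacency, n_perm = 50), "100")
})

test_that("significant-electrode counting covers each channel once per bin", {
  mon <- toy_montage(3)
  set.seed(11)
  dm <- c(3, 3, 4)
  a <- lapply(1:8, function(i) {
    x <- array(rnorm(prod(dm)), dm)
    x[, 2, 2:3] <- x[, 2, 2:3] + 5
    x
  })
  b <- lapply(1:8, function(i) array(rnorm(prod(dm)), dm))
  r <- cluster_permutation(a, b, mon$adjacency, n_perm = 200, seed = 5)
  counts <- count_significant_electrodes(r)
  expect_true(all(dim(counts) == c(3, 4)))
  expect_true(all(counts >= 0 & counts <= 3))
  # recomputation oracle from the id map
  sig_ids <- r$clusters$id[r$clusters$significant]
  expect_equal(unclass(counts),
               apply(array(r$cluster_id %in% sig_ids, dm), c(2, 3), sum))
  expect_gte(counts[2, 2], 2)
  # no significant cluster -> all zero
  rnull <- cluster_permutation(b, lapply(1:8, function(i)
    array(rnorm(prod(dm)), dm)), mon$adjacency, n_perm = 200, seed = 6)
  if (!any(rnull$clusters$significant)) {
    expect_true(all(count_significant_electrodes(rnull) == 0))
  }
})

test_that("the electrode-count binomial test matches exact tail enumeration", {
  expect_equal(binomial_freq_test(10, 10), 1)
  expect_equal(binomial_freq_test(15, 0), 2 * 0.5^15, tolerance = 1e-12)
  expect_equal(binomial_freq_test(0, 15), binomial_freq_test(15, 0))
  expect_true(is.na(binomial_freq_test(0, 0)))
  # agreement with direct minlike enumeration for an asymmetric case
  k <- 12; n <- 16
  pk <- dbinom(0:n, n, 0.5)
  p_direct <- sum(pk[pk <= pk[k + 1] + 1e-12])
  expect_equal(binomial_freq_test(12, 4), p_direct, tolerance = 1e-12)
})

test_that("the pulse ANOVA has the design degrees of freedom and exact F", {
  set.seed(13)
  tab <- matrix(rnorm(14 * 6), 14, 6)
  r <- anova_pulse(tab)
  expect_equal(c(r$df1, r$df2), c(5, 78))
  # sums-of-squares oracle
  gm <- mean(tab)
  ss_b <- 14 * sum((colMeans(tab) - gm)^2)
  ss_w <- sum(sweep(tab, 2, colMeans(tab))^2)
  f_oracle <- (ss_b / 5) / (ss_w / 78)
  expect_equal(r$F, f_oracle, tolerance = 1e-10)
  expect_equal(r$p, pf(f_oracle, 5, 78, lower.tail = FALSE), tolerance = 1e-10)
  expect_warning(rc <- anova_pulse(matrix(1, 5, 6)), "undefined")
  expect_error(anova_pulse(matrix(c(1, NA), 2, 6)), "missing")
})

test_that("Dunnett comparisons agree with multcomp and respect symmetry", {
  set.seed(19)
  tab <- matrix(rnorm(10 * 4), 10, 4)
  colnames(tab) <- c("ctrl", "p1", "p2", "p3")
  r <- dunnett_vs_ctrl(tab)
  expect_equal(nrow(r), 3)
  skip_if_not_installed("multcomp")
  df <- data.frame(y = as.numeric(tab),
                   g = factor(rep(colnames(tab), each = 10),
                              levels = colnames(tab)))
  gl <- multcomp::glht(stats::aov(y ~ g, df),
                       linfct = multcomp::mcp(g = "Dunnett"))
  p_mc <- summary(gl, test = multcomp::adjusted("single-step"))$test$pvalues
  expect_equal(r$p_adj, as.numeric(p_mc), tolerance = 5e-3)
  # duplicated level data give identical adjusted p
  tab2 <- cbind(tab[, 1:2], tab[, 2], tab[, 4])
  r2 <- dunnett_vs_ctrl(tab2)
  expect_equal(r2$p_adj[1], r2$p_adj[2], tolerance = 1e-6)
})

test_that("a 3-SD shifted level is flagged by Dunnett essentially always", {
  hits <- vapply(1:20, function(s) {
    set.seed(300 + s)
    tab <- matrix(rnorm(14 * 6), 14, 6)
    tab[, 4] <- tab[, 4] + 3
    min(dunnett_vs_ctrl(tab)$p_adj[3], 1)
  }, 0)
  expect_gt(mean(hits < 0.05), 0.95)
})

test_that("the Pearson pulse trend behaves on trends, anti-trends and noise", {
  idx <- rep(1:5, 14)
  r1 <- pearson_trend(idx, idx * 2 + rep(rnorm(14, sd = 0), each = 5))
  expect_equal(r1$r, 1)
  r2 <- pearson_trend(idx, -idx + rnorm(70, sd = 0.1))
  expect_lt(r2$r, 0)
  set.seed(23)
  r3 <- pearson_trend(idx, rnorm(70))
  expect_lt(abs(r3$r), 0.3)
  expect_warning(pearson_trend(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("peak response frequency picks the window maximum with low-frequency ties", {
  v <- array(0, c(1, 5, 10))
  v[1, 3, 4:6] <- 2
  zm <- toy_zplf(v, freqs = c(5, 8, 11, 14, 17),
                 times = seq(0, 0.9, by = 0.1), channels = "Oz")
  expect_equal(peak_response_frequency(zm, c(0.3, 0.6), "Oz"), 11)
  # flat map resolves to the lowest frequency
  zf <- toy_zplf(array(1, c(1, 5, 10)), freqs = c(5, 8, 11, 14, 17),
                 times = seq(0, 0.9, by = 0.1), channels = "Oz")
  expect_equal(peak_response_frequency(zf, c(0, 0.9), "Oz"), 5)
})
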