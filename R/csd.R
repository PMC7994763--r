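#' Current source density (spherical-spline surface Laplacian)
#'
#' Transforms scalp potentials into reference-free current source density by
#' spherical-spline interpolation: per time sample a spline of flexibility
#' `csd_spline_order` with smoothing `csd_lambda` is fit to the electrode
#' potentials, and its surface Laplacian is evaluated at the electrodes.
#' Because the fit is linear in the data, the whole transform is a single
#' channel-by-channel matrix applied to every sample. Adding a constant to all
#' channels leaves the output unchanged, and a spatially constant map
#' transforms to (numerically) zero.
#'
#' @param trials a [trialset()] with at least 32 scalp channels.
#' @param cfg a [preproc_config()] supplying `csd_spline_order`, `csd_lambda`,
#'   `csd_n_legendre`.
#' @return a [trialset()] whose data are CSD values in microvolts per square
#'   meter (using the montage head radius).
#' @export
csd_transform <- function(trials, cfg = preproc_config()) {
  scalp <- which(trials$montage$scalp)
  if (length(scalp) < 32) stop("need at least 32 scalp channels for CSD")
  L <- csd_matrix(trials$montage$pos[scalp, , drop = FALSE],
                  m = cfg$csd_spline_order, lambda = cfg$csd_lambda,
                  n_leg = cfg$csd_n_legendre,
                  head_radius_m = trials$montage$head_radius_mm / 1000)
  out <- trials
  d <- dim(trials$data)
  for (tr in seq_len(d[1])) {
    out$data[tr, scalp, ] <- L %*% trials$data[tr, scalp, , drop = TRUE]
  }
  out
}

#' CSD transform matrix for a set of electrode positions
#'
#' @param pos n x 3 unit vectors.
#' @param m spline flexibility (Perrin's m).
#' @param lambda smoothing constant added to the diagonal of the spline
#'   system.
#' @param n_leg number of Legendre terms.
#' @param head_radius_m head radius in meters (scales output to uV/m^2).
#' @return n x n matrix mapping potentials to CSD.
#' @export
csd_matrix <- function(pos, m = 4, lambda = 1e-5, n_leg = 50,
                       head_radius_m = 0.092) {
  cosang <- tcrossprod(pos)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  G <- legendre_series(cosang, n_leg, m)
  # CSD = -surface Laplacian of the spline potential; the Laplacian of P_n on
  # the sphere is -n(n+1) P_n / R^2, so the minus signs cancel here.
  H <- legendre_series(cosang, n_leg, m - 1)
  Gs <- G + diag(lambda, nrow(G))
  Gi <- tryCatch(solve(Gs), error = function(e) {
    stop("spline system is ill-conditioned; increase csd_lambda")
  })
  one <- rep(1, nrow(G))
  # c0 absorbs the mean so that sum of spline coefficients is zero
  denom <- sum(Gi)
  P <- Gi - (Gi %*% one %*% crossprod(one, Gi)) / denom
  (H %*% P) / head_radius_m^2
}

# sum_{n=1}^{N} (2n+1) / (n(n+1))^m * P_n(x) / (4 pi), elementwise
legendre_series <- function(x, n_leg, m) {
  out <- array(0, dim = dim(x))
  Pnm1 <- array(1, dim = dim(x))    # P_0
  Pn <- x                           # P_1
  for (n in seq_len(n_leg)) {
    out <- out + (2 * n + 1) / (n * (n + 1))^m * Pn
    Pnp1 <- ((2 * n + 1) * x * Pn - n * Pnm1) / (n + 1)
    Pnm1 <- Pn
    Pn <- Pnp1
  }
  out / (4 * pi)
}
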