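#' Band-pass filter and instantaneous phases of node time series
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass per node,
#' then takes the angle of the analytic signal (Hilbert transform via FFT).
#' Edge volumes are trimmed on both sides to remove filter and Hilbert edge
#' effects.
#'
#' @param ts N x T matrix of node time series, or a `"hopf_sim"` (its `x` is
#'   used).
#' @param TR sampling interval in seconds (taken from a `"hopf_sim"` input).
#' @param band band edges in Hz; must lie inside `(0, 1/(2 TR))`. Default
#'   0.008-0.08 Hz, the standard resting-state band.
#' @param order Butterworth order (default 2).
#' @param edge_trim volumes removed per side after filtering (default 10).
#' @return list of class `"phase_field"` with `phases` (N x T' radians in
#'   `(-pi, pi]`), `filtered` (N x T'), `band`, `edge_trim`.
#' @export
bandpass_phase <- function(ts, TR = NULL, band = c(0.008, 0.08), order = 2,
                           edge_trim = 10) {
  if (inherits(ts, "hopf_sim")) {
    TR <- ts$TR
    ts <- ts$x
  }
  ts <- as.matrix(ts)
  if (is.null(TR)) stop("TR is required")
  nyq <- 1 / (2 * TR)
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
    stop(sprintf("band must lie inside (0, %.4g Hz)", nyq))
  Tn <- ncol(ts)
  if (Tn <= 3 * order) stop("time series too short for the filter order")
  if (Tn <= 2 * edge_trim) stop("time series too short for the edge trim")
  bf <- signal::butter(order, band / nyq, type = "pass")
  filt <- t(apply(ts, 1, function(v) {
    signal::filtfilt(bf, v - mean(v))
  }))
  if (nrow(ts) == 1L) filt <- matrix(filt, nrow = 1L)
  an <- analytic_signal(filt)
  keep <- seq.int(edge_trim + 1L, Tn - edge_trim)
  structure(list(phases = Arg(an)[, keep, drop = FALSE],
                 filtered = filt[, keep, drop = FALSE],
                 band = band, edge_trim = edge_trim),
            class = "phase_field")
}

# analytic signal of each row via the frequency-domain Hilbert transform
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  f <- mvfft(t(x)) * h
  t(mvfft(f, inverse = TRUE)) / n
}

#' Local Kuramoto order parameter
#'
#' The modulus `R_n(t)` of the spatially weighted mean phase factor around
#' each node: `R_n(t) e^{i theta} = sum_p (C_np / sum_q C_nq) e^{i phi_p(t)}`.
#' It measures the local level of synchronization. The weights are
#' conventionally the exponential-distance-rule kernel (see [edr_kernel()]).
#'
#' @param phases a `"phase_field"` or an N x T matrix of phases (radians).
#' @param weights N x N nonnegative weight matrix with strictly positive row
#'   sums.
#' @return list of class `"local_order"` with `R` (N x T matrix in `[0,1]`)
#'   and `weights`.
#' @export
local_kuramoto <- function(phases, weights) {
  ph <- if (inherits(phases, "phase_field")) phases$phases else as.matrix(phases)
  w <- as.matrix(weights)
  if (nrow(w) != nrow(ph)) stop("weights do not match the number of nodes")
  rs <- rowSums(w)
  if (any(rs <= 0)) stop("zero row sum in local weighting matrix")
  z <- (w / rs) %*% exp(1i * ph)
  R <- Mod(z)
  dimnames(R) <- NULL
  R[R > 1] <- 1 # clip rounding overshoot
  structure(list(R = R, weights = w), class = "local_order")
}

#' Amplitude turbulence
#'
#' The standard deviation of the local Kuramoto order parameter pooled
#' across space and time: `D = sqrt(<R^2> - <R>^2)`. It quantifies the
#' variability of local synchronization, the whole-brain analogue of
#' amplitude turbulence in coupled-oscillator media.
#'
#' @param R a `"local_order"` object or a numeric matrix of `R_n(t)` values.
#' @return scalar `D >= 0`.
#' @export
amplitude_turbulence <- function(R) {
  r <- if (inherits(R, "local_order")) R$R else as.matrix(R)
  if (length(r) == 0L) stop("empty local order field")
  sqrt(max(0, mean(r^2) - mean(r)^2))
}

#' Global Kuramoto order parameter
#'
#' `gR(t) = |mean_p e^{i phi_p(t)}|`, the global level of phase synchrony at
#' each time point, in `[0, 1]`.
#'
#' @inheritParams local_kuramoto
#' @return numeric vector of length T.
#' @export
global_kuramoto <- function(phases) {
  ph <- if (inherits(phases, "phase_field")) phases$phases else as.matrix(phases)
  g <- Mod(colMeans(exp(1i * ph)))
  g[g > 1] <- 1
  g
}

#' Metastability
#'
#' The standard deviation over time of the global Kuramoto order parameter,
#' `M = sqrt(<gR^2> - <gR>^2)`; the coarse-parcellation counterpart of
#' amplitude turbulence.
#'
#' @param gR numeric vector as returned by [global_kuramoto()].
#' @return scalar `M >= 0`.
#' @export
metastability <- function(gR) {
  sqrt(max(0, mean(gR^2) - mean(gR)^2))
}

#' Functional connectivity
#'
#' Pearson correlation between all pairs of node signals.
#'
#' @param ts N x T matrix (nodes x time), or a `"hopf_sim"`.
#' @return symmetric N x N correlation matrix with unit diagonal.
#' @export
functional_connectivity <- function(ts) {
  if (inherits(ts, "hopf_sim")) ts <- ts$x
  fc <- cor(t(as.matrix(ts)))
  fc[!is.finite(fc)] <- 0
  diag(fc) <- 1
  dimnames(fc) <- NULL
  (fc + t(fc)) / 2
}

#' Compare simulated and empirical functional connectivity
#'
#' Three complementary metrics: `eFC`, the Euclidean distance between the
#' upper-triangle vectors normalized by the square root of the number of
#' elements (a root-mean-square difference, comparable across parcellation
#' sizes; the raw norm is also returned as `eFC_raw`); `corrFC`, the Pearson
#' correlation of the upper triangles; and `ssimFC`, a single global
#' structural-similarity index with the conventional stabilizing constants
#' (`K1 = 0.01`, `K2 = 0.03`) computed on the two matrices after a common
#' rescale to `[0, 1]`.
#'
#' @param fc_sim,fc_emp N x N functional-connectivity matrices.
#' @return list with `eFC`, `eFC_raw`, `corrFC`, `ssimFC`.
#' @export
fc_metrics <- function(fc_sim, fc_emp) {
  fc_sim <- as.matrix(fc_sim); fc_emp <- as.matrix(fc_emp)
  if (!identical(dim(fc_sim), dim(fc_emp)))
    stop("FC matrices must have the same dimensions")
  ut <- upper.tri(fc_sim)
  d <- fc_sim[ut] - fc_emp[ut]
  eFC_raw <- sqrt(sum(d^2))
  corrFC <- if (sd(fc_sim[ut]) == 0 || sd(fc_emp[ut]) == 0) NA_real_
            else cor(fc_sim[ut], fc_emp[ut])
  list(eFC = eFC_raw / sqrt(length(d)), eFC_raw = eFC_raw, corrFC = corrFC,
       ssimFC = ssim_global(fc_sim, fc_emp))
}

# single global SSIM on matrices rescaled together to [0, 1]
ssim_global <- function(a, b) {
  lo <- min(a, b); hi <- max(a, b)
  if (hi > lo) {
    a <- (a - lo) / (hi - lo)
    b <- (b - lo) / (hi - lo)
  } else {
    a <- a * 0
    b <- b * 0
  }
  c1 <- 0.01^2; c2 <- 0.03^2
  ma <- mean(a); mb <- mean(b)
  va <- mean((a - ma)^2); vb <- mean((b - mb)^2)
  cab <- mean((a - ma) * (b - mb))
  ((2 * ma * mb + c1) * (2 * cab + c2)) /
    ((ma^2 + mb^2 + c1) * (va + vb + c2))
}

#' Turbulence and metastability fitting errors
#'
#' Absolute differences between simulated and empirical values:
#' `eD = |D_sim - D_emp|` and `eM = |M_sim - M_emp|`.
#'
#' @param D_sim,D_emp simulated and empirical amplitude turbulence.
#' @return scalar absolute error.
#' @export
turbulence_error <- function(D_sim, D_emp) abs(D_sim - D_emp)

#' @rdname turbulence_error
#' @param M_sim,M_emp simulated and empirical metastability.
#' @export
metastability_error <- function(M_sim, M_emp) abs(M_sim - M_emp)

#' All fitting observables of one run
#'
#' Convenience wrapper: band-pass + phases, then amplitude turbulence (when
#' `weights` are supplied), metastability, and functional connectivity of
#' the filtered signals.
#'
#' @inheritParams bandpass_phase
#' @param weights local-synchronization weights for [local_kuramoto()]
#'   (e.g. [edr_kernel()]); `NULL` skips `D`.
#' @return list with `D` (or `NULL`), `M`, `fc`, `gR`.
#' @export
compute_observables <- function(ts, TR = NULL, band = c(0.008, 0.08),
                                weights = NULL, edge_trim = 10) {
  pf <- bandpass_phase(ts, TR = TR, band = band, edge_trim = edge_trim)
  gR <- global_kuramoto(pf)
  D <- if (!is.null(weights)) amplitude_turbulence(local_kuramoto(pf, weights))
  list(D = D, M = metastability(gR), fc = functional_connectivity(pf$filtered),
       gR = gR)
}
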