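#' Model parameters for one simulation regime
#'
#' Bundles the per-run parameters of the coupled Stuart-Landau system. The
#' bifurcation parameter `a` selects the dynamical regime: strongly negative
#' gives noise-driven fluctuations around a fixed point, slightly negative a
#' fluctuating (subcritical) regime, positive a self-sustained oscillatory
#' (supercritical) regime. `beta` is the shear (nonisochronicity) factor
#' coupling amplitude to frequency, and `G` scales all pairwise structural
#' couplings.
#'
#' The integrator step is tied to the output sampling interval: `TR` must be
#' an integer multiple of `dt` (within 1e-6 relative tolerance); the step
#' actually used is `TR / round(TR / dt)`. The default `dt = TR/16` (0.045 s
#' for TR = 0.72 s) keeps the stochastic Heun scheme stable and accurate in
#' every regime used here, including supercritical working points with shear
#' up to 6.
#'
#' @param a bifurcation parameter, scalar or per node.
#' @param omega intrinsic angular frequency per node, rad/s (scalar recycled).
#' @param beta shear factor (scalar).
#' @param G global coupling scale.
#' @param nu additive noise standard deviation (default 0.01, the value used
#'   across the Hopf whole-brain literature).
#' @param TR output sampling interval in seconds (0.72 for the reference
#'   acquisition).
#' @param n_volumes number of output volumes retained.
#' @param discard transient volumes dropped from the start (default 20).
#' @param dt integrator step in seconds; default `TR/16`.
#' @param shared_noise if `TRUE`, the real and imaginary equations of a node
#'   share one noise realization per step; default `FALSE` (independent
#'   streams).
#' @return list of class `"model_params"`.
#' @export
model_params <- function(a, omega, beta = 0, G = 0, nu = 0.01, TR = 0.72,
                         n_volumes = 400L, discard = 20L, dt = TR / 16,
                         shared_noise = FALSE) {
  stopifnot(dt > 0, TR > 0, nu >= 0, n_volumes >= 1, discard >= 0,
            length(beta) == 1L, length(G) == 1L)
  if (!all(is.finite(omega)) || any(omega <= 0))
    stop("omega must be finite and positive (rad/s)")
  sub <- round(TR / dt)
  if (sub < 1L || abs(TR / dt - sub) > 1e-6 * sub)
    stop("TR must be an integer multiple of dt")
  structure(list(a = a, omega = omega, beta = beta, G = G, nu = nu, TR = TR,
                 n_volumes = as.integer(n_volumes),
                 discard = as.integer(discard), sub = as.integer(sub),
                 dt = TR / sub, shared_noise = isTRUE(shared_noise)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> a = %s, beta = %g, G = %g, nu = %g\n  TR = %g s, dt = %g s, %d volumes (+%d transient)\n",
    paste(format(unique(x$a)), collapse = "/"), x$beta, x$G, x$nu, x$TR,
    x$dt, x$n_volumes, x$discard))
  invisible(x)
}

#' External periodic forcing specification
#'
#' The stimulus is an additive periodic force `F0_j * cos(wf_j t)` on the
#' real equation and `F0_j * sin(wf_j t)` on the imaginary equation of node
#' j, emulating external stimulation. `F0` is zero for untargeted nodes.
#' The forcing frequency defaults to each node's intrinsic frequency at
#' simulation time.
#'
#' @param F0 forcing amplitude: scalar (applied to all nodes) or per node.
#' @param omega_forcing forcing angular frequency, rad/s: `NULL` (node's own
#'   intrinsic frequency), scalar, or per node.
#' @param schedule `"sustained"` (on for the whole run, including the
#'   transient), `"off"`, or `"on_then_off"` (on for the first `n_on`
#'   retained volumes, off for the following `n_off`).
#' @param n_on,n_off on/off lengths in volumes for `"on_then_off"`.
#' @return list of class `"forcing_spec"`.
#' @export
forcing_spec <- function(F0 = 0, omega_forcing = NULL,
                         schedule = c("sustained", "off", "on_then_off"),
                         n_on = NULL, n_off = NULL) {
  schedule <- match.arg(schedule)
  if (any(F0 < 0)) stop("forcing amplitudes must be nonnegative")
  if (schedule == "on_then_off" && (is.null(n_on) || is.null(n_off)))
    stop("on_then_off schedule needs n_on and n_off")
  structure(list(F0 = F0, omega_forcing = omega_forcing, schedule = schedule,
                 n_on = n_on, n_off = n_off), class = "forcing_spec")
}

#' Force a set of nodes (e.g. a homotopic pair)
#'
#' Convenience wrapper building a [forcing_spec()] whose amplitude vector is
#' `F0` on `nodes` and zero elsewhere.
#'
#' @param nodes integer node indices to force.
#' @param F0 scalar amplitude applied to those nodes.
#' @param n total number of nodes.
#' @inheritParams forcing_spec
#' @return a `"forcing_spec"`.
#' @export
forcing_nodes <- function(nodes, F0, n, omega_forcing = NULL,
                          schedule = "sustained", n_on = NULL, n_off = NULL) {
  amp <- numeric(n)
  amp[nodes] <- F0
  forcing_spec(F0 = amp, omega_forcing = omega_forcing, schedule = schedule,
               n_on = n_on, n_off = n_off)
}

#' Simulate the coupled stochastic Stuart-Landau system
#'
#' Integrates the whole-brain model in cartesian coordinates: each node
#' follows the Hopf normal form
#' `dz/dt = (a + i*omega) z - (1 + i*beta) z |z|^2`, plus diffusive coupling
#' `G * sum_j C_ij (z_j - z_i)`, additive Gaussian noise of standard
#' deviation `nu` in each coordinate, and optional periodic forcing. Time
#' stepping uses the stochastic Heun scheme (trapezoidal drift, additive
#' noise), which remains stable at the default step in the fast-rotating
#' supercritical working points where a plain Euler-Maruyama step diverges.
#' The real part `x` plays the role of the simulated BOLD signal. The state
#' is subsampled at TR after discarding the transient.
#'
#' Identical `(params, coupling, forcing, seed)` give bit-identical output.
#' A trajectory whose modulus exceeds the divergence guard
#' `10 * max(1, sqrt(max(a, 0)))` aborts with an error of class
#' `"hopfwb_divergence"` reporting the volume and node.
#'
#' @param params a [model_params()] object.
#' @param coupling N x N [coupling_matrix()] (matching `length(omega)` after
#'   recycling).
#' @param forcing a [forcing_spec()]; default: no forcing.
#' @param seed integer RNG seed (required: runs must be reproducible).
#' @return list of class `"hopf_sim"` with elements `x`, `y` (N x n_volumes
#'   matrices), `TR`, `seed`, `forcing_on` (logical per retained volume) and
#'   `params`.
#' @examples
#' C <- coupling_matrix(matrix(0, 1, 1))
#' p <- model_params(a = 1, omega = 2 * pi * 0.05, nu = 0, n_volumes = 50)
#' s <- simulate_hopf(p, C, seed = 1)
#' max(abs(s$x)) # close to sqrt(a) = 1
#' @export
simulate_hopf <- function(params, coupling, forcing = forcing_spec(F0 = 0),
                          seed) {
  stopifnot(inherits(params, "model_params"))
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  N <- nrow(coupling)
  a <- rep_len(params$a, N)
  omega <- rep_len(params$omega, N)
  F0 <- rep_len(forcing$F0, N)
  wf <- if (is.null(forcing$omega_forcing)) omega
        else rep_len(forcing$omega_forcing, N)
  n_total <- params$n_volumes + params$discard
  sched <- switch(forcing$schedule,
    off = rep(FALSE, n_total),
    sustained = rep(TRUE, n_total),
    on_then_off = {
      if (forcing$n_on + forcing$n_off != params$n_volumes)
        stop("n_on + n_off must equal n_volumes")
      # forcing stays on through the transient so the on-window is stationary
      c(rep(TRUE, params$discard + forcing$n_on), rep(FALSE, forcing$n_off))
    })
  guard <- 10 * max(1, sqrt(max(c(a, 0))))
  set.seed(seed)
  x0 <- runif(N, -0.1, 0.1)
  y0 <- runif(N, -0.1, 0.1)
  res <- sim_hopf_cpp(a, omega, params$beta, params$G,
                      unclass(as.matrix(coupling)), params$nu, params$dt,
                      params$sub, n_total, x0, y0, F0, wf, sched, guard,
                      params$shared_noise)
  if (isTRUE(res$diverged)) {
    cond <- structure(class = c("hopfwb_divergence", "error", "condition"),
                      list(message = sprintf(
                        "simulation diverged at volume %d, node %d (|z| > %.3g)",
                        res$volume, res$node, guard),
                        call = sys.call(), volume = res$volume,
                        node = res$node))
    stop(cond)
  }
  keep <- seq.int(params$discard + 1L, n_total)
  structure(list(x = res$x[, keep, drop = FALSE],
                 y = res$y[, keep, drop = FALSE],
                 TR = params$TR, seed = as.integer(seed),
                 forcing_on = sched[keep], params = params),
            class = "hopf_sim")
}

#' @export
print.hopf_sim <- function(x, ...) {
  cat(sprintf("<hopf_sim> %d nodes x %d volumes (TR = %g s), seed %d\n",
              nrow(x$x), ncol(x$x), x$TR, x$seed))
  invisible(x)
}

#' Estimate node-wise intrinsic frequencies from BOLD series
#'
#' Per node, the intrinsic angular frequency is `2*pi` times the location of
#' the periodogram peak within the analysis band. When several subjects are
#' supplied (a list of N x T matrices), their periodograms are averaged
#' before taking the peak, mirroring how empirical node frequencies are
#' averaged across participants.
#'
#' A node whose in-band spectrum is flat falls back to the band midpoint
#' with a warning. Flatness is judged against the white-noise null: with K
#' in-band bins averaged over S subjects, a genuinely peaked spectrum must
#' exceed `1 + (log(K) + 3) / sqrt(S)` times the in-band mean power (for
#' S = 1 this is roughly the 5% exceedance level of the maximum of K
#' independent exponential periodogram ordinates).
#'
#' @param bold N x T matrix of node time series, or a list of such matrices
#'   (one per subject, same N).
#' @param TR sampling interval in seconds.
#' @param band analysis band in Hz; default the resting-state 0.008-0.08 Hz.
#' @return numeric vector of angular frequencies (rad/s) with attribute
#'   `"fallback"` marking nodes where the flat-spectrum fallback fired.
#' @export
estimate_node_frequencies <- function(bold, TR, band = c(0.008, 0.08)) {
  if (!is.list(bold)) bold <- list(as.matrix(bold))
  bold <- lapply(bold, as.matrix)
  Tn <- ncol(bold[[1L]])
  if (Tn < 16L) stop("time series too short for spectral estimation")
  if (any(vapply(bold, ncol, 1L) != Tn))
    stop("all subjects must have the same number of volumes")
  S <- length(bold)
  N <- nrow(bold[[1L]])
  freqs <- seq.int(0L, Tn - 1L) / (Tn * TR)
  inb <- which(freqs >= band[1] & freqs <= band[2])
  K <- length(inb)
  if (K < 3L) stop("fewer than 3 frequency bins in band: series too short")
  pool <- matrix(0, N, K)
  for (b in bold) {
    for (i in seq_len(N)) {
      v <- b[i, ] - mean(b[i, ])
      pool[i, ] <- pool[i, ] + Mod(fft(v))[inb]^2
    }
  }
  thr <- 1 + (log(K) + 3) / sqrt(S)
  fallback <- logical(N)
  om <- numeric(N)
  for (i in seq_len(N)) {
    p <- pool[i, ]
    if (mean(p) <= 0 || max(p) < thr * mean(p)) {
      fallback[i] <- TRUE
      om[i] <- 2 * pi * mean(band)
    } else {
      om[i] <- 2 * pi * freqs[inb[which.max(p)]]
    }
  }
  if (any(fallback))
    warning(sum(fallback), " node(s) had a flat in-band spectrum; ",
            "falling back to the band midpoint")
  structure(om, fallback = fallback)
}
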