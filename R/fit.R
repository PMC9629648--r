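#' Dynamical regime presets
#'
#' The four canonical regimes of the model, identified by their bifurcation
#' parameter: `noise` (a = -1.3), `fluctuating` (a = -0.02, the subcritical
#' working regime), `supercritical_fluctuations` (a = 0.02) and `oscillatory`
#' (a = 1.3).
#'
#' @param label regime name.
#' @return list with `label` and `a`.
#' @export
regime_spec <- function(label = c("fluctuating", "noise",
                                  "supercritical_fluctuations",
                                  "oscillatory")) {
  label <- match.arg(label)
  a <- c(noise = -1.3, fluctuating = -0.02,
         supercritical_fluctuations = 0.02, oscillatory = 1.3)[[label]]
  list(label = label, a = a)
}

#' Published (G, beta) exploration grids
#'
#' Named presets for the exhaustive parameter-space explorations: fine-scale
#' (1000-node) supercritical and noise/subcritical grids, coarse-scale
#' (68-node) supercritical and subcritical grids, and the extended coarse
#' grid. The printed fine supercritical coupling range 0.13-0.22 is only
#' consistent with a 0.01 coupling step, which is what the preset uses.
#'
#' @param name preset name.
#' @return list with numeric vectors `G` and `beta`.
#' @export
grid_preset <- function(name = c("coarse_subcritical", "coarse_supercritical",
                                 "coarse_extended", "fine_subcritical",
                                 "fine_supercritical")) {
  switch(match.arg(name),
    fine_supercritical = list(G = seq(0.13, 0.22, by = 0.01),
                              beta = seq(1.7, 2.5, by = 0.1)),
    fine_subcritical = list(G = seq(0.45, 1.8, by = 0.15),
                            beta = seq(0, 0.8, by = 0.1)),
    coarse_subcritical = list(G = seq(0, 3.4, by = 0.2),
                              beta = seq(0, 1, by = 0.2)),
    coarse_supercritical = list(G = seq(0.1, 0.5, by = 0.02),
                                beta = seq(1.9, 2.4, by = 0.1)),
    coarse_extended = list(G = seq(0, 3.4, by = 0.2),
                           beta = seq(0, 2.4, by = 0.2)))
}

#' Fit the whole-brain Hopf model on a (G, beta) grid
#'
#' Exhaustive exploration of the coupling/shear parameter plane for one
#' regime. Every cell runs `n_sims` simulations matched in length and
#' sampling rate to the empirical reference, and averages the fitting
#' observables. The optimal working point minimizes the amplitude-turbulence
#' error `eD` in `mode = "fine"` or the metastability error `eM` in
#' `mode = "coarse"` -- never the FC error, which is reported alongside.
#' Ties break towards lower `G`, then lower `beta`. Cells where any
#' simulation diverges are flagged and excluded from the optimum with a
#' warning.
#'
#' All cells share one per-simulation seed stream (common random numbers):
#' enlarging the grid never changes existing cells, and cell-to-cell
#' comparisons -- the argmin -- are made under identical noise and initial
#' conditions, which sharpens the optimum considerably when the error
#' surface is shallow.
#'
#' @param empirical list of reference observables: `D` (fine) or `M`
#'   (coarse), and `fc`; [make_pseudo_empirical()] returns a suitable list,
#'   as does [compute_observables()] on real data.
#' @param coupling N x N [coupling_matrix()] used in the dynamics.
#' @param a bifurcation parameter (scalar or per node), or a regime label
#'   understood by [regime_spec()].
#' @param omega per-node intrinsic angular frequencies (rad/s), typically
#'   estimated from the reference data with [estimate_node_frequencies()].
#' @param grid list with numeric vectors `G` and `beta` (see
#'   [grid_preset()]).
#' @param mode `"coarse"` fits metastability, `"fine"` fits amplitude
#'   turbulence (requires `weights`).
#' @param n_sims simulations per grid cell.
#' @param n_volumes,TR simulation length and sampling interval; default
#'   taken from `empirical` when present, else 400 volumes at 0.72 s.
#' @param nu noise standard deviation.
#' @param weights local-synchronization weights ([edr_kernel()]) for
#'   turbulence; required in fine mode.
#' @param band analysis band (Hz).
#' @param omega_sampler optional `function(seed)` returning per-simulation
#'   intrinsic frequencies (rad/s). With multi-subject reference data the
#'   per-subject frequency variability is part of the generative law; letting
#'   every fitting simulation draw its own frequencies from that law keeps
#'   the simulated observables distributionally matched to the reference.
#' @param seed master seed.
#' @return object of class `"hopf_fit"`: a list with the per-cell results
#'   table `grid` (columns `G`, `beta`, the fitted error, FC metrics,
#'   `diverged`), the `optimum` row, and the fitting context. Methods:
#'   [print.hopf_fit()], [summary.hopf_fit()], [coef.hopf_fit()],
#'   [plot.hopf_fit()], [simulate.hopf_fit()].
#' @export
hopf_fit <- function(empirical, coupling, a, omega,
                     grid = grid_preset("coarse_subcritical"),
                     mode = c("coarse", "fine"), n_sims = 10,
                     n_volumes = NULL, TR = NULL, nu = 0.01, weights = NULL,
                     band = c(0.008, 0.08), omega_sampler = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (is.character(a)) a <- regime_spec(a)$a
  if (mode == "fine" && is.null(weights))
    stop("fine mode (turbulence fitting) requires local weights")
  ref <- if (mode == "fine") empirical$D else empirical$M
  if (is.null(ref))
    stop("empirical reference ", if (mode == "fine") "D" else "M",
         " is missing")
  if (is.null(empirical$fc)) stop("empirical reference fc is missing")
  n_volumes <- n_volumes %||% empirical$n_volumes %||% 400L
  TR <- TR %||% empirical$TR %||% 0.72
  cells <- expand.grid(G = grid$G, beta = grid$beta, KEEP.OUT.ATTRS = FALSE)
  # per-sim frequency draws, shared across cells (common random numbers)
  omega_sims <- lapply(seq_len(n_sims), function(s) {
    if (is.null(omega_sampler)) omega
    else omega_sampler(derive_seed(seed, 600000L + s))
  })
  res <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    G <- cells$G[ci]; beta <- cells$beta[ci]
    err <- efc <- efc_raw <- corrfc <- ssimfc <- numeric(n_sims)
    diverged <- FALSE
    for (s in seq_len(n_sims)) {
      pars <- model_params(a = a, omega = omega_sims[[s]], beta = beta,
                           G = G, nu = nu, TR = TR, n_volumes = n_volumes)
      sim <- tryCatch(
        simulate_hopf(pars, coupling, seed = derive_seed(seed, s)),
        hopfwb_divergence = function(e) e)
      if (inherits(sim, "condition")) { diverged <- TRUE; break }
      obs <- compute_observables(sim, band = band, weights = weights)
      err[s] <- if (mode == "fine") turbulence_error(obs$D, ref)
                else metastability_error(obs$M, ref)
      fm <- fc_metrics(obs$fc, empirical$fc)
      efc[s] <- fm$eFC; efc_raw[s] <- fm$eFC_raw
      corrfc[s] <- fm$corrFC; ssimfc[s] <- fm$ssimFC
    }
    res[[ci]] <- data.frame(
      G = G, beta = beta,
      err = if (diverged) NA_real_ else mean(err),
      eFC = if (diverged) NA_real_ else mean(efc),
      eFC_raw = if (diverged) NA_real_ else mean(efc_raw),
      corrFC = if (diverged) NA_real_ else mean(corrfc),
      ssimFC = if (diverged) NA_real_ else mean(ssimfc),
      diverged = diverged)
  }
  tab <- do.call(rbind, res)
  names(tab)[names(tab) == "err"] <- if (mode == "fine") "eD" else "eM"
  if (any(tab$diverged))
    warning(sum(tab$diverged),
            " grid cell(s) diverged and were excluded from the optimum")
  ok <- which(!tab$diverged)
  if (!length(ok)) stop("all grid cells diverged")
  errcol <- tab[[if (mode == "fine") "eD" else "eM"]]
  best <- ok[order(errcol[ok], tab$G[ok], tab$beta[ok])][1L]
  structure(list(grid = tab, optimum = tab[best, , drop = FALSE],
                 mode = mode, metric = if (mode == "fine") "eD" else "eM",
                 a = a, omega = omega, nu = nu, TR = TR,
                 n_volumes = n_volumes, n_sims = n_sims, band = band,
                 weights = weights, coupling = coupling,
                 empirical = empirical, seed = seed),
            class = "hopf_fit")
}

#' @export
print.hopf_fit <- function(x, ...) {
  cat(sprintf(
    "<hopf_fit> %s-mode grid fit (%s), a = %s\n  %d cells x %d sims; optimum: G = %g, beta = %g (%s = %.4g)\n",
    x$mode, x$metric, paste(format(unique(x$a)), collapse = "/"),
    nrow(x$grid), x$n_sims, x$optimum$G, x$optimum$beta, x$metric,
    x$optimum[[x$metric]]))
  invisible(x)
}

#' Summary of a grid fit
#' @param object a `"hopf_fit"`.
#' @param ... unused.
#' @return the object, invisibly; prints the grid context and optimum.
#' @export
summary.hopf_fit <- function(object, ...) {
  cat(sprintf("Grid fit of the whole-brain Hopf model (%s mode)\n",
              object$mode))
  cat(sprintf("  bifurcation parameter a: %s\n",
              paste(format(unique(object$a)), collapse = "/")))
  cat(sprintf("  grid: %d cells, %d simulations each (%d volumes, TR %g s)\n",
              nrow(object$grid), object$n_sims, object$n_volumes, object$TR))
  if (any(object$grid$diverged))
    cat(sprintf("  diverged cells: %d\n", sum(object$grid$diverged)))
  cat("  optimum (minimum ", object$metric, "):\n", sep = "")
  print(object$optimum, row.names = FALSE)
  invisible(object)
}

#' Optimal working point of a grid fit
#' @param object a `"hopf_fit"`.
#' @param ... unused.
#' @return named vector `c(G, beta, a)`.
#' @export
coef.hopf_fit <- function(object, ...) {
  c(G = object$optimum$G, beta = object$optimum$beta, a = object$a[1L])
}

#' Heat map of the fitting error over the (beta, G) plane
#' @param x a `"hopf_fit"`.
#' @param metric column of the grid table to display (default the fitted
#'   error).
#' @param ... passed to [graphics::image()].
#' @export
plot.hopf_fit <- function(x, metric = x$metric, ...) {
  g <- sort(unique(x$grid$G)); b <- sort(unique(x$grid$beta))
  z <- matrix(NA_real_, length(b), length(g))
  z[cbind(match(x$grid$beta, b), match(x$grid$G, g))] <- x$grid[[metric]]
  image(b, g, z, xlab = expression(beta), ylab = "G",
        main = sprintf("%s over the parameter plane", metric), ...)
  points(x$optimum$beta, x$optimum$G, pch = 8, cex = 2)
  invisible(x)
}

#' Simulate at the optimal working point
#'
#' Runs `nsim` fresh simulations of the fitted model at its optimum.
#'
#' @param object a `"hopf_fit"`.
#' @param nsim number of simulations.
#' @param seed master seed; defaults to the fit's seed.
#' @param ... unused.
#' @return list of `"hopf_sim"` objects (length `nsim`).
#' @export
simulate.hopf_fit <- function(object, nsim = 1, seed = NULL, ...) {
  seed <- seed %||% object$seed
  pars <- model_params(a = object$a, omega = object$omega,
                       beta = object$optimum$beta, G = object$optimum$G,
                       nu = object$nu, TR = object$TR,
                       n_volumes = object$n_volumes)
  lapply(seq_len(nsim), function(s) {
    simulate_hopf(pars, object$coupling, seed = derive_seed(seed, 990000 + s))
  })
}

#' Working-point parameters of a fit
#'
#' Builds the [model_params()] of a fitted (or manually chosen) working
#' point.
#'
#' @param object a `"hopf_fit"`, or a list with `a`, `omega`, `G`, `beta`
#'   (and optionally `nu`, `TR`, `n_volumes`).
#' @param n_volumes optional override of the output length.
#' @return a `"model_params"`.
#' @export
working_point <- function(object, n_volumes = NULL) {
  if (inherits(object, "hopf_fit")) {
    model_params(a = object$a, omega = object$omega,
                 beta = object$optimum$beta, G = object$optimum$G,
                 nu = object$nu, TR = object$TR,
                 n_volumes = n_volumes %||% object$n_volumes)
  } else {
    model_params(a = object$a, omega = object$omega, beta = object$beta,
                 G = object$G, nu = object$nu %||% 0.01,
                 TR = object$TR %||% 0.72,
                 n_volumes = n_volumes %||% object$n_volumes %||% 400L)
  }
}

#' Shear-inflated surrogate of a working point
#'
#' Copies a working point's parameters with the shear factor replaced.
#' Raising the shear is known to suppress turbulence, so these surrogates
#' serve as negative controls when comparing regimes (published values: 6 at
#' the fine 1000-node scale, 3 at the coarse 68-node scale).
#'
#' @param params a `"model_params"` (see [working_point()]).
#' @param beta_surrogate replacement shear value.
#' @return a `"model_params"` identical to `params` except for `beta`.
#' @export
surrogate_model <- function(params, beta_surrogate = 6) {
  stopifnot(inherits(params, "model_params"))
  params$beta <- beta_surrogate
  params
}

#' Compare fitted regimes at their working points
#'
#' For each named working point, runs `n_trials` trials of `n_sims`
#' simulations and records the trial-level mean of the fitted observable
#' (amplitude turbulence `D` in fine mode, metastability `M` in coarse mode)
#' and of the FC error. Regimes are then compared pairwise on the trial
#' means with two-sided Wilcoxon rank-sum tests.
#'
#' @param points named list of `"model_params"` (working points and
#'   surrogates, e.g. from [working_point()] and [surrogate_model()]).
#' @param coupling shared coupling matrix.
#' @param empirical reference observables (as in [hopf_fit()]); `fc`
#'   required, `D`/`M` used for the error columns when present.
#' @param mode `"coarse"` (metastability) or `"fine"` (turbulence;
#'   requires `weights`).
#' @param n_trials trials per regime (published protocol: 20).
#' @param n_sims simulations per trial (published protocol: 100).
#' @param weights local weights for fine mode.
#' @param band analysis band (Hz).
#' @param seed master seed.
#' @return list of class `"regime_comparison"`: `samples` (long table of
#'   trial means), `table` (per-regime summary), `pairwise` (list of p-value
#'   matrices for the observable and the FC error).
#' @export
compare_regimes <- function(points, coupling, empirical,
                            mode = c("coarse", "fine"), n_trials = 20,
                            n_sims = 10, weights = NULL,
                            band = c(0.008, 0.08), seed = 1) {
  mode <- match.arg(mode)
  if (length(points) < 2L) stop("need at least 2 working points to compare")
  if (is.null(names(points)) || any(names(points) == ""))
    stop("working points must be named")
  if (n_trials < 2L) stop("need at least 2 trials for statistics")
  ref <- if (mode == "fine") empirical$D else empirical$M
  rows <- list()
  # regimes share the per-(trial, sim) seed stream: identical working points
  # give identical samples, and contrasts benefit from common random numbers
  for (ri in seq_along(points)) {
    pars <- points[[ri]]
    for (tr in seq_len(n_trials)) {
      obs_v <- efc_v <- numeric(n_sims)
      for (s in seq_len(n_sims)) {
        sim <- simulate_hopf(pars, coupling,
                             seed = derive_seed(seed, (tr - 1) * n_sims + s))
        obs <- compute_observables(sim, band = band, weights = weights)
        obs_v[s] <- if (mode == "fine") obs$D else obs$M
        efc_v[s] <- fc_metrics(obs$fc, empirical$fc)$eFC
      }
      rows[[length(rows) + 1L]] <- data.frame(
        regime = names(points)[ri], trial = tr, value = mean(obs_v),
        err = if (is.null(ref)) NA_real_ else abs(mean(obs_v) - ref),
        eFC = mean(efc_v))
    }
  }
  samples <- do.call(rbind, rows)
  metric <- if (mode == "fine") "D" else "M"
  tab <- do.call(rbind, lapply(split(samples, samples$regime), function(d) {
    data.frame(regime = d$regime[1L], mean = mean(d$value), sd = sd(d$value),
               mean_err = mean(d$err), mean_eFC = mean(d$eFC))
  }))
  tab <- tab[match(names(points), tab$regime), ]
  rownames(tab) <- NULL
  pw <- function(col) {
    k <- length(points)
    p <- matrix(NA_real_, k, k, dimnames = list(names(points), names(points)))
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
      xi <- samples[[col]][samples$regime == names(points)[i]]
      xj <- samples[[col]][samples$regime == names(points)[j]]
      p[i, j] <- p[j, i] <-
        if (sd(c(xi, xj)) == 0) 1 # fully tied samples
        else suppressWarnings(wilcox.test(xi, xj, exact = FALSE)$p.value)
    }
    p
  }
  structure(list(samples = samples, table = tab, metric = metric,
                 pairwise = list(value = pw("value"), eFC = pw("eFC")),
                 n_trials = n_trials, n_sims = n_sims),
            class = "regime_comparison")
}

#' @export
print.regime_comparison <- function(x, ...) {
  cat(sprintf("<regime_comparison> %d regimes, %d trials x %d sims (metric %s)\n",
              nrow(x$table), x$n_trials, x$n_sims, x$metric))
  print(x$table, row.names = FALSE)
  cat("pairwise rank-sum p-values (", x$metric, "):\n", sep = "")
  print(signif(x$pairwise$value, 3))
  invisible(x)
}
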