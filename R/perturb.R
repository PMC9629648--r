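#' Paired perturbed/unperturbed trials
#'
#' Core sampling step of the strength-dependent perturbation protocols. For
#' each trial and simulation, the model is run twice from the same RNG seed:
#' once with the forcing and once without, so the two runs share noise and
#' initial conditions (a paired design; at `F0 = 0` the difference is
#' exactly zero). The recorded quantity is the time mean of the local
#' Kuramoto order parameter per node (`observable = "local"`) or of the
#' global order parameter (`"global"`), and the stored sample is the
#' per-trial mean over simulations of the perturbed-minus-unperturbed
#' difference.
#'
#' @param params a `"model_params"`.
#' @param coupling N x N coupling matrix.
#' @param forcing a sustained [forcing_spec()].
#' @param n_trials,n_sims trials and simulations per trial.
#' @param seed master seed; per-(trial, sim) seeds are derived from it.
#' @param observable `"global"` (scalar gR) or `"local"` (per-node R;
#'   requires `weights`).
#' @param weights local weights ([edr_kernel()]) for the local observable.
#' @param band,edge_trim phase-extraction settings.
#' @return list of class `"paired_samples"`: `delta` (n_trials x K matrix of
#'   per-trial mean differences, K = N for local, 1 for global), `per_sim`
#'   (n_trials x n_sims x K array for re-aggregation), `n_excluded`
#'   (diverged simulations), and the protocol settings.
#' @export
paired_trials <- function(params, coupling, forcing, n_trials, n_sims, seed,
                          observable = c("global", "local"), weights = NULL,
                          band = c(0.008, 0.08), edge_trim = 10) {
  observable <- match.arg(observable)
  if (forcing$schedule != "sustained")
    stop("paired_trials expects a sustained forcing schedule")
  if (observable == "local" && is.null(weights))
    stop("local observable requires weights")
  K <- if (observable == "local") nrow(coupling) else 1L
  off <- forcing_spec(F0 = 0, schedule = "off")
  per_sim <- array(NA_real_, c(n_trials, n_sims, K))
  n_excluded <- 0L
  static <- identical(forcing$F0, 0) || all(forcing$F0 == 0)
  obs_fun <- function(sim) {
    pf <- bandpass_phase(sim, band = band, edge_trim = edge_trim)
    if (observable == "local") rowMeans(local_kuramoto(pf, weights)$R)
    else mean(global_kuramoto(pf))
  }
  for (tr in seq_len(n_trials)) {
    for (s in seq_len(n_sims)) {
      sseed <- derive_seed(seed, (tr - 1L) * n_sims + s)
      if (static) {
        # zero forcing: perturbed and unperturbed runs are identical
        per_sim[tr, s, ] <- 0
        next
      }
      pert <- tryCatch(simulate_hopf(params, coupling, forcing, seed = sseed),
                       hopfwb_divergence = function(e) e)
      unpert <- tryCatch(simulate_hopf(params, coupling, off, seed = sseed),
                         hopfwb_divergence = function(e) e)
      if (inherits(pert, "condition") || inherits(unpert, "condition")) {
        n_excluded <- n_excluded + 1L
        next
      }
      per_sim[tr, s, ] <- obs_fun(pert) - obs_fun(unpert)
    }
  }
  if (n_excluded > 0L)
    warning(n_excluded, " diverged simulation(s) excluded")
  delta <- apply(per_sim, c(1L, 3L), mean, na.rm = TRUE)
  delta[!is.finite(delta)] <- NA_real_
  structure(list(delta = delta, per_sim = per_sim, observable = observable,
                 F0 = forcing$F0, n_trials = n_trials, n_sims = n_sims,
                 seed = seed, n_excluded = n_excluded),
            class = "paired_samples")
}

#' Susceptibility of the model to sustained forcing
#'
#' The mean shift of the (local or global) Kuramoto order parameter under
#' forcing, relative to paired unperturbed runs: the average over time,
#' trials and (in the local case) space of the perturbed-minus-unperturbed
#' order parameter.
#'
#' @param samples a `"paired_samples"` object from [paired_trials()].
#' @return scalar susceptibility.
#' @export
susceptibility <- function(samples) {
  stopifnot(inherits(samples, "paired_samples"))
  mean(samples$delta, na.rm = TRUE)
}

#' Information capability of the model under sustained forcing
#'
#' The across-trial standard deviation of the per-trial mean difference
#' between the perturbed and unperturbed order parameter, averaged over
#' space in the local case. It captures how variably (hence how richly)
#' external stimulation is encoded. The population convention (divide by the
#' number of trials) is the default; the sample convention is available.
#' The absolute information capability used in the protocols is
#' `|IC(F0) - IC(0)|`, which the paired design makes equal to `IC(F0)`
#' because `IC(0) = 0` by construction.
#'
#' @param samples a `"paired_samples"`.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return scalar information capability.
#' @export
information_capability <- function(samples,
                                   sd_type = c("population", "sample")) {
  stopifnot(inherits(samples, "paired_samples"))
  sd_type <- match.arg(sd_type)
  per_node <- apply(samples$delta, 2L, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L) return(NA_real_)
    if (sd_type == "population") sqrt(mean((v - mean(v))^2)) else sd(v)
  })
  mean(per_node, na.rm = TRUE)
}

# Shared engine of the amplitude-sweep protocols.
#
# Per repetition, one ensemble of unperturbed simulations is generated and
# reused as the paired reference for every forcing amplitude (each perturbed
# run shares its seed -- noise and initial conditions -- with an unperturbed
# run). Susceptibility at each F0 is the mean paired difference of the
# time-averaged order parameter; information capability is the across-trial
# population SD of the per-trial means of those paired differences. Both are
# exactly zero at F0 = 0, so the zero-forcing reference of the absolute
# information capability is zero and ic_abs coincides with the raw IC.
# When `omega_sampler` is given, each *trial* draws its own intrinsic
# frequencies (shared by all runs of the trial), emulating
# subject-to-subject variability; the forcing stays at the fixed average
# frequencies, so the across-trial SD also captures how differently detuned
# system instances encode the same stimulus.
sweep_engine <- function(params, coupling, F0_vec, F0_grid, reps, n_trials,
                         n_sims, observable, weights, omega_forcing,
                         omega_sampler, band, seed) {
  N <- nrow(coupling)
  K <- if (observable == "local") N else 1L
  if (observable == "local" && is.null(weights))
    stop("local observable requires weights")
  wf <- if (is.null(omega_forcing)) rep_len(params$omega, N)
        else rep_len(omega_forcing, N)
  off <- forcing_spec(F0 = 0, schedule = "off")
  obs_fun <- function(sim) {
    pf <- bandpass_phase(sim, band = band)
    if (observable == "local") rowMeans(local_kuramoto(pf, weights)$R)
    else mean(global_kuramoto(pf))
  }
  nF <- length(F0_grid)
  chi <- ic <- matrix(NA_real_, reps, nF)
  trial_deltas <- vector("list", reps)
  n_excluded <- 0L
  for (r in seq_len(reps)) {
    rseed <- derive_seed(seed, 7000L + r)
    g_u <- array(NA_real_, c(n_trials, n_sims, K))
    pars_tr <- vector("list", n_trials)
    for (tr in seq_len(n_trials)) {
      pars_tr[[tr]] <- params
      if (!is.null(omega_sampler))
        pars_tr[[tr]]$omega <- omega_sampler(derive_seed(rseed, 500000L + tr))
      for (k in seq_len(n_sims)) {
        su <- tryCatch(
          simulate_hopf(pars_tr[[tr]], coupling, off,
                        seed = derive_seed(rseed, (tr - 1L) * n_sims + k)),
          hopfwb_divergence = function(e) e)
        if (inherits(su, "condition")) { n_excluded <- n_excluded + 1L; next }
        g_u[tr, k, ] <- obs_fun(su)
      }
    }
    tl <- vector("list", nF)
    for (fi in seq_len(nF)) {
      F0 <- F0_grid[fi]
      if (F0 == 0) {
        # seed-paired: the zero-amplitude runs are the unperturbed runs
        chi[r, fi] <- 0
        ic[r, fi] <- 0
        tl[[fi]] <- matrix(0, n_trials, K)
        next
      }
      frc <- forcing_spec(F0 = F0_vec * F0, omega_forcing = wf)
      dp <- array(NA_real_, c(n_trials, n_sims, K))
      for (tr in seq_len(n_trials)) for (k in seq_len(n_sims)) {
        sp <- tryCatch(
          simulate_hopf(pars_tr[[tr]], coupling, frc,
                        seed = derive_seed(rseed, (tr - 1L) * n_sims + k)),
          hopfwb_divergence = function(e) e)
        if (inherits(sp, "condition")) { n_excluded <- n_excluded + 1L; next }
        dp[tr, k, ] <- obs_fun(sp) - g_u[tr, k, ]
      }
      chi[r, fi] <- mean(dp, na.rm = TRUE)
      ic[r, fi] <- ic_of(dp)
      tl[[fi]] <- apply(dp, c(1L, 3L), mean, na.rm = TRUE)
    }
    trial_deltas[[r]] <- tl
  }
  if (n_excluded > 0L)
    warning(n_excluded, " diverged simulation(s) excluded")
  list(chi = chi, ic = ic, trial_deltas = trial_deltas,
       n_excluded = n_excluded)
}

# across-trial population SD of per-trial means, space-averaged
ic_of <- function(d) {
  tm <- apply(d, c(1L, 3L), mean, na.rm = TRUE) # trials x K
  if (is.null(dim(tm))) tm <- matrix(tm, ncol = 1L)
  mean(apply(tm, 2L, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L) return(NA_real_)
    sqrt(mean((v - mean(v))^2))
  }), na.rm = TRUE)
}

#' Global strength-dependent sustained perturbation protocol
#'
#' Applies the external periodic forcing equally to all nodes, sweeping the
#' forcing amplitude over `F0_grid` (published protocol: 0 to 0.001 in steps
#' of 0.0001), and computes susceptibility and absolute information
#' capability per amplitude. The whole computation is repeated `reps` times
#' (published: 20) and the across-repetition mean and SD are reported.
#'
#' All runs are seed-paired: each perturbed simulation shares its noise and
#' initial conditions with an unperturbed simulation, so susceptibility and
#' information capability are exactly zero at `F0 = 0` and the absolute
#' information capability (referenced to zero forcing) coincides with the
#' raw across-trial standard deviation.
#'
#' @inheritParams paired_trials
#' @param F0_grid forcing amplitudes (should include 0, the reference).
#' @param reps independent repetitions of the whole sweep.
#' @param omega_forcing forcing angular frequencies: default the model's
#'   `omega` (each node forced at its average intrinsic frequency).
#' @param omega_sampler optional `function(seed)` returning intrinsic
#'   frequencies (rad/s), drawn once per trial and shared by all of that
#'   trial's runs; use it to emulate subject-to-subject frequency
#'   variability, which is the across-trial diversity the information
#'   capability measures. The forcing frequency stays at `omega_forcing`.
#' @return data.frame of class `"perturbation_response"` with columns `F0`,
#'   `chi`, `chi_sd`, `ic_abs`, `ic_abs_sd`; attribute `"trial_deltas"`
#'   keeps the per-rep, per-amplitude trial means for re-aggregation checks.
#' @export
run_global_protocol <- function(params, coupling,
                                F0_grid = seq(0, 0.001, by = 1e-4),
                                reps = 20, n_trials = 50, n_sims = 50,
                                observable = c("global", "local"),
                                weights = NULL, omega_forcing = NULL,
                                omega_sampler = NULL,
                                band = c(0.008, 0.08), seed = 1) {
  observable <- match.arg(observable)
  N <- nrow(coupling)
  eng <- sweep_engine(params, coupling, F0_vec = rep(1, N),
                      F0_grid = F0_grid, reps = reps, n_trials = n_trials,
                      n_sims = n_sims, observable = observable,
                      weights = weights, omega_forcing = omega_forcing,
                      omega_sampler = omega_sampler, band = band,
                      seed = seed)
  sd0 <- function(m) apply(m, 2L, function(v) if (length(v) > 1L) sd(v) else 0)
  out <- data.frame(F0 = F0_grid,
                    chi = colMeans(eng$chi), chi_sd = sd0(eng$chi),
                    ic_abs = colMeans(eng$ic), ic_abs_sd = sd0(eng$ic))
  class(out) <- c("perturbation_response", class(out))
  attr(out, "protocol") <- "global"
  attr(out, "reps") <- reps
  attr(out, "trial_deltas") <- eng$trial_deltas
  attr(out, "n_excluded") <- eng$n_excluded
  out
}

#' Local strength-dependent sustained perturbation protocol
#'
#' Forces one homotopic node pair at a time, sweeping the forcing amplitude
#' (published protocol: 0 to 0.02), and computes the global-order-parameter
#' susceptibility and absolute information capability per pair and
#' amplitude. The ranking of pairs by susceptibility at `reference_F0`
#' defines the perturbative node hierarchy.
#'
#' @inheritParams run_global_protocol
#' @param pairs 2-column integer matrix of node pairs
#'   (see [homotopic_pairs()]).
#' @param reference_F0 amplitude at which the hierarchy is read out.
#' @return data.frame of class `"perturbation_response"` with columns
#'   `pair`, `node_left`, `node_right`, `F0`, `chi`, `ic_abs`; attribute
#'   `"hierarchy"` holds the pair ranking at `reference_F0`.
#' @export
run_local_protocol <- function(params, coupling, pairs,
                               F0_grid = seq(0, 0.02, by = 0.001),
                               n_trials = 50, n_sims = 100,
                               observable = c("global", "local"),
                               weights = NULL, omega_forcing = NULL,
                               omega_sampler = NULL, reference_F0 = 0.01,
                               band = c(0.008, 0.08), seed = 1) {
  observable <- match.arg(observable)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L) stop("empty pair list")
  N <- nrow(coupling)
  rows <- list()
  for (m in seq_len(nrow(pairs))) {
    F0_vec <- numeric(N)
    F0_vec[pairs[m, ]] <- 1
    eng <- sweep_engine(params, coupling, F0_vec = F0_vec,
                        F0_grid = F0_grid, reps = 1L, n_trials = n_trials,
                        n_sims = n_sims, observable = observable,
                        weights = weights, omega_forcing = omega_forcing,
                        omega_sampler = omega_sampler, band = band,
                        seed = derive_seed(seed, 3000L + m))
    rows[[length(rows) + 1L]] <- data.frame(
      pair = m, node_left = unname(pairs[m, 1L]),
      node_right = unname(pairs[m, 2L]),
      F0 = F0_grid, chi = unname(eng$chi[1L, ]),
      ic_abs = unname(eng$ic[1L, ]))
  }
  out <- do.call(rbind, rows)
  ref <- out[abs(out$F0 - reference_F0) ==
               min(abs(out$F0 - reference_F0)), ]
  ref <- ref[!duplicated(ref$pair), ]
  hier <- ref$pair[order(ref$chi, decreasing = TRUE)]
  class(out) <- c("perturbation_response", class(out))
  attr(out, "protocol") <- "local"
  attr(out, "hierarchy") <- hier
  attr(out, "reference_F0") <- reference_F0
  out
}
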