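#' Specification for the synthetic-data generator
#'
#' Bundles the parameters of the synthetic study: a bilateral parcellation
#' on a hemispheric shell, an EDR-plus-long-range coupling, and
#' pseudo-empirical BOLD generated at a known ground-truth working point.
#' Defaults emulate the coarse 68-node study conditions: subcritical
#' fluctuating regime `a = -0.02` at `(G, beta) = (2.2, 0)` (the coarse
#' working point of the fitted model), node frequencies drawn around
#' 0.05 Hz (SD 0.005 Hz) inside the 0.008-0.08 Hz band, TR = 0.72 s, and a
#' desk-scale run length of 400 volumes for 10 subjects.
#'
#' @param N even number of nodes.
#' @param radius shell radius in mm (70 mm, human-cortex scale).
#' @param lambda_decay EDR decay (0.18 /mm).
#' @param n_long_range number of random long-range additions.
#' @param a,G,beta ground-truth regime parameters.
#' @param nu noise SD.
#' @param f_mean,f_sd node peak-frequency distribution in Hz.
#' @param TR sampling interval (s).
#' @param n_volumes volumes per subject.
#' @param n_subjects number of pseudo-subjects.
#' @param seed master seed.
#' @return list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(N = 68, radius = 70, lambda_decay = 0.18,
                           n_long_range = 40, a = -0.02, G = 2.2, beta = 0,
                           nu = 0.01, f_mean = 0.05, f_sd = 0.005, TR = 0.72,
                           n_volumes = 400, n_subjects = 10, seed = 1) {
  if (N %% 2L != 0L) stop("N must be even (bilateral parcellation)")
  if (f_mean < 0.008 || f_mean > 0.08)
    stop("mean node frequency must lie in the 0.008-0.08 Hz band")
  structure(list(N = as.integer(N), radius = radius,
                 lambda_decay = lambda_decay,
                 n_long_range = as.integer(n_long_range), a = a, G = G,
                 beta = beta, nu = nu, f_mean = f_mean, f_sd = f_sd, TR = TR,
                 n_volumes = as.integer(n_volumes),
                 n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Synthetic bilateral parcellation
#'
#' Samples N/2 region centroids on a right-hemisphere shell (radius jittered
#' by 10% for realism) and mirrors them across the midline (x -> -x) to
#' create exact homotopic pairs. Region names are shared across hemispheres;
#' network labels come from a spatial k-means of the right-hemisphere
#' coordinates into the seven canonical resting-state networks, mirrored to
#' the left so pairs share a network.
#'
#' @param spec a [synthetic_spec()].
#' @return a `"parcellation"` with rows 1..N/2 left, N/2+1..N right.
#' @export
make_parcellation <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$seed, 11L))
  half <- spec$N %/% 2L
  dir <- matrix(rnorm(3L * half), half, 3L)
  dir <- dir / sqrt(rowSums(dir^2))
  dir[, 1L] <- abs(dir[, 1L]) # right hemisphere: x > 0
  r <- spec$radius * runif(half, 0.9, 1.1)
  right <- dir * r
  left <- right
  left[, 1L] <- -left[, 1L]
  nets <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic", "Cont",
            "Default")
  k <- min(7L, half)
  cl <- kmeans(right, centers = k, nstart = 5L)$cluster
  nm <- sprintf("region%03d", seq_len(half))
  as_parcellation(data.frame(
    name = c(nm, nm), hemi = rep(c("L", "R"), each = half),
    x = c(left[, 1L], right[, 1L]), y = c(left[, 2L], right[, 2L]),
    z = c(left[, 3L], right[, 3L]), network = rep(nets[cl], 2L)))
}

#' Synthetic EDR-plus-long-range coupling
#'
#' Exponential-distance-rule kernel at the spec's decay rate plus
#' `n_long_range` random symmetric long-range additions drawn among the
#' top-distance-quartile node pairs, with weights uniform in
#' `[cap/2, cap]` (cap 0.2, the structural-connectivity normalization
#' maximum). Optionally adds `modular_weight` to every within-network pair,
#' giving a modular connectome for network-specificity experiments.
#'
#' @param spec a [synthetic_spec()].
#' @param parc parcellation from [make_parcellation()].
#' @param modular_weight extra within-network coupling (default 0).
#' @param cap maximum long-range weight.
#' @return a `"coupling_matrix"` of kind `"EDR_LR"`; attribute `"lr_pairs"`
#'   lists the added pairs.
#' @export
make_coupling <- function(spec, parc, modular_weight = 0, cap = 0.2) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$seed, 22L))
  d <- euclidean_distances(parc)
  w <- exp(-spec$lambda_decay * d)
  diag(w) <- 0
  ut <- which(upper.tri(d), arr.ind = TRUE)
  q75 <- quantile(d[upper.tri(d)], 0.75)
  cand <- ut[d[ut] > q75, , drop = FALSE]
  n_lr <- min(spec$n_long_range, nrow(cand))
  lr_pairs <- NULL
  if (n_lr > 0L) {
    pick <- cand[sample.int(nrow(cand), n_lr), , drop = FALSE]
    wts <- runif(n_lr, cap / 2, cap)
    for (i in seq_len(n_lr)) {
      w[pick[i, 1L], pick[i, 2L]] <- w[pick[i, 1L], pick[i, 2L]] + wts[i]
      w[pick[i, 2L], pick[i, 1L]] <- w[pick[i, 2L], pick[i, 1L]] + wts[i]
    }
    lr_pairs <- cbind(pick, weight = wts)
  }
  if (modular_weight > 0) {
    nets <- as.data.frame(parc)$network
    if (is.null(nets)) stop("modular coupling requires network labels")
    same <- outer(nets, nets, "==")
    diag(same) <- FALSE
    w <- w + modular_weight * same
  }
  out <- coupling_matrix(w, kind = "EDR_LR",
                         lambda_decay = spec$lambda_decay, cap = cap)
  attr(out, "lr_pairs") <- lr_pairs
  out
}

#' Pseudo-empirical BOLD and reference observables
#'
#' Runs the simulator at the ground-truth working point once per synthetic
#' subject (per-subject node frequencies drawn from the spec's distribution,
#' truncated to the analysis band) and returns the per-subject BOLD together
#' with the pooled reference observables used by the fitting stage:
#' amplitude turbulence `D` and metastability `M` averaged across subjects
#' (per-subject-then-average convention) and the subject-mean functional
#' connectivity. Node frequencies re-estimated from the generated BOLD are
#' returned as `omega` for use in fitting, mirroring how empirical
#' frequencies seed the model.
#'
#' @param spec a [synthetic_spec()].
#' @param parc parcellation.
#' @param coupling coupling matrix.
#' @param band analysis band (Hz).
#' @return list with `bold` (list of N x T matrices), `D`, `M`, `fc`,
#'   `omega` (estimated from the BOLD, rad/s), `omega_bar` (the generative
#'   node-mean frequencies, for recovery experiments that isolate the
#'   fitted parameters from frequency-estimation error), `omega_true`
#'   (per-subject list), `D_subj`, `M_subj`, `n_volumes`, `TR`, and the
#'   ground truth `a`, `G`, `beta`.
#' @export
make_pseudo_empirical <- function(spec, parc, coupling,
                                  band = c(0.008, 0.08)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  d <- euclidean_distances(parc)
  wk <- edr_kernel(d, spec$lambda_decay)
  bold <- vector("list", spec$n_subjects)
  omega_true <- vector("list", spec$n_subjects)
  D_subj <- M_subj <- numeric(spec$n_subjects)
  fcs <- 0
  for (k in seq_len(spec$n_subjects)) {
    set.seed(derive_seed(spec$seed, 100L + k))
    f <- rnorm(spec$N, spec$f_mean, spec$f_sd)
    f <- pmin(pmax(f, band[1] + 1e-4), band[2] - 1e-4)
    omega_true[[k]] <- 2 * pi * f
    pars <- model_params(a = spec$a, omega = omega_true[[k]],
                         beta = spec$beta, G = spec$G, nu = spec$nu,
                         TR = spec$TR, n_volumes = spec$n_volumes)
    sim <- simulate_hopf(pars, coupling,
                         seed = derive_seed(spec$seed, 200L + k))
    bold[[k]] <- sim$x
    obs <- compute_observables(sim, band = band, weights = wk)
    D_subj[k] <- obs$D
    M_subj[k] <- obs$M
    fcs <- fcs + obs$fc
  }
  omega_hat <- estimate_node_frequencies(bold, spec$TR, band)
  list(bold = bold, D = mean(D_subj), M = mean(M_subj),
       fc = fcs / spec$n_subjects, omega = as.numeric(omega_hat),
       omega_bar = Reduce(`+`, omega_true) / spec$n_subjects,
       omega_true = omega_true, D_subj = D_subj, M_subj = M_subj,
       n_volumes = spec$n_volumes, TR = spec$TR, a = spec$a, G = spec$G,
       beta = spec$beta)
}

#' Synthetic regional heterogeneity maps
#'
#' Spatially smooth node maps emulating regional heterogeneity data such as
#' the T1w:T2w (myelination) ratio or the first principal component of
#' regional gene expression. Each map is a mixture
#' `rho * scale(SCstrength) + sqrt(1 - rho^2) * g`, where `g` is a draw from
#' a Gaussian process over the node coordinates with exponential covariance
#' (length scale `ell` mm), so `rho` sets the expected correlation with the
#' structural node strength.
#'
#' @param spec a [synthetic_spec()].
#' @param parc parcellation.
#' @param coupling coupling matrix (for SC strength).
#' @param rho correlations with SC strength for the two maps (recycled).
#' @param ell GP length scale in mm.
#' @return data.frame with columns `t1t2` and `gene_pc1`.
#' @export
make_heterogeneity <- function(spec, parc, coupling, rho = c(0.5, 0.3),
                               ell = 30) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$seed, 33L))
  rho <- rep_len(rho, 2L)
  stopifnot(all(abs(rho) <= 1))
  d <- euclidean_distances(parc)
  K <- exp(-d / ell) + diag(1e-8, nrow(d))
  Lc <- chol(K)
  scs <- as.numeric(scale(rowSums(as.matrix(coupling))))
  draw <- function(r) {
    g <- as.numeric(scale(crossprod(Lc, rnorm(nrow(d)))))
    r * scs + sqrt(1 - r^2) * g
  }
  data.frame(t1t2 = draw(rho[1L]), gene_pc1 = draw(rho[2L]))
}
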