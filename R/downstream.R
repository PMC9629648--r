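#' Node strength maps
#'
#' `SCstrength(n) = sum_p C_np` (row sums of the structural coupling) and
#' `FCstrength(n) = sum_p FC_np` excluding the unit diagonal -- the latter
#' also known as global brain connectivity (GBC).
#'
#' @param coupling N x N coupling matrix (optional).
#' @param fc N x N functional-connectivity matrix (optional).
#' @return data.frame with the available columns `sc_strength`,
#'   `fc_strength`.
#' @export
strength_maps <- function(coupling = NULL, fc = NULL) {
  if (is.null(coupling) && is.null(fc))
    stop("supply at least one of coupling, fc")
  out <- list()
  if (!is.null(coupling)) out$sc_strength <- rowSums(as.matrix(coupling))
  if (!is.null(fc)) {
    f <- as.matrix(fc)
    out$fc_strength <- rowSums(f) - diag(f)
  }
  as.data.frame(out)
}

#' Resting-state-network modulation under local sustained forcing
#'
#' For each perturbed homotopic pair, runs paired perturbed/unperturbed
#' simulations (shared seeds) at a fixed forcing amplitude (published
#' protocol: `F0 = 0.01`), computes the functional connectivity of each run,
#' and summarizes the mean within-network FC -- the mean over off-diagonal
#' FC entries among each network's nodes -- for the perturbed and
#' unperturbed case. Per network, perturbed and unperturbed per-simulation
#' samples are compared with a two-sided Wilcoxon rank-sum test.
#'
#' @param params working-point `"model_params"`.
#' @param coupling N x N coupling matrix.
#' @param parc parcellation with a `network` column labelling every node.
#' @param pairs 2-column matrix of node pairs to perturb; default all
#'   homotopic pairs of `parc`.
#' @param F0 forcing amplitude.
#' @param n_sims paired simulations per pair.
#' @param band analysis band (Hz).
#' @param seed master seed.
#' @return list of class `"rsn_modulation"`: `table` with one row per
#'   (pair, network) holding mean perturbed/unperturbed within-network FC,
#'   their `diff`, and the rank-sum `p`; `samples` (per-sim values);
#'   `networks`; `F0`.
#' @export
rsn_modulation <- function(params, coupling, parc, pairs = NULL, F0 = 0.01,
                           n_sims = 10, band = c(0.008, 0.08), seed = 1) {
  parc <- as_parcellation(as.data.frame(parc))
  if (is.null(parc$network) || anyNA(parc$network))
    stop("every node must carry a network label")
  if (is.null(pairs)) pairs <- homotopic_pairs(parc)
  pairs <- as.matrix(pairs)
  nets <- sort(unique(parc$network))
  members <- lapply(nets, function(nw) which(parc$network == nw))
  names(members) <- nets
  N <- nrow(coupling)
  within_fc <- function(fc) {
    vapply(members, function(idx) {
      if (length(idx) < 2L) return(NA_real_)
      sub <- fc[idx, idx]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
  }
  rows <- list(); samp <- list()
  for (m in seq_len(nrow(pairs))) {
    frc <- forcing_nodes(pairs[m, ], F0, N)
    off <- forcing_spec(F0 = 0, schedule = "off")
    wp <- wu <- matrix(NA_real_, n_sims, length(nets),
                       dimnames = list(NULL, nets))
    for (s in seq_len(n_sims)) {
      sseed <- derive_seed(seed, m * 1000L + s)
      simp <- simulate_hopf(params, coupling, frc, seed = sseed)
      simu <- simulate_hopf(params, coupling, off, seed = sseed)
      fcp <- functional_connectivity(
        bandpass_phase(simp, band = band)$filtered)
      fcu <- functional_connectivity(
        bandpass_phase(simu, band = band)$filtered)
      wp[s, ] <- within_fc(fcp)
      wu[s, ] <- within_fc(fcu)
    }
    for (k in seq_along(nets)) {
      p <- if (sd(c(wp[, k], wu[, k])) == 0) 1
           else suppressWarnings(wilcox.test(wp[, k], wu[, k],
                                             exact = FALSE)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = m, node_left = pairs[m, 1L], node_right = pairs[m, 2L],
        network = nets[k], fc_pert = mean(wp[, k]), fc_unpert = mean(wu[, k]),
        diff = mean(wp[, k] - wu[, k]), p = p)
    }
    samp[[m]] <- list(pert = wp, unpert = wu)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, samples = samp,
                 networks = nets, pairs = pairs, F0 = F0, n_sims = n_sims),
            class = "rsn_modulation")
}

#' @export
print.rsn_modulation <- function(x, ...) {
  cat(sprintf("<rsn_modulation> %d pairs x %d networks at F0 = %g\n",
              nrow(x$pairs), length(x$networks), x$F0))
  agg <- stats::aggregate(diff ~ network, data = x$table, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Network specificity of a stimulation
#'
#' Per-network perturbed-minus-unperturbed within-network FC profile for one
#' perturbed pair, normalized by its maximum absolute value so the most
#' modulated network scores 1 in magnitude. Networks in the top 15% of the
#' profile are flagged.
#'
#' @param mod an `"rsn_modulation"`.
#' @param pair which perturbed pair to profile (default 1).
#' @return data.frame with `network`, `diff`, `profile` (normalized) and
#'   `top15` (logical).
#' @export
network_specificity <- function(mod, pair = 1) {
  stopifnot(inherits(mod, "rsn_modulation"))
  d <- mod$table[mod$table$pair == pair, c("network", "diff")]
  mx <- max(abs(d$diff))
  d$profile <- if (mx > 0) d$diff / mx else rep(0, nrow(d))
  d$top15 <- d$profile >= quantile(d$profile, 0.85)
  rownames(d) <- NULL
  d
}

#' Correlate a perturbative node hierarchy with heterogeneity maps
#'
#' Pairwise correlation (Pearson by default, Spearman available) of the
#' node-level PCI against every other numeric column of the hierarchy table
#' (susceptibility, information capability, SC/FC strength, T1w:T2w ratio,
#' gene-expression PC1, ...), with the test p-value per column. Missing
#' columns are simply absent from the output; rows with missing values are
#' dropped per comparison.
#'
#' @param table data.frame with one row per node and a `pci` column plus any
#'   other numeric columns.
#' @param method `"pearson"` or `"spearman"`.
#' @return data.frame with `variable`, `r`, `p`, `n`.
#' @export
hierarchy_correlations <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(table))
  if (is.null(table$pci)) stop("hierarchy table needs a 'pci' column")
  vars <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], "pci")
  if (!length(vars)) stop("no numeric columns to correlate against pci")
  rows <- lapply(vars, function(v) {
    ok <- is.finite(table$pci) & is.finite(table[[v]])
    if (sum(ok) < 3L)
      return(data.frame(variable = v, r = NA_real_, p = NA_real_,
                        n = sum(ok)))
    ct <- suppressWarnings(cor.test(table$pci[ok], table[[v]][ok],
                                    method = method, exact = FALSE))
    data.frame(variable = v, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok))
  })
  do.call(rbind, rows)
}
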