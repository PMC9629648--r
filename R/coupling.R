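#' Coupling matrix constructor
#'
#' Internal-facing constructor that validates and tags an N x N coupling
#' matrix. All coupling matrices in this package are symmetric, nonnegative
#' and have a zero diagonal; `kind` records the provenance: pure exponential
#' distance rule (`"EDR"`), EDR plus long-range structural connections
#' (`"EDR_LR"`), or normalized structural connectivity (`"SC"`).
#'
#' @param weights numeric N x N matrix.
#' @param kind one of `"EDR"`, `"EDR_LR"`, `"SC"`.
#' @param lambda_decay exponential decay rate in 1/mm (EDR kinds).
#' @param cap normalization maximum (SC kind).
#' @return the matrix with class `"coupling_matrix"` and attributes `kind`,
#'   `lambda_decay`, `cap`.
#' @export
coupling_matrix <- function(weights, kind = c("EDR", "EDR_LR", "SC"),
                            lambda_decay = NA_real_, cap = NA_real_) {
  kind <- match.arg(kind)
  w <- as.matrix(weights)
  if (nrow(w) != ncol(w)) stop("coupling matrix must be square")
  if (any(!is.finite(w))) stop("non-finite coupling weights")
  if (any(w < 0)) stop("coupling weights must be nonnegative")
  if (max(abs(w - t(w))) > 1e-12) stop("coupling matrix must be symmetric")
  if (any(diag(w) != 0)) stop("coupling matrix must have zero diagonal")
  structure(w, class = c("coupling_matrix", "matrix", "array"),
            kind = kind, lambda_decay = lambda_decay, cap = cap)
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf("<coupling_matrix> %d x %d, kind = %s", nrow(x), ncol(x),
              attr(x, "kind")))
  if (is.finite(attr(x, "lambda_decay")))
    cat(sprintf(", lambda = %g /mm", attr(x, "lambda_decay")))
  if (is.finite(attr(x, "cap")))
    cat(sprintf(", cap = %g", attr(x, "cap")))
  cat(sprintf("\n  weights: max %.4g, density %.2f\n", max(x),
              mean(x[upper.tri(x)] > 0)))
  invisible(x)
}

#' Exponential distance rule coupling
#'
#' Off-diagonal weights decay exponentially with inter-node distance,
#' `w_ij = exp(-lambda * r_ij)`; the diagonal is zero. The decay constant
#' default, 0.18 /mm, is the value fitted on human cortical connectivity in
#' the turbulence literature this model builds on.
#'
#' @param dist N x N distance matrix in mm (see [euclidean_distances()]).
#' @param lambda_decay decay rate in 1/mm, must be positive.
#' @return a `"coupling_matrix"` of kind `"EDR"`.
#' @export
edr_coupling <- function(dist, lambda_decay = 0.18) {
  if (!is.numeric(lambda_decay) || length(lambda_decay) != 1L ||
      !is.finite(lambda_decay) || lambda_decay <= 0)
    stop("lambda_decay must be a positive scalar")
  d <- as.matrix(dist)
  w <- exp(-lambda_decay * d)
  diag(w) <- 0
  w <- (w + t(w)) / 2 # guard against asymmetric rounding in `dist`
  coupling_matrix(w, kind = "EDR", lambda_decay = lambda_decay)
}

#' EDR kernel for local-synchronization weighting
#'
#' Same exponential kernel as [edr_coupling()] but keeping the diagonal at
#' `exp(0) = 1`, so a node's own phase participates in its local Kuramoto
#' order parameter. This is the weighting used when measuring amplitude
#' turbulence; the zero-diagonal [edr_coupling()] is what enters the
#' dynamics.
#'
#' @inheritParams edr_coupling
#' @return symmetric N x N matrix with unit diagonal.
#' @export
edr_kernel <- function(dist, lambda_decay = 0.18) {
  if (lambda_decay <= 0) stop("lambda_decay must be positive")
  exp(-lambda_decay * as.matrix(dist))
}

#' Normalize a structural connectivity matrix
#'
#' Rescales a raw (e.g. tractography streamline-count) matrix so its maximum
#' equals `cap`, symmetrizes it by the arithmetic mean, and zeroes the
#' diagonal. The default cap of 0.2 follows the convention of normalising
#' whole-brain structural connectomes to a maximum of 0.2.
#'
#' @param raw_sc nonnegative square matrix.
#' @param cap target maximum weight.
#' @return a `"coupling_matrix"` of kind `"SC"`.
#' @export
normalize_sc <- function(raw_sc, cap = 0.2) {
  w <- as.matrix(raw_sc)
  if (any(w < 0)) stop("structural connectivity must be nonnegative")
  w <- (w + t(w)) / 2
  diag(w) <- 0
  m <- max(w)
  if (m == 0) stop("degenerate input: all-zero structural connectivity")
  coupling_matrix(w * cap / m, kind = "SC", cap = cap)
}

#' Long-range selection rule: positive residuals over the EDR fit
#'
#' Selects structural-connectivity entries whose weight exceeds the
#' exponential decay fitted on the SC's own distance-weight relation
#' (log-linear least squares on positive entries), i.e. connections stronger
#' than the exponential distance rule predicts. The `k` largest positive
#' residuals are kept.
#'
#' @param k number of (unordered) long-range pairs to keep; default `NULL`
#'   keeps `N` pairs.
#' @return a rule function `f(sc, dist)` returning a logical N x N selection
#'   matrix (symmetric, zero diagonal).
#' @export
lr_positive_residuals <- function(k = NULL) {
  force(k)
  function(sc, dist) {
    w <- as.matrix(sc); d <- as.matrix(dist)
    ut <- upper.tri(w)
    pos <- ut & w > 0
    if (!any(pos)) return(matrix(FALSE, nrow(w), ncol(w)))
    fit <- stats::lm.fit(cbind(1, d[pos]), log(w[pos]))
    resid <- log(w[pos]) - cbind(1, d[pos]) %*% fit$coefficients
    kk <- min(k %||% nrow(w), sum(resid > 0))
    sel <- matrix(FALSE, nrow(w), ncol(w))
    if (kk > 0L) {
      idx <- which(pos)[order(resid, decreasing = TRUE)[seq_len(kk)]]
      sel[idx] <- TRUE
      sel <- sel | t(sel)
    }
    sel
  }
}

#' Long-range selection rule: distance threshold
#'
#' Selects all positive structural-connectivity entries between nodes
#' farther apart than `min_dist` mm.
#'
#' @param min_dist minimum distance in mm.
#' @return a rule function `f(sc, dist)` returning a logical selection matrix.
#' @export
lr_distance_threshold <- function(min_dist) {
  force(min_dist)
  function(sc, dist) {
    as.matrix(sc) > 0 & as.matrix(dist) > min_dist & !diag(TRUE, nrow(sc))
  }
}

#' Add long-range structural connections to an EDR coupling
#'
#' Produces the EDR-LR coupling: the exponential-distance-rule weights plus
#' the structural-connectivity weights of the entries selected as long-range
#' by `rule`. No entry ever decreases relative to the EDR matrix.
#'
#' @param edr an EDR [coupling_matrix()].
#' @param sc a structural-connectivity [coupling_matrix()] (same N).
#' @param dist N x N distance matrix (needed by distance-aware rules).
#' @param rule selection-rule function as returned by
#'   [lr_positive_residuals()] (default) or [lr_distance_threshold()], or a
#'   logical N x N matrix selecting entries directly.
#' @return a `"coupling_matrix"` of kind `"EDR_LR"`.
#' @export
add_long_range <- function(edr, sc, dist, rule = lr_positive_residuals()) {
  if (!identical(dim(edr), dim(sc)))
    stop("EDR and SC matrices must have the same dimensions")
  sel <- if (is.matrix(rule)) rule else rule(sc, dist)
  sel <- sel | t(sel)
  diag(sel) <- FALSE
  w <- unclass(edr) + ifelse(sel, unclass(sc), 0)
  coupling_matrix(w, kind = "EDR_LR",
                  lambda_decay = attr(edr, "lambda_decay"),
                  cap = attr(sc, "cap"))
}
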