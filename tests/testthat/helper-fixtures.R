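# Shared small fixtures, built once per test run.

# tiny bilateral synthetic study (16 nodes) for unit tests
tiny_spec <- synthetic_spec(N = 16, n_long_range = 6, n_volumes = 160,
                            n_subjects = 3, seed = 101)
tiny_parc <- make_parcellation(tiny_spec)
tiny_dist <- euclidean_distances(tiny_parc)
tiny_coupling <- make_coupling(tiny_spec, tiny_parc)
tiny_kernel <- edr_kernel(tiny_dist)

# a single uncoupled node
one_node <- coupling_matrix(matrix(0, 1, 1))

# deterministic omega set for the tiny system, inside the analysis band
tiny_omega <- local({
  set.seed(3)
  2 * pi * pmin(pmax(rnorm(16, 0.05, 0.005), 0.009), 0.079)
})

# brute-force local Kuramoto order parameter (double loop over nodes/time)
oracle_local_R <- function(phases, w) {
  N <- nrow(phases); Tn <- ncol(phases)
  R <- matrix(0, N, Tn)
  for (n in seq_len(N)) {
    rs <- sum(w[n, ])
    for (t in seq_len(Tn)) {
      z <- 0
      for (p in seq_len(N)) z <- z + w[n, p] / rs * exp(1i * phases[p, t])
      R[n, t] <- Mod(z)
    }
  }
  R
}

# LZ76 phrase count by definitional scanning with substring search:
# the next phrase is the shortest prefix of the remainder that does not
# occur as a substring of everything produced so far plus the phrase minus
# its last symbol (exhaustive history).
oracle_lz76 <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  c <- 0L
  i <- 1L
  while (i <= n) {
    k <- 1L
    while (i + k - 1L <= n) {
      phrase <- substr(s, i, i + k - 1L)
      hist <- substr(s, 1L, i + k - 2L)
      if (!grepl(phrase, hist, fixed = TRUE)) break
      k <- k + 1L
    }
    c <- c + 1L
    i <- i + k
  }
  c
}
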