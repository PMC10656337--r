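# Independent oracles used across tests.

# Grid-search minimizer of h(c) = sum |gamma - a c| over a fine grid
# bracketing all ratio points.
grid_argmin_h <- function(gamma, a, step = 1e-4) {
  r <- gamma[a != 0] / a[a != 0]
  cs <- seq(min(r) - 1, max(r) + 1, by = step)
  hs <- vapply(cs, function(ci) sum(abs(gamma - a * ci)), numeric(1))
  cs[which.min(hs)]
}

# Benjamini-Hochberg step-up rule written directly from its definition.
bh_stepup_oracle <- function(p, alpha) {
  J <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- max(c(0L, which(ps <= seq_len(J) * alpha / J)))
  reject <- rep(FALSE, J)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  reject
}

# Random parameter set for property tests.
random_params <- function(J, sparse = TRUE) {
  gamma <- if (sparse) {
    g <- numeric(J)
    k <- sample(0:(J %/% 3), 1)
    if (k > 0) g[sample(J, k)] <- runif(k, -1.5, 1.5)
    g
  } else runif(J, -1.5, 1.5)
  mimic_params(beta = runif(1, -1, 1), sigma2 = runif(1, 0.3, 2),
               a = runif(J, 0.5, 2.5), d = runif(J, -2, 2), gamma = gamma)
}

# Small J-item subset of the packaged design, for fast fitting tests.
small_design <- function(J = 5, dif = c(0, 0, 0, 0.8, 0)) {
  tab <- ml1dif::sim_design_params()
  mimic_params(beta = 0.5, sigma2 = 0.25, a = tab$a[seq_len(J)],
               d = tab$d_small[seq_len(J)], gamma = dif[seq_len(J)])
}
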