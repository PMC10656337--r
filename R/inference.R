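# G_j map applied to a matrix of perturbed (gamma, a) rows: for each row,
# gamma - a * weighted-median-shift. Returns an M x J matrix.
gj_map_rows <- function(gamma_mat, a_mat) {
  M <- nrow(gamma_mat)
  out <- matrix(NA_real_, M, ncol(gamma_mat))
  for (m in seq_len(M)) {
    a <- a_mat[m, ]
    keep <- a != 0
    shift <- weighted_median_lower(gamma_mat[m, keep] / a[keep],
                                   abs(a[keep]))
    out[m, ] <- gamma_mat[m, ] - a * shift
  }
  out
}

#' Monte-Carlo draws of the DIF estimator's sampling error
#'
#' Approximates the distribution of `gamma_hat_j - gamma_j*` by a parametric
#' bootstrap on the stage-1 estimate: draws `Z ~ N(0, Sigma_hat_N)` over the
#' free parameters (the constrained DIF coordinate padded with 0), forms the
#' perturbed parameter sets `stage1 + Z / sqrt(N)`, pushes each through the
#' minimal-L1 map `G_j`, and returns the differences `G_j(perturbed) -
#' G_j(stage1)`. The constrained item still receives nonzero draws through
#' `G_j`'s dependence on all coordinates, so it is testable like any other.
#'
#' @param fit An `ml1_fit` with a covariance matrix (`covariance = TRUE`).
#' @param M Number of Monte-Carlo draws (>= 100). Default 10000.
#' @param seed Integer seed; draws are reproducible given it.
#' @return An M x J matrix of draws `D_m^(j)`.
#' @export
draw_gj_perturbations <- function(fit, M = 10000L, seed = 1L) {
  stopifnot(inherits(fit, "ml1_fit"))
  if (is.null(fit$sigma_hat))
    abort("`fit` has no covariance matrix; refit with `covariance = TRUE`.")
  if (M < 100) abort("`M` must be at least 100.")
  Sigma <- fit$sigma_hat
  eg <- eigen(Sigma, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values)))
    abort("Covariance is not positive semi-definite; rerun estimate_covariance().")
  vals <- pmax(eg$values, 0)
  set.seed(as.integer(seed))
  Z <- matrix(rnorm(M * length(vals)), M) %*%
    (t(eg$vectors) * sqrt(vals))           # M x P, rows ~ N(0, Sigma)
  st <- fit$stage1
  J <- st$params$J
  free_g <- setdiff(seq_len(J), st$fixed_gamma)
  a_idx <- seq_len(J)
  g_idx <- 2L * J + seq_along(free_g)
  scl <- 1 / sqrt(fit$n)
  a_mat <- matrix(st$params$a, M, J, byrow = TRUE) + Z[, a_idx] * scl
  gamma_mat <- matrix(st$params$gamma, M, J, byrow = TRUE)
  gamma_mat[, free_g] <- gamma_mat[, free_g] + Z[, g_idx] * scl
  gj0 <- fit$params$gamma                  # G_j of the unperturbed stage-1 fit
  sweep(gj_map_rows(gamma_mat, a_mat), 2L, gj0, `-`)
}

#' Basic (pivotal) bootstrap confidence intervals for DIF effects
#'
#' Builds, for each item, the interval `[gamma_hat - q_{(1+level)/2}(D),
#' gamma_hat - q_{(1-level)/2}(D)]` from the empirical quantiles of the
#' Monte-Carlo draws of the estimator's sampling error.
#'
#' @param draws M x J matrix from [draw_gj_perturbations()].
#' @param gamma_hat Length-J vector of DIF estimates.
#' @param level Nominal confidence level in (0, 1). Default 0.95.
#' @return A tibble with columns `item`, `gamma_hat`, `ci_lo`, `ci_hi`.
#' @export
confidence_intervals <- function(draws, gamma_hat, level = 0.95) {
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  M <- nrow(draws)
  if (ncol(draws) != length(gamma_hat))
    abort("`draws` and `gamma_hat` disagree on the number of items.")
  if (M * (1 - level) / 2 < 1)
    abort("Too few draws for the requested level; increase `M`.")
  qs <- apply(draws, 2L, quantile,
              probs = c((1 - level) / 2, (1 + level) / 2), names = FALSE)
  tibble::tibble(item = seq_along(gamma_hat), gamma_hat = gamma_hat,
                 ci_lo = gamma_hat - qs[2L, ], ci_hi = gamma_hat - qs[1L, ])
}

#' Two-sided Monte-Carlo P-values for DIF effects
#'
#' For each item, the add-one two-sided Monte-Carlo P-value
#' `min(1, 2 * min((1 + #\{D >= gamma_hat\}) / (M + 1),
#' (1 + #\{D <= gamma_hat\}) / (M + 1)))`,
#' testing `gamma_j = 0` against the bootstrap null distribution of the
#' estimator's sampling error. Values are bounded below by `1 / (M + 1)`.
#'
#' @inheritParams confidence_intervals
#' @return Length-J numeric vector of P-values in (0, 1].
#' @export
p_values <- function(draws, gamma_hat) {
  if (ncol(draws) != length(gamma_hat))
    abort("`draws` and `gamma_hat` disagree on the number of items.")
  M <- nrow(draws)
  up <- (1 + colSums(sweep(draws, 2L, gamma_hat, `>=`))) / (M + 1)
  lo <- (1 + colSums(sweep(draws, 2L, gamma_hat, `<=`))) / (M + 1)
  pmin(1, 2 * pmin(up, lo))
}

#' Benjamini-Hochberg DIF detection
#'
#' Applies the Benjamini-Hochberg step-up procedure at FDR level `alpha`:
#' sort the P-values ascending, find the largest k with `p_(k) <= k * alpha
#' / J`, and reject the k smallest.
#'
#' @param pvals Numeric vector of P-values in \[0, 1\].
#' @param alpha FDR level in (0, 1). Default 0.05.
#' @return Logical vector: `TRUE` for detected (rejected) items.
#' @export
bh_select <- function(pvals, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    abort("P-values must lie in [0, 1].")
  p.adjust(pvals, method = "BH") <= alpha
}

#' Anchor-free DIF inference (parametric bootstrap + B-H detection)
#'
#' The full inference pipeline on a fitted model: Monte-Carlo perturbation
#' draws through the minimal-L1 map, basic bootstrap confidence intervals,
#' two-sided Monte-Carlo P-values, and Benjamini-Hochberg detection.
#'
#' @param fit An `ml1_fit` with covariance.
#' @param M Number of Monte-Carlo draws. Default 10000 (50000 is
#'   recommended for final data analyses).
#' @param level Nominal confidence level. Default 0.95.
#' @param alpha FDR level for detection. Default 0.05.
#' @param seed Integer seed for the draws.
#' @return A tibble of class `dif_inference` with columns `item`,
#'   `gamma_hat`, `ci_lo`, `ci_hi`, `p_value`, `bh_reject`, and attributes
#'   `M`, `level`, `alpha`, `seed`.
#' @examples
#' \donttest{
#' dat <- sim_responses(sim_params("small", "large", "low"), n = 500, seed = 1)
#' fit <- fit_ml1(dat)
#' dif_infer(fit, M = 2000, seed = 7)
#' }
#' @export
dif_infer <- function(fit, M = 10000L, level = 0.95, alpha = 0.05,
                      seed = 1L) {
  draws <- draw_gj_perturbations(fit, M = M, seed = seed)
  ci <- confidence_intervals(draws, fit$params$gamma, level = level)
  pv <- p_values(draws, fit$params$gamma)
  out <- dplyr::mutate(ci, item = fit$items, p_value = pv,
                       bh_reject = bh_select(pv, alpha = alpha))
  attr(out, "M") <- as.integer(M)
  attr(out, "level") <- level
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("dif_inference", class(out))
  out
}
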