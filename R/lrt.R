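#' Anchor-based likelihood-ratio tests for DIF
#'
#' Classical comparator requiring a known set of anchor (DIF-free) items.
#' The full model is fitted with `gamma_j = 0` for every anchor and all
#' other DIF effects free; then, for each non-anchor item j, a null model
#' additionally fixes `gamma_j = 0`. The statistic `2 * (loglik_full -
#' loglik_null)` (floored at 0, since optimizer tolerance can make it
#' marginally negative) is referred to a chi-square distribution with one
#' degree of freedom. Null refits are warm-started from the full fit.
#'
#' @param data Data frame with group column plus item columns, or a
#'   `response_data` object.
#' @param anchors Integer indices of the anchor items (nonempty, within
#'   1..J).
#' @param quad A [gh_quadrature()] rule.
#' @param tol,max_iter Optimizer controls, as in [fit_constrained_mle()].
#' @param group_col Group column name.
#' @return A tibble of class `lrt_dif` with one row per non-anchor item:
#'   `item`, `item_index`, `gamma_hat` (free estimate under the full
#'   anchored model), `statistic`, `p_value`, `converged`; the full
#'   anchored fit is attached as attribute `fit`.
#' @examples
#' \donttest{
#' dat <- sim_responses(sim_params("small", "large", "low"), n = 500, seed = 1)
#' lrt_dif(dat, anchors = 1:5)
#' }
#' @export
lrt_dif <- function(data, anchors, quad = gh_quadrature(), tol = 1e-8,
                    max_iter = 500L, group_col = "group") {
  rd <- as_response_data(data, group_col = group_col)
  J <- ncol(rd$responses)
  anchors <- sort(unique(as.integer(anchors)))
  if (length(anchors) < 1L)
    abort("`anchors` must be nonempty: the anchored model is unidentified otherwise.")
  if (any(anchors < 1L | anchors > J))
    abort("`anchors` out of range 1..J.")
  full <- fit_constrained_mle(rd, fixed_gamma = anchors, quad = quad,
                              tol = tol, max_iter = max_iter)
  non_anchor <- setdiff(seq_len(J), anchors)
  res <- purrr::map_dfr(non_anchor, function(j) {
    start <- full$params
    start$gamma[j] <- 0
    null_fit <- fit_constrained_mle(rd, fixed_gamma = c(anchors, j),
                                    quad = quad, init = start, tol = tol,
                                    max_iter = max_iter)
    stat <- max(0, 2 * (full$loglik - null_fit$loglik))
    tibble::tibble(item = rd$items[j], item_index = j,
                   gamma_hat = full$params$gamma[j], statistic = stat,
                   p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                   converged = full$converged && null_fit$converged)
  })
  attr(res, "fit") <- full
  attr(res, "anchors") <- anchors
  class(res) <- c("lrt_dif", class(res))
  res
}

#' Anchor-based Wald confidence intervals for DIF effects
#'
#' Fits the anchored model (DIF effects of `anchors` fixed at 0) and builds
#' per-item Wald intervals `gamma_hat_j +/- z * se_j` for the non-anchor
#' items, with standard errors from the inverse observed information. Used
#' as the coverage comparator for the parametric-bootstrap intervals.
#'
#' @inheritParams lrt_dif
#' @param level Nominal confidence level. Default 0.95.
#' @return A tibble with one row per non-anchor item: `item`, `item_index`,
#'   `gamma_hat`, `se`, `ci_lo`, `ci_hi`.
#' @export
wald_dif <- function(data, anchors, level = 0.95, quad = gh_quadrature(),
                     tol = 1e-8, max_iter = 500L, group_col = "group") {
  rd <- as_response_data(data, group_col = group_col)
  J <- ncol(rd$responses)
  anchors <- sort(unique(as.integer(anchors)))
  fit <- fit_constrained_mle(rd, fixed_gamma = anchors, quad = quad,
                             tol = tol, max_iter = max_iter)
  Sigma <- estimate_covariance(fit)
  non_anchor <- setdiff(seq_len(J), anchors)
  g_idx <- 2L * J + seq_along(non_anchor)
  se <- sqrt(pmax(0, diag(Sigma)[g_idx]) / fit$n)
  z <- qnorm((1 + level) / 2)
  gh <- fit$params$gamma[non_anchor]
  tibble::tibble(item = rd$items[non_anchor], item_index = non_anchor,
                 gamma_hat = gh, se = se,
                 ci_lo = gh - z * se, ci_hi = gh + z * se)
}
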