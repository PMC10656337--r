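#' Gauss-Hermite quadrature rule for latent-trait integration
#'
#' Fixed (non-adaptive) Gauss-Hermite nodes and weights used to integrate the
#' latent trait out of the marginal likelihood. For a group with latent mean
#' `mu` and standard deviation `s`, the substitution `theta = mu + s *
#' sqrt(2) * t` turns the Gaussian integral into the Gauss-Hermite form, so
#' the same rule serves both groups exactly.
#'
#' @param n_nodes Number of nodes (>= 5). Default 31, accurate to well below
#'   1e-8 for the unimodal integrands that arise here.
#' @return An object of class `gh_quadrature` with elements `t` (raw nodes),
#'   `w` (raw weights), `logw` (log of weights normalised so the rule
#'   integrates a Gaussian density to 1), and `n_nodes`.
#' @examples
#' q <- gh_quadrature(31)
#' sum(exp(q$logw)) # integrates the density to 1
#' @export
gh_quadrature <- function(n_nodes = 31) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 5)
    abort("`n_nodes` must be a single integer >= 5.")
  gh <- pracma::gaussHermite(as.integer(n_nodes))
  structure(
    list(t = gh$x, w = gh$w, logw = log(gh$w) - 0.5 * log(pi),
         n_nodes = as.integer(n_nodes)),
    class = "gh_quadrature"
  )
}

# theta nodes for a group with mean mu and sd s
gh_nodes_for <- function(quad, mu, s) mu + s * sqrt(2) * quad$t

#' Item response probability under the 2PL model with uniform DIF
#'
#' Probability of a correct/positive response given latent trait `theta` and
#' group membership `x`: `plogis(a * theta + d + gamma * x)`. `exp(gamma)` is
#' the odds ratio comparing focal to reference respondents at the same latent
#' trait level; `gamma = 0` means the item is DIF-free.
#'
#' @param a Discrimination slope.
#' @param d Easiness intercept.
#' @param gamma Uniform DIF effect.
#' @param theta Latent trait value(s).
#' @param x Group label(s), 0 (reference) or 1 (focal).
#' @return Response probabilities in (0, 1), recycled over `theta`/`x`.
#' @examples
#' irf_prob(a = 1, d = 0, gamma = log(2), theta = 0, x = 1) # 2/3
#' @export
irf_prob <- function(a, d, gamma, theta, x) {
  args <- c(a, d, gamma, theta, x)
  if (!is.numeric(args) || !all(is.finite(args)))
    abort("All arguments to `irf_prob()` must be finite numerics.")
  if (!all(x %in% c(0, 1)))
    abort("`x` must be 0 or 1.")
  plogis(a * theta + d + gamma * x)
}

# Forward pass of the quadrature-approximated marginal likelihood.
# Returns per-respondent log-likelihood plus the pieces the gradient needs.
# rd: response_data; par: mimic_params; quad: gh_quadrature.
loglik_forward <- function(par, rd, quad, keep = FALSE) {
  sigma <- sqrt(par$sigma2)
  out <- list(groups = list())
  ll <- 0
  for (g in 0:1) {
    idx <- rd$groups == g
    if (!any(idx)) next
    Yg <- rd$responses[idx, , drop = FALSE]
    theta <- if (g == 0) gh_nodes_for(quad, 0, 1)
             else gh_nodes_for(quad, par$beta, sigma)
    # J x K linear predictors
    lin <- outer(par$a, theta) + par$d + if (g == 1) par$gamma else 0
    logp <- plogis(lin, log.p = TRUE)
    log1mp <- plogis(-lin, log.p = TRUE)
    # N_g x K joint log-density of the response vector at each node
    logf <- Yg %*% (logp - log1mp) + matrix(colSums(log1mp),
                                            nrow(Yg), length(theta),
                                            byrow = TRUE)
    lw <- sweep(logf, 2L, quad$logw, `+`)
    mx <- apply(lw, 1L, max)
    li <- mx + log(rowSums(exp(lw - mx)))
    ll <- ll + sum(li)
    if (keep) {
      Q <- exp(lw - li)                     # posterior node weights
      out$groups[[as.character(g)]] <-
        list(Y = Yg, theta = theta, p = plogis(lin), Q = Q)
    }
  }
  out$loglik <- ll
  out
}

#' Marginal log-likelihood of the MIMIC 2PL model
#'
#' Evaluates the log marginal likelihood, integrating the latent trait out by
#' Gauss-Hermite quadrature with the group-specific mean/scale substitution
#' (reference group N(0, 1); focal group N(beta, sigma2)). Computation is
#' overflow-safe (log1p-style response probabilities, log-sum-exp over
#' nodes), and deterministic for fixed inputs.
#'
#' @param params A [mimic_params()] object.
#' @param data A data frame with a group column, or a `response_data` object.
#' @param quad A [gh_quadrature()] rule. Default 31 nodes.
#' @param group_col Group column name when `data` is a data frame.
#' @return The log-likelihood (a non-positive scalar).
#' @export
marginal_loglik <- function(params, data, quad = gh_quadrature(),
                            group_col = "group") {
  stopifnot(inherits(params, "mimic_params"))
  rd <- as_response_data(data, group_col = group_col)
  if (ncol(rd$responses) != params$J)
    abort("Number of item columns does not match `params`.")
  ll <- loglik_forward(params, rd, quad)$loglik
  if (!is.finite(ll)) abort("Log-likelihood evaluation failed (non-finite).")
  ll
}

# Analytic gradient of the quadrature-approximated log-likelihood with
# respect to (a_1..J, d_1..J, gamma_free, beta, log sigma), where gamma_free
# excludes the indices in `fixed_gamma`. Shares the forward pass.
loglik_gradient <- function(par, rd, quad, fixed_gamma = integer(0)) {
  fw <- loglik_forward(par, rd, quad, keep = TRUE)
  J <- par$J
  ga <- gd <- gg <- numeric(J)
  gbeta <- glogsig <- 0
  sigma <- sqrt(par$sigma2)
  for (g in names(fw$groups)) {
    pc <- fw$groups[[g]]
    ck <- colSums(pc$Q)
    A <- crossprod(pc$Y, pc$Q)              # J x K: sum_i y_ij q_ik
    B <- A - pc$p * matrix(ck, nrow(A), ncol(A), byrow = TRUE)
    rsB <- rowSums(B)
    gd <- gd + rsB
    ga <- ga + drop(B %*% pc$theta)
    if (g == "1") {
      gg <- gg + rsB
      gbeta <- sum(par$a * rsB)
      glogsig <- sqrt(2) * sigma * sum(par$a * drop(B %*% quad$t))
    }
  }
  free_g <- setdiff(seq_len(J), fixed_gamma)
  c(ga, gd, gg[free_g], gbeta, glogsig)
}
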