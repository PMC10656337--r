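# Packing/unpacking of the free-parameter vector used by the optimizer:
# (a_1..J, d_1..J, gamma_j for j not in fixed_gamma, beta, log sigma).
pack_params <- function(par, fixed_gamma) {
  free_g <- setdiff(seq_len(par$J), fixed_gamma)
  c(par$a, par$d, par$gamma[free_g], par$beta, 0.5 * log(par$sigma2))
}

unpack_params <- function(theta, J, fixed_gamma) {
  free_g <- setdiff(seq_len(J), fixed_gamma)
  gamma <- numeric(J)
  gamma[free_g] <- theta[2L * J + seq_along(free_g)]
  n <- 2L * J + length(free_g)
  mimic_params(beta = theta[n + 1L], sigma2 = exp(2 * theta[n + 2L]),
               a = theta[seq_len(J)], d = theta[J + seq_len(J)],
               gamma = gamma)
}

param_labels <- function(J, fixed_gamma, items = paste0("item", seq_len(J))) {
  free_g <- setdiff(seq_len(J), fixed_gamma)
  c(paste0("a[", items, "]"), paste0("d[", items, "]"),
    paste0("gamma[", items[free_g], "]"), "beta", "log_sigma")
}

default_init <- function(rd, fixed_gamma) {
  J <- ncol(rd$responses)
  d0 <- pmin(pmax(qlogis(colMeans(rd$responses)), -3), 3)
  mimic_params(beta = 0, sigma2 = 1, a = rep(1, J), d = d0,
               gamma = rep(0, J))
}

#' Constrained marginal maximum likelihood fit (stage 1)
#'
#' Maximizes the quadrature-approximated marginal log-likelihood of the
#' MIMIC 2PL model over all 3J + 1 free parameters, with the DIF effects of
#' the items in `fixed_gamma` held at zero. The default single constraint
#' `gamma_1 = 0` removes the location indeterminacy without restricting the
#' achievable likelihood (any equivalent constraint works and leads to the
#' same minimal-L1 estimate after [ml1_transform()]). Supplying several
#' indices fits an anchored model, as used by the likelihood-ratio
#' comparator.
#'
#' Optimization is quasi-Newton (L-BFGS-B) with analytic gradients;
#' `sigma` enters as `log(sigma)` so the variance stays positive.
#'
#' @param data Data frame with a binary group column plus binary item
#'   columns, or a `response_data` object.
#' @param fixed_gamma Integer indices of items whose DIF effect is fixed at
#'   0. Default `1`.
#' @param quad A [gh_quadrature()] rule. Default 31 nodes.
#' @param init Optional `mimic_params` starting value.
#' @param tol Relative log-likelihood convergence tolerance. Default 1e-8.
#' @param max_iter Maximum optimizer iterations. Default 500.
#' @param group_col Group column name. Default `"group"`.
#' @return An object of class `mimic_fit`: list with `params` (the
#'   constrained MLE as `mimic_params`), `loglik`, `converged`, `n_iter`,
#'   `fixed_gamma`, `items`, `n`, `quad`, and `data` (the validated
#'   `response_data`, kept for covariance estimation).
#' @export
fit_constrained_mle <- function(data, fixed_gamma = 1L,
                                quad = gh_quadrature(), init = NULL,
                                tol = 1e-8, max_iter = 500L,
                                group_col = "group") {
  rd <- as_response_data(data, group_col = group_col)
  check_fit_ready(rd)
  J <- ncol(rd$responses)
  fixed_gamma <- sort(unique(as.integer(fixed_gamma)))
  if (length(fixed_gamma) < 1L || any(fixed_gamma < 1L | fixed_gamma > J))
    abort("`fixed_gamma` must be a nonempty set of item indices in 1..J.")
  start <- init %||% default_init(rd, fixed_gamma)
  if (any(start$gamma[fixed_gamma] != 0)) {
    start$gamma[fixed_gamma] <- 0
  }
  theta0 <- pack_params(start, fixed_gamma)

  negll <- function(th) {
    p <- unpack_params(th, J, fixed_gamma)
    -loglik_forward(p, rd, quad)$loglik
  }
  neggr <- function(th) {
    p <- unpack_params(th, J, fixed_gamma)
    -loglik_gradient(p, rd, quad, fixed_gamma)
  }
  opt <- optim(theta0, negll, neggr, method = "L-BFGS-B",
               control = list(maxit = as.integer(max_iter),
                              factr = tol / .Machine$double.eps,
                              pgtol = 0))
  converged <- opt$convergence == 0L
  if (!converged)
    warn(sprintf("Stage-1 optimizer did not converge (code %d): %s",
                 opt$convergence, opt$message %||% ""))
  params <- unpack_params(opt$par, J, fixed_gamma)
  structure(
    list(params = params, loglik = -opt$value, converged = converged,
         n_iter = opt$counts[["function"]], fixed_gamma = fixed_gamma,
         items = rd$items, n = nrow(rd$responses), quad = quad, data = rd),
    class = "mimic_fit"
  )
}

#' @export
print.mimic_fit <- function(x, ...) {
  cat(sprintf(
    "<mimic_fit> J = %d, N = %d | loglik = %.4f | gamma fixed at 0 for item(s) %s\n",
    x$params$J, x$n, x$loglik, paste(x$fixed_gamma, collapse = ", ")))
  invisible(x)
}

#' Scaled covariance of the constrained MLE
#'
#' Estimates the covariance of `sqrt(N) * (estimate - truth)` for the free
#' parameters of a stage-1 fit as `N` times the inverse observed information
#' (negative Hessian of the total marginal log-likelihood at the fit). The
#' Hessian is obtained by central finite differences of the analytic
#' gradient with step `1e-4 * max(1, |param|)` and symmetrized; the result
#' is made positive semi-definite by flooring eigenvalues at
#' `1e-10 * trace / P`.
#'
#' @param fit A `mimic_fit` from [fit_constrained_mle()].
#' @return A symmetric P x P matrix (P = 3J + 1 for a single constraint),
#'   with parameter labels as dimnames.
#' @export
estimate_covariance <- function(fit) {
  stopifnot(inherits(fit, "mimic_fit"))
  rd <- fit$data
  J <- fit$params$J
  th <- pack_params(fit$params, fit$fixed_gamma)
  P <- length(th)
  H <- matrix(0, P, P)
  for (p in seq_len(P)) {
    h <- 1e-4 * max(1, abs(th[p]))
    tp <- th; tp[p] <- th[p] + h
    tm <- th; tm[p] <- th[p] - h
    gp <- loglik_gradient(unpack_params(tp, J, fit$fixed_gamma), rd,
                          fit$quad, fit$fixed_gamma)
    gm <- loglik_gradient(unpack_params(tm, J, fit$fixed_gamma), rd,
                          fit$quad, fit$fixed_gamma)
    H[, p] <- (gp - gm) / (2 * h)
  }
  H <- -(H + t(H)) / 2                       # observed information
  Sigma <- tryCatch(solve(H), error = function(e) {
    warn("Observed information numerically singular; using pseudo-inverse.")
    MASS::ginv(H)
  })
  Sigma <- fit$n * (Sigma + t(Sigma)) / 2
  eg <- eigen(Sigma, symmetric = TRUE)
  floor_at <- 1e-10 * sum(diag(Sigma)) / P
  vals <- pmax(eg$values, floor_at)
  Sigma <- eg$vectors %*% (vals * t(eg$vectors))
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- rep(list(param_labels(J, fit$fixed_gamma, fit$items)), 2)
  Sigma
}

#' Two-stage minimal-L1 estimator for anchor-free DIF analysis
#'
#' Runs the full estimation pipeline: (1) constrained marginal MLE with
#' `gamma_1 = 0` (any single-item constraint may be chosen), (2) covariance
#' estimation from the observed information, and (3) re-identification of
#' the fit to the minimal-L1 representative of its equivalence class via
#' [ml1_transform()]. The resulting DIF estimates have the smallest L1 norm
#' among all parameter sets attaining the same likelihood, and the marginal
#' log-likelihood is unchanged by the re-identification.
#'
#' @inheritParams fit_constrained_mle
#' @param constraint_item Index of the item whose DIF effect is fixed at 0
#'   in stage 1. Default 1.
#' @param covariance Compute the scaled covariance matrix (needed for
#'   [dif_infer()])? Default `TRUE`.
#' @return An object of class `ml1_fit`: list with `params` (the minimal-L1
#'   estimate), `shift` (the applied location shift), `stage1` (the
#'   `mimic_fit`), `sigma_hat` (scaled covariance or `NULL`), `loglik`,
#'   `items`, `n`.
#' @examples
#' \donttest{
#' truth <- sim_params("small", "large", "low")
#' dat <- sim_responses(truth, n = 500, seed = 1)
#' fit <- fit_ml1(dat)
#' glance(fit)
#' tidy(fit)
#' }
#' @export
fit_ml1 <- function(data, constraint_item = 1L, quad = gh_quadrature(),
                    init = NULL, tol = 1e-8, max_iter = 500L,
                    covariance = TRUE, group_col = "group") {
  stage1 <- fit_constrained_mle(data, fixed_gamma = constraint_item,
                                quad = quad, init = init, tol = tol,
                                max_iter = max_iter, group_col = group_col)
  sigma_hat <- if (covariance) estimate_covariance(stage1) else NULL
  tr <- ml1_transform(stage1$params)
  structure(
    list(params = tr$params, shift = tr$shift, stage1 = stage1,
         sigma_hat = sigma_hat, loglik = stage1$loglik,
         items = stage1$items, n = stage1$n),
    class = "ml1_fit"
  )
}

#' @export
print.ml1_fit <- function(x, ...) {
  cat(sprintf(
    "<ml1_fit> J = %d, N = %d | loglik = %.4f | ML1 shift = %.4g\n",
    x$params$J, x$n, x$loglik, x$shift))
  cat(sprintf("  beta = %.4g, sigma2 = %.4g, sum|gamma| = %.4g\n",
              x$params$beta, x$params$sigma2, sum(abs(x$params$gamma))))
  invisible(x)
}

#' @describeIn fit_ml1 Per-item parameter estimates as a tibble (`item`,
#'   `a`, `d`, `gamma`).
#' @param x An `ml1_fit`.
#' @param ... Unused.
#' @export
tidy.ml1_fit <- function(x, ...) {
  tibble::tibble(item = x$items, a = x$params$a, d = x$params$d,
                 gamma = x$params$gamma)
}

#' @describeIn fit_ml1 One-row model summary: `beta`, `sigma2`, `shift`,
#'   `loglik`, `converged`, `n_iter`, `n_obs`, `n_items`.
#' @export
glance.ml1_fit <- function(x, ...) {
  tibble::tibble(beta = x$params$beta, sigma2 = x$params$sigma2,
                 shift = x$shift, loglik = x$loglik,
                 converged = x$stage1$converged,
                 n_iter = as.integer(x$stage1$n_iter),
                 n_obs = x$n, n_items = x$params$J)
}
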