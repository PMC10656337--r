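# True item parameters of the packaged 25-item study design.
sim_gamma_block <- function(dif_prop) {
  g5 <- c(-0.60, 0.60, -0.65, 0.70, 0.65)
  switch(dif_prop,
    high = c(rep(0, 11), g5[1:4], g5, g5),
    medium = c(rep(0, 15), g5, g5),
    low = c(rep(0, 20), g5),
    abort("`dif_prop` must be 'high', 'medium' or 'low'."))
}

#' True item parameters of the packaged simulation design
#'
#' The 25-item design used throughout the package's simulation study: five
#' discrimination values (1.3, 1.4, 1.5, 1.7, 1.6) repeated across blocks of
#' five items, two easiness regimes (small `d` in \[-1, 1\], large `d` in
#' \[-2, 2\]), and six DIF-effect columns crossing magnitude (small: values
#' up to 0.7 in absolute value; large: exactly double) with the proportion
#' of affected items (high/medium/low = 14/10/5 DIF items out of 25). DIF
#' effects alternate in sign, so the minimal-L1 identification condition
#' holds in every design cell.
#'
#' @return A tibble with columns `item`, `a`, `d_small`, `d_large`, and
#'   `gamma_<magnitude>_<proportion>` for the six DIF columns.
#' @export
sim_design_params <- function() {
  tibble::tibble(
    item = 1:25,
    a = rep(c(1.3, 1.4, 1.5, 1.7, 1.6), 5),
    d_small = rep(c(0.8, 0.2, -0.4, -1.0, 1.0), 5),
    d_large = rep(c(0.8, -0.4, -1.2, -2.0, 2.0), 5),
    gamma_small_high = sim_gamma_block("high"),
    gamma_small_medium = sim_gamma_block("medium"),
    gamma_small_low = sim_gamma_block("low"),
    gamma_large_high = 2 * sim_gamma_block("high"),
    gamma_large_medium = 2 * sim_gamma_block("medium"),
    gamma_large_low = 2 * sim_gamma_block("low")
  )
}

#' Resolve one simulation design cell to a parameter set
#'
#' @param d_regime Easiness regime: `"small"` or `"large"`.
#' @param dif_size DIF magnitude: `"small"` or `"large"`.
#' @param dif_prop Proportion of DIF items: `"high"` (14/25), `"medium"`
#'   (10/25) or `"low"` (5/25).
#' @param beta Focal-group latent mean. Default 0.5.
#' @param sigma Focal-group latent standard deviation. Default 0.5.
#' @return A [mimic_params()] object.
#' @examples
#' sim_params("small", "small", "high")
#' @export
sim_params <- function(d_regime = c("small", "large"),
                       dif_size = c("small", "large"),
                       dif_prop = c("high", "medium", "low"),
                       beta = 0.5, sigma = 0.5) {
  d_regime <- match.arg(d_regime)
  dif_size <- match.arg(dif_size)
  dif_prop <- match.arg(dif_prop)
  tab <- sim_design_params()
  mimic_params(
    beta = beta, sigma2 = sigma^2, a = tab$a,
    d = tab[[paste0("d_", d_regime)]],
    gamma = tab[[paste0("gamma_", dif_size, "_", dif_prop)]]
  )
}

#' A simulation setting (design cell plus sample size)
#'
#' @param n Number of respondents, split equally between the two groups
#'   (an odd `n` gives the focal group the extra respondent).
#' @inheritParams sim_params
#' @param label Optional setting label; a descriptive one is built by
#'   default.
#' @return A list of class `sim_setting` with the resolved `params`.
#' @export
sim_setting <- function(n, d_regime = "small", dif_size = "small",
                        dif_prop = "high", beta = 0.5, sigma = 0.5,
                        label = NULL) {
  params <- sim_params(d_regime, dif_size, dif_prop, beta, sigma)
  structure(
    list(n = as.integer(n), d_regime = d_regime, dif_size = dif_size,
         dif_prop = dif_prop, beta = beta, sigma = sigma, params = params,
         label = label %||%
           sprintf("N%d_%sd_%sDIF_%s", n, d_regime, dif_size, dif_prop)),
    class = "sim_setting")
}

#' Simulate binary item responses from the MIMIC 2PL model
#'
#' Draws latent traits from N(0, 1) for the reference group and
#' N(beta, sigma2) for the focal group, then responses from the 2PL item
#' response function with uniform DIF. Groups are of equal size (focal
#' group gets the extra respondent when `n` is odd).
#'
#' @param params A [mimic_params()] object.
#' @param n Total number of respondents.
#' @param seed Integer seed; the dataset is reproducible given it.
#' @return A tibble with a `group` column (0/1) and item columns `y1..yJ`.
#' @examples
#' sim_responses(sim_params("small", "small", "high"), n = 10, seed = 1)
#' @export
sim_responses <- function(params, n, seed = 1L) {
  stopifnot(inherits(params, "mimic_params"))
  if (n < 2) abort("`n` must be at least 2 (one respondent per group).")
  n_ref <- n %/% 2L
  n_foc <- n - n_ref
  set.seed(as.integer(seed))
  x <- c(rep(0L, n_ref), rep(1L, n_foc))
  theta <- c(rnorm(n_ref), rnorm(n_foc, params$beta, sqrt(params$sigma2)))
  eta <- outer(theta, params$a) +
    matrix(params$d, n, params$J, byrow = TRUE) +
    x * matrix(params$gamma, n, params$J, byrow = TRUE)
  Y <- matrix(rbinom(n * params$J, 1L, plogis(eta)), n, params$J)
  colnames(Y) <- paste0("y", seq_len(params$J))
  dplyr::bind_cols(tibble::tibble(group = x),
                   tibble::as_tibble(as.data.frame(Y)))
}

#' Average mean-squared errors of replicated estimates
#'
#' Per-parameter squared errors against the truth, averaged over
#' replications, then averaged across items for the `a`, `d` and `gamma`
#' blocks; `beta` and `sigma` (the standard deviation, not the variance)
#' are reported individually.
#'
#' @param estimates List of `mimic_params` estimates, one per replication.
#' @param truth The generating `mimic_params`.
#' @return A tibble with columns `block` (`a`, `d`, `gamma`, `beta`,
#'   `sigma`) and `mse`.
#' @export
compute_mse <- function(estimates, truth) {
  stopifnot(inherits(truth, "mimic_params"))
  if (length(estimates) < 2L) abort("Need at least 2 replications.")
  ok <- vapply(estimates, function(e)
    inherits(e, "mimic_params") && e$J == truth$J, logical(1))
  if (!all(ok)) abort("All estimates must be mimic_params with matching J.")
  block_mse <- function(f) {
    errs <- vapply(estimates, function(e) (f(e) - f(truth))^2,
                   numeric(length(f(truth))))
    mean(rowMeans(matrix(errs, ncol = length(estimates))))
  }
  tibble::tibble(
    block = c("a", "d", "gamma", "beta", "sigma"),
    mse = c(block_mse(function(p) p$a),
            block_mse(function(p) p$d),
            block_mse(function(p) p$gamma),
            block_mse(function(p) p$beta),
            block_mse(function(p) sqrt(p$sigma2))))
}

#' Empirical false discovery rate over replications
#'
#' Per replication, the false-discovery proportion is the number of
#' detected items whose true DIF effect is zero divided by the total number
#' of detections (0 when nothing is detected); the empirical FDR is its
#' average over replications.
#'
#' @param detections Logical matrix, replications x items: `TRUE` =
#'   detected.
#' @param truth The generating `mimic_params`, or a logical vector marking
#'   the true DIF items.
#' @return Scalar empirical FDR in \[0, 1\].
#' @export
compute_fdr <- function(detections, truth) {
  is_dif <- if (inherits(truth, "mimic_params")) truth$gamma != 0
            else as.logical(truth)
  detections <- as.matrix(detections)
  if (ncol(detections) != length(is_dif))
    abort("`detections` and `truth` disagree on the number of items.")
  fdp <- apply(detections, 1L, function(det) {
    nd <- sum(det)
    if (nd == 0) 0 else sum(det & !is_dif) / nd
  })
  mean(fdp)
}

#' Per-item empirical coverage of replicated confidence intervals
#'
#' @param intervals Tibble with columns `rep`, `item_index`, `ci_lo`,
#'   `ci_hi` (one row per replication and item).
#' @param truth The generating `mimic_params`, or a numeric vector of true
#'   DIF effects indexed by `item_index`.
#' @return A tibble with columns `item_index` and `coverage`.
#' @export
compute_coverage <- function(intervals, truth) {
  g <- if (inherits(truth, "mimic_params")) truth$gamma else as.numeric(truth)
  intervals |>
    dplyr::mutate(truth = g[.data$item_index],
                  hit = .data$ci_lo <= .data$truth &
                        .data$truth <= .data$ci_hi) |>
    dplyr::group_by(.data$item_index) |>
    dplyr::summarise(coverage = mean(.data$hit), .groups = "drop")
}

# Per-replication empirical ROC evaluated on a fixed FPR grid
# (vertical averaging): TPR at FPR x is the step-function value of the
# empirical curve. scores: lower = stronger evidence of DIF.
roc_on_grid <- function(scores, is_dif, fpr_grid) {
  if (!any(is_dif) || all(is_dif))
    abort("ROC needs both DIF and non-DIF items.")
  cuts <- sort(unique(scores))
  fpr <- vapply(cuts, function(t) mean(scores[!is_dif] <= t), numeric(1))
  tpr <- vapply(cuts, function(t) mean(scores[is_dif] <= t), numeric(1))
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  best <- vapply(split(tpr, fpr), max, numeric(1))
  xs <- as.numeric(names(best))
  stats::approx(xs, best, xout = fpr_grid, method = "constant",
                f = 0, rule = 2)$y
}

#' Averaged ROC curve and AUC over replications
#'
#' Per replication, the empirical ROC of the per-item scores (P-values:
#' smaller means stronger evidence of DIF) is evaluated on a fixed grid of
#' false-positive rates; the true-positive rates are averaged vertically
#' across replications and the AUC is the trapezoid-rule area under the
#' averaged curve.
#'
#' @param scores Numeric matrix, replications x items, of per-item scores
#'   (typically P-values).
#' @param truth The generating `mimic_params`, a logical DIF indicator, or
#'   a numeric vector of true DIF effects for the scored items.
#' @param n_grid Number of FPR grid points. Default 512.
#' @return A list with `curve` (tibble `fpr`, `tpr`) and `auc` (scalar).
#' @export
compute_roc_auc <- function(scores, truth, n_grid = 512L) {
  is_dif <- if (inherits(truth, "mimic_params")) truth$gamma != 0
            else if (is.logical(truth)) truth else as.numeric(truth) != 0
  scores <- as.matrix(scores)
  if (ncol(scores) != length(is_dif))
    abort("`scores` and `truth` disagree on the number of items.")
  fpr_grid <- seq(0, 1, length.out = n_grid)
  tprs <- apply(scores, 1L, roc_on_grid, is_dif = is_dif,
                fpr_grid = fpr_grid)
  tpr <- rowMeans(tprs)
  auc <- sum(diff(fpr_grid) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(curve = tibble::tibble(fpr = fpr_grid, tpr = tpr), auc = auc)
}

# Deterministic per-replication seed derivation (counter-based).
derive_seed <- function(master, setting_idx, rep_idx, purpose) {
  v <- (as.double(master) * 69069 + setting_idx * 1000003 +
        rep_idx * 2063 + purpose * 101) %% 2147483647
  as.integer(v) + 1L
}

parse_method <- function(method) {
  if (method == "proposed") return(list(kind = "proposed"))
  m <- regmatches(method, regexec("^(lrt|wald)-([0-9]+)$", method))[[1]]
  if (length(m) == 3L)
    return(list(kind = m[2], n_anchor = as.integer(m[3])))
  abort(sprintf("Unknown method '%s'.", method))
}

#' Replicated simulation study of anchor-free DIF inference
#'
#' Runs the full generate / fit / infer / detect pipeline over replicated
#' synthetic datasets for one or more design settings and computes the
#' study metrics: average mean-squared errors of the minimal-L1 estimates,
#' empirical FDR of Benjamini-Hochberg detection at `alpha`, per-item
#' confidence interval coverage, and vertically averaged ROC curves with
#' AUC per method. Anchored comparators use the lowest-indexed items
#' (DIF-free in every packaged design cell) as anchors.
#'
#' Replication-level failures are caught, logged and excluded; a setting
#' aborts if more than 10 percent of its replications fail.
#'
#' @param settings A `sim_setting` or list of them.
#' @param n_reps Replications per setting. Default 50.
#' @param methods Character vector from `"proposed"`, `"lrt-<k>"` (LRT with
#'   the first k items as anchors), `"wald-<k>"` (anchored Wald
#'   intervals). Default `"proposed"`.
#' @param M Monte-Carlo draws per replication for the proposed method.
#'   Default 2000.
#' @param alpha FDR level for detection. Default 0.05.
#' @param level Confidence level for intervals. Default 0.95.
#' @param master_seed Master seed; all per-replication seeds derive from it.
#' @param nodes Quadrature nodes. Default 31.
#' @param verbose Print a progress line per setting? Default `FALSE`.
#' @return An object of class `dif_study`: list with `settings` (tibble),
#'   `mse`, `fdr`, `coverage`, `auc`, `roc` (tibbles), `inference`
#'   (per-rep item-level results), `estimates` (per-rep parameter
#'   estimates), `failures`, and the study configuration.
#' @examples
#' \donttest{
#' st <- sim_setting(500, "small", "large", "low")
#' run_study(st, n_reps = 2, M = 500, master_seed = 1)
#' }
#' @export
run_study <- function(settings, n_reps = 50L, methods = "proposed",
                      M = 2000L, alpha = 0.05, level = 0.95,
                      master_seed = 1L, nodes = 31L, verbose = FALSE) {
  if (inherits(settings, "sim_setting")) settings <- list(settings)
  stopifnot(all(vapply(settings, inherits, logical(1), "sim_setting")))
  specs <- lapply(methods, parse_method)
  names(specs) <- methods
  quad <- gh_quadrature(nodes)

  est_rows <- list(); inf_rows <- list(); fail_rows <- list()
  for (si in seq_along(settings)) {
    st <- settings[[si]]
    truth <- st$params
    n_fail <- 0L
    for (r in seq_len(n_reps)) {
      res <- tryCatch({
        dat <- sim_responses(truth, st$n,
                             seed = derive_seed(master_seed, si, r, 1L))
        rep_est <- NULL; rep_inf <- list()
        for (mname in methods) {
          spec <- specs[[mname]]
          if (spec$kind == "proposed") {
            fit <- fit_ml1(dat, quad = quad)
            inf <- dif_infer(fit, M = M, level = level, alpha = alpha,
                             seed = derive_seed(master_seed, si, r, 2L))
            rep_est <- tibble::tibble(
              setting = st$label, rep = r, item_index = seq_len(truth$J),
              a = fit$params$a, d = fit$params$d,
              gamma = fit$params$gamma, beta = fit$params$beta,
              sigma2 = fit$params$sigma2)
            rep_inf[[mname]] <- tibble::tibble(
              setting = st$label, rep = r, method = mname,
              item_index = seq_len(truth$J), p_value = inf$p_value,
              detected = inf$bh_reject, ci_lo = inf$ci_lo,
              ci_hi = inf$ci_hi)
          } else if (spec$kind == "lrt") {
            lrt <- lrt_dif(dat, anchors = seq_len(spec$n_anchor),
                           quad = quad)
            rep_inf[[mname]] <- tibble::tibble(
              setting = st$label, rep = r, method = mname,
              item_index = lrt$item_index, p_value = lrt$p_value,
              detected = bh_select(lrt$p_value, alpha = alpha),
              ci_lo = NA_real_, ci_hi = NA_real_)
          } else {
            wd <- wald_dif(dat, anchors = seq_len(spec$n_anchor),
                           level = level, quad = quad)
            rep_inf[[mname]] <- tibble::tibble(
              setting = st$label, rep = r, method = mname,
              item_index = wd$item_index, p_value = NA_real_,
              detected = NA, ci_lo = wd$ci_lo, ci_hi = wd$ci_hi)
          }
        }
        list(est = rep_est, inf = dplyr::bind_rows(rep_inf))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        n_fail <- n_fail + 1L
        fail_rows[[length(fail_rows) + 1L]] <- tibble::tibble(
          setting = st$label, rep = r, message = conditionMessage(res))
        if (n_fail > 0.1 * n_reps)
          abort(sprintf(
            "Setting '%s': more than 10%% of replications failed (last: %s)",
            st$label, conditionMessage(res)))
        next
      }
      est_rows[[length(est_rows) + 1L]] <- res$est
      inf_rows[[length(inf_rows) + 1L]] <- res$inf
    }
    if (verbose)
      message(sprintf("setting %s: %d/%d replications ok",
                      st$label, n_reps - n_fail, n_reps))
  }

  estimates <- dplyr::bind_rows(est_rows)
  inference <- dplyr::bind_rows(inf_rows)
  truth_of <- setNames(lapply(settings, function(s) s$params),
                       vapply(settings, function(s) s$label, character(1)))

  mse <- NULL
  if (nrow(estimates) > 0) {
    mse <- estimates |>
      dplyr::group_by(.data$setting) |>
      dplyr::group_modify(function(df, key) {
        tr <- truth_of[[key$setting]]
        ests <- lapply(split(df, df$rep), function(dr) {
          dr <- dr[order(dr$item_index), ]
          mimic_params(dr$beta[1], dr$sigma2[1], dr$a, dr$d, dr$gamma)
        })
        compute_mse(ests, tr)
      }) |>
      dplyr::ungroup()
  }

  fdr <- coverage <- auc <- roc <- NULL
  if (nrow(inference) > 0) {
    fdr <- inference |>
      dplyr::filter(!is.na(.data$detected)) |>
      dplyr::group_by(.data$setting, .data$method) |>
      dplyr::group_modify(function(df, key) {
        tr <- truth_of[[key$setting]]
        items <- sort(unique(df$item_index))
        det <- df |>
          dplyr::arrange(.data$rep, .data$item_index)
        dmat <- matrix(det$detected, ncol = length(items), byrow = TRUE)
        fdp <- apply(dmat, 1L, function(dd) {
          nd <- sum(dd)
          if (nd == 0) 0 else sum(dd & tr$gamma[items] == 0) / nd
        })
        tibble::tibble(fdr = mean(fdp), mc_se = stats::sd(fdp) /
                         sqrt(length(fdp)), n_reps = length(fdp))
      }) |>
      dplyr::ungroup()
    coverage <- inference |>
      dplyr::filter(!is.na(.data$ci_lo)) |>
      dplyr::group_by(.data$setting, .data$method) |>
      dplyr::group_modify(function(df, key)
        compute_coverage(df, truth_of[[key$setting]])) |>
      dplyr::ungroup()
    rocs <- inference |>
      dplyr::filter(!is.na(.data$p_value)) |>
      dplyr::group_by(.data$setting, .data$method) |>
      dplyr::group_modify(function(df, key) {
        tr <- truth_of[[key$setting]]
        items <- sort(unique(df$item_index))
        pmat <- df |>
          dplyr::arrange(.data$rep, .data$item_index) |>
          dplyr::pull(.data$p_value) |>
          matrix(ncol = length(items), byrow = TRUE)
        ra <- compute_roc_auc(pmat, tr$gamma[items] != 0)
        dplyr::mutate(ra$curve, auc = ra$auc)
      }) |>
      dplyr::ungroup()
    auc <- rocs |>
      dplyr::distinct(.data$setting, .data$method, .data$auc)
    roc <- dplyr::select(rocs, -"auc")
  }

  structure(
    list(
      settings = tibble::tibble(
        setting = vapply(settings, function(s) s$label, character(1)),
        n = vapply(settings, function(s) s$n, integer(1)),
        d_regime = vapply(settings, function(s) s$d_regime, character(1)),
        dif_size = vapply(settings, function(s) s$dif_size, character(1)),
        dif_prop = vapply(settings, function(s) s$dif_prop, character(1))),
      mse = mse, fdr = fdr, coverage = coverage, auc = auc, roc = roc,
      estimates = estimates, inference = inference,
      failures = dplyr::bind_rows(fail_rows),
      n_reps = n_reps, methods = methods, M = M, alpha = alpha,
      level = level, master_seed = master_seed, truth = truth_of),
    class = "dif_study")
}

#' @export
print.dif_study <- function(x, ...) {
  cat(sprintf("<dif_study> %d setting(s) x %d replications | methods: %s\n",
              nrow(x$settings), x$n_reps, paste(x$methods, collapse = ", ")))
  if (!is.null(x$fdr)) { cat("Empirical FDR:\n"); print(x$fdr) }
  if (!is.null(x$auc)) { cat("AUC:\n"); print(x$auc) }
  invisible(x)
}
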