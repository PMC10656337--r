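#' L1 profile of the DIF vector over location shifts
#'
#' `l1_profile()` evaluates `h(c) = sum_j |gamma_j - a_j * c|`, the L1 norm
#' of the DIF-effect vector after a location shift `c` of the focal-group
#' latent mean. `h` is a nonnegative, convex, piecewise-linear function of
#' `c`; the minimal-L1 identification picks the representative of the
#' equivalence class at its minimizer.
#'
#' @param gamma Numeric vector of DIF effects, length J.
#' @param a Numeric vector of discrimination slopes, length J.
#' @param c Shift value(s); vectorised.
#' @return `h(c)`, same length as `c`.
#' @examples
#' l1_profile(c(rep(0, 8), 1, 1), rep(1, 10), c = 0) # 2
#' @export
l1_profile <- function(gamma, a, c) {
  if (length(gamma) != length(a))
    abort("`gamma` and `a` must have the same length.")
  vapply(c, function(ci) sum(abs(gamma - a * ci)), numeric(1))
}

# Lower weighted median of points r with weights w (> 0): the smallest r_(k)
# whose cumulative weight reaches half the total. This is the smallest
# minimizer of sum_j w_j |r_j - c|.
weighted_median_lower <- function(r, w) {
  o <- order(r)
  cw <- cumsum(w[o])
  r[o][which(cw >= cw[length(cw)] / 2)[1]]
}

#' Minimal-L1 location shift (weighted-median LAD solver)
#'
#' Finds `c* = argmin_c sum_j |gamma_j - a_j * c|`. Writing each term as
#' `|a_j| * |gamma_j / a_j - c|`, the problem is a one-dimensional least
#' absolute deviations fit whose solution is a weighted median of the ratio
#' points `gamma_j / a_j` with weights `|a_j|`. When the minimizing set is a
#' flat interval (total weight splits exactly in half) the lower weighted
#' median - the smallest minimizing breakpoint - is returned.
#'
#' Items with `a_j = 0` contribute a constant to the profile and are dropped
#' from the minimization with a warning.
#'
#' @inheritParams l1_profile
#' @return The minimizing shift `c*` (scalar).
#' @examples
#' ml1_shift(c(rep(0, 8), 1, 1), rep(1, 10)) # 0
#' @export
ml1_shift <- function(gamma, a) {
  if (length(gamma) != length(a))
    abort("`gamma` and `a` must have the same length.")
  keep <- a != 0
  if (!any(keep))
    abort("All discrimination slopes are zero: the shift is unidentified.")
  if (!all(keep))
    warn(sprintf("%d item(s) with a_j = 0 dropped from the L1 minimization.",
                 sum(!keep)))
  g <- gamma[keep]; aa <- a[keep]
  weighted_median_lower(g / aa, abs(aa))
}

new_ml1_verdict <- function(holds, ineq7, ineq8, rho_star = NA_real_,
                            notes = "") {
  structure(list(holds = holds, ineq7_lhs = ineq7, ineq8_lhs = ineq8,
                 rho_star = rho_star, notes = notes),
            class = "ml1_verdict")
}

#' @export
print.ml1_verdict <- function(x, ...) {
  cat(sprintf("<ml1_verdict> holds: %s\n", x$holds))
  cat(sprintf("  left-derivative sum:  %.6g (needs < 0)\n", x$ineq7_lhs))
  cat(sprintf("  right-derivative sum: %.6g (needs > 0)\n", x$ineq8_lhs))
  if (is.finite(x$rho_star))
    cat(sprintf("  rho* = %.6g\n", x$rho_star))
  if (nzchar(x$notes)) cat(" ", x$notes, "\n")
  invisible(x)
}

#' Necessary-and-sufficient check of the minimal-L1 condition
#'
#' The minimal-L1 (ML1) condition holds for a parameter set when its DIF
#' vector has strictly the smallest L1 norm within its location-shift
#' equivalence class, i.e. `h(c)` has its unique minimum at `c = 0`.
#' `check_prop1()` evaluates the two signed indicator sums that are the one-
#' sided derivatives of `h` at 0: with `r_j = gamma_j / a_j`,
#' `sum_j |a_j| (-I(r_j >= 0) + I(r_j < 0))` must be strictly negative
#' (left derivative) and `sum_j |a_j| (-I(r_j > 0) + I(r_j <= 0))` strictly
#' positive (right derivative). Both hold if and only if the condition does.
#'
#' @inheritParams l1_profile
#' @return An `ml1_verdict` with fields `holds`, `ineq7_lhs`, `ineq8_lhs`.
#' @examples
#' check_prop1(c(rep(0, 8), 1, 1), rep(1, 10))$holds # TRUE
#' @export
check_prop1 <- function(gamma, a) {
  if (length(gamma) != length(a))
    abort("`gamma` and `a` must have the same length.")
  if (any(a == 0))
    abort("The condition check assumes a_j != 0 for every item.")
  r <- gamma / a
  w <- abs(a)
  lhs7 <- sum(w * (-(r >= 0) + (r < 0)))
  lhs8 <- sum(w * (-(r > 0) + (r <= 0)))
  new_ml1_verdict(lhs7 < 0 && lhs8 > 0, lhs7, lhs8,
                  notes = "necessary and sufficient form")
}

#' Sufficient (count-based) check of the minimal-L1 condition
#'
#' A coarser check than [check_prop1()] that only uses item counts and the
#' discrimination spread `rho* = max|a| / min|a|`: the condition holds if
#' `#\{r_j <= 0\} > rho* * #\{r_j > 0\}` and `#\{r_j >= 0\} > rho* *
#' #\{r_j < 0\}` (with `r_j = gamma_j / a_j`). Sufficient but not necessary:
#' it can fail while [check_prop1()] holds, e.g. with balanced positive and
#' negative DIF and a large `rho*`.
#'
#' @inheritParams l1_profile
#' @return An `ml1_verdict`; `ineq7_lhs`/`ineq8_lhs` hold the two count
#'   margins (`lhs - rho* * rhs`, both must be > 0) and `rho_star` the
#'   discrimination ratio.
#' @export
check_cor1 <- function(gamma, a) {
  if (length(gamma) != length(a))
    abort("`gamma` and `a` must have the same length.")
  if (any(a == 0))
    abort("The condition check assumes a_j != 0 for every item.")
  r <- gamma / a
  rho <- max(abs(a)) / min(abs(a))
  m1 <- sum(r <= 0) - rho * sum(r > 0)
  m2 <- sum(r >= 0) - rho * sum(r < 0)
  new_ml1_verdict(m1 > 0 && m2 > 0, m1, m2, rho_star = rho,
                  notes = "sufficient (count) form")
}

#' Re-identify a parameter set to its minimal-L1 representative
#'
#' Computes the minimal-L1 shift `c_hat = ml1_shift(gamma, a)` and returns
#' the equivalent parameter set `\{beta + c_hat, sigma2, a, d, gamma - a *
#' c_hat\}`. The j-th DIF effect of the result is the `G_j` map of the
#' input: the DIF effect of the minimal-L1 representative of its equivalence
#' class. The transform never increases the L1 norm of `gamma` and is
#' idempotent.
#'
#' @param params A [mimic_params()] object.
#' @return A list with `params` (the re-identified `mimic_params`) and
#'   `shift` (the applied `c_hat`).
#' @export
ml1_transform <- function(params) {
  stopifnot(inherits(params, "mimic_params"))
  c_hat <- ml1_shift(params$gamma, params$a)
  list(params = shift_params(params, c_hat), shift = c_hat)
}
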