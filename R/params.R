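#' MIMIC 2PL parameter set
#'
#' Bundles the full parameter set of the MIMIC two-parameter logistic model
#' for uniform DIF: the focal-group latent mean `beta` and variance `sigma2`
#' (the reference group's latent trait is fixed at N(0, 1)), the item
#' discrimination slopes `a`, easiness intercepts `d`, and uniform DIF
#' effects `gamma`, one per item.
#'
#' @param beta Focal-group latent mean (real scalar).
#' @param sigma2 Focal-group latent variance (positive scalar).
#' @param a Numeric vector of discrimination slopes, length J.
#' @param d Numeric vector of easiness intercepts, length J.
#' @param gamma Numeric vector of uniform DIF effects, length J.
#'
#' @return An object of class `mimic_params`: a list with elements `beta`,
#'   `sigma2`, `a`, `d`, `gamma`, and `J` (number of items).
#'
#' @examples
#' p <- mimic_params(beta = 0.5, sigma2 = 0.25,
#'                   a = c(1.3, 1.4, 1.5), d = c(0.8, 0.2, -0.4),
#'                   gamma = c(0, 0, 0.6))
#' tidy(p)
#' @export
mimic_params <- function(beta, sigma2, a, d, gamma) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta))
    abort("`beta` must be a finite numeric scalar.")
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) ||
      sigma2 <= 0)
    abort("`sigma2` must be a finite positive scalar.")
  a <- as.numeric(a); d <- as.numeric(d); gamma <- as.numeric(gamma)
  J <- length(a)
  if (length(d) != J || length(gamma) != J)
    abort("`a`, `d` and `gamma` must have the same length.")
  if (J < 1L) abort("At least one item is required.")
  if (!all(is.finite(a)) || !all(is.finite(d)) || !all(is.finite(gamma)))
    abort("All item parameters must be finite.")
  structure(
    list(beta = beta, sigma2 = sigma2, a = a, d = d, gamma = gamma, J = J),
    class = "mimic_params"
  )
}

#' @export
print.mimic_params <- function(x, ...) {
  cat("<mimic_params> J =", x$J,
      sprintf("| beta = %.4g, sigma2 = %.4g\n", x$beta, x$sigma2))
  print(tidy(x), ...)
  invisible(x)
}

#' @describeIn mimic_params Per-item parameters as a tibble with columns
#'   `item`, `a`, `d`, `gamma`.
#' @param x A `mimic_params` object.
#' @param ... Unused.
#' @method tidy mimic_params
#' @export
tidy.mimic_params <- function(x, ...) {
  tibble::tibble(item = seq_len(x$J), a = x$a, d = x$d, gamma = x$gamma)
}

#' Apply a location shift within the equivalence class
#'
#' For any constant `c`, replacing `beta` by `beta + c` and every DIF effect
#' `gamma_j` by `gamma_j - a_j * c` leaves the data distribution of the MIMIC
#' model unchanged. This helper produces that equivalent parameter set; it is
#' the map whose orbit the minimal-L1 identification selects from.
#'
#' @param params A [mimic_params()] object.
#' @param c Location shift (real scalar).
#' @return A `mimic_params` object representing the same data distribution.
#' @export
shift_params <- function(params, c) {
  stopifnot(inherits(params, "mimic_params"))
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c))
    abort("`c` must be a finite numeric scalar.")
  mimic_params(params$beta + c, params$sigma2,
               params$a, params$d, params$gamma - params$a * c)
}
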