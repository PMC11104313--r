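#' Learner parameters for the competing-critics model
#'
#' Bundles the five scalar parameters that govern learning and choice:
#' the shared learning rate `alpha`, discount factor `gamma`, exploration
#' probability `epsilon`, and the two asymmetry weights `k_plus` (optimism:
#' how strongly the optimistic critic up-weights positive prediction errors)
#' and `k_minus` (pessimism: how strongly the pessimistic critic up-weights
#' negative prediction errors).
#'
#' Defaults are the reference simulation setting
#' `(alpha, epsilon, gamma, k_plus, k_minus) = (0.5, 0.3, 0, 0.9, 0.9)`.
#'
#' @param alpha Learning rate, in (0, 1].
#' @param epsilon Exploration probability, in \[0, 1\].
#' @param gamma Discount factor, in \[0, 1).
#' @param k_plus Optimism weight, in \[0, 1\].
#' @param k_minus Pessimism weight, in \[0, 1\].
#' @return An object of class `critic_params` (a named list).
#' @examples
#' p <- critic_params()
#' sensitivity_coords(p)
#' @export
critic_params <- function(alpha = 0.5, epsilon = 0.3, gamma = 0,
                          k_plus = 0.9, k_minus = 0.9) {
  chk_scalar <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("`%s` must be a finite numeric scalar", nm), call. = FALSE)
  }
  for (nm in c("alpha", "epsilon", "gamma", "k_plus", "k_minus"))
    chk_scalar(get(nm), nm)
  if (alpha <= 0 || alpha > 1)
    stop("`alpha` must lie in (0, 1], got ", alpha, call. = FALSE)
  if (gamma < 0 || gamma >= 1)
    stop("`gamma` must lie in [0, 1), got ", gamma, call. = FALSE)
  if (epsilon < 0 || epsilon > 1)
    stop("`epsilon` must lie in [0, 1], got ", epsilon, call. = FALSE)
  if (k_plus < 0 || k_plus > 1)
    stop("`k_plus` must lie in [0, 1], got ", k_plus, call. = FALSE)
  if (k_minus < 0 || k_minus > 1)
    stop("`k_minus` must lie in [0, 1], got ", k_minus, call. = FALSE)
  structure(
    list(alpha = alpha, epsilon = epsilon, gamma = gamma,
         k_plus = k_plus, k_minus = k_minus),
    class = "critic_params"
  )
}

#' @export
print.critic_params <- function(x, ...) {
  cat("<critic_params>\n")
  cat(sprintf("  alpha = %g, epsilon = %g, gamma = %g\n",
              x$alpha, x$epsilon, x$gamma))
  cat(sprintf("  k_plus = %g, k_minus = %g  (s_r = %g, s_u = %g)\n",
              x$k_plus, x$k_minus,
              x$k_plus - x$k_minus, x$k_plus + x$k_minus))
  invisible(x)
}

#' Risk- and uncertainty-sensitivity coordinates
#'
#' The behaviourally meaningful axes are a 45-degree rotation of the
#' `(k_plus, k_minus)` parameter axes: the risk-sensitivity axis
#' `s_r = k_plus - k_minus` (shifts the midpoint of the two critics relative
#' to expected reward) and the uncertainty-sensitivity axis
#' `s_u = k_plus + k_minus` (widens the interval between them, governing how
#' many actions look like viable competitors).
#'
#' @param params A [critic_params()] object, or anything with `k_plus` and
#'   `k_minus` fields.
#' @return A named list with `s_r` in \[-1, 1\] and `s_u` in \[0, 2\].
#' @seealso [coords_to_weights()] for the inverse map.
#' @export
sensitivity_coords <- function(params) {
  list(s_r = params$k_plus - params$k_minus,
       s_u = params$k_plus + params$k_minus)
}

#' Invert sensitivity coordinates back to asymmetry weights
#'
#' @param s_r Risk sensitivity, in \[-1, 1\].
#' @param s_u Uncertainty sensitivity, in \[0, 2\].
#' @return Named list with `k_plus = (s_u + s_r) / 2` and
#'   `k_minus = (s_u - s_r) / 2`.
#' @export
coords_to_weights <- function(s_r, s_u) {
  k_plus <- (s_u + s_r) / 2
  k_minus <- (s_u - s_r) / 2
  if (any(k_plus < -1e-12) || any(k_plus > 1 + 1e-12) ||
      any(k_minus < -1e-12) || any(k_minus > 1 + 1e-12))
    stop("(s_r, s_u) maps outside the unit square of (k_plus, k_minus)",
         call. = FALSE)
  list(k_plus = pmin(pmax(k_plus, 0), 1), k_minus = pmin(pmax(k_minus, 0), 1))
}
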