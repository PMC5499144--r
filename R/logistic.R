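#' Logistic growth law
#'
#' Population density under logistic growth,
#' \deqn{G(t) = \frac{K G_0 e^{rt}}{K + G_0 (e^{rt} - 1)},}
#' the generative model assumed for every culture in a QFA screen. The
#' implementation uses the overflow-safe form
#' \eqn{G(t) = K / (1 + ((K - G_0)/G_0) e^{-rt})}.
#'
#' @param t Time in days (vector allowed), `t >= 0`.
#' @param K Carrying capacity, intensity units, `K > 0`.
#' @param r Intrinsic growth rate, 1/day, `r >= 0`.
#' @param G0 Inoculum density, intensity units, `0 < G0 <= K`.
#' @return Density at `t`, same length as `t`. `G(0) = G0`; `G(t) -> K` as
#'   `t -> Inf`; constant at `G0` when `r = 0`.
#' @examples
#' logistic_growth(0:5, K = 0.2, r = 3, G0 = 0.003)
#' @export
logistic_growth <- function(t, K, r, G0) {
  check_logistic_params(K, r, G0)
  if (!all(is.finite(t)) || any(t < 0)) {
    stop("invalid parameter: 't' must be finite and >= 0", call. = FALSE)
  }
  K / (1 + ((K - G0) / G0) * exp(-r * t))
}

# shared validation for the logistic kernel
check_logistic_params <- function(K, r, G0) {
  ok <- length(K) == 1 && length(r) == 1 && length(G0) == 1 &&
    is.finite(K) && is.finite(r) && is.finite(G0) &&
    K > 0 && r >= 0 && G0 > 0 && G0 <= K
  if (!ok) {
    stop("invalid parameter: need K > 0, r >= 0, 0 < G0 <= K, all finite",
         call. = FALSE)
  }
  invisible(TRUE)
}

# log of the logistic kernel, numerically stable for large r*t
log_logistic_growth <- function(t, K, r, G0) {
  log(K) - log1p(((K - G0) / G0) * exp(-r * t))
}

#' Population doubling time from the inoculum
#'
#' Time for a logistic culture to grow from `G0` to `2 * G0`. Closed form:
#' `t_d = log(2 * (K - G0) / (K - 2 * G0)) / r`, defined when `K > 2 * G0`
#' and `r > 0`; `Inf` when doubling is impossible (`K <= 2 * G0` or `r = 0`).
#'
#' @inheritParams logistic_growth
#' @return Doubling time in days.
#' @export
doubling_time <- function(K, r, G0) {
  check_logistic_params(K, r, G0)
  if (r == 0 || K <= 2 * G0) return(Inf)
  log(2 * (K - G0) / (K - 2 * G0)) / r
}
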