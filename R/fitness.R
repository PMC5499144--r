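#' Fitness of a culture: MDR, MDP and their product
#'
#' Converts a logistic fit into the three QFA fitness summaries:
#'
#' * MDP (Maximum Doubling Potential) — doublings from inoculum to carrying
#'   capacity, `log2(K / G0)`.
#' * MDR (Maximum Doubling Rate) — reciprocal of the time the culture takes
#'   to double from its inoculum, `r / log(2 * (K - G0) / (K - 2 * G0))`
#'   (doublings/day). When `K <= 2 * G0` the culture can never double within
#'   its logistic ceiling, so MDR falls back to the exponential-phase rate
#'   `r / log(2)` and the result is flagged (`mdr_fallback`).
#' * fitness — `MDR * MDP`, doublings squared per day.
#'
#' Fits with status `"dead"` or `"failed"` get fitness exactly 0 (all three
#' components 0), the QFA convention for cultures that never grow.
#'
#' @param fit A `logistic_fit` (see [fit_logistic()]), or any list with
#'   elements `K`, `r`, `G0` and `status`.
#' @return A `fitness_measure`: list with `mdr` (doublings/day), `mdp`
#'   (doublings), `fitness` (doublings^2/day) and `mdr_fallback` (logical).
#' @examples
#' f <- list(K = 1.024, r = 2, G0 = 0.001, status = "ok")
#' compute_fitness(f)$mdp  # 10 doublings
#' @export
compute_fitness <- function(fit) {
  if (is.null(fit$status)) stop("fit must carry a 'status' field", call. = FALSE)
  if (fit$status != "ok") {
    out <- list(mdr = 0, mdp = 0, fitness = 0, mdr_fallback = FALSE)
    class(out) <- "fitness_measure"
    return(out)
  }
  K <- fit$K; r <- fit$r; G0 <- fit$G0
  check_logistic_params(K, r, G0)
  mdp <- log2(K / G0)
  fallback <- K <= 2 * G0
  mdr <- if (fallback) r / log(2) else r / log(2 * (K - G0) / (K - 2 * G0))
  out <- list(mdr = mdr, mdp = mdp, fitness = mdr * mdp, mdr_fallback = fallback)
  class(out) <- "fitness_measure"
  out
}

#' @export
print.fitness_measure <- function(x, ...) {
  cat(sprintf("MDR %.4g doublings/day, MDP %.4g doublings, fitness %.4g d^2/day%s\n",
              x$mdr, x$mdp, x$fitness,
              if (isTRUE(x$mdr_fallback)) " (MDR exponential-phase fallback)" else ""))
  invisible(x)
}

# vectorized fitness from parameter vectors; status vector gates zeros
fitness_from_params <- function(K, r, G0, status = NULL) {
  mdp <- log2(K / G0)
  fallback <- K <= 2 * G0
  denom <- ifelse(fallback, log(2), log(2 * (K - G0) / (K - 2 * G0)))
  mdr <- r / denom
  fit <- mdr * mdp
  if (!is.null(status)) {
    bad <- status != "ok"
    mdr[bad] <- 0; mdp[bad] <- 0; fit[bad] <- 0
  }
  data.frame(mdr = mdr, mdp = mdp, fitness = fit, mdr_fallback = fallback)
}
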