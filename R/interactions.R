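#' Estimate the genetic-independence slope
#'
#' Under multiplicative genetic independence, a query mutation scales every
#' non-interacting deletion strain's fitness by a common factor `m`, so the
#' per-gene (control, query) mean fitnesses of non-interacting genes lie on a
#' line through the origin with slope `m`. `lsq_origin` is ordinary least
#' squares through the origin, `sum(x*y) / sum(x^2)` over per-gene means.
#' `robust` (the default used by the pipeline) is iteratively reweighted
#' least squares with Tukey bisquare weights, so a minority of true
#' suppressors/enhancers does not bias the slope; it iterates at most 20
#' times to a tolerance of 1e-8 on `m`, with the bisquare tuning constant
#' 4.685 times the MAD of residuals.
#'
#' @param control,query `screen_fitness_table`s sharing at least 10 ORFs.
#' @param method `"robust"` or `"lsq_origin"`.
#' @return The slope `m > 0`.
#' @export
estimate_independence_slope <- function(control, query,
                                        method = c("robust", "lsq_origin")) {
  method <- match.arg(method)
  sh <- shared_means(control, query)
  if (nrow(sh) < 10) {
    stop("insufficient overlap: need >= 10 shared ORFs, have ", nrow(sh),
         call. = FALSE)
  }
  x <- sh$F_control; y <- sh$F_query
  if (all(x == 0)) stop("degenerate screen: all control mean fitnesses are 0",
                        call. = FALSE)
  m <- sum(x * y) / sum(x^2)
  if (method == "lsq_origin") return(m)
  for (i in 1:20) {
    res <- y - m * x
    s <- stats::mad(res, center = 0)
    if (s <= 0) break
    u <- res / (4.685 * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    denom <- sum(w * x^2)
    if (denom <= 0) break
    m_new <- sum(w * x * y) / denom
    if (abs(m_new - m) < 1e-8) {
      m <- m_new
      break
    }
    m <- m_new
  }
  m
}

# per-gene mean fitness for ORFs present in both screens, plus replicates
shared_means <- function(control, query) {
  common <- intersect(control$table$orf, query$table$orf)
  common <- sort(common)
  ic <- match(common, control$table$orf)
  iq <- match(common, query$table$orf)
  data.frame(orf = common,
             gene = control$table$gene[ic],
             F_control = control$table$fitness_mean[ic],
             F_query = query$table$fitness_mean[iq],
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (delegating to
#' [stats::p.adjust()] with `method = "BH"` on the non-missing entries).
#' Missing values pass through as missing and do not count toward the number
#' of tests.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`; `NA` allowed.
#' @return Adjusted q-values, order-preserving with the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("invalid input: p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(pvalues))
  q[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  q
}

#' Score genetic interactions between a control and a query screen
#'
#' For each ORF shared by the two screens, compares observed query-background
#' fitness with the independence prediction `m * F_control`. The genetic
#' interaction strength is `gis = F_query - m * F_control` (doublings squared
#' per day): positive deviations are suppressors of the query defect (the
#' point lies above the independence line of a fitness plot), negative ones
#' enhancers. Significance comes from a two-sided Welch t-test of the query
#' replicate fitnesses against the m-scaled control replicate fitnesses, so
#' the null is centered on the independence prediction; q-values are
#' Benjamini-Hochberg across all shared ORFs, and calls are made at
#' `q <= q_threshold` with the direction given by the sign of `gis`.
#'
#' Genes with fewer than 2 replicates in either screen get `NA` p/q, call
#' `"none"` and `flagged = TRUE`. Genes absent from either screen are
#' dropped and listed in the `coverage` attribute.
#'
#' @param control,query `screen_fitness_table`s.
#' @param m Independence slope; `NULL` (default) estimates it with
#'   [estimate_independence_slope()].
#' @param q_threshold FDR threshold for suppressor/enhancer calls, in (0, 1).
#' @param slope_method Passed to the slope estimate when `m` is `NULL`.
#' @return A `data.frame` of class `interaction_table`, one row per shared
#'   ORF: `orf`, `gene`, `F_control`, `F_query`, `F_pred`, `gis`, `p`, `q`,
#'   `call`, `flagged`; attributes `m`, `q_threshold`, `screen_ids` and
#'   `coverage` (ORFs present in only one screen).
#' @export
compute_interactions <- function(control, query, m = NULL, q_threshold = 0.05,
                                 slope_method = "robust") {
  stopifnot(q_threshold > 0, q_threshold < 1)
  if (is.null(m)) {
    m <- estimate_independence_slope(control, query, method = slope_method)
  }
  sh <- shared_means(control, query)
  dropped <- sort(union(setdiff(control$table$orf, query$table$orf),
                        setdiff(query$table$orf, control$table$orf)))
  p <- vapply(sh$orf, function(o) {
    qc <- query$replicates[[o]]
    cc <- control$replicates[[o]] * m
    if (length(qc) < 2 || length(cc) < 2) return(NA_real_)
    if (stats::sd(qc) == 0 && stats::sd(cc) == 0) {
      return(if (isTRUE(all.equal(mean(qc), mean(cc)))) 1 else 0)
    }
    tryCatch(stats::t.test(qc, cc)$p.value, error = function(e) NA_real_)
  }, 0)
  q <- bh_fdr(p)
  gis <- sh$F_query - m * sh$F_control
  call <- ifelse(is.na(q) | q > q_threshold, "none",
                 ifelse(gis > 0, "suppressor", "enhancer"))
  out <- data.frame(orf = sh$orf, gene = sh$gene,
                    F_control = sh$F_control, F_query = sh$F_query,
                    F_pred = m * sh$F_control, gis = gis,
                    p = unname(p), q = unname(q), call = call,
                    flagged = is.na(p))
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "q_threshold") <- q_threshold
  attr(out, "screen_ids") <- c(control = control$screen_id,
                               query = query$screen_id)
  attr(out, "coverage") <- dropped
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("interaction_table: %d ORFs, m=%.4g, %d suppressors / %d enhancers at q<=%.3g\n",
              nrow(x), attr(x, "m"), sum(x$call == "suppressor"),
              sum(x$call == "enhancer"), attr(x, "q_threshold")))
  NextMethod()
}
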