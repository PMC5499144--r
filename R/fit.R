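#' Construct a growth curve record
#'
#' One culture's timed colony-intensity series plus its plate and gene
#' metadata: the unit of measurement behind every point on a fitness plot.
#'
#' @param time Observation times in days, strictly increasing, `>= 0`.
#' @param intensity Colony intensities, arbitrary units, `> 0`.
#' @param screen_id,barcode Screen and plate identifiers.
#' @param row,column 1-based plate coordinates.
#' @param orf,gene Systematic ORF name and gene name.
#' @param background `"control"` or `"query"`.
#' @param treatment Treatment label (e.g. `"chronic_27C"`, `"UD"`).
#' @return A `growth_curve` object.
#' @export
growth_curve <- function(time, intensity, screen_id = "S1", barcode = "P001",
                         row = 1L, column = 1L, orf = "YXX0001W", gene = orf,
                         background = "control", treatment = "chronic") {
  if (length(time) != length(intensity)) {
    stop("time and intensity must have equal length", call. = FALSE)
  }
  if (is.unsorted(time, strictly = TRUE)) {
    stop("data error: times must be strictly increasing within a culture",
         call. = FALSE)
  }
  if (any(time < 0) || any(!is.finite(time)) || any(!is.finite(intensity))) {
    stop("data error: times must be finite and >= 0, intensities finite",
         call. = FALSE)
  }
  if (!background %in% c("control", "query")) {
    stop("data error: unknown background label '", background, "'",
         call. = FALSE)
  }
  structure(list(screen_id = screen_id, barcode = barcode,
                 row = as.integer(row), column = as.integer(column),
                 orf = orf, gene = gene, background = background,
                 treatment = treatment,
                 time = as.numeric(time), intensity = as.numeric(intensity)),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("growth_curve %s/%s (%d,%d) %s [%s]: %d obs over %.3g days\n",
              x$screen_id, x$barcode, x$row, x$column, x$orf, x$background,
              length(x$time), max(x$time)))
  invisible(x)
}

#' Fit the logistic growth model to one culture
#'
#' Least squares on log intensities (matching multiplicative imaging noise),
#' minimized by Levenberg-Marquardt with box constraints and an analytic
#' Jacobian. Cultures whose intensity range never exceeds `dead_threshold`
#' fold change are classed dead without fitting; dead and failed cultures get
#' fitness 0 downstream.
#'
#' Initialization: `K0 = max(intensity)`, `G00 = min(intensity)`, `r0` from
#' the slope of log intensity regressed on time over observations between 10
#' and 90 per cent of the maximum; one retry from `(2*K0, r0/2, G00/2)`
#' before declaring the fit failed. Bounds: `K` in `[0.5, 10] * max`, `G0`
#' in `[0.1 * min, 0.25 * max]`, `r` in `[1e-3, 50]` per day.
#'
#' @param curve A [growth_curve()] with at least 4 observations, or any list
#'   with numeric `time` and `intensity`.
#' @param dead_threshold Minimum fold change `max/min` a culture must show to
#'   be fit at all (default 1.75).
#' @return A `logistic_fit`: list with `K`, `r`, `G0`, `rss` (residual sum of
#'   squares on log intensities), `n_obs` and `status` in
#'   `{"ok", "dead", "failed"}`.
#' @export
fit_logistic <- function(curve, dead_threshold = 1.75) {
  t <- curve$time; y <- curve$intensity
  if (length(t) < 4) {
    stop("insufficient data: need at least 4 observations to fit", call. = FALSE)
  }
  if (is.unsorted(t, strictly = TRUE)) {
    stop("data error: times must be strictly increasing", call. = FALSE)
  }
  out <- fit_logistic_core(t, y, dead_threshold)
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("logistic_fit [ok]: K=%.5g, r=%.5g /day, G0=%.5g, rss=%.3g (n=%d)\n",
                x$K, x$r, x$G0, x$rss, x$n_obs))
  } else {
    cat(sprintf("logistic_fit [%s] (n=%d)\n", x$status, x$n_obs))
  }
  invisible(x)
}

# intensity floor guarding log() of near-zero readings
INTENSITY_FLOOR <- 1e-6

# workhorse: no class dispatch, called in bulk by fit_screen()
fit_logistic_core <- function(t, y, dead_threshold = 1.75) {
  n <- length(y)
  ymax <- max(y); ymin <- min(y)
  if (ymax < dead_threshold * ymin) {
    return(list(K = NA_real_, r = NA_real_, G0 = NA_real_, rss = NA_real_,
                n_obs = n, status = "dead"))
  }
  logy <- log(pmax(y, INTENSITY_FLOOR))

  # r0 from log-linear slope over the 10-90% band of the range
  band <- y >= 0.1 * ymax & y <= 0.9 * ymax
  r0 <- if (sum(band) >= 2 && diff(range(t[band])) > 0) {
    stats::cov(t[band], logy[band]) / stats::var(t[band])
  } else {
    (logy[n] - logy[1]) / max(t[n] - t[1], .Machine$double.eps)
  }
  lower <- c(K = 0.5 * ymax, r = 1e-3, G0 = 0.1 * ymin)
  upper <- c(K = 10 * ymax, r = 50, G0 = 0.25 * ymax)
  clip <- function(p) pmin(pmax(p, lower), upper)

  resid_fn <- function(p) {
    A <- ((p[1] - p[3]) / p[3]) * exp(-p[2] * t)
    (log(p[1]) - log1p(A)) - logy
  }
  jac_fn <- function(p) {
    e <- exp(-p[2] * t)
    A <- ((p[1] - p[3]) / p[3]) * e
    S <- 1 + A
    cbind(1 / p[1] - (e / p[3]) / S,
          t * A / S,
          (p[1] * e / p[3]^2) / S)
  }
  try_fit <- function(start) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = clip(start), lower = lower, upper = upper,
                         fn = resid_fn, jac = jac_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) return(NULL)
    p <- fit$par
    if (!all(is.finite(p)) || p[1] <= p[3] || p[3] <= 0 || p[2] <= 0) return(NULL)
    list(p = p, rss = sum(fit$fvec^2))
  }

  start1 <- c(K = ymax, r = r0, G0 = ymin)
  res <- try_fit(start1)
  if (is.null(res)) res <- try_fit(c(K = 2 * ymax, r = r0 / 2, G0 = ymin / 2))
  if (is.null(res)) {
    return(list(K = NA_real_, r = NA_real_, G0 = NA_real_, rss = NA_real_,
                n_obs = n, status = "failed"))
  }
  list(K = unname(res$p[1]), r = unname(res$p[2]), G0 = unname(res$p[3]),
       rss = res$rss, n_obs = n, status = "ok")
}

#' Fit every culture of a raw screen table
#'
#' Groups a long raw time-series table (one row per culture per timepoint;
#' see [read_raw_timeseries()] for the schema) into cultures, fits the
#' logistic model to each and attaches MDR, MDP and fitness.
#'
#' @param raw Raw screen `data.frame` in the long schema.
#' @param dead_threshold Passed to the dead-culture rule of [fit_logistic()].
#' @return A `data.frame` with one row per culture: the culture key columns,
#'   fitted `K`, `r`, `G0`, `rss`, `status`, and `mdr`, `mdp`, `fitness`.
#' @export
fit_screen <- function(raw, dead_threshold = 1.75) {
  raw <- validate_raw_schema(raw)
  key <- culture_key(raw)
  ord <- order(key, raw$time_days)
  raw <- raw[ord, ]
  key <- key[ord]
  idx <- split(seq_len(nrow(raw)), factor(key, levels = unique(key)))
  first <- vapply(idx, `[`, integer(1), 1L)
  meta <- raw[first, c("screen_id", "barcode", "row", "column", "orf", "gene",
                       "background", "treatment")]
  fits <- lapply(idx, function(i) {
    ti <- raw$time_days[i]
    if (anyDuplicated(ti)) {
      stop("data error: non-monotone times in culture ", key[i[1]], call. = FALSE)
    }
    fit_logistic_core(ti, raw$intensity[i], dead_threshold)
  })
  fdf <- data.frame(K = vapply(fits, `[[`, 0, "K"),
                    r = vapply(fits, `[[`, 0, "r"),
                    G0 = vapply(fits, `[[`, 0, "G0"),
                    rss = vapply(fits, `[[`, 0, "rss"),
                    n_obs = vapply(fits, `[[`, 0L, "n_obs"),
                    status = vapply(fits, `[[`, "", "status"))
  fitm <- fitness_from_params(fdf$K, fdf$r, fdf$G0, fdf$status)
  fitm$mdr_fallback[fdf$status != "ok"] <- FALSE
  out <- cbind(meta, fdf, fitm)
  rownames(out) <- NULL
  out
}

#' Summarize a screen as per-gene replicate fitnesses
#'
#' Aggregates culture-level fitness into the per-ORF table downstream
#' interaction scoring consumes: one row per ORF with its replicate fitness
#' values, replicate count, mean and median. Dead and failed cultures
#' contribute fitness 0 and are counted as replicates.
#'
#' @param curves A list of [growth_curve()]s, a raw screen `data.frame`, or a
#'   culture-level fit table from [fit_screen()]. All cultures must share one
#'   `screen_id` and one `background`.
#' @param dead_threshold Dead-culture rule threshold, see [fit_logistic()].
#' @return A `screen_fitness_table`: list with `screen_id`, `background`,
#'   `treatment`, `table` (data.frame: `orf`, `gene`, `n`, `mdr_mean`,
#'   `mdp_mean`, `fitness_mean`, `fitness_median`, ORFs sorted
#'   lexicographically), `replicates` (named list of per-ORF fitness
#'   vectors) and `cultures` (the culture-level fit table).
#' @export
summarize_screen <- function(curves, dead_threshold = 1.75) {
  fits <- if (is.data.frame(curves) && "fitness" %in% names(curves)) {
    curves
  } else if (is.data.frame(curves)) {
    fit_screen(curves, dead_threshold)
  } else {
    fit_screen(raw_from_curves(curves), dead_threshold)
  }
  if (length(unique(fits$screen_id)) != 1 || length(unique(fits$background)) != 1) {
    stop("inconsistency error: cultures mix screen_id or background labels",
         call. = FALSE)
  }
  o <- order(fits$orf)
  fits <- fits[o, ]
  reps <- split(fits$fitness, factor(fits$orf, levels = unique(fits$orf)))
  mdr <- split(fits$mdr, factor(fits$orf, levels = unique(fits$orf)))
  mdp <- split(fits$mdp, factor(fits$orf, levels = unique(fits$orf)))
  genes <- fits$gene[!duplicated(fits$orf)]
  tab <- data.frame(
    orf = names(reps),
    gene = genes,
    n = lengths(reps),
    mdr_mean = vapply(mdr, mean, 0),
    mdp_mean = vapply(mdp, mean, 0),
    fitness_mean = vapply(reps, mean, 0),
    fitness_median = vapply(reps, stats::median, 0))
  rownames(tab) <- NULL
  structure(list(screen_id = fits$screen_id[1],
                 background = fits$background[1],
                 treatment = fits$treatment[1],
                 table = tab, replicates = reps, cultures = fits),
            class = "screen_fitness_table")
}

#' @export
print.screen_fitness_table <- function(x, ...) {
  cat(sprintf("screen_fitness_table %s [%s, %s]: %d ORFs, %d cultures\n",
              x$screen_id, x$background, x$treatment,
              nrow(x$table), nrow(x$cultures)))
  invisible(x)
}
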