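#' Configuration for a synthetic paired screen
#'
#' Defines the generative model for one paired control/query screen: a
#' genome-wide deletion library with gene-level logistic growth parameters,
#' a query mutation that multiplies every non-interacting gene's fitness by
#' a common factor `m_true`, a planted minority of suppressors and
#' enhancers, a fraction of dead cultures, and a chronic or acute
#' temperature-cycling (up-down, "UD") treatment.
#'
#' Distribution parameters are log-normal `(meanlog, sdlog)` pairs; defaults
#' emulate colony-image intensities: carrying capacity `K` around 0.2,
#' inoculum `G0` around 0.003 (dilute spotting) and growth rate `r` around 3
#' per day, giving fitnesses of roughly 20-40 doublings squared per day for
#' healthy strains.
#'
#' @param n_genes Number of deletion strains (library genes).
#' @param n_replicates Cultures per gene per background.
#' @param timepoints Imaging times in days, sorted ascending, first `>= 0`.
#' @param plate_geometry `c(rows, columns)` of the arrayed plates
#'   (default 16 x 24 = 384 positions).
#' @param K_dist,r_dist,G0_dist `c(meanlog, sdlog)` of gene-level baseline
#'   carrying capacity, growth rate (1/day) and inoculum.
#' @param noise_sigma Multiplicative measurement noise scale: intensities are
#'   multiplied by `exp(N(0, noise_sigma^2))` independently per timepoint.
#' @param m_true Global multiplicative fitness effect of the query mutation,
#'   in `(0, 1]`.
#' @param planted_fraction_sup,planted_fraction_enh Fractions of the library
#'   planted as suppressors / enhancers; counts are
#'   `floor(fraction * n_genes)`.
#' @param effect_size_sup Multiplier (`>= 1`) applied to a planted
#'   suppressor's query-background fitness.
#' @param effect_size_enh Multiplier in `(0, 1]` for planted enhancers.
#' @param dead_fraction Fraction of cultures that never grow.
#' @param treatment `"chronic"` or `"UD"`.
#' @param ud_viability_scale Under `"UD"`, per-gene log-kill scale: each
#'   gene's query fitness is further multiplied by `exp(-E)`,
#'   `E ~ Exponential(1 / ud_viability_scale)` (0 disables).
#' @param seed Integer seed; fixes the whole screen pair.
#' @return A validated `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1000,
                              n_replicates = 8,
                              timepoints = seq(0, 5, length.out = 15),
                              plate_geometry = c(16, 24),
                              K_dist = c(meanlog = log(0.2), sdlog = 0.15),
                              r_dist = c(meanlog = log(3), sdlog = 0.2),
                              G0_dist = c(meanlog = log(0.003), sdlog = 0.1),
                              noise_sigma = 0.02,
                              m_true = 0.5,
                              planted_fraction_sup = 0.05,
                              planted_fraction_enh = 0.05,
                              effect_size_sup = 1.8,
                              effect_size_enh = 0.5,
                              dead_fraction = 0.01,
                              treatment = c("chronic", "UD"),
                              ud_viability_scale = 0.3,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_replicates = as.integer(n_replicates),
              timepoints = as.numeric(timepoints),
              plate_geometry = as.integer(plate_geometry),
              K_dist = as.numeric(K_dist), r_dist = as.numeric(r_dist),
              G0_dist = as.numeric(G0_dist),
              noise_sigma = noise_sigma, m_true = m_true,
              planted_fraction_sup = planted_fraction_sup,
              planted_fraction_enh = planted_fraction_enh,
              effect_size_sup = effect_size_sup,
              effect_size_enh = effect_size_enh,
              dead_fraction = dead_fraction,
              treatment = match.arg(treatment),
              ud_viability_scale = ud_viability_scale,
              seed = as.integer(seed))
  problems <- validate_simulation_config(cfg)
  if (length(problems)) {
    stop("configuration error:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  p <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  chk(cfg$n_genes >= 1, "n_genes: must be a positive integer")
  chk(cfg$n_replicates >= 1, "n_replicates: must be a positive integer")
  chk(length(cfg$timepoints) >= 1 && !is.unsorted(cfg$timepoints) &&
        cfg$timepoints[1] >= 0 && all(is.finite(cfg$timepoints)),
      "timepoints: must be sorted ascending with first value >= 0")
  chk(length(cfg$plate_geometry) == 2 && all(cfg$plate_geometry >= 1),
      "plate_geometry: must be positive rows x columns")
  for (d in c("K_dist", "r_dist", "G0_dist")) {
    chk(length(cfg[[d]]) == 2 && is.finite(cfg[[d]][2]) && cfg[[d]][2] > 0,
        paste0(d, ": scale (sdlog) must be > 0"))
  }
  chk(cfg$G0_dist[1] < cfg$K_dist[1],
      "G0_dist: location must be below K_dist location (inoculum < capacity)")
  chk(is.finite(cfg$noise_sigma) && cfg$noise_sigma >= 0,
      "noise_sigma: must be >= 0")
  chk(is.finite(cfg$m_true) && cfg$m_true > 0 && cfg$m_true <= 1,
      "m_true: must be in (0, 1]")
  chk(cfg$planted_fraction_sup >= 0 && cfg$planted_fraction_sup < 1,
      "planted_fraction_sup: must be in [0, 1)")
  chk(cfg$planted_fraction_enh >= 0 && cfg$planted_fraction_enh < 1,
      "planted_fraction_enh: must be in [0, 1)")
  chk(cfg$planted_fraction_sup + cfg$planted_fraction_enh < 1,
      "planted fractions: sup + enh must be < 1")
  chk(cfg$effect_size_sup >= 1, "effect_size_sup: must be >= 1")
  chk(cfg$effect_size_enh > 0 && cfg$effect_size_enh <= 1,
      "effect_size_enh: must be in (0, 1]")
  chk(cfg$dead_fraction >= 0 && cfg$dead_fraction < 1,
      "dead_fraction: must be in [0, 1)")
  chk(cfg$ud_viability_scale >= 0, "ud_viability_scale: must be >= 0")
  p
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("simulation_config: %d genes x %d replicates x %d timepoints, ",
                     "m_true=%.3g, %s treatment, seed=%d\n"),
              x$n_genes, x$n_replicates, length(x$timepoints), x$m_true,
              x$treatment, x$seed))
  invisible(x)
}

#' Simulate one culture's intensity series
#'
#' Evaluates the logistic kernel at the given timepoints and multiplies by
#' i.i.d. log-normal measurement noise. A dead culture stays at its inoculum
#' level (times noise) throughout.
#'
#' @param params Named numeric `c(K=, r=, G0=)`.
#' @param timepoints Times in days, non-empty.
#' @param noise_sigma Multiplicative noise scale (`>= 0`).
#' @param dead Logical, culture never grows.
#' @param seed Optional integer; when given the series is bit-reproducible.
#' @param ... Metadata passed to [growth_curve()].
#' @return A [growth_curve()].
#' @export
simulate_culture <- function(params, timepoints, noise_sigma = 0, dead = FALSE,
                             seed = NULL, ...) {
  if (!is.finite(noise_sigma) || noise_sigma < 0) {
    stop("invalid parameter: noise_sigma must be >= 0", call. = FALSE)
  }
  if (length(timepoints) < 1) {
    stop("invalid parameter: timepoints must be non-empty", call. = FALSE)
  }
  K <- params[["K"]]; r <- params[["r"]]; G0 <- params[["G0"]]
  check_logistic_params(K, r, G0)
  if (!is.null(seed)) set.seed(seed)
  mu <- if (dead) rep(G0, length(timepoints)) else logistic_growth(timepoints, K, r, G0)
  eps <- if (noise_sigma > 0) stats::rnorm(length(timepoints), 0, noise_sigma) else 0
  growth_curve(time = timepoints,
               intensity = pmax(mu * exp(eps), INTENSITY_FLOOR), ...)
}

#' Simulate a paired control/query screen with ground truth
#'
#' Draws gene-level baseline growth parameters, plants suppressors and
#' enhancers, and emits two raw screens (long tab-delimited schema, see
#' [read_raw_timeseries()]) plus the ground truth needed to validate every
#' downstream stage.
#'
#' Construction of query-background truth: each gene's target fitness is
#' `m_true * F_control`, multiplied by its planted effect size and, under the
#' UD treatment, by a per-gene viability factor. Because fitness is linear in
#' the growth rate `r` with `K` and `G0` held fixed, the target is realized
#' exactly by scaling `r`; for non-interacting genes under the chronic
#' treatment `F_query = m_true * F_control` to machine precision.
#'
#' Planted counts are `floor(fraction * n_genes)`, suppressors assigned
#' before enhancers from a seed-shuffled gene order. Dead cultures are drawn
#' per culture.
#'
#' @param config A [simulation_config()].
#' @return List with `control` and `query` raw screen `data.frame`s and
#'   `truth`, a `ground_truth` object: `genes` data.frame (`orf`, `gene`,
#'   `label`, true `K`, `G0`, `r_control`, `r_query`, `F_control`, `F_query`,
#'   `ud_viability`), `m_true`, per-culture `dead` flags and the config.
#' @export
simulate_screen_pair <- function(config) {
  if (!inherits(config, "simulation_config")) {
    problems <- validate_simulation_config(config)
    if (length(problems)) {
      stop("configuration error:\n  - ", paste(problems, collapse = "\n  - "),
           call. = FALSE)
    }
  }
  cfg <- config
  set.seed(cfg$seed)
  ng <- cfg$n_genes

  orf <- sprintf("YSIM%04d%s", seq_len(ng), rep_len(c("C", "W"), ng))
  gene <- sprintf("sim%04d", seq_len(ng))

  K <- stats::rlnorm(ng, cfg$K_dist[1], cfg$K_dist[2])
  r <- stats::rlnorm(ng, cfg$r_dist[1], cfg$r_dist[2])
  G0 <- stats::rlnorm(ng, cfg$G0_dist[1], cfg$G0_dist[2])
  G0 <- pmin(G0, K / 4)  # keep inoculum well below capacity

  shuffled <- sample.int(ng)
  n_sup <- floor(cfg$planted_fraction_sup * ng)
  n_enh <- floor(cfg$planted_fraction_enh * ng)
  label <- rep("none", ng)
  if (n_sup > 0) label[shuffled[seq_len(n_sup)]] <- "suppressor"
  if (n_enh > 0) label[shuffled[n_sup + seq_len(n_enh)]] <- "enhancer"

  effect <- ifelse(label == "suppressor", cfg$effect_size_sup,
                   ifelse(label == "enhancer", cfg$effect_size_enh, 1))
  ud_viability <- rep(1, ng)
  if (cfg$treatment == "UD" && cfg$ud_viability_scale > 0) {
    ud_viability <- exp(-stats::rexp(ng, rate = 1 / cfg$ud_viability_scale))
  }

  # fitness is linear in r at fixed (K, G0): scale r to hit the target exactly
  r_query <- r * cfg$m_true * effect * ud_viability
  F_control <- fitness_from_params(K, r, G0)$fitness
  F_query <- fitness_from_params(K, r_query, G0)$fitness

  n_cultures <- ng * cfg$n_replicates
  dead_ctrl <- stats::runif(n_cultures) < cfg$dead_fraction
  dead_query <- stats::runif(n_cultures) < cfg$dead_fraction

  control <- simulate_raw_background(cfg, orf, gene, K, r, G0, dead_ctrl,
                                     background = "control",
                                     screen_id = sprintf("SIM%05d_ctrl", cfg$seed))
  query <- simulate_raw_background(cfg, orf, gene, K, r_query, G0, dead_query,
                                   background = "query",
                                   screen_id = sprintf("SIM%05d_query", cfg$seed))

  truth <- structure(
    list(genes = data.frame(orf = orf, gene = gene, label = label,
                            K = K, G0 = G0, r_control = r, r_query = r_query,
                            F_control = F_control, F_query = F_query,
                            effect = effect, ud_viability = ud_viability),
         m_true = cfg$m_true,
         dead_control = dead_ctrl, dead_query = dead_query,
         config = cfg),
    class = "ground_truth")
  list(control = control, query = query, truth = truth)
}

# lay n_genes x n_replicates cultures onto 16x24-style plates and sample
# noisy intensities; vectorized over all cultures at once
simulate_raw_background <- function(cfg, orf, gene, K, r, G0, dead,
                                    background, screen_id) {
  ng <- cfg$n_genes; nr <- cfg$n_replicates
  nt <- length(cfg$timepoints)
  n_cult <- ng * nr
  gidx <- rep(seq_len(ng), each = nr)

  npos <- cfg$plate_geometry[1] * cfg$plate_geometry[2]
  pos <- seq_len(n_cult) - 1L
  plate <- pos %/% npos + 1L
  within <- pos %% npos
  row <- within %/% cfg$plate_geometry[2] + 1L
  col <- within %% cfg$plate_geometry[2] + 1L

  tt <- rep(cfg$timepoints, times = n_cult)
  ci <- rep(seq_len(n_cult), each = nt)
  gK <- K[gidx][ci]; gr <- r[gidx][ci]; gG0 <- G0[gidx][ci]
  mu <- ifelse(rep(dead, each = nt),
               gG0,
               gK / (1 + ((gK - gG0) / gG0) * exp(-gr * tt)))
  if (cfg$noise_sigma > 0) {
    mu <- mu * exp(stats::rnorm(length(mu), 0, cfg$noise_sigma))
  }
  data.frame(screen_id = screen_id,
             barcode = sprintf("%s_P%03d", screen_id, plate[ci]),
             row = row[ci], column = col[ci],
             orf = orf[gidx][ci], gene = gene[gidx][ci],
             background = background,
             treatment = if (cfg$treatment == "UD") "UD" else "chronic",
             time_days = tt,
             intensity = pmax(mu, INTENSITY_FLOOR))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d genes (%d suppressors, %d enhancers), m_true=%.3g\n",
              nrow(x$genes), sum(x$genes$label == "suppressor"),
              sum(x$genes$label == "enhancer"), x$m_true))
  invisible(x)
}

#' Simulate a profile matrix with a planted co-functional module
#'
#' Generates a gene-by-screen fitness-profile matrix in which a small module
#' of genes shares one underlying profile (plus independent noise) while the
#' remaining genes have independent profiles — the structure profile
#' similarity ranking is meant to detect (genes acting in one complex or
#' pathway respond alike across screens).
#'
#' @param n_genes Total genes.
#' @param n_screens Screen conditions (columns).
#' @param module_size Genes sharing the planted profile.
#' @param noise_sd Standard deviation of the noise added to each module
#'   member's copy of the shared profile.
#' @param seed Integer seed.
#' @return List with `matrix` (a `profile_matrix`) and `module` (ORF names of
#'   the planted members; the module occupies the first `module_size` genes).
#' @export
simulate_profile_matrix <- function(n_genes = 500, n_screens = 12,
                                    module_size = 10, noise_sd = 0.3,
                                    seed = 3L) {
  stopifnot(module_size <= n_genes, n_screens >= 2)
  set.seed(seed)
  orf <- sprintf("YSIM%04d%s", seq_len(n_genes), rep_len(c("C", "W"), n_genes))
  vals <- matrix(stats::rnorm(n_genes * n_screens), n_genes, n_screens)
  shared <- stats::rnorm(n_screens)
  for (i in seq_len(module_size)) {
    vals[i, ] <- shared + stats::rnorm(n_screens, 0, noise_sd)
  }
  rownames(vals) <- orf
  colnames(vals) <- sprintf("screen%02d", seq_len(n_screens))
  pm <- new_profile_matrix(vals, value_kind = "fitness")
  list(matrix = pm, module = orf[seq_len(module_size)])
}
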