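#' Run configuration
#'
#' Everything one end-to-end run needs: either a [simulation_config()] (the
#' run simulates its own paired screen) or paths to raw control and query
#' time-series tables — exactly one of the two — plus the analysis knobs.
#'
#' @param simulate A [simulation_config()], a plain list of its arguments, or
#'   `NULL`.
#' @param input `list(control = path, query = path)` of raw tables, or `NULL`.
#' @param dead_threshold Dead-culture fold-change threshold
#'   (see [fit_logistic()]).
#' @param slope_method `"robust"` or `"lsq_origin"`.
#' @param q_threshold FDR threshold for interaction calls.
#' @param profile_metric `"pearson"` or `"euclidean"`.
#' @param min_overlap Minimum shared screens for similarity ranking.
#' @param outdir Output directory.
#' @param seed Integer seed for the run (overrides the simulation seed).
#' @param highlights Optional path to a tab-delimited file with columns
#'   `orf`, `group` used to color fitness plots.
#' @return A validated `run_config`.
#' @export
run_config <- function(simulate = NULL, input = NULL, dead_threshold = 1.75,
                       slope_method = "robust", q_threshold = 0.05,
                       profile_metric = "pearson", min_overlap = 4,
                       outdir = "qfa_out", seed = 1L, highlights = NULL) {
  if (is.null(simulate) == is.null(input)) {
    stop("configuration error: supply exactly one of 'simulate' or 'input'",
         call. = FALSE)
  }
  if (!is.null(simulate) && !inherits(simulate, "simulation_config")) {
    simulate$seed <- simulate$seed %||% seed
    simulate <- do.call(simulation_config, simulate)
  }
  if (!is.null(simulate)) simulate$seed <- as.integer(seed)
  if (!is.null(input) && !all(c("control", "query") %in% names(input))) {
    stop("configuration error: 'input' needs control and query paths",
         call. = FALSE)
  }
  structure(list(simulate = simulate, input = input,
                 dead_threshold = dead_threshold,
                 slope_method = match.arg(slope_method,
                                          c("robust", "lsq_origin")),
                 q_threshold = q_threshold,
                 profile_metric = match.arg(profile_metric,
                                            c("pearson", "euclidean")),
                 min_overlap = min_overlap, outdir = outdir,
                 seed = as.integer(seed), highlights = highlights),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from a YAML file
#'
#' The file mirrors [run_config()]: top-level keys are its arguments, with
#' `simulate:` a nested block of [simulation_config()] arguments.
#'
#' @param path YAML file.
#' @param ... Overrides applied on top of the file's values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  do.call(run_config, vals)
}

#' Run the full QFA pipeline
#'
#' Simulate (or read) a paired control/query screen, fit every culture,
#' summarize per-gene fitness, estimate the independence slope, score
#' genetic interactions, assemble the two-condition profile matrix, and
#' write tables, plots and a run log under `config$outdir`. Re-running with
#' an identical config and seed reproduces every table byte for byte.
#'
#' @param config A [run_config()].
#' @return A report list: `status` (`"complete"`/`"incomplete"`), per-stage
#'   `counts`, `files` written, the fitted objects (`fitness`,
#'   `interactions`, `profiles`) and, for simulated runs, the ground `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- list(status = "incomplete", stage = NULL, counts = list(),
                 files = character())
  stage <- function(name, expr) {
    report$stage <<- name
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) {
    stop("I/O error: output directory '", outdir, "' is not writable",
         call. = FALSE)
  }

  truth <- NULL
  inputs <- stage("input", {
    if (!is.null(config$simulate)) {
      sim <- simulate_screen_pair(config$simulate)
      truth <- sim$truth
      list(control = sim$control, query = sim$query)
    } else {
      list(control = read_raw_table(config$input$control),
           query = read_raw_table(config$input$query))
    }
  })
  report$counts$raw_rows <- vapply(inputs, nrow, 0L)

  fitness <- stage("fit", {
    lapply(inputs, function(raw) {
      summarize_screen(fit_screen(raw, config$dead_threshold))
    })
  })
  report$counts$orfs <- vapply(fitness, function(s) nrow(s$table), 0L)
  report$counts$dead_cultures <- vapply(fitness, function(s) {
    sum(s$cultures$status == "dead")
  }, 0L)
  report$counts$failed_fits <- vapply(fitness, function(s) {
    sum(s$cultures$status == "failed")
  }, 0L)

  interactions <- stage("interactions", {
    compute_interactions(fitness$control, fitness$query,
                         q_threshold = config$q_threshold,
                         slope_method = config$slope_method)
  })
  report$counts$suppressors <- sum(interactions$call == "suppressor")
  report$counts$enhancers <- sum(interactions$call == "enhancer")

  profiles <- stage("profiles", {
    build_profile_matrix(fitness, value_kind = "fitness")
  })

  files <- stage("write", {
    f <- write_results_tables(fitness = fitness, interactions = interactions,
                              outdir = outdir)
    pm <- file.path(outdir, "profile_matrix.tsv")
    write_profile_matrix(profiles, pm)
    c(f, pm)
  })

  if (!is.null(truth)) {
    tf <- file.path(outdir, "ground_truth.tsv")
    gt <- truth$genes
    for (cl in c("K", "G0", "r_control", "r_query", "F_control", "F_query",
                 "effect", "ud_viability")) {
      gt[[cl]] <- fmt_num(gt[[cl]], 6)
    }
    write_tsv(gt, tf)
    files <- c(files, tf)
  }

  plot_files <- stage("plots", {
    hi <- NULL
    if (!is.null(config$highlights)) {
      hi <- utils::read.delim(config$highlights, sep = "\t", header = TRUE)
    }
    fp <- file.path(outdir, "fitness_plot.png")
    grDevices::png(fp, width = 1400, height = 1200, res = 200)
    print(plot_fitness_comparison(interactions, highlights = hi))
    grDevices::dev.off()
    top <- interactions$orf[order(-abs(interactions$gis))][1:min(8, nrow(interactions))]
    pp <- file.path(outdir, "profile_plot.png")
    grDevices::png(pp, width = 1400, height = 1000, res = 200)
    print(plot_fitness_profiles(profiles, top))
    grDevices::dev.off()
    c(fp, pp)
  })
  files <- c(files, plot_files)

  log_file <- stage("log", {
    cfg_file <- file.path(outdir, "config_used.yaml")
    yaml::write_yaml(serialize_config(config), cfg_file)
    lf <- file.path(outdir, "run_log.txt")
    writeLines(c(
      sprintf("qfascreen %s on %s", as.character(utils::packageVersion("qfascreen")),
              R.version.string),
      sprintf("seed: %d", config$seed),
      sprintf("config_md5: %s", unname(tools::md5sum(cfg_file))),
      sprintf("stage counts: %s",
              paste(names(report$counts), vapply(report$counts, function(x)
                paste(x, collapse = "/"), ""), sep = "=", collapse = "; ")),
      sprintf("files: %s", paste(basename(files), collapse = ", "))
    ), lf)
    c(cfg_file, lf)
  })

  report$files <- c(files, log_file)
  report$fitness <- fitness
  report$interactions <- interactions
  report$profiles <- profiles
  report$truth <- truth
  report$stage <- NULL
  report$status <- "complete"
  report
}

# plain-list view of a run_config for YAML round-tripping / hashing
serialize_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulate)) cfg$simulate <- unclass(cfg$simulate)
  cfg[!vapply(cfg, is.null, TRUE)]
}
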