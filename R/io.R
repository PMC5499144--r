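RAW_COLUMNS <- c("screen_id", "barcode", "row", "column", "orf", "gene",
                 "background", "treatment", "time_days", "intensity")

culture_key <- function(raw) {
  paste(raw$screen_id, raw$barcode, raw$row, raw$column, sep = "\r")
}

validate_raw_schema <- function(raw, time_col = "time_days") {
  missing_cols <- setdiff(RAW_COLUMNS, names(raw))
  if ("time_hours" %in% names(raw) && "time_days" %in% missing_cols) {
    raw$time_days <- as.numeric(raw$time_hours) / 24
    raw$time_hours <- NULL
    missing_cols <- setdiff(missing_cols, "time_days")
  }
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_bg <- setdiff(unique(raw$background), c("control", "query"))
  if (length(bad_bg)) {
    stop("data error: unknown background label(s): ",
         paste(bad_bg, collapse = ", "), call. = FALSE)
  }
  raw
}

#' Read a raw colony time-series table
#'
#' Reads the long tab-delimited raw format: one row per culture per
#' timepoint, columns `screen_id`, `barcode`, `row`, `column`, `orf`,
#' `gene`, `background`, `treatment`, `time_days`, `intensity`. A file whose
#' header declares `time_hours` instead of `time_days` is converted (divided
#' by 24) on read. Rows are grouped into cultures by
#' `(screen_id, barcode, row, column)` and sorted by time within a culture,
#' so on-disk row order is irrelevant; duplicated times within one culture
#' are a data error.
#'
#' @param path Path to a tab-delimited file with a header.
#' @return A list of [growth_curve()] objects (stable key order).
#' @export
read_raw_timeseries <- function(path) {
  raw <- read_raw_table(path)
  curves_from_raw(raw)
}

# raw table as a data.frame (the bulk interface the pipeline uses)
read_raw_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  raw <- validate_raw_schema(raw)
  for (col in c("time_days", "intensity")) raw[[col]] <- as.numeric(raw[[col]])
  for (col in c("row", "column")) raw[[col]] <- as.integer(raw[[col]])
  raw[RAW_COLUMNS]
}

#' Group a raw screen table into growth-curve records
#'
#' @param raw Raw screen `data.frame` (long schema).
#' @return List of [growth_curve()]s keyed by
#'   `(screen_id, barcode, row, column)`, sorted by key.
#' @export
curves_from_raw <- function(raw) {
  raw <- validate_raw_schema(raw)
  key <- culture_key(raw)
  ord <- order(key, raw$time_days)
  raw <- raw[ord, ]; key <- key[ord]
  idx <- split(seq_len(nrow(raw)), factor(key, levels = unique(key)))
  lapply(idx, function(i) {
    ti <- raw$time_days[i]
    if (anyDuplicated(ti)) {
      stop("data error: non-monotone times in culture (",
           gsub("\r", ", ", key[i[1]]), ")", call. = FALSE)
    }
    growth_curve(time = ti, intensity = raw$intensity[i],
                 screen_id = raw$screen_id[i[1]], barcode = raw$barcode[i[1]],
                 row = raw$row[i[1]], column = raw$column[i[1]],
                 orf = raw$orf[i[1]], gene = raw$gene[i[1]],
                 background = raw$background[i[1]],
                 treatment = raw$treatment[i[1]])
  })
}

#' Flatten growth curves into a raw screen table
#'
#' @param curves List of [growth_curve()]s.
#' @return Long-format raw `data.frame` (see [read_raw_timeseries()]).
#' @export
raw_from_curves <- function(curves) {
  do.call(rbind, lapply(curves, function(cu) {
    data.frame(screen_id = cu$screen_id, barcode = cu$barcode,
               row = cu$row, column = cu$column, orf = cu$orf, gene = cu$gene,
               background = cu$background, treatment = cu$treatment,
               time_days = cu$time, intensity = cu$intensity)
  }))
}

# numeric -> fixed-width-free text at given significant digits; NA -> "NA"
fmt_num <- function(x, digits) {
  out <- ifelse(is.na(x), "NA", sprintf("%.*g", digits, x))
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  path
}

#' Write a raw screen table
#'
#' Serializes a raw screen (long schema) as tab-delimited text with numeric
#' fields at 15 significant digits, so a write/read round trip recovers the
#' values to the declared precision.
#'
#' @param raw Raw screen `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw_timeseries <- function(raw, path) {
  raw <- validate_raw_schema(raw)
  out <- raw[RAW_COLUMNS]
  out$time_days <- fmt_num(raw$time_days, 15)
  out$intensity <- fmt_num(raw$intensity, 15)
  write_tsv(out, path)
  invisible(path)
}

fitness_table_df <- function(sft) {
  tab <- sft$table
  nmax <- max(tab$n)
  repmat <- t(vapply(sft$replicates[tab$orf], function(v) {
    c(v, rep(NA_real_, nmax - length(v)))
  }, numeric(nmax)))
  if (nmax == 1) repmat <- matrix(repmat, ncol = 1)
  colnames(repmat) <- sprintf("fitness_rep%d", seq_len(nmax))
  df <- data.frame(screen_id = sft$screen_id, orf = tab$orf, gene = tab$gene,
                   background = sft$background, treatment = sft$treatment,
                   n = tab$n)
  num <- cbind(tab[c("mdr_mean", "mdp_mean", "fitness_mean", "fitness_median")],
               as.data.frame(repmat))
  for (cl in names(num)) num[[cl]] <- fmt_num(num[[cl]], 6)
  cbind(df, num)
}

#' Write a per-gene fitness table
#'
#' Tab-delimited, one row per ORF: `screen_id`, `orf`, `gene`, `background`,
#' `treatment`, `n`, `mdr_mean`, `mdp_mean`, `fitness_mean`,
#' `fitness_median`, then replicate fitness values in repeated columns
#' `fitness_rep1..fitness_repN` (padded with `NA`). Numeric fields carry 6
#' significant digits; missing values are written as `"NA"`.
#'
#' @param sft A `screen_fitness_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fitness_table <- function(sft, path) {
  write_tsv(fitness_table_df(sft), path)
  invisible(path)
}

#' Read back a written fitness table
#'
#' @param path Path written by [write_fitness_table()].
#' @return A `screen_fitness_table` (without culture-level fits).
#' @export
read_fitness_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE)
  repcols <- grep("^fitness_rep", names(df), value = TRUE)
  reps <- lapply(seq_len(nrow(df)), function(i) {
    v <- as.numeric(df[i, repcols])
    v[!is.na(v)]
  })
  names(reps) <- df$orf
  tab <- data.frame(orf = df$orf, gene = df$gene, n = df$n,
                    mdr_mean = df$mdr_mean, mdp_mean = df$mdp_mean,
                    fitness_mean = df$fitness_mean,
                    fitness_median = df$fitness_median)
  structure(list(screen_id = df$screen_id[1], background = df$background[1],
                 treatment = df$treatment[1], table = tab, replicates = reps,
                 cultures = NULL),
            class = "screen_fitness_table")
}

interaction_table_df <- function(it) {
  sid <- attr(it, "screen_ids")[["query"]]
  df <- data.frame(screen_id = rep(sid, nrow(it)), orf = it$orf,
                   gene = it$gene)
  num <- data.frame(F_control = it$F_control, F_query = it$F_query,
                    m = rep(attr(it, "m"), nrow(it)), F_pred = it$F_pred,
                    gis = it$gis, p = it$p, q = it$q)
  for (cl in names(num)) num[[cl]] <- fmt_num(num[[cl]], 6)
  cbind(df, num, data.frame(call = it$call))
}

#' Write a genetic-interaction-strength table
#'
#' Columns: `screen_id`, `orf`, `gene`, `F_control`, `F_query`, `m`,
#' `F_pred`, `gis`, `p`, `q`, `call`; 6 significant digits, `NA` for missing.
#'
#' @param it An `interaction_table` from [compute_interactions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(it, path) {
  write_tsv(interaction_table_df(it), path)
  invisible(path)
}

#' Read back a written interaction table
#'
#' @param path Path written by [write_interaction_table()].
#' @return A `data.frame` of class `interaction_table`.
#' @export
read_interaction_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c(call = "character"))
  out <- df[c("orf", "gene", "F_control", "F_query", "F_pred", "gis",
              "p", "q", "call")]
  out$flagged <- is.na(out$p)
  attr(out, "m") <- df$m[1]
  attr(out, "screen_ids") <- c(control = NA_character_,
                               query = df$screen_id[1])
  class(out) <- c("interaction_table", "data.frame")
  out
}

ranking_df <- function(rk) {
  df <- data.frame(query_orf = attr(rk, "query_orf"), position = rk$position,
                   orf = rk$orf, gene = rk$gene)
  df$similarity <- fmt_num(rk$similarity, 6)
  df$n_overlap <- rk$n_overlap
  df
}

#' Write results tables for a run
#'
#' Writes fitness tables, the interaction table and any similarity rankings
#' as tab-delimited files under `outdir` (created if needed). Fails before
#' writing anything if `outdir` cannot be created or written.
#'
#' @param fitness List of `screen_fitness_table`s (may be empty).
#' @param interactions An `interaction_table` or `NULL`.
#' @param rankings A `similarity_ranking`, list thereof, or `NULL`.
#' @param outdir Output directory.
#' @return Character vector of the files written.
#' @export
write_results_tables <- function(fitness = list(), interactions = NULL,
                                 rankings = NULL, outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) {
    stop("I/O error: output directory '", outdir, "' is not writable",
         call. = FALSE)
  }
  files <- character()
  for (sft in fitness) {
    f <- file.path(outdir, sprintf("fitness_%s_%s.tsv", sft$screen_id,
                                   sft$background))
    write_fitness_table(sft, f)
    files <- c(files, f)
  }
  if (!is.null(interactions)) {
    sid <- attr(interactions, "screen_ids")[["query"]]
    f <- file.path(outdir, sprintf("interactions_%s.tsv", sid))
    write_interaction_table(interactions, f)
    files <- c(files, f)
  }
  if (inherits(rankings, "similarity_ranking")) rankings <- list(rankings)
  for (rk in rankings) {
    f <- file.path(outdir, sprintf("ranking_%s.tsv", attr(rk, "query_orf")))
    write_tsv(ranking_df(rk), f)
    files <- c(files, f)
  }
  files
}

#' Write and read a profile matrix
#'
#' Tab-delimited with genes as the first column (`orf`) and one column per
#' screen condition; values at 6 significant digits, missing as `"NA"`.
#'
#' @param matrix A `profile_matrix`.
#' @param path File path.
#' @return `path` invisibly / the `profile_matrix`.
#' @export
write_profile_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "profile_matrix"))
  v <- matrix$values
  df <- data.frame(orf = rownames(v))
  for (j in seq_len(ncol(v))) df[[colnames(v)[j]]] <- fmt_num(v[, j], 6)
  attr_line <- sprintf("# value_kind=%s", matrix$value_kind)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_profile_matrix
#' @param path File written by `write_profile_matrix`.
#' @export
read_profile_matrix <- function(path) {
  first <- readLines(path, n = 1)
  kind <- sub("^# value_kind=", "", first)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, skip = 1,
                          check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$orf
  new_profile_matrix(v, kind)
}
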