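#' Assemble a gene-by-screen profile matrix
#'
#' Stacks per-screen fitness tables (or interaction tables) into the
#' gene x screen-condition matrix behind multi-screen fitness profiles: each
#' row is one gene deletion's fitness (or genetic interaction strength)
#' across every screen, the substrate for profile-similarity ranking.
#'
#' @param tables List of `screen_fitness_table`s (for `value_kind =
#'   "fitness"`, taking per-gene mean fitness) or `interaction_table`s (for
#'   `value_kind = "gis"`).
#' @param value_kind `"fitness"` or `"gis"`; mixing the two in one matrix is
#'   forbidden.
#' @param labels Optional screen-condition labels, one per table; defaults to
#'   `screen_id` x treatment (x background for fitness tables). Must be
#'   unique.
#' @return A `profile_matrix`: genes (sorted lexicographically) x screens (in
#'   input order) numeric matrix with `NA` marking gene/screen pairs absent
#'   from the input, plus the recorded `value_kind`.
#' @export
build_profile_matrix <- function(tables, value_kind = c("fitness", "gis"),
                                 labels = NULL) {
  value_kind <- match.arg(value_kind)
  if (length(tables) < 2) {
    stop("need at least 2 screen conditions to build a profile matrix",
         call. = FALSE)
  }
  pull <- function(tb) {
    if (value_kind == "fitness") {
      if (!inherits(tb, "screen_fitness_table")) {
        stop("value_kind 'fitness' needs screen_fitness_table inputs",
             call. = FALSE)
      }
      list(orf = tb$table$orf, value = tb$table$fitness_mean,
           label = paste(tb$screen_id, tb$treatment, tb$background, sep = "|"))
    } else {
      if (!inherits(tb, "interaction_table")) {
        stop("value_kind 'gis' needs interaction_table inputs", call. = FALSE)
      }
      list(orf = tb$orf, value = tb$gis,
           label = paste(attr(tb, "screen_ids")[["query"]], "gis", sep = "|"))
    }
  }
  cols <- lapply(tables, pull)
  labs <- if (is.null(labels)) vapply(cols, `[[`, "", "label") else labels
  if (anyDuplicated(labs)) {
    stop("inconsistency error: duplicate screen condition labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  }
  genes <- sort(Reduce(union, lapply(cols, `[[`, "orf")))
  vals <- matrix(NA_real_, length(genes), length(cols),
                 dimnames = list(genes, labs))
  for (j in seq_along(cols)) {
    vals[match(cols[[j]]$orf, genes), j] <- cols[[j]]$value
  }
  new_profile_matrix(vals, value_kind)
}

new_profile_matrix <- function(values, value_kind) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("inconsistency error: duplicate gene or screen labels", call. = FALSE)
  }
  if (any(is.infinite(values))) {
    stop("profile values must be finite or missing", call. = FALSE)
  }
  structure(list(values = values, value_kind = value_kind,
                 genes = rownames(values), screens = colnames(values)),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix [%s]: %d genes x %d screens, %d missing values\n",
              x$value_kind, length(x$genes), length(x$screens),
              sum(is.na(x$values))))
  invisible(x)
}

#' Normalize a profile matrix column-wise
#'
#' Z-scores each screen column (mean 0, sample standard deviation 1 over its
#' non-missing entries) so screens run at different temperatures or scales
#' become comparable. The missing mask is preserved.
#'
#' @param matrix A `profile_matrix`; every column needs at least 3
#'   non-missing values and nonzero spread.
#' @return The normalized `profile_matrix`.
#' @export
normalize_profiles <- function(matrix) {
  stopifnot(inherits(matrix, "profile_matrix"))
  v <- matrix$values
  for (j in seq_len(ncol(v))) {
    col <- v[, j]
    nn <- sum(!is.na(col))
    if (nn < 3) {
      stop("degenerate column: screen '", colnames(v)[j],
           "' has fewer than 3 values", call. = FALSE)
    }
    s <- stats::sd(col, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("degenerate column: screen '", colnames(v)[j],
           "' has zero spread", call. = FALSE)
    }
    v[, j] <- (col - mean(col, na.rm = TRUE)) / s
  }
  new_profile_matrix(v, matrix$value_kind)
}

#' Rank genes by fitness-profile similarity to a query gene
#'
#' Finds the gene deletions whose behavior across screens most resembles a
#' query deletion's — similar profiles suggest shared function (e.g. members
#' of one checkpoint complex track each other across telomere-defect
#' backgrounds). Similarity is computed over the screens where both genes
#' are non-missing (pairwise-complete): Pearson correlation, or the negative
#' root-mean-square difference for `metric = "euclidean"`. Genes overlapping
#' the query in fewer than `min_overlap` screens are excluded; ties are
#' broken lexicographically by ORF; positions are 1-based and the query is
#' excluded from its own ranking.
#'
#' Similarity is computed on the matrix as given. Because screens are run at
#' different temperatures and scales, the intended workflow is to rank on a
#' [normalize_profiles()]-normalized matrix: the normalized ranking is
#' invariant to per-screen affine rescaling of the raw values.
#'
#' @param matrix A `profile_matrix`.
#' @param query_orf ORF whose profile is the query.
#' @param metric `"pearson"` or `"euclidean"`.
#' @param min_overlap Minimum shared non-missing screens (`>= 2`).
#' @return A `similarity_ranking`: data.frame `position`, `orf`, `gene`
#'   (equal to `orf` when unknown), `similarity`, `n_overlap`, with
#'   attributes `query_orf`, `metric`, `min_overlap`.
#' @export
rank_similar_profiles <- function(matrix, query_orf,
                                  metric = c("pearson", "euclidean"),
                                  min_overlap = 4) {
  stopifnot(inherits(matrix, "profile_matrix"), min_overlap >= 2)
  metric <- match.arg(metric)
  v <- matrix$values
  if (!query_orf %in% rownames(v)) {
    stop("no profile: query ORF '", query_orf, "' not in matrix", call. = FALSE)
  }
  qp <- v[query_orf, ]
  if (all(is.na(qp))) {
    stop("no profile: query ORF '", query_orf, "' is entirely missing",
         call. = FALSE)
  }
  others <- setdiff(rownames(v), query_orf)
  sim <- rep(NA_real_, length(others))
  nov <- integer(length(others))
  for (i in seq_along(others)) {
    gp <- v[others[i], ]
    shared <- !is.na(qp) & !is.na(gp)
    nov[i] <- sum(shared)
    if (nov[i] < min_overlap) next
    if (metric == "pearson") {
      sq <- stats::sd(qp[shared]); sg <- stats::sd(gp[shared])
      if (sq == 0 || sg == 0) next
      sim[i] <- stats::cor(qp[shared], gp[shared])
    } else {
      sim[i] <- -sqrt(mean((qp[shared] - gp[shared])^2))
    }
  }
  keep <- !is.na(sim)
  out <- data.frame(orf = others[keep], similarity = sim[keep],
                    n_overlap = nov[keep])
  out <- out[order(-out$similarity, out$orf), ]
  out <- data.frame(position = seq_len(nrow(out)), orf = out$orf,
                    gene = out$orf, similarity = out$similarity,
                    n_overlap = out$n_overlap)
  rownames(out) <- NULL
  attr(out, "query_orf") <- query_orf
  attr(out, "metric") <- metric
  attr(out, "min_overlap") <- min_overlap
  class(out) <- c("similarity_ranking", "data.frame")
  out
}

#' @export
print.similarity_ranking <- function(x, ...) {
  cat(sprintf("similarity_ranking: %d genes vs query %s (%s, min_overlap=%d)\n",
              nrow(x), attr(x, "query_orf"), attr(x, "metric"),
              attr(x, "min_overlap")))
  NextMethod()
}
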