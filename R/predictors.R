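# Stream-level landscape predictor preparation: multi-year aggregation,
# standardization, Spearman collinearity screening.

#' Collapse multi-year predictor values to one value per stream
#'
#' Predictors available across multiple years (e.g. air temperature,
#' precipitation) are reduced to a single unweighted mean of the available
#' annual values for each stream, matching the static per-stream predictor
#' design of the occurrence models.
#'
#' @param per_year_values Data frame with columns `stream_id`, `year`,
#'   `value` (one row per stream-year).
#' @return Data frame with columns `stream_id`, `value` (the annual mean).
#' @export
aggregate_annual_means <- function(per_year_values) {
  .require_columns(per_year_values, c("stream_id", "year", "value"),
                   "per-year predictor")
  vals <- per_year_values$value
  empty <- tapply(vals, per_year_values$stream_id,
                  function(v) all(is.na(v)) || length(v) == 0L)
  if (any(empty)) {
    stop("missing data: stream '", names(empty)[which(empty)[1L]],
         "' has no yearly values", call. = FALSE)
  }
  m <- tapply(vals, per_year_values$stream_id, mean, na.rm = TRUE)
  out <- data.frame(stream_id = names(m), value = as.numeric(m),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.predictor_columns <- function(table) {
  setdiff(names(table), "stream_id")
}

.predictor_matrix <- function(table) {
  cols <- .predictor_columns(table)
  m <- as.matrix(table[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Standardize predictor columns to zero mean and unit standard deviation
#'
#' Each predictor column is centered and scaled as `(x - mean) / sd` with
#' the sample standard deviation (n - 1 denominator). The returned transform
#' record allows new data and prediction grids to be mapped onto the same
#' standardized scale (see [standardize_with()] and [destandardize_with()]).
#'
#' @param table Predictor data frame: a `stream_id` column plus numeric
#'   predictor columns. Constant columns are rejected.
#' @return List with `table` (standardized copy) and `transform` (data frame
#'   with columns `predictor`, `mean`, `sd`).
#' @export
standardize_predictors <- function(table) {
  cols <- .predictor_columns(table)
  if (length(cols) == 0L) stop("no predictor columns", call. = FALSE)
  mu <- vapply(table[cols], mean, numeric(1))
  s <- vapply(table[cols], sd, numeric(1))
  degenerate <- which(!is.finite(s) | s == 0)
  if (length(degenerate) > 0L) {
    stop("degenerate predictor: column '", cols[degenerate[1L]],
         "' is constant", call. = FALSE)
  }
  out <- table
  for (j in seq_along(cols)) {
    out[[cols[j]]] <- (table[[cols[j]]] - mu[j]) / s[j]
  }
  list(table = out,
       transform = data.frame(predictor = cols, mean = unname(mu),
                              sd = unname(s), stringsAsFactors = FALSE))
}

#' Map values onto (or back from) a standardization transform
#'
#' @param transform Transform record from [standardize_predictors()].
#' @param values Numeric vector of values of one predictor, in original
#'   units for [standardize_with()] or standardized units for
#'   [destandardize_with()].
#' @param predictor Name of the predictor the values belong to.
#' @return Numeric vector on the other scale.
#' @export
standardize_with <- function(transform, values, predictor) {
  row <- transform[transform$predictor == predictor, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("unknown predictor '", predictor, "' in transform record",
         call. = FALSE)
  }
  (values - row$mean) / row$sd
}

#' @rdname standardize_with
#' @export
destandardize_with <- function(transform, values, predictor) {
  row <- transform[transform$predictor == predictor, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("unknown predictor '", predictor, "' in transform record",
         call. = FALSE)
  }
  values * row$sd + row$mean
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), used to screen
#' predictor pairs for collinearity.
#'
#' @param x,y Numeric vectors of equal length (at least 3), finite,
#'   non-constant.
#' @return Correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    stop("length mismatch: ", length(x), " vs ", length(y), call. = FALSE)
  }
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("constant vector: correlation undefined", call. = FALSE)
  }
  cor(x, y, method = "spearman")
}

#' Greedy Spearman collinearity screen
#'
#' Visits predictors in priority order and drops a predictor iff its
#' absolute Spearman correlation against any already-retained predictor
#' reaches the threshold, so that no retained pair has `|rho| >=
#' threshold`. Every drop is reported with the retained partner and the
#' offending correlation.
#'
#' @param table Predictor data frame (`stream_id` + numeric columns).
#' @param threshold Correlation threshold in (0, 1\]; default 0.90.
#' @param priority Character vector: a permutation of the predictor columns
#'   giving the visiting order. Defaults to column order.
#' @return List with `table` (reduced predictor table), `retained`
#'   (character), and `dropped` (data frame with columns `predictor`,
#'   `partner`, `rho`).
#' @export
drop_collinear <- function(table, threshold = 0.90, priority = NULL) {
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  cols <- .predictor_columns(table)
  if (is.null(priority)) priority <- cols
  if (!setequal(priority, cols) || length(priority) != length(cols)) {
    stop("priority must be a permutation of the predictor columns",
         call. = FALSE)
  }
  rho <- cor(.predictor_matrix(table), method = "spearman")
  retained <- character(0)
  dropped <- data.frame(predictor = character(0), partner = character(0),
                        rho = numeric(0), stringsAsFactors = FALSE)
  for (p in priority) {
    if (length(retained) == 0L) {
      retained <- p
      next
    }
    r <- rho[p, retained]
    worst <- which.max(abs(r))
    if (abs(r[worst]) >= threshold) {
      dropped <- rbind(dropped, data.frame(
        predictor = p, partner = retained[worst], rho = unname(r[worst]),
        stringsAsFactors = FALSE))
    } else {
      retained <- c(retained, p)
    }
  }
  keep <- c(intersect(names(table), "stream_id"), retained)
  list(table = table[, keep, drop = FALSE], retained = retained,
       dropped = dropped)
}
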