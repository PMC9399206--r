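# ---------------------------------------------------------------------------
# Robust Z-score normalisation and correlation-based feature selection.
#
# z_i = (x_i - x_m) / NIQR, with x_m the median and NIQR = 0.7414 * IQR
# (IQR from type-7 linear-interpolation quantiles). NIQR rescales the
# IQR to a standard-deviation equivalent under normality, making the
# standardisation outlier-resistant.
# ---------------------------------------------------------------------------

NIQR_FACTOR <- 0.7414

#' Fit robust Z-score normalisation parameters
#'
#' @param values A data.frame/matrix of metric columns, or a single
#'   numeric vector. Missing values are ignored per metric.
#' @param min_n Minimum non-missing values required per metric.
#' @return data.frame of class `robust_z_params`: `metric`, `median`,
#'   `niqr`, `n`, `degenerate`. Metrics with zero IQR (or too few
#'   values) are flagged degenerate, not errors; [robust_z_apply()]
#'   returns `NA` for them.
#' @export
robust_z_fit <- function(values, min_n = 4L) {
  if (is.numeric(values) && is.null(dim(values))) {
    values <- data.frame(x = values)
  }
  values <- as.data.frame(values)
  num <- vapply(values, is.numeric, logical(1))
  values <- values[num]
  params <- do.call(rbind, lapply(names(values), function(m) {
    x <- values[[m]]
    x <- x[is.finite(x)]
    n <- length(x)
    if (n < min_n) {
      return(data.frame(metric = m, median = NA_real_, niqr = NA_real_,
                        n = n, degenerate = TRUE, stringsAsFactors = FALSE))
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    niqr <- NIQR_FACTOR * (q[3] - q[1])
    data.frame(metric = m, median = q[2], niqr = niqr, n = n,
               degenerate = niqr <= 0, stringsAsFactors = FALSE)
  }))
  rownames(params) <- NULL
  class(params) <- c("robust_z_params", class(params))
  params
}

#' Apply fitted robust Z-score parameters
#'
#' @param params A [robust_z_fit()] result.
#' @param values data.frame/matrix (or vector) with the same metric
#'   columns; extra columns pass through untouched if non-numeric,
#'   unknown numeric columns are an error.
#' @return Same shape as `values` with each metric mapped to
#'   `(x - median) / NIQR`; missing stays missing; degenerate metrics
#'   map to `NA`.
#' @export
robust_z_apply <- function(params, values) {
  single <- is.numeric(values) && is.null(dim(values))
  if (single) values <- data.frame(x = values)
  values <- as.data.frame(values)
  for (m in names(values)) {
    if (!is.numeric(values[[m]])) next
    row <- params[params$metric == m, ]
    if (nrow(row) == 0L) {
      stop("contract error: metric '", m, "' was not fitted", call. = FALSE)
    }
    values[[m]] <- if (row$degenerate) {
      rep(NA_real_, nrow(values))
    } else {
      (values[[m]] - row$median) / row$niqr
    }
  }
  if (single) values$x else values
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), computed
#' on pairwise-complete observations.
#'
#' @param x,y Numeric vectors of equal length.
#' @return rho in `[-1, 1]`; `NA` with fewer than 3 complete pairs or
#'   zero rank variance in either argument.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Correlation heatmap of metrics against mean GOALS scores
#'
#' @param features [extract_feature_table()] output (or any data.frame
#'   with `session_id` plus metric columns).
#' @param mean_goals data.frame with `session_id`, one column per GOALS
#'   item and `total` (mean-of-raters scores, see [mean_goals()]).
#' @return Matrix metrics x (items + total) of Spearman rho values
#'   (pairwise-complete), class `correlation_heatmap`.
#' @export
correlation_heatmap <- function(features, mean_goals) {
  merged <- merge(features, mean_goals, by = "session_id",
                  suffixes = c("", ".goals"))
  if (nrow(merged) == 0L) stop("contract error: no overlapping sessions", call. = FALSE)
  items <- intersect(c(GOALS_ITEMS, "total"), names(mean_goals))
  metrics <- setdiff(names(features), c("session_id", "task"))
  metrics <- metrics[vapply(features[metrics], is.numeric, logical(1))]
  H <- matrix(NA_real_, length(metrics), length(items),
              dimnames = list(metrics, items))
  for (m in metrics) {
    for (it in items) {
      H[m, it] <- spearman_rho(merged[[m]], merged[[it]])
    }
  }
  class(H) <- c("correlation_heatmap", class(H))
  H
}

#' Select metrics per GOALS item by correlation threshold
#'
#' For each item, keeps every metric whose absolute Spearman correlation
#' with that item's mean score strictly exceeds `threshold`, then
#' applies optional manual overrides (add/remove lists encoding
#' hypothesis-driven curation of the automatic screen).
#'
#' @param heatmap A [correlation_heatmap()] (metrics x items matrix).
#' @param threshold Selection threshold in `(0, 1]`; strict inequality.
#' @param overrides Optional named list: per item, a list with `add`
#'   and/or `remove` character vectors of metric names. Names must exist
#'   in the heatmap rows (for `add`) or be selectable.
#' @param task Task label recorded on the result.
#' @return Named list of class `selection_map`: per item (and `total`),
#'   the selected metric names; attribute `provenance` marks each as
#'   `correlation` or `override`.
#' @export
select_features <- function(heatmap, threshold = 0.4, overrides = NULL,
                            task = "task1") {
  if (threshold <= 0) stop("configuration error: threshold must be positive", call. = FALSE)
  items <- colnames(heatmap)
  metrics <- rownames(heatmap)
  sel <- list()
  prov <- list()
  for (it in items) {
    rho <- heatmap[, it]
    picked <- metrics[!is.na(rho) & abs(rho) > threshold]
    origin <- rep("correlation", length(picked))
    ov <- overrides[[it]]
    if (!is.null(ov)) {
      add <- setdiff(ov$add %||% character(0), picked)
      bad <- setdiff(add, metrics)
      if (length(bad) > 0) {
        stop("configuration error: override names unknown metric(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      rm_ <- ov$remove %||% character(0)
      keep <- !(picked %in% rm_)
      picked <- c(picked[keep], add)
      origin <- c(origin[keep], rep("override", length(add)))
    }
    sel[[it]] <- picked
    prov[[it]] <- origin
  }
  attr(sel, "provenance") <- prov
  attr(sel, "task") <- task
  attr(sel, "threshold") <- threshold
  class(sel) <- "selection_map"
  sel
}

#' Read a selection-override file
#'
#' CSV with columns `item`, `action` (`add`/`remove`), `metric`.
#'
#' @param path CSV path.
#' @return Overrides list for [select_features()].
#' @export
read_selection_overrides <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("item", "action", "metric")
  if (!all(needed %in% names(d))) {
    stop("configuration error: override file needs columns item, action, metric",
         call. = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(d))) {
    it <- d$item[i]; act <- d$action[i]
    if (!act %in% c("add", "remove")) {
      stop("configuration error: unknown override action '", act, "'", call. = FALSE)
    }
    out[[it]][[act]] <- c(out[[it]][[act]], d$metric[i])
  }
  out
}
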