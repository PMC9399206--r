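# ---------------------------------------------------------------------------
# Validation protocol: nested (10x10) repeated stratified cross-validation
# with per-repetition MAE accounting, algorithm comparison and interrater
# agreement.
# ---------------------------------------------------------------------------

#' Mean absolute error
#'
#' `MAE = (1/n) * sum_i |y_i - yhat_i|` over the n subjects.
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
mae <- function(actual, predicted) {
  if (length(actual) == 0L || length(actual) != length(predicted)) {
    stop("contract error: actual and predicted must have equal nonzero length",
         call. = FALSE)
  }
  mean(abs(actual - predicted))
}

#' Stratified outer folds by total-score quartiles
#'
#' Sessions are binned into 4 groups at the 1st-3rd quartiles of the
#' total GOALS score; each group is shuffled (seeded) and dealt
#' round-robin across the k folds with a deal position that carries over
#' between groups, so fold sizes differ by at most 1 and each fold's
#' composition mirrors the score distribution.
#'
#' @param total_scores Numeric total scores, one per session.
#' @param k Fold count.
#' @param seed Integer seed.
#' @return List of k integer index vectors (disjoint, covering all
#'   sessions).
#' @export
stratified_outer_folds <- function(total_scores, k, seed) {
  n <- length(total_scores)
  if (n < k) stop("configuration error: fewer sessions (", n, ") than folds (",
                  k, ")", call. = FALSE)
  q <- stats::quantile(total_scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  group <- findInterval(total_scores, q, left.open = TRUE) + 1L  # 1..4
  set.seed(seed)
  folds <- vector("list", k)
  pos <- 0L
  for (g in 1:4) {
    idx <- which(group == g)
    if (length(idx) == 0L) next
    idx <- idx[sample.int(length(idx))]
    for (i in idx) {
      f <- (pos %% k) + 1L
      folds[[f]] <- c(folds[[f]], i)
      pos <- pos + 1L
    }
  }
  folds
}

# draw one child seed per (repetition, fold, algorithm) and per-repetition
# partition seed from the master seed; auditable counter-based layout
spawn_seeds <- function(master, repetitions, k_outer, n_alg) {
  set.seed(master)
  total <- repetitions * (1L + k_outer * n_alg)
  seeds <- sample.int(.Machine$integer.max - 1L, total)
  list(
    partition = seeds[seq_len(repetitions)],
    inner = array(seeds[-seq_len(repetitions)],
                  dim = c(k_outer, n_alg, repetitions))
  )
}

#' Nested, repeated, stratified cross-validation of GOALS estimation
#'
#' For every repetition a fresh quartile-stratified outer partition is
#' drawn. In each outer fold the normalisation parameters are fitted and
#' the hyperparameter grid searched on the training part only (inner
#' plain k-fold CV); clipped test predictions are pooled over the outer
#' folds into one MAE per repetition, algorithm and target.
#'
#' Features enter raw: robust-z parameters are refitted per outer
#' training part and applied to its test part, and missing values are
#' imputed at the training median (z = 0), so no test information leaks
#' into training. `paper_faithful = TRUE` instead normalises once on the
#' whole table before splitting.
#'
#' @param features Raw feature table ([extract_feature_table()]).
#' @param goals Mean-of-raters score table ([mean_goals()]); matched to
#'   `features` by `session_id`.
#' @param selection_map [select_features()] output naming the feature
#'   set per target.
#' @param algorithms Character subset of `SVR`, `PCA_SVR`, `RR`, `PLSR`;
#'   `"baseline"` may be included for the train-mean predictor.
#' @param config [pipeline_config()]; uses `k_outer`, `k_inner`,
#'   `repetitions`, `seed`, `grids`, `selection_threshold`.
#' @param targets Targets to estimate (items and/or `"total"`); defaults
#'   to every target present in the selection map with at least one
#'   selected feature.
#' @param paper_faithful Normalise on the whole dataset before splitting
#'   instead of per training fold.
#' @return Object of class `cv_result`: `mae` (long data.frame:
#'   repetition x algorithm x target), `predictions` (pooled clipped
#'   predictions of the last repetition), `folds` (per-repetition outer
#'   fold assignments), `seeds`, `task`, `config` echo.
#' @export
nested_repeated_cv <- function(features, goals, selection_map,
                               algorithms = ALGORITHMS,
                               config = pipeline_config(),
                               targets = NULL,
                               paper_faithful = FALSE) {
  merged <- merge(features, goals, by = "session_id", suffixes = c("", ".goals"))
  if (nrow(merged) < config$k_outer) {
    stop("configuration error: fewer matched sessions than outer folds",
         call. = FALSE)
  }
  task <- attr(selection_map, "task") %||% (merged$task[1] %||% "task1")
  if (is.null(targets)) {
    targets <- names(selection_map)[lengths(selection_map) > 0]
    targets <- targets[targets %in% names(merged)]
  }
  bad <- setdiff(targets, names(selection_map))
  if (length(bad) > 0) {
    stop("contract error: no feature selection for target(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nrow(merged)
  R <- config$repetitions
  k <- config$k_outer
  alg_fit <- setdiff(algorithms, "baseline")
  seeds <- spawn_seeds(config$seed, R, k, max(1L, length(alg_fit)))
  total <- merged$total

  score_range_for <- function(target) {
    if (target == "total") task_total_range(task) else c(1, 5)
  }

  mae_rows <- list()
  fold_log <- vector("list", R)
  last_predictions <- NULL

  for (r in seq_len(R)) {
    folds <- stratified_outer_folds(total, k, seeds$partition[r])
    fold_log[[r]] <- folds
    preds <- list()
    for (target in targets) {
      sel <- selection_map[[target]]
      y <- merged[[target]]
      rng <- score_range_for(target)
      yhat <- matrix(NA_real_, n, length(algorithms),
                     dimnames = list(NULL, algorithms))
      glob_params <- if (paper_faithful) robust_z_fit(merged[sel]) else NULL
      for (f in seq_along(folds)) {
        test <- folds[[f]]
        if (n - length(test) < 2L) {
          stop("configuration error: outer fold leaves < 2 training sessions",
               call. = FALSE)
        }
        params <- glob_params %||% robust_z_fit(merged[-test, sel, drop = FALSE])
        Ztr <- as.matrix(robust_z_apply(params, merged[-test, sel, drop = FALSE]))
        Zte <- as.matrix(robust_z_apply(params, merged[test, sel, drop = FALSE]))
        Ztr[!is.finite(Ztr)] <- 0  # training-median imputation
        Zte[!is.finite(Zte)] <- 0
        for (a in seq_along(algorithms)) {
          alg <- algorithms[a]
          if (alg == "baseline") {
            yhat[test, a] <- pmin(pmax(mean(y[-test]), rng[1]), rng[2])
            next
          }
          ai <- match(alg, alg_fit)
          spec <- model_spec(alg, grid = config$grids[[alg]])
          fit <- suppressWarnings(fit_with_grid_search(
            spec, Ztr, y[-test], k_inner = config$k_inner,
            seed = seeds$inner[f, ai, r], score_range = rng
          ))
          yhat[test, a] <- predict_clipped(fit, Zte)
        }
      }
      for (alg in algorithms) {
        mae_rows[[length(mae_rows) + 1L]] <- data.frame(
          task = task, target = target, algorithm = alg, repetition = r,
          mae = mae(y, yhat[, alg]), stringsAsFactors = FALSE
        )
      }
      preds[[target]] <- data.frame(
        session_id = merged$session_id, target = target, actual = y,
        yhat, check.names = FALSE, stringsAsFactors = FALSE
      )
    }
    last_predictions <- preds
  }

  structure(list(
    task = task,
    mae = do.call(rbind, mae_rows),
    predictions = last_predictions,
    folds = fold_log,
    seeds = seeds,
    algorithms = algorithms,
    targets = targets,
    k_outer = k, k_inner = config$k_inner, repetitions = R,
    master_seed = config$seed
  ), class = "cv_result")
}

#' Summarise a cross-validation result
#'
#' @param cv A [nested_repeated_cv()] result (or its `mae` data.frame).
#' @return data.frame: per task/target/algorithm the median MAE and its
#'   interquartile range over repetitions.
#' @export
summarize_cv <- function(cv) {
  d <- if (inherits(cv, "cv_result")) cv$mae else cv
  out <- do.call(rbind, lapply(split(d, d[c("task", "target", "algorithm")], drop = TRUE),
    function(g) {
      q <- stats::quantile(g$mae, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      data.frame(task = g$task[1], target = g$target[1], algorithm = g$algorithm[1],
                 repetitions = nrow(g), mae_median = q[2],
                 mae_q1 = q[1], mae_q3 = q[3], stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test wrapper
#'
#' Two-sided rank-sum test; the default uses the normal approximation
#' with tie correction (appropriate at 100 repetitions), `exact = TRUE`
#' enumerates (small samples, no ties).
#'
#' @param x,y Numeric samples.
#' @param exact Use the exact null distribution.
#' @return `htest` object from [stats::wilcox.test()].
#' @export
mwu_test <- function(x, y, exact = FALSE) {
  stats::wilcox.test(x, y, exact = exact, correct = FALSE,
                     alternative = "two.sided")
}

#' Compare algorithm accuracies across repetitions
#'
#' Tie-corrected Kruskal-Wallis across the per-repetition MAE
#' distributions of all algorithms, plus all pairwise two-sided
#' Mann-Whitney U tests, per target.
#'
#' @param cv A [nested_repeated_cv()] result (or its `mae` data.frame).
#' @param exact Exact Mann-Whitney p-values (only sensible for very few
#'   repetitions).
#' @return data.frame per target: Kruskal-Wallis H and p, then one row
#'   per algorithm pair with the MWU p-value.
#' @export
compare_algorithms <- function(cv, exact = FALSE) {
  d <- if (inherits(cv, "cv_result")) cv$mae else cv
  d <- d[d$algorithm != "baseline", ]
  out <- list()
  for (target in unique(d$target)) {
    g <- d[d$target == target, ]
    algs <- unique(g$algorithm)
    if (length(algs) < 2L) stop("contract error: need >= 2 algorithms", call. = FALSE)
    reps <- table(g$algorithm)
    if (min(reps) < 3L) {
      stop("contract error: need >= 3 repetitions per algorithm", call. = FALSE)
    }
    if (length(unique(reps)) != 1L) {
      stop("contract error: unequal repetition counts", call. = FALSE)
    }
    kw <- stats::kruskal.test(g$mae, factor(g$algorithm))
    out[[length(out) + 1L]] <- data.frame(
      task = g$task[1], target = target, comparison = "Kruskal-Wallis",
      statistic = unname(kw$statistic), p_value = kw$p.value,
      stringsAsFactors = FALSE
    )
    for (pair in utils::combn(algs, 2, simplify = FALSE)) {
      w <- mwu_test(g$mae[g$algorithm == pair[1]],
                    g$mae[g$algorithm == pair[2]], exact = exact)
      out[[length(out) + 1L]] <- data.frame(
        task = g$task[1], target = target,
        comparison = paste(pair[1], "vs", pair[2]),
        statistic = unname(w$statistic), p_value = w$p.value,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Interrater agreement and mean scores
#'
#' Spearman correlation between the two raters per GOALS item and for
#' the total, plus the mean-of-raters score table used as the
#' regression target.
#'
#' @param scores List of [goals_score()] records (two raters per
#'   session) or a [goals_table()] data.frame.
#' @return List: `rho` (named vector per item + total), `mean_scores`
#'   (data.frame `session_id`, items, `total`), `raters`.
#' @export
interrater_agreement <- function(scores) {
  d <- if (is.data.frame(scores)) scores else goals_table(scores)
  raters <- sort(unique(d$rater_id))
  if (length(raters) != 2L) {
    stop("contract error: expected exactly 2 raters, got ", length(raters),
         call. = FALSE)
  }
  a <- d[d$rater_id == raters[1], ]
  b <- d[d$rater_id == raters[2], ]
  common <- intersect(a$session_id, b$session_id)
  a <- a[match(common, a$session_id), ]
  b <- b[match(common, b$session_id), ]
  items <- task_items(a$task[1])
  rho <- vapply(c(items, total = "total"), function(col) {
    spearman_rho(a[[col]], b[[col]])
  }, numeric(1))
  names(rho) <- c(items, "total")
  mean_scores <- data.frame(session_id = common, task = a$task,
                            stringsAsFactors = FALSE)
  for (col in items) mean_scores[[col]] <- (a[[col]] + b[[col]]) / 2
  mean_scores$total <- (a$total + b$total) / 2
  list(rho = rho, mean_scores = mean_scores, raters = raters)
}

#' Mean-of-raters GOALS table
#'
#' Convenience wrapper returning just the `mean_scores` component of
#' [interrater_agreement()].
#'
#' @param scores As in [interrater_agreement()].
#' @return data.frame `session_id`, `task`, items, `total`.
#' @export
mean_goals <- function(scores) interrater_agreement(scores)$mean_scores
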