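# ---------------------------------------------------------------------------
# GOALS estimation: four regression algorithms (SVR, PCA-SVR, ridge,
# PLSR) with inner-cross-validated grid search and range clipping.
# ---------------------------------------------------------------------------

ALGORITHMS <- c("SVR", "PCA_SVR", "RR", "PLSR")

#' Default hyperparameter grids
#'
#' SVR: RBF kernel, cost, epsilon-tube width and kernel width gamma.
#' PCA-SVR: retained component counts crossed with the SVR grid.
#' Ridge: log-spaced penalties. PLSR: component counts 1-8.
#' Candidate lists are ordered so that when inner-CV MAE ties, the
#' simpler model (fewer components, larger penalty, smaller cost) wins.
#'
#' @param n_features Feature count of the design matrix; enters the
#'   gamma candidates as `1/n_features` and caps component counts.
#' @return Named list of grids, one per algorithm.
#' @export
default_grids <- function(n_features = 10L) {
  svr <- list(
    cost = c(0.1, 1, 10, 100),
    epsilon = c(0.5, 0.1, 0.01),
    gamma = sort(unique(c(0.01, 0.1, 1 / n_features, 1)))
  )
  list(
    SVR = svr,
    PCA_SVR = c(list(ncomp = c(2, 3, 5, 8)), svr),
    RR = list(alpha = rev(10^seq(-3, 3, length.out = 7))),
    PLSR = list(ncomp = 1:8)
  )
}

#' Specify a regression model
#'
#' @param algorithm One of `"SVR"`, `"PCA_SVR"`, `"RR"`, `"PLSR"`.
#' @param grid Hyperparameter grid (named list of candidate vectors);
#'   `NULL` uses [default_grids()] at fit time.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(algorithm, grid = NULL) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  if (!is.null(grid) && (!is.list(grid) || length(grid) == 0L ||
                         any(lengths(grid) == 0L))) {
    stop("configuration error: grid must be a non-empty named list", call. = FALSE)
  }
  structure(list(algorithm = algorithm, grid = grid), class = "model_spec")
}

# plain k-fold split: permute indices, deal as evenly as possible
make_inner_folds <- function(n, k, seed) {
  if (n < k) stop("configuration error: fewer rows (", n, ") than folds (", k, ")",
                  call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  unname(split(perm, rep_len(seq_len(k), n)))
}

# closed-form ridge with unpenalised intercept via centring; tolerates
# constant columns (the penalty keeps the system well-posed)
fit_ridge <- function(X, y, alpha) {
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  A <- crossprod(Xc) + diag(alpha, ncol(X))
  beta <- solve(A, crossprod(Xc, y - ybar))
  list(beta = beta, intercept = ybar - sum(xbar * beta))
}

predict_ridge <- function(fit, X) as.vector(X %*% fit$beta + fit$intercept)

fit_svr_raw <- function(X, y, cost, epsilon, gamma) {
  e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
             cost = cost, epsilon = epsilon, gamma = gamma, scale = FALSE)
}

fit_plsr_raw <- function(X, y, ncomp) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  mixOmics::pls(X, y, ncomp = ncomp, mode = "regression", scale = FALSE)
}

predict_plsr <- function(fit, X, ncomp) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  p <- stats::predict(fit, X)$predict
  p[, 1, ncomp]
}

expand_grid_ordered <- function(grid) {
  # first-listed parameter varies slowest so candidate order (and hence
  # tie-breaking) follows the stated simplicity ordering
  g <- expand.grid(rev(grid), KEEP.OUT.ATTRS = FALSE)
  g[, rev(seq_along(grid)), drop = FALSE]
}

#' Fit a model with inner-cross-validated grid search
#'
#' For every grid candidate, mean MAE over `k_inner` plain (unstratified)
#' folds of the training rows; the model is then refitted on all rows
#' with the first candidate attaining the minimum (grids are ordered
#' simplest-first, so ties favour the simpler model). Deterministic
#' given `seed`.
#'
#' @param spec A [model_spec()].
#' @param X Numeric design matrix with column names (already normalised;
#'   no missing values).
#' @param y Numeric response.
#' @param k_inner Inner fold count (default 10).
#' @param seed Integer seed controlling the fold split.
#' @param score_range Length-2 clipping range for downstream prediction
#'   (item `[1, 5]`; totals `[5, 25]` / `[4, 20]`).
#' @return Object of class `trained_model` with the chosen
#'   hyperparameters, the refitted model and the grid-search table.
#' @export
fit_with_grid_search <- function(spec, X, y, k_inner = 10L, seed = 1L,
                                 score_range = c(1, 5)) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("contract error: X and y must be finite (impute or drop upstream)",
         call. = FALSE)
  }
  if (length(y) != n) stop("contract error: nrow(X) != length(y)", call. = FALSE)

  feature_names <- colnames(X)
  base <- list(algorithm = spec$algorithm, feature_names = feature_names,
               score_range = as.numeric(score_range), seed = as.integer(seed))

  if (stats::sd(y) == 0) {
    warning("degenerate response: constant y; model predicts the constant")
    out <- c(base, list(hyperparameters = list(), constant = y[1], fit = NULL,
                        search = NULL))
    class(out) <- "trained_model"
    return(out)
  }

  grid <- spec$grid %||% default_grids(ncol(X))[[spec$algorithm]]
  if (!is.null(grid$ncomp)) {
    cap <- min(ncol(X), n - 2L)
    grid$ncomp <- grid$ncomp[grid$ncomp <= cap]
    if (length(grid$ncomp) == 0L) grid$ncomp <- cap
  }
  folds <- make_inner_folds(n, k_inner, seed)
  cand <- expand_grid_ordered(grid)
  fold_mae <- matrix(NA_real_, nrow(cand), length(folds))

  for (f in seq_along(folds)) {
    test <- folds[[f]]
    Xtr <- X[-test, , drop = FALSE]; ytr <- y[-test]
    Xte <- X[test, , drop = FALSE]; yte <- y[test]
    if (length(ytr) < 2L) {
      stop("configuration error: inner fold leaves < 2 training rows", call. = FALSE)
    }
    fold_mae[, f] <- switch(spec$algorithm,
      RR = vapply(seq_len(nrow(cand)), function(i) {
        fit <- fit_ridge(Xtr, ytr, cand$alpha[i])
        mean(abs(yte - predict_ridge(fit, Xte)))
      }, numeric(1)),
      SVR = vapply(seq_len(nrow(cand)), function(i) {
        fit <- fit_svr_raw(Xtr, ytr, cand$cost[i], cand$epsilon[i], cand$gamma[i])
        mean(abs(yte - stats::predict(fit, Xte)))
      }, numeric(1)),
      PLSR = {
        fit <- fit_plsr_raw(Xtr, ytr, max(cand$ncomp))
        vapply(seq_len(nrow(cand)), function(i) {
          mean(abs(yte - predict_plsr(fit, Xte, cand$ncomp[i])))
        }, numeric(1))
      },
      PCA_SVR = {
        pca <- stats::prcomp(Xtr, center = TRUE, scale. = FALSE)
        str_all <- pca$x
        ste_all <- stats::predict(pca, Xte)
        vapply(seq_len(nrow(cand)), function(i) {
          nc <- min(cand$ncomp[i], ncol(str_all))
          fit <- fit_svr_raw(str_all[, seq_len(nc), drop = FALSE], ytr,
                             cand$cost[i], cand$epsilon[i], cand$gamma[i])
          mean(abs(yte - stats::predict(fit, ste_all[, seq_len(nc), drop = FALSE])))
        }, numeric(1))
      }
    )
  }

  mean_mae <- rowMeans(fold_mae)
  best <- which.min(mean_mae)  # first minimum = simplest on ties
  chosen <- as.list(cand[best, , drop = FALSE])

  fit <- switch(spec$algorithm,
    RR = fit_ridge(X, y, chosen$alpha),
    SVR = fit_svr_raw(X, y, chosen$cost, chosen$epsilon, chosen$gamma),
    PLSR = fit_plsr_raw(X, y, chosen$ncomp),
    PCA_SVR = {
      pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
      nc <- min(chosen$ncomp, ncol(pca$x))
      list(pca = pca, ncomp = nc,
           svr = fit_svr_raw(pca$x[, seq_len(nc), drop = FALSE], y,
                             chosen$cost, chosen$epsilon, chosen$gamma))
    }
  )
  out <- c(base, list(hyperparameters = chosen, constant = NULL, fit = fit,
                      search = cbind(cand, inner_mae = mean_mae)))
  class(out) <- "trained_model"
  out
}

predict_raw <- function(model, X) {
  switch(model$algorithm,
    RR = predict_ridge(model$fit, X),
    SVR = as.vector(stats::predict(model$fit, X)),
    PLSR = as.vector(predict_plsr(model$fit, X, model$hyperparameters$ncomp)),
    PCA_SVR = {
      scores <- stats::predict(model$fit$pca, X)
      as.vector(stats::predict(model$fit$svr,
                               scores[, seq_len(model$fit$ncomp), drop = FALSE]))
    }
  )
}

#' Predict with clipping to the GOALS score range
#'
#' Raw predictions outside the target's score range are clipped to its
#' bounds (items to `[1, 5]`, totals to `[5, 25]` or `[4, 20]`), as raw
#' regression output can leave the scale.
#'
#' @param model A [fit_with_grid_search()] result.
#' @param X Design matrix with the training feature columns.
#' @return Numeric vector of clipped predictions.
#' @export
predict_clipped <- function(model, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!identical(colnames(X), model$feature_names)) {
    stop("contract error: feature columns do not match the training manifest",
         call. = FALSE)
  }
  if (!is.null(model$constant)) {
    raw <- rep(model$constant, nrow(X))
  } else {
    raw <- predict_raw(model, X)
  }
  pmin(pmax(raw, model$score_range[1]), model$score_range[2])
}
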