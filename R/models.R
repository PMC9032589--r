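#' Default hyperparameter grid for the boosted-tree learner
#'
#' The grid crosses tree depth, ensemble size and learning rate; it is the
#' search space for the inner cross-validation loop and can be overridden
#' per run.
#'
#' @param reduced if TRUE, a small grid for desk-scale runs.
#' @return list of parameter lists.
#' @export
default_gbt_grid <- function(reduced = FALSE) {
  if (reduced) {
    grid <- expand.grid(max_depth = c(3L, 6L), nrounds = 30L, eta = 0.1)
  } else {
    grid <- expand.grid(
      max_depth = c(3L, 6L), nrounds = c(100L, 300L), eta = c(0.05, 0.1)
    )
  }
  lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, ]))
}

#' Default L1 penalty grid
#'
#' @param n_lambda number of log-spaced penalties.
#' @param lambda_min,lambda_max grid range.
#' @return list of parameter lists, one `lambda` each.
#' @export
default_lasso_grid <- function(n_lambda = 20, lambda_min = 1e-4, lambda_max = 1) {
  lambdas <- exp(seq(log(lambda_max), log(lambda_min), length.out = n_lambda))
  lapply(lambdas, function(l) list(lambda = l))
}

check_design_matrix <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.numeric(x)) stop("design matrix must be numeric")
  if (any(!is.finite(x))) stop("design matrix contains non-finite values")
  x
}

#' Fit a gradient-boosted tree ensemble
#'
#' Second-order gradient boosting with exact greedy splits, squared-error
#' loss for numeric targets and weighted logistic loss for two-level
#' factors; factors with more than two levels are fitted one-vs-rest. The
#' learner exposes total-gain ("impurity") feature importances and is fully
#' deterministic (no row/column subsampling), so refits on identical data
#' give identical predictions.
#'
#' @param x numeric feature matrix.
#' @param y numeric target or factor labels.
#' @param weights non-negative sample weights (default 1).
#' @param max_depth,nrounds,eta,lambda,min_child_weight boosting
#'   hyperparameters (tree depth, number of trees, learning rate, L2 leaf
#'   penalty, minimum child hessian).
#' @return a `wf_gbt` model.
#' @export
fit_boosted_trees <- function(x, y, weights = NULL, max_depth = 6, nrounds = 100,
                              eta = 0.1, lambda = 1, min_child_weight = 1e-3) {
  x <- check_design_matrix(x)
  if (is.null(weights)) weights <- rep(1, nrow(x))
  if (length(weights) != nrow(x) || any(weights < 0)) stop("bad sample weights")
  if (is.character(y)) y <- factor(y)
  if (is.factor(y)) {
    lev <- levels(droplevels(y))
    if (length(lev) < 2L) stop("classification target has a single class")
    y <- droplevels(y)
    if (length(lev) == 2L) {
      fit <- gbt_train_cpp(
        x, as.numeric(y == lev[2L]), as.numeric(weights), 1L,
        as.integer(nrounds), as.integer(max_depth), eta, lambda, min_child_weight
      )
      fits <- list(fit)
    } else {
      fits <- lapply(lev, function(cl) {
        gbt_train_cpp(
          x, as.numeric(y == cl), as.numeric(weights), 1L,
          as.integer(nrounds), as.integer(max_depth), eta, lambda, min_child_weight
        )
      })
    }
    obj <- "classification"
  } else {
    if (any(!is.finite(y))) stop("non-finite regression target")
    fits <- list(gbt_train_cpp(
      x, as.numeric(y), as.numeric(weights), 0L,
      as.integer(nrounds), as.integer(max_depth), eta, lambda, min_child_weight
    ))
    lev <- NULL
    obj <- "regression"
  }
  gain <- Reduce(`+`, lapply(fits, function(f) f$gain))
  names(gain) <- colnames(x)
  structure(
    list(
      fits = fits, levels = lev, objective = obj, gain = gain,
      feature_names = colnames(x),
      params = list(
        max_depth = max_depth, nrounds = nrounds, eta = eta,
        lambda = lambda, min_child_weight = min_child_weight
      )
    ),
    class = "wf_gbt"
  )
}

#' Predict from a boosted-tree model
#'
#' @param object a `wf_gbt` model.
#' @param newdata numeric feature matrix.
#' @param type "response" (probability of the positive class / per-class
#'   probability matrix / numeric prediction), "class" (predicted label),
#'   or "link" (raw margin).
#' @param ... unused.
#' @export
predict.wf_gbt <- function(object, newdata, type = c("response", "class", "link"), ...) {
  type <- match.arg(type)
  newdata <- check_design_matrix(newdata)
  if (object$objective == "regression") {
    return(gbt_predict_cpp(object$fits[[1L]], newdata))
  }
  raw <- vapply(
    object$fits, function(f) gbt_predict_cpp(f, newdata),
    numeric(nrow(newdata))
  )
  raw <- matrix(raw, nrow = nrow(newdata))
  prob <- 1 / (1 + exp(-raw))
  if (length(object$levels) == 2L) {
    if (type == "link") return(raw[, 1L])
    if (type == "response") return(prob[, 1L])
    factor(object$levels[1L + (prob[, 1L] >= 0.5)], levels = object$levels)
  } else {
    prob <- prob / rowSums(prob) # normalize one-vs-rest scores
    colnames(prob) <- object$levels
    if (type == "link") return(raw)
    if (type == "response") return(prob)
    factor(object$levels[max.col(prob, ties.method = "first")], levels = object$levels)
  }
}

#' @export
print.wf_gbt <- function(x, ...) {
  cat(sprintf(
    "<wf_gbt> %s, %d tree(s) x depth %d, eta %g%s\n",
    x$objective, x$params$nrounds, x$params$max_depth, x$params$eta,
    if (!is.null(x$levels)) paste0(", classes: ", paste(x$levels, collapse = "/")) else ""
  ))
  invisible(x)
}

#' Fit an L1-penalized linear model
#'
#' L1-penalized logistic regression for two-level factors and L1-penalized
#' least squares for numeric targets, via glmnet. Features are standardized
#' internally using the training data only; coefficients are reported on
#' the original scale. Constant feature columns are dropped with a warning.
#'
#' @param x numeric feature matrix.
#' @param y target (factor for classification, numeric for regression).
#' @param weights non-negative sample weights.
#' @param lambda the penalty to use for prediction; the full `lambda_grid`
#'   path is fitted so any grid value can be scored.
#' @param lambda_grid descending penalty path (default
#'   [default_lasso_grid()] values).
#' @return a `wf_lasso` model.
#' @export
fit_l1_linear <- function(x, y, weights = NULL, lambda = NULL, lambda_grid = NULL) {
  x <- check_design_matrix(x)
  if (is.null(weights)) weights <- rep(1, nrow(x))
  if (is.null(lambda_grid)) {
    lambda_grid <- vapply(default_lasso_grid(), `[[`, numeric(1), "lambda")
  }
  lambda_grid <- sort(unique(c(lambda_grid, lambda)), decreasing = TRUE)
  keep <- apply(x, 2L, function(col) stats::sd(col) > 0)
  if (!all(keep)) {
    warning(
      "dropping constant feature column(s): ",
      paste(colnames(x)[!keep], collapse = ", ")
    )
  }
  if (!any(keep)) stop("all feature columns constant")
  if (is.character(y)) y <- factor(y)
  family <- if (is.factor(y)) "binomial" else "gaussian"
  if (is.factor(y)) {
    y <- droplevels(y)
    if (nlevels(y) != 2L) stop("l1 classifier requires exactly two classes")
  }
  fit <- glmnet::glmnet(
    x[, keep, drop = FALSE], y,
    family = family, weights = weights,
    lambda = lambda_grid, standardize = TRUE
  )
  structure(
    list(
      fit = fit, keep = keep, family = family,
      levels = if (family == "binomial") levels(y) else NULL,
      lambda = if (is.null(lambda)) lambda_grid[length(lambda_grid)] else lambda,
      feature_names = colnames(x)
    ),
    class = "wf_lasso"
  )
}

#' Predict from an L1-penalized linear model
#'
#' @param object a `wf_lasso` model.
#' @param newdata numeric feature matrix.
#' @param type "response", "class" or "link".
#' @param lambda penalty at which to predict (default: the model's).
#' @param ... unused.
#' @export
predict.wf_lasso <- function(object, newdata,
                             type = c("response", "class", "link"),
                             lambda = NULL, ...) {
  type <- match.arg(type)
  newdata <- check_design_matrix(newdata)[, object$keep, drop = FALSE]
  s <- if (is.null(lambda)) object$lambda else lambda
  if (object$family == "binomial") {
    pr <- as.numeric(predict(object$fit, newdata, s = s, type = "response", exact = FALSE))
    if (type == "response") return(pr)
    if (type == "link") return(stats::qlogis(pmin(1 - 1e-12, pmax(1e-12, pr))))
    factor(object$levels[1L + (pr >= 0.5)], levels = object$levels)
  } else {
    as.numeric(predict(object$fit, newdata, s = s))
  }
}

#' Coefficients of an L1 model at its working penalty
#'
#' @param object a `wf_lasso` model.
#' @param lambda penalty (default: the model's).
#' @param ... unused.
#' @export
coef.wf_lasso <- function(object, lambda = NULL, ...) {
  s <- if (is.null(lambda)) object$lambda else lambda
  cf <- as.matrix(coef(object$fit, s = s))
  out <- numeric(length(object$feature_names) + 1L)
  names(out) <- c("(Intercept)", object$feature_names)
  out[rownames(cf)] <- cf[, 1L]
  out
}

#' Rank features by model importance
#'
#' For boosted trees, total split gain scaled to sum to one (the "scaled
#' impurity" convention); for linear models, absolute coefficients at the
#' working penalty, flagged as coefficient-based.
#'
#' @param model a `wf_gbt` or `wf_lasso` model.
#' @param feature_names names to report (default: from the model).
#' @param top_k number of features to return; clipped to the number
#'   available.
#' @return data.frame `feature`, `importance` (sums to 1 over all
#'   features), `rank`, with attribute `basis` = "gain" or "coefficient".
#' @export
rank_importance <- function(model, feature_names = NULL, top_k = 15) {
  if (inherits(model, "wf_gbt")) {
    imp <- model$gain
    basis <- "gain"
  } else if (inherits(model, "wf_lasso")) {
    cf <- coef(model)[-1L]
    imp <- abs(cf)
    basis <- "coefficient"
    warning("linear model: importance ranking is |coefficient|-based")
  } else {
    stop("unsupported model type")
  }
  if (is.null(feature_names)) feature_names <- names(imp)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_along(imp))
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  top_k <- min(top_k, length(imp))
  ord <- order(imp, decreasing = TRUE)[seq_len(top_k)]
  out <- data.frame(
    feature = feature_names[ord], importance = unname(imp[ord]),
    rank = seq_len(top_k), stringsAsFactors = FALSE
  )
  attr(out, "basis") <- basis
  out
}
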