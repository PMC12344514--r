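#' Cross-validated elastic-net regression on connectivity features
#'
#' Fits the elastic net
#'   min (1/2n) sum(y - b0 - X b)^2 + lambda * ((1-alpha) ||b||^2 / 2 + alpha ||b||_1)
#' over a grid of mixing parameters alpha and a descending lambda path,
#' selecting the (alpha, lambda) pair with the minimum mean cross-validated
#' squared error. Folds are one random partition fixed by `seed` and reused
#' across the whole alpha grid. Features are standardized internally on the
#' training data (mean 0, SD 1); coefficients are reported on the
#' standardized scale and the standardization parameters are stored so test
#' data are transformed identically. The outcome stays on its native scale.
#'
#' alpha = 0 (pure ridge) is excluded from the default grid so that "number
#' of selected features" remains well defined.
#'
#' @param X_train subjects x feature numeric matrix (column names = feature
#'   ids).
#' @param y_train numeric outcome vector (no missing values; drop them
#'   before fitting).
#' @param alpha_grid mixing parameters to search (default 0.1, 0.2, ..., 1).
#' @param n_folds folds for cross-validation (default 10).
#' @param seed integer seed controlling the fold partition.
#' @return a `prediction_model`: list with `alpha`, `lambda`, `intercept`,
#'   `coefficients` (standardized scale, named), `center`, `scale`,
#'   `cv_curve` (alpha, lambda, cvm, cvsd records), `n_selected`,
#'   `degenerate` (TRUE when no features selected), `seed`.
#' @export
fit_elastic_net_cv <- function(X_train, y_train,
                               alpha_grid = seq(0.1, 1, by = 0.1),
                               n_folds = 10, seed = 1) {
  X_train <- as.matrix(X_train)
  n <- nrow(X_train)
  if (anyNA(y_train) || anyNA(X_train)) stop("missing values: drop incomplete rows first")
  if (length(y_train) != n) stop("X_train and y_train disagree on subject count")
  if (stats::sd(y_train) == 0) stop("constant outcome: nothing to fit")
  if (n < n_folds) stop("fewer subjects (", n, ") than folds (", n_folds, ")")
  stopifnot(all(alpha_grid >= 0), all(alpha_grid <= 1), n_folds >= 2)

  ctr <- colMeans(X_train)
  scl <- apply(X_train, 2L, stats::sd)
  scl[scl == 0] <- 1 # constant features contribute nothing either way
  Xs <- sweep(sweep(X_train, 2L, ctr), 2L, scl, `/`)

  set.seed(seed)
  foldid <- sample(rep_len(seq_len(n_folds), n))

  fits <- vector("list", length(alpha_grid))
  best <- NULL
  curve <- vector("list", length(alpha_grid))
  for (ai in seq_along(alpha_grid)) {
    a <- alpha_grid[ai]
    cv <- glmnet::cv.glmnet(
      Xs, y_train,
      alpha = a, foldid = foldid, family = "gaussian",
      standardize = FALSE, type.measure = "mse"
    )
    fits[[ai]] <- cv
    curve[[ai]] <- data.frame(
      alpha = a, lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd
    )
    m <- min(cv$cvm)
    if (is.null(best) || m < best$cvm) {
      best <- list(ai = ai, cvm = m, lambda = cv$lambda.min)
    }
  }
  cv_best <- fits[[best$ai]]
  beta <- as.numeric(stats::coef(cv_best, s = "lambda.min"))
  fn <- colnames(X_train)
  if (is.null(fn)) fn <- sprintf("f%04d", seq_len(ncol(X_train)))
  coefficients <- stats::setNames(beta[-1], fn)
  n_selected <- sum(coefficients != 0)
  structure(
    list(
      alpha = alpha_grid[best$ai], lambda = best$lambda,
      intercept = beta[1], coefficients = coefficients,
      center = stats::setNames(ctr, fn), scale = stats::setNames(scl, fn),
      cv_curve = do.call(rbind, curve), cv_error = best$cvm,
      n_selected = n_selected, degenerate = n_selected == 0L,
      feature_names = fn, seed = seed
    ),
    class = "prediction_model"
  )
}

#' @export
print.prediction_model <- function(x, ...) {
  cat(sprintf(
    "Elastic net: alpha = %.2f, lambda = %.4g, %d selected feature%s%s\n",
    x$alpha, x$lambda, x$n_selected, if (x$n_selected == 1) "" else "s",
    if (x$degenerate) " (degenerate: intercept-only)" else ""
  ))
  invisible(x)
}

#' Predicted scores for train or test subjects
#'
#' Applies the trained model (training-set standardization, then intercept
#' plus standardized coefficients) to a feature matrix and pairs predictions
#' with observed outcomes. Subjects with missing observed outcome are
#' dropped.
#'
#' @param model a `prediction_model`.
#' @param X subjects x feature matrix; columns must match the training
#'   enumeration.
#' @param y observed outcomes (may contain NA; those rows are dropped).
#' @param subject_id optional ids (default rownames of X or sub-NNN).
#' @param set_label `"train"` or `"test"`.
#' @param measure outcome label carried through to reports.
#' @return a `score_table` data frame (subject_id, observed, predicted) with
#'   attributes `set`, `measure`, `degenerate`.
#' @export
predict_scores <- function(model, X, y, subject_id = NULL,
                           set_label = "train", measure = "outcome") {
  stopifnot(inherits(model, "prediction_model"))
  X <- as.matrix(X)
  cn <- colnames(X)
  if (is.null(cn)) {
    if (ncol(X) != length(model$feature_names)) stop("feature enumeration mismatch")
  } else if (!identical(cn, model$feature_names)) {
    stop("feature enumeration mismatch with training data")
  }
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, `/`)
  predicted <- drop(model$intercept + Xs %*% model$coefficients)
  if (is.null(subject_id)) subject_id <- rownames(X)
  if (is.null(subject_id)) subject_id <- sprintf("sub-%03d", seq_len(nrow(X)))
  keep <- !is.na(y)
  out <- data.frame(
    subject_id = subject_id[keep], observed = y[keep],
    predicted = predicted[keep], stringsAsFactors = FALSE
  )
  attr(out, "set") <- set_label
  attr(out, "measure") <- measure
  attr(out, "degenerate") <- model$degenerate
  class(out) <- c("score_table", "data.frame")
  out
}

#' Model performance: predicted-observed correlation
#'
#' Pearson correlation between predicted and observed scores. A degenerate
#' model (constant predictions, e.g. zero selected features) is reported as
#' r = 0 with `attr(, "degenerate") = TRUE`, matching the convention of
#' reporting r = 0 for intercept-only models.
#'
#' @param scores a `score_table` with >= 3 rows.
#' @return scalar correlation with a `degenerate` attribute.
#' @export
performance_r <- function(scores) {
  stopifnot(nrow(scores) >= 3L)
  if (stats::sd(scores$predicted) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(stats::cor(scores$predicted, scores$observed), degenerate = FALSE)
}
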