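#' Does group similarity moderate predictive performance?
#'
#' Ordinary least squares of observed ~ predicted + icc + predicted:icc
#' (+ optional covariates entered as main effects only). Predictors are
#' entered uncentered, so the `predicted` main effect is the conditional
#' slope at ICC = 0 and a conditional slope of 1 reflects optimal
#' prediction. The predicted x ICC interaction is the focal term: a
#' positive coefficient means prediction is stronger for subjects more
#' similar to the group.
#'
#' @param scores a `score_table` (subject_id, observed, predicted).
#' @param icc a `similarity_table` (subject_id, icc) for the same set.
#' @param covariates optional data frame with `subject_id` plus covariate
#'   columns, merged by id and entered as main effects.
#' @param alpha two-sided significance level for reporting (default 0.05).
#' @return a `moderation_result`: list with `coefficients` (estimate, se,
#'   t, p per term), `vcov`, `df_residual`, `n`, `r_squared`, `alpha`,
#'   `measure`, `set`.
#' @export
fit_moderation <- function(scores, icc, covariates = NULL, alpha = 0.05) {
  if (isTRUE(attr(scores, "degenerate"))) {
    stop("degenerate prediction model (constant predicted score): moderation undefined")
  }
  dat <- merge(
    scores[, c("subject_id", "observed", "predicted")],
    icc[, c("subject_id", "icc")],
    by = "subject_id"
  )
  if (!is.null(covariates)) dat <- merge(dat, covariates, by = "subject_id")
  if (nrow(dat) < 10L) stop("need at least 10 aligned subjects, got ", nrow(dat))
  if (stats::sd(dat$predicted) == 0) {
    stop("degenerate prediction model (constant predicted score): moderation undefined")
  }
  cov_terms <- if (is.null(covariates)) character(0) else {
    setdiff(colnames(covariates), "subject_id")
  }
  rhs <- paste(c("predicted * icc", cov_terms), collapse = " + ")
  fml <- stats::as.formula(paste("observed ~", rhs))
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    stop(
      "rank-deficient moderation model; collinear terms: ",
      paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", ")
    )
  }
  sm <- summary(fit)
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("estimate", "se", "t", "p")
  coefs$term <- rownames(coefs)
  rownames(coefs) <- NULL
  coefs <- coefs[, c("term", "estimate", "se", "t", "p")]
  structure(
    list(
      coefficients = coefs, vcov = stats::vcov(fit),
      df_residual = fit$df.residual, n = nrow(dat),
      r_squared = sm$r.squared, alpha = alpha,
      measure = attr(scores, "measure"), set = attr(scores, "set"),
      icc_range = range(dat$icc)
    ),
    class = "moderation_result"
  )
}

#' @export
print.moderation_result <- function(x, ...) {
  cat(sprintf(
    "Moderation model (%s, %s set): n = %d, R^2 = %.3f\n",
    x$measure %||% "outcome", x$set %||% "?", x$n, x$r_squared
  ))
  print(transform(x$coefficients,
    estimate = signif(estimate, 4), se = signif(se, 3),
    t = round(t, 2), p = signif(p, 3)
  ), row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

coef_of <- function(result, term) {
  i <- match(term, result$coefficients$term)
  if (is.na(i)) stop("term not in model: ", term)
  result$coefficients$estimate[i]
}

#' Johnson-Neyman region of significance
#'
#' The conditional slope of predicted score at similarity s is
#' theta(s) = b1 + b3 s with SE(s)^2 = Var(b1) + s^2 Var(b3) + 2 s
#' Cov(b1, b3). Boundaries are the real roots of theta(s)^2 = t_crit^2
#' SE(s)^2, a quadratic in s; there are 0, 1, or 2 of them. Significance
#' labels are reported only inside the observed ICC range.
#'
#' @param result a `moderation_result` containing `predicted` and
#'   `predicted:icc` terms.
#' @param alpha two-sided level (default 0.05).
#' @param icc_range interval over which to label regions; defaults to the
#'   observed ICC range of the fitted data.
#' @return a `jn_region`: list with `boundaries` (sorted real roots),
#'   `regions` (data frame: lower, upper, significant, slope_sign),
#'   `t_crit`, `alpha`, and the conditional slope function `theta`.
#' @export
johnson_neyman <- function(result, alpha = 0.05, icc_range = NULL) {
  stopifnot(inherits(result, "moderation_result"))
  b1 <- coef_of(result, "predicted")
  b3 <- coef_of(result, "predicted:icc")
  V <- result$vcov
  v11 <- V["predicted", "predicted"]
  v33 <- V["predicted:icc", "predicted:icc"]
  v13 <- V["predicted", "predicted:icc"]
  if (v33 == 0) stop("zero variance for the interaction term: JN boundaries undefined")
  if (is.null(icc_range)) icc_range <- result$icc_range
  t_crit <- stats::qt(1 - alpha / 2, df = result$df_residual)

  A <- b3^2 - t_crit^2 * v33
  B <- 2 * (b1 * b3 - t_crit^2 * v13)
  C <- b1^2 - t_crit^2 * v11
  disc <- B^2 - 4 * A * C
  boundaries <- if (abs(A) < .Machine$double.eps * max(1, b3^2)) {
    if (B != 0) -C / B else numeric(0)
  } else if (disc < 0) {
    numeric(0)
  } else {
    sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  }

  theta <- function(s) b1 + b3 * s
  se_theta <- function(s) sqrt(v11 + s^2 * v33 + 2 * s * v13)

  cuts <- sort(unique(c(
    icc_range[1], boundaries[boundaries > icc_range[1] & boundaries < icc_range[2]],
    icc_range[2]
  )))
  regions <- do.call(rbind, lapply(seq_len(length(cuts) - 1L), function(i) {
    mid <- (cuts[i] + cuts[i + 1]) / 2
    tval <- theta(mid) / se_theta(mid)
    data.frame(
      lower = cuts[i], upper = cuts[i + 1],
      significant = abs(tval) > t_crit,
      slope_sign = sign(theta(mid))
    )
  }))
  structure(
    list(
      boundaries = boundaries, regions = regions, t_crit = t_crit,
      alpha = alpha, icc_range = icc_range, theta = theta, se_theta = se_theta
    ),
    class = "jn_region"
  )
}

#' @export
print.jn_region <- function(x, ...) {
  cat(sprintf(
    "Johnson-Neyman region (alpha = %.3g, t_crit = %.3f)\n", x$alpha, x$t_crit
  ))
  if (length(x$boundaries)) {
    cat("  boundaries:", paste(signif(x$boundaries, 4), collapse = ", "), "\n")
  } else {
    cat("  no real boundaries (slope significance uniform)\n")
  }
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Screen covariates for association with group similarity
#'
#' One OLS per covariate with ICC as the outcome. Categorical covariates
#' (character/factor, e.g. scanning site) enter as fixed-effect indicators;
#' a single-level categorical is an error. Terms are flagged at the
#' Bonferroni-corrected level.
#'
#' @param icc a `similarity_table` (subject_id, icc).
#' @param covariates data frame with `subject_id` plus covariate columns
#'   (e.g. age, sex, site, mean FD).
#' @param alpha per-term flag threshold (default 0.01, Bonferroni-style).
#' @return data frame: covariate, term, estimate, se, t, p, significant.
#' @export
covariate_screen <- function(icc, covariates, alpha = 0.01) {
  dat <- merge(icc[, c("subject_id", "icc")], covariates, by = "subject_id")
  covs <- setdiff(colnames(covariates), "subject_id")
  if (!length(covs)) stop("no covariate columns")
  rows <- lapply(covs, function(cv) {
    x <- dat[[cv]]
    if (is.character(x) || is.factor(x)) {
      x <- factor(x)
      if (nlevels(x) < 2L) {
        stop("covariate '", cv, "' has a single level: cannot model")
      }
      dat[[cv]] <- x
    }
    fit <- stats::lm(stats::as.formula(paste("icc ~", cv)), data = dat)
    sm <- summary(fit)$coefficients
    terms <- rownames(sm)[-1] # drop intercept
    data.frame(
      covariate = cv, term = terms,
      estimate = sm[-1, 1], se = sm[-1, 2], t = sm[-1, 3], p = sm[-1, 4],
      significant = sm[-1, 4] < alpha,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  out
}
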