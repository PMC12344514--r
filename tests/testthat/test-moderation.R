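make_scores <- function(observed, predicted, ids = NULL) {
  ids <- ids %||% sprintf("s%03d", seq_along(observed))
  out <- data.frame(subject_id = ids, observed = observed, predicted = predicted)
  attr(out, "set") <- "train"
  attr(out, "measure") <- "toy"
  class(out) <- c("score_table", "data.frame")
  out
}

make_sim <- function(icc, ids = NULL) {
  ids <- ids %||% sprintf("s%03d", seq_along(icc))
  out <- data.frame(subject_id = ids, icc = icc, label = classify_icc(pmin(icc, 1)),
    set = "train")
  class(out) <- c("similarity_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a perfectly predicted outcome gives b1 = 1 and null other terms", {
  set.seed(500)
  pred <- rnorm(40)
  icc <- runif(40, 0.2, 0.9)
  fit <- suppressWarnings( # "essentially perfect fit" is the point here
    fit_moderation(make_scores(pred, pred), make_sim(icc))
  )
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "predicted"], 1, tolerance = 1e-8)
  expect_equal(cf$estimate[cf$term == "icc"], 0, tolerance = 1e-8)
  expect_equal(cf$estimate[cf$term == "predicted:icc"], 0, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
})

test_that("moderation coefficients match the normal-equations oracle", {
  set.seed(501)
  for (i in 1:10) {
    n <- 60
    pred <- rnorm(n)
    icc <- runif(n, 0, 1)
    y <- 0.5 + 1.2 * pred + 0.3 * icc + 0.8 * pred * icc + rnorm(n)
    fit <- fit_moderation(make_scores(y, pred), make_sim(icc))
    X <- cbind(1, pred, icc, pred * icc)
    orc <- ols_oracle(X, y)
    expect_equal(fit$coefficients$estimate, unname(orc$beta), tolerance = 1e-8)
    expect_equal(unname(diag(fit$vcov)), unname(diag(orc$vcov)), tolerance = 1e-8)
    expect_equal(fit$df_residual, orc$df)
  }
})

test_that("degenerate predictors and rank deficiency raise errors", {
  icc <- runif(20, 0.2, 0.8)
  expect_error(
    fit_moderation(make_scores(rnorm(20), rep(2, 20)), make_sim(icc)),
    "degenerate"
  )
  sc <- make_scores(rnorm(5), rnorm(5))
  expect_error(fit_moderation(sc, make_sim(runif(5))), "at least 10")
  # icc perfectly collinear with predicted -> interaction collapses
  pred <- rnorm(20)
  expect_error(
    fit_moderation(make_scores(rnorm(20), pred), make_sim(pred)),
    "collinear|rank"
  )
})

test_that("positive attenuation yields positive interactions in expectation", {
  set.seed(502)
  signs <- replicate(200, {
    mc <- simulate_moderation_cohort(n = 150)
    fit <- fit_moderation(mc$scores, mc$similarity)
    fit$coefficients$estimate[fit$coefficients$term == "predicted:icc"] > 0
  })
  expect_gte(mean(signs), 0.9)
})

test_that("JN boundaries satisfy their defining identity", {
  set.seed(503)
  mc <- simulate_moderation_cohort(n = 300)
  fit <- fit_moderation(mc$scores, mc$similarity)
  jn <- johnson_neyman(fit)
  expect_gt(length(jn$boundaries), 0)
  for (s in jn$boundaries) {
    expect_lt(abs(abs(jn$theta(s) / jn$se_theta(s)) - jn$t_crit), 1e-6)
  }
  # significance labels agree with a direct grid evaluation
  grid <- seq(fit$icc_range[1], fit$icc_range[2], length.out = 50)
  for (k in seq_len(nrow(jn$regions))) {
    inside <- grid[grid > jn$regions$lower[k] & grid < jn$regions$upper[k]]
    if (!length(inside)) next
    tv <- jn$theta(inside) / jn$se_theta(inside)
    expect_true(all((abs(tv) > jn$t_crit) == jn$regions$significant[k]))
  }
})

test_that("JN regions degenerate gracefully when b3 is null and b1 strong", {
  set.seed(504)
  n <- 200
  pred <- rnorm(n)
  icc <- runif(n, 0.2, 0.9)
  y <- 2 * pred + rnorm(n, 0, 0.3) # no interaction, strong slope
  fit <- fit_moderation(make_scores(y, pred), make_sim(icc))
  jn <- johnson_neyman(fit)
  # slope uniformly significant in the observed range
  expect_true(all(jn$regions$significant))
  inside <- jn$boundaries > fit$icc_range[1] & jn$boundaries < fit$icc_range[2]
  expect_false(any(inside))
})

test_that("JN t statistics are invariant to affine outcome rescaling", {
  set.seed(505)
  mc <- simulate_moderation_cohort(n = 200)
  fit1 <- fit_moderation(mc$scores, mc$similarity)
  sc2 <- mc$scores
  sc2$observed <- 10 * sc2$observed + 3
  sc2$predicted <- mc$scores$predicted # predictor unchanged
  fit2 <- fit_moderation(sc2, mc$similarity)
  jn1 <- johnson_neyman(fit1)
  jn2 <- johnson_neyman(fit2)
  expect_equal(jn1$boundaries, jn2$boundaries, tolerance = 1e-8)
  s <- mean(fit1$icc_range)
  expect_equal(
    jn1$theta(s) / jn1$se_theta(s), jn2$theta(s) / jn2$se_theta(s),
    tolerance = 1e-8
  )
})

test_that("orthogonal covariates barely move the focal interaction", {
  set.seed(506)
  mc <- simulate_moderation_cohort(n = 400)
  covs <- data.frame(
    subject_id = mc$scores$subject_id,
    nuisance = rnorm(400)
  )
  f0 <- fit_moderation(mc$scores, mc$similarity)
  f1 <- fit_moderation(mc$scores, mc$similarity, covariates = covs)
  b3_0 <- f0$coefficients$estimate[f0$coefficients$term == "predicted:icc"]
  b3_1 <- f1$coefficients$estimate[f1$coefficients$term == "predicted:icc"]
  se_0 <- f0$coefficients$se[f0$coefficients$term == "predicted:icc"]
  expect_lt(abs(b3_0 - b3_1), 0.25 * se_0)
})

test_that("covariate screen recovers a planted FD effect and flags errors", {
  set.seed(507)
  n <- 300
  ids <- sprintf("s%03d", 1:n)
  fd <- runif(n, 0.02, 0.3)
  icc <- 0.8 - 1.5 * fd + rnorm(n, 0, 0.05)
  sim <- make_sim(pmin(pmax(icc, -1), 1), ids = ids)
  covs <- data.frame(
    subject_id = ids, mean_fd = fd,
    age = runif(n, 130, 155),
    site = sample(c("s1", "s2", "s3"), n, replace = TRUE)
  )
  scr <- covariate_screen(sim, covs, alpha = 0.01)
  fd_row <- scr[scr$covariate == "mean_fd", ]
  expect_true(fd_row$significant)
  expect_equal(fd_row$estimate, -1.5, tolerance = 3 * fd_row$se)
  # site enters as indicators, one row per non-reference level
  expect_equal(sum(scr$covariate == "site"), 2)
  # independent covariate: not flagged at the strict threshold (usually)
  expect_error(
    covariate_screen(sim, data.frame(subject_id = ids, sex = rep("F", n))),
    "single level"
  )
})

test_that("independent covariates reject near the nominal 1% rate", {
  set.seed(508)
  hits <- replicate(400, {
    n <- 80
    ids <- sprintf("s%02d", 1:n)
    sim <- make_sim(runif(n, 0.2, 0.9), ids = ids)
    covs <- data.frame(subject_id = ids, x = rnorm(n))
    covariate_screen(sim, covs, alpha = 0.01)$significant
  })
  # 95% binomial interval around 0.01 with 400 draws
  expect_gte(mean(hits), 0.0)
  expect_lte(mean(hits), 0.01 + 2.576 * sqrt(0.01 * 0.99 / 400))
})
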