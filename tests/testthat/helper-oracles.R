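# Independent oracles, written as plain loops so they share no code path
# with the implementation they check.

# Two-way crossed ANOVA (objects x 2 raters, one observation per cell),
# sums of squares by explicit looping, then the ICC(A,1) ratio.
icc_a1_oracle <- function(x, y) {
  n <- length(x)
  k <- 2
  cells <- cbind(x, y)
  grand <- mean(cells)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(cells[i, ]) - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(cells[, j]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) ss_tot <- ss_tot + (cells[i, j] - grand)^2
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  unname((msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)))
}

# OLS via the normal equations, no lm().
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  list(beta = drop(beta), vcov = sigma2 * solve(XtX), df = df)
}

# Mean z per network cell by brute-force edge enumeration.
network_cells_oracle <- function(R_z, net_labels, networks) {
  K <- length(networks)
  out <- matrix(NA_real_, K, K, dimnames = list(networks, networks))
  for (a in seq_len(K)) {
    for (b in a:K) {
      ia <- which(net_labels == networks[a])
      ib <- which(net_labels == networks[b])
      vals <- c()
      for (i in ia) for (j in ib) {
        if (i < j) vals <- c(vals, R_z[i, j])
      }
      out[a, b] <- out[b, a] <- mean(vals)
    }
  }
  out
}

# small default cohort used across tests (cheap: 12 subjects, 400 frames)
tiny_cohort <- function(seed = 42, n_subjects = 12, T = 400, eta = 0.2) {
  simulate_cohort(n_subjects = n_subjects, T = T, eta = eta, seed = seed)
}

censored_edges <- function(cohort, rois = NULL) {
  scans <- lapply(cohort$scans, censor_and_concatenate)
  lapply(scans, correlation_edges, rois = rois)
}
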