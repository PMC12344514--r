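#' Project a symmetric matrix to the nearest correlation matrix
#'
#' Eigenvalue clipping at a small floor followed by diagonal
#' renormalization: eigenvalues below `floor` are raised to it, the matrix
#' is reconstructed, and rows/columns are rescaled to unit diagonal. Cheap
#' and structure-preserving for mild indefiniteness.
#'
#' @param A symmetric matrix with unit diagonal (approximately).
#' @param floor eigenvalue floor (default 1e-8).
#' @return a valid correlation matrix.
#' @export
nearest_correlation <- function(A, floor = 1e-8) {
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  B <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(B))
  out <- B / tcrossprod(d)
  diag(out) <- 1
  out
}

#' Block-structured group correlation matrix
#'
#' Builds the block analogue of canonical intrinsic networks: ROIs in the
#' same network correlate at `within_r`, ROIs in different networks at the
#' corresponding entry of `between_r`, then the matrix is repaired to the
#' nearest correlation matrix by eigenvalue clipping. If the repair moves
#' any entry by more than 0.05 the requested structure is deemed
#' non-repairable and an error identifies the offending blocks.
#'
#' @param network_sizes positive integer vector, ROIs per network.
#' @param within_r within-network correlation, |r| < 1 (scalar or one per
#'   network).
#' @param between_r between-network correlation, |r| < 1 (scalar or K x K
#'   matrix).
#' @return ROI x ROI correlation matrix with `attr(, "network_sizes")`.
#' @export
make_group_structure <- function(network_sizes, within_r, between_r = 0) {
  stopifnot(all(network_sizes >= 1), all(network_sizes == round(network_sizes)))
  K <- length(network_sizes)
  if (length(within_r) == 1L) within_r <- rep(within_r, K)
  stopifnot(length(within_r) == K, all(abs(within_r) < 1))
  if (length(between_r) == 1L) between_r <- matrix(between_r, K, K)
  between_r <- as.matrix(between_r)
  stopifnot(nrow(between_r) == K, ncol(between_r) == K, all(abs(between_r) < 1))
  between_r <- (between_r + t(between_r)) / 2

  n <- sum(network_sizes)
  block <- rep(seq_len(K), network_sizes)
  A <- between_r[block, block]
  for (k in seq_len(K)) {
    idx <- which(block == k)
    A[idx, idx] <- within_r[k]
  }
  diag(A) <- 1
  R <- nearest_correlation(A)
  delta <- abs(R - A)
  if (max(delta) > 0.05) {
    w <- which(delta == max(delta), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "requested block structure is not repairable to a correlation matrix: projection moved entry (%d, %d) [networks %d-%d] by %.3f",
      w[1], w[2], block[w[1]], block[w[2]], max(delta)
    ))
  }
  attr(R, "network_sizes") <- network_sizes
  R
}

#' Random correlation matrix
#'
#' Normalized random Gaussian factor construction: W is n x n iid standard
#' normal, A = W W', returned as cov2cor(A). Full support over correlation
#' matrices, seedable through the R RNG.
#'
#' @param n dimension.
#' @return n x n correlation matrix.
#' @export
random_correlation <- function(n) {
  W <- matrix(stats::rnorm(n * n), n, n)
  stats::cov2cor(tcrossprod(W))
}

#' Draw one subject's true correlation matrix
#'
#' Convex mixture of the group structure and an independent random
#' correlation matrix: (1 - eta) * group_R + eta * Q_i, projected back to a
#' correlation matrix (a convex mixture of correlation matrices is already
#' one; projection only cleans numerical noise). eta = 0 returns `group_R`
#' exactly; eta = 1 ignores the group structure entirely.
#'
#' @param group_R group correlation matrix.
#' @param eta heterogeneity in \[0, 1\].
#' @return correlation matrix of the same dimension.
#' @export
sample_subject_matrix <- function(group_R, eta) {
  stopifnot(is.numeric(eta), length(eta) == 1L, eta >= 0, eta <= 1)
  if (eta == 0) return(group_R)
  Q <- random_correlation(nrow(group_R))
  nearest_correlation((1 - eta) * group_R + eta * Q)
}

#' Simulate a parcellated scan with a motion trace
#'
#' Frames are iid draws from a multivariate normal with covariance `R` plus
#' a per-ROI positive mean offset (so tSnR is finite and positive). The FD
#' trace is a lognormal baseline capped below the censoring threshold, with
#' spikes injected at `round(censor_fraction * T)` randomly chosen frames
#' so that approximately that fraction of frames exceeds the threshold.
#' The spiked frames' signal is NOT corrupted; the trace exists to exercise
#' the censoring path.
#'
#' @param R correlation (covariance) matrix; must be positive definite.
#' @param T frame count (>= 2 x ROI count recommended).
#' @param censor_fraction fraction of frames to push above the FD
#'   threshold, in \[0, 1).
#' @param tr repetition time in seconds (default 0.8).
#' @param fd_threshold censoring threshold in mm (default 0.10).
#' @param mean_offset per-ROI positive mean (scalar or vector; default 100).
#' @return a [subject_scan()] (column names from `colnames(R)` if set).
#' @export
sample_timeseries <- function(R, T, censor_fraction = 0, tr = 0.8,
                              fd_threshold = 0.10, mean_offset = 100) {
  stopifnot(censor_fraction >= 0, censor_fraction < 1, T >= 2)
  n <- nrow(R)
  L <- tryCatch(chol(R), error = function(e) {
    stop("R is not positive definite: ", conditionMessage(e))
  })
  X <- matrix(stats::rnorm(T * n), T, n) %*% L
  X <- sweep(X, 2L, rep_len(mean_offset, n), `+`)
  colnames(X) <- colnames(R)
  fd <- pmin(stats::rlnorm(T, meanlog = log(0.04), sdlog = 0.4), fd_threshold)
  n_spike <- round(censor_fraction * T)
  if (n_spike > 0) {
    at <- sample.int(T, n_spike)
    fd[at] <- fd_threshold * (1 + stats::rlnorm(n_spike, meanlog = log(0.5), sdlog = 0.5))
  }
  subject_scan(X, fd, tr)
}

#' Outcome parameters of the generative brain-behavior model
#'
#' The synthetic outcome for subject i with edge features z_i and true group
#' similarity s_i is
#'
#'   y_i = beta0 + (c + d * s_i) * (w . z_i) + eps_i,  eps_i ~ N(0, sigma^2)
#'
#' Signal is multiplicatively attenuated for subjects less similar to the
#' group: d > 0 encodes the hypothesis that higher group similarity yields
#' stronger predicted-observed coupling; d = 0 encodes the null (no
#' moderation).
#'
#' @param beta0 intercept.
#' @param w edge-weight vector (aligned to the feature enumeration).
#' @param c baseline coupling (signal multiplier at s = 0).
#' @param d attenuation slope on similarity (>= 0).
#' @param sigma residual SD (> 0 unless exactly zero noise is wanted).
#' @export
outcome_params <- function(beta0 = 2, w, c = 0.5, d = 1, sigma = 1) {
  stopifnot(d >= 0, sigma >= 0)
  structure(list(beta0 = beta0, w = as.numeric(w), c = c, d = d, sigma = sigma),
            class = "outcome_params")
}

#' Simulate behavioral outcomes from edge features and similarities
#'
#' @param edge_features subjects x edge matrix of Fisher-z features.
#' @param similarities per-subject true similarity s_i in \[0, 1\].
#' @param params an [outcome_params()].
#' @return data frame with `subject_id` and `outcome`.
#' @export
sample_outcomes <- function(edge_features, similarities, params) {
  edge_features <- as.matrix(edge_features)
  stopifnot(inherits(params, "outcome_params"))
  if (length(params$w) != ncol(edge_features)) {
    stop(
      "weight length (", length(params$w), ") does not match feature count (",
      ncol(edge_features), ")"
    )
  }
  S <- nrow(edge_features)
  stopifnot(length(similarities) == S)
  signal <- drop(edge_features %*% params$w)
  y <- params$beta0 + (params$c + params$d * similarities) * signal +
    stats::rnorm(S, 0, params$sigma)
  ids <- rownames(edge_features)
  if (is.null(ids)) ids <- sprintf("sub-%03d", seq_len(S))
  data.frame(subject_id = ids, outcome = y, stringsAsFactors = FALSE)
}

#' Nine-subject homogeneous / heterogeneous correlation fixtures
#'
#' Homogeneous mode: one base correlation matrix, each subject gets an
#' independent uniform jitter on \[-0.15, +0.15\] per edge (so every edge
#' spans at most a 0.30 range across subjects before PSD projection).
#' Heterogeneous mode: fully independent random correlation matrices per
#' subject. The pre-projection matrices are kept in `attr(, "raw")`.
#'
#' @param mode `"homogeneous"` or `"heterogeneous"`.
#' @param n_subjects number of subjects (default 9).
#' @param n_rois matrix dimension.
#' @return list of `n_subjects` correlation matrices.
#' @export
make_heterogeneity_fixture <- function(mode = c("homogeneous", "heterogeneous"),
                             n_subjects = 9, n_rois = 12) {
  mode <- match.arg(mode)
  if (mode == "heterogeneous") {
    mats <- lapply(seq_len(n_subjects), function(i) random_correlation(n_rois))
    attr(mats, "raw") <- mats
    return(mats)
  }
  base <- random_correlation(n_rois)
  raw <- lapply(seq_len(n_subjects), function(i) {
    jit <- matrix(0, n_rois, n_rois)
    jit[upper.tri(jit)] <- stats::runif(n_rois * (n_rois - 1) / 2, -0.15, 0.15)
    jit <- jit + t(jit)
    M <- base + jit
    diag(M) <- 1
    M
  })
  mats <- lapply(raw, nearest_correlation)
  attr(mats, "raw") <- raw
  attr(mats, "base") <- base
  mats
}

#' Simulate a full multi-subject cohort with known ground truth
#'
#' Generates per-subject true correlation matrices as mixtures of a
#' block-structured group matrix and independent random matrices, samples
#' time series with motion-like FD traces, and draws outcomes whose
#' predictability attenuates with decreasing group similarity. The default
#' scale (40 ROIs in 4 networks of 10, T = 2000 frames) keeps the edge
#' count (780) well above typical subject counts, mirroring the p >> n
#' regime of real connectome-wide analyses.
#'
#' Per-subject similarity is drawn as s_i ~ Uniform(1 - eta, 1) and the
#' subject's true matrix is the mixture s_i * group_R + (1 - s_i) * Q_i, so
#' eta = 0 gives every subject the group matrix exactly and eta = 1 gives
#' fully idiosyncratic structure.
#'
#' @param n_subjects total subjects (default 120; split into train/test by
#'   alternation downstream).
#' @param network_sizes ROIs per network (default `rep(10, 4)`).
#' @param within_r,between_r block correlations of the group structure.
#' @param eta heterogeneity in \[0, 1\] (default 0.2).
#' @param T frames per subject (default 2000).
#' @param tr repetition time, s (default 0.8).
#' @param censor_fraction fraction of motion-spiked frames (default 0.1).
#' @param params an [outcome_params()]; default plants weight 0.3 on 10
#'   random edges of the true-edge feature space.
#' @param n_signal_edges planted edge count for the default `params`.
#' @param seed integer seed; the cohort is a deterministic function of it.
#' @return a `synthetic_cohort`: list with `scans` (named list of
#'   [subject_scan()]), `parcellation`, `outcomes`, `covariates`, `truth`
#'   (group matrix, eta, per-subject similarities, subject matrices, outcome
#'   params), and `seed`.
#' @export
simulate_cohort <- function(n_subjects = 120, network_sizes = rep(10, 4),
                            within_r = 0.35, between_r = 0.10, eta = 0.2,
                            T = 2000, tr = 0.8, censor_fraction = 0.1,
                            params = NULL, n_signal_edges = 10, seed = 1) {
  set.seed(seed)
  n_rois <- sum(network_sizes)
  K <- length(network_sizes)
  parc <- parcellation(
    sprintf("roi_%03d", seq_len(n_rois)),
    rep(sprintf("net%d", seq_len(K)), network_sizes),
    TRUE
  )
  group_R <- make_group_structure(network_sizes, within_r, between_r)
  dimnames(group_R) <- list(parc$roi_id, parc$roi_id)

  s <- stats::runif(n_subjects, 1 - eta, 1)
  ids <- sprintf("sub-%03d", seq_len(n_subjects))
  mats <- vector("list", n_subjects)
  scans <- vector("list", n_subjects)
  offsets <- stats::runif(n_rois, 80, 120)
  for (i in seq_len(n_subjects)) {
    Ri <- if (s[i] == 1) group_R else {
      M <- nearest_correlation(s[i] * group_R + (1 - s[i]) * random_correlation(n_rois))
      dimnames(M) <- dimnames(group_R)
      M
    }
    mats[[i]] <- Ri
    scans[[i]] <- sample_timeseries(
      Ri, T, censor_fraction = censor_fraction, tr = tr, mean_offset = offsets
    )
  }
  names(mats) <- names(scans) <- ids

  # outcome features: Fisher z of the TRUE subject matrices, so measurement
  # noise enters only through the estimated pipeline
  ei <- edge_index(n_rois)
  Z <- t(vapply(mats, function(M) {
    r <- M[cbind(ei$i, ei$j)]
    atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
  }, numeric(nrow(ei))))
  rownames(Z) <- ids
  if (is.null(params)) {
    w <- numeric(nrow(ei))
    w[sample.int(nrow(ei), n_signal_edges)] <- 0.3
    params <- outcome_params(w = w)
  }
  outcomes <- sample_outcomes(Z, s, params)

  covariates <- data.frame(
    subject_id = ids,
    age = stats::runif(n_subjects, 130, 155), # months
    sex = sample(c("F", "M"), n_subjects, replace = TRUE),
    site = sample(sprintf("site%02d", 1:4), n_subjects, replace = TRUE),
    mean_fd = vapply(scans, function(sc) mean(sc$fd), 1.0),
    stringsAsFactors = FALSE
  )

  structure(
    list(
      scans = scans, parcellation = parc, outcomes = outcomes,
      covariates = covariates,
      truth = list(
        group_correlation = group_R, heterogeneity = eta,
        subject_similarities = stats::setNames(s, ids),
        subject_matrices = mats, outcome_params = params
      ),
      seed = seed
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d subjects, %d ROIs, %d frames; eta = %.2f (seed %d)\n",
    length(x$scans), ncol(x$scans[[1]]$series), nrow(x$scans[[1]]$series),
    x$truth$heterogeneity, x$seed
  ))
  invisible(x)
}

#' Lightweight moderation cohort (scores + similarities only)
#'
#' Draws iid standard-normal edge features, similarities s_i ~ Uniform(0.3,
#' 1) (a plausible observed ICC range), outcomes from the attenuation model,
#' and the oracle predicted score w . z. Used for calibration/power studies
#' of the moderation stage without re-fitting an elastic net per replicate.
#'
#' @param n subjects (default 200).
#' @param p feature count (default 10).
#' @param params an [outcome_params()]; default weight 0.3 on all p edges.
#' @return list with `scores` (a score table: subject_id, observed,
#'   predicted), `similarity` (a `similarity_table`-shaped data frame) and
#'   the generating `params`.
#' @export
simulate_moderation_cohort <- function(n = 200, p = 10, params = NULL) {
  Z <- matrix(stats::rnorm(n * p), n, p)
  s <- stats::runif(n, 0.3, 1)
  if (is.null(params)) params <- outcome_params(w = rep(0.3, p))
  out <- sample_outcomes(Z, s, params)
  scores <- data.frame(
    subject_id = out$subject_id, observed = out$outcome,
    predicted = drop(Z %*% params$w), stringsAsFactors = FALSE
  )
  sim <- data.frame(
    subject_id = out$subject_id, icc = s, label = classify_icc(pmin(s, 1)),
    set = "train", stringsAsFactors = FALSE
  )
  class(sim) <- c("similarity_table", "data.frame")
  list(scores = scores, similarity = sim, params = params)
}
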