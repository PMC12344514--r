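#' ICC(A,1): two-way random effects, absolute agreement, single rater
#'
#' The two "raters" are the group model and one individual; the "objects"
#' are connectivity features. With k = 2 raters and n objects, the two-way
#' crossed layout (one observation per cell) gives mean squares for objects
#' (MSR, df n-1), raters (MSC, df k-1) and residual (MSE, df (n-1)(k-1)),
#' and
#'
#'   ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))
#'
#' Absolute agreement penalizes both rank-order and mean-level differences,
#' so adding a constant to one sequence lowers the ICC. Values can be
#' negative; they are reported as computed (no truncation at zero).
#'
#' @param x,y numeric sequences of equal length n >= 3; at least one must be
#'   non-constant.
#' @return an `icc_result`: list with `value`, `n_objects`, and mean squares
#'   `msr`, `msc`, `mse`.
#' @export
icc_a1 <- function(x, y) {
  if (length(x) != length(y)) {
    stop("length mismatch: ", length(x), " vs ", length(y))
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 objects")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    stop("both sequences constant: ICC undefined")
  }
  k <- 2L
  gm <- (sum(x) + sum(y)) / (n * k)
  row_means <- (x + y) / 2
  ssr <- k * sum((row_means - gm)^2)
  ssc <- n * ((mean(x) - gm)^2 + (mean(y) - gm)^2)
  sst <- sum((x - gm)^2) + sum((y - gm)^2)
  sse <- max(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  value <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  structure(
    list(value = value, n_objects = n, msr = msr, msc = msc, mse = mse),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC(A,1) = %.4f over %d features (MSR %.4g, MSC %.4g, MSE %.4g)\n",
    x$value, x$n_objects, x$msr, x$msc, x$mse
  ))
  invisible(x)
}

#' Benchmark classification of group-to-individual ICC
#'
#' poor: ICC < .50; moderate: .50 <= ICC < .75; good: .75 <= ICC < .90;
#' excellent: ICC >= .90. Lower bounds are closed.
#'
#' @param value numeric vector of ICC values (<= 1).
#' @return character vector of labels.
#' @export
classify_icc <- function(value) {
  stopifnot(all(value <= 1 + 1e-12))
  as.character(cut(
    value,
    breaks = c(-Inf, 0.50, 0.75, 0.90, Inf),
    labels = c("poor", "moderate", "good", "excellent"),
    right = FALSE
  ))
}

extract_values <- function(obj) {
  if (inherits(obj, c("edge_vector", "network_matrix"))) return(obj$values)
  if (is.numeric(obj)) return(as.numeric(obj))
  stop("cannot extract connectivity values from class ", paste(class(obj), collapse = "/"))
}

#' Per-subject similarity to the group model
#'
#' Computes one ICC(A,1) between the (training-set) group model and each
#' subject's connectivity representation. Test-set subjects are always
#' compared against the training group model.
#'
#' @param group a `group_model` (or bare numeric referent).
#' @param subjects named list of per-subject `edge_vector` /
#'   `network_matrix` objects restricted to the group model's enumeration.
#' @param set_label `"train"` or `"test"`.
#' @return a `similarity_table` data frame with columns `subject_id`, `icc`,
#'   `label`, `set`; summary statistics in `attr(, "summary")`.
#' @export
cohort_similarity <- function(group, subjects, set_label = "train") {
  ref <- if (inherits(group, "group_model")) group$referent else group
  gvals <- extract_values(ref)
  if (inherits(ref, "edge_vector")) {
    ok <- vapply(subjects, function(s) same_enumeration(s, ref), TRUE)
    if (!all(ok)) stop("subject edge enumeration mismatch with group model")
  } else if (inherits(ref, "network_matrix")) {
    ok <- vapply(subjects, function(s) identical(s$networks, ref$networks), TRUE)
    if (!all(ok)) stop("subject network enumeration mismatch with group model")
  }
  icc <- vapply(subjects, function(s) icc_a1(gvals, extract_values(s))$value, 1.0)
  ids <- names(subjects)
  if (is.null(ids)) ids <- sprintf("sub-%03d", seq_along(subjects))
  out <- data.frame(
    subject_id = ids, icc = unname(icc), label = classify_icc(icc),
    set = set_label, stringsAsFactors = FALSE
  )
  attr(out, "summary") <- c(
    mean = mean(icc), sd = stats::sd(icc), min = min(icc), max = max(icc)
  )
  class(out) <- c("similarity_table", "data.frame")
  out
}

#' Shuffled-network-assignment permutation null
#'
#' Per iteration, the ROI-to-network labels are permuted uniformly at
#' random (network sizes preserved; one shared permutation for the group
#' model and every subject), each subject's network matrix and the training
#' group model are recomputed under the shuffled labels, all subject ICCs
#' are computed against that shuffled group model, and the sample mean ICC
#' is recorded. A shuffled mean well below the true-structure mean indicates
#' that high network-level similarity reflects real network structure
#' rather than aggregation.
#'
#' @param subject_edge_vectors named list of full-ROI `edge_vector`s (the
#'   training subjects).
#' @param parc a [parcellation()].
#' @param networks network labels to aggregate over.
#' @param n_iter number of shuffles (default 500).
#' @param seed optional integer seed.
#' @param perms optional list of explicit permutations (integer vectors over
#'   the analysed ROIs) overriding random shuffling; used for testing.
#' @return a `permutation_null_result`: list with `n_iter`,
#'   `iteration_means`, `overall_mean`, `sd_across_iterations`,
#'   `max_iteration_mean`, `seed`.
#' @export
shuffled_network_null <- function(subject_edge_vectors, parc,
                                  networks = networks_of(parc, association_only = TRUE),
                                  n_iter = 500, seed = NULL, perms = NULL) {
  stopifnot(length(subject_edge_vectors) >= 2L, n_iter >= 1L)
  v1 <- subject_edge_vectors[[1]]
  ok <- vapply(subject_edge_vectors, same_enumeration, TRUE, b = v1)
  if (!all(ok)) stop("subjects disagree on edge enumeration")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(perms)) n_iter <- length(perms)

  net_of <- parc$network[match(v1$roi_ids, parc$roi_id)]
  in_scope <- which(net_of %in% networks)
  labels0 <- match(net_of[in_scope], networks) # labels over analysed ROIs
  K <- length(networks)
  n_cells <- K * (K + 1) / 2

  # edges with both endpoints in scope, re-indexed to the analysed ROI set
  pos <- match(seq_along(v1$roi_ids), in_scope) # NA if out of scope
  ei <- pos[v1$edges$i]
  ej <- pos[v1$edges$j]
  keep <- !is.na(ei) & !is.na(ej)
  ei <- ei[keep]
  ej <- ej[keep]
  Z <- vapply(subject_edge_vectors, `[[`, numeric(length(v1$values)), "values")
  Z <- Z[keep, , drop = FALSE] # edges x subjects

  iteration_means <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    lab <- if (is.null(perms)) {
      labels0[sample.int(length(labels0))]
    } else {
      labels0[perms[[it]]]
    }
    a <- pmin(lab[ei], lab[ej])
    b <- pmax(lab[ei], lab[ej])
    cell <- network_cell_id(a, b, K)
    cnts <- tabulate(cell, nbins = n_cells)
    if (any(cnts == 0)) stop("a shuffled network cell has no edges")
    sums <- rowsum(Z, cell) # n_cells x subjects
    cells <- sums / cnts
    gref <- rowMeans(cells)
    iccs <- apply(cells, 2L, function(v) icc_a1(gref, v)$value)
    iteration_means[it] <- mean(iccs)
  }
  structure(
    list(
      n_iter = n_iter, iteration_means = iteration_means,
      overall_mean = mean(iteration_means),
      sd_across_iterations = stats::sd(iteration_means),
      max_iteration_mean = max(iteration_means),
      seed = seed
    ),
    class = "permutation_null_result"
  )
}

#' @export
print.permutation_null_result <- function(x, ...) {
  cat(sprintf(
    "Shuffled-network null: %d iterations; mean ICC %.3f (SD %.3f, max %.3f)\n",
    x$n_iter, x$overall_mean,
    ifelse(is.na(x$sd_across_iterations), 0, x$sd_across_iterations),
    x$max_iteration_mean
  ))
  invisible(x)
}
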