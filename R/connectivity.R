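#' Pearson correlations per ROI pair, Fisher z-transformed
#'
#' Computes the Pearson correlation of every ROI pair over the retained
#' frames and applies the Fisher z transform (atanh). Correlations are
#' clamped to +/-(1 - 1e-12) before atanh so duplicated or degenerate ROI
#' pairs stay finite. Edge enumeration follows [edge_index()] over the
#' requested ROI subset in parcellation order.
#'
#' @param scan a `subject_scan` with >= 3 frames.
#' @param rois optional character vector of ROI ids to restrict to (order is
#'   taken from the scan's columns, which follow the parcellation).
#' @return an `edge_vector`: list with `roi_ids`, `edges` (i, j indices into
#'   `roi_ids`), `values` (Fisher z per edge), `scale = "z"`.
#' @export
correlation_edges <- function(scan, rois = NULL) {
  stopifnot(inherits(scan, "subject_scan"))
  x <- scan$series
  if (!is.null(rois)) {
    missing <- setdiff(rois, colnames(x))
    if (length(missing)) stop("ROIs absent from scan: ", paste(missing, collapse = ", "))
    x <- x[, colnames(x)[colnames(x) %in% rois], drop = FALSE]
  }
  if (nrow(x) < 3L) stop("need at least 3 retained frames to correlate")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    stop("constant ROI series: ", paste(bad, collapse = ", "))
  }
  R <- stats::cor(x)
  ei <- edge_index(ncol(x))
  r <- R[cbind(ei$i, ei$j)]
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  edge_vector(colnames(x), ei, atanh(r))
}

#' Construct an edge vector
#'
#' @param roi_ids ordered ROI identifiers
#' @param edges data frame with columns `i`, `j` (indices into `roi_ids`,
#'   i < j); defaults to the full canonical enumeration
#' @param values numeric Fisher-z values, one per edge
#' @param scale `"z"` (default) or `"r"`
#' @export
edge_vector <- function(roi_ids, edges = edge_index(length(roi_ids)), values,
                        scale = "z") {
  stopifnot(
    nrow(edges) == length(values), all(edges$i < edges$j),
    all(is.finite(values)), scale %in% c("r", "z")
  )
  structure(
    list(
      roi_ids = as.character(roi_ids), edges = edges,
      values = as.numeric(values), scale = scale
    ),
    class = "edge_vector"
  )
}

#' @export
print.edge_vector <- function(x, ...) {
  cat(
    "Edge vector:", length(x$values), "edges over", length(x$roi_ids),
    "ROIs (scale:", paste0(x$scale, ")\n")
  )
  invisible(x)
}

same_enumeration <- function(a, b) {
  identical(a$roi_ids, b$roi_ids) && identical(a$edges, b$edges)
}

#' Select high-between-subject-variance edges on training data
#'
#' Ranks edges by their sample variance (n-1 denominator) across training
#' subjects and retains the `ceiling(p * E)` edges with the largest
#' variance. Ties are broken by canonical edge order (the earlier edge
#' wins). The selection is defined on training subjects only and is then
#' applied unchanged to test subjects.
#'
#' @param training_vectors list of >= 2 `edge_vector`s sharing enumeration.
#' @param p fraction of edges to retain, in (0, 1]; default 0.10.
#' @return a `feature_set`: list with `indices` (into the candidate edge
#'   enumeration, ascending), `roi_ids`, `edges`, `variances` (of the
#'   selected edges), and the selection `rule`.
#' @export
select_high_variance_edges <- function(training_vectors, p = 0.10) {
  if (!(is.numeric(p) && length(p) == 1L && p > 0 && p <= 1)) {
    stop("p must lie in (0, 1]")
  }
  stopifnot(length(training_vectors) >= 2L)
  v1 <- training_vectors[[1]]
  ok <- vapply(training_vectors, same_enumeration, TRUE, b = v1)
  if (!all(ok)) stop("training vectors disagree on edge enumeration")
  Z <- vapply(training_vectors, `[[`, numeric(length(v1$values)), "values")
  mu <- rowMeans(Z)
  vars <- rowSums((Z - mu)^2) / (ncol(Z) - 1L)
  m <- n_selected_edges(length(vars), p)
  ord <- order(-vars, seq_along(vars))
  idx <- sort(ord[seq_len(m)])
  structure(
    list(
      indices = idx, roi_ids = v1$roi_ids, edges = v1$edges[idx, , drop = FALSE],
      variances = vars[idx],
      rule = list(variance_fraction = p, n_candidates = length(vars))
    ),
    class = "feature_set"
  )
}

#' Number of edges retained at fraction p (ceiling rule)
#' @param n_edges candidate edge count
#' @param p retained fraction in (0, 1]
#' @export
n_selected_edges <- function(n_edges, p) {
  as.integer(ceiling(p * n_edges))
}

#' Restrict an edge vector to a feature set
#' @param ev an `edge_vector` on the feature set's enumeration
#' @param fs a `feature_set` from [select_high_variance_edges()]
#' @return an `edge_vector` over the selected edges
#' @export
restrict_edges <- function(ev, fs) {
  stopifnot(inherits(ev, "edge_vector"), inherits(fs, "feature_set"))
  if (!identical(ev$roi_ids, fs$roi_ids)) stop("edge enumeration mismatch")
  edge_vector(ev$roi_ids, fs$edges, ev$values[fs$indices], ev$scale)
}

#' Aggregate an edge vector to a network-by-network matrix
#'
#' Cell (A, A) is the mean z over all edges within network A; cell (A, B)
#' is the mean z over all edges between A and B. For K networks there are
#' K(K+1)/2 distinct cells. Cells are stored both as a symmetric K x K
#' matrix and as a canonical value vector (row-major upper triangle with
#' diagonal).
#'
#' @param ev an `edge_vector` over the full ROI set (all pairwise edges of
#'   its ROIs).
#' @param parc a [parcellation()] covering the edge vector's ROIs.
#' @param networks ordered network labels to aggregate over (each with >= 2
#'   ROIs in the edge vector).
#' @return a `network_matrix`: list with `networks`, `cells` (K x K),
#'   `values` (length K(K+1)/2), `scale`.
#' @export
network_matrix <- function(ev, parc,
                           networks = networks_of(parc, association_only = TRUE)) {
  stopifnot(inherits(ev, "edge_vector"))
  net_of <- parc$network[match(ev$roi_ids, parc$roi_id)]
  if (anyNA(net_of)) stop("edge vector contains ROIs absent from the parcellation")
  counts <- table(factor(net_of, levels = networks))
  if (any(counts < 2L)) {
    stop(
      "networks with fewer than 2 ROIs: ",
      paste(names(counts)[counts < 2L], collapse = ", ")
    )
  }
  ni <- match(net_of[ev$edges$i], networks)
  nj <- match(net_of[ev$edges$j], networks)
  keep <- !is.na(ni) & !is.na(nj)
  a <- pmin(ni[keep], nj[keep])
  b <- pmax(ni[keep], nj[keep])
  K <- length(networks)
  # canonical row-major upper-triangle-with-diagonal cell id
  cell <- network_cell_id(a, b, K)
  sums <- rowsum(ev$values[keep], cell)
  cnts <- tabulate(cell, nbins = K * (K + 1) / 2)
  stopifnot(all(cnts[as.integer(rownames(sums))] > 0))
  values <- rep(NA_real_, K * (K + 1) / 2)
  values[as.integer(rownames(sums))] <- sums[, 1] / cnts[as.integer(rownames(sums))]
  if (anyNA(values)) stop("some network cells have no edges")
  cells <- matrix(0, K, K, dimnames = list(networks, networks))
  ci <- network_cell_index(K)
  cells[cbind(ci$a, ci$b)] <- values
  cells[cbind(ci$b, ci$a)] <- values
  structure(
    list(networks = networks, cells = cells, values = values, scale = ev$scale),
    class = "network_matrix"
  )
}

# row-major upper-triangle-with-diagonal enumeration for K networks:
# (1,1),(1,2),...,(1,K),(2,2),...
network_cell_index <- function(K) {
  counts <- K:1
  data.frame(
    a = rep(seq_len(K), counts),
    b = sequence(counts, from = seq_len(K))
  )
}

network_cell_id <- function(a, b, K) {
  # offset of row a = sum_{r<a} (K - r + 1)
  offset <- (a - 1L) * K - (a - 1L) * (a - 2L) / 2
  as.integer(offset + (b - a + 1L))
}

#' @export
print.network_matrix <- function(x, ...) {
  cat("Network matrix:", length(x$networks), "networks,",
      length(x$values), "distinct cells (scale:", paste0(x$scale, ")\n"))
  print(round(x$cells, 3))
  invisible(x)
}

#' Training-set group model
#'
#' Element-wise arithmetic mean of per-subject connectivity representations
#' on the Fisher-z scale (no back-transform to r). Accepts a list of
#' `edge_vector`s or of `network_matrix`es sharing enumeration.
#'
#' @param vectors non-empty list of `edge_vector` or `network_matrix`.
#' @return a `group_model`: list with `referent` (same class as the inputs,
#'   values averaged) and `n_train`.
#' @export
group_average <- function(vectors) {
  stopifnot(is.list(vectors), length(vectors) >= 1L)
  v1 <- vectors[[1]]
  if (inherits(v1, "edge_vector")) {
    ok <- vapply(vectors, same_enumeration, TRUE, b = v1)
    if (!all(ok)) stop("edge enumeration mismatch across subjects")
  } else if (inherits(v1, "network_matrix")) {
    ok <- vapply(vectors, function(v) identical(v$networks, v1$networks), TRUE)
    if (!all(ok)) stop("network enumeration mismatch across subjects")
  } else {
    stop("vectors must be edge_vector or network_matrix objects")
  }
  vals <- rowMeans(vapply(vectors, `[[`, numeric(length(v1$values)), "values"))
  ref <- v1
  ref$values <- vals
  if (inherits(v1, "network_matrix")) {
    K <- length(v1$networks)
    ci <- network_cell_index(K)
    ref$cells[cbind(ci$a, ci$b)] <- vals
    ref$cells[cbind(ci$b, ci$a)] <- vals
  }
  structure(list(referent = ref, n_train = length(vectors)), class = "group_model")
}

#' @export
print.group_model <- function(x, ...) {
  cat("Group model over", x$n_train, "training subjects\n")
  print(x$referent)
  invisible(x)
}
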