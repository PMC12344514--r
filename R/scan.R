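#' Construct a subject scan
#'
#' A scan is a frames x ROI matrix of parcellated BOLD signal together with a
#' per-frame filtered framewise-displacement (FD) trace in millimetres and
#' the repetition time in seconds.
#'
#' @param series numeric matrix, frames in rows, ROIs in columns. Column
#'   names, when present, are ROI identifiers and must match the
#'   parcellation order used downstream.
#' @param fd numeric vector of per-frame FD (mm), length `nrow(series)`.
#' @param tr repetition time in seconds per frame (> 0).
#' @return a `subject_scan` object.
#' @export
subject_scan <- function(series, fd, tr = 0.8) {
  series <- as.matrix(series)
  if (!is.numeric(series)) stop("series must be numeric")
  if (length(fd) != nrow(series)) {
    stop("fd length (", length(fd), ") must equal frame count (", nrow(series), ")")
  }
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) stop("tr must be a positive scalar")
  structure(
    list(series = series, fd = as.numeric(fd), tr = tr),
    class = "subject_scan"
  )
}

#' @export
print.subject_scan <- function(x, ...) {
  cat(
    "Subject scan:", nrow(x$series), "frames x", ncol(x$series), "ROIs, TR =",
    x$tr, "s; median FD =", signif(stats::median(x$fd), 3), "mm\n"
  )
  invisible(x)
}

#' Censor high-motion frames and concatenate runs
#'
#' Drops every frame whose filtered FD strictly exceeds `fd_threshold`
#' (frames at exactly the threshold are retained) and concatenates the
#' surviving frames across runs in the given order. Censored frames are
#' removed, not interpolated.
#'
#' @param runs a single `subject_scan` or list of them sharing ROI ordering.
#' @param fd_threshold censoring threshold in mm (default 0.10).
#' @return a single censored, concatenated `subject_scan`.
#' @export
censor_and_concatenate <- function(runs, fd_threshold = 0.10) {
  if (inherits(runs, "subject_scan")) runs <- list(runs)
  stopifnot(length(runs) >= 1L, all(vapply(runs, inherits, TRUE, "subject_scan")))
  nc <- vapply(runs, function(r) ncol(r$series), 1L)
  if (length(unique(nc)) != 1L) stop("runs disagree on ROI count")
  cn <- lapply(runs, function(r) colnames(r$series))
  if (!all(vapply(cn, identical, TRUE, cn[[1]]))) stop("runs disagree on ROI ordering")
  trs <- vapply(runs, function(r) r$tr, 1.0)
  if (length(unique(trs)) != 1L) stop("runs disagree on TR")
  kept <- lapply(runs, function(r) {
    keep <- r$fd <= fd_threshold
    list(series = r$series[keep, , drop = FALSE], fd = r$fd[keep])
  })
  series <- do.call(rbind, lapply(kept, `[[`, "series"))
  fd <- unlist(lapply(kept, `[[`, "fd"), use.names = FALSE)
  if (nrow(series) == 0L) {
    stop("no frames survive censoring at fd_threshold = ", fd_threshold)
  }
  subject_scan(series, fd, trs[[1]])
}

#' Minimum-data inclusion rule
#'
#' A subject is included when the retained (post-censoring) scan time is at
#' least `min_minutes` of data: retained frames x TR >= min_minutes * 60.
#' The boundary is inclusive.
#'
#' @param scan a `subject_scan` (censored or not; frames with
#'   `fd > fd_threshold` are not counted).
#' @param min_minutes required minutes of clean data (default 10).
#' @param fd_threshold censoring threshold in mm (default 0.10).
#' @return logical scalar
#' @export
subject_included <- function(scan, min_minutes = 10, fd_threshold = 0.10) {
  stopifnot(inherits(scan, "subject_scan"))
  retained <- sum(scan$fd <= fd_threshold)
  retained * scan$tr >= min_minutes * 60
}

#' Temporal signal-to-noise ratio per ROI
#'
#' tSnR is the temporal mean of each ROI's series divided by its temporal
#' standard deviation (sample, n-1 denominator).
#'
#' @param scan a `subject_scan` with at least 2 frames.
#' @return named numeric vector, one tSnR per ROI.
#' @export
compute_tsnr <- function(scan) {
  stopifnot(inherits(scan, "subject_scan"))
  x <- scan$series
  if (nrow(x) < 2L) stop("tSnR requires at least 2 frames")
  m <- colMeans(x)
  s <- sqrt(colSums(sweep(x, 2L, m)^2) / (nrow(x) - 1L))
  if (any(s == 0)) {
    bad <- colnames(x)[s == 0]
    if (is.null(bad)) bad <- which(s == 0)
    stop("degenerate (constant) ROI series: ", paste(bad, collapse = ", "))
  }
  out <- m / s
  names(out) <- colnames(x)
  out
}

#' Select ROIs by network membership and training-set tSnR
#'
#' Restricts ROIs to the requested networks, averages tSnR across training
#' subjects per ROI, and drops ROIs whose average tSnR falls more than
#' `sd_k` standard deviations below the grand mean of those ROI-wise
#' averages. The resulting ROI set is computed on training subjects only and
#' reused verbatim for test subjects.
#'
#' @param training_tsnr subjects x ROI numeric matrix of tSnR values; column
#'   names are ROI ids.
#' @param parc a [parcellation()].
#' @param sd_k exclusion threshold in SD units below the mean (default 2).
#' @param networks network labels to retain; default = association-flagged
#'   networks of `parc`.
#' @return character vector of retained ROI ids, in parcellation order.
#' @export
select_rois <- function(training_tsnr, parc, sd_k = 2,
                        networks = networks_of(parc, association_only = TRUE)) {
  training_tsnr <- as.matrix(training_tsnr)
  if (is.null(colnames(training_tsnr))) stop("training_tsnr needs ROI column names")
  keep_net <- parc$roi_id[parc$network %in% networks]
  cand <- intersect(colnames(training_tsnr), keep_net)
  if (length(cand) < 2L) stop("fewer than 2 candidate ROIs in the requested networks")
  roi_mean <- colMeans(training_tsnr[, cand, drop = FALSE])
  thr <- mean(roi_mean) - sd_k * stats::sd(roi_mean)
  kept <- cand[roi_mean >= thr]
  if (length(kept) == 0L) stop("tSnR exclusion removed every ROI")
  # parcellation order is canonical
  parc$roi_id[parc$roi_id %in% kept]
}
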