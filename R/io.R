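#' Write a cohort to plain-text files
#'
#' Layout under `dir`:
#'   parcellation.tsv           roi_id, network, association
#'   outcomes.csv               subject_id, outcome columns
#'   covariates.csv             subject_id, covariate columns
#'   truth.json                 ground truth (when the cohort is synthetic)
#'   timeseries/<id>_run1.tsv   frames x ROIs, header = ROI ids
#'   fd/<id>_run1.tsv           one FD value per line (no header)
#'
#' @param cohort a `synthetic_cohort` (or compatible list).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "fd"), showWarnings = FALSE)
  utils::write.table(
    as.data.frame(cohort$parcellation), file.path(dir, "parcellation.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"), row.names = FALSE)
  if (!is.null(cohort$covariates)) {
    utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
  }
  for (id in names(cohort$scans)) {
    sc <- cohort$scans[[id]]
    utils::write.table(
      sc$series, file.path(dir, "timeseries", paste0(id, "_run1.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    utils::write.table(
      data.frame(fd = sc$fd), file.path(dir, "fd", paste0(id, "_run1.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  if (!is.null(cohort$truth)) {
    truth <- cohort$truth
    jsonlite::write_json(
      list(
        heterogeneity = truth$heterogeneity,
        subject_similarities = as.list(truth$subject_similarities),
        outcome_params = truth$outcome_params[c("beta0", "c", "d", "sigma")],
        tr = cohort$scans[[1]]$tr,
        seed = cohort$seed
      ),
      file.path(dir, "truth.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @param tr repetition time in seconds for the scans (default 0.8; the
#'   time-series files do not carry it).
#' @return a list with `scans`, `parcellation`, `outcomes`, `covariates`.
#' @export
read_cohort <- function(dir, tr = 0.8) {
  ptab <- utils::read.delim(file.path(dir, "parcellation.tsv"), stringsAsFactors = FALSE)
  parc <- parcellation(ptab$roi_id, ptab$network, as.logical(ptab$association))
  outcomes <- utils::read.csv(file.path(dir, "outcomes.csv"), stringsAsFactors = FALSE)
  cov_path <- file.path(dir, "covariates.csv")
  covariates <- if (file.exists(cov_path)) {
    utils::read.csv(cov_path, stringsAsFactors = FALSE)
  }
  ts_files <- sort(list.files(file.path(dir, "timeseries"), full.names = TRUE))
  ids <- unique(sub("_run[0-9]+\\.tsv$", "", basename(ts_files)))
  scans <- lapply(ids, function(id) {
    runs <- sort(list.files(
      file.path(dir, "timeseries"),
      pattern = paste0("^", id, "_run[0-9]+\\.tsv$"), full.names = TRUE
    ))
    lapply(runs, function(f) {
      series <- as.matrix(utils::read.delim(f, check.names = FALSE))
      fdf <- file.path(dir, "fd", basename(f))
      fd <- utils::read.delim(fdf)$fd
      subject_scan(series, fd, tr)
    })
  })
  names(scans) <- ids
  list(scans = scans, parcellation = parc, outcomes = outcomes, covariates = covariates)
}
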