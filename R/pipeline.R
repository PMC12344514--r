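#' Pipeline configuration
#'
#' Collects every stage parameter in one record; defaults reproduce the
#' primary analysis settings (FD censoring at 0.10 mm, at least 10 minutes
#' of clean data, tSnR exclusion at 2 SD below the mean, top 10% variance
#' edges, 10-fold cross-validated elastic net, 500 shuffling iterations,
#' alpha = .05 with a Bonferroni-style .01 covariate screen).
#'
#' @param mode `"synthetic"` (simulate a cohort) or `"files"` (read one
#'   written by [write_cohort()] from `input_dir`).
#' @param fd_threshold censoring threshold, mm.
#' @param min_minutes minimum clean minutes for inclusion.
#' @param tr repetition time, s.
#' @param tsnr_sd_k tSnR exclusion threshold in SD units (1 or 2).
#' @param variance_fraction fraction of edges retained, (0, 1].
#' @param networks network labels for aggregation; `NULL` = association
#'   networks of the parcellation (minus any `subcortical` label).
#' @param alpha_grid elastic-net mixing grid.
#' @param n_folds CV folds.
#' @param n_permutations shuffled-network iterations.
#' @param alpha significance level for moderation and JN regions.
#' @param bonferroni_alpha covariate-screen threshold.
#' @param seed master seed; all stage seeds derive from it.
#' @param sim list of [simulate_cohort()] arguments for synthetic mode.
#' @param input_dir cohort directory for files mode.
#' @param out optional output directory; stage tables and the report are
#'   written there as CSV/JSON.
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "files"), fd_threshold = 0.10,
                       min_minutes = 10, tr = 0.8, tsnr_sd_k = 2,
                       variance_fraction = 0.10, networks = NULL,
                       alpha_grid = seq(0.1, 1, by = 0.1), n_folds = 10,
                       n_permutations = 500, alpha = 0.05,
                       bonferroni_alpha = 0.01, seed = 1, sim = list(),
                       input_dir = NULL, out = NULL) {
  structure(
    list(
      mode = match.arg(mode), fd_threshold = fd_threshold,
      min_minutes = min_minutes, tr = tr, tsnr_sd_k = tsnr_sd_k,
      variance_fraction = variance_fraction, networks = networks,
      alpha_grid = alpha_grid, n_folds = n_folds,
      n_permutations = n_permutations, alpha = alpha,
      bonferroni_alpha = bonferroni_alpha, seed = seed, sim = sim,
      input_dir = input_dir, out = out
    ),
    class = "run_config"
  )
}

#' Validate a configuration without running it
#'
#' @param config a [run_config()].
#' @return data frame of findings with columns `level` ("error"/"warning")
#'   and `message`; zero rows means clean.
#' @export
validate_config <- function(config) {
  f <- list()
  add <- function(level, msg) f[[length(f) + 1L]] <<- data.frame(level = level, message = msg)
  if (!(config$variance_fraction > 0 && config$variance_fraction <= 1)) {
    add("error", "variance_fraction must lie in (0, 1]")
  }
  if (config$fd_threshold <= 0) add("error", "fd_threshold must be positive")
  if (config$n_folds < 2) add("error", "n_folds must be at least 2")
  if (config$mode == "synthetic") {
    n_sub <- config$sim$n_subjects %||% formals(simulate_cohort)$n_subjects
    if (config$n_folds > ceiling(n_sub / 2)) {
      add("error", "n_folds exceeds the training-set subject count")
    }
  }
  if (config$mode == "files" &&
      (is.null(config$input_dir) || !dir.exists(config$input_dir))) {
    add("error", "files mode requires an existing input_dir")
  }
  if (config$n_permutations < 100) {
    add("warning", "n_permutations < 100: null summaries will be unstable")
  }
  if (!config$tsnr_sd_k %in% c(1, 2)) {
    add("warning", "tsnr_sd_k outside the standard {1, 2} settings")
  }
  if (length(f)) do.call(rbind, f) else {
    data.frame(level = character(0), message = character(0))
  }
}

derive_seeds <- function(master) {
  set.seed(master)
  stats::setNames(
    sample.int(.Machine$integer.max, 4L),
    c("simulate", "folds", "permutation", "misc")
  )
}

#' Run the full heterogeneity analysis end-to-end
#'
#' Subject inclusion -> censoring/concatenation -> training-set tSnR ROI
#' selection -> per-subject Fisher-z edges -> training-set variance-based
#' feature selection -> group model -> train and test similarity (ROI and
#' network level) -> shuffled-network permutation null -> per-outcome
#' elastic net -> predicted x ICC moderation with Johnson-Neyman regions ->
#' covariate screen. Subjects are assigned alternately (by position) to
#' training and testing sets.
#'
#' @param config a [run_config()].
#' @return a `run_report` list; also writes stage tables under `config$out`
#'   when set.
#' @export
run_pipeline <- function(config = run_config()) {
  findings <- validate_config(config)
  if (any(findings$level == "error")) {
    stop("invalid config: ", paste(findings$message[findings$level == "error"], collapse = "; "))
  }
  seeds <- derive_seeds(config$seed)

  cohort <- if (config$mode == "synthetic") {
    do.call(simulate_cohort, c(config$sim, list(seed = seeds[["simulate"]], tr = config$tr)))
  } else {
    read_cohort(config$input_dir, tr = config$tr)
  }
  parc <- cohort$parcellation

  # --- censoring + inclusion ------------------------------------------------
  scans <- lapply(cohort$scans, censor_and_concatenate, fd_threshold = config$fd_threshold)
  included <- vapply(
    scans, subject_included, TRUE,
    min_minutes = config$min_minutes, fd_threshold = config$fd_threshold
  )
  scans <- scans[included]
  if (length(scans) < 2 * config$n_folds) {
    stop("stage inclusion: too few subjects retained (", length(scans), ")")
  }
  ids <- names(scans)
  train_ids <- ids[seq_along(ids) %% 2L == 1L]
  test_ids <- ids[seq_along(ids) %% 2L == 0L]

  networks <- config$networks %||%
    setdiff(networks_of(parc, association_only = TRUE), "subcortical")
  roi_pool_nets <- networks_of(parc, association_only = TRUE)

  # --- tSnR ROI selection (training set only) -------------------------------
  tsnr <- t(vapply(
    scans[train_ids], compute_tsnr, numeric(ncol(scans[[1]]$series))
  ))
  rois <- select_rois(tsnr, parc, sd_k = config$tsnr_sd_k, networks = roi_pool_nets)

  # --- ROI-based edges + feature selection ----------------------------------
  edges_roi <- lapply(scans, correlation_edges, rois = rois)
  fs <- select_high_variance_edges(edges_roi[train_ids], p = config$variance_fraction)
  feat <- lapply(edges_roi, restrict_edges, fs = fs)
  gm_roi <- group_average(feat[train_ids])
  sim_roi_train <- cohort_similarity(gm_roi, feat[train_ids], "train")
  sim_roi_test <- cohort_similarity(gm_roi, feat[test_ids], "test")

  # --- network-based representation (no tSnR / variance reduction) ----------
  net_rois <- parc$roi_id[parc$network %in% networks]
  edges_net <- lapply(scans, correlation_edges, rois = net_rois)
  nm <- lapply(edges_net, network_matrix, parc = parc, networks = networks)
  gm_net <- group_average(nm[train_ids])
  sim_net_train <- cohort_similarity(gm_net, nm[train_ids], "train")
  sim_net_test <- cohort_similarity(gm_net, nm[test_ids], "test")

  # --- shuffled-network null ------------------------------------------------
  null_res <- shuffled_network_null(
    edges_net[train_ids], parc,
    networks = networks,
    n_iter = config$n_permutations, seed = seeds[["permutation"]]
  )

  # --- prediction + moderation per outcome and representation ---------------
  measures <- setdiff(colnames(cohort$outcomes), "subject_id")
  y_all <- cohort$outcomes
  feature_sets <- list(
    roi = t(vapply(feat, `[[`, numeric(length(fs$indices)), "values")),
    network = t(vapply(nm, `[[`, numeric(length(nm[[1]]$values)), "values"))
  )
  colnames(feature_sets$roi) <- sprintf("edge_%05d", fs$indices)
  colnames(feature_sets$network) <- sprintf("cell_%02d", seq_len(ncol(feature_sets$network)))
  sims <- list(
    roi = list(train = sim_roi_train, test = sim_roi_test),
    network = list(train = sim_net_train, test = sim_net_test)
  )

  prediction <- list()
  moderation <- list()
  for (rep_name in names(feature_sets)) {
    X <- feature_sets[[rep_name]]
    for (ms in measures) {
      y <- y_all[[ms]][match(rownames(X), y_all$subject_id)]
      tr_keep <- rownames(X) %in% train_ids & !is.na(y)
      model <- fit_elastic_net_cv(
        X[tr_keep, , drop = FALSE], y[tr_keep],
        alpha_grid = config$alpha_grid, n_folds = config$n_folds,
        seed = seeds[["folds"]]
      )
      for (set_name in c("train", "test")) {
        set_ids <- if (set_name == "train") train_ids else test_ids
        rows <- rownames(X) %in% set_ids
        scores <- predict_scores(
          model, X[rows, , drop = FALSE], y[rows],
          subject_id = rownames(X)[rows], set_label = set_name, measure = ms
        )
        perf <- performance_r(scores)
        key <- paste(rep_name, ms, set_name, sep = ".")
        prediction[[key]] <- list(
          representation = rep_name, measure = ms, set = set_name,
          r = as.numeric(perf), degenerate = attr(perf, "degenerate"),
          n_selected = model$n_selected, alpha = model$alpha, lambda = model$lambda
        )
        if (!model$degenerate) {
          mod <- fit_moderation(scores, sims[[rep_name]][[set_name]], alpha = config$alpha)
          jn <- johnson_neyman(mod, alpha = config$alpha)
          moderation[[key]] <- list(model = mod, jn = jn)
        }
      }
    }
  }

  # --- covariate screen -----------------------------------------------------
  screens <- NULL
  if (!is.null(cohort$covariates)) {
    screens <- lapply(sims, function(s) {
      lapply(s, covariate_screen,
        covariates = cohort$covariates, alpha = config$bonferroni_alpha
      )
    })
  }

  report <- structure(
    list(
      config = config, seeds = as.list(seeds),
      version = as.character(utils::packageVersion("fcgroupsim")),
      counts = list(
        n_input = length(cohort$scans), n_included = length(ids),
        n_train = length(train_ids), n_test = length(test_ids),
        n_rois_candidate = length(unique(parc$roi_id[parc$network %in% roi_pool_nets])),
        n_rois_retained = length(rois),
        n_edges_candidate = fs$rule$n_candidates,
        n_edges_selected = length(fs$indices)
      ),
      similarity = list(
        roi = list(
          train = attr(sim_roi_train, "summary"), test = attr(sim_roi_test, "summary")
        ),
        network = list(
          train = attr(sim_net_train, "summary"), test = attr(sim_net_test, "summary")
        )
      ),
      similarity_tables = sims,
      null = null_res,
      prediction = prediction,
      moderation = moderation,
      covariate_screen = screens
    ),
    class = "run_report"
  )
  if (!is.null(config$out)) write_report(report, config$out)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat(sprintf(
    "  subjects: %d included (%d train / %d test); ROIs %d -> %d; edges %d -> %d\n",
    x$counts$n_included, x$counts$n_train, x$counts$n_test,
    x$counts$n_rois_candidate, x$counts$n_rois_retained,
    x$counts$n_edges_candidate, x$counts$n_edges_selected
  ))
  for (r in names(x$similarity)) {
    for (s in names(x$similarity[[r]])) {
      sm <- x$similarity[[r]][[s]]
      cat(sprintf(
        "  %s-based ICC (%s): mean %.3f (SD %.3f, range %.3f-%.3f)\n",
        r, s, sm["mean"], sm["sd"], sm["min"], sm["max"]
      ))
    }
  }
  cat(sprintf(
    "  shuffled-network null: mean %.3f, max iteration mean %.3f (%d iterations)\n",
    x$null$overall_mean, x$null$max_iteration_mean, x$null$n_iter
  ))
  for (key in names(x$prediction)) {
    p <- x$prediction[[key]]
    cat(sprintf(
      "  %s | %s (%s): r = %.3f, %d features%s\n",
      p$representation, p$measure, p$set, p$r, p$n_selected,
      if (p$degenerate) " [degenerate]" else ""
    ))
  }
  invisible(x)
}

write_report <- function(report, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (r in names(report$similarity_tables)) {
    for (s in names(report$similarity_tables[[r]])) {
      utils::write.csv(
        report$similarity_tables[[r]][[s]],
        file.path(out, sprintf("similarity_%s_%s.csv", r, s)),
        row.names = FALSE
      )
    }
  }
  utils::write.csv(
    data.frame(
      iteration = seq_len(report$null$n_iter),
      mean_icc = report$null$iteration_means
    ),
    file.path(out, "null_distribution.csv"), row.names = FALSE
  )
  perf <- do.call(rbind, lapply(report$prediction, function(p) {
    data.frame(
      representation = p$representation, measure = p$measure, set = p$set,
      r = p$r, degenerate = p$degenerate, n_selected = p$n_selected,
      alpha = p$alpha, lambda = p$lambda
    )
  }))
  utils::write.csv(perf, file.path(out, "performance.csv"), row.names = FALSE)
  mods <- do.call(rbind, lapply(names(report$moderation), function(key) {
    cf <- report$moderation[[key]]$model$coefficients
    cf$key <- key
    cf
  }))
  if (!is.null(mods)) {
    utils::write.csv(mods, file.path(out, "moderation.csv"), row.names = FALSE)
  }
  jsonlite::write_json(
    list(
      seed = report$config$seed, version = report$version,
      counts = report$counts,
      similarity = report$similarity,
      null = report$null[c("n_iter", "overall_mean", "sd_across_iterations", "max_iteration_mean")],
      performance = report$prediction
    ),
    file.path(out, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out)
}
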