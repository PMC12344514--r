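test_that("censoring keeps boundary frames and concatenates runs in order", {
  mk <- function(fd, base) {
    subject_scan(matrix(base + seq_along(fd), ncol = 1), fd, tr = 0.8)
  }
  # fd all zeros: everything retained across two runs
  out <- censor_and_concatenate(list(mk(rep(0, 100), 0), mk(rep(0, 100), 100)))
  expect_equal(nrow(out$series), 200)
  # strict inequality: frames 1 and 3 retained, boundary would survive
  out2 <- censor_and_concatenate(mk(c(.05, .15, .09), 0), fd_threshold = 0.10)
  expect_equal(drop(out2$series), c(1, 3))
  expect_equal(out2$fd, c(.05, .09))
  out3 <- censor_and_concatenate(mk(c(.10, .2), 0), fd_threshold = 0.10)
  expect_equal(drop(out3$series), 1) # exactly-at-threshold frame kept
  expect_error(
    censor_and_concatenate(mk(c(.5, .5), 0), fd_threshold = 0.10),
    "no frames survive"
  )
  # synthetic censor_fraction flows through: ~30% censored
  set.seed(1)
  sc <- sample_timeseries(diag(4), T = 1000, censor_fraction = 0.3)
  expect_equal(nrow(censor_and_concatenate(sc)$series), 700)
})

test_that("inclusion rule is retained-frames x TR >= minutes, inclusive", {
  mk <- function(n) subject_scan(matrix(rnorm(n), ncol = 1), rep(0, n), tr = 0.8)
  expect_true(subject_included(mk(750)))   # 600 s exactly
  expect_false(subject_included(mk(749)))  # 599.2 s
  # a half-censored synthetic scan: T = 1600 at 50% censoring ~ 640 s
  set.seed(2)
  sc <- sample_timeseries(diag(3), T = 1600, censor_fraction = 0.5)
  retained <- sum(sc$fd <= 0.10)
  expect_equal(retained, 800)
  expect_true(subject_included(sc))
})

test_that("tSnR is mean over sample SD per ROI", {
  s <- subject_scan(matrix(c(1, 2, 3), ncol = 1), rep(0, 3))
  expect_equal(unname(compute_tsnr(s)), 2) # mean 2, sd 1
  set.seed(3)
  big <- subject_scan(matrix(100 + rnorm(10000), ncol = 1), rep(0, 10000))
  expect_equal(unname(compute_tsnr(big)), 100, tolerance = 0.05)
  zero_mean <- subject_scan(matrix(rnorm(5000), ncol = 1), rep(0, 5000))
  expect_lt(abs(compute_tsnr(zero_mean)), 0.1)
  const <- subject_scan(cbind(a = rnorm(5), b = rep(1, 5)), rep(0, 5))
  expect_error(compute_tsnr(const), "b")
})

test_that("ROI selection drops low-tSnR outliers at the configured k", {
  parc <- parcellation(sprintf("r%02d", 1:12), rep("net1", 12), TRUE)
  # all equal: nothing dropped
  eq <- matrix(50, nrow = 4, ncol = 12, dimnames = list(NULL, parc$roi_id))
  expect_equal(select_rois(eq, parc), parc$roi_id)
  # one ROI at mean - 3 SD among others: exactly that ROI dropped at k = 2
  set.seed(4)
  tsnr <- matrix(rep(50 + rnorm(12, sd = 1), each = 4), nrow = 4,
    dimnames = list(NULL, parc$roi_id)
  )
  mu <- colMeans(tsnr)
  tsnr[, 5] <- mean(mu[-5]) - 3.5 * sd(mu[-5]) # well below the pack
  kept2 <- select_rois(tsnr, parc, sd_k = 2)
  expect_identical(setdiff(parc$roi_id, kept2), "r05")
  # k = 1 drops a superset of k = 2's drops
  kept1 <- select_rois(tsnr, parc, sd_k = 1)
  expect_true(all(setdiff(parc$roi_id, kept2) %in% setdiff(parc$roi_id, kept1)))
})

test_that("edge enumeration is canonical and counts follow n(n-1)/2", {
  for (n in c(2, 3, 10, 57, 400)) {
    ei <- edge_index(n)
    expect_equal(nrow(ei), n * (n - 1) / 2)
    expect_true(all(ei$i < ei$j))
    expect_false(any(duplicated(ei)))
  }
  # row-major ordering
  expect_equal(edge_index(4)$i, c(1, 1, 1, 2, 2, 3))
  expect_equal(edge_index(4)$j, c(2, 3, 4, 3, 4, 4))
  expect_equal(n_edges(352), 61776)
})

test_that("correlation_edges matches cor() + atanh and clamps r = 1", {
  set.seed(5)
  X <- matrix(rnorm(200 * 4), 200, 4)
  colnames(X) <- sprintf("r%d", 1:4)
  sc <- subject_scan(X, rep(0, 200))
  ev <- correlation_edges(sc)
  R <- cor(X)
  expect_equal(ev$values[1], atanh(R[1, 2]))
  expect_equal(length(ev$values), 6)
  # duplicated ROI: z clamped finite
  X2 <- cbind(a = X[, 1], b = X[, 1], c = X[, 2])
  ev2 <- correlation_edges(subject_scan(X2, rep(0, 200)))
  expect_true(all(is.finite(ev2$values)))
  expect_equal(ev2$values[1], atanh(1 - 1e-12))
  # independent long series: |z| below ~3 null SDs
  set.seed(6)
  Xl <- matrix(rnorm(10000 * 2), ncol = 2)
  colnames(Xl) <- c("a", "b")
  evl <- correlation_edges(subject_scan(Xl, rep(0, 10000)))
  expect_lt(abs(evl$values[1]), 3 / sqrt(10000 - 3))
  expect_error(
    correlation_edges(subject_scan(cbind(a = rnorm(9), b = rep(2, 9)), rep(0, 9))),
    "constant ROI series: b"
  )
})

test_that("variance-based edge selection implements the ceiling rule", {
  expect_equal(n_selected_edges(17205, 0.10), 1721L)
  expect_equal(n_selected_edges(17205, 0.01), 173L)
  expect_equal(n_selected_edges(17205, 0.05), 861L)
  expect_equal(n_selected_edges(17205, 0.25), 4302L)
  expect_equal(n_selected_edges(17205, 0.50), 8603L)

  set.seed(7)
  roi_ids <- sprintf("r%02d", 1:10)
  evs <- lapply(1:6, function(i) {
    edge_vector(roi_ids, values = rnorm(45))
  })
  for (p in c(.01, .05, .10, .25, .50, 1)) {
    fs <- select_high_variance_edges(evs, p = p)
    expect_equal(length(fs$indices), ceiling(p * 45))
  }
  # selected edges really are the top-variance ones
  Z <- sapply(evs, `[[`, "values")
  v <- apply(Z, 1, var)
  fs10 <- select_high_variance_edges(evs, p = 0.10)
  expect_true(min(v[fs10$indices]) >= sort(v, decreasing = TRUE)[6])
  # deterministic tie-break: earlier canonical edge wins
  tied <- lapply(1:3, function(i) edge_vector(c("a", "b", "c"), values = c(i, i, 0)))
  fs_t <- select_high_variance_edges(tied, p = 1 / 3)
  expect_equal(fs_t$indices, 1L)
  expect_error(select_high_variance_edges(evs, p = 0), "\\(0, 1\\]")
  expect_error(select_high_variance_edges(evs, p = 1.2), "\\(0, 1\\]")
})

test_that("network aggregation matches brute-force cell means", {
  # 2 networks x 2 ROIs with hand-set z values over the 6 edges
  roi_ids <- c("a1", "a2", "b1", "b2")
  parc <- parcellation(roi_ids, c("A", "A", "B", "B"), TRUE)
  z <- c(0.5, 0.1, 0.2, 0.3, 0.4, 0.6) # (a1a2, a1b1, a1b2, a2b1, a2b2, b1b2)
  ev <- edge_vector(roi_ids, values = z)
  nm <- network_matrix(ev, parc, networks = c("A", "B"))
  expect_equal(nm$cells["A", "A"], 0.5)
  expect_equal(nm$cells["B", "B"], 0.6)
  expect_equal(nm$cells["A", "B"], mean(c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(nm$values, c(0.5, 0.25, 0.6))
  # against the loop oracle on a random instance
  set.seed(8)
  n <- 12
  labels <- rep(c("A", "B", "C"), each = 4)
  parc2 <- parcellation(sprintf("r%02d", 1:n), labels, TRUE)
  vals <- rnorm(n_edges(n))
  ev2 <- edge_vector(parc2$roi_id, values = vals)
  Rz <- matrix(0, n, n)
  Rz[cbind(edge_index(n)$i, edge_index(n)$j)] <- vals
  Rz <- Rz + t(Rz)
  oracle <- network_cells_oracle(Rz, labels, c("A", "B", "C"))
  nm2 <- network_matrix(ev2, parc2, networks = c("A", "B", "C"))
  expect_equal(nm2$cells, oracle)
  # K = 8 networks give 36 distinct cells
  parc8 <- parcellation(sprintf("r%02d", 1:16), rep(sprintf("n%d", 1:8), each = 2), TRUE)
  ev8 <- edge_vector(parc8$roi_id, values = rnorm(n_edges(16)))
  expect_equal(length(network_matrix(ev8, parc8)$values), 36)
  # constant edges propagate
  evc <- edge_vector(roi_ids, values = rep(0.7, 6))
  expect_equal(network_matrix(evc, parc, networks = c("A", "B"))$values, rep(0.7, 3))
  expect_error(
    network_matrix(ev, parc, networks = c("A", "B", "missing")),
    "fewer than 2 ROIs"
  )
})

test_that("group averaging is the elementwise z mean and commutes with aggregation", {
  set.seed(9)
  roi_ids <- sprintf("r%02d", 1:8)
  parc <- parcellation(roi_ids, rep(c("A", "B"), each = 4), TRUE)
  evs <- lapply(1:5, function(i) edge_vector(roi_ids, values = rnorm(28)))
  gm <- group_average(evs)
  expect_equal(gm$referent$values, rowMeans(sapply(evs, `[[`, "values")))
  expect_equal(gm$n_train, 5)
  # one subject: referent equals that subject
  expect_equal(group_average(evs[1])$referent$values, evs[[1]]$values)
  # antisymmetric pair averages to zero
  ev_neg <- edge_vector(roi_ids, values = -evs[[1]]$values)
  expect_equal(group_average(list(evs[[1]], ev_neg))$referent$values, rep(0, 28))
  # means commute: network_matrix(group mean) == mean(network matrices)
  nm_of_mean <- network_matrix(gm$referent, parc, networks = c("A", "B"))
  mean_of_nm <- group_average(lapply(evs, network_matrix, parc = parc, networks = c("A", "B")))
  expect_equal(nm_of_mean$values, mean_of_nm$referent$values, tolerance = 1e-12)
  # enumeration mismatch
  expect_error(
    group_average(list(evs[[1]], edge_vector(sprintf("x%02d", 1:8), values = rnorm(28)))),
    "mismatch"
  )
})

test_that("per-subject edge extraction is deterministic on fixed input", {
  co <- tiny_cohort(seed = 10, n_subjects = 2)
  e1 <- censored_edges(co)
  e2 <- censored_edges(co)
  expect_identical(e1, e2)
})
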