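test_that("GFP is the per-frame population SD across channels", {
  lay <- make_sensor_layout(4)
  rec <- recording(matrix(3, 4, 5), 100, lay)
  expect_equal(global_field_power(rec)$values, rep(0, 5))
  lay2 <- make_sensor_layout(2)
  rec2 <- recording(matrix(c(1, -1), 2, 1), 100, lay2)
  expect_equal(global_field_power(rec2)$values, 1)
  set.seed(1)
  x <- matrix(rnorm(64 * 20), 64)
  g <- global_field_power(recording(x, 100, make_sensor_layout(64)))$values
  brute <- apply(x, 2, function(col) sqrt(mean((col - mean(col))^2)))
  expect_equal(g, brute, tolerance = 1e-12)
  expect_error(global_field_power(recording(matrix(1, 1, 5), 100,
                                            make_sensor_layout(1))),
               "2 channels")
})

test_that("GFP peaks are strict interior local maxima, plateau-leftmost", {
  expect_length(extract_gfp_peaks(1:10), 0)
  expect_equal(extract_gfp_peaks(c(0, 1, 0, 2, 0)), c(2L, 4L))
  expect_equal(extract_gfp_peaks(c(0, 3, 3, 3, 0, 1, 0)), c(2L, 6L))
  expect_length(extract_gfp_peaks(c(5, 1, 1, 5)), 0)   # endpoints excluded
  t <- seq(1 / 1000, 1, by = 1 / 1000)
  expect_length(extract_gfp_peaks(abs(sin(2 * pi * 10 * t))), 20)
  expect_error(extract_gfp_peaks(c(1, 2)), "at least 3")
})

test_that("spatial correlation is Pearson across sensors, optionally unsigned", {
  set.seed(2)
  a <- rnorm(64); b <- rnorm(64)
  expect_equal(spatial_correlation(a, a), 1)
  expect_equal(spatial_correlation(a, -a), 1)
  expect_equal(spatial_correlation(a, -a, polarity_invariant = FALSE), -1)
  expect_equal(spatial_correlation(a, b), abs(pearson_direct(a, b)),
               tolerance = 1e-12)
  expect_error(spatial_correlation(a, rep(1, 64)), "zero-variance")
  expect_error(spatial_correlation(a, b[1:10]), "length")
})

test_that("modified k-means recovers planted topographies", {
  lay <- make_sensor_layout(64)
  tpl <- make_templates(lay, 3, max_abs_corr = 0.3, seed = 11)
  set.seed(12)
  X <- tpl$maps[rep(1:3, each = 200), ]
  X <- X * sample(c(-1, 1), 600, replace = TRUE)     # random polarity
  X <- X + matrix(rnorm(600 * 64, 0, sqrt(mean(X^2)) / 10), 600, 64)
  sol <- kmeans_microstates(X, 3, n_restarts = 20, seed = 13)
  # match centroids to templates by maximal |r| under brute-force search
  cr <- abs(sol$maps$maps %*% t(tpl$maps))
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  best <- max(vapply(perms, function(p) min(cr[cbind(p, 1:3)]), numeric(1)))
  expect_gt(best, 0.99)
  expect_true(all(table(sol$assignment) > 0))
})

test_that("k-means degenerate cases follow the contracts", {
  set.seed(14)
  X <- matrix(rnorm(5 * 16), 5)
  sol <- kmeans_microstates(X, 5, n_restarts = 5, seed = 1)
  expect_equal(sol$gev, 1, tolerance = 1e-9)   # each map its own centroid
  expect_error(kmeans_microstates(X, 6), "fewer maps")
  # maps are centred unit-norm
  expect_equal(rowSums(sol$maps$maps^2), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rowMeans(sol$maps$maps), rep(0, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("best-of-restarts GEV is non-decreasing in K", {
  lay <- make_sensor_layout(32)
  tpl <- make_templates(lay, 4, seed = 15)
  set.seed(16)
  X <- tpl$maps[sample(1:4, 300, replace = TRUE), ] +
    matrix(rnorm(300 * 32, 0, 0.05), 300, 32)
  gev <- vapply(2:8, function(K)
    kmeans_microstates(X, K, n_restarts = 10, seed = 17)$gev, numeric(1))
  expect_true(all(diff(gev) >= -1e-6))
})

test_that("GEV matches its definition and bounds", {
  # frames exactly proportional to their assigned maps
  lay <- make_sensor_layout(16)
  tpl <- make_templates(lay, 3, seed = 18)
  lab <- rep(1:3, each = 4)
  X <- tpl$maps[lab, ] * seq(0.5, 6, length.out = 12)
  expect_equal(global_explained_variance(tpl, X, lab), 1, tolerance = 1e-12)
  # orthogonal maps explain nothing
  M <- matrix(0, 2, 4); M[1, ] <- c(1, -1, 0, 0); M[2, ] <- c(0, 0, 1, -1)
  M <- M / sqrt(rowSums(M^2))
  X2 <- matrix(rep(c(1, 1, -1, -1), 5), 5, 4, byrow = TRUE)
  expect_equal(global_explained_variance(microstate_maps(M), X2,
                                         rep(1, 5)), 0, tolerance = 1e-12)
  # brute-force term-by-term evaluation on a random instance
  set.seed(19)
  Xr <- matrix(rnorm(20 * 16), 20)
  labr <- sample(1:3, 20, replace = TRUE)
  got <- global_explained_variance(tpl, Xr, labr)
  gfp <- apply(Xr, 1, function(v) sqrt(mean((v - mean(v))^2)))
  num <- sum(vapply(1:20, function(t)
    (gfp[t] * spatial_correlation(Xr[t, ], tpl$maps[labr[t], ]))^2,
    numeric(1)))
  expect_equal(got, num / sum(gfp^2), tolerance = 1e-12)
  expect_gte(got, 0); expect_lte(got, 1)
})

test_that("kneedle finds the knee of concave increasing curves", {
  expect_true(is.na(kneedle_optimal_k(1:10, seq(0, 1, length.out = 10))))
  k <- 1:10
  y <- 1 - exp(-k / 2)
  expect_equal(kneedle_optimal_k(k, y), kneedle_oracle(k, y))
  expect_equal(kneedle_optimal_k(k, y), 4L)
  # a sharper curve knees earlier; oracle agreement across shapes
  for (rate in c(1, 1.5, 3)) {
    y2 <- 1 - exp(-k / rate)
    expect_equal(kneedle_optimal_k(k, y2), kneedle_oracle(k, y2),
                 info = paste("rate", rate))
  }
  expect_error(kneedle_optimal_k(c(3, 2, 4), c(1, 2, 3)), "increasing")
  expect_error(kneedle_optimal_k(1:2, 1:2), "3 points")
})

test_that("grand-mean clustering reduces to subject maps for a degenerate cohort", {
  lay <- make_sensor_layout(32)
  tpl <- make_templates(lay, 4, max_abs_corr = 0.5, seed = 20)
  sol1 <- kmeans_microstates(tpl$maps[rep(1:4, 10), ] +
                               matrix(rnorm(40 * 32, 0, 0.01), 40, 32),
                             4, n_restarts = 10, seed = 21)
  subs <- list(sol1, sol1, sol1)
  grp <- group_level_maps(subs, 4, n_restarts = 10, seed = 22)
  cr <- abs(grp$maps$maps %*% t(sol1$maps$maps))
  expect_equal(unname(sort(apply(cr, 2, max))), rep(1, 4), tolerance = 1e-9)
  expect_equal(rowSums(grp$maps$maps^2), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  # heterogeneous sensor counts refuse to pool
  small <- kmeans_microstates(matrix(rnorm(10 * 16), 10), 4,
                              n_restarts = 3, seed = 23)
  expect_error(group_level_maps(list(sol1, small), 4), "heterogeneous")
})

test_that("backfitting is an argmax over polarity-invariant correlation", {
  lay <- make_sensor_layout(32)
  tpl <- make_templates(lay, 5, seed = 24)
  # frames equal to the maps in sequence -> identity labels
  rec <- recording(t(tpl$maps), 100, lay)
  expect_equal(backfit(rec, tpl)$labels, 1:5)
  # global sign flip leaves labels unchanged
  rec_neg <- recording(-t(tpl$maps), 100, lay)
  expect_equal(backfit(rec_neg, tpl)$labels, 1:5)
  # random recording vs exhaustive per-sample oracle
  set.seed(25)
  X <- matrix(rnorm(32 * 200), 32)
  recr <- recording(X, 100, lay)
  got <- backfit(recr, tpl)$labels
  oracle <- vapply(1:200, function(t)
    which.max(vapply(1:5, function(k)
      abs(pearson_direct(X[, t], tpl$maps[k, ])), numeric(1))),
    integer(1))
  expect_equal(got, oracle)
  # per-sample positive rescaling and sign flips change nothing
  scl <- runif(200, 0.1, 4) * sample(c(-1, 1), 200, replace = TRUE)
  rec_s <- recording(sweep(X, 2, scl, `*`), 100, lay)
  expect_equal(backfit(rec_s, tpl)$labels, got)
  # threshold rule and zero-variance frames produce unassigned samples
  X0 <- X; X0[, 7] <- 5
  bf <- backfit(recording(X0, 100, lay), tpl)
  expect_true(is.na(bf$labels[7]))
  bf_hi <- backfit(recr, tpl, min_corr = 0.99)
  expect_gt(sum(is.na(bf_hi$labels)), 0)
})

test_that("subject clustering of a noiseless single-template recording is exact", {
  lay <- make_sensor_layout(32)
  tpl <- make_templates(lay, 1, seed = 26)
  lab <- label_sequence(rep(1L, 500), 1, 100)
  rec <- render_recording(tpl, lab, lay, snr = Inf, seed = 27)
  g <- global_field_power(rec)
  pk <- extract_gfp_peaks(g)
  sol <- kmeans_microstates(t(rec$data[, pk]), 1, n_restarts = 3, seed = 28)
  expect_equal(abs(spatial_correlation(sol$maps$maps[1, ], tpl$maps[1, ])),
               1, tolerance = 1e-9)
})
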