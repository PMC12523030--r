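test_that("sensor layout covers the upper hemisphere quasi-uniformly", {
  lay <- make_sensor_layout(64)
  expect_equal(lay$n_sensors, 64L)
  expect_equal(nrow(lay$positions), 64L)
  expect_true(all(lay$positions[, 3] >= 0))
  expect_equal(unname(rowSums(lay$positions^2)), rep(1, 64),
               tolerance = 1e-12)
  # brute-force pairwise angular separation
  g <- tcrossprod(lay$positions)
  g[g > 1] <- 1; g[g < -1] <- -1
  ang <- acos(g); diag(ang) <- Inf
  min_ang <- min(ang)
  expect_gt(min_ang, 0)
  # within 2x of the hexagonal uniform-packing value on the hemisphere
  packing <- sqrt(2 * (2 * pi / 64) / sqrt(3))
  expect_gt(min_ang, packing / 2)
  expect_lt(min_ang, packing * 2)
  expect_equal(anyDuplicated(lay$positions), 0L)
})

test_that("degenerate layouts and neighbour queries behave", {
  lay1 <- make_sensor_layout(1)
  expect_equal(drop(lay1$positions), c(0, 0, 1))
  expect_error(make_sensor_layout(0), "positive integer")
  expect_error(make_sensor_layout(-3), "positive integer")
  lay <- make_sensor_layout(20)
  nb <- sensor_neighbors(lay, 5)
  expect_equal(dim(nb), c(20L, 5L))
  for (s in seq_len(20)) expect_false(s %in% nb[s, ])
  expect_error(sensor_neighbors(lay, 20), "smaller than")
})

test_that("templates are centred, unit-norm and decorrelated as requested", {
  lay <- make_sensor_layout(64)
  tpl <- make_templates(lay, 6, max_abs_corr = 0.7, seed = 3)
  expect_equal(tpl$K, 6L)
  expect_equal(rowMeans(tpl$maps), rep(0, 6), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rowSums(tpl$maps^2), rep(1, 6), tolerance = 1e-12,
               ignore_attr = TRUE)
  # exhaustive pairwise |r| check (centred unit-norm rows: r = dot product)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_lte(abs(spatial_correlation(tpl$maps[i, ], tpl$maps[j, ])), 0.7)
  }
  expect_equal(tpl$class_labels, sprintf("Ms%d", 1:6))
  # single template: no pairwise constraint
  expect_silent(make_templates(lay, 1, seed = 4))
  # infeasible decorrelation budget fails loudly
  expect_error(make_templates(make_sensor_layout(8), 8,
                              max_abs_corr = 0.01, seed = 5,
                              max_tries = 10),
               "template generation failed")
})

test_that("state sequences reproduce the configured dwell and transitions", {
  expect_equal(simulate_state_sequence(transition_model(1, 50), 1, 100,
                                       seed = 1)$labels,
               rep(1L, 100))
  mod <- transition_model(6, 50)
  ls <- simulate_state_sequence(mod, 480, 1000, seed = 42)
  expect_length(ls$labels, 480000L)
  r <- rle(ls$labels)
  # empirical mean dwell within 10% of 50 ms (fs 1000: samples == ms)
  expect_lt(abs(mean(r$lengths) - 50) / 50, 0.10)
  # collapsed-run transition matrix within 0.03/cell of uniform 0.2
  P <- transition_probabilities(ls)
  off <- P[row(P) != col(P)]
  expect_lt(max(abs(off - 0.2)), 0.03)
  expect_equal(unname(diag(P)), rep(0, 6))
  # bit-reproducibility
  ls2 <- simulate_state_sequence(mod, 480, 1000, seed = 42)
  expect_identical(ls$labels, ls2$labels)
})

test_that("realized coverage matches the semi-Markov stationary law", {
  set.seed(1)
  J <- matrix(runif(36), 6, 6); diag(J) <- 0; J <- J / rowSums(J)
  mod <- transition_model(6, c(40, 50, 60, 70, 90, 120), J)
  cov_theory <- stationary_coverage(mod)
  expect_equal(sum(cov_theory), 1, tolerance = 1e-12)
  ls <- simulate_state_sequence(mod, 480, 1000, seed = 9)
  cov_emp <- tabulate(ls$labels, 6) / length(ls$labels)
  expect_lt(max(abs(cov_emp - cov_theory)), 0.02)
})

test_that("coverage injection by dwell rescaling is exact in expectation", {
  mod <- transition_model(6, 60)
  adj <- adjust_model_coverage(mod, 2, 0.04)
  expect_equal(stationary_coverage(adj)[2],
               stationary_coverage(mod)[2] + 0.04, tolerance = 1e-12)
  expect_identical(adj$conditional_jump, mod$conditional_jump)
  expect_error(adjust_model_coverage(mod, 2, 0.9), "outside")
})

test_that("rendered recordings honour the shape, snr and polarity contracts", {
  lay <- fix_layout(32)
  tpl <- fix_templates(lay, 6)
  mod <- transition_model(6, 60)
  lab <- simulate_state_sequence(mod, 10, 200, seed = 2)
  rec <- render_recording(tpl, lab, lay, snr = 5, seed = 3)
  expect_equal(dim(rec$data), c(32L, round(10 * 200)))
  expect_error(render_recording(tpl, lab, lay, snr = -1), "snr")
  # noiseless render -> backfit recovers truth exactly, despite sign flips
  recI <- render_recording(tpl, lab, lay, snr = Inf, seed = 3, flip_prob = 1)
  expect_identical(backfit(recI, tpl)$labels, lab$labels)
  # at snr 5 recovery stays high
  expect_gte(mean(backfit(rec, tpl)$labels == lab$labels), 0.90)
  # generators are bit-reproducible
  rec2 <- render_recording(tpl, lab, lay, snr = 5, seed = 3)
  expect_identical(rec$data, rec2$data)
})

test_that("cohort simulation wires group sizes, effects and manifests", {
  cfg <- cohort_config(n_patients = 3, n_controls = 2, n_sensors = 16,
                       fs = 100, duration_s = 5, K = 4, snr = 5, seed = 6)
  out <- withr::local_tempdir()
  sim <- simulate_cohort(cfg, out_dir = out)
  expect_length(sim$recordings, 5L)
  expect_equal(table(sim$manifest$group)[["patient"]], 3L)
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(all(file.exists(paste0(sim$manifest$file, ".tsv"))))
  # zero injected effect: identical generators for the two groups
  expect_identical(sim$base_models$patient, sim$base_models$control)
  # defaults carry the study design
  dflt <- cohort_config()
  expect_equal(dflt$n_patients, 25L)
  expect_equal(dflt$n_controls, 18L)
  expect_equal(dflt$n_sensors, 64L)
  expect_equal(dflt$fs, 1000)
  expect_equal(dflt$duration_s, 480)
})

test_that("injected stationary effect is realized in ground-truth labels", {
  # jitter disabled: checks the injection mechanics against the linear-solve
  # stationary distribution, 20 subjects per group
  base <- transition_model(6, 60)
  shifted <- adjust_model_coverage(base, 2, 0.04)
  cov_of <- function(mod, seed) {
    ls <- simulate_state_sequence(mod, 480, 1000, seed = seed)
    tabulate(ls$labels, 6)[2] / length(ls$labels)
  }
  c_ctrl <- vapply(1:20, function(i) cov_of(base, 1000 + i), numeric(1))
  c_pat <- vapply(1:20, function(i) cov_of(shifted, 2000 + i), numeric(1))
  expect_lt(abs((mean(c_pat) - mean(c_ctrl)) - 0.04), 0.01)
})

test_that("clinical tables reproduce the configured group moments", {
  dflt <- clinical_defaults <- megastate:::clinical_defaults()
  expect_equal(dflt$both$education$patient[1], 16.04)
  expect_equal(dflt$both$education$control[1], 19.17)
  man <- data.frame(subject_id = sprintf("s%02d", 1:43),
                    group = rep(c("patient", "control"), c(25, 18)))
  clin <- simulate_clinical_table(man, seed = 1)
  expect_equal(nrow(clin), 43L)
  expect_true(all(is.na(clin$VAS[clin$group == "control"])))
  expect_true(all(!is.na(clin$VAS[clin$group == "patient"])))
  expect_true(all(clin$VAS >= 0 & clin$VAS <= 10, na.rm = TRUE))
  # moments at large n approach the configured parameters
  big <- data.frame(subject_id = sprintf("s%04d", 1:800),
                    group = rep(c("patient", "control"), each = 400))
  cb <- simulate_clinical_table(big, seed = 2)
  expect_equal(mean(cb$education[cb$group == "patient"]), 16.04,
               tolerance = 0.05)
  expect_equal(mean(cb$education[cb$group == "control"]), 19.17,
               tolerance = 0.05)
})

test_that("clinical coupling injects the requested correlation", {
  man <- data.frame(subject_id = sprintf("s%02d", 1:43),
                    group = rep(c("patient", "control"), c(25, 18)))
  set.seed(3)
  metric <- rnorm(25)
  clin <- simulate_clinical_table(
    man, seed = 4,
    coupling = list(clinical = "attack_duration", metric = metric, r = -0.5))
  r_hat <- cor(metric, clin$attack_duration[clin$group == "patient"])
  expect_lt(abs(r_hat - (-0.5)), 0.3)   # Fisher-z sampling band at n = 25
  expect_error(simulate_clinical_table(
    man, seed = 4,
    coupling = list(clinical = "VAS", metric = metric, r = 1.2)),
    "must be < 1")
})
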