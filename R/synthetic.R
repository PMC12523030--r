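# Synthetic MEG cohorts with known microstate ground truth.
#
# The generator follows the standard microstate model: brain activity is a
# sequence of quasi-stable topographies (dwell times of tens of ms), each
# sample being an amplitude-modulated, possibly sign-flipped copy of the
# active class map plus sensor noise. Ground-truth labels are retained so
# every downstream stage can be validated.

#' Quasi-uniform helmet sensor layout
#'
#' Places `n_sensors` points on the upper unit hemisphere using a Fibonacci
#' (golden-angle) lattice restricted to non-negative height, emulating a
#' full-head OPM helmet array. The construction is deterministic; `seed` only
#' matters when `jitter > 0`, which adds a small tangential perturbation.
#'
#' @param n_sensors number of sensors (>= 1).
#' @param seed integer RNG seed (used only if `jitter > 0`).
#' @param jitter standard deviation of optional angular jitter (radians).
#' @return an object of class `sensor_layout`: list with `n_sensors`,
#'   `positions` (n x 3, unit radius), `names`.
#' @export
make_sensor_layout <- function(n_sensors, seed = 0L, jitter = 0) {
  if (!is.numeric(n_sensors) || length(n_sensors) != 1 || n_sensors < 1 ||
      n_sensors != round(n_sensors)) {
    stop_invalid("n_sensors must be a positive integer, got %s",
                 deparse(substitute(n_sensors)))
  }
  n <- as.integer(n_sensors)
  if (n == 1L) {
    pos <- matrix(c(0, 0, 1), 1, 3)
  } else {
    i <- seq_len(n) - 1
    golden <- pi * (3 - sqrt(5))
    z <- (i + 0.5) / n          # heights in (0, 1): upper hemisphere only
    r <- sqrt(pmax(0, 1 - z^2))
    th <- golden * i
    pos <- cbind(r * cos(th), r * sin(th), z)
    if (jitter > 0) {
      set.seed(seed)
      pos <- pos + matrix(stats::rnorm(3 * n, 0, jitter), n, 3)
      pos[, 3] <- abs(pos[, 3])
      pos <- pos / sqrt(rowSums(pos^2))
    }
  }
  dimnames(pos) <- NULL
  structure(
    list(n_sensors = n, positions = pos,
         names = sprintf("MEG%03d", seq_len(n))),
    class = "sensor_layout")
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("<sensor_layout> %d sensors on the upper unit hemisphere\n",
              x$n_sensors))
  invisible(x)
}

#' k nearest neighbours of each sensor
#'
#' @param layout a `sensor_layout`.
#' @param k neighbours per sensor (self excluded); must be < n_sensors.
#' @return integer matrix n_sensors x k of neighbour indices, nearest first.
#' @export
sensor_neighbors <- function(layout, k) {
  n <- layout$n_sensors
  if (k >= n) stop_invalid("k (%d) must be smaller than n_sensors (%d)", k, n)
  d <- as.matrix(stats::dist(layout$positions))
  if (any(d[upper.tri(d)] < 1e-12)) {
    stop_invalid("degenerate layout: duplicate sensor positions")
  }
  diag(d) <- Inf
  t(apply(d, 1, function(row) order(row)[seq_len(k)]))
}

#' Construct a set of microstate class maps
#'
#' @param K number of classes.
#' @param maps K x n_sensors matrix; rows are centred and L2-normalised.
#' @param class_labels labels, default `Ms1..MsK`.
#' @return `microstate_maps` object.
#' @export
microstate_maps <- function(maps, class_labels = NULL) {
  maps <- as.matrix(maps)
  K <- nrow(maps)
  if (K < 1) stop_invalid("need at least one map")
  maps <- normalize_maps(maps)
  if (length(attr(maps, "degenerate"))) {
    stop_invalid("zero-variance map row(s): %s",
                 paste(attr(maps, "degenerate"), collapse = ", "))
  }
  attr(maps, "degenerate") <- NULL
  labels <- class_labels %||% sprintf("Ms%d", seq_len(K))
  rownames(maps) <- labels
  structure(list(K = K, maps = maps, class_labels = labels),
            class = "microstate_maps")
}

#' @export
print.microstate_maps <- function(x, ...) {
  cat(sprintf("<microstate_maps> K = %d classes x %d sensors (%s)\n",
              x$K, ncol(x$maps), paste(x$class_labels, collapse = ", ")))
  invisible(x)
}

#' Draw smooth random template topographies
#'
#' Templates are spatially smooth random fields: white noise on the sensors
#' multiplied by a Gaussian distance kernel `exp(-d^2 / (2 * smoothness^2))`
#' over the helmet, then centred and normalised. Candidates are
#' rejection-resampled until every pair satisfies
#' `|spatial correlation| <= max_abs_corr`.
#'
#' @param layout a `sensor_layout`.
#' @param K number of templates (K <= n_sensors).
#' @param smoothness kernel length scale in the layout's (unit-radius) units.
#' @param max_abs_corr pairwise absolute-correlation ceiling in [0, 1).
#' @param seed RNG seed.
#' @param max_tries per-template rejection budget within one set attempt.
#' @param set_restarts whole-set retry budget: if some map cannot be placed
#'   (earlier greedy acceptances can wedge the constraint), the entire set
#'   is redrawn from scratch up to this many times before failing.
#' @return a `microstate_maps` object.
#' @export
make_templates <- function(layout, K, smoothness = 0.6, max_abs_corr = 0.7,
                           seed = 1L, max_tries = 500L, set_restarts = 20L) {
  n <- layout$n_sensors
  if (K > n) stop_invalid("K (%d) cannot exceed n_sensors (%d)", K, n)
  if (max_abs_corr < 0 || max_abs_corr >= 1) {
    stop_invalid("max_abs_corr must lie in [0, 1)")
  }
  d <- as.matrix(stats::dist(layout$positions))
  kern <- exp(-d^2 / (2 * smoothness^2))
  set.seed(seed)
  for (attempt in seq_len(set_restarts)) {
    maps <- matrix(0, K, n)
    kept <- 0L
    wedged <- FALSE
    while (kept < K && !wedged) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- drop(kern %*% stats::rnorm(n))
        cand <- cand - mean(cand)
        nc <- sqrt(sum(cand^2))
        if (nc < 1e-12) next
        cand <- cand / nc
        if (kept == 0L ||
            all(abs(maps[seq_len(kept), , drop = FALSE] %*% cand) <=
                  max_abs_corr)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        wedged <- TRUE
      } else {
        kept <- kept + 1L
        maps[kept, ] <- cand
      }
    }
    if (!wedged) return(microstate_maps(maps))
  }
  stop_invalid(paste0(
    "template generation failed: could not draw %d maps with all pairwise ",
    "|r| <= %.3f (smoothness %.2f, %d tries per map, %d set restarts); ",
    "relax max_abs_corr or reduce smoothness"),
    K, max_abs_corr, smoothness, max_tries, set_restarts)
}

#' Semi-Markov transition model over microstate classes
#'
#' Holds per-state mean dwell times (ms) and the conditional jump matrix
#' (probability of the next class given a departure; zero diagonal, rows sum
#' to one for K >= 2).
#'
#' @param K number of states.
#' @param dwell_mean_ms per-state mean dwell in milliseconds (recycled).
#' @param conditional_jump K x K jump matrix; default uniform off-diagonal.
#' @return `transition_model` object.
#' @export
transition_model <- function(K, dwell_mean_ms = 60,
                             conditional_jump = NULL) {
  K <- as.integer(K)
  if (K < 1) stop_invalid("K must be >= 1")
  dwell <- rep_len(dwell_mean_ms, K)
  if (any(dwell <= 0)) stop_invalid("dwell_mean_ms must be positive")
  if (is.null(conditional_jump)) {
    conditional_jump <- matrix(if (K > 1) 1 / (K - 1) else 0, K, K)
    diag(conditional_jump) <- 0
  }
  conditional_jump <- as.matrix(conditional_jump)
  if (!all(dim(conditional_jump) == K)) {
    stop_invalid("conditional_jump must be %d x %d", K, K)
  }
  if (any(abs(diag(conditional_jump)) > 1e-12)) {
    stop_invalid("conditional_jump must have a zero diagonal")
  }
  if (K >= 2 && any(abs(rowSums(conditional_jump) - 1) > 1e-8)) {
    stop_invalid("each row of conditional_jump must sum to 1")
  }
  structure(list(K = K, dwell_mean_ms = dwell,
                 conditional_jump = conditional_jump),
            class = "transition_model")
}

#' Stationary class-coverage distribution of a transition model
#'
#' The embedded jump chain's stationary distribution `pi` (left eigenvector
#' of the conditional jump matrix) is weighted by mean dwell time:
#' coverage_i = pi_i d_i / sum_j pi_j d_j.
#'
#' @param model a `transition_model`.
#' @return numeric vector of per-class stationary coverage (sums to 1).
#' @export
stationary_coverage <- function(model) {
  K <- model$K
  if (K == 1L) return(1)
  P <- model$conditional_jump
  # solve pi P = pi, sum(pi) = 1 by a bordered linear system
  A <- rbind(t(P) - diag(K), rep(1, K))
  b <- c(rep(0, K), 1)
  pi_jump <- as.numeric(qr.solve(A, b))
  w <- pi_jump * model$dwell_mean_ms
  w / sum(w)
}

#' Rescale one state's dwell time to shift its stationary coverage
#'
#' Returns a model identical to `model` except that the dwell time of class
#' `class` is rescaled (closed form) so its stationary coverage changes by
#' exactly `delta`. The jump matrix is untouched.
#'
#' @param model a `transition_model`.
#' @param class state index.
#' @param delta coverage change (new coverage must stay in (0, 1)).
#' @return adjusted `transition_model`.
#' @export
adjust_model_coverage <- function(model, class, delta) {
  cov <- stationary_coverage(model)
  target <- cov[class] + delta
  if (target <= 0 || target >= 1) {
    stop_invalid("target coverage %.3f outside (0, 1)", target)
  }
  P <- model$conditional_jump
  K <- model$K
  A <- rbind(t(P) - diag(K), rep(1, K))
  pi_jump <- as.numeric(qr.solve(A, c(rep(0, K), 1)))
  w <- pi_jump * model$dwell_mean_ms
  rest <- sum(w[-class])
  scale <- target * rest / ((1 - target) * w[class])
  dwell <- model$dwell_mean_ms
  dwell[class] <- dwell[class] * scale
  transition_model(K, dwell, P)
}

#' Per-sample label sequence
#'
#' @param labels integer class per sample; `NA` marks unassigned samples.
#' @param K number of classes.
#' @param fs sampling rate (Hz).
#' @return `label_sequence` object.
#' @export
label_sequence <- function(labels, K, fs) {
  if (fs <= 0) stop_invalid("fs must be positive")
  labels <- as.integer(labels)
  if (any(labels < 1 | labels > K, na.rm = TRUE)) {
    stop_invalid("labels outside 1..K")
  }
  structure(list(labels = labels, K = as.integer(K), fs = fs),
            class = "label_sequence")
}

#' @export
print.label_sequence <- function(x, ...) {
  cat(sprintf("<label_sequence> %d samples @ %g Hz, K = %d (%d unassigned)\n",
              length(x$labels), x$fs, x$K, sum(is.na(x$labels))))
  invisible(x)
}

#' Simulate a semi-Markov microstate label sequence
#'
#' Dwell times are geometric in samples (support >= 1) with mean
#' `dwell_mean_ms * fs / 1000`; successors are drawn from the conditional
#' jump matrix. The initial state is drawn from the stationary coverage
#' distribution so realised class fractions are unbiased.
#'
#' @param model a `transition_model`.
#' @param duration_s recording length in seconds.
#' @param fs sampling rate (Hz).
#' @param seed RNG seed.
#' @return a `label_sequence` of `round(duration_s * fs)` samples.
#' @export
simulate_state_sequence <- function(model, duration_s, fs, seed = 1L) {
  if (fs <= 0 || duration_s <= 0) stop_invalid("fs and duration_s must be > 0")
  n <- round(duration_s * fs)
  K <- model$K
  set.seed(seed)
  if (K == 1L) return(label_sequence(rep(1L, n), 1L, fs))
  mean_samp <- model$dwell_mean_ms * fs / 1000
  p_exit <- 1 / pmax(mean_samp, 1)   # geometric success prob per state
  cov <- stationary_coverage(model)
  P <- model$conditional_jump
  labels <- integer(n)
  state <- sample.int(K, 1, prob = cov)
  filled <- 0L
  while (filled < n) {
    dwell <- 1L + stats::rgeom(1, p_exit[state])
    take <- min(dwell, n - filled)
    labels[(filled + 1L):(filled + take)] <- state
    filled <- filled + take
    state <- sample.int(K, 1, prob = P[state, ])
  }
  label_sequence(labels, K, fs)
}

#' Sensor-space recording container
#'
#' @param data n_sensors x n_samples numeric matrix (arbitrary field units).
#' @param fs sampling rate in Hz.
#' @param layout a `sensor_layout` matching `nrow(data)`.
#' @param truth_labels optional ground-truth `label_sequence` (simulations).
#' @return `recording` object.
#' @export
recording <- function(data, fs, layout, truth_labels = NULL) {
  data <- as.matrix(data)
  if (fs <= 0) stop_invalid("fs must be positive")
  if (nrow(data) != layout$n_sensors) {
    stop_invalid("data has %d rows but layout has %d sensors",
                 nrow(data), layout$n_sensors)
  }
  if (!is.null(truth_labels) &&
      length(truth_labels$labels) != ncol(data)) {
    stop_invalid("truth labels length != n_samples")
  }
  rownames(data) <- layout$names
  structure(list(data = data, fs = fs, layout = layout,
                 truth_labels = truth_labels),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              if (is.null(x$truth_labels)) "" else ", with truth labels"))
  invisible(x)
}

#' Render a recording from maps and a label sequence
#'
#' Each sample is the active class map scaled by a positive smooth amplitude
#' envelope (rectified low-pass noise, floored at 10% of its mean, mimicking
#' global field power fluctuation), with the polarity of each state run
#' flipped independently with probability `flip_prob` to exercise polarity
#' invariance downstream. Independent Gaussian sensor noise is added with a
#' standard deviation set so the array-wide RMS amplitude ratio
#' signal / noise equals `snr` (`snr = Inf` disables noise).
#'
#' @param maps a `microstate_maps`.
#' @param labels a `label_sequence` referencing classes present in `maps`.
#' @param fs sampling rate (Hz); defaults to `labels$fs`.
#' @param snr signal-to-noise amplitude ratio (> 0, may be `Inf`).
#' @param seed RNG seed.
#' @param layout sensor layout; required to build the `recording`.
#' @param envelope_lp_hz envelope smoothness (approximate low-pass cutoff).
#' @param flip_prob probability that a run's polarity is negative.
#' @return a `recording` with `truth_labels` set.
#' @export
render_recording <- function(maps, labels, layout, fs = labels$fs, snr = 5,
                             seed = 1L, envelope_lp_hz = 10, flip_prob = 0.5) {
  if (!is.finite(snr) && snr > 0) snr <- Inf
  if (snr <= 0) stop_invalid("snr must be positive")
  lab <- labels$labels
  if (any(lab > maps$K, na.rm = TRUE)) {
    stop_invalid("labels reference classes absent from maps")
  }
  n <- length(lab)
  set.seed(seed)
  # smooth positive envelope: gaussian-smoothed white noise, rectified
  width <- max(3, round(fs / envelope_lp_hz))
  kern <- stats::dnorm(seq(-3, 3, length.out = 2 * width + 1))
  kern <- kern / sum(kern)
  env <- stats::filter(stats::rnorm(n + 2 * width), kern, sides = 2)
  env <- abs(as.numeric(env[(width + 1):(width + n)]))
  env <- pmax(env, 0.1 * mean(env))
  # per-run polarity
  r <- rle(lab)
  signs <- ifelse(stats::runif(length(r$lengths)) < flip_prob, -1, 1)
  sgn <- inverse.rle(list(lengths = r$lengths, values = signs))
  amp <- env * sgn
  sig <- maps$maps[lab, , drop = FALSE] * amp   # n x C
  sig <- t(sig)                                 # C x n
  if (is.finite(snr)) {
    rms_sig <- sqrt(mean(sig^2))
    sig <- sig + matrix(stats::rnorm(length(sig), 0, rms_sig / snr),
                        nrow(sig), ncol(sig))
  }
  recording(sig, fs, layout, truth_labels = labels)
}

#' Cohort simulation configuration
#'
#' Defaults mirror the study design this package emulates: two groups of
#' 25 patients and 18 controls, 64-channel helmet array, 1000 Hz sampling,
#' 8-minute eyes-closed recordings, six microstate classes. Group effects on
#' microstate dynamics are injected by shifting the stationary coverage of
#' chosen classes in the patient group (implemented by closed-form dwell
#' rescaling, see [adjust_model_coverage()]).
#'
#' @param n_patients,n_controls group sizes.
#' @param n_sensors,fs,duration_s recording geometry.
#' @param K number of microstate classes.
#' @param snr signal-to-noise amplitude ratio.
#' @param dwell_mean_ms base per-state mean dwell (ms).
#' @param conditional_jump base jump matrix (default uniform off-diagonal).
#' @param coverage_effects named numeric vector, e.g. `c(Ms2 = 0.04)`:
#'   stationary-coverage increments applied to the patient group.
#' @param subject_dwell_sd log-scale SD of per-subject dwell multipliers
#'   (between-subject variability; 0 disables).
#' @param smoothness,max_abs_corr template-generation controls.
#' @param flip_prob per-run polarity flip probability.
#' @param seed master seed for the cohort.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 25L, n_controls = 18L,
                          n_sensors = 64L, fs = 1000, duration_s = 480,
                          K = 6L, snr = 5, dwell_mean_ms = 60,
                          conditional_jump = NULL,
                          coverage_effects = numeric(0),
                          subject_dwell_sd = 0.2,
                          smoothness = 0.6, max_abs_corr = 0.7,
                          flip_prob = 0.5, seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_controls = as.integer(n_controls),
              n_sensors = as.integer(n_sensors), fs = fs,
              duration_s = duration_s, K = as.integer(K), snr = snr,
              dwell_mean_ms = dwell_mean_ms,
              conditional_jump = conditional_jump,
              coverage_effects = coverage_effects,
              subject_dwell_sd = subject_dwell_sd,
              smoothness = smoothness, max_abs_corr = max_abs_corr,
              flip_prob = flip_prob, seed = seed)
  class(cfg) <- "cohort_config"
  cfg
}

effect_class_index <- function(name, K) {
  idx <- match(name, sprintf("Ms%d", seq_len(K)))
  if (is.na(idx)) stop_invalid("unknown class '%s' in coverage_effects", name)
  idx
}

#' Simulate a two-group MEG cohort with ground truth
#'
#' Shared templates are drawn once; each subject gets a per-subject
#' semi-Markov model (group base model, optionally jittered by log-normal
#' dwell multipliers), a simulated label sequence, and a rendered recording.
#' When `out_dir` is given, recordings are written in the text+JSON container
#' (see [write_recording()]) together with a JSON manifest.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional output directory.
#' @return list with `recordings` (list of `recording`), `manifest`
#'   (data.frame: subject_id, group, seed, file), `templates`
#'   (`microstate_maps`), `models` (per-subject `transition_model`),
#'   `config`.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  layout <- make_sensor_layout(config$n_sensors)
  templates <- make_templates(layout, config$K,
                              smoothness = config$smoothness,
                              max_abs_corr = config$max_abs_corr,
                              seed = derive_seed(config$seed, 1))
  base <- transition_model(config$K, config$dwell_mean_ms,
                           config$conditional_jump)
  patient_base <- base
  if (length(config$coverage_effects)) {
    for (nm in names(config$coverage_effects)) {
      patient_base <- adjust_model_coverage(
        patient_base, effect_class_index(nm, config$K),
        config$coverage_effects[[nm]])
    }
  }
  groups <- c(rep("patient", config$n_patients),
              rep("control", config$n_controls))
  n_total <- length(groups)
  ids <- sprintf("sub-%02d", seq_len(n_total))
  recs <- vector("list", n_total)
  models <- vector("list", n_total)
  seeds <- numeric(n_total)
  files <- rep(NA_character_, n_total)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_invalid("cannot create output directory '%s'", out_dir)
  }
  for (i in seq_len(n_total)) {
    gbase <- if (groups[i] == "patient") patient_base else base
    s <- derive_seed(config$seed, 100 + i)
    seeds[i] <- s
    dwell <- gbase$dwell_mean_ms
    if (config$subject_dwell_sd > 0) {
      set.seed(derive_seed(config$seed, 500 + i))
      dwell <- dwell * exp(stats::rnorm(config$K, 0, config$subject_dwell_sd))
    }
    mod <- transition_model(config$K, dwell, gbase$conditional_jump)
    models[[i]] <- mod
    lab <- simulate_state_sequence(mod, config$duration_s, config$fs, seed = s)
    recs[[i]] <- render_recording(templates, lab, layout, fs = config$fs,
                                  snr = config$snr,
                                  seed = derive_seed(config$seed, 900 + i),
                                  flip_prob = config$flip_prob)
    if (!is.null(out_dir)) {
      files[i] <- file.path(out_dir, ids[i])
      write_recording(recs[[i]], files[i])
    }
  }
  names(recs) <- ids
  manifest <- data.frame(subject_id = ids, group = groups, seed = seeds,
                         file = files, stringsAsFactors = FALSE)
  out <- list(recordings = recs, manifest = manifest, templates = templates,
              models = models, base_models = list(control = base,
                                                  patient = patient_base),
              config = config)
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(subjects = manifest,
           config = config[setdiff(names(config), "conditional_jump")],
           effects = as.list(config$coverage_effects)),
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

# group-level means/SDs used as simulation defaults for the clinical table
# (two-group demographics plus patient-only headache measures)
clinical_defaults <- function() {
  list(
    both = list(
      age       = list(patient = c(32.64, 7.86), control = c(30.33, 9.22),
                       lower = 18, upper = 60),
      education = list(patient = c(16.04, 2.87), control = c(19.17, 1.89),
                       lower = 0, upper = Inf),
      HAMD24    = list(patient = c(9.08, 8.75), control = c(3.06, 1.56),
                       lower = 0, upper = Inf),
      HAMA14    = list(patient = c(6.88, 5.16), control = c(2.67, 1.03),
                       lower = 0, upper = Inf)),
    sex_female_prob = c(patient = 21 / 25, control = 13 / 18),
    patient_only = list(
      migraine_duration = list(mean = 9.48, sd = 5.43, lower = 0, upper = Inf),
      attack_frequency  = list(mean = 6.84, sd = 7.53, lower = 0, upper = Inf),
      attack_duration   = list(mean = 10.70, sd = 11.42, lower = 0, upper = Inf),
      VAS               = list(mean = 6.32, sd = 0.98, lower = 0, upper = 10),
      HIT6              = list(mean = 65.88, sd = 5.83, lower = 0, upper = 78),
      MIDAS             = list(mean = 17.36, sd = 14.55, lower = 0, upper = Inf))
  )
}

rtruncnorm_inv <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate a per-subject clinical table
#'
#' Clinical scores are drawn per group from (truncated) normal distributions
#' whose default means and SDs reproduce the emulated study's demographic
#' table; headache-specific measures exist only for patients. An optional
#' coupling injects a linear association (target Pearson r) between one
#' clinical column and a supplied per-subject metric, to exercise the
#' correlation-screening stage.
#'
#' @param manifest data.frame with `subject_id` and `group` columns.
#' @param seed RNG seed.
#' @param coupling optional list `list(clinical =, metric =, r =)` where
#'   `metric` is a numeric vector aligned to patient rows (or all rows with
#'   names); `|r| < 1` required.
#' @param params overrides for the default moments (same shape as the
#'   internal defaults; rarely needed).
#' @return data.frame, one row per subject: `subject_id`, `group`, `age`,
#'   `sex`, `education`, `HAMD24`, `HAMA14`, and patient-only
#'   `migraine_duration`, `attack_frequency`, `attack_duration`, `VAS`,
#'   `HIT6`, `MIDAS` (NA for controls).
#' @export
simulate_clinical_table <- function(manifest, seed = 1L, coupling = NULL,
                                    params = clinical_defaults()) {
  set.seed(seed)
  grp <- manifest$group
  n <- nrow(manifest)
  is_pat <- grp == "patient"
  out <- data.frame(subject_id = manifest$subject_id, group = grp,
                    stringsAsFactors = FALSE)
  for (v in names(params$both)) {
    spec <- params$both[[v]]
    x <- numeric(n)
    for (g in c("patient", "control")) {
      sel <- grp == g
      x[sel] <- rtruncnorm_inv(sum(sel), spec[[g]][1], spec[[g]][2],
                               spec$lower, spec$upper)
    }
    out[[v]] <- x
  }
  out$sex <- ifelse(stats::runif(n) <
                      params$sex_female_prob[ifelse(is_pat, "patient",
                                                    "control")],
                    "female", "male")
  for (v in names(params$patient_only)) {
    spec <- params$patient_only[[v]]
    x <- rep(NA_real_, n)
    x[is_pat] <- rtruncnorm_inv(sum(is_pat), spec$mean, spec$sd,
                                spec$lower, spec$upper)
    out[[v]] <- x
  }
  if (!is.null(coupling)) {
    r <- coupling$r
    if (abs(r) >= 1) stop_invalid("coupling target |r| must be < 1")
    v <- coupling$clinical
    metric <- coupling$metric
    sel <- if (v %in% names(params$patient_only)) is_pat else rep(TRUE, n)
    if (length(metric) != sum(sel)) {
      stop_invalid("coupling metric length (%d) != subjects targeted (%d)",
                   length(metric), sum(sel))
    }
    zm <- as.numeric(scale(metric))
    z <- r * zm + sqrt(1 - r^2) * stats::rnorm(length(zm))
    spec <- params$patient_only[[v]] %||% params$both[[v]]
    mu <- spec$mean %||% spec$patient[1]
    sdv <- spec$sd %||% spec$patient[2]
    out[[v]][sel] <- mu + sdv * z
  }
  out
}
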