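# Orchestration: simulate (or load) -> preprocess -> segment -> metrics ->
# stats -> report, fully seeded, with serialized-config provenance.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis with its default: filter settings
#' (1-40 Hz band-pass, 50 Hz notch), bad-channel threshold, spatial-filter
#' variant, clustering controls and K sweep (2-8), backfit threshold, FDR
#' family policy, t-test policy, and the cohort specification.
#'
#' @param cohort a [cohort_config()] describing the simulated cohort.
#' @param filter list: `enabled`, `low`, `high`, `notch`.
#' @param bad_channels list: `enabled`, `z_thresh`.
#' @param spatial_filter list: `enabled`, `k`, `method`
#'   (`"midrange"`/`"mean"`).
#' @param cluster list: `k_min`, `k_max`, `n_restarts`, `max_iter`, `tol`,
#'   `polarity_invariant`; set `k_min == k_max` to skip model selection.
#' @param kneedle_sensitivity Kneedle S parameter.
#' @param backfit list: `min_corr`, `peaks_only`.
#' @param stats list: `covariates`, `family_policy`, `ttest_variant`,
#'   `clinical_cols` (for the Pearson screen).
#' @param clinical_coupling optional coupling spec passed to
#'   [simulate_clinical_table()].
#' @param clinical_params optional moment specification passed to
#'   [simulate_clinical_table()]'s `params`; `"exchangeable"` gives both
#'   groups the control-group moments (covariates independent of group),
#'   the setting used for power/calibration cohorts.
#' @param write_recordings also write every simulated recording to disk?
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            filter = list(enabled = TRUE, low = 1,
                                          high = 40, notch = 50),
                            bad_channels = list(enabled = TRUE,
                                                z_thresh = 3),
                            spatial_filter = list(enabled = TRUE, k = 6,
                                                  method = "midrange"),
                            cluster = list(k_min = 2L, k_max = 8L,
                                           n_restarts = 50L,
                                           max_iter = 500L, tol = 1e-6,
                                           polarity_invariant = TRUE),
                            kneedle_sensitivity = 1,
                            backfit = list(min_corr = 0,
                                           peaks_only = FALSE),
                            stats = list(covariates = c("education",
                                                        "HAMD24", "HAMA14"),
                                         family_policy = "per_type",
                                         ttest_variant = "auto",
                                         clinical_cols = c(
                                           "migraine_duration",
                                           "attack_frequency",
                                           "attack_duration", "VAS",
                                           "HIT6", "MIDAS")),
                            clinical_coupling = NULL,
                            clinical_params = NULL,
                            write_recordings = FALSE,
                            seed = 1L) {
  cfg <- list(cohort = cohort, filter = filter, bad_channels = bad_channels,
              spatial_filter = spatial_filter, cluster = cluster,
              kneedle_sensitivity = kneedle_sensitivity, backfit = backfit,
              stats = stats, clinical_coupling = clinical_coupling,
              clinical_params = clinical_params,
              write_recordings = write_recordings, seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

drop_channels <- function(rec, idx) {
  if (!length(idx)) return(rec)
  keep <- setdiff(seq_len(rec$layout$n_sensors), idx)
  layout <- structure(list(n_sensors = length(keep),
                           positions = rec$layout$positions[keep, ,
                                                            drop = FALSE],
                           names = rec$layout$names[keep]),
                      class = "sensor_layout")
  recording(rec$data[keep, , drop = FALSE], rec$fs, layout,
            truth_labels = rec$truth_labels)
}

# backfit a pooled peak-map matrix against candidate group maps and return
# the GFP-weighted global explained variance
gev_backfit <- function(maps, peak_maps, weights) {
  Xn <- normalize_maps(peak_maps)
  cr <- abs(corr_matrix(Xn, maps$maps))
  best <- cr[cbind(seq_len(nrow(cr)), max.col(cr, ties.method = "first"))]
  degen <- attr(Xn, "degenerate")
  if (length(degen)) best[degen] <- 0
  sum(weights^2 * best^2) / sum(weights^2)
}

#' Segment a cohort of recordings into microstates
#'
#' Two-level procedure: per subject, maps are extracted at GFP peaks and
#' clustered by the polarity-invariant modified k-means; subject maps are
#' pooled and re-clustered at the group level for each K in the sweep, the
#' group GEV-vs-K curve (made non-decreasing by cumulative maximum) is fed
#' to Kneedle to select K, and the selected group maps are backfitted to
#' every sample of every recording. Classes are finally ordered Ms1..MsK by
#' descending total coverage.
#'
#' @param recordings named list of `recording`.
#' @param k_min,k_max K sweep bounds (equal = fixed K, no selection).
#' @param n_restarts,max_iter,tol,polarity_invariant clustering controls.
#' @param kneedle_sensitivity Kneedle S parameter.
#' @param min_corr,peaks_only backfit controls.
#' @param seed RNG seed.
#' @return list: `k_selected`, `k_values`, `gev_curve`, `group_solution`,
#'   `label_seqs` (named, relabelled by coverage), `subject_solutions` (at
#'   the selected K), `peak_counts`.
#' @export
segment_cohort <- function(recordings, k_min = 2L, k_max = 8L,
                           n_restarts = 50L, max_iter = 500L, tol = 1e-6,
                           polarity_invariant = TRUE,
                           kneedle_sensitivity = 1,
                           min_corr = 0, peaks_only = FALSE, seed = 1L) {
  stopifnot(k_min >= 1, k_max >= k_min)
  ids <- names(recordings) %||% sprintf("sub-%02d", seq_along(recordings))
  peaks <- lapply(recordings, function(rec) {
    g <- global_field_power(rec)
    pk <- extract_gfp_peaks(g)
    if (length(pk) < k_max) {
      stop_invalid("recording has %d GFP peaks, fewer than k_max = %d",
                   length(pk), k_max)
    }
    list(maps = t(rec$data[, pk, drop = FALSE]), w = g$values[pk])
  })
  ks <- seq.int(k_min, k_max)
  pooled_peaks <- do.call(rbind, lapply(peaks, `[[`, "maps"))
  pooled_w <- unlist(lapply(peaks, `[[`, "w"), use.names = FALSE)
  subj_sols <- vector("list", length(ks))
  group_sols <- vector("list", length(ks))
  gev <- numeric(length(ks))
  for (i in seq_along(ks)) {
    K <- ks[i]
    subj_sols[[i]] <- lapply(seq_along(peaks), function(s)
      kmeans_microstates(peaks[[s]]$maps, K, weights = peaks[[s]]$w,
                         n_restarts = n_restarts, max_iter = max_iter,
                         tol = tol,
                         seed = derive_seed(seed, 1000 * i + s),
                         polarity_invariant = polarity_invariant))
    group_sols[[i]] <- group_level_maps(subj_sols[[i]], K,
                                        n_restarts = n_restarts,
                                        max_iter = max_iter, tol = tol,
                                        seed = derive_seed(seed, 1000 * i),
                                        polarity_invariant =
                                          polarity_invariant)
    gev[i] <- gev_backfit(group_sols[[i]]$maps, pooled_peaks, pooled_w)
  }
  gev_curve <- cummax(gev)
  if (length(ks) >= 3) {
    k_sel <- kneedle_optimal_k(ks, gev_curve, kneedle_sensitivity)
    if (is.na(k_sel)) {
      warning("no knee found in the GEV curve; using k_max")
      k_sel <- k_max
    }
  } else {
    k_sel <- k_max
  }
  i_sel <- match(k_sel, ks)
  sol <- group_sols[[i_sel]]
  labs <- lapply(recordings, backfit, group_maps = sol$maps,
                 min_corr = min_corr,
                 polarity_invariant = polarity_invariant,
                 peaks_only = peaks_only)
  names(labs) <- ids
  reord <- order_by_coverage(sol, labs)
  list(k_selected = as.integer(k_sel), k_values = ks, gev_curve = gev_curve,
       group_solution = reord$solution, label_seqs = reord$label_seqs,
       subject_solutions = subj_sols[[i_sel]],
       peak_counts = vapply(peaks, function(p) nrow(p$maps), integer(1)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate, preprocess (filtering,
#' bad-channel removal across the cohort, spatial filter), segment,
#' metrics, statistics, report — writing intermediate tables, the
#' serialized configuration and a manifest under `out_dir`. Re-running with
#' the same configuration reproduces every numeric output exactly.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param recordings optional named list of pre-loaded `recording`s plus a
#'   `manifest` attribute; when omitted the cohort is simulated from
#'   `config$cohort`.
#' @return (invisibly) list with `config`, `manifest`, `clinical`,
#'   `segmentation`, `metrics`, `stats_glm`, `stats_logistic`,
#'   `correlations`, `report`, `paths`.
#' @export
run_pipeline <- function(config, out_dir, recordings = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop_invalid("cannot create output directory '%s'", out_dir)
  }
  log_lines <- character(0)
  say <- function(stage, fmt, ...) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ## stage: simulate (or accept supplied recordings)
  if (is.null(recordings)) {
    sim <- run_stage("simulate", simulate_cohort(config$cohort))
    recs <- sim$recordings
    manifest <- sim$manifest
    templates <- sim$templates
    say("simulate", "%d subjects (%d patients / %d controls), seed %s",
        nrow(manifest), sum(manifest$group == "patient"),
        sum(manifest$group == "control"), format(config$seed))
    if (isTRUE(config$write_recordings)) {
      rec_dir <- file.path(out_dir, "recordings")
      dir.create(rec_dir, showWarnings = FALSE)
      for (id in names(recs)) {
        write_recording(recs[[id]], file.path(rec_dir, id))
      }
    }
  } else {
    recs <- recordings
    manifest <- attr(recordings, "manifest")
    if (is.null(manifest)) stop_invalid("supplied recordings need a manifest")
    templates <- NULL
    say("simulate", "skipped: %d recordings supplied", length(recs))
  }
  cparams <- config$clinical_params
  if (identical(cparams, "exchangeable")) {
    cparams <- clinical_defaults()
    for (v in names(cparams$both)) {
      cparams$both[[v]]$patient <- cparams$both[[v]]$control
    }
    cparams$sex_female_prob["patient"] <- cparams$sex_female_prob["control"]
  }
  clinical <- run_stage("clinical",
    simulate_clinical_table(manifest,
                            seed = derive_seed(config$seed, 7),
                            coupling = config$clinical_coupling,
                            params = cparams %||% clinical_defaults()))

  ## stage: preprocess
  recs <- run_stage("preprocess", {
    if (isTRUE(config$filter$enabled)) {
      recs <- lapply(recs, bandpass_notch, low = config$filter$low,
                     high = config$filter$high, notch = config$filter$notch)
      say("preprocess", "band-pass %g-%g Hz, notch %s Hz",
          config$filter$low, config$filter$high,
          format(config$filter$notch))
    }
    if (isTRUE(config$bad_channels$enabled)) {
      reports <- lapply(recs, detect_bad_channels,
                        z_thresh = config$bad_channels$z_thresh)
      bad <- sort(unique(unlist(lapply(reports, function(r)
        which(r$flag)))))
      if (length(bad)) {
        say("preprocess", "dropping %d bad channel(s) cohort-wide: %s",
            length(bad),
            paste(recs[[1]]$layout$names[bad], collapse = ", "))
        recs <- lapply(recs, drop_channels, idx = bad)
      } else {
        say("preprocess", "no bad channels flagged at |z| > %g",
            config$bad_channels$z_thresh)
      }
    }
    if (isTRUE(config$spatial_filter$enabled)) {
      recs <- lapply(recs, spatial_neighbor_filter,
                     k = config$spatial_filter$k,
                     method = config$spatial_filter$method)
      say("preprocess", "spatial %s filter, k = %d",
          config$spatial_filter$method, config$spatial_filter$k)
    }
    recs
  })

  ## stage: segment
  seg <- run_stage("segment",
    segment_cohort(recs,
                   k_min = config$cluster$k_min,
                   k_max = config$cluster$k_max,
                   n_restarts = config$cluster$n_restarts,
                   max_iter = config$cluster$max_iter,
                   tol = config$cluster$tol,
                   polarity_invariant = config$cluster$polarity_invariant,
                   kneedle_sensitivity = config$kneedle_sensitivity,
                   min_corr = config$backfit$min_corr,
                   peaks_only = config$backfit$peaks_only,
                   seed = derive_seed(config$seed, 11)))
  say("segment", "selected K = %d (GEV %.3f at K = %s)", seg$k_selected,
      seg$gev_curve[match(seg$k_selected, seg$k_values)],
      paste(seg$k_values, collapse = ","))

  ## stage: metrics
  metrics <- run_stage("metrics",
    cohort_metrics(seg$label_seqs, manifest, clinical))
  say("metrics", "%d subjects x %d classes", nrow(metrics), seg$k_selected)

  ## stage: stats
  stats_glm <- run_stage("stats",
    group_comparison_table(metrics,
                           covariates = config$stats$covariates,
                           family_policy = config$stats$family_policy))
  sig <- stats_glm$parameter[stats_glm$significant]
  stats_logistic <- run_stage("stats", {
    if (length(sig)) {
      lg <- do.call(rbind, lapply(sig, logistic_complementary,
                                  metrics = metrics,
                                  covariates = config$stats$covariates))
      lg$p_fdr <- fdr_bh(ifelse(is.na(lg$p), 1, lg$p),
                         fdr_family_of(lg$parameter,
                                       config$stats$family_policy))
      lg
    } else NULL
  })
  cl_cols <- intersect(config$stats$clinical_cols, names(metrics))
  param_cols <- grep("^(coverage|occurrence|duration)_Ms\\d+$|^p_Ms\\d+_to_Ms\\d+$",
                     names(metrics), value = TRUE)
  correlations <- run_stage("stats",
    suppressWarnings(pearson_screen(metrics, cl_cols, param_cols)))
  say("stats", "%d GLM contrasts (%d significant at FDR 0.05), %d correlations",
      nrow(stats_glm), length(sig), nrow(correlations))

  ## stage: report + artifacts
  results <- list(config = config, manifest = manifest, clinical = clinical,
                  layout = recs[[1]]$layout,
                  segmentation = seg, metrics = metrics,
                  stats_glm = stats_glm, stats_logistic = stats_logistic,
                  correlations = correlations, templates = templates,
                  log = log_lines)
  rep_lines <- run_stage("report", pipeline_report(results))
  results$report <- rep_lines

  paths <- list(
    config = file.path(out_dir, "config.json"),
    manifest = file.path(out_dir, "manifest.json"),
    metrics = file.path(out_dir, "metrics.tsv"),
    stats_glm = file.path(out_dir, "stats_glm.tsv"),
    correlations = file.path(out_dir, "correlations.tsv"),
    group_maps = file.path(out_dir, "group_maps.tsv"),
    report = file.path(out_dir, "report.txt"),
    log = file.path(out_dir, "pipeline.log"))
  write_config(config, paths$config)
  jsonlite::write_json(list(subjects = manifest,
                            config_hash = config_hash(config)),
                       paths$manifest, auto_unbox = TRUE, digits = NA,
                       null = "null")
  data.table::fwrite(metrics, paths$metrics, sep = "\t")
  data.table::fwrite(stats_glm, paths$stats_glm, sep = "\t")
  if (!is.null(stats_logistic)) {
    data.table::fwrite(stats_logistic,
                       file.path(out_dir, "stats_logistic.tsv"), sep = "\t")
  }
  data.table::fwrite(correlations, paths$correlations, sep = "\t")
  gm <- data.table::as.data.table(seg$group_solution$maps$maps)
  gm <- cbind(data.table::data.table(
    class = seg$group_solution$maps$class_labels), gm)
  data.table::fwrite(gm, paths$group_maps, sep = "\t")
  writeLines(rep_lines, paths$report)
  writeLines(log_lines, paths$log)
  results$paths <- paths
  invisible(results)
}
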