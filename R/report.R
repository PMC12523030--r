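# Human-readable run summary: demographics with tests, parameter panels
# with FDR-significance stars, exploratory correlations, and the
# serialized-config hash for provenance.

fmt_mean_sd <- function(x) sprintf("%.2f ± %.2f",
                                   mean(x, na.rm = TRUE),
                                   stats::sd(x, na.rm = TRUE))

#' Build the pipeline's human-readable report
#'
#' @param results the list produced by [run_pipeline()] (config, clinical,
#'   metrics, stats tables, segmentation).
#' @return character vector of report lines.
#' @export
pipeline_report <- function(results) {
  cfg <- results$config
  clin <- results$clinical
  met <- results$metrics
  seg <- results$segmentation
  glm <- results$stats_glm
  K <- seg$k_selected
  cls <- sprintf("Ms%d", seq_len(K))
  pat <- clin$group == "patient"
  lines <- c(
    "MEG microstate analysis report",
    sprintf("config hash: %s", config_hash(cfg)),
    sprintf("subjects: %d patients, %d controls", sum(pat), sum(!pat)),
    sprintf("selected number of classes: K = %d (GEV %.2f%%)", K,
            100 * seg$gev_curve[match(K, seg$k_values)]),
    "",
    "Demographics and clinical scores (mean ± SD, group test)")
  ttv <- cfg$stats$ttest_variant %||% "auto"
  for (v in c("age", "education", "HAMD24", "HAMA14")) {
    g1 <- clin[[v]][pat]
    g2 <- clin[[v]][!pat]
    tt <- ttest_from_summary(mean(g1), stats::sd(g1), length(g1),
                             mean(g2), stats::sd(g2), length(g2),
                             variant = ttv)
    lines <- c(lines, sprintf("  %-10s %s vs %s  p = %.3g (%s t)", v,
                              fmt_mean_sd(g1), fmt_mean_sd(g2), tt$p,
                              tt$variant))
  }
  n_f <- c(sum(clin$sex[pat] == "female"), sum(clin$sex[!pat] == "female"))
  fp <- fisher_exact_2x2(n_f[1], sum(pat) - n_f[1],
                         n_f[2], sum(!pat) - n_f[2])
  lines <- c(lines, sprintf(
    "  %-10s %d/%d vs %d/%d female  p = %.3g (Fisher exact)", "sex",
    n_f[1], sum(pat), n_f[2], sum(!pat), fp), "")

  star <- function(param) {
    row <- glm[glm$parameter == param, ]
    if (nrow(row) == 1 && isTRUE(row$significant)) " *" else ""
  }
  for (type in c("coverage", "occurrence", "duration")) {
    unit <- c(coverage = "%", occurrence = "/s", duration = "ms")[[type]]
    lines <- c(lines, sprintf("Microstate %s (%s; patients vs controls)",
                              type, unit))
    for (k in cls) {
      col <- paste0(type, "_", k)
      lines <- c(lines, sprintf("  %-4s %s vs %s%s", k,
                                fmt_mean_sd(met[[col]][met$group == "patient"]),
                                fmt_mean_sd(met[[col]][met$group == "control"]),
                                star(col)))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "Transition probabilities (significant rows only)")
  tr_cols <- grep("^p_Ms\\d+_to_Ms\\d+$", names(met), value = TRUE)
  any_tr <- FALSE
  for (col in tr_cols) {
    if (nzchar(star(col))) {
      any_tr <- TRUE
      lines <- c(lines, sprintf("  %-16s %s vs %s *", col,
                                fmt_mean_sd(met[[col]][met$group == "patient"]),
                                fmt_mean_sd(met[[col]][met$group == "control"])))
    }
  }
  if (!any_tr) lines <- c(lines, "  (none significant at FDR 0.05)")
  lines <- c(lines, "")
  if (!is.null(results$correlations) && nrow(results$correlations)) {
    sigc <- results$correlations[results$correlations$p < 0.05, ,
                                 drop = FALSE]
    lines <- c(lines,
               "Exploratory Pearson correlations (patients, uncorrected p < 0.05)")
    if (nrow(sigc)) {
      for (i in seq_len(nrow(sigc))) {
        lines <- c(lines, sprintf("  %s ~ %s: r = %.3f, p = %.3g, n = %d",
                                  sigc$clinical[i], sigc$parameter[i],
                                  sigc$r[i], sigc$p[i], sigc$n[i]))
      }
    } else {
      lines <- c(lines, "  (none)")
    }
  }
  lines
}
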