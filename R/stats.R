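# Group-level statistics: t-tests from printed summaries, Fisher's exact
# test by hypergeometric enumeration, normality testing, covariate-adjusted
# GLM group contrasts with BH-FDR families, E-value sensitivity analysis,
# complementary logistic regression, and exploratory Pearson screening.

#' Two-sample t-test from summary statistics
#'
#' Classical pooled or Welch (Satterthwaite) t-test computed directly from
#' group means, SDs, and sizes — the form needed to reproduce demographic
#' comparisons from a published summary table. The `"auto"` policy uses
#' Welch when the variance ratio exceeds 4 and pooled otherwise.
#'
#' @param mean1,sd1,n1 first group (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 second group.
#' @param variant `"auto"`, `"pooled"`, or `"welch"`.
#' @return list: `t`, `df`, `p` (two-sided), `estimate` (mean1 - mean2),
#'   `se`, `variant`.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               variant = c("auto", "pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop_invalid("both groups need n >= 2")
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) {
      return(list(t = 0, df = n1 + n2 - 2, p = 1, estimate = 0, se = 0,
                  variant = variant))
    }
    stop_invalid("degenerate input: zero SD in both groups, unequal means")
  }
  if (sd1 == 0 || sd2 == 0) stop_invalid("degenerate input: zero SD")
  if (variant == "auto") {
    vr <- max(sd1, sd2)^2 / min(sd1, sd2)^2
    variant <- if (vr > 4) "welch" else "pooled"
  }
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       estimate = mean1 - mean2, se = se, variant = variant)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by exact hypergeometric enumeration: the sum of probabilities
#' of all tables with the observed margins whose point probability does not
#' exceed that of the observed table (absolute tie tolerance 1e-12). An
#' empty margin yields p = 1.
#'
#' @param a,b,c,d cell counts of the table \code{rbind(c(a, b), c(c, d))}.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_invalid("cell counts must be non-negative integers")
  }
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs + 1e-12])
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard routine with explicit domain checks
#' (3 <= n <= 5000, non-constant input).
#'
#' @param x numeric sample.
#' @return list: `W`, `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3 || n > 5000) stop_invalid("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop_invalid("degenerate input: constant sample")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' E-value sensitivity analysis for a continuous group contrast
#'
#' The adjusted mean difference is standardised (d = estimate /
#' residual SD), converted to an approximate risk ratio RR = exp(0.91 d)
#' (taken away from the null), and transformed by
#' E = RR + sqrt(RR (RR - 1)). The lower control limit applies the same
#' transform to the 95% confidence bound of RR closer to the null
#' (from d +/- 1.96 se / residual SD); if the interval crosses the null the
#' LCL is 1.
#'
#' @param estimate adjusted group difference (outcome units).
#' @param se standard error of the estimate.
#' @param residual_sd residual SD of the outcome model (> 0).
#' @param conf_level confidence level for the LCL bound.
#' @return list: `d`, `rr`, `e_value`, `e_value_lcl`.
#' @export
evalue_sensitivity <- function(estimate, se, residual_sd,
                               conf_level = 0.95) {
  if (residual_sd <= 0) stop_invalid("residual_sd must be positive")
  evalue_of_rr <- function(rr) {
    if (rr < 1) rr <- 1 / rr
    if (rr == 1) return(1)
    rr + sqrt(rr * (rr - 1))
  }
  d <- estimate / residual_sd
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  d_lo <- d - z * se / residual_sd
  d_hi <- d + z * se / residual_sd
  rr <- exp(0.91 * d)
  e_value <- evalue_of_rr(rr)
  near_null_bound <- if (d >= 0) exp(0.91 * d_lo) else exp(0.91 * d_hi)
  crosses <- (d_lo <= 0 && d_hi >= 0)
  e_lcl <- if (crosses) 1 else evalue_of_rr(near_null_bound)
  list(d = d, rr = rr, e_value = e_value, e_value_lcl = e_lcl)
}

#' Covariate-adjusted group comparison of one microstate parameter
#'
#' Gaussian identity-link linear model
#' `outcome ~ group + covariates`, fitted by least squares; the group
#' coefficient (patient minus control), its standard error, and a two-sided
#' p from the t distribution with residual df are returned together with
#' the E-value sensitivity quantities.
#'
#' @param metrics a metrics/clinical data.frame with a `group` column
#'   (`"patient"` / `"control"`).
#' @param outcome outcome column name.
#' @param covariates covariate column names (default: education, HAMD24,
#'   HAMA14); use `character(0)` for an unadjusted contrast.
#' @return one-row data.frame: `parameter`, `estimate`, `se`, `t`, `df`,
#'   `p`, `d`, `rr`, `e_value`, `e_value_lcl`.
#' @export
glm_group_comparison <- function(metrics, outcome,
                                 covariates = c("education", "HAMD24",
                                                "HAMA14")) {
  need <- c(outcome, covariates, "group")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stop_invalid("missing column(s): %s",
                                 paste(miss, collapse = ", "))
  dat <- metrics[, need, drop = FALSE]
  if (anyNA(dat)) stop_invalid("missing values in outcome or covariates")
  dat$group <- factor(dat$group, levels = c("control", "patient"))
  if (any(table(dat$group) < 2)) stop_invalid("need >= 2 subjects per group")
  fml <- stats::reformulate(c("group", covariates), response = outcome)
  fit <- stats::lm(fml, data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_invalid("rank-deficient design; collinear term(s): %s",
                 paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients["grouppatient", ]
  rsd <- sm$sigma
  ev <- evalue_sensitivity(co[["Estimate"]], co[["Std. Error"]], rsd)
  data.frame(parameter = outcome, estimate = co[["Estimate"]],
             se = co[["Std. Error"]], t = co[["t value"]],
             df = fit$df.residual, p = co[["Pr(>|t|)"]],
             d = ev$d, rr = ev$rr, e_value = ev$e_value,
             e_value_lcl = ev$e_value_lcl, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment within families
#'
#' Step-up adjusted p-values, computed independently within each family and
#' returned in input order.
#'
#' @param p p-values in [0, 1].
#' @param family optional family label per p-value (default: one family).
#' @return adjusted p-values.
#' @export
fdr_bh <- function(p, family = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_invalid("p-values outside [0, 1]")
  if (is.null(family)) return(stats::p.adjust(p, method = "BH"))
  if (length(family) != length(p)) stop_invalid("family length != p length")
  out <- p
  for (f in unique(family)) {
    idx <- which(family == f)
    out[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  out
}

# family label for the default per-parameter-type FDR policy
fdr_family_of <- function(parameter, policy = c("per_type", "global")) {
  policy <- match.arg(policy)
  if (policy == "global") return(rep("all", length(parameter)))
  fam <- sub("_Ms\\d+$", "", parameter)            # coverage/occurrence/duration
  tr <- grepl("^p_Ms\\d+_to_Ms\\d+$", parameter)
  fam[tr] <- sub("^p_(Ms\\d+)_to_Ms\\d+$", "trans_from_\\1", parameter[tr])
  fam
}

#' Group comparison across all microstate parameters with FDR
#'
#' Runs [glm_group_comparison()] on every supplied parameter column and
#' adjusts p-values by Benjamini-Hochberg within families. Default family
#' policy (`"per_type"`): one family per parameter type — coverage,
#' occurrence, duration (each across the K classes) — and one family per
#' transition-source row; `"global"` pools everything.
#'
#' @param metrics a `metrics_table` (with clinical covariates joined).
#' @param parameters parameter column names; default: every
#'   coverage_/occurrence_/duration_/p_* column.
#' @param covariates covariate columns for adjustment.
#' @param family_policy `"per_type"` or `"global"`.
#' @return data.frame of [glm_group_comparison()] rows plus `family`,
#'   `p_fdr`, `significant` (p_fdr < 0.05).
#' @export
group_comparison_table <- function(metrics, parameters = NULL,
                                   covariates = c("education", "HAMD24",
                                                  "HAMA14"),
                                   family_policy = c("per_type", "global")) {
  family_policy <- match.arg(family_policy)
  parameters <- parameters %||% grep(
    "^(coverage|occurrence|duration)_Ms\\d+$|^p_Ms\\d+_to_Ms\\d+$",
    names(metrics), value = TRUE)
  res <- do.call(rbind, lapply(parameters, function(p)
    glm_group_comparison(metrics, p, covariates)))
  res$family <- fdr_family_of(res$parameter, family_policy)
  res$p_fdr <- fdr_bh(res$p, res$family)
  res$significant <- res$p_fdr < 0.05
  rownames(res) <- NULL
  res
}

#' Complementary logistic regression for one parameter
#'
#' Maximum-likelihood logistic regression `group ~ parameter + covariates`;
#' Wald p for the parameter coefficient. Complete or quasi-separation is
#' detected (non-convergence, huge coefficient/SE, or fitted probabilities
#' pinned at 0/1) and reported as a flagged result without an estimate.
#'
#' @param metrics metrics/clinical data.frame with a binary `group` column.
#' @param parameter parameter column name.
#' @param covariates covariate column names.
#' @return one-row data.frame: `parameter`, `coef`, `odds_ratio`, `se`,
#'   `p`, `separation` (logical), `message`.
#' @export
logistic_complementary <- function(metrics, parameter,
                                   covariates = c("education", "HAMD24",
                                                  "HAMA14")) {
  need <- c(parameter, covariates, "group")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stop_invalid("missing column(s): %s",
                                 paste(miss, collapse = ", "))
  dat <- metrics[, need, drop = FALSE]
  dat$y <- as.integer(dat$group == "patient")
  fml <- stats::reformulate(c(parameter, covariates), response = "y")
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- summary(fit)$coefficients[parameter, ]
  sep <- warned || !fit$converged ||
    abs(co[["Estimate"]]) > 20 / stats::sd(dat[[parameter]]) ||
    co[["Std. Error"]] > 1e3
  if (sep) {
    return(data.frame(parameter = parameter, coef = NA_real_,
                      odds_ratio = NA_real_, se = NA_real_, p = NA_real_,
                      separation = TRUE,
                      message = "complete or quasi-separation detected",
                      stringsAsFactors = FALSE))
  }
  data.frame(parameter = parameter, coef = co[["Estimate"]],
             odds_ratio = exp(co[["Estimate"]]), se = co[["Std. Error"]],
             p = co[["Pr(>|z|)"]], separation = FALSE, message = "",
             stringsAsFactors = FALSE)
}

#' Exploratory Pearson correlation screen (patient group)
#'
#' Pearson r with a two-sided t-based p (n - 2 df) for every clinical x
#' parameter pair, computed within the patient group only. P-values are
#' reported uncorrected and flagged exploratory; zero-variance or
#' too-small-n pairs are omitted with a warning.
#'
#' @param metrics metrics table with clinical columns joined.
#' @param clinical_cols clinical column names.
#' @param parameter_cols microstate parameter column names.
#' @return data.frame (`clinical`, `parameter`, `r`, `p`, `n`,
#'   `exploratory`).
#' @export
pearson_screen <- function(metrics, clinical_cols, parameter_cols) {
  pat <- metrics[metrics$group == "patient", , drop = FALSE]
  rows <- list()
  for (cl in clinical_cols) for (pm in parameter_cols) {
    x <- pat[[cl]]
    y <- pat[[pm]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3) {
      warning(sprintf("skipping %s vs %s: fewer than 3 complete pairs",
                      cl, pm))
      next
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning(sprintf("skipping %s vs %s: zero variance", cl, pm))
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    rows[[length(rows) + 1L]] <-
      data.frame(clinical = cl, parameter = pm,
                 r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
                 exploratory = TRUE, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(clinical = character(0), parameter = character(0),
                      r = numeric(0), p = numeric(0), n = integer(0),
                      exploratory = logical(0)))
  }
  do.call(rbind, rows)
}
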