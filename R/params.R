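# The four microstate parameters: mean duration (ms), occurrence per
# second, coverage (%), and the run-level transition-probability matrix.

label_runs <- function(ls) {
  lab <- ls$labels
  lab[is.na(lab)] <- 0L           # sentinel for unassigned stretches
  r <- rle(lab)
  list(values = r$values, lengths = r$lengths)
}

#' Per-class duration, occurrence, and coverage
#'
#' Runs are maximal constant-label segments. For class k:
#' duration_ms = mean run length x 1000 / fs; occurrence_per_s = number of
#' runs / assigned time in seconds; coverage_pct = 100 x samples of k /
#' assigned samples. Classes absent from the sequence get zeros. These
#' satisfy the exact identity coverage/100 = occurrence x duration / 1000.
#'
#' @param ls a `label_sequence` with at least one assigned sample.
#' @return data.frame: `class` (Ms1..MsK), `duration_ms`,
#'   `occurrence_per_s`, `coverage_pct`.
#' @export
microstate_metrics <- function(ls) {
  K <- ls$K
  assigned <- sum(!is.na(ls$labels))
  if (assigned == 0) stop_invalid("no assigned samples in sequence")
  r <- label_runs(ls)
  keep <- r$values != 0L
  vals <- r$values[keep]
  lens <- r$lengths[keep]
  n_runs <- tabulate(vals, nbins = K)
  n_samp <- vapply(seq_len(K), function(k) sum(lens[vals == k]), numeric(1))
  dur <- ifelse(n_runs > 0, n_samp / pmax(n_runs, 1) * 1000 / ls$fs, 0)
  occ <- n_runs / (assigned / ls$fs)
  cov <- 100 * n_samp / assigned
  data.frame(class = sprintf("Ms%d", seq_len(K)), duration_ms = dur,
             occurrence_per_s = occ, coverage_pct = cov,
             stringsAsFactors = FALSE)
}

#' Run-level transition probability matrix
#'
#' The sequence is collapsed to its run-class sequence; ordered pairs
#' (i -> j), i != j, are counted and each row is normalised by its departure
#' count. Self-transitions are structurally zero; unassigned runs break
#' adjacency (no transition is counted across them); rows without departures
#' are all zero and reported in the `zero_rows` attribute.
#'
#' @param ls a `label_sequence`.
#' @return K x K matrix (rows = source class) with attributes `departures`
#'   (count matrix) and `zero_rows`. A sequence with a single run yields an
#'   all-zero matrix with a warning.
#' @export
transition_probabilities <- function(ls) {
  K <- ls$K
  r <- label_runs(ls)
  v <- r$values
  lab_names <- sprintf("Ms%d", seq_len(K))
  counts <- matrix(0, K, K, dimnames = list(lab_names, lab_names))
  if (length(v) >= 2) {
    from <- v[-length(v)]
    to <- v[-1]
    ok <- from != 0L & to != 0L
    if (any(ok)) {
      tab <- table(factor(from[ok], levels = seq_len(K)),
                   factor(to[ok], levels = seq_len(K)))
      counts <- counts + unclass(tab)
    }
  }
  dimnames(counts) <- list(lab_names, lab_names)
  dep <- rowSums(counts)
  if (all(dep == 0)) {
    warning("no transitions in sequence; returning an all-zero matrix")
  }
  P <- counts / ifelse(dep > 0, dep, 1)
  attr(P, "departures") <- counts
  attr(P, "zero_rows") <- which(dep == 0)
  P
}

#' Cohort-wide metrics table
#'
#' One row per subject with stable wide column naming: `coverage_Ms1` ...
#' `coverage_MsK`, `occurrence_Ms*`, `duration_Ms*`, and flattened
#' transition probabilities `p_MsI_to_MsJ` (I != J). Group labels come from
#' the manifest; clinical columns are joined when a clinical table is
#' supplied.
#'
#' @param label_seqs named list of `label_sequence`, one per subject.
#' @param manifest data.frame with `subject_id` and `group`; every sequence
#'   name must appear in it.
#' @param clinical optional clinical table (from
#'   [simulate_clinical_table()] or equivalent) keyed by `subject_id`.
#' @return data.frame (class `metrics_table`).
#' @export
cohort_metrics <- function(label_seqs, manifest, clinical = NULL) {
  ids <- names(label_seqs)
  if (is.null(ids)) stop_invalid("label_seqs must be a named list")
  missing <- setdiff(ids, manifest$subject_id)
  if (length(missing)) {
    stop_invalid("subject(s) missing from manifest: %s",
                 paste(missing, collapse = ", "))
  }
  Ks <- vapply(label_seqs, function(x) x$K, integer(1))
  if (length(unique(Ks)) != 1) stop_invalid("inconsistent K across subjects")
  K <- Ks[1]
  cls <- sprintf("Ms%d", seq_len(K))
  rows <- lapply(ids, function(id) {
    ls <- label_seqs[[id]]
    m <- microstate_metrics(ls)
    P <- suppressWarnings(transition_probabilities(ls))
    out <- c(stats::setNames(m$coverage_pct, paste0("coverage_", cls)),
             stats::setNames(m$occurrence_per_s, paste0("occurrence_", cls)),
             stats::setNames(m$duration_ms, paste0("duration_", cls)))
    for (i in seq_len(K)) for (j in seq_len(K)) {
      if (i != j) out[[sprintf("p_%s_to_%s", cls[i], cls[j])]] <- P[i, j]
    }
    out
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(data.frame(subject_id = ids,
                          group = manifest$group[match(ids,
                                                       manifest$subject_id)],
                          stringsAsFactors = FALSE),
               tab)
  if (!is.null(clinical)) {
    add <- clinical[match(ids, clinical$subject_id),
                    setdiff(names(clinical), c("subject_id", "group")),
                    drop = FALSE]
    tab <- cbind(tab, add)
  }
  rownames(tab) <- NULL
  class(tab) <- c("metrics_table", "data.frame")
  tab
}
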