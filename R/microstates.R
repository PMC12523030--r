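# Microstate segmentation: GFP, GFP-peak map extraction, polarity-invariant
# modified k-means, global explained variance, kneedle model selection,
# two-level (grand-mean) clustering, and backfitting.
#
# The canonical microstate k-means differs from ordinary k-means in two
# ways: similarity is the (absolute) spatial Pearson correlation between
# topographies, so a map and its polarity reversal belong to the same class,
# and the centroid update is the dominant eigenvector of the assigned maps'
# outer-product sum rather than their arithmetic mean.

#' Global field power
#'
#' GFP at frame t is the standard deviation of the field across sensors
#' (population convention, divisor n).
#'
#' @param rec a `recording` with >= 2 channels.
#' @return object of class `gfp_series`: list with `values` (length
#'   n_samples, non-negative) and `fs`.
#' @export
global_field_power <- function(rec) {
  x <- rec$data
  if (nrow(x) < 2) stop_invalid("GFP needs at least 2 channels")
  m <- colMeans(x)
  v <- colMeans(x^2) - m^2
  structure(list(values = sqrt(pmax(v, 0)), fs = rec$fs),
            class = "gfp_series")
}

#' Indices of GFP peaks
#'
#' Strict local maxima (greater than both neighbouring values); a plateau
#' maximum contributes its leftmost sample; endpoints are never peaks.
#'
#' @param gfp a `gfp_series` or numeric vector (length >= 3).
#' @return integer vector of peak sample indices (possibly empty).
#' @export
extract_gfp_peaks <- function(gfp) {
  v <- if (inherits(gfp, "gfp_series")) gfp$values else as.numeric(gfp)
  if (length(v) < 3) stop_invalid("need at least 3 samples")
  r <- rle(v)
  nr <- length(r$lengths)
  if (nr < 3) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-nr]))
  mid <- 2:(nr - 1)
  is_peak <- r$values[mid] > r$values[mid - 1] & r$values[mid] > r$values[mid + 1]
  starts[mid][is_peak]
}

#' Spatial correlation between two topographies
#'
#' Pearson correlation across sensors; with `polarity_invariant = TRUE`
#' (default, the MEG microstate convention) the absolute value is returned.
#'
#' @param a,b numeric vectors of equal length with non-zero variance.
#' @param polarity_invariant return `|r|`?
#' @return scalar correlation.
#' @export
spatial_correlation <- function(a, b, polarity_invariant = TRUE) {
  if (length(a) != length(b)) stop_invalid("maps differ in length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_invalid("undefined correlation: zero-variance input")
  }
  r <- stats::cor(a, b)
  if (polarity_invariant) abs(r) else r
}

# correlation of every (centred, normalised) row of Xn with every map row of
# Mn; both inputs must already be centred + unit norm
corr_matrix <- function(Xn, Mn) tcrossprod(Xn, Mn)

#' Polarity-invariant modified k-means over topographic maps
#'
#' Maps (typically extracted at GFP peaks) are assigned to the class with
#' maximal squared spatial correlation; each centroid is updated to the
#' dominant eigenvector of the weighted outer-product sum of its assigned
#' maps. Iterations stop when the relative change in global explained
#' variance (GEV) falls below `tol` or after `max_iter` sweeps; the best of
#' `n_restarts` random initialisations (by GEV) is returned. With
#' `polarity_invariant = FALSE` a plain signed k-means (mean centroid,
#' signed-correlation assignment) is used instead.
#'
#' @param peak_maps n_maps x n_sensors matrix (rows are topographies).
#' @param K number of classes (<= number of maps).
#' @param weights optional per-map weights (e.g. GFP at the peak); default 1.
#' @param n_restarts,max_iter,tol algorithm controls.
#' @param seed RNG seed (restart initialisations are drawn sequentially from
#'   this seed, so results are reproducible).
#' @param polarity_invariant treat a map and its reversal as the same class?
#' @return object of class `cluster_solution`: list with `maps`
#'   (`microstate_maps`), `assignment` (class per input map), `gev`, `K`,
#'   `n_restarts`, `converged`.
#' @export
kmeans_microstates <- function(peak_maps, K, weights = NULL,
                               n_restarts = 50L, max_iter = 500L,
                               tol = 1e-6, seed = 1L,
                               polarity_invariant = TRUE) {
  X <- as.matrix(peak_maps)
  P <- nrow(X)
  if (P < K) stop_invalid("fewer maps (%d) than clusters (%d)", P, K)
  w <- weights %||% rep(1, P)
  if (length(w) != P) stop_invalid("weights length != number of maps")
  Xn <- normalize_maps(X)
  keep <- setdiff(seq_len(P), attr(Xn, "degenerate"))
  if (length(keep) < K) stop_invalid("too few non-degenerate maps")
  w2 <- w^2
  set.seed(seed)
  best <- list(gev = -Inf)
  for (rs in seq_len(n_restarts)) {
    M <- Xn[sample(keep, K), , drop = FALSE]
    gev_prev <- -Inf
    converged <- FALSE
    assign <- integer(P)
    sel2 <- numeric(P)
    for (it in seq_len(max_iter)) {
      cr <- corr_matrix(Xn, M)
      score <- if (polarity_invariant) cr^2 else cr
      assign <- max.col(score, ties.method = "first")
      sel <- cr[cbind(seq_len(P), assign)]
      sel2 <- sel^2
      gev <- sum(w2 * sel2) / sum(w2)
      # re-seed empty clusters from the worst-explained map
      empties <- setdiff(seq_len(K), unique(assign))
      if (length(empties)) {
        worst <- order(sel2)
        for (j in seq_along(empties)) {
          M[empties[j], ] <- Xn[worst[j], ]
        }
        next
      }
      if (is.finite(gev_prev) &&
          abs(gev - gev_prev) <= tol * max(abs(gev_prev), 1e-12)) {
        converged <- TRUE
        break
      }
      gev_prev <- gev
      for (k in seq_len(K)) {
        idx <- which(assign == k)
        if (polarity_invariant) {
          S <- crossprod(Xn[idx, , drop = FALSE] * w[idx])
          e <- eigen(S, symmetric = TRUE)$vectors[, 1]
        } else {
          e <- colSums(Xn[idx, , drop = FALSE] * w[idx])
        }
        e <- e - mean(e)
        nrm <- sqrt(sum(e^2))
        if (nrm > 1e-300) M[k, ] <- e / nrm
      }
    }
    if (gev > best$gev) {
      best <- list(M = M, assignment = assign, gev = gev,
                   converged = converged)
    }
  }
  structure(list(maps = microstate_maps(best$M),
                 assignment = best$assignment, gev = best$gev,
                 K = as.integer(K), n_restarts = as.integer(n_restarts),
                 converged = best$converged),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> K = %d, GEV = %.4f (%s, %d restarts)\n",
              x$K, x$gev,
              if (x$converged) "converged" else "not converged",
              x$n_restarts))
  invisible(x)
}

#' Global explained variance of labelled maps
#'
#' GEV = sum_t (g_t * C(x_t, a_{L(t)}))^2 / sum_t g_t^2, where g_t is the
#' frame's GFP (or supplied weight), C the polarity-invariant spatial
#' correlation and a_{L(t)} the class map assigned to frame t. Unassigned
#' frames (`NA` labels) contribute zero to the numerator but remain in the
#' denominator.
#'
#' @param maps a `microstate_maps` (or matrix of class maps in rows).
#' @param data_maps frames/maps in rows (n x n_sensors).
#' @param labels integer class per row of `data_maps` (NA = unassigned).
#' @param weights per-row GFP weights; default: each row's own GFP
#'   (population SD across sensors).
#' @return GEV fraction in [0, 1].
#' @export
global_explained_variance <- function(maps, data_maps, labels,
                                      weights = NULL) {
  M <- if (inherits(maps, "microstate_maps")) maps$maps else
    normalize_maps(as.matrix(maps))
  X <- as.matrix(data_maps)
  if (is.null(weights)) {
    mu <- rowMeans(X)
    weights <- sqrt(pmax(rowMeans(X^2) - mu^2, 0))
  }
  g2 <- weights^2
  if (sum(g2) <= 0) stop_invalid("undefined GEV: all weights zero")
  Xn <- normalize_maps(X)
  ok <- !is.na(labels) & !(seq_len(nrow(X)) %in% attr(Xn, "degenerate"))
  num <- 0
  if (any(ok)) {
    cr <- rowSums(Xn[ok, , drop = FALSE] * M[labels[ok], , drop = FALSE])
    num <- sum(g2[ok] * cr^2)
  }
  num / sum(g2)
}

#' Kneedle knee-point selection on a concave increasing curve
#'
#' Discrete Kneedle: both axes are min-max normalised, the difference curve
#' d_i = y_i - x_i is formed, and local maxima of d exceeding their
#' sensitivity-adjusted threshold (the difference curve must drop below
#' `d_max - sensitivity * mean(diff(x_norm))` before the next local maximum)
#' are knee candidates; the first qualifying k is returned.
#'
#' @param k_values strictly increasing x values (>= 3 points).
#' @param gev_values y values (non-decreasing; enforce upstream).
#' @param sensitivity Kneedle S parameter (default 1).
#' @return selected k, or `NA` if no knee is found.
#' @export
kneedle_optimal_k <- function(k_values, gev_values, sensitivity = 1) {
  n <- length(k_values)
  if (n < 3) stop_invalid("need at least 3 points")
  if (length(gev_values) != n) stop_invalid("k and gev lengths differ")
  if (is.unsorted(k_values, strictly = TRUE)) {
    stop_invalid("k_values must be strictly increasing")
  }
  if (diff(range(gev_values)) == 0) return(NA_integer_)
  xn <- (k_values - k_values[1]) / (k_values[n] - k_values[1])
  yn <- (gev_values - min(gev_values)) / diff(range(gev_values))
  d <- yn - xn
  mid <- 2:(n - 1)
  lmx <- mid[d[mid] > d[mid - 1] & d[mid] >= d[mid + 1]]
  if (!length(lmx)) return(NA_integer_)
  thr_gap <- sensitivity * mean(diff(xn))
  for (i in lmx) {
    thr <- d[i] - thr_gap
    nxt <- lmx[lmx > i]
    stop_at <- if (length(nxt)) nxt[1] - 1 else n
    j <- i + 1
    while (j <= stop_at) {
      if (d[j] < thr) return(k_values[i])
      j <- j + 1
    }
  }
  NA_integer_
}

#' Grand-mean (two-level) clustering of subject solutions
#'
#' Pools every subject's class maps and re-runs the polarity-invariant
#' k-means on the pooled set. The returned group maps are provisionally
#' ordered by descending pooled-assignment count; final Ms1..MsK labelling
#' by descending coverage is applied after backfitting (see
#' [order_by_coverage()]).
#'
#' @param subject_solutions list of `cluster_solution` (equal sensor count).
#' @param K number of group classes.
#' @param ... passed to [kmeans_microstates()].
#' @return a `cluster_solution` over the pooled subject maps.
#' @export
group_level_maps <- function(subject_solutions, K, ...) {
  ns <- vapply(subject_solutions, function(s) ncol(s$maps$maps), integer(1))
  if (length(unique(ns)) != 1) {
    stop_invalid("subjects have heterogeneous sensor counts: %s",
                 paste(unique(ns), collapse = ", "))
  }
  pool <- do.call(rbind, lapply(subject_solutions, function(s) s$maps$maps))
  sol <- kmeans_microstates(pool, K, ...)
  cnt <- tabulate(sol$assignment, nbins = K)
  ord <- order(cnt, decreasing = TRUE)
  remap <- match(seq_len(K), ord)
  sol$maps <- microstate_maps(sol$maps$maps[ord, , drop = FALSE])
  sol$assignment <- remap[sol$assignment]
  sol
}

#' Backfit group maps to every sample of a recording
#'
#' Each frame is labelled with the class of maximal polarity-invariant
#' spatial correlation; ties go to the lowest class index. Frames whose best
#' correlation falls below `min_corr`, and zero-variance frames, are marked
#' unassigned (`NA`). With `peaks_only = TRUE` only GFP peak frames are
#' labelled (others NA).
#'
#' @param rec a `recording` in the same sensor space as `group_maps`.
#' @param group_maps a `microstate_maps`.
#' @param min_corr assignment threshold in [0, 1]; default 0 (all assigned).
#' @param polarity_invariant use `|r|` (default TRUE).
#' @param peaks_only label GFP peaks only.
#' @return a `label_sequence`; attribute `best_corr` holds each frame's
#'   winning correlation.
#' @export
backfit <- function(rec, group_maps, min_corr = 0,
                    polarity_invariant = TRUE, peaks_only = FALSE) {
  M <- group_maps$maps
  if (ncol(M) != nrow(rec$data)) {
    stop_invalid("sensor mismatch: maps have %d sensors, recording %d",
                 ncol(M), nrow(rec$data))
  }
  X <- t(rec$data)                       # frames in rows
  Xn <- normalize_maps(X)
  degen <- attr(Xn, "degenerate")
  cr <- corr_matrix(Xn, M)
  score <- if (polarity_invariant) abs(cr) else cr
  lab <- max.col(score, ties.method = "first")
  best <- score[cbind(seq_len(nrow(X)), lab)]
  lab[best < min_corr] <- NA_integer_
  if (length(degen)) lab[degen] <- NA_integer_
  if (peaks_only) {
    pk <- extract_gfp_peaks(global_field_power(rec))
    drop_idx <- setdiff(seq_along(lab), pk)
    lab[drop_idx] <- NA_integer_
  }
  out <- label_sequence(lab, group_maps$K, rec$fs)
  attr(out, "best_corr") <- best
  out
}

#' Relabel group maps by descending backfit coverage
#'
#' Orders classes Ms1..MsK by total coverage over the supplied label
#' sequences (descending) and remaps both the maps and the sequences.
#'
#' @param solution a `cluster_solution` (group level).
#' @param label_seqs list of `label_sequence` backfitted with the solution.
#' @return list `solution` (reordered) and `label_seqs` (relabelled).
#' @export
order_by_coverage <- function(solution, label_seqs) {
  K <- solution$K
  counts <- Reduce(`+`, lapply(label_seqs, function(ls)
    tabulate(ls$labels[!is.na(ls$labels)], nbins = K)))
  ord <- order(counts, decreasing = TRUE)
  remap <- match(seq_len(K), ord)
  solution$maps <- microstate_maps(solution$maps$maps[ord, , drop = FALSE])
  solution$assignment <- remap[solution$assignment]
  new_seqs <- lapply(label_seqs, function(ls) {
    ls$labels <- remap[ls$labels]
    ls
  })
  names(new_seqs) <- names(label_seqs)
  list(solution = solution, label_seqs = new_seqs)
}
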