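# Sensor-space cleaning: zero-phase band-pass + notch filtering, PSD-based
# bad-channel flagging, and the nearest-neighbour spatial filter applied
# before topographic map extraction. ICA-based artifact removal is an
# interface hook only: the pipeline accepts pre-cleaned data.

# expand a polynomial from its roots (ascending-degree coefficient order
# reversed: returns c(1, ...) for the monic polynomial in z^-1)
poly_from_roots <- function(r) {
  p <- 1
  for (x in r) p <- c(p, 0) - c(0, p * x)
  p
}

# factor a transfer function into second-order sections (biquads).
# High-order Butterworth polynomials in direct form are ill-conditioned
# (poles clustered near z = 1 for low cutoffs); cascaded biquads keep the
# forward-backward application accurate to near machine precision.
as_sos <- function(filt) {
  b <- filt$b
  a <- filt$a
  zz <- polyroot(rev(b / b[1]))
  pp <- polyroot(rev(a / a[1]))
  pair_up <- function(r) {
    used <- rep(FALSE, length(r))
    pairs <- list()
    for (i in order(abs(Im(r)), decreasing = TRUE)) {
      if (used[i]) next
      used[i] <- TRUE
      if (abs(Im(r[i])) > 1e-8) {
        j <- which(!used & abs(r - Conj(r[i])) < 1e-6)[1]
      } else {
        j <- which(!used & abs(Im(r)) <= 1e-8)[1]
      }
      if (!is.na(j)) {
        used[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(r[i], r[j])
      } else {
        pairs[[length(pairs) + 1L]] <- r[i]
      }
    }
    pairs
  }
  zp <- pair_up(zz)
  pl <- pair_up(pp)
  sos <- lapply(seq_len(max(length(zp), length(pl))), function(k) {
    list(b = if (k <= length(zp)) Re(poly_from_roots(zp[[k]])) else 1,
         a = if (k <= length(pl)) Re(poly_from_roots(pl[[k]])) else 1)
  })
  sos[[1]]$b <- sos[[1]]$b * (b[1] / a[1])
  sos
}

sos_filtfilt <- function(sos, x) {
  for (s in sos) x <- signal::filtfilt(signal::Arma(b = s$b, a = s$a), x)
  x
}

#' Zero-phase band-pass and notch filtering
#'
#' Applies a 4th-order Butterworth high-pass at `low` and low-pass at
#' `high` (each factored into second-order sections for numerical
#' stability) and a narrow IIR notch (biquad, quality factor `notch_q`),
#' all forward-backward (zero phase), channel by channel. Each channel is
#' extended by odd reflection before filtering and trimmed afterwards to
#' suppress start-up transients. Defaults match the conventional
#' resting-state MEG setting: 1-40 Hz pass band and a 50 Hz power-line
#' notch.
#'
#' @param rec a `recording`.
#' @param low,high band edges in Hz (0 < low < high < fs/2).
#' @param notch notch frequency in Hz (`NULL` or `NA` disables); must be
#'   below Nyquist.
#' @param order Butterworth order per edge.
#' @param notch_q notch quality factor (centre frequency / -3 dB width).
#' @return filtered `recording` of the same shape.
#' @export
bandpass_notch <- function(rec, low = 1, high = 40, notch = 50,
                           order = 4, notch_q = 30) {
  fs <- rec$fs
  nyq <- fs / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop_invalid("band edges must satisfy 0 < low < high < fs/2 = %g", nyq)
  }
  hp <- as_sos(signal::butter(order, low / nyq, type = "high"))
  lp <- as_sos(signal::butter(order, high / nyq, type = "low"))
  use_notch <- !is.null(notch) && !is.na(notch)
  if (use_notch) {
    if (notch >= nyq) stop_invalid("notch %g Hz >= Nyquist %g Hz", notch, nyq)
    # RBJ audio-cookbook notch biquad
    w0 <- 2 * pi * notch / fs
    alpha <- sin(w0) / (2 * notch_q)
    nf <- list(list(b = c(1, -2 * cos(w0), 1) / (1 + alpha),
                    a = c(1, -2 * cos(w0) / (1 + alpha),
                          (1 - alpha) / (1 + alpha))))
  }
  x <- rec$data
  n <- ncol(x)
  npad <- min(n - 1L, ceiling(3 * fs / low))
  for (ch in seq_len(nrow(x))) {
    v <- x[ch, ]
    head_pad <- 2 * v[1] - v[(npad + 1):2]
    tail_pad <- 2 * v[n] - v[(n - 1):(n - npad)]
    v <- c(head_pad, v, tail_pad)
    v <- sos_filtfilt(lp, sos_filtfilt(hp, v))
    if (use_notch) v <- sos_filtfilt(nf, v)
    x[ch, ] <- v[(npad + 1):(npad + n)]
  }
  recording(x, fs, rec$layout, truth_labels = rec$truth_labels)
}

#' PSD-based bad-channel detection
#'
#' Computes each channel's total power in `band` from a Hann-windowed,
#' 50%-overlap averaged periodogram, then flags channels whose log band
#' power deviates from the channel ensemble by more than `z_thresh` robust
#' z-units (median / scaled-MAD). Flagged channels are meant to be dropped
#' downstream, not interpolated.
#'
#' @param rec a `recording` with at least 3 channels.
#' @param z_thresh robust z threshold (default 3).
#' @param band frequency band (Hz) over which power is summed.
#' @return data.frame (class `channel_quality_report`): `channel`,
#'   `band_power`, `z`, `flag` (logical, TRUE = bad).
#' @export
detect_bad_channels <- function(rec, z_thresh = 3, band = c(1, 40)) {
  x <- rec$data
  if (nrow(x) < 3) stop_invalid("need at least 3 channels")
  bp <- vapply(seq_len(nrow(x)),
               function(ch) band_power_welch(x[ch, ], rec$fs, band),
               numeric(1))
  lp <- log(pmax(bp, .Machine$double.xmin))
  med <- stats::median(lp)
  s <- stats::mad(lp)  # 1.4826 * MAD, consistent for the normal
  dev <- lp - med
  z <- if (s > 1e-12) dev / s else ifelse(abs(dev) < 1e-8, 0, Inf * sign(dev))
  flag <- abs(z) > z_thresh
  if (all(flag)) {
    stop_invalid(paste0("all %d channels flagged bad at |z| > %g -- ",
                        "aborting: check units/recording integrity"),
                 nrow(x), z_thresh)
  }
  structure(data.frame(channel = rec$layout$names, band_power = bp, z = z,
                       flag = flag, stringsAsFactors = FALSE),
            class = c("channel_quality_report", "data.frame"))
}

#' Nearest-neighbour spatial filter
#'
#' For every sensor and time frame, the value is replaced by the midrange of
#' its `k` nearest neighbours (Euclidean distance on the layout, self
#' excluded): `(max + min) / 2` over the neighbourhood. A neighbourhood-mean
#' variant (self included) is available via `method = "mean"`.
#'
#' @param x a `recording` or an n_sensors x n_frames matrix (a single frame
#'   may be passed as a vector).
#' @param layout a `sensor_layout`; taken from the recording when omitted.
#' @param k neighbours per sensor (default 6; must be < n_sensors).
#' @param method `"midrange"` (default) or `"mean"`.
#' @return object of the same type/shape as `x`.
#' @export
spatial_neighbor_filter <- function(x, layout = NULL, k = 6,
                                    method = c("midrange", "mean")) {
  method <- match.arg(method)
  is_rec <- inherits(x, "recording")
  if (is_rec) {
    layout <- layout %||% x$layout
    dat <- x$data
  } else {
    if (is.null(layout)) stop_invalid("layout required for matrix input")
    dat <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  }
  if (nrow(dat) != layout$n_sensors) {
    stop_invalid("data rows (%d) != layout sensors (%d)",
                 nrow(dat), layout$n_sensors)
  }
  nb <- sensor_neighbors(layout, k)
  out <- dat
  for (s in seq_len(nrow(dat))) {
    rows <- asplit(dat[nb[s, ], , drop = FALSE], 1)
    if (method == "midrange") {
      out[s, ] <- 0.5 * (Reduce(pmax, rows) + Reduce(pmin, rows))
    } else {
      out[s, ] <- Reduce(`+`, c(rows, list(dat[s, ]))) / (k + 1)
    }
  }
  if (is_rec) {
    recording(out, x$fs, layout, truth_labels = x$truth_labels)
  } else if (is.matrix(x)) out else drop(out)
}
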