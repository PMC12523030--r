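# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

#' Row-wise centre and L2-normalise a matrix of topographic maps
#'
#' Each row is a sensor map; the mean across sensors is removed and the row is
#' scaled to unit Euclidean norm. Rows with (near) zero variance are returned
#' as zero rows and reported through the `degenerate` attribute.
#'
#' @param x numeric matrix, maps in rows.
#' @return matrix of the same shape; attribute `degenerate` holds the indices
#'   of zero-variance rows.
#' @keywords internal
normalize_maps <- function(x) {
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  bad <- which(nrm < 1e-300)
  nrm[bad] <- 1
  out <- x / nrm
  attr(out, "degenerate") <- bad
  out
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits.
# Used to stamp serialized configs into reports (provenance, not crypto).
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(paste(s, collapse = "\n"))))
  h <- 2166136261
  for (b in bytes) {
    # XOR touches only the low byte (b < 256); keep h as a double to avoid
    # 32-bit integer overflow
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619, in two halves
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# derive a child seed from a base seed and a stream index, kept below 2^31
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647
}

# Welch-style averaged periodogram band power for one channel.
# Hann window, 50% overlap; returns total power in [band_lo, band_hi] Hz.
band_power_welch <- function(x, fs, band = c(1, 40), nper = NULL) {
  n <- length(x)
  nper <- nper %||% min(n, max(256, 2 * fs))
  nper <- min(nper, n)
  step <- max(1, floor(nper / 2))
  starts <- seq(1, n - nper + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))
  acc <- numeric(floor(nper / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + nper - 1)] * w
    ft <- stats::fft(seg)
    pg <- Mod(ft[seq_along(acc)])^2 / (sum(w^2) * fs)
    acc <- acc + pg
  }
  psd <- acc / length(starts)
  freqs <- (seq_along(psd) - 1) * fs / nper
  sel <- freqs >= band[1] & freqs <= band[2]
  sum(psd[sel]) * fs / nper
}
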