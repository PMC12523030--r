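# Small in-code fixtures shared across test files.

rms <- function(x) sqrt(mean(x^2))

# a modest helmet + well-separated templates, deterministic
fix_layout <- function(n = 32) make_sensor_layout(n)

fix_templates <- function(layout = fix_layout(), K = 6, seed = 7,
                          max_abs_corr = 0.7) {
  make_templates(layout, K, max_abs_corr = max_abs_corr, seed = seed)
}

# quick single-subject simulated recording with truth labels
fix_recording <- function(K = 6, n_sensors = 32, fs = 200, duration_s = 10,
                          snr = 5, seed = 1, dwell = 60) {
  lay <- fix_layout(n_sensors)
  tpl <- fix_templates(lay, K, seed = seed + 100)
  mod <- transition_model(K, dwell)
  lab <- simulate_state_sequence(mod, duration_s, fs, seed = seed)
  render_recording(tpl, lab, lay, fs = fs, snr = snr, seed = seed + 1)
}

# independent Pearson correlation from first principles (oracle)
pearson_direct <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  num / den
}

# independent two-sided Fisher exact p by explicit enumeration of all
# tables with the observed margins, using log-factorials (no dhyper)
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  lp <- function(x) {
    # P(table) with margins fixed: hypergeometric via factorials
    lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(n - c1 + 1) -
      lgamma(n + 1) - lgamma(x + 1) - lgamma(r1 - x + 1) -
      lgamma(c1 - x + 1) - lgamma(r2 - c1 + x + 1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  logs <- vapply(support, lp, numeric(1))
  pobs <- exp(lp(a))
  sum(exp(logs)[exp(logs) <= pobs + 1e-12])
}

# independent discrete-kneedle oracle, written as an explicit step-by-step
# walk over the normalized difference curve
kneedle_oracle <- function(k, y, S = 1) {
  n <- length(k)
  xn <- (k - k[1]) / (k[n] - k[1])
  yn <- (y - min(y)) / (max(y) - min(y))
  d <- yn - xn
  knees <- c()
  i <- 2
  while (i <= n - 1) {
    if (d[i] > d[i - 1] && d[i] >= d[i + 1]) {
      thresh <- d[i] - S * mean(diff(xn))
      j <- i + 1
      while (j <= n) {
        if (j <= n - 1 && d[j] > d[j - 1] && d[j] >= d[j + 1]) break
        if (d[j] < thresh) {
          knees <- c(knees, k[i])
          break
        }
        j <- j + 1
      }
    }
    i <- i + 1
  }
  if (length(knees)) knees[1] else NA_integer_
}
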