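# Brute-force recomputations from first principles, written as explicit
# loops so they stay independent of the package's vectorized paths.

oracle_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

oracle_var <- function(x) {
  m <- oracle_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  s / (length(x) - 1)
}

oracle_sd <- function(x) sqrt(oracle_var(x))

oracle_flux <- function(scores) oracle_sd(scores)

oracle_pulse <- function(ax, ay) {
  mags <- numeric(length(ax))
  for (i in seq_along(ax)) mags[i] <- sqrt(ax[i]^2 + ay[i]^2)
  oracle_sd(mags)
}

oracle_angle <- function(ax, ay, mode = "literal") {
  mag <- sqrt(ax^2 + ay^2)
  if (mag == 0) return(NA_real_)
  if (mode == "literal") {
    acos(min(1, abs(ax) / mag)) * 180 / pi
  } else {
    abs(atan2(ay, ax)) * 180 / pi
  }
}

oracle_spin <- function(ax, ay, mode = "literal") {
  angles <- c()
  for (i in seq_along(ax)) {
    a <- oracle_angle(ax[i], ay[i], mode)
    if (!is.na(a)) angles <- c(angles, a)
  }
  if (length(angles) < 2) return(NA_real_)
  oracle_sd(angles)
}

oracle_rmssd <- function(series) {
  sq <- c()
  for (i in seq_len(length(series) - 1)) {
    if (!is.na(series[i]) && !is.na(series[i + 1])) {
      sq <- c(sq, (series[i + 1] - series[i])^2)
    }
  }
  if (length(sq) == 0) return(NA_real_)
  sqrt(oracle_mean(sq))
}
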