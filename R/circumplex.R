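#' Flux: SD of scalar affect scores along one dimension
#'
#' Flux operationalizes (in)consistency of affect along a single circumplex
#' axis: the sample SD of the day's z-standardized word scores on that
#' dimension. It is magnitude-sensitive and direction-agnostic.
#'
#' @param scores Numeric vector of z-scores for the day's mapped words.
#' @return The sample SD, or `NA_real_` when fewer than 2 scores are
#'   available (the statistic is undefined and propagates as missing).
#' @export
flux <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 2L) return(NA_real_)
  .sd_fun(scores)
}

#' Euclidean magnitude of a word vector in a 2D affect plane
#'
#' Distance from the circumplex origin (0, 0) to (`ax`, `ay`). Vectorized.
#'
#' @param ax,ay Numeric coordinates (z-scores) in the chosen plane.
#' @return Non-negative numeric vector.
#' @export
vector_magnitude <- function(ax, ay) {
  sqrt(ax^2 + ay^2)
}

#' Pulse: SD of word-vector magnitudes in a 2D affect plane
#'
#' Pulse operationalizes consistency of affective extremity: the sample SD
#' of the Euclidean magnitudes of the day's word vectors. Like flux it is
#' an SD, but taken over vector magnitudes rather than scalar scores, so it
#' reflects both coordinates of the plane. Invariant to rotating all points
#' by a common angle.
#'
#' @param ax,ay Numeric coordinate vectors (equal length).
#' @return Sample SD of magnitudes, or `NA_real_` for fewer than 2 points.
#' @export
pulse <- function(ax, ay) {
  stopifnot(length(ax) == length(ay))
  ok <- !is.na(ax) & !is.na(ay)
  if (sum(ok) < 2L) return(NA_real_)
  .sd_fun(vector_magnitude(ax[ok], ay[ok]))
}

#' Angular displacement of a word vector from the horizontal axis
#'
#' Two readings of the angle are supported. `"literal"` (the default)
#' evaluates the cosine of the angle between u = (ax, 0) and v = (ax, ay),
#' i.e. arccos(|ax| / ||v||), which folds every quadrant into \[0, 90\]
#' degrees because u.v = ax^2 is non-negative. `"signed"` is the standard
#' geometric alternative |atan2(ay, ax)| in \[0, 180\] degrees, the
#' absolute angular displacement from the positive horizontal axis. When
#' ax = 0 with ay != 0 both modes give 90 degrees (the limit of the
#' formula); the zero vector has no defined angle and returns `NA`.
#'
#' @param ax,ay Numeric coordinate vectors (equal length; vectorized).
#' @param mode `"literal"` or `"signed"`.
#' @return Angles in degrees.
#' @export
word_angle <- function(ax, ay, mode = c("literal", "signed")) {
  mode <- match.arg(mode)
  stopifnot(length(ax) == length(ay))
  mag <- vector_magnitude(ax, ay)
  ang <- if (mode == "literal") {
    acos(pmin(1, abs(ax) / mag)) * 180 / pi
  } else {
    abs(atan2(ay, ax)) * 180 / pi
  }
  ang[mag == 0] <- NA_real_
  ang
}

#' Spin: SD of word-vector angular displacements in a 2D affect plane
#'
#' Spin operationalizes consistency of angular position (affective "tone"):
#' the ordinary sample SD, in degrees, of the word angles given by
#' [word_angle()]. It is intensity-agnostic — rescaling any word vector by
#' a positive constant leaves it unchanged. Words at the plane's origin
#' have no angle and are excluded; spin is missing when fewer than 2
#' defined angles remain.
#'
#' @inheritParams word_angle
#' @return Sample SD of angles in degrees, or `NA_real_`.
#' @export
spin <- function(ax, ay, mode = c("literal", "signed")) {
  mode <- match.arg(mode)
  ok <- !is.na(ax) & !is.na(ay)
  ang <- word_angle(ax[ok], ay[ok], mode = mode)
  ang <- ang[!is.na(ang)]
  if (length(ang) < 2L) return(NA_real_)
  .sd_fun(ang)
}

#' Daily circumplex features from pooled tokens
#'
#' Computes, for each (state, date) pool: token-weighted mean V/A/D; flux
#' along each dimension; and pulse and spin in each of the VA, VD and AD
#' planes. Means are defined for n_mapped >= 1; flux, pulse and spin
#' require n_mapped >= 2 and are otherwise emitted as `NA` (spin
#' additionally requires >= 2 tokens off the plane's origin).
#'
#' @param pools Output of [pool_daily()] (or any tibble with `state`,
#'   `date`, `n_mapped` and a `tokens` list-column of `V`/`A`/`D` tables).
#' @param angle_mode Angle convention for spin; see [word_angle()].
#' @return A tibble, one row per (state, date), with `n_mapped`, `mean_V`,
#'   `mean_A`, `mean_D`, `Flux_V`, `Flux_A`, `Flux_D`, `Pulse_VA`,
#'   `Pulse_VD`, `Pulse_AD`, `Spin_VA`, `Spin_VD`, `Spin_AD`. The
#'   `angle_mode` used is recorded as an attribute.
#' @export
compute_daily_features <- function(pools,
                                   angle_mode = c("literal", "signed")) {
  angle_mode <- match.arg(angle_mode)
  one_day <- function(tok) {
    V <- tok$V; A <- tok$A; D <- tok$D
    mean_or_na <- function(x) if (length(x) >= 1L) mean(x) else NA_real_
    tibble::tibble(
      mean_V = mean_or_na(V), mean_A = mean_or_na(A), mean_D = mean_or_na(D),
      Flux_V = flux(V), Flux_A = flux(A), Flux_D = flux(D),
      Pulse_VA = pulse(V, A), Pulse_VD = pulse(V, D), Pulse_AD = pulse(A, D),
      Spin_VA = spin(V, A, angle_mode),
      Spin_VD = spin(V, D, angle_mode),
      Spin_AD = spin(A, D, angle_mode)
    )
  }
  feats <- dplyr::bind_rows(lapply(pools$tokens, one_day))
  out <- dplyr::bind_cols(
    pools[, c("state", "date", "n_mapped"), drop = FALSE],
    feats
  )
  attr(out, "angle_mode") <- angle_mode
  out
}

#' Write daily features to CSV
#'
#' One row per (state, date) with all 13 feature columns plus `n_mapped`;
#' missing values are written as empty fields.
#'
#' @param features Output of [compute_daily_features()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_daily_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE, na = "")
  invisible(path)
}
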