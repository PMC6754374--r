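#' ERB model constants
#'
#' The average equivalent rectangular bandwidth for young normal-hearing
#' listeners at moderate levels is ERB_N = c1 (c2 f + 1) with the standard
#' constants c1 = 24.7 Hz and c2 = 0.00437 per Hz. Sensorineural hearing
#' loss h (dB HL) widens the filter as ERB(h) = ERB_N (1 + h / 50), a
#' relation supported by measured filter widths for losses up to 50 dB HL.
#' The ERB_N formula itself predicts masking-derived bandwidths well from
#' roughly 50 Hz to 15 kHz; outside that range results are advisory.
#'
#' @param c1 Bandwidth intercept in Hz.
#' @param c2 Bandwidth slope per Hz of center frequency.
#' @param h_scale Loss normalization in dB HL (widening doubles the band at
#'   `h = h_scale`).
#' @param f_valid Advisory validity range of the bandwidth formula, Hz.
#' @return An object of class `erb_model`.
#' @export
erb_model <- function(c1 = 24.7, c2 = 0.00437, h_scale = 50,
                      f_valid = c(50, 15000)) {
  stopifnot(c1 > 0, c2 > 0, h_scale > 0,
            length(f_valid) == 2L, all(f_valid > 0), f_valid[1] < f_valid[2])
  structure(list(c1 = c1, c2 = c2, h_scale = h_scale, f_valid = f_valid),
            class = "erb_model")
}

check_validity <- function(f, model) {
  out <- f < model$f_valid[1] | f > model$f_valid[2]
  if (any(out))
    warning(sprintf(
      "frequency %s Hz outside the (%g, %g) Hz range where the ERB formula is well supported",
      paste(format(f[out]), collapse = ", "),
      model$f_valid[1], model$f_valid[2]), call. = FALSE)
  invisible(out)
}

#' Normal-hearing equivalent rectangular bandwidth
#'
#' @param f Center frequencies in Hz (vectorized), all positive.
#' @param model An [erb_model].
#' @param warn Warn when `f` lies outside the model's advisory range.
#' @return ERB_N in Hz for each `f`.
#' @examples
#' erb_n(1000) # 132.639 Hz
#' @export
erb_n <- function(f, model = erb_model(), warn = TRUE) {
  if (any(!is.finite(f)) || any(f <= 0))
    stop("center frequency must be positive and finite")
  if (warn) check_validity(f, model)
  model$c1 * (model$c2 * f + 1)
}

#' Hearing-loss-widened ERB
#'
#' ERB(h) = ERB_N(f) * (1 + h / 50) where h is the effective hearing loss
#' at `f` taken from the audiogram and clamped to [0, 50] dB HL.
#'
#' @inheritParams erb_n
#' @param ag An [audiogram], or `NULL` for normal hearing.
#' @return Widened ERB in Hz for each `f`.
#' @export
erb_at <- function(f, ag = NULL, model = erb_model(), warn = TRUE) {
  h <- effective_loss(ag, f)$h
  erb_n(f, model, warn = warn) * (1 + h / model$h_scale)
}

#' ERB-wide band around a tone
#'
#' The band centered at `f` extends half the (loss-widened) ERB to either
#' side: lower edge a = f - ERB/2, upper edge b = f + ERB/2.
#'
#' @inheritParams erb_at
#' @return A data.frame of class `erb_band` with columns `f`, `a`, `b`,
#'   `width`, one row per element of `f`.
#' @examples
#' band_at(934)   # upper edge 996.76 Hz
#' @export
band_at <- function(f, ag = NULL, model = erb_model(), warn = TRUE) {
  w <- erb_at(f, ag, model, warn = warn)
  structure(data.frame(f = f, a = f - w / 2, b = f + w / 2, width = w),
            class = c("erb_band", "data.frame"))
}

band_row <- function(band) {
  if (!is.list(band) || is.null(band$a) || is.null(band$b) || is.null(band$f))
    stop("band must have elements f, a, b (see band_at())")
  band
}

#' Relative overlap of a CR tone band with the tinnitus band
#'
#' Overlap of the band around a CR tone with the band around the tinnitus
#' frequency, normalized by the tinnitus band width. For a tone below the
#' tinnitus frequency the overlapping edge is the tone's upper edge:
#' rd = (b_j - a_T) / (b_T - a_T); for a tone above, rd =
#' (b_T - a_j) / (b_T - a_T). Positive values are overlaps, negative values
#' gaps, zero coinciding edges.
#'
#' @param band_j Band of the CR tone (one row of [band_at()]).
#' @param band_T Band of the tinnitus frequency.
#' @param side `"below"` if the tone lies below the tinnitus frequency,
#'   `"above"` otherwise.
#' @return Dimensionless relative overlap.
#' @export
rd_erb_tinnitus <- function(band_j, band_T, side = c("below", "above")) {
  side <- match.arg(side)
  band_j <- band_row(band_j); band_T <- band_row(band_T)
  wT <- band_T$b - band_T$a
  if (any(wT <= 0)) stop("degenerate tinnitus band: width must be positive")
  if (side == "below") (band_j$b - band_T$a) / wT
  else                 (band_T$b - band_j$a) / wT
}

#' Relative overlap of two neighboring CR tone bands
#'
#' Overlap of the bands around two adjacent CR tones, normalized either by
#' the smaller (`"min"`) or the larger (`"max"`) of the two band widths:
#' rd = (b_j - a_k) / min-or-max(width_j, width_k), with the lower tone as
#' j. Min normalization is conservative (bounds the overlap relative to the
#' narrower filter); max normalization is appropriate when large overlaps
#' are sought. Positive = overlap, negative = gap, zero = coinciding edges.
#'
#' @param band_j Band of the lower tone; `band_j$f < band_k$f` is required.
#' @param band_k Band of the upper tone.
#' @param normalization `"min"` or `"max"`.
#' @return Dimensionless relative overlap.
#' @export
rd_erb_pair <- function(band_j, band_k, normalization = c("min", "max")) {
  normalization <- match.arg(normalization)
  band_j <- band_row(band_j); band_k <- band_row(band_k)
  if (any(band_j$f >= band_k$f))
    stop("bands must be ordered: band_j$f < band_k$f")
  wj <- band_j$b - band_j$a
  wk <- band_k$b - band_k$a
  den <- if (normalization == "min") pmin(wj, wk) else pmax(wj, wk)
  (band_j$b - band_k$a) / den
}

#' Classify a relative overlap value
#'
#' @param rd Relative overlap values (vectorized).
#' @param tol Non-negative tolerance within which edges count as coincident.
#' @return Character vector: `"overlap"`, `"gap"`, or `"coincident"`.
#' @export
classify_rd <- function(rd, tol = 1e-9) {
  if (tol < 0) stop("tol must be non-negative")
  ifelse(abs(rd) <= tol, "coincident", ifelse(rd > 0, "overlap", "gap"))
}
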