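#' Legacy fixed-ratio CR tone set
#'
#' The original acoustic CR therapy places four tones at fixed ratios of the
#' tinnitus frequency: 0.766, 0.9, 1.1 and 1.4 times f_T.
#'
#' @param f_T Tinnitus frequency in Hz, positive.
#' @return Numeric vector of four tone frequencies, ascending.
#' @examples
#' standard_tones(1000) # 766 900 1100 1400
#' @export
standard_tones <- function(f_T) {
  if (!is.finite(f_T) || f_T <= 0) stop("f_T must be positive and finite")
  c(0.766, 0.9, 1.1, 1.4) * f_T
}

# one warning string per (frequency, cause); used by reports and the CLI
collect_warnings <- function(freqs, ag, model) {
  w <- character(0)
  if (!is.null(ag)) {
    raw <- threshold_at(ag, freqs)
    over <- freqs[raw > 50]
    if (length(over))
      w <- c(w, sprintf("loss_clamped_50dB f=%.6g", unique(over)))
    under <- freqs[raw < 0]
    if (length(under))
      w <- c(w, sprintf("loss_clamped_0dB f=%.6g", unique(under)))
  }
  out <- freqs[freqs < model$f_valid[1] | freqs > model$f_valid[2]]
  if (length(out))
    w <- c(w, sprintf("erb_formula_range f=%.6g", unique(out)))
  unique(w)
}

#' Overlap analysis of a CR tone set against a tinnitus frequency
#'
#' Computes the ERB-wide band of every tone and of the tinnitus frequency,
#' the relative overlap of each adjacent tone pair (normalized by the
#' min or max pair width), and each tone's relative overlap with the
#' tinnitus band (normalized by the tinnitus band width; tones below f_T
#' use their upper edge, tones above use their lower edge). A tone exactly
#' at f_T is reported with tinnitus overlap 1 (full self-overlap).
#'
#' @param tones Tone frequencies in Hz, strictly increasing, all positive.
#' @param f_T Tinnitus frequency in Hz.
#' @param ag An [audiogram] or `NULL` for normal hearing.
#' @param normalization Pairwise normalization, `"min"` or `"max"`.
#' @param model An [erb_model].
#' @return An object of class `overlap_report`.
#' @export
analyze_alignment <- function(tones, f_T, ag = NULL,
                              normalization = c("min", "max"),
                              model = erb_model()) {
  normalization <- match.arg(normalization)
  if (any(!is.finite(tones)) || any(tones <= 0))
    stop("tones must be positive and finite")
  if (is.unsorted(tones, strictly = TRUE))
    stop("tones must be strictly increasing")
  if (!is.finite(f_T) || f_T <= 0) stop("f_T must be positive")

  bands <- band_at(tones, ag, model, warn = FALSE)
  band_T <- band_at(f_T, ag, model, warn = FALSE)
  n <- length(tones)

  pairwise <- if (n >= 2L) {
    rd <- vapply(seq_len(n - 1L), function(j)
      rd_erb_pair(bands[j, ], bands[j + 1L, ], normalization), numeric(1))
    data.frame(lower = seq_len(n - 1L), upper = seq_len(n - 1L) + 1L,
               overlap_hz = bands$b[-n] - bands$a[-1L],
               rd = rd, classification = classify_rd(rd))
  } else {
    data.frame(lower = integer(0), upper = integer(0),
               overlap_hz = numeric(0), rd = numeric(0),
               classification = character(0))
  }

  side <- ifelse(tones < f_T, "below", ifelse(tones > f_T, "above", "at"))
  rd_T <- vapply(seq_len(n), function(j) {
    if (side[j] == "at") 1
    else rd_erb_tinnitus(bands[j, ], band_T, side[j])
  }, numeric(1))
  tinnitus <- data.frame(tone_index = seq_len(n), side = side, rd = rd_T,
                         classification = classify_rd(rd_T))

  structure(list(
    f_T = f_T, tones = tones, bands = bands, band_T = band_T,
    normalization = normalization,
    pairwise = pairwise, tinnitus = tinnitus,
    warnings = collect_warnings(c(tones, f_T), ag, model)
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("ERB overlap report: f_T = %g Hz, %d tones (%s-normalized pairs)\n",
              x$f_T, length(x$tones), x$normalization))
  df <- data.frame(tone = seq_along(x$tones),
                   f = round(x$tones, 2),
                   a = round(x$bands$a, 2),
                   b = round(x$bands$b, 2),
                   rd_tinnitus = round(x$tinnitus$rd, 4))
  print(df, row.names = FALSE)
  cat("adjacent pairs:\n")
  print(data.frame(pair = paste0(x$pairwise$lower, "-", x$pairwise$upper),
                   rd = round(x$pairwise$rd, 4),
                   class = x$pairwise$classification), row.names = FALSE)
  if (length(x$warnings)) cat("warnings:", x$warnings, sep = "\n  ")
  invisible(x)
}

#' Sweep the standard CR tone analysis over tinnitus frequencies
#'
#' Evaluates [analyze_alignment()] with the legacy fixed-ratio tones at each
#' grid point over a range of tinnitus frequencies. The default grid is
#' 500 logarithmically spaced points over 250-10000 Hz; pass `step` for an
#' arithmetic grid instead.
#'
#' @param f_T_range Length-2 positive range of tinnitus frequencies, Hz.
#' @param n_points Number of logarithmic grid points (ignored when `step`
#'   is given).
#' @param step Optional arithmetic grid step in Hz.
#' @param ag An [audiogram] or `NULL`.
#' @param normalization Pairwise normalization.
#' @param model An [erb_model].
#' @return Long-format data.frame with one row per (f_T, tone): columns
#'   `f_T`, `tone_index`, `f_j`, `a_j`, `b_j`, `rd_pair` (overlap with the
#'   next tone up; `NA` for the highest tone), `rd_tinnitus`.
#' @export
sweep_standard <- function(f_T_range = c(250, 10000), n_points = 500,
                           step = NULL, ag = NULL,
                           normalization = c("min", "max"),
                           model = erb_model()) {
  normalization <- match.arg(normalization)
  if (length(f_T_range) != 2L || any(f_T_range <= 0) ||
      f_T_range[1] > f_T_range[2])
    stop("f_T_range must be a positive increasing interval")
  grid <- if (is.null(step)) {
    exp(seq(log(f_T_range[1]), log(f_T_range[2]), length.out = n_points))
  } else {
    if (step <= 0) stop("step must be positive")
    seq(f_T_range[1], f_T_range[2], by = step)
  }
  if (!length(grid)) stop("empty sweep grid")
  rows <- lapply(grid, function(ft) {
    rep_ <- analyze_alignment(standard_tones(ft), ft, ag, normalization, model)
    n <- length(rep_$tones)
    data.frame(f_T = ft, tone_index = seq_len(n), f_j = rep_$tones,
               a_j = rep_$bands$a, b_j = rep_$bands$b,
               rd_pair = c(rep_$pairwise$rd, NA_real_),
               rd_tinnitus = rep_$tinnitus$rd)
  })
  do.call(rbind, rows)
}

#' Largest tinnitus frequency at which two standard tones' bands overlap
#'
#' For an adjacent pair of the legacy fixed-ratio tones, finds the largest
#' f_T in the search range at which the bands still touch, i.e. the root of
#' the edge residual b_j(f_T) - a_k(f_T), by sign-change bracketing and
#' bisection. The residual is affine in f_T for normal hearing, so a single
#' root exists whenever the signs at the range ends differ.
#'
#' @param pair Integer pair of adjacent standard-tone indices:
#'   `c(1,2)`, `c(2,3)` or `c(3,4)`.
#' @param ag An [audiogram] or `NULL`.
#' @param f_T_range Search range, Hz.
#' @param resolution Reporting resolution in Hz (the crossing is rounded to
#'   the nearest multiple).
#' @param model An [erb_model].
#' @return A list with `crossing` (TRUE/FALSE), exact root `f_T` and
#'   `f_T_rounded` (NA when the residual does not change sign in range).
#' @examples
#' overlap_threshold(c(1, 2))$f_T_rounded # 560
#' @export
overlap_threshold <- function(pair, ag = NULL, f_T_range = c(100, 10000),
                              resolution = 10, model = erb_model()) {
  pair <- as.integer(pair)
  if (length(pair) != 2L || pair[2] != pair[1] + 1L ||
      pair[1] < 1L || pair[2] > 4L)
    stop("pair must be adjacent standard-tone indices: (1,2), (2,3) or (3,4)")
  residual <- function(ft) {
    tones <- standard_tones(ft)
    b_j <- band_at(tones[pair[1]], ag, model, warn = FALSE)
    a_k <- band_at(tones[pair[2]], ag, model, warn = FALSE)
    b_j$b - a_k$a
  }
  lo <- f_T_range[1]; hi <- f_T_range[2]
  r_lo <- residual(lo); r_hi <- residual(hi)
  if (sign(r_lo) == sign(r_hi))
    return(list(pair = pair, crossing = FALSE,
                f_T = NA_real_, f_T_rounded = NA_real_))
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    r_mid <- residual(mid)
    if (sign(r_mid) == sign(r_lo)) { lo <- mid; r_lo <- r_mid }
    else hi <- mid
  }
  root <- (lo + hi) / 2
  list(pair = pair, crossing = TRUE, f_T = root,
       f_T_rounded = round(root / resolution) * resolution)
}
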