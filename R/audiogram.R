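#' Construct an audiogram
#'
#' An audiogram stores measured hearing thresholds (dB HL) at a set of
#' frequencies (Hz). Thresholds between measured points are obtained by
#' linear interpolation on a logarithmic frequency axis; outside the
#' measured range the nearest endpoint's threshold is used.
#'
#' @param frequencies Numeric vector of measurement frequencies in Hz,
#'   all positive. Stored sorted ascending.
#' @param thresholds Numeric vector of thresholds in dB HL, one per
#'   frequency; must be finite.
#' @param label Free-text label for reports.
#' @return An object of class `audiogram`: a list with elements
#'   `frequencies`, `thresholds` and `label`.
#' @examples
#' ag <- audiogram(c(250, 1000, 4000), c(10, 10, 40))
#' threshold_at(ag, 2000)
#' @export
audiogram <- function(frequencies, thresholds, label = "audiogram") {
  frequencies <- as.numeric(frequencies)
  thresholds <- as.numeric(thresholds)
  if (length(frequencies) != length(thresholds))
    stop("frequencies and thresholds must have the same length")
  if (length(frequencies) < 1L)
    stop("audiogram needs at least one measured point")
  if (anyNA(frequencies) || any(!is.finite(frequencies)))
    stop("frequencies must be finite")
  if (any(frequencies <= 0))
    stop("frequencies must be positive")
  if (anyNA(thresholds) || any(!is.finite(thresholds)))
    stop("thresholds must be finite")
  o <- order(frequencies)
  frequencies <- frequencies[o]
  thresholds <- thresholds[o]
  if (anyDuplicated(frequencies)) {
    d <- frequencies[duplicated(frequencies)][1L]
    stop("duplicate frequency ", format(d))
  }
  structure(
    list(frequencies = frequencies, thresholds = thresholds,
         label = as.character(label)[1L]),
    class = "audiogram"
  )
}

#' @export
print.audiogram <- function(x, ...) {
  cat("Audiogram:", x$label, "\n")
  print(data.frame(frequency_hz = x$frequencies,
                   threshold_db_hl = x$thresholds), row.names = FALSE)
  invisible(x)
}

#' Read an audiogram from a CSV file
#'
#' Expects two numeric columns, frequency in Hz then threshold in dB HL.
#' A header line (e.g. `frequency_hz,threshold_db_hl`) is detected
#' automatically. Rows may appear in any order; duplicated or non-positive
#' frequencies are rejected with an error naming the offending row.
#'
#' @param path Path to a CSV file.
#' @param label Label for the resulting audiogram; defaults to the file name.
#' @return An [audiogram] object.
#' @export
read_audiogram <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("audiogram file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  fields <- strsplit(first, ",", fixed = TRUE)[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields))))
  tab <- utils::read.csv(path, header = has_header,
                         stringsAsFactors = FALSE, strip.white = TRUE)
  if (ncol(tab) < 2L)
    stop("audiogram CSV must have two columns (frequency_hz, threshold_db_hl)")
  f_raw <- tab[[1L]]
  t_raw <- tab[[2L]]
  f <- suppressWarnings(as.numeric(f_raw))
  thr <- suppressWarnings(as.numeric(t_raw))
  offset <- if (has_header) 1L else 0L
  bad <- which(is.na(f) | is.na(thr))
  if (length(bad))
    stop("non-numeric value in audiogram row ", bad[1L] + offset)
  nonpos <- which(f <= 0)
  if (length(nonpos))
    stop("non-positive frequency ", format(f[nonpos[1L]]),
         " in audiogram row ", nonpos[1L] + offset)
  if (anyDuplicated(f)) {
    d <- f[duplicated(f)][1L]
    stop("duplicate frequency ", format(d), " in audiogram ", path)
  }
  audiogram(f, thr, label = label)
}

#' Write an audiogram to CSV
#'
#' @param ag An [audiogram].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_audiogram <- function(ag, path) {
  stopifnot(inherits(ag, "audiogram"))
  utils::write.csv(
    data.frame(frequency_hz = ag$frequencies,
               threshold_db_hl = ag$thresholds),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolated hearing threshold at arbitrary frequencies
#'
#' Linear interpolation of threshold against log-frequency between the
#' bracketing measured points; beyond the measured range the nearest
#' endpoint's threshold is returned (constant extrapolation). At a measured
#' frequency the measured threshold is reproduced exactly.
#'
#' @param ag An [audiogram].
#' @param f Frequencies in Hz (vectorized), all positive.
#' @return Thresholds in dB HL, same length as `f`.
#' @export
threshold_at <- function(ag, f) {
  stopifnot(inherits(ag, "audiogram"))
  if (any(f <= 0)) stop("frequency must be positive")
  if (length(ag$frequencies) == 1L)
    return(rep(ag$thresholds, length(f)))
  stats::approx(x = log(ag$frequencies), y = ag$thresholds,
                xout = log(f), method = "linear", rule = 2)$y
}

#' Effective hearing loss driving ERB widening
#'
#' The ERB widening model is supported by data only for losses between 0 and
#' 50 dB HL, so the interpolated threshold is clamped to that range; the
#' `clamped` flag records where clamping occurred (thresholds better than
#' 0 dB HL, or losses exceeding 50 dB HL).
#'
#' @param ag An [audiogram], or `NULL` for normal hearing (0 dB HL).
#' @param f Frequencies in Hz (vectorized).
#' @return A list with numeric `h` (clamped loss, dB HL) and logical
#'   `clamped`, both the length of `f`.
#' @export
effective_loss <- function(ag, f) {
  if (any(f <= 0)) stop("frequency must be positive")
  if (is.null(ag))
    return(list(h = rep(0, length(f)), clamped = rep(FALSE, length(f))))
  raw <- threshold_at(ag, f)
  h <- pmin(pmax(raw, 0), 50)
  list(h = h, clamped = raw < 0 | raw > 50)
}

# Standard extended audiometric grid, 250 Hz - 12.5 kHz. Extends past the
# usual 8-kHz limit because tone placement may need thresholds above it.
audiometric_frequencies <- function() {
  c(250, 500, 750, 1000, 1500, 2000, 3000, 4000, 6000, 8000, 10000, 12500)
}

#' Synthesize an audiogram fixture
#'
#' Generates deterministic audiograms on the standard extended audiometric
#' grid (250-12500 Hz) for testing and demonstration: a flat loss, a
#' high-frequency sloping loss, or a notched loss such as produced by noise
#' exposure. Optional Gaussian jitter (reproducible under `seed`) roughens
#' the thresholds. All thresholds are kept within [-10, 90] dB HL.
#'
#' @param kind One of `"flat"`, `"sloping"`, `"notch"`.
#' @param level Flat threshold in dB HL (`kind = "flat"`).
#' @param start,end,corner Sloping loss: threshold is `start` up to the
#'   `corner` frequency (Hz), then rises linearly in log-frequency to `end`
#'   at the top of the grid.
#' @param center,depth,width_oct,base Notch loss: Gaussian bump of `depth`
#'   dB over a flat `base`, centered at `center` Hz with standard deviation
#'   `width_oct` octaves.
#' @param jitter_db Standard deviation of added threshold jitter in dB
#'   (default 0: exact deterministic shapes).
#' @param seed Integer seed used when `jitter_db > 0`.
#' @return An [audiogram].
#' @examples
#' synth_audiogram("notch", center = 4000, depth = 40)
#' @export
synth_audiogram <- function(kind = c("flat", "sloping", "notch"),
                            level = 20,
                            start = 10, end = 60, corner = 1000,
                            center = 4000, depth = 40, width_oct = 0.75,
                            base = 5,
                            jitter_db = 0, seed = 1L) {
  kind <- match.arg(kind)
  f <- audiometric_frequencies()
  thr <- switch(kind,
    flat = {
      if (!is.finite(level)) stop("invalid flat level")
      rep(level, length(f))
    },
    sloping = {
      if (!is.finite(start) || !is.finite(end) || corner <= 0)
        stop("invalid sloping parameters")
      top <- max(f)
      frac <- pmin(pmax(log(f / corner) / log(top / corner), 0), 1)
      start + frac * (end - start)
    },
    notch = {
      if (center <= 0 || depth < 0 || width_oct <= 0)
        stop("invalid notch parameters")
      base + depth * exp(-0.5 * (log2(f / center) / width_oct)^2)
    }
  )
  if (jitter_db > 0) {
    rng <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    thr <- thr + stats::rnorm(length(f), sd = jitter_db)
    if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv())
  }
  thr <- pmin(pmax(thr, -10), 90)
  audiogram(f, thr, label = sprintf("synthetic %s", kind))
}
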