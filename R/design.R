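#' Specification of a CR tone alignment design
#'
#' Three alignment styles are supported. `"centered"` places the middle
#' tone at the tinnitus frequency (odd tone count) and grows the set
#' outward so that every adjacent pair of ERB-wide bands meets the target
#' relative overlap `r`. `"enclosing_edge"` (even tone count) places the
#' inner pair so that both inner band edges sit exactly at f_T (their
#' mutual overlap is 0 by construction; `r` governs the remaining pairs).
#' `"enclosing_balanced"` (even tone count) solves the inner pair jointly
#' so that its mutual overlap is `r` and the tinnitus frequency lies at
#' the midpoint of the interval spanned by the two inner bands,
#' f_T = (a_lower + b_upper) / 2.
#'
#' @param style One of `"centered"`, `"enclosing_edge"`,
#'   `"enclosing_balanced"`.
#' @param n_tones Number of CR tones (odd for centered, even for enclosing
#'   styles; at least 2, or 3 for centered).
#' @param r Target relative overlap for adjacent pairs, in (-1, 1):
#'   positive = overlap, negative = gap, 0 = coinciding edges.
#' @param normalization Pairwise overlap normalization, `"min"` or `"max"`.
#' @param f_T Tinnitus frequency in Hz (may be `NA` in a sweep template).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(style = c("centered", "enclosing_edge",
                                  "enclosing_balanced"),
                        n_tones = 4L, r = 0,
                        normalization = c("min", "max"), f_T = NA_real_) {
  style <- match.arg(style)
  normalization <- match.arg(normalization)
  n_tones <- as.integer(n_tones)
  if (is.na(n_tones) || n_tones < 2L) stop("n_tones must be at least 2")
  if (style == "centered" && n_tones %% 2L == 0L)
    stop("centered alignment requires an odd number of tones")
  if (style != "centered" && n_tones %% 2L == 1L)
    stop("enclosing alignments require an even number of tones")
  if (!is.finite(r) || abs(r) >= 1)
    stop("target relative overlap r must satisfy |r| < 1")
  if (!is.na(f_T) && f_T <= 0) stop("f_T must be positive")
  structure(list(style = style, n_tones = n_tones, r = r,
                 normalization = normalization, f_T = f_T),
            class = "design_spec")
}

solver_error <- function(message, bracket = NULL) {
  stop(structure(class = c("erbcr_solver_error", "error", "condition"),
                 list(message = message, call = sys.call(-1),
                      bracket = bracket)))
}

# Solve edge(f) = target for f, where edge is the lower (a) or upper (b)
# band edge. Both edges are increasing in f for audiograms within the
# model's supported loss range, so a geometric bracket expansion plus
# uniroot suffices.
solve_edge <- function(target, edge = c("lower", "upper"), ag = NULL,
                       model = erb_model(), tol = 1e-9) {
  edge <- match.arg(edge)
  val <- function(f) {
    b <- band_at(f, ag, model, warn = FALSE)
    if (edge == "lower") b$a else b$b
  }
  if (edge == "lower") { # f > target
    lo <- target; hi <- target + erb_at(target, ag, model, warn = FALSE)
    tries <- 0L
    while (val(hi) < target && tries < 60L) {
      hi <- target + 2 * (hi - target); tries <- tries + 1L
      if (hi > 4 * target)
        solver_error(sprintf("no bracket for lower edge = %g Hz", target),
                     c(lo, hi))
    }
  } else {               # f < target
    hi <- target; lo <- max(target - erb_at(target, ag, model, warn = FALSE),
                            target / 4)
    tries <- 0L
    while (val(lo) > target && tries < 60L) {
      lo <- max(target - 2 * (target - lo), target / 4); tries <- tries + 1L
      if (lo <= target / 4 && val(lo) > target)
        solver_error(sprintf("no bracket for upper edge = %g Hz", target),
                     c(lo, hi))
    }
  }
  stats::uniroot(function(f) val(f) - target, c(lo, hi), tol = tol)$root
}

#' Place a neighboring CR tone at a target relative overlap
#'
#' Given a tone, finds the frequency of the adjacent tone above or below it
#' whose ERB-wide band overlaps the known tone's band by the target
#' relative amount `r`. The defining equation is implicit (the new tone's
#' band width depends on the audiogram at the unknown frequency), so it is
#' solved by bracketed root finding: the bracket is seeded from the local
#' ERB width and expanded geometrically until the overlap residual changes
#' sign. With steep audiogram features the residual can have several roots;
#' the root closest to the known tone is returned and a multiplicity
#' warning is emitted.
#'
#' @param f_known Known tone frequency in Hz.
#' @param direction `"up"` (new tone above) or `"down"` (below).
#' @param r Target relative overlap, |r| < 1.
#' @param ag An [audiogram] or `NULL`.
#' @param normalization Pairwise normalization, `"min"` or `"max"`.
#' @param model An [erb_model].
#' @param tol Absolute frequency tolerance of the root in Hz.
#' @return The new tone frequency in Hz.
#' @examples
#' place_neighbor(934, "up", r = 0) # 1066.70 Hz: edges coincide
#' @export
place_neighbor <- function(f_known, direction = c("up", "down"), r = 0,
                           ag = NULL, normalization = c("min", "max"),
                           model = erb_model(), tol = 1e-9) {
  direction <- match.arg(direction)
  normalization <- match.arg(normalization)
  if (!is.finite(f_known) || f_known <= 0) stop("f_known must be positive")
  if (!is.finite(r) || abs(r) >= 1) stop("|r| < 1 required")
  band_known <- band_at(f_known, ag, model, warn = FALSE)
  residual <- function(f) {
    b <- band_at(f, ag, model, warn = FALSE)
    if (direction == "up") rd_erb_pair(band_known, b, normalization) - r
    else                   rd_erb_pair(b, band_known, normalization) - r
  }
  w <- band_known$width
  eps <- 1e-6
  # expand away from f_known until the overlap residual changes sign;
  # near f_known the bands nearly coincide so the residual is ~ 1 - r > 0
  offset <- w
  sign_near <- sign(residual(if (direction == "up") f_known + eps
                             else f_known - eps))
  history <- numeric(0)
  repeat {
    cand <- if (direction == "up") f_known + offset else f_known - offset
    if (direction == "up" && cand > 4 * f_known ||
        direction == "down" && cand < f_known / 4)
      solver_error(sprintf(
        "no overlap sign change placing a tone %s from %g Hz (r = %g); bracket offsets tried: %s",
        direction, f_known, r, paste(format(history), collapse = ", ")),
        history)
    history <- c(history, offset)
    if (sign(residual(cand)) != sign_near) break
    offset <- offset * 2
  }
  lo <- if (direction == "up") f_known + eps else cand
  hi <- if (direction == "up") cand else f_known - eps
  # coarse scan: take the sign-change interval nearest the known tone and
  # warn if the residual crosses zero more than once inside the bracket
  grid <- seq(lo, hi, length.out = 65L)
  vals <- vapply(grid, residual, numeric(1))
  flips <- which(diff(sign(vals)) != 0)
  if (length(flips) > 1L)
    warning(sprintf(
      "multiple candidate placements between %.6g and %.6g Hz; choosing the one nearest %g Hz",
      lo, hi, f_known), call. = FALSE)
  pick <- if (direction == "up") flips[1L] else flips[length(flips)]
  if (length(flips) == 0L) pick <- NULL
  interval <- if (is.null(pick)) c(lo, hi) else grid[c(pick, pick + 1L)]
  stats::uniroot(residual, interval, tol = tol)$root
}

make_alignment <- function(spec, tones, ag, model, governed,
                           balance_residual = NA_real_) {
  report <- analyze_alignment(tones, spec$f_T, ag, spec$normalization, model)
  n <- length(tones)
  structure(list(
    spec = spec, tones = tones, bands = report$bands,
    band_T = report$band_T,
    achieved_rd = data.frame(lower = seq_len(n - 1L),
                             upper = seq_len(n - 1L) + 1L,
                             rd = report$pairwise$rd,
                             governed_by_r = governed),
    tinnitus_rd = report$tinnitus$rd,
    balance_residual = balance_residual,
    warnings = report$warnings
  ), class = "tone_alignment")
}

#' @export
print.tone_alignment <- function(x, ...) {
  cat(sprintf("CR tone alignment (%s, n = %d, r = %g, %s-normalized), f_T = %g Hz\n",
              x$spec$style, x$spec$n_tones, x$spec$r,
              x$spec$normalization, x$spec$f_T))
  print(data.frame(tone = seq_along(x$tones),
                   f = round(x$tones, 2),
                   ratio = round(x$tones / x$spec$f_T, 4),
                   a = round(x$bands$a, 2), b = round(x$bands$b, 2)),
        row.names = FALSE)
  cat("achieved adjacent rd:",
      paste(round(x$achieved_rd$rd, 6), collapse = ", "), "\n")
  if (!is.na(x$balance_residual))
    cat("balance residual:", format(x$balance_residual), "Hz\n")
  if (length(x$warnings)) cat("warnings:", x$warnings, sep = "\n  ")
  invisible(x)
}

place_chain <- function(f_start, k, direction, spec, ag, model) {
  out <- numeric(k)
  f <- f_start
  for (i in seq_len(k)) {
    f <- tryCatch(
      place_neighbor(f, direction, spec$r, ag, spec$normalization, model),
      erbcr_solver_error = function(e)
        solver_error(sprintf("tone %d (%s of %g Hz): %s",
                             i, direction, f, conditionMessage(e)), e$bracket))
    out[i] <- f
  }
  out
}

#' Tinnitus-centered CR tone alignment
#'
#' The middle tone equals the tinnitus frequency; the remaining tones are
#' placed outward, one ERB-overlap condition at a time, so that every
#' adjacent pair of bands achieves the target relative overlap `r`.
#'
#' @param spec A [design_spec] with `style = "centered"` (odd `n_tones`)
#'   and a finite `f_T`.
#' @param ag An [audiogram] or `NULL` for normal hearing.
#' @param model An [erb_model].
#' @return A `tone_alignment` object: tones ascending, their bands, the
#'   achieved pairwise overlaps, and accumulated warnings.
#' @examples
#' design_centered(design_spec("centered", 5, r = 0, f_T = 1000))
#' @export
design_centered <- function(spec, ag = NULL, model = erb_model()) {
  stopifnot(inherits(spec, "design_spec"), spec$style == "centered")
  if (!is.finite(spec$f_T)) stop("spec$f_T must be set")
  k <- (spec$n_tones - 1L) %/% 2L
  up <- place_chain(spec$f_T, k, "up", spec, ag, model)
  down <- rev(place_chain(spec$f_T, k, "down", spec, ag, model))
  tones <- c(down, spec$f_T, up)
  make_alignment(spec, tones, ag, model,
                 governed = rep(TRUE, spec$n_tones - 1L))
}

#' Tinnitus-enclosing alignment with inner edges at the tinnitus frequency
#'
#' The two inner tones are solved so that the upper edge of the lower inner
#' band and the lower edge of the upper inner band both sit exactly at f_T;
#' their mutual overlap is therefore 0 by construction, and the target `r`
#' governs the remaining adjacent pairs placed outward.
#'
#' @inheritParams design_centered
#' @param spec A [design_spec] with `style = "enclosing_edge"` (even
#'   `n_tones`).
#' @return A `tone_alignment`; `achieved_rd$governed_by_r` is `FALSE` for
#'   the inner pair.
#' @export
design_enclosing_edge <- function(spec, ag = NULL, model = erb_model()) {
  stopifnot(inherits(spec, "design_spec"), spec$style == "enclosing_edge")
  if (!is.finite(spec$f_T)) stop("spec$f_T must be set")
  f_lo <- solve_edge(spec$f_T, "upper", ag, model)  # b(f_lo) = f_T
  f_hi <- solve_edge(spec$f_T, "lower", ag, model)  # a(f_hi) = f_T
  k <- spec$n_tones %/% 2L - 1L
  up <- place_chain(f_hi, k, "up", spec, ag, model)
  down <- rev(place_chain(f_lo, k, "down", spec, ag, model))
  tones <- c(down, f_lo, f_hi, up)
  governed <- rep(TRUE, spec$n_tones - 1L)
  governed[k + 1L] <- FALSE  # inner pair fixed at rd = 0 by construction
  make_alignment(spec, tones, ag, model, governed)
}

#' Tinnitus-enclosing ERB-balanced alignment
#'
#' The two inner tones are solved jointly so that (i) their bands achieve
#' the target relative overlap `r` and (ii) the tinnitus frequency lies at
#' the midpoint of the interval spanned by the two inner bands,
#' f_T = (a_lower + b_upper) / 2, i.e. the tinnitus band sits symmetrically
#' inside the enclosing pair whether the inner bands coincide, overlap or
#' gap. Implemented as nested 1-D root finds: for each candidate upper
#' inner tone the lower inner tone is recovered from the balancing
#' condition, and the outer residual is the inner-pair overlap minus `r`.
#' Remaining tones are placed outward at `r`.
#'
#' @inheritParams design_centered
#' @param spec A [design_spec] with `style = "enclosing_balanced"` (even
#'   `n_tones`).
#' @return A `tone_alignment` with `balance_residual` =
#'   f_T - (a_lower + b_upper)/2 of the converged inner pair (Hz).
#' @export
design_enclosing_balanced <- function(spec, ag = NULL, model = erb_model()) {
  stopifnot(inherits(spec, "design_spec"), spec$style == "enclosing_balanced")
  if (!is.finite(spec$f_T)) stop("spec$f_T must be set")
  f_T <- spec$f_T
  lower_for <- function(f_hi) {
    b_hi <- band_at(f_hi, ag, model, warn = FALSE)$b
    solve_edge(2 * f_T - b_hi, "lower", ag, model)  # a(f_lo) = 2 f_T - b_hi
  }
  inner_resid <- function(f_hi) {
    f_lo <- lower_for(f_hi)
    if (f_lo >= f_hi) return(2 - spec$r)  # fully merged: far above target
    rd_erb_pair(band_at(f_lo, ag, model, warn = FALSE),
                band_at(f_hi, ag, model, warn = FALSE),
                spec$normalization) - spec$r
  }
  w <- erb_at(f_T, ag, model, warn = FALSE)
  lo <- f_T + 1e-6
  hi <- f_T + w
  tries <- 0L
  last <- NA_real_
  while (sign(inner_resid(hi)) == sign(inner_resid(lo))) {
    hi <- f_T + 2 * (hi - f_T); tries <- tries + 1L
    last <- hi
    if (hi > 4 * f_T || tries > 60L)
      solver_error(sprintf(
        "balanced inner pair did not converge for f_T = %g Hz (last upper iterate %g Hz)",
        f_T, last), c(lo, hi))
  }
  f_hi <- stats::uniroot(inner_resid, c(lo, hi), tol = 1e-9)$root
  f_lo <- lower_for(f_hi)
  k <- spec$n_tones %/% 2L - 1L
  up <- place_chain(f_hi, k, "up", spec, ag, model)
  down <- rev(place_chain(f_lo, k, "down", spec, ag, model))
  tones <- c(down, f_lo, f_hi, up)
  bal <- f_T - (band_at(f_lo, ag, model, warn = FALSE)$a +
                  band_at(f_hi, ag, model, warn = FALSE)$b) / 2
  make_alignment(spec, tones, ag, model,
                 governed = rep(TRUE, spec$n_tones - 1L),
                 balance_residual = bal)
}

#' Run the design solver matching a specification's style
#'
#' @param spec A [design_spec] with finite `f_T`.
#' @param ag An [audiogram] or `NULL`.
#' @param model An [erb_model].
#' @return A `tone_alignment`.
#' @export
design_alignment <- function(spec, ag = NULL, model = erb_model()) {
  switch(spec$style,
         centered = design_centered(spec, ag, model),
         enclosing_edge = design_enclosing_edge(spec, ag, model),
         enclosing_balanced = design_enclosing_balanced(spec, ag, model))
}

#' Independently verify a tone alignment
#'
#' Recomputes every band and pairwise overlap from the stored tones and the
#' audiogram, and reports the worst deviation from the design target, the
#' balancing residual (balanced style), and any ordering violations.
#' Violations are reported, never raised.
#'
#' @param al A `tone_alignment`.
#' @param ag The [audiogram] the alignment was designed for (or `NULL`).
#' @param model An [erb_model].
#' @return A list: `max_rd_residual` (over pairs governed by `r`),
#'   `balance_residual_hz`, `ordering_ok`, `centered_ok` (middle tone at
#'   f_T, centered style only), and a character vector `violations`.
#' @export
verify_alignment <- function(al, ag = NULL, model = erb_model()) {
  stopifnot(inherits(al, "tone_alignment"))
  spec <- al$spec
  tones <- al$tones
  violations <- character(0)
  ordering_ok <- !is.unsorted(tones, strictly = TRUE)
  if (!ordering_ok) violations <- c(violations, "tones not strictly increasing")
  bands <- band_at(sort(tones), ag, model, warn = FALSE)
  n <- length(tones)
  rd <- vapply(seq_len(n - 1L), function(j)
    rd_erb_pair(bands[j, ], bands[j + 1L, ], spec$normalization), numeric(1))
  governed <- al$achieved_rd$governed_by_r
  max_resid <- if (any(governed)) max(abs(rd[governed] - spec$r)) else 0
  if (max_resid > 1e-6)
    violations <- c(violations,
                    sprintf("max pairwise rd residual %.3g exceeds 1e-6",
                            max_resid))
  bal <- NA_real_
  if (spec$style == "enclosing_balanced") {
    half <- spec$n_tones %/% 2L
    bal <- spec$f_T - (bands$a[half] + bands$b[half + 1L]) / 2
    if (abs(bal) > 1e-6)
      violations <- c(violations,
                      sprintf("balance residual %.3g Hz exceeds 1e-6", bal))
  }
  centered_ok <- NA
  if (spec$style == "centered") {
    centered_ok <- isTRUE(all.equal(tones[(n + 1L) %/% 2L], spec$f_T))
    if (!centered_ok)
      violations <- c(violations, "middle tone does not equal f_T")
  }
  list(max_rd_residual = max_resid, balance_residual_hz = bal,
       ordering_ok = ordering_ok, centered_ok = centered_ok,
       violations = violations)
}
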