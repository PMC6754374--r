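# Closed-form oracles for normal hearing (h = 0). Every edge is affine in
# frequency: b(f) = A f + c, a(f) = B f - c, width w(f) = 2k f + 2c, with
# A = 1 + k, B = 1 - k, k = c1 c2 / 2, c = c1 / 2. All placement equations
# are therefore linear and solvable exactly, independent of the package's
# root-finding path.

.oc <- local({
  c1 <- 24.7; c2 <- 0.00437
  k <- c1 * c2 / 2
  list(k = k, c = c1 / 2, A = 1 + k, B = 1 - k, c1 = c1, c2 = c2)
})

oracle_erb <- function(f) .oc$c1 * (.oc$c2 * f + 1)
oracle_a <- function(f) .oc$B * f - .oc$c
oracle_b <- function(f) .oc$A * f + .oc$c

# place the neighbor of a tone at relative overlap r (h = 0)
oracle_place <- function(f, direction, r, normalization = "min") {
  k <- .oc$k; c <- .oc$c; A <- .oc$A; B <- .oc$B
  if (direction == "up") {
    if (normalization == "min") (oracle_b(f) - r * oracle_erb(f) + c) / B
    else (oracle_b(f) + c - 2 * r * c) / (B + 2 * r * k)
  } else {
    if (normalization == "min") (oracle_a(f) - c + 2 * r * c) / (A - 2 * r * k)
    else (oracle_a(f) + r * oracle_erb(f) - c) / A
  }
}

oracle_chain <- function(f_start, n_steps, direction, r, normalization = "min") {
  out <- numeric(n_steps)
  f <- f_start
  for (i in seq_len(n_steps)) {
    f <- oracle_place(f, direction, r, normalization)
    out[i] <- f
  }
  out
}

oracle_centered <- function(f_T, n, r, normalization = "min") {
  half <- (n - 1L) %/% 2L
  c(rev(oracle_chain(f_T, half, "down", r, normalization)), f_T,
    oracle_chain(f_T, half, "up", r, normalization))
}

oracle_enclosing_edge <- function(f_T, n, r, normalization = "min") {
  f_lo <- (f_T - .oc$c) / .oc$A  # b(f_lo) = f_T
  f_hi <- (f_T + .oc$c) / .oc$B  # a(f_hi) = f_T
  half <- n %/% 2L - 1L
  c(rev(oracle_chain(f_lo, half, "down", r, normalization)), f_lo, f_hi,
    oracle_chain(f_hi, half, "up", r, normalization))
}

# inner pair of the balanced enclosing alignment: 2x2 linear system
#   rd(lo, hi) = r  and  a(lo) + b(hi) = 2 f_T
oracle_enclosing_balanced <- function(f_T, n, r, normalization = "min") {
  k <- .oc$k; c <- .oc$c; A <- .oc$A; B <- .oc$B
  # row 1: overlap equation; lower band is the narrower one, so min picks it
  m11 <- if (normalization == "min") A - 2 * r * k else A
  m12 <- if (normalization == "min") -B else -(B + 2 * r * k)
  rhs1 <- 2 * c * (r - 1)
  # row 2: balancing equation  B f_lo + A f_hi = 2 f_T
  det <- m11 * A - m12 * B
  f_lo <- (rhs1 * A - m12 * 2 * f_T) / det
  f_hi <- (m11 * 2 * f_T - rhs1 * B) / det
  half <- n %/% 2L - 1L
  c(rev(oracle_chain(f_lo, half, "down", r, normalization)), f_lo, f_hi,
    oracle_chain(f_hi, half, "up", r, normalization))
}

oracle_design <- function(style, f_T, n, r, normalization = "min") {
  switch(style,
         centered = oracle_centered(f_T, n, r, normalization),
         enclosing_edge = oracle_enclosing_edge(f_T, n, r, normalization),
         enclosing_balanced = oracle_enclosing_balanced(f_T, n, r, normalization))
}

# brute-force grid search for the neighbor placement under an arbitrary
# audiogram: scan the overlap residual on a uniform grid and return the
# sign-change interval nearest the known tone
brute_place <- function(f_known, direction, r, ag, normalization = "min",
                        by = 0.01, span_erbs = 6) {
  w <- erb_at(f_known, ag, warn = FALSE)
  grid <- if (direction == "up")
    seq(f_known + by, f_known + span_erbs * w, by = by)
  else
    seq(max(f_known - span_erbs * w, f_known / 4), f_known - by, by = by)
  bands <- band_at(grid, ag, warn = FALSE)
  known <- band_at(f_known, ag, warn = FALSE)
  num <- if (direction == "up") known$b - bands$a else bands$b - known$a
  den <- if (normalization == "min") pmin(known$width, bands$width)
         else pmax(known$width, bands$width)
  resid <- num / den - r
  flips <- which(diff(sign(resid)) != 0)
  if (!length(flips)) return(NA_real_)
  i <- if (direction == "up") flips[1L] else flips[length(flips)]
  mean(grid[c(i, i + 1L)])
}

# shared synthetic audiograms
ag_flat0 <- function() synth_audiogram("flat", level = 0)
ag_flat40 <- function() synth_audiogram("flat", level = 40)
ag_notch4k <- function() synth_audiogram("notch", center = 4000, depth = 40,
                                         base = 5)
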