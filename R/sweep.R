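# long-format row schema shared by every exportable result
long_table <- function(f_T, tones, bands, rd_pair, rd_tinnitus, warnings) {
  n <- length(tones)
  data.frame(
    f_T = rep(f_T, n),
    tone_index = seq_len(n),
    f_j = tones,
    ratio = tones / f_T,
    a_j = bands$a,
    b_j = bands$b,
    rd_pair = c(rd_pair, NA_real_)[seq_len(n)],
    rd_tinnitus = rd_tinnitus,
    warnings = rep(paste(warnings, collapse = "; "), n),
    stringsAsFactors = FALSE
  )
}

#' @export
as.data.frame.overlap_report <- function(x, ...) {
  long_table(x$f_T, x$tones, x$bands, x$pairwise$rd, x$tinnitus$rd,
             x$warnings)
}

#' @export
as.data.frame.tone_alignment <- function(x, ...) {
  long_table(x$spec$f_T, x$tones, x$bands, x$achieved_rd$rd,
             x$tinnitus_rd, x$warnings)
}

#' Sweep a tone design (or the standard-tone analysis) over f_T
#'
#' Runs the design solver of a [design_spec] template (its `f_T` is
#' replaced by each grid value), or the legacy standard-tone analysis when
#' `template = "standard"`, at every point of a logarithmic grid of
#' tinnitus frequencies. Solver failures at individual grid points are
#' recorded and do not abort the sweep.
#'
#' @param template A [design_spec] (the `f_T` field may be `NA`) or the
#'   string `"standard"`.
#' @param f_T_range Length-2 positive range of tinnitus frequencies, Hz.
#' @param n_points Number of logarithmically spaced grid points.
#' @param ag An [audiogram] or `NULL`.
#' @param model An [erb_model].
#' @return An object of class `sweep_result`: `tag`, `grid`, a long-format
#'   `table` (columns `f_T`, `tone_index`, `f_j`, `ratio`, `a_j`, `b_j`,
#'   `rd_pair`, `rd_tinnitus`, `warnings`), a `failures` data.frame and an
#'   aggregate `warnings` vector.
#' @export
run_sweep <- function(template, f_T_range = c(250, 10000), n_points = 100,
                      ag = NULL, model = erb_model()) {
  if (length(f_T_range) != 2L || any(f_T_range <= 0) ||
      f_T_range[1] > f_T_range[2])
    stop("f_T_range must be a positive increasing interval")
  if (n_points < 1L) stop("n_points must be at least 1")
  standard <- identical(template, "standard")
  if (!standard && !inherits(template, "design_spec"))
    stop("template must be a design_spec or \"standard\"")
  grid <- exp(seq(log(f_T_range[1]), log(f_T_range[2]),
                  length.out = n_points))
  rows <- vector("list", length(grid))
  fails <- list()
  for (i in seq_along(grid)) {
    ft <- grid[i]
    res <- tryCatch({
      if (standard) {
        rep_ <- analyze_alignment(standard_tones(ft), ft, ag,
                                  model = model)
        as.data.frame(rep_)
      } else {
        spec_i <- template
        spec_i$f_T <- ft
        as.data.frame(design_alignment(spec_i, ag, model))
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(f_T = ft, error = conditionMessage(res))
    } else {
      rows[[i]] <- res
    }
  }
  table <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  failures <- if (length(fails)) do.call(rbind, fails)
              else data.frame(f_T = numeric(0), error = character(0))
  structure(list(
    tag = if (standard) "standard" else template$style,
    grid = grid, table = table, failures = failures,
    warnings = unique(unlist(strsplit(
      table$warnings[nzchar(table$warnings)], "; ", fixed = TRUE)))
  ), class = "sweep_result")
}

#' @export
as.data.frame.sweep_result <- function(x, ...) x$table

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep (%s): %d grid points, %d rows, %d failures\n",
              x$tag, length(x$grid), nrow(x$table), nrow(x$failures)))
  if (length(x$warnings)) cat("warnings:", x$warnings, sep = "\n  ")
  invisible(x)
}

#' Export a result to CSV or JSON
#'
#' Writes the long-format table of a sweep, overlap report or tone
#' alignment (fixed column order `f_T`, `tone_index`, `f_j`, `ratio`,
#' `a_j`, `b_j`, `rd_pair`, `rd_tinnitus`, `warnings`) as CSV, or a
#' structured JSON document. Floats carry 6 significant digits.
#'
#' @param result A `sweep_result`, `overlap_report` or `tone_alignment`.
#' @param format `"csv"` or `"json"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_result <- function(result, format = c("csv", "json"), path) {
  format <- match.arg(format)
  tab <- as.data.frame(result)
  if (is.null(tab)) tab <- long_table(numeric(0), numeric(0),
                                      data.frame(a = numeric(0),
                                                 b = numeric(0)),
                                      numeric(0), numeric(0), character(0))
  ok <- tryCatch({
    if (format == "csv") {
      num <- vapply(tab, is.numeric, logical(1)) &
        names(tab) != "tone_index"
      tab[num] <- lapply(tab[num], signif, digits = 6)
      utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
    } else {
      payload <- list(table = tab)
      if (inherits(result, "tone_alignment")) {
        payload <- c(list(
          spec = unclass(result$spec),
          tones = result$tones,
          achieved_rd = result$achieved_rd,
          balance_residual_hz = result$balance_residual,
          warnings = result$warnings), payload)
      } else if (inherits(result, "sweep_result")) {
        payload <- c(list(tag = result$tag,
                          failures = result$failures,
                          warnings = result$warnings), payload)
      } else if (inherits(result, "overlap_report")) {
        payload <- c(list(f_T = result$f_T,
                          normalization = result$normalization,
                          warnings = result$warnings), payload)
      }
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 6,
                           na = "null")
    }
    TRUE
  }, error = function(e)
    stop("failed to write ", path, ": ", conditionMessage(e)))
  invisible(path)
}
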