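#' Tukey median polish of a plate grid
#'
#' Decomposes a rectangular plate of values for one feature additively into
#' `overall median + row effect + column effect + residual`, removing
#' positional artifacts such as evaporation towards plate borders.  The
#' polished value of a well is `overall + residual`, i.e. the measurement
#' with the positional effects removed.
#'
#' Sweeps alternate between rows and columns (rows first) until the change
#' in the sum of absolute residuals falls below `eps` or `maxiter` is
#' reached; ties in medians use the usual midpoint convention.  Plates with
#' a single row (or column) degenerate to a column-only (row-only) polish,
#' with a warning.
#'
#' @param x numeric matrix laid out as the physical plate (rows x columns).
#'   `NA` entries (absent wells) are allowed and ignored in medians.
#' @param eps convergence tolerance, default `1e-6`.
#' @param maxiter maximum number of full sweeps, default 100.
#'
#' @return list with elements `overall`, `row` (row effects), `col`
#'   (column effects), `residuals`, and `polished` (= overall + residuals).
#' @export
polish_plate <- function(x, eps = 1e-6, maxiter = 100L) {
  x <- as.matrix(x)
  if (nrow(x) == 1L || ncol(x) == 1L) {
    warning("plate grid has a single ", if (nrow(x) == 1L) "row" else "column",
            "; polishing the other dimension only")
    if (nrow(x) == 1L) {
      ce <- apply(x, 2, median, na.rm = TRUE)
      overall <- median(ce)
      ce <- ce - overall
      res <- sweep(x, 2, ce) - overall
      return(list(overall = overall, row = 0, col = ce,
                  residuals = res, polished = overall + res))
    } else {
      re <- apply(x, 1, median, na.rm = TRUE)
      overall <- median(re)
      re <- re - overall
      res <- sweep(x, 1, re) - overall
      return(list(overall = overall, row = re, col = 0,
                  residuals = res, polished = overall + res))
    }
  }
  fit <- medpolish(x, eps = eps, maxiter = maxiter, trace.iter = FALSE,
                   na.rm = TRUE)
  list(overall = fit$overall, row = fit$row, col = fit$col,
       residuals = fit$residuals, polished = fit$overall + fit$residuals)
}

#' Remove plate-position artifacts from a well table
#'
#' Runs [polish_plate()] per plate and per feature and replaces each well's
#' value by its polished value (overall median + residual).
#'
#' @param wt a [well_table()].
#' @param eps,maxiter passed to [polish_plate()].
#' @return the polished `well_table` (flag `"polished"` added).
#' @export
polish_wells <- function(wt, eps = 1e-6, maxiter = 100L) {
  stopifnot(inherits(wt, "well_table"))
  vals <- wt$values
  meta <- wt$meta
  for (p in unique(meta$plate)) {
    idx <- which(meta$plate == p)
    rows <- sort(unique(meta$row[idx]))
    cols <- sort(unique(meta$col[idx]))
    ri <- match(meta$row[idx], rows)
    ci <- match(meta$col[idx], cols)
    grid <- matrix(NA_real_, length(rows), length(cols))
    for (f in seq_len(ncol(vals))) {
      grid[] <- NA_real_
      grid[cbind(ri, ci)] <- vals[idx, f]
      pol <- polish_plate(grid, eps = eps, maxiter = maxiter)
      vals[idx, f] <- pol$polished[cbind(ri, ci)]
    }
  }
  wt$values <- vals
  wt$flags <- union(wt$flags, "polished")
  wt
}

#' Scale features to the unit interval with percentile clipping
#'
#' Per feature and per batch, values outside the configured lower/upper
#' percentiles are treated as outliers and clipped, then the clip bounds
#' are mapped linearly onto \[0, 1\].  The default clip pair is the
#' symmetric (0.5th, 99.5th) percentiles.
#'
#' @param wt a [well_table()].
#' @param lower,upper clip percentiles as probabilities (defaults 0.005 and
#'   0.995).
#' @return the scaled `well_table` (flag `"scaled"`).  Features whose clip
#'   bounds coincide (zero spread) are mapped to 0.5 and recorded in the
#'   `"zero_spread"` attribute.
#' @export
scale_unit_interval <- function(wt, lower = 0.005, upper = 0.995) {
  stopifnot(inherits(wt, "well_table"), lower < upper)
  vals <- wt$values
  flagged <- character()
  for (b in unique(wt$meta$batch)) {
    idx <- which(wt$meta$batch == b)
    for (f in seq_len(ncol(vals))) {
      x <- vals[idx, f]
      lo <- quantile(x, lower, names = FALSE)
      hi <- quantile(x, upper, names = FALSE)
      if (hi - lo < .Machine$double.eps^0.5) {
        vals[idx, f] <- 0.5
        flagged <- union(flagged, colnames(vals)[f])
      } else {
        x <- pmin(pmax(x, lo), hi)
        vals[idx, f] <- (x - lo) / (hi - lo)
      }
    }
  }
  wt$values <- vals
  wt$flags <- union(wt$flags, "scaled")
  attr(wt, "zero_spread") <- flagged
  wt
}

#' Full plate normalisation
#'
#' Convenience wrapper: median polish per plate ([polish_wells()]) followed
#' by robust unit-interval scaling per batch ([scale_unit_interval()]).
#'
#' @inheritParams polish_wells
#' @inheritParams scale_unit_interval
#' @param polish set to `FALSE` to skip the median polish.
#' @return normalized `well_table`.
#' @export
normalize_wells <- function(wt, polish = TRUE, eps = 1e-6, maxiter = 100L,
                            lower = 0.005, upper = 0.995) {
  if (polish) wt <- polish_wells(wt, eps = eps, maxiter = maxiter)
  scale_unit_interval(wt, lower = lower, upper = upper)
}
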