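#' Perturbation validity filter
#'
#' Decides which perturbations are usable: wells below the minimum cell
#' count are flagged invalid; single-drug perturbations need at least
#' `min_wells` valid replicate wells; drugs whose activity drifts over the
#' screen are excluded by a stability test.  Stability fits a linear
#' regression `f(x) = a + b x` of the DMSO-normalized well cell count
#' against the temporal replicate order; a drug fails if BOTH `b >
#' stability_slope` AND the relative difference between its largest and
#' smallest well cell count is at least `stability_diff`.
#'
#' Cell counts enter the regression divided by the median DMSO cell count
#' of the same plate, which makes the slope threshold dimensionless.
#'
#' @param wt a [well_table()] whose metadata carries `cell_count` and
#'   `t_order`.
#' @param min_cells minimum cells per well (default 30; a well with 29
#'   cells is excluded, one with 30 retained).
#' @param min_wells minimum valid replicate wells per single drug
#'   (default 3).
#' @param stability_slope slope threshold (default 0.05).
#' @param stability_diff relative max-min cell-count difference threshold
#'   (default 0.30).
#'
#' @return An object of class `perturbation_validity`: list with
#'   `treatments` (per-treatment diagnostics and the overall `valid` flag)
#'   and `wells` (per-well cell-count validity).  A drug is valid iff all
#'   criteria pass; drugs observed at a single time point are marked
#'   `"not assessed"` for stability and pass that criterion.
#' @export
filter_perturbations <- function(wt, min_cells = 30L, min_wells = 3L,
                                 stability_slope = 0.05,
                                 stability_diff = 0.30) {
  stopifnot(inherits(wt, "well_table"))
  meta <- wt$meta
  if (all(is.na(meta$cell_count)))
    stop("cell counts unavailable; aggregate from a cell table first")
  well_ok <- !is.na(meta$cell_count) & meta$cell_count >= min_cells
  wells <- data.frame(key = meta$key, cell_count = meta$cell_count,
                      valid = well_ok, stringsAsFactors = FALSE)

  # plate-wise DMSO median counts for slope normalization
  dmso_med <- tapply(meta$cell_count[meta$role == "control"],
                     meta$plate[meta$role == "control"], median)

  trts <- unique(meta$treatment[meta$role != "control"])
  out <- lapply(trts, function(tr) {
    i <- which(meta$treatment == tr)
    role <- meta$role[i[1]]
    nv <- sum(well_ok[i])
    slope <- intercept <- rel_diff <- NA_real_
    stab_fail <- FALSE
    note <- ""
    if (role == "single") {
      j <- i[well_ok[i]]
      if (length(unique(meta$t_order[j])) < 2) {
        note <- "not assessed"
      } else {
        y <- meta$cell_count[j] / unname(dmso_med[as.character(meta$plate[j])])
        x <- meta$t_order[j]
        cf <- coef(lm(y ~ x))
        intercept <- unname(cf[1]); slope <- unname(cf[2])
        cnt <- meta$cell_count[j]
        rel_diff <- (max(cnt) - min(cnt)) / max(cnt)
        stab_fail <- slope > stability_slope && rel_diff >= stability_diff
      }
      min_wells_fail <- nv < min_wells
    } else {
      min_wells_fail <- nv < 1L
    }
    data.frame(treatment = tr, role = role, n_wells = length(i),
               n_valid_wells = nv, intercept = intercept, slope = slope,
               rel_diff = rel_diff, stability_fail = stab_fail,
               min_wells_fail = min_wells_fail,
               valid = !min_wells_fail && !stab_fail,
               note = note, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  structure(list(treatments = tab, wells = wells,
                 params = list(min_cells = min_cells, min_wells = min_wells,
                               stability_slope = stability_slope,
                               stability_diff = stability_diff)),
            class = "perturbation_validity")
}

#' @export
print.perturbation_validity <- function(x, ...) {
  tab <- x$treatments
  cat("Perturbation validity:", sum(tab$valid), "of", nrow(tab),
      "treatments valid;",
      sum(!x$wells$valid), "of", nrow(x$wells), "wells below",
      x$params$min_cells, "cells\n")
  if (any(tab$stability_fail))
    cat("  unstable drugs:",
        paste(tab$treatment[tab$stability_fail], collapse = ", "), "\n")
  invisible(x)
}
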