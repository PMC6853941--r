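#' Well-level feature table
#'
#' Container for a wells x features matrix together with per-well metadata
#' (plate layout, batch, treatment role and identity, replicate structure,
#' cell counts).  This is the unit all preprocessing operates on.
#'
#' @param values numeric matrix, one row per well, one column per feature.
#'   Row names must equal `plate:well` keys of `meta`.
#' @param meta data.frame with one row per well.  Required columns:
#'   `plate`, `well`, `row`, `col`, `role` (one of `"control"`, `"single"`,
#'   `"combination"`), `drug_a`, `drug_b` (`NA` where not applicable),
#'   `replicate`, `t_order` (temporal replicate order), `cell_count`.
#'   A `batch` column is added (single batch) if absent, and a `treatment`
#'   id column is derived from the drug columns if absent.
#' @param flags character vector of provenance flags (e.g. `"aggregated"`,
#'   `"polished"`, `"scaled"`).
#'
#' @return An object of class `well_table`: a list with elements `values`,
#'   `meta` and `flags`.
#' @export
well_table <- function(values, meta, flags = character()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("plate", "well", "row", "col", "role")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("plate map is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"batch" %in% names(meta)) meta$batch <- 1L
  for (col in c("drug_a", "drug_b")) if (!col %in% names(meta)) meta[[col]] <- NA_character_
  if (!"replicate" %in% names(meta)) meta$replicate <- 1L
  if (!"t_order" %in% names(meta)) meta$t_order <- meta$replicate
  if (!"cell_count" %in% names(meta)) meta$cell_count <- NA_integer_
  if (!"treatment" %in% names(meta)) {
    meta$treatment <- ifelse(meta$role == "control", "control",
                      ifelse(meta$role == "single", meta$drug_a,
                             .pair_id(meta$drug_a, meta$drug_b)))
  }
  bad_role <- setdiff(unique(meta$role), c("control", "single", "combination"))
  if (length(bad_role))
    stop("unknown treatment role(s): ", paste(bad_role, collapse = ", "))
  meta$key <- .pt_key(meta$plate, meta$well)
  if (anyDuplicated(meta$key))
    stop("duplicated plate/well entries in plate map")
  if (is.null(rownames(values)))
    stop("feature matrix must carry plate:well row names")
  if (!all(rownames(values) %in% meta$key))
    stop("wells present in the feature table but absent from the plate map")
  meta <- meta[match(rownames(values), meta$key), , drop = FALSE]
  rownames(meta) <- NULL
  if (!all(is.finite(values)))
    stop("feature values must be finite")
  if (any(!is.na(meta$cell_count) & meta$cell_count < 0))
    stop("cell counts must be non-negative")
  structure(list(values = values, meta = meta, flags = flags),
            class = "well_table")
}

#' @export
print.well_table <- function(x, ...) {
  cat("Well feature table:", nrow(x$values), "wells x",
      ncol(x$values), "features\n")
  cat("  plates:", length(unique(x$meta$plate)),
      " batches:", length(unique(x$meta$batch)), "\n")
  cat("  roles: ", paste(sprintf("%s=%d", names(table(x$meta$role)),
                                 table(x$meta$role)), collapse = ", "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate per-cell measurements to per-well medians
#'
#' Collapses a per-cell feature table to one row per well by taking, for
#' every feature, the median over all cells of the well.  The median is
#' robust against the heavy-tailed single-cell variation typical of
#' image-based profiling.
#'
#' @param cells data.frame of per-cell measurements.  Either wide (columns
#'   `plate`, `well`, optionally `cell`, plus one numeric column per
#'   feature) or long (columns `plate`, `well`, `cell`, `feature`,
#'   `value`).
#' @param meta plate-map data.frame, see [well_table()].  Wells listed in
#'   the plate map but without any cells are dropped with a logged reason
#'   (attribute `"dropped"` of the result), not an error.
#'
#' @return A [well_table()] with flag `"aggregated"`.  Cell counts are
#'   recomputed from the cell table.
#' @export
aggregate_wells <- function(cells, meta) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  if (all(c("feature", "value") %in% names(cells))) {
    # long form -> wide
    key <- .pt_key(cells$plate, cells$well)
    cellid <- if ("cell" %in% names(cells)) cells$cell else 1L
    wide <- reshape(
      data.frame(key = key, cell = cellid, feature = cells$feature,
                 value = cells$value, stringsAsFactors = FALSE),
      idvar = c("key", "cell"), timevar = "feature", direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    feats <- setdiff(names(wide), c("key", "cell"))
    keys <- wide$key
    mat <- as.matrix(wide[, feats, drop = FALSE])
  } else {
    keys <- .pt_key(cells$plate, cells$well)
    feats <- setdiff(names(cells), c("plate", "well", "cell"))
    mat <- as.matrix(cells[, feats, drop = FALSE])
    storage.mode(mat) <- "double"
  }
  idx <- split(seq_len(nrow(mat)), keys)
  med <- vapply(idx, function(i)
    apply(mat[i, , drop = FALSE], 2, median), numeric(ncol(mat)))
  med <- if (is.matrix(med)) t(med)
         else matrix(med, ncol = 1,
                     dimnames = list(names(idx), colnames(mat)))
  counts <- vapply(idx, length, integer(1))

  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  mkey <- .pt_key(meta$plate, meta$well)
  extra <- setdiff(rownames(med), mkey)
  if (length(extra))
    stop("cells observed in wells absent from the plate map: ",
         paste(head(extra, 5), collapse = ", "))
  dropped <- setdiff(mkey, rownames(med))
  if (length(dropped)) {
    meta <- meta[!mkey %in% dropped, , drop = FALSE]
    mkey <- .pt_key(meta$plate, meta$well)
  }
  med <- med[match(mkey, rownames(med)), , drop = FALSE]
  meta$cell_count <- counts[match(mkey, names(counts))]
  wt <- well_table(med, meta, flags = "aggregated")
  attr(wt, "dropped") <- if (length(dropped))
    data.frame(key = dropped, reason = "no cells", stringsAsFactors = FALSE)
  else NULL
  wt
}
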