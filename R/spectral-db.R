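# Labelled pixel-spectra tables: the X / Y_h / Y_c matrices used for
# modelling. X holds one reflectance spectrum per row (columns =
# wavelengths); Y_h carries the continuous annotations (beaker mean
# concentration, polyp mortality) used by PLS; Y_c the exposure category
# used by the classifier.

#' Construct a spectra table
#'
#' @param X numeric matrix, rows = pixels, columns = wavelengths
#' @param wavelengths numeric vector, nm, one per column of `X`
#' @param meta data.frame with one row per row of `X`; must contain
#'   `sample_id`, `morph`, `px_row`, `px_col`
#' @param y_h optional data.frame with columns `concentration_mg_l`,
#'   `mortality`
#' @param y_c optional factor/character of exposure categories
#' @return object of class `spectra_table`
#' @export
spectra_table <- function(X, wavelengths, meta, y_h = NULL, y_c = NULL) {
  stopifnot(is.matrix(X), length(wavelengths) == ncol(X),
            nrow(meta) == nrow(X),
            all(c("sample_id", "morph", "px_row", "px_col") %in% names(meta)))
  if (!is.null(y_h)) {
    stopifnot(nrow(y_h) == nrow(X))
    if (any(y_h$mortality < 0 | y_h$mortality > 1, na.rm = TRUE))
      stop("mortality must lie in [0, 1]")
  }
  if (!is.null(y_c)) stopifnot(length(y_c) == nrow(X))
  structure(list(X = X, wavelengths = as.numeric(wavelengths), meta = meta,
                 y_h = y_h, y_c = y_c), class = "spectra_table")
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("<spectra_table> %d pixels x %d wavelengths (%.1f-%.1f nm), %d samples\n",
              nrow(x$X), ncol(x$X), min(x$wavelengths), max(x$wavelengths),
              length(unique(x$meta$sample_id))))
  if (!is.null(x$y_c)) cat("  annotated: Y_h, Y_c present\n")
  invisible(x)
}

#' Number of pixel rows in a spectra table
#' @param table a `spectra_table`
#' @return integer row count
#' @export
n_spectra <- function(table) nrow(table$X)

#' Extract labelled pixel spectra from a reflectance cube
#'
#' One row per masked, unsaturated pixel. Samples whose mask is empty (or
#' fully saturated) are dropped with a warning. Per-sample pixel counts are
#' attached as attribute `pixel_counts`.
#'
#' @param refl_cube a reflectance [spectral_cube]
#' @param rois named list of logical masks `[rows, cols]`, one per sample;
#'   masks must be disjoint
#' @param sample_info optional data.frame with `sample_id`, `morph` (and any
#'   further columns to carry along, e.g. `group`, `replicate`)
#' @return a [spectra_table] (unannotated: `y_h`, `y_c` are `NULL`)
#' @export
extract_pixels <- function(refl_cube, rois, sample_info = NULL) {
  stopifnot(inherits(refl_cube, "spectral_cube"), length(rois) > 0,
            !is.null(names(rois)))
  d <- dim(refl_cube$data)
  overlap <- Reduce(`+`, lapply(rois, function(m) m * 1L))
  if (any(overlap > 1)) stop("ROI masks must be disjoint across samples")
  Xs <- list(); metas <- list(); counts <- integer(0)
  flat <- matrix(refl_cube$data, d[1] * d[2], d[3])
  for (id in names(rois)) {
    m <- rois[[id]] & !refl_cube$saturated
    idx <- which(m)
    if (length(idx) == 0) {
      warning("sample ", id, " has no usable pixels; excluded")
      next
    }
    counts[id] <- length(idx)
    rc <- arrayInd(idx, d[1:2])
    Xs[[id]] <- flat[idx, , drop = FALSE]
    info <- if (!is.null(sample_info) && id %in% sample_info$sample_id)
      sample_info[sample_info$sample_id == id, , drop = FALSE][1, ]
      else data.frame(sample_id = id, morph = NA_character_)
    meta_i <- info[rep(1, length(idx)), setdiff(names(info), c("px_row", "px_col")),
                   drop = FALSE]
    meta_i$px_row <- rc[, 1]; meta_i$px_col <- rc[, 2]
    metas[[id]] <- meta_i
  }
  if (length(Xs) == 0) stop("no sample yielded any usable pixels")
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  out <- spectra_table(do.call(rbind, Xs), refl_cube$wavelengths, meta)
  attr(out, "pixel_counts") <- counts
  out
}

#' Crop a spectra table to a wavelength interval
#'
#' Retains columns whose wavelength lies in the closed interval
#' `[low_nm, high_nm]`. Row count is never changed. On the default
#' instrument grid (823 channels over 381--846 nm) the 400--750 nm crop
#' keeps 619 channels.
#'
#' @param table a [spectra_table]
#' @param low_nm,high_nm closed crop bounds, nm; must lie inside the
#'   recorded range
#' @return the cropped [spectra_table]
#' @export
crop_wavelengths <- function(table, low_nm = 400, high_nm = 750) {
  stopifnot(inherits(table, "spectra_table"))
  wl <- table$wavelengths
  tol <- 1e-9
  if (low_nm < min(wl) - tol || high_nm > max(wl) + tol)
    stop(sprintf("requested range [%g, %g] outside recorded range [%g, %g]",
                 low_nm, high_nm, min(wl), max(wl)))
  keep <- wl >= low_nm - tol & wl <= high_nm + tol
  if (!any(keep)) stop("crop removes every wavelength column")
  table$X <- table$X[, keep, drop = FALSE]
  table$wavelengths <- wl[keep]
  table
}

#' Annotate a spectra table with exposure chemistry and mortality
#'
#' Fills `Y_h` with each row's beaker mean concentration (arithmetic mean of
#' the beaker measurements at 0, 24, 48 and 72 h) and its sample's polyp
#' mortality, and `Y_c` with the exposure category from the LC rule.
#'
#' @param table a [spectra_table] whose `meta` contains `group` and
#'   `replicate` columns (the beaker assignment)
#' @param chemistry long-format chemistry table (see
#'   [simulate_experiment()]): columns `group`, `replicate`, `phase`,
#'   `time_h`, `concentration_mg_l`
#' @param polyps per-sample polyp table: columns `sample_id`,
#'   `polyps_alive_before`, `polyps_dead_after`
#' @param rule a [category_rule()]
#' @return the annotated [spectra_table]
#' @export
annotate_spectra <- function(table, chemistry, polyps,
                             rule = category_rule()) {
  stopifnot(inherits(table, "spectra_table"),
            all(c("group", "replicate") %in% names(table$meta)))
  bk <- chemistry[chemistry$phase == "beaker" &
                    chemistry$time_h %in% c(0, 24, 48, 72), ]
  key <- paste(bk$group, bk$replicate)
  means <- tapply(bk$concentration_mg_l, key, mean)
  row_key <- paste(table$meta$group, table$meta$replicate)
  missing <- setdiff(unique(row_key), names(means))
  if (length(missing) > 0)
    stop("missing chemistry for beakers: ", paste(missing, collapse = ", "))
  conc <- as.numeric(means[row_key])
  mort_map <- setNames(polyps$polyps_dead_after / polyps$polyps_alive_before,
                       polyps$sample_id)
  missing_p <- setdiff(unique(table$meta$sample_id), names(mort_map))
  if (length(missing_p) > 0)
    stop("missing polyp records for samples: ", paste(missing_p, collapse = ", "))
  table$y_h <- data.frame(concentration_mg_l = conc,
                          mortality = as.numeric(mort_map[table$meta$sample_id]))
  table$y_c <- assign_category(conc, rule)
  table
}

#' Split a spectra table by colour morph
#'
#' @param table a [spectra_table]
#' @return named list of [spectra_table]s, one per morph present
#' @export
split_by_morph <- function(table) {
  morphs <- unique(table$meta$morph)
  out <- lapply(morphs, function(m) subset_spectra(table, table$meta$morph == m))
  names(out) <- morphs
  out
}

#' Subset the rows of a spectra table
#'
#' @param table a [spectra_table]
#' @param i logical or integer row index
#' @return the subsetted [spectra_table]
#' @export
subset_spectra <- function(table, i) {
  spectra_table(table$X[i, , drop = FALSE], table$wavelengths,
                table$meta[i, , drop = FALSE],
                if (!is.null(table$y_h)) table$y_h[i, , drop = FALSE],
                if (!is.null(table$y_c)) table$y_c[i])
}

#' Write / read a spectra table as CSV + JSON sidecar
#'
#' The flat CSV holds the metadata and annotation columns followed by one
#' column per wavelength (`wl_<nm>`); the JSON sidecar records the
#' wavelength grid.
#'
#' @param table a [spectra_table]
#' @param path CSV path; the sidecar is written at `<path>.json`
#' @return `path`, invisibly
#' @export
spectra_write <- function(table, path) {
  df <- table$meta
  if (!is.null(table$y_h)) df <- cbind(df, table$y_h)
  if (!is.null(table$y_c)) df$category <- as.character(table$y_c)
  Xdf <- as.data.frame(table$X)
  names(Xdf) <- sprintf("wl_%.4f", table$wavelengths)
  write.csv(cbind(df, Xdf), path, row.names = FALSE)
  jsonlite::write_json(list(wavelengths = table$wavelengths,
                            n_pixels = nrow(table$X)),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname spectra_write
#' @export
spectra_read <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  wl_cols <- grep("^wl_", names(df))
  X <- as.matrix(df[, wl_cols])
  dimnames(X) <- NULL
  meta_cols <- setdiff(names(df)[-wl_cols],
                       c("concentration_mg_l", "mortality", "category"))
  y_h <- if (all(c("concentration_mg_l", "mortality") %in% names(df)))
    df[, c("concentration_mg_l", "mortality")]
  y_c <- if ("category" %in% names(df))
    factor(df$category, levels = c("low", "medium", "high"))
  spectra_table(X, side$wavelengths, df[, meta_cols, drop = FALSE], y_h, y_c)
}
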