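# Reflectance calibration against a Spectralon panel and an inclined PVC
# plate. Intensity recorded through water is converted to reflectance by
# dividing by a per-pixel, per-height conversion factor A(x, z, lambda) that
# bundles illumination, cross-track geometry and water-column attenuation.

#' Fit the Spectralon panel calibration
#'
#' For every slit column x covered by the panel mask, the conversion factor
#' is the mean recorded panel intensity divided wavelength-wise by the
#' calibrated panel reflectance: `A_spec(x, lambda) = I_spec(x, lambda) /
#' R_spec(lambda)`. Masked frames along the scan direction are averaged
#' (reduces noise; identical expectation to using single frames).
#'
#' @param cube a [spectral_cube] of recorded intensity
#' @param spectralon_mask logical matrix `[rows, cols]` marking panel pixels
#' @param r_spec calibrated Spectralon reflectance: scalar or vector on the
#'   cube's wavelength grid; strictly positive
#' @param panel_height_cm height of the panel's top surface, cm
#' @return object of class `panel_calibration` with per-column conversion
#'   factors `a_spec` (`[n_cols_covered, n_bands]`), the covered column
#'   indices `x`, `r_spec`, the panel pixel count `n_spec` and the count of
#'   excluded saturated pixels
#' @export
fit_spectralon <- function(cube, spectralon_mask, r_spec,
                           panel_height_cm = 3) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$data)
  stopifnot(identical(dim(spectralon_mask), d[1:2]))
  r_spec <- rep_len(as.numeric(r_spec), d[3])
  if (any(r_spec <= 0)) stop("r_spec must be strictly positive")
  usable <- spectralon_mask & !cube$saturated
  n_excluded <- sum(spectralon_mask & cube$saturated)
  if (!any(usable)) stop("all Spectralon pixels are saturated or mask is empty")
  cols <- which(colSums(usable) > 0)
  a_spec <- matrix(NA_real_, length(cols), d[3])
  for (j in seq_along(cols)) {
    rows_j <- which(usable[, cols[j]])
    i_mean <- if (length(rows_j) == 1L) cube$data[rows_j, cols[j], ]
      else colMeans(matrix(cube$data[rows_j, cols[j], ], length(rows_j), d[3]))
    a_spec[j, ] <- i_mean / r_spec
  }
  structure(list(a_spec = a_spec, x = cols, r_spec = r_spec,
                 n_spec = sum(usable), n_saturated_excluded = n_excluded,
                 panel_height_cm = panel_height_cm,
                 wavelengths = cube$wavelengths),
            class = "panel_calibration")
}

#' Derive the PVC plate reflectance from panel-height PVC pixels
#'
#' Applies the Spectralon conversion factors to PVC pixels observed at the
#' panel's height: `R_PVC(lambda) = sum_x I_PVC(x, z_panel, lambda) /
#' (N A_spec(x, lambda))`, pooled over the panel's slit columns into a
#' single spectrum (the left side is x-independent).
#'
#' @param cube a [spectral_cube] containing the PVC plate
#' @param pvc_mask_at_panel_height logical matrix marking PVC pixels whose
#'   height equals the panel height
#' @param panel_cal a `panel_calibration` from [fit_spectralon()]
#' @return numeric reflectance spectrum `r_pvc` on the cube's grid
#' @export
derive_pvc_reflectance <- function(cube, pvc_mask_at_panel_height, panel_cal) {
  stopifnot(inherits(cube, "spectral_cube"),
            inherits(panel_cal, "panel_calibration"))
  d <- dim(cube$data)
  usable <- pvc_mask_at_panel_height & !cube$saturated
  if (!any(usable)) stop("empty PVC mask at panel height")
  cols <- intersect(which(colSums(usable) > 0), panel_cal$x)
  if (length(cols) == 0)
    stop("PVC mask does not overlap the Spectralon slit columns")
  acc <- matrix(0, length(cols), d[3])
  for (j in seq_along(cols)) {
    rows_j <- which(usable[, cols[j]])
    i_mean <- if (length(rows_j) == 1L) cube$data[rows_j, cols[j], ]
      else colMeans(matrix(cube$data[rows_j, cols[j], ], length(rows_j), d[3]))
    acc[j, ] <- i_mean / panel_cal$a_spec[match(cols[j], panel_cal$x), ]
  }
  colMeans(acc)
}

#' Build the height-resolved calibration from the inclined PVC plate
#'
#' For every slit column x and every plate height z, the conversion factor
#' is `A(x, z, lambda) = I_PVC(x, z, lambda) / R_PVC(lambda)`. With the
#' forward model's doubled-vertical-distance path, higher objects have a
#' shorter optical path, so with positive attenuation A *increases* with z
#' (this generator sign convention is asserted in the tests). Between
#' sampled heights A is interpolated linearly in z.
#'
#' @param cube a [spectral_cube] containing the inclined plate
#' @param pvc_mask logical matrix marking inclined-plate pixels
#' @param heights_cm numeric matrix of per-pixel heights (cm), used where
#'   `pvc_mask` is `TRUE`
#' @param r_pvc PVC reflectance spectrum from [derive_pvc_reflectance()]
#' @return object of class `height_calibration`: array `a` of shape
#'   `[n_cols, n_heights, n_bands]`, `height_grid_cm`, covered columns `x`
#' @export
build_height_calibration <- function(cube, pvc_mask, heights_cm, r_pvc) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$data)
  r_pvc <- rep_len(as.numeric(r_pvc), d[3])
  if (any(r_pvc <= 0)) stop("r_pvc must be strictly positive")
  usable <- pvc_mask & !cube$saturated
  if (!any(usable)) stop("empty inclined-plate mask")
  zs <- sort(unique(heights_cm[usable]))
  cols <- which(colSums(usable) > 0)
  a <- array(NA_real_, c(length(cols), length(zs), d[3]))
  for (k in seq_along(zs)) {
    at_z <- usable & heights_cm == zs[k]
    for (j in seq_along(cols)) {
      rows_j <- which(at_z[, cols[j]])
      if (length(rows_j) == 0) next
      i_mean <- if (length(rows_j) == 1L) cube$data[rows_j, cols[j], ]
        else colMeans(matrix(cube$data[rows_j, cols[j], ],
                             length(rows_j), d[3]))
      a[j, k, ] <- i_mean / r_pvc
    }
  }
  # columns must cover every height; drop heights with gaps
  ok <- apply(a, 2, function(m) all(is.finite(m)))
  if (!any(ok)) stop("no plate height is covered across all its columns")
  structure(list(a = a[, ok, , drop = FALSE], height_grid_cm = zs[ok],
                 x = cols, r_pvc = r_pvc, wavelengths = cube$wavelengths),
            class = "height_calibration")
}

#' Interpolate the conversion factor at a requested height
#'
#' @param height_cal a `height_calibration`
#' @param height_cm requested object height, cm; must lie inside the plate's
#'   spanned height range
#' @return matrix `[n_cols, n_bands]` of conversion factors at that height
#' @export
conversion_at_height <- function(height_cal, height_cm) {
  stopifnot(inherits(height_cal, "height_calibration"))
  z <- height_cal$height_grid_cm
  if (height_cm < min(z) || height_cm > max(z))
    stop(sprintf("height %.2f cm outside calibrated range [%.2f, %.2f] cm",
                 height_cm, min(z), max(z)))
  k <- findInterval(height_cm, z)
  if (z[k] == height_cm) return(height_cal$a[, k, ])
  w <- (height_cm - z[k]) / (z[k + 1] - z[k])
  (1 - w) * height_cal$a[, k, ] + w * height_cal$a[, k + 1, ]
}

#' Convert a recorded intensity cube to reflectance
#'
#' Per-pixel division by the conversion factor interpolated at the stated
#' sample height: `R(x, y, lambda) = I(x, y, lambda) / A(x, z, lambda)`.
#' Saturated pixels are flagged in the output mask, never clipped; negative
#' reflectance from noise at dark wavelengths is retained.
#'
#' @param cube a [spectral_cube] of recorded intensity
#' @param height_cal a `height_calibration` covering all cube columns
#' @param sample_height_cm object height at which to calibrate, cm
#' @return a [spectral_cube] of reflectance with `meta$type = "reflectance"`
#' @export
to_reflectance <- function(cube, height_cal, sample_height_cm = 7) {
  stopifnot(inherits(cube, "spectral_cube"),
            inherits(height_cal, "height_calibration"))
  if (!isTRUE(all.equal(cube$wavelengths, height_cal$wavelengths)))
    stop("wavelength grids of cube and calibration differ")
  d <- dim(cube$data)
  if (!all(seq_len(d[2]) %in% height_cal$x))
    stop("calibration does not cover all cube columns")
  a7 <- conversion_at_height(height_cal, sample_height_cm)
  a7 <- a7[match(seq_len(d[2]), height_cal$x), , drop = FALSE]
  # divide each pixel spectrum by its column's conversion factor
  denom <- array(rep(a7, each = d[1]), d)    # [rows, cols, bands]
  out <- cube$data / denom
  spectral_cube(out, cube$wavelengths, saturated = cube$saturated,
                meta = c(cube$meta,
                         list(type = "reflectance",
                              sample_height_cm = sample_height_cm)))
}

# ---------------------------------------------------------------------------
# HDF5 serialisation of calibrations

#' Serialise panel and height calibrations to one HDF5 container
#'
#' @param panel_cal a `panel_calibration`
#' @param height_cal a `height_calibration`
#' @param path output `.h5` file (overwritten)
#' @return `path`, invisibly
#' @export
calibration_write <- function(panel_cal, height_cal, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "panel")
  rhdf5::h5createGroup(path, "height")
  rhdf5::h5write(panel_cal$a_spec, path, "panel/a_spec")
  rhdf5::h5write(panel_cal$x, path, "panel/x")
  rhdf5::h5write(panel_cal$r_spec, path, "panel/r_spec")
  rhdf5::h5write(panel_cal$n_spec, path, "panel/n_spec")
  rhdf5::h5write(panel_cal$panel_height_cm, path, "panel/panel_height_cm")
  rhdf5::h5write(height_cal$a, path, "height/a")
  rhdf5::h5write(height_cal$height_grid_cm, path, "height/height_grid_cm")
  rhdf5::h5write(height_cal$x, path, "height/x")
  rhdf5::h5write(height_cal$r_pvc, path, "height/r_pvc")
  rhdf5::h5write(height_cal$wavelengths, path, "wavelengths")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a calibration container written by [calibration_write()]
#'
#' @param path `.h5` file
#' @return list with `panel` (`panel_calibration`) and `height`
#'   (`height_calibration`)
#' @export
calibration_read <- function(path) {
  wl <- as.numeric(rhdf5::h5read(path, "wavelengths"))
  panel <- structure(list(
    a_spec = rhdf5::h5read(path, "panel/a_spec"),
    x = as.integer(rhdf5::h5read(path, "panel/x")),
    r_spec = as.numeric(rhdf5::h5read(path, "panel/r_spec")),
    n_spec = as.integer(rhdf5::h5read(path, "panel/n_spec")),
    n_saturated_excluded = NA_integer_,
    panel_height_cm = as.numeric(rhdf5::h5read(path, "panel/panel_height_cm")),
    wavelengths = wl), class = "panel_calibration")
  height <- structure(list(
    a = rhdf5::h5read(path, "height/a"),
    height_grid_cm = as.numeric(rhdf5::h5read(path, "height/height_grid_cm")),
    x = as.integer(rhdf5::h5read(path, "height/x")),
    r_pvc = as.numeric(rhdf5::h5read(path, "height/r_pvc")),
    wavelengths = wl), class = "height_calibration")
  rhdf5::h5closeAll()
  list(panel = panel, height = height)
}

#' One-call calibration of a synthetic scene
#'
#' Convenience wrapper chaining [fit_spectralon()],
#' [derive_pvc_reflectance()], [build_height_calibration()] and
#' [to_reflectance()] using the masks of a rendered scene.
#'
#' @param cube a [spectral_cube]
#' @param masks masks from [scene_masks()]
#' @param r_spec calibrated Spectralon reflectance (scalar or spectrum)
#' @param panel_height_cm Spectralon height, cm
#' @param sample_height_cm coral sample height, cm
#' @return list with `reflectance` (cube), `panel`, `r_pvc`, `height`
#' @export
calibrate_scene <- function(cube, masks, r_spec, panel_height_cm = 3,
                            sample_height_cm = 7) {
  panel <- fit_spectralon(cube, masks$spectralon, r_spec, panel_height_cm)
  r_pvc <- derive_pvc_reflectance(cube, masks$pvc_at_panel_height, panel)
  height <- build_height_calibration(cube, masks$pvc, masks$pvc_heights, r_pvc)
  refl <- to_reflectance(cube, height, sample_height_cm)
  list(reflectance = refl, panel = panel, r_pvc = r_pvc, height = height)
}
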