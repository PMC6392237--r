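# Synthetic tank scenes with known ground truth.
#
# The generator emulates the imaging geometry the calibration procedure
# assumes: a push-broom camera at fixed altitude, wavelength-dependent
# attenuation of the water column, a cross-track illumination profile, a
# Spectralon reference panel at known height, an inclined PVC plate spanning
# heights 0..max, and coral samples whose reflectance depends on colour morph
# and exposure category.

#' Evaluate an expression with a fixed RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so all generators are pure functions of their seed arguments
#' and never disturb global random state.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed, kept below 2^31.
.child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 65536) * 31627 + 7919 * i) %% 2147483629L
}

#' Built-in water attenuation curve
#'
#' A smooth clear-seawater-like attenuation coefficient (per metre): minimum
#' near 480 nm, rising steeply beyond 700 nm where water absorbs strongly.
#'
#' @param wavelength_nm numeric vector, nm
#' @return attenuation in m^-1, strictly positive
#' @export
seawater_attenuation <- function(wavelength_nm) {
  0.02 + 0.25 * ((wavelength_nm - 480) / 270)^2 +
    2.5 * plogis((wavelength_nm - 720) / 15)
}

#' Built-in halogen-like illumination spectrum
#'
#' Approximate relative spectral irradiance of a 3200 K halogen source
#' (Planck shape), normalised to 1 at 550 nm.
#'
#' @param wavelength_nm numeric vector, nm
#' @return relative irradiance, strictly positive
#' @export
halogen_illumination <- function(wavelength_nm) {
  planck <- function(l_nm) {
    l <- l_nm * 1e-9
    l^-5 / (exp(1.4388e-2 / (l * 3200)) - 1)
  }
  planck(wavelength_nm) / planck(550)
}

.resolve_curve <- function(x, which = c("attenuation", "illumination")) {
  which <- match.arg(which)
  if (is.function(x)) return(x)
  if (is.character(x)) {
    return(switch(x,
      seawater = seawater_attenuation,
      halogen = halogen_illumination,
      none = function(wl) rep(if (which == "attenuation") 0 else 1,
                              length(wl)),
      stop("unknown built-in curve: ", x)))
  }
  stop("curve must be a function or a built-in curve name")
}

#' Scene specification for the synthetic renderer
#'
#' @param wavelength_start_nm,wavelength_end_nm wavelength range of the
#'   simulated sensor, nm
#' @param n_bands number of spectral channels. The default 823 gives a
#'   channel spacing of about 0.57 nm, the effective spacing of an instrument
#'   sampling "approximately every 0.5 nm" with 619 channels inside the
#'   closed 400--750 nm analysis range.
#' @param wavelength_step_nm optional explicit channel spacing; overrides
#'   `n_bands` when supplied
#' @param image_shape integer `(rows, cols)`; rows = scan direction
#' @param camera_altitude_m vertical camera--tank-bottom distance, m
#' @param sample_height_cm height of coral samples above the bottom, cm
#' @param panel_height_cm Spectralon panel thickness/height, cm
#' @param plate_max_height_cm top height reached by the inclined PVC plate, cm
#' @param plate_step_cm height difference between consecutive plate rows, cm
#' @param spectralon_reflectance calibrated (true) Spectralon reflectance
#' @param pvc_reflectance nominal PVC plate reflectance (flat)
#' @param attenuation attenuation curve: function of wavelength (m^-1), or
#'   built-in name `"seawater"` / `"none"`
#' @param illumination illumination spectrum: function of wavelength, or
#'   built-in name `"halogen"` / `"none"`
#' @param geometry_falloff relative cross-track illumination drop at the
#'   slit edges (0 = flat field)
#' @param noise_sd_relative multiplicative sensor noise sd (relative)
#' @param saturation_level intensity at which the sensor saturates
#'   (`Inf` = never)
#' @param endmember options from [endmember_opts()]
#' @param rng_seed integer seed
#' @return object of class `scene_spec`
#' @export
scene_spec <- function(wavelength_start_nm = 381,
                       wavelength_end_nm = 846,
                       n_bands = 823L,
                       wavelength_step_nm = NULL,
                       image_shape = c(72L, 120L),
                       camera_altitude_m = 0.35,
                       sample_height_cm = 7,
                       panel_height_cm = 3,
                       plate_max_height_cm = 10,
                       plate_step_cm = 0.5,
                       spectralon_reflectance = 0.985,
                       pvc_reflectance = 0.55,
                       attenuation = "seawater",
                       illumination = "halogen",
                       geometry_falloff = 0.2,
                       noise_sd_relative = 0.01,
                       saturation_level = Inf,
                       endmember = endmember_opts(),
                       rng_seed = 1L) {
  if (!is.null(wavelength_step_nm)) {
    wl <- seq(wavelength_start_nm, wavelength_end_nm, by = wavelength_step_nm)
  } else {
    wl <- seq(wavelength_start_nm, wavelength_end_nm, length.out = n_bands)
  }
  if (any(diff(wl) <= 0)) stop("wavelength grid must be strictly increasing")
  heights <- c(sample_height_cm, panel_height_cm, plate_max_height_cm)
  if (any(heights >= camera_altitude_m * 100))
    stop("all object heights must be below the camera altitude")
  a_fun <- .resolve_curve(attenuation, "attenuation")
  e_fun <- .resolve_curve(illumination, "illumination")
  if (any(a_fun(wl) < 0)) stop("attenuation must be non-negative on the grid")
  if (any(e_fun(wl) <= 0)) stop("illumination must be positive on the grid")
  if (noise_sd_relative < 0) stop("noise_sd_relative must be >= 0")
  structure(list(
    wavelengths = wl,
    image_shape = as.integer(image_shape),
    camera_altitude_m = camera_altitude_m,
    sample_height_cm = sample_height_cm,
    panel_height_cm = panel_height_cm,
    plate_max_height_cm = plate_max_height_cm,
    plate_step_cm = plate_step_cm,
    spectralon_reflectance = spectralon_reflectance,
    pvc_reflectance = pvc_reflectance,
    attenuation = attenuation, illumination = illumination,
    geometry_falloff = geometry_falloff,
    noise_sd_relative = noise_sd_relative,
    saturation_level = saturation_level,
    endmember = endmember,
    rng_seed = as.integer(rng_seed)), class = "scene_spec")
}

#' Endmember-model options
#'
#' Controls the synthetic coral reflectance model: a smooth morph-specific
#' base spectrum plus exposure-linked features whose amplitude and band
#' position change monotonically with category severity (low = 0, medium = 1,
#' high = 2 units), plus smooth within-class variation.
#'
#' @param effect_amplitude reflectance-unit amplitude of the exposure feature
#'   per severity unit
#' @param edge_shift_nm band-position shift of the morph's pigment edge per
#'   severity unit, nm
#' @param within_sd sd of the smooth per-sample spectral perturbation
#' @param pixel_sd sd of the smooth per-pixel perturbation within a sample
#' @param brightness_sd sd of per-pixel log-normal brightness jitter
#' @return list of options
#' @export
endmember_opts <- function(effect_amplitude = 0.05, edge_shift_nm = 5,
                           within_sd = 0.02, pixel_sd = 0.01,
                           brightness_sd = 0.05) {
  list(effect_amplitude = effect_amplitude, edge_shift_nm = edge_shift_nm,
       within_sd = within_sd, pixel_sd = pixel_sd,
       brightness_sd = brightness_sd)
}

.severity <- c(low = 0, medium = 1, high = 2)

.gauss <- function(wl, centre, width) exp(-0.5 * ((wl - centre) / width)^2)

# Orthonormal-ish smooth basis: unit marginal variance per band.
.smooth_basis <- function(wl, spacing = 35, width = 28) {
  centres <- seq(min(wl) - width, max(wl) + width, by = spacing)
  B <- vapply(centres, function(ck) .gauss(wl, ck, width), numeric(length(wl)))
  B <- t(B)                             # K x nbands
  sweep(B, 2, sqrt(colSums(B^2)), "/")
}

# Deterministic class-mean spectrum for a morph x severity cell.
.base_spectrum <- function(morph, sev, wl, opts) {
  amp <- opts$effect_amplitude * sev
  shift <- opts$edge_shift_nm * sev
  if (morph == "white") {
    base <- 0.16 + 0.40 * plogis((wl - (470 - shift)) / 55)
    eff <- .gauss(wl, 545, 30) - 0.5 * .gauss(wl, 610, 25)
  } else {
    base <- 0.07 + 0.45 * plogis((wl - (565 - 1.2 * shift)) / 22) +
      0.05 * .gauss(wl, 640, 80)
    eff <- .gauss(wl, 525, 35) + 0.4 * .gauss(wl, 585, 20)
  }
  pmin(pmax(base + amp * eff, 0), 1)
}

#' Generate a synthetic coral endmember spectrum
#'
#' Returns the reflectance spectrum of one coral sample: the morph x
#' category class mean plus a smooth random within-class perturbation. The
#' perturbation depends only on the seed, so setting `effect_amplitude = 0`
#' and `edge_shift_nm = 0` makes all categories identical for a fixed seed.
#'
#' @param morph `"white"` or `"orange"`
#' @param category exposure category: `"low"`, `"medium"` or `"high"`
#' @param wavelengths wavelength grid, nm
#' @param seed integer seed for the within-class draw
#' @param opts options from [endmember_opts()]
#' @return numeric reflectance spectrum in `[0, 1]` on the grid
#' @export
generate_endmembers <- function(morph, category, wavelengths, seed = 1L,
                                opts = endmember_opts()) {
  morph <- match.arg(morph, c("white", "orange"))
  category <- match.arg(category, c("low", "medium", "high"))
  base <- .base_spectrum(morph, .severity[[category]], wavelengths, opts)
  B <- .smooth_basis(wavelengths)
  pert <- with_seed(seed, rnorm(nrow(B), sd = opts$within_sd)) %*% B
  pmin(pmax(base + drop(pert), 0), 1)
}

#' Experiment design for the synthetic toxicity study
#'
#' Mirrors the exposure setup: five treatment groups (C0 control plus four
#' exposed), four replicate beakers each, three coral samples per beaker
#' (one orange, two white), 3--9 polyps per sample, and a sigmoidal
#' concentration--mortality relationship on the logit scale in
#' log-concentration.
#'
#' @param n_groups number of treatment groups (first is the control)
#' @param n_replicates replicate beakers per group
#' @param samples_per_beaker coral samples per beaker (must be 3: one orange,
#'   two white)
#' @param polyp_range integer `(min, max)` polyps per sample
#' @param nominal_concentrations nominal 2-methylnaphthalene concentration
#'   per group, mg/L (first must be 0 for the control)
#' @param realized_fraction_mean,realized_fraction_sd distribution of the
#'   realised beaker concentration as a fraction of nominal
#' @param fraction_override named list of per-beaker realised-fraction
#'   overrides, e.g. `list("C3.R2" = 0.02)` to reproduce a faulty pump
#' @param measurement_sd_relative relative sd of individual water-sample
#'   concentration measurements around the beaker's realised level
#' @param mortality_params `(beta0, beta1)` of the true dose-response
#'   `logit(p) = beta0 + beta1 * log(C)`. The default curve has LC5 = 1.25
#'   and LC25 = 2.30 mg/L.
#' @param category_rule a [category_rule()] used for ground-truth categories
#' @param rng_seed integer seed
#' @return object of class `experiment_design`
#' @export
experiment_design <- function(n_groups = 5L, n_replicates = 4L,
                              samples_per_beaker = 3L,
                              polyp_range = c(3L, 9L),
                              nominal_concentrations = c(0, 1.0, 2.3, 5.0, 8.0),
                              realized_fraction_mean = 0.375,
                              realized_fraction_sd = 0.08,
                              fraction_override = NULL,
                              measurement_sd_relative = 0.15,
                              mortality_params = c(-3.6199187, 3.0271088),
                              category_rule = uhicoral::category_rule(),
                              rng_seed = 1L) {
  if (n_groups < 1 || n_replicates < 1) stop("group/replicate counts must be positive")
  if (length(nominal_concentrations) != n_groups)
    stop("need one nominal concentration per group")
  if (any(nominal_concentrations < 0)) stop("concentrations must be non-negative")
  if (samples_per_beaker != 3L)
    stop("each beaker holds exactly one orange and two white samples (3 total)")
  if (polyp_range[1] < 1 || polyp_range[2] < polyp_range[1])
    stop("invalid polyp range")
  structure(list(
    n_groups = as.integer(n_groups), n_replicates = as.integer(n_replicates),
    samples_per_beaker = 3L, polyp_range = as.integer(polyp_range),
    nominal_concentrations = nominal_concentrations,
    realized_fraction_mean = realized_fraction_mean,
    realized_fraction_sd = realized_fraction_sd,
    fraction_override = fraction_override,
    measurement_sd_relative = measurement_sd_relative,
    mortality_params = mortality_params,
    category_rule = category_rule,
    rng_seed = as.integer(rng_seed)), class = "experiment_design")
}

#' True dose-response mortality probability of a design
#'
#' @param design an [experiment_design()]
#' @param concentration mg/L (vectorised)
#' @return probability of polyp death; 0 at zero concentration
#' @export
true_mortality <- function(design, concentration) {
  b <- design$mortality_params
  ifelse(concentration <= 0, 0, plogis(b[1] + b[2] * log(concentration)))
}

#' Simulate the exposure experiment tables
#'
#' Draws realised beaker concentrations (fraction of nominal), a measured
#' chemistry time series per beaker and stock bottle, and per-sample polyp
#' counts with binomial deaths at the true dose-response evaluated at the
#' beaker's mean measured concentration.
#'
#' @param design an [experiment_design()]
#' @return list with elements `chemistry` (long-format measurement table),
#'   `polyps` (per-sample polyp counts) and `samples` (sample registry with
#'   beaker mean concentration, mortality and ground-truth category)
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  with_seed(design$rng_seed, {
    groups <- paste0("C", seq_len(design$n_groups) - 1L)
    reps <- paste0("R", seq_len(design$n_replicates))
    time_h <- c(0, 24, 48, 72)
    chem <- list(); beaker_rows <- list(); k <- 0L

    for (g in seq_along(groups)) {
      nominal <- design$nominal_concentrations[g]
      # stock bottle: near-nominal, sampled after (A) and before (B) replacement
      for (ph in c("A_after_replacement", "B_before_replacement")) {
        conc <- pmax(nominal * (1 + rnorm(length(time_h), 0, 0.15)), 0)
        chem[[length(chem) + 1L]] <- data.frame(
          group = groups[g], replicate = "stock", phase = ph,
          time_h = time_h, duplicate = "I", concentration_mg_l = conc)
      }
      for (r in seq_along(reps)) {
        key <- paste0(groups[g], ".", reps[r])
        frac <- max(rnorm(1, design$realized_fraction_mean,
                          design$realized_fraction_sd), 0)
        if (!is.null(design$fraction_override[[key]]))
          frac <- design$fraction_override[[key]]
        realized <- nominal * frac
        for (dup in c("I", "II")) {
          conc <- pmax(realized *
                         (1 + rnorm(length(time_h), 0,
                                    design$measurement_sd_relative)), 0)
          chem[[length(chem) + 1L]] <- data.frame(
            group = groups[g], replicate = reps[r], phase = "beaker",
            time_h = time_h, duplicate = dup, concentration_mg_l = conc)
        }
        k <- k + 1L
        beaker_rows[[k]] <- data.frame(group = groups[g], replicate = reps[r],
                                       realized_mg_l = realized)
      }
    }
    chemistry <- do.call(rbind, chem)
    beakers <- do.call(rbind, beaker_rows)

    # Beaker mean over time points and duplicates: the annotation rule used
    # downstream (arithmetic mean of the 0/24/48/72 h measurements).
    bk <- chemistry[chemistry$phase == "beaker", ]
    key <- paste(bk$group, bk$replicate)
    means <- tapply(bk$concentration_mg_l, key, mean)
    beakers$mean_mg_l <- as.numeric(means[paste(beakers$group,
                                                beakers$replicate)])

    morphs <- c("orange", "white", "white")
    rows <- list()
    for (i in seq_len(nrow(beakers))) {
      for (s in seq_len(design$samples_per_beaker)) {
        alive <- sample(seq(design$polyp_range[1], design$polyp_range[2]), 1)
        p <- true_mortality(design, beakers$mean_mg_l[i])
        dead <- rbinom(1, alive, p)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s.%s.S%d", beakers$group[i],
                              beakers$replicate[i], s),
          group = beakers$group[i], replicate = beakers$replicate[i],
          morph = morphs[s],
          polyps_alive_before = alive, polyps_dead_after = dead,
          mortality = dead / alive,
          beaker_mean_mg_l = beakers$mean_mg_l[i])
      }
    }
    samples <- do.call(rbind, rows)
    samples$category <- assign_category(samples$beaker_mean_mg_l,
                                        design$category_rule)
    polyps <- samples[, c("sample_id", "group", "replicate", "morph",
                          "polyps_alive_before", "polyps_dead_after",
                          "mortality", "beaker_mean_mg_l")]
    list(chemistry = chemistry, polyps = polyps, samples = samples,
         beakers = beakers)
  })
}

# ---------------------------------------------------------------------------
# Scene layout and rendering

.scene_layout <- function(spec, n_samples) {
  rows <- spec$image_shape[1]; cols <- spec$image_shape[2]
  n_plate <- length(seq(0, spec$plate_max_height_cm, by = spec$plate_step_cm))
  panel_rows <- 15L; panel_cols <- 30L
  cell_r <- 28L; cell_c <- 38L
  cells_per_row <- max(cols %/% cell_c, 0L)
  coral_row0 <- n_plate + 3L + panel_rows + 3L
  need_cell_rows <- if (n_samples > 0 && cells_per_row > 0)
    ceiling(n_samples / cells_per_row) else if (n_samples > 0) Inf else 0
  min_rows <- coral_row0 + need_cell_rows * cell_r
  min_cols <- max(6L + panel_cols, if (n_samples > 0) cell_c else 0L)
  if (rows < min_rows || cols < min_cols)
    stop(sprintf(paste0("image too small for %d samples: need at least ",
                        "%d rows x %d cols, got %d x %d"),
                 n_samples, min_rows, min_cols, rows, cols))
  list(plate_rows = seq_len(n_plate),
       plate_heights = seq(0, spec$plate_max_height_cm, by = spec$plate_step_cm),
       panel_rows = (n_plate + 4L):(n_plate + 3L + panel_rows),
       panel_cols = 6:(5L + panel_cols),
       coral_row0 = coral_row0, cell_r = cell_r, cell_c = cell_c,
       cells_per_row = cells_per_row)
}

.ellipse_mask <- function(rows, cols, cr, cc, a_row, a_col) {
  rr <- matrix(seq_len(rows), rows, cols)
  cc_m <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  ((rr - cr) / a_row)^2 + ((cc_m - cc) / a_col)^2 <= 1
}

#' Render a synthetic hyperspectral tank scene
#'
#' Builds the ground-truth reflectance of a scene (inclined PVC plate,
#' Spectralon panel, coral samples, dark background) and pushes it through
#' the forward model
#' `I = R_true * E(lambda) * G(x) * exp(-a(lambda) * path(z)) * (1 + noise)`,
#' where the optical path is the doubled camera-to-object vertical distance
#' `path(z) = 2 * (H - z)` (down- and up-welling legs). Higher objects have a
#' shorter path and therefore suffer less attenuation.
#'
#' @param spec a [scene_spec()]
#' @param design an [experiment_design()]; ignored when `samples` is given
#' @param experiment optional precomputed [simulate_experiment()] result (so
#'   the same experiment can be split over several scenes)
#' @param sample_ids which samples of the experiment to place in this scene
#'   (default: all — the image must be large enough)
#' @return list with `cube` (a [spectral_cube] of recorded intensity) and
#'   `truth` (a `ground_truth` object: per-pixel label and height matrices,
#'   true reflectance array, sample registry and experiment tables)
#' @export
render_scene <- function(spec, design, experiment = NULL, sample_ids = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(experiment)) experiment <- simulate_experiment(design)
  samples <- experiment$samples
  if (!is.null(sample_ids)) samples <- samples[samples$sample_id %in% sample_ids, ]
  n_s <- nrow(samples)
  lay <- .scene_layout(spec, n_s)
  rows <- spec$image_shape[1]; cols <- spec$image_shape[2]
  wl <- spec$wavelengths; nb <- length(wl)
  a <- .resolve_curve(spec$attenuation, "attenuation")(wl)
  E <- .resolve_curve(spec$illumination, "illumination")(wl)

  label <- matrix("background", rows, cols)
  height <- matrix(0, rows, cols)

  label[lay$plate_rows, ] <- "pvc"
  height[lay$plate_rows, ] <- lay$plate_heights
  label[lay$panel_rows, lay$panel_cols] <- "spectralon"
  height[lay$panel_rows, lay$panel_cols] <- spec$panel_height_cm

  npix <- rows * cols
  R <- matrix(0, npix, nb)            # column-major pixel order
  em_opts <- spec$endmember

  with_seed(.child_seed(spec$rng_seed, 1L), {
    bg <- 0.07 + 0.02 * plogis((wl - 600) / 80)
    idx_bg <- which(label == "background")
    R[idx_bg, ] <- matrix(bg, length(idx_bg), nb, byrow = TRUE) +
      rnorm(length(idx_bg) * nb, sd = 0.003)
    pvc <- spec$pvc_reflectance + 0.03 * plogis((wl - 500) / 100)
    idx_pvc <- which(label == "pvc")
    R[idx_pvc, ] <- matrix(pvc, length(idx_pvc), nb, byrow = TRUE)
    idx_sp <- which(label == "spectralon")
    R[idx_sp, ] <- spec$spectralon_reflectance

    if (n_s > 0) {
      B <- .smooth_basis(wl)
      for (i in seq_len(n_s)) {
        cell <- i - 1L
        crow <- lay$coral_row0 + (cell %/% lay$cells_per_row) * lay$cell_r +
          lay$cell_r / 2
        ccol <- (cell %% lay$cells_per_row) * lay$cell_c + lay$cell_c / 2
        a_col <- runif(1, 11, 15); a_row <- runif(1, 9, 13)
        crow <- crow + runif(1, -1.5, 1.5); ccol <- ccol + runif(1, -1.5, 1.5)
        m <- .ellipse_mask(rows, cols, crow, ccol, a_row, a_col) &
          label == "background"
        idx <- which(m)
        em <- generate_endmembers(samples$morph[i],
                                  as.character(samples$category[i]), wl,
                                  seed = .child_seed(spec$rng_seed, 100L + i),
                                  opts = em_opts)
        pert <- matrix(rnorm(length(idx) * nrow(B), sd = em_opts$pixel_sd),
                       length(idx), nrow(B)) %*% B
        bright <- exp(rnorm(length(idx), 0, em_opts$brightness_sd))
        R[idx, ] <- pmin(pmax((matrix(em, length(idx), nb, byrow = TRUE) +
                                 pert) * bright, 0), 1.2)
        label[idx] <- samples$sample_id[i]
        height[idx] <- spec$sample_height_cm
      }
    }

    path_m <- 2 * (spec$camera_altitude_m - height / 100)  # metres
    atten <- exp(outer(as.vector(path_m), a, function(p, aa) -p * aa))
    u <- (2 * (seq_len(cols) - 1) / max(cols - 1, 1)) - 1
    G <- 1 - spec$geometry_falloff * u^2
    Gpix <- rep(G, each = rows)
    I <- R * atten * matrix(E, npix, nb, byrow = TRUE) * Gpix
    if (spec$noise_sd_relative > 0)
      I <- I * (1 + rnorm(npix * nb, sd = spec$noise_sd_relative))
    saturated <- matrix(FALSE, rows, cols)
    if (is.finite(spec$saturation_level)) {
      sat_pix <- apply(I, 1, max) >= spec$saturation_level
      I[I > spec$saturation_level] <- spec$saturation_level
      saturated <- matrix(sat_pix, rows, cols)
    }
    cube <- spectral_cube(array(I, c(rows, cols, nb)), wl,
                          saturated = saturated,
                          meta = list(seed = spec$rng_seed))
    truth <- structure(list(
      label = label, height_cm = height,
      r_true = array(R, c(rows, cols, nb)),
      wavelengths = wl, samples = samples,
      experiment = experiment, spec = spec), class = "ground_truth")
    list(cube = cube, truth = truth)
  })
}

#' Masks derived from a ground-truth object
#'
#' @param truth a `ground_truth` from [render_scene()]
#' @return list with `spectralon` (logical matrix), `pvc` (logical matrix),
#'   `pvc_heights` (list with `mask` and `heights_cm` per plate row),
#'   `pvc_at_panel_height` (logical matrix) and `rois` (named list of
#'   per-sample logical masks)
#' @export
scene_masks <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  lab <- truth$label
  pvc <- lab == "pvc"
  spec <- truth$spec
  at_panel <- pvc & truth$height_cm == spec$panel_height_cm
  ids <- truth$samples$sample_id
  rois <- lapply(ids, function(id) lab == id)
  names(rois) <- ids
  list(spectralon = lab == "spectralon", pvc = pvc,
       pvc_heights = truth$height_cm,
       pvc_at_panel_height = at_panel, rois = rois)
}

# ---------------------------------------------------------------------------
# Scenario (YAML) serialisation

#' Write a scenario (scene spec + experiment design) to YAML
#'
#' Curves must be built-in names (not R functions) to be serialisable.
#'
#' @param spec a [scene_spec()]
#' @param design an [experiment_design()]
#' @param path output YAML file
#' @return `path`, invisibly
#' @export
scenario_write <- function(spec, design, path) {
  if (is.function(spec$attenuation) || is.function(spec$illumination))
    stop("only built-in curve names can be serialised to YAML")
  sc <- list(
    scene = list(
      wavelength_start_nm = min(spec$wavelengths),
      wavelength_end_nm = max(spec$wavelengths),
      n_bands = length(spec$wavelengths),
      image_shape = as.integer(spec$image_shape),
      camera_altitude_m = spec$camera_altitude_m,
      sample_height_cm = spec$sample_height_cm,
      panel_height_cm = spec$panel_height_cm,
      plate_max_height_cm = spec$plate_max_height_cm,
      plate_step_cm = spec$plate_step_cm,
      spectralon_reflectance = spec$spectralon_reflectance,
      pvc_reflectance = spec$pvc_reflectance,
      attenuation = spec$attenuation, illumination = spec$illumination,
      geometry_falloff = spec$geometry_falloff,
      noise_sd_relative = spec$noise_sd_relative,
      saturation_level = if (is.finite(spec$saturation_level))
        spec$saturation_level else "Inf",
      endmember = spec$endmember, rng_seed = spec$rng_seed),
    design = list(
      n_groups = design$n_groups, n_replicates = design$n_replicates,
      samples_per_beaker = design$samples_per_beaker,
      polyp_range = design$polyp_range,
      nominal_concentrations = design$nominal_concentrations,
      realized_fraction_mean = design$realized_fraction_mean,
      realized_fraction_sd = design$realized_fraction_sd,
      fraction_override = design$fraction_override,
      measurement_sd_relative = design$measurement_sd_relative,
      mortality_params = design$mortality_params,
      category_rule = list(lc5 = design$category_rule$lc5,
                           lc25 = design$category_rule$lc25),
      rng_seed = design$rng_seed))
  yaml::write_yaml(sc, path)
  invisible(path)
}

#' Read a scenario written by [scenario_write()]
#'
#' @param path YAML file
#' @return list with `spec` and `design`
#' @export
scenario_read <- function(path) {
  sc <- yaml::read_yaml(path)
  s <- sc$scene
  spec <- scene_spec(
    wavelength_start_nm = s$wavelength_start_nm,
    wavelength_end_nm = s$wavelength_end_nm, n_bands = s$n_bands,
    image_shape = unlist(s$image_shape),
    camera_altitude_m = s$camera_altitude_m,
    sample_height_cm = s$sample_height_cm,
    panel_height_cm = s$panel_height_cm,
    plate_max_height_cm = s$plate_max_height_cm,
    plate_step_cm = s$plate_step_cm,
    spectralon_reflectance = s$spectralon_reflectance,
    pvc_reflectance = s$pvc_reflectance,
    attenuation = s$attenuation, illumination = s$illumination,
    geometry_falloff = s$geometry_falloff,
    noise_sd_relative = s$noise_sd_relative,
    saturation_level = if (identical(s$saturation_level, "Inf")) Inf
      else s$saturation_level,
    endmember = do.call(endmember_opts, s$endmember),
    rng_seed = s$rng_seed)
  d <- sc$design
  design <- experiment_design(
    n_groups = d$n_groups, n_replicates = d$n_replicates,
    samples_per_beaker = d$samples_per_beaker,
    polyp_range = unlist(d$polyp_range),
    nominal_concentrations = unlist(d$nominal_concentrations),
    realized_fraction_mean = d$realized_fraction_mean,
    realized_fraction_sd = d$realized_fraction_sd,
    fraction_override = d$fraction_override,
    measurement_sd_relative = d$measurement_sd_relative,
    mortality_params = unlist(d$mortality_params),
    category_rule = category_rule(d$category_rule$lc5, d$category_rule$lc25),
    rng_seed = d$rng_seed)
  list(spec = spec, design = design)
}
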