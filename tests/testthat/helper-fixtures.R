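# Small fixtures shared across test files. All synthetic: nothing is read
# from disk. The tiny scene uses a coarse 64-band grid and a 1 cm inclined
# plate step so a beaker scene renders in about a second.

tiny_spec <- function(seed = 1L, noise_sd_relative = 0.005, ...) {
  scene_spec(n_bands = 64L, image_shape = c(62L, 114L), plate_step_cm = 1,
             noise_sd_relative = noise_sd_relative, rng_seed = seed, ...)
}

# Render just the first beaker (3 samples) of a design.
render_beaker <- function(spec, design, experiment = NULL) {
  if (is.null(experiment)) experiment <- simulate_experiment(design)
  render_scene(spec, design, experiment = experiment,
               sample_ids = experiment$samples$sample_id[1:3])
}

# 3 groups x 2 beakers; nominal levels chosen so that the realised beaker
# means (about 37.5 % of nominal) fall into the low / medium / high bands.
tiny_design <- function(seed = 1L, ...) {
  experiment_design(n_groups = 3L, n_replicates = 2L,
                    nominal_concentrations = c(0, 4, 8), rng_seed = seed, ...)
}

# One rendered + calibrated beaker scene, cached per session.
.fixture_env <- new.env(parent = emptyenv())

tiny_scene <- function() {
  if (is.null(.fixture_env$scene)) {
    spec <- tiny_spec()
    design <- tiny_design()
    ex <- simulate_experiment(design)
    sc <- render_scene(spec, design, experiment = ex,
                       sample_ids = ex$samples$sample_id[1:3])
    masks <- scene_masks(sc$truth)
    cal <- calibrate_scene(sc$cube, masks, spec$spectralon_reflectance,
                           spec$panel_height_cm, spec$sample_height_cm)
    .fixture_env$scene <- list(spec = spec, design = design, experiment = ex,
                               scene = sc, masks = masks, cal = cal)
  }
  .fixture_env$scene
}

# The full default scenario (the acceptance "stated world") and the
# classifier bundles trained on it, cached per session. These are shared by
# the acceptance criteria and the deeper classification tests.
default_run <- function() {
  if (is.null(.fixture_env$default)) {
    scn <- default_scenario(seed = 1L)
    rs <- run_scenario(scn$spec, scn$design)
    .fixture_env$default <- list(scn = scn, table = rs$table,
                                 experiment = rs$experiment)
  }
  .fixture_env$default
}

default_bundles <- function() {
  if (is.null(.fixture_env$bundles)) {
    .fixture_env$bundles <- train_morph_pipelines(
      default_run()$table, n_latent = 10, nu = 0.1, split_frac = 0.8,
      seed = 1)
  }
  .fixture_env$bundles
}

# Flat [n_pixels x n_bands] view of a cube array.
flat_pixels <- function(arr) matrix(arr, prod(dim(arr)[1:2]), dim(arr)[3])

# A quick labelled spectra table drawn directly from the endmember model
# (no rendering): `n_samples` coral samples per morph x category cell, each
# with its own within-class endmember draw and n_per_cell/n_samples pixels.
endmember_table <- function(n_per_cell = 60, n_bands = 64, seed = 1L,
                            opts = endmember_opts(), n_samples = 3L,
                            morphs = c("white", "orange"),
                            categories = c("low", "medium", "high")) {
  wl <- seq(400, 750, length.out = n_bands)
  conc_of <- c(low = 0.5, medium = 1.8, high = 3.2)
  mort_of <- c(low = 0.02, medium = 0.15, high = 0.5)
  B <- uhicoral:::.smooth_basis(wl)
  n_px <- max(1L, n_per_cell %/% n_samples)
  rows <- list(); X <- list(); k <- 0L
  for (m in morphs) for (cat in categories) for (s in seq_len(n_samples)) {
    k <- k + 1L
    em <- generate_endmembers(m, cat, wl, seed = seed * 1000 + k * 17,
                              opts = opts)
    pix <- with_seed(seed * 100 + k, {
      pert <- matrix(rnorm(n_px * nrow(B), sd = opts$pixel_sd),
                     n_px, nrow(B)) %*% B
      bright <- exp(rnorm(n_px, 0, opts$brightness_sd))
      (matrix(em, n_px, n_bands, byrow = TRUE) + pert) * bright
    })
    X[[k]] <- pix
    rows[[k]] <- data.frame(
      sample_id = sprintf("%s.%s.S%d", m, cat, s),
      morph = m, px_row = seq_len(n_px), px_col = k,
      category = cat, concentration_mg_l = conc_of[[cat]],
      mortality = mort_of[[cat]])
  }
  meta <- do.call(rbind, rows)
  spectra_table(do.call(rbind, X), wl,
                meta[c("sample_id", "morph", "px_row", "px_col")],
                y_h = meta[c("concentration_mg_l", "mortality")],
                y_c = factor(meta$category, levels = c("low", "medium", "high")))
}

# Polyp records drawn from a known dose-response curve.
simulate_records <- function(design = experiment_design(), seed = 1L) {
  d <- design; d$rng_seed <- seed
  simulate_experiment(d)$polyps
}
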