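# End-to-end orchestration of the synthetic study: simulate the experiment,
# render one tank scene per exposure beaker, calibrate each scene to
# reflectance, extract labelled pixel spectra, and annotate them with the
# chemistry and mortality tables.

#' Default synthetic scenario
#'
#' The stated world of the synthetic study: 5 treatment groups x 4
#' replicate beakers x 3 coral samples (1 orange + 2 white), 3--9 polyps
#' per sample, coral blobs of 300--700 pixels, 1 % multiplicative sensor
#' noise, default attenuation/illumination/effect sizes.
#'
#' @param seed integer master seed
#' @return list with `spec` (a [scene_spec()]) and `design`
#'   (an [experiment_design()])
#' @export
default_scenario <- function(seed = 1L) {
  list(spec = scene_spec(rng_seed = seed),
       design = experiment_design(rng_seed = .child_seed(seed, 9L)))
}

#' Run the synthetic study up to the annotated spectra table
#'
#' Simulates the experiment tables once, then renders and calibrates one
#' scene per exposure beaker (3 corals each), extracts the masked coral
#' pixels, crops to the analysis wavelength range and annotates with beaker
#' mean concentration, sample mortality and exposure category.
#'
#' @param spec a [scene_spec()]; per-beaker scenes derive their seeds from
#'   `spec$rng_seed`
#' @param design an [experiment_design()]
#' @param crop closed wavelength crop `(low, high)` in nm (default
#'   `c(400, 750)`)
#' @param experiment optional precomputed [simulate_experiment()] output
#' @param keep_scenes return the rendered scenes too (memory-hungry;
#'   default `FALSE`)
#' @return list with `table` (annotated [spectra_table]), `experiment`, and
#'   optionally `scenes`
#' @export
run_scenario <- function(spec, design, crop = c(400, 750),
                         experiment = NULL, keep_scenes = FALSE) {
  if (is.null(experiment)) experiment <- simulate_experiment(design)
  samples <- experiment$samples
  beakers <- unique(samples[, c("group", "replicate")])
  tabs <- list(); scenes <- list()
  for (i in seq_len(nrow(beakers))) {
    sel <- samples$group == beakers$group[i] &
      samples$replicate == beakers$replicate[i]
    spec_i <- spec
    spec_i$rng_seed <- .child_seed(spec$rng_seed, 1000L + i)
    sc <- render_scene(spec_i, design, experiment = experiment,
                       sample_ids = samples$sample_id[sel])
    masks <- scene_masks(sc$truth)
    cal <- calibrate_scene(sc$cube, masks, spec$spectralon_reflectance,
                           panel_height_cm = spec$panel_height_cm,
                           sample_height_cm = spec$sample_height_cm)
    tab <- extract_pixels(cal$reflectance, masks$rois,
                          sample_info = samples[sel, c("sample_id", "morph",
                                                       "group", "replicate")])
    tabs[[i]] <- crop_wavelengths(tab, crop[1], crop[2])
    if (keep_scenes) scenes[[i]] <- sc
  }
  X <- do.call(rbind, lapply(tabs, function(t) t$X))
  meta <- do.call(rbind, lapply(tabs, function(t) t$meta))
  table <- spectra_table(X, tabs[[1]]$wavelengths, meta)
  table <- annotate_spectra(table, experiment$chemistry, experiment$polyps,
                            design$category_rule)
  out <- list(table = table, experiment = experiment)
  if (keep_scenes) out$scenes <- scenes
  out
}

#' Render and extract a healthy reference group
#'
#' Generates hold-out coral samples that were never exposed (category
#' `low`, zero concentration), imaged and calibrated like the treatment
#' scenes: the synthetic analogue of reference-alive corals.
#'
#' @param spec a [scene_spec()]
#' @param design an [experiment_design()] (for the endmember/category rule)
#' @param n_white,n_orange number of reference samples per morph
#' @param crop wavelength crop, nm
#' @param seed integer seed
#' @return a cropped, unannotated [spectra_table] of reference pixels
#' @export
reference_group <- function(spec, design, n_white = 4L, n_orange = 2L,
                            crop = c(400, 750), seed = 77L) {
  n <- n_white + n_orange
  samples <- data.frame(
    sample_id = sprintf("REF.S%d", seq_len(n)),
    group = "REF", replicate = "R0",
    morph = c(rep("white", n_white), rep("orange", n_orange)),
    polyps_alive_before = 5L, polyps_dead_after = 0L, mortality = 0,
    beaker_mean_mg_l = 0)
  samples$category <- assign_category(samples$beaker_mean_mg_l,
                                      design$category_rule)
  experiment <- list(samples = samples)
  spec_i <- spec
  spec_i$rng_seed <- .child_seed(seed, 4242L)
  # reference scenes hold up to 3 corals each, like the treatment scenes
  tabs <- list()
  for (start in seq(1, n, by = 3)) {
    ids <- samples$sample_id[start:min(start + 2, n)]
    spec_j <- spec_i
    spec_j$rng_seed <- .child_seed(spec_i$rng_seed, start)
    sc <- render_scene(spec_j, design, experiment = experiment,
                       sample_ids = ids)
    masks <- scene_masks(sc$truth)
    cal <- calibrate_scene(sc$cube, masks, spec$spectralon_reflectance,
                           panel_height_cm = spec$panel_height_cm,
                           sample_height_cm = spec$sample_height_cm)
    tab <- extract_pixels(cal$reflectance, masks$rois,
                          sample_info = samples[samples$sample_id %in% ids,
                                                c("sample_id", "morph",
                                                  "group", "replicate")])
    tabs[[length(tabs) + 1L]] <- crop_wavelengths(tab, crop[1], crop[2])
  }
  X <- do.call(rbind, lapply(tabs, function(t) t$X))
  meta <- do.call(rbind, lapply(tabs, function(t) t$meta))
  spectra_table(X, tabs[[1]]$wavelengths, meta)
}
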