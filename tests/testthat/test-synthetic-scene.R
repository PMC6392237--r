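# Synthetic scene generator: endmember model, forward model, experiment
# simulation, determinism.

test_that("endmembers: within-class variation, morph separability, null effect", {
  wl <- seq(400, 750, length.out = 120)
  opts <- endmember_opts()
  w1 <- generate_endmembers("white", "low", wl, seed = 1)
  w2 <- generate_endmembers("white", "low", wl, seed = 2)
  # same class, different seeds: only within-class variation, bounded by the
  # smooth-perturbation amplitude
  expect_false(isTRUE(all.equal(w1, w2)))
  expect_lt(max(abs(w1 - w2)), 8 * opts$within_sd)

  # morphs differ by a broad pigment band well beyond within-class sd
  o1 <- generate_endmembers("orange", "low", wl, seed = 1)
  band <- wl >= 480 & wl <= 620
  expect_gt(max(abs(w1 - o1)[band]), 5 * opts$within_sd)

  # null category effect: all categories identical for a fixed seed
  null_opts <- endmember_opts(effect_amplitude = 0, edge_shift_nm = 0)
  for (m in c("white", "orange")) {
    lo <- generate_endmembers(m, "low", wl, seed = 3, opts = null_opts)
    md <- generate_endmembers(m, "medium", wl, seed = 3, opts = null_opts)
    hi <- generate_endmembers(m, "high", wl, seed = 3, opts = null_opts)
    expect_identical(lo, md)
    expect_identical(lo, hi)
  }
  expect_error(generate_endmembers("pink", "low", wl), "arg")
  expect_error(generate_endmembers("white", "extreme", wl), "arg")
})

test_that("endmember category effect magnitude is monotone in severity", {
  wl <- seq(400, 750, length.out = 200)
  null_opts <- endmember_opts(within_sd = 0)   # class means only
  for (m in c("white", "orange")) {
    lo <- generate_endmembers(m, "low", wl, seed = 1, opts = null_opts)
    md <- generate_endmembers(m, "medium", wl, seed = 1, opts = null_opts)
    hi <- generate_endmembers(m, "high", wl, seed = 1, opts = null_opts)
    expect_gt(max(abs(hi - lo)), max(abs(md - lo)))
    expect_gt(max(abs(md - lo)), 0)
  }
})

test_that("identity forward model records true reflectance", {
  spec <- tiny_spec(attenuation = "none", illumination = "none",
                    geometry_falloff = 0, noise_sd_relative = 0)
  sc <- render_beaker(spec, tiny_design())
  expect_equal(sc$cube$data, sc$truth$r_true, tolerance = 1e-12)
})

test_that("rendering is deterministic under a fixed seed", {
  spec <- tiny_spec(seed = 7L)
  design <- tiny_design()
  s1 <- render_beaker(spec, design)
  s2 <- render_beaker(spec, design)
  expect_identical(s1$cube$data, s2$cube$data)
  expect_identical(s1$truth$label, s2$truth$label)
})

test_that("attenuation makes equal-reflectance panel pixels dimmer at longer path", {
  sc <- render_beaker(tiny_spec(noise_sd_relative = 0), tiny_design())
  truth <- sc$truth; cube <- sc$cube
  # inclined PVC rows: identical true reflectance, height increases by row;
  # lower height = longer path = dimmer at every wavelength
  pvc_rows <- which(apply(truth$label == "pvc", 1, all))
  r_lo <- pvc_rows[which.min(truth$height_cm[pvc_rows, 1])]
  r_hi <- pvc_rows[which.max(truth$height_cm[pvc_rows, 1])]
  mid_col <- ncol(truth$label) %/% 2
  i_lo <- cube$data[r_lo, mid_col, ]
  i_hi <- cube$data[r_hi, mid_col, ]
  expect_true(all(i_lo < i_hi))
})

test_that("scene rejects images too small to place all regions", {
  spec <- tiny_spec()
  spec$image_shape <- c(30L, 114L)
  expect_error(render_scene(spec, tiny_design()), "need at least")
})

test_that("ground truth is consistent: one sample per coral pixel, counts in range", {
  fx <- tiny_scene()
  lab <- fx$scene$truth$label
  ids <- fx$scene$truth$samples$sample_id
  expect_true(all(unique(as.vector(lab)) %in%
                    c("background", "pvc", "spectralon", ids)))
  counts <- table(lab[lab %in% ids])
  expect_true(all(counts >= 300 & counts <= 700))
  expect_true(all(fx$scene$truth$r_true >= 0 & fx$scene$truth$r_true <= 1.2))
})

test_that("simulate_experiment: structure, null mortality, exact means", {
  ex <- simulate_experiment(tiny_design())
  # one orange + two white per beaker
  morph_tab <- table(ex$samples$group, ex$samples$replicate, ex$samples$morph)
  expect_true(all(morph_tab[, , "orange"] == 1))
  expect_true(all(morph_tab[, , "white"] == 2))
  expect_true(all(ex$polyps$polyps_alive_before >= 3 &
                    ex$polyps$polyps_alive_before <= 9))
  expect_true(all(ex$polyps$polyps_dead_after <= ex$polyps$polyps_alive_before))

  # null mortality: beta1 = 0 and beta0 -> -Inf gives zero deaths everywhere
  d0 <- tiny_design(mortality_params = c(-Inf, 0))
  ex0 <- simulate_experiment(d0)
  expect_true(all(ex0$polyps$polyps_dead_after == 0))

  # deterministic realised fractions: beaker mean = fraction x nominal
  dx <- tiny_design(realized_fraction_sd = 0, measurement_sd_relative = 0)
  exx <- simulate_experiment(dx)
  nominal <- setNames(dx$nominal_concentrations, c("C0", "C1", "C2"))
  expect_equal(exx$beakers$mean_mg_l,
               unname(nominal[exx$beakers$group]) * dx$realized_fraction_mean,
               tolerance = 1e-12)
})

test_that("faulty-pump override reproduces a near-zero beaker", {
  d <- tiny_design(fraction_override = list("C2.R2" = 0.02))
  ex <- simulate_experiment(d)
  bad <- ex$beakers$mean_mg_l[ex$beakers$group == "C2" &
                                ex$beakers$replicate == "R2"]
  good <- ex$beakers$mean_mg_l[ex$beakers$group == "C2" &
                                 ex$beakers$replicate != "R2"]
  expect_lt(bad, 0.1 * min(good))
})

test_that("Monte-Carlo: dead fraction at C = LC25 matches the generating curve", {
  design <- experiment_design()   # true LC25 = 2.30 mg/L
  p <- true_mortality(design, 2.30)
  expect_equal(p, 0.25, tolerance = 1e-6)
  n_rep <- 1e4
  sim <- with_seed(99, {
    alive <- sample(3:9, n_rep, replace = TRUE)
    dead <- rbinom(n_rep, alive, p)
    dead / alive
  })
  se <- sd(sim) / sqrt(n_rep)
  expect_lt(abs(mean(sim) - 0.25), 3 * se + 1e-12)
})

test_that("pixel-level category separation within morph (QDA oracle)", {
  skip_if_not_installed("MASS")
  # Bayes-error stand-in: quadratic discriminant on the first 10 PCs of
  # endmember-model pixels must misclassify < 10 %
  tab <- endmember_table(n_per_cell = 150, seed = 5)
  for (m in c("white", "orange")) {
    sel <- tab$meta$morph == m
    X <- tab$X[sel, ]
    y <- droplevels(tab$y_c[sel])
    pc <- prcomp(X, rank. = 10)
    fit <- MASS::qda(pc$x, y)
    err <- mean(predict(fit)$class != y)
    expect_lt(err, 0.10)
  }
})

test_that("scenario YAML round trip preserves spec and design", {
  path <- withr::local_tempfile(fileext = ".yaml")
  spec <- tiny_spec(); design <- tiny_design()
  scenario_write(spec, design, path)
  back <- scenario_read(path)
  expect_equal(back$spec$wavelengths, spec$wavelengths)
  expect_equal(back$spec$noise_sd_relative, spec$noise_sd_relative)
  expect_equal(back$design$nominal_concentrations,
               design$nominal_concentrations)
  expect_equal(back$design$mortality_params, design$mortality_params)
  # round-tripped scenario renders the identical cube
  s1 <- render_beaker(spec, design)
  s2 <- render_beaker(back$spec, back$design)
  expect_identical(s1$cube$data, s2$cube$data)
})

test_that("generators do not disturb global RNG state", {
  set.seed(123); before <- .Random.seed
  invisible(simulate_experiment(tiny_design()))
  invisible(generate_endmembers("white", "low", seq(400, 700, 10), seed = 4))
  expect_identical(.Random.seed, before)
})
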