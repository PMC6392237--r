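# Standardisation, PLS, nu-SVM, metrics, majority vote, splits, pipeline.

test_that("standardizer uses population SD and handles constant columns", {
  X <- cbind(a = c(1, 2, 3), b = c(2, 2, 2), c = c(0, 10, 20))
  expect_warning(std <- fit_standardizer(X), "zero-variance")
  Z <- apply_standardizer(std, X)
  expect_equal(Z[, 1], c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(ncol(Z), 2)                     # constant column dropped
  expect_true(all(abs(colMeans(Z)) < 1e-10))   # training means zero
  expect_equal(unname(apply(Z, 2, function(v) mean(v^2))), c(1, 1))
})

test_that("PLS: exact linear case, nesting, sign indeterminacy, ordering", {
  set.seed(4)
  X <- matrix(rnorm(120 * 8), 120)
  B <- matrix(rnorm(8 * 2), 8)
  Y <- X %*% B
  sx <- fit_standardizer(X); sy <- fit_standardizer(Y)
  Z <- apply_standardizer(sx, X); W <- apply_standardizer(sy, Y)
  pls <- fit_pls(Z, W, n_latent = 8)
  expect_lt(max(abs(pls$residual_y)), 1e-8)    # noiseless: E ~ 0
  expect_lt(max(abs(Z %*% pls$B - W)), 1e-8)

  # scores are nested: first columns identical for smaller model
  pls5 <- fit_pls(Z, W, n_latent = 5)
  expect_equal(pls_scores(pls, Z, 5), pls5$T, tolerance = 1e-8)

  # flipping the sign of a weight/loading/score triple leaves predictions
  # unchanged
  flipped <- pls
  flipped$W[, 2] <- -flipped$W[, 2]; flipped$P[, 2] <- -flipped$P[, 2]
  flipped$Q[, 2] <- -flipped$Q[, 2]; flipped$T[, 2] <- -flipped$T[, 2]
  flipped$R <- flipped$W %*% solve(crossprod(flipped$P, flipped$W))
  flipped$B <- flipped$R %*% t(flipped$Q)
  expect_equal(Z %*% flipped$B, Z %*% pls$B, tolerance = 1e-8)

  # X-Y covariance captured per component is non-increasing
  covs <- sapply(seq_len(8), function(a)
    sum(crossprod(pls$T[, a], W)^2) / sum(pls$T[, a]^2))
  expect_true(all(diff(covs) < 1e-8))

  expect_error(fit_pls(Z, W, n_latent = 200), "exceeds")
})

test_that("PLS rank failure triggers on deficient X", {
  X <- matrix(rnorm(40), 20, 2)
  X3 <- cbind(X, X[, 1] + X[, 2])
  Y <- matrix(X[, 1], 20, 1)
  sx <- fit_standardizer(X3); sy <- fit_standardizer(Y)
  expect_error(fit_pls(apply_standardizer(sx, X3), apply_standardizer(sy, Y),
                       n_latent = 3), "rank")
})

test_that("nu-SVM: separable blobs, degenerate classes, determinism", {
  set.seed(10)
  n <- 120
  X <- rbind(matrix(rnorm(n * 10, 0), n), matrix(rnorm(n * 10, 3), n),
             matrix(rnorm(n * 10, -3), n))
  y <- factor(rep(c("low", "medium", "high"), each = n),
              levels = c("low", "medium", "high"))
  sp <- stratified_split(y, 0.8, seed = 2)
  m <- fit_svm(X[sp$train, ], y[sp$train], nu = 0.1)
  acc <- mean(predict(m, X[sp$test, ]) == y[sp$test])
  expect_gte(acc, 0.95)

  # single-class training data fails
  expect_error(fit_svm(X[1:50, ], y[1:50]), "one class")
  # infeasible nu names the bound
  y2 <- factor(c(rep("low", 95), rep("high", 5)))
  expect_error(fit_svm(X[1:100, ], y2, nu = 0.5), "infeasible")

  # determinism: identical support-vector count and predictions
  m2 <- fit_svm(X[sp$train, ], y[sp$train], nu = 0.1)
  expect_identical(sapply(m$models, `[[`, "n_sv"),
                   sapply(m2$models, `[[`, "n_sv"))
  expect_identical(predict(m, X[sp$test, ]), predict(m2, X[sp$test, ]))
})

test_that("nu controls the support-vector fraction from below", {
  set.seed(11)
  n <- 200
  X <- rbind(matrix(rnorm(n * 5, 0), n), matrix(rnorm(n * 5, 2), n))
  y <- factor(rep(c("a", "b"), each = n))
  for (nu in c(0.1, 0.3)) {
    m <- fit_svm(X, y, nu = nu)
    expect_gte(m$models[[1]]$n_sv / (2 * n), nu - 0.01)
  }
})

test_that("evaluate: published-style P/R pairs and harmonic totals", {
  # hand-checkable fabricated predictions
  truth <- factor(c(rep("low", 10), rep("medium", 6), rep("high", 4)),
                  levels = c("low", "medium", "high"))
  pred <- truth
  pred[1] <- "medium"           # one low -> medium
  rep_ <- evaluate(pred, truth)
  low <- rep_$per_class[rep_$per_class$class == "low", ]
  expect_equal(low$recall, 9 / 10)
  expect_equal(low$precision, 1)
  expect_equal(low$f1, f1_score(1, 0.9))
  med <- rep_$per_class[rep_$per_class$class == "medium", ]
  expect_equal(med$precision, 6 / 7)
  expect_equal(med$recall, 1)

  # P = R implies F1 = P
  expect_equal(f1_score(0.8, 0.8), 0.8)

  # empty class in truth is reported absent
  t2 <- factor(rep(c("low", "medium"), 5), levels = c("low", "medium", "high"))
  r2 <- evaluate(t2, t2)
  expect_false("high" %in% r2$per_class$class)

  expect_error(evaluate(factor(c("x", "y")), factor(c("low", "high"))),
               "label sets")
})

test_that("weighted harmonic totals reproduce the published totals rows", {
  # per-class (P, R, pixels) as printed for the orange morph
  p <- c(0.85, 0.94, 0.97); r <- c(0.98, 0.79, 0.78); w <- c(512, 235, 216)
  expect_equal(round(weighted_harmonic(p, w), 2), 0.90)
  # white morph precision and recall totals
  pw <- c(0.87, 0.87, 0.92); rw <- c(0.95, 0.80, 0.78); ww <- c(1252, 457, 440)
  expect_equal(round(weighted_harmonic(pw, ww), 2), 0.88)
  expect_equal(round(weighted_harmonic(rw, ww), 2), 0.88)
})

test_that("majority vote: plurality, severity tie-break, unclassified", {
  lev <- c("low", "medium", "high")
  pred <- factor(c(rep("low", 60), rep("medium", 3), rep("high", 2)), lev)
  v <- majority_vote(pred, rep("s1", 65))
  expect_equal(v$label, "low")
  expect_equal(v$low, 60)

  pred2 <- factor(c(rep("low", 5), rep("medium", 5)), lev)
  expect_warning(v2 <- majority_vote(pred2, rep("s2", 10)), "tie")
  expect_equal(v2$label, "medium")   # broken toward the more severe

  expect_warning(v3 <- majority_vote(pred, rep("s1", 65),
                                     all_samples = c("s1", "ghost")),
                 "unclassified")
  expect_true(is.na(v3$label[v3$sample_id == "ghost"]))
})

test_that("stratified split preserves class proportions and reproduces", {
  y <- factor(rep(c("low", "medium", "high"), times = c(200, 85, 63)))
  sp <- stratified_split(y, 0.8, seed = 5)
  for (k in levels(y)) {
    n_k <- sum(y == k)
    expect_lte(abs(sum(y[sp$train] == k) - 0.8 * n_k), 1)
  }
  expect_identical(sp, stratified_split(y, 0.8, seed = 5))
  expect_false(identical(sp$train, stratified_split(y, 0.8, seed = 6)$train))
  expect_identical(sort(c(sp$train, sp$test)), seq_along(y))
})

test_that("latent-count selection: fixed candidate, informative directions", {
  # single candidate returns itself
  expect_equal(select_n_latent(matrix(rnorm(100), 50), matrix(rnorm(100), 50),
                               factor(rep(c("a", "b"), 25)),
                               candidates = 10), 10)

  # three informative spectral directions, with the class carried by the
  # third: CV must select at least 3 components
  set.seed(21)
  n <- 240; p <- 30
  D <- qr.Q(qr(matrix(rnorm(p * 3), p)))     # orthonormal directions
  u <- matrix(rnorm(n * 3), n)
  X <- 2 * u %*% t(D) + matrix(rnorm(n * p, 0, 0.3), n)
  yc <- cut(u[, 3], quantile(u[, 3], c(0, 1/3, 2/3, 1)),
            labels = c("low", "medium", "high"), include.lowest = TRUE)
  Yh <- cbind(u[, 1] + 0.2 * u[, 3], u[, 2] + 0.2 * u[, 3])
  sel <- select_n_latent(X, Yh, yc, candidates = 1:6, k = 5, seed = 3)
  expect_gte(sel, 3)
})

test_that("pipeline on endmember tables: accuracy and per-morph isolation", {
  tab <- endmember_table(n_per_cell = 120, seed = 2)
  bundles <- train_morph_pipelines(tab, n_latent = 6, seed = 3)
  expect_setequal(names(bundles), c("white", "orange"))
  for (m in names(bundles)) {
    expect_true(all(bundles[[m]]$report$per_class$f1 >= 0.8))
  }
  # per-morph isolation: no shared fitted state
  expect_false(isTRUE(all.equal(bundles$white$standardizer_x$mu,
                                bundles$orange$standardizer_x$mu)))

  # morph without a model fails
  ref <- endmember_table(n_per_cell = 30, seed = 9, categories = "low")
  expect_error(evaluate_reference_group(bundles["white"],
                                        subset_spectra(ref, ref$meta$morph ==
                                                         "orange")),
               "no trained model")
  expect_error(evaluate_reference_group(bundles["white"],
                                        subset_spectra(ref, logical(0))),
               "zero pixels")
})

test_that("healthy reference hold-out votes low on the default scenario", {
  # reference corals rendered as new scenes, never used in training
  dr <- default_run()
  bundles <- default_bundles()
  ref <- reference_group(dr$scn$spec, dr$scn$design)
  refres <- evaluate_reference_group(bundles, ref)
  expect_setequal(names(refres), c("white", "orange"))
  for (m in names(refres)) {
    expect_equal(refres[[m]]$precision, 1)
    expect_gte(refres[[m]]$recall, 0.8)
    # 100 % of reference samples vote into the unexposed category
    expect_true(all(refres[[m]]$votes$label == "low"))
  }
})

test_that("classification map writes PNG + legend", {
  dir <- withr::local_tempdir()
  pred <- factor(c("low", "medium", "high"), c("low", "medium", "high"))
  path <- write_classification_map(c(10, 10), c(2, 3, 4), c(2, 3, 4), pred,
                                   file.path(dir, "map"))
  expect_true(file.exists(file.path(dir, "map.png")))
  legend <- jsonlite::read_json(file.path(dir, "map.json"))
  expect_equal(legend$low, "#E69F00")
  img <- png::readPNG(file.path(dir, "map.png"))
  expect_equal(dim(img), c(10, 10, 3))
})
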