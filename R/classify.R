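# The three-stage spectral classification pipeline: column standardisation,
# projection to latent structures (PLS2, NIPALS), and a nu-SVM with RBF
# kernel on the latent scores, trained separately per colour morph, with
# per-organism majority voting on the pixel predictions.

# ---------------------------------------------------------------------------
# Standardisation (population-SD convention)

#' Fit a column standardizer
#'
#' Centres and scales every column to zero mean and unit variance using the
#' population standard deviation. Zero-variance columns are dropped with a
#' warning and recorded.
#'
#' @param X numeric training matrix
#' @param tol variance tolerance below which a column counts as constant
#' @return object of class `standardizer` with `mu`, `sigma` and the kept
#'   column indices
#' @export
fit_standardizer <- function(X, tol = 1e-12) {
  mu <- colMeans(X)
  sigma <- sqrt(colMeans(sweep(X, 2, mu)^2))
  keep <- which(sigma > tol)
  if (length(keep) < ncol(X))
    warning(sprintf("%d zero-variance column(s) dropped", ncol(X) - length(keep)))
  if (length(keep) == 0) stop("all columns are constant")
  structure(list(mu = mu[keep], sigma = sigma[keep], keep = keep,
                 n_input = ncol(X)), class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param std a `standardizer`
#' @param X matrix with the same columns as the training matrix
#' @return standardized matrix (dropped columns removed)
#' @export
apply_standardizer <- function(std, X) {
  stopifnot(inherits(std, "standardizer"), ncol(X) == std$n_input)
  sweep(sweep(X[, std$keep, drop = FALSE], 2, std$mu), 2, std$sigma, "/")
}

# ---------------------------------------------------------------------------
# PLS2 regression by NIPALS

#' Fit a two-block PLS regression (NIPALS)
#'
#' Projects standardized spectra X onto latent variables that maximise
#' covariance with the standardized response block Y (here: toxicant
#' concentration and polyp mortality), `Y = X B + E`. Scores are nested: the
#' first n columns of the score matrix are identical for any larger number
#' of components. The sign of each loading/score pair is indeterminate; both
#' signs give identical predictions.
#'
#' @param X standardized predictor matrix (n x p)
#' @param Y standardized response matrix (n x q)
#' @param n_latent number of latent variables (default 10)
#' @param max_iter,tol NIPALS inner-iteration controls
#' @return object of class `pls_model` with weights `W`, X-loadings `P`,
#'   Y-loadings `Q`, scores `T`, rotation `R` (so `scores = X %*% R`) and
#'   coefficients `B`
#' @export
fit_pls <- function(X, Y, n_latent = 10, max_iter = 500, tol = 1e-10) {
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (n_latent > min(n - 1, p))
    stop("n_latent exceeds min(n_rows - 1, n_columns)")
  W <- matrix(0, p, n_latent); P <- matrix(0, p, n_latent)
  Q <- matrix(0, q, n_latent); Tm <- matrix(0, n, n_latent)
  Xd <- X; Yd <- Y
  for (a in seq_len(n_latent)) {
    u <- Yd[, which.max(apply(Yd, 2, var))]
    w_old <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14)
        stop(sprintf("n_latent = %d exceeds the effective rank of X (component %d)",
                     n_latent, a))
      w <- w / nw
      t_ <- Xd %*% w
      qv <- crossprod(Yd, t_) / sum(t_^2)
      u <- Yd %*% qv / sum(qv^2)
      if (sum((w - w_old)^2) < tol^2) break
      w_old <- w
    }
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    if (tt < 1e-14)
      stop(sprintf("n_latent = %d exceeds the effective rank of X (component %d)",
                   n_latent, a))
    p_ <- crossprod(Xd, t_) / tt
    qv <- crossprod(Yd, t_) / tt
    Xd <- Xd - t_ %*% t(p_)
    Yd <- Yd - t_ %*% t(qv)
    W[, a] <- w; P[, a] <- p_; Q[, a] <- qv; Tm[, a] <- t_
  }
  R <- W %*% solve(crossprod(P, W))
  structure(list(W = W, P = P, Q = Q, T = Tm, R = R,
                 B = R %*% t(Q), n_latent = n_latent,
                 residual_y = Yd), class = "pls_model")
}

#' Latent-variable scores for new data
#'
#' @param pls a `pls_model`
#' @param X standardized matrix on the training columns
#' @param n_latent use only the first `n_latent` components (default: all)
#' @return score matrix (n x n_latent)
#' @export
pls_scores <- function(pls, X, n_latent = pls$n_latent) {
  stopifnot(n_latent <= pls$n_latent)
  X %*% pls$R[, seq_len(n_latent), drop = FALSE]
}

#' Predict the response block from spectra
#'
#' @param pls a `pls_model`
#' @param X standardized matrix
#' @return predicted (standardized) response matrix
#' @export
pls_predict <- function(pls, X) X %*% pls$B

# ---------------------------------------------------------------------------
# nu-SVM (one-vs-one, RBF kernel)

#' RBF kernel width heuristic
#'
#' The reciprocal of (number of features x total variance of the feature
#' matrix), the common "scale" default.
#'
#' @param X feature matrix
#' @return gamma
#' @export
gamma_scale <- function(X) {
  v <- var(as.vector(X))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(X) * v)
}

#' Train a multiclass nu-SVM
#'
#' One-vs-one decomposition: one binary nu-SVC per unordered pair of classes
#' present in the training labels, combined by voting. Training is
#' deterministic given the data and parameters. `nu` upper-bounds the
#' fraction of margin errors and lower-bounds the fraction of support
#' vectors in each binary problem; it must satisfy
#' `nu <= 2 min(n_a, n_b) / (n_a + n_b)` for every class pair.
#'
#' @param X numeric feature matrix (e.g. PLS scores)
#' @param y factor of class labels (>= 2 classes present)
#' @param nu the nu parameter (default 0.1)
#' @param gamma RBF kernel width; default [gamma_scale()] of `X`
#' @param eps SMO stopping tolerance
#' @return object of class `nusvm_model`
#' @export
fit_svm <- function(X, y, nu = 0.1, gamma = NULL, eps = 1e-3) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  lev <- levels(y)
  if (length(lev) < 2) stop("training data contains only one class")
  if (!(nu > 0 && nu < 1)) stop("nu must lie in (0, 1)")
  if (is.null(gamma)) gamma <- gamma_scale(X)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    idx <- y %in% pr
    Xi <- X[idx, , drop = FALSE]
    yi <- ifelse(y[idx] == pr[1], 1L, -1L)
    fit <- .nusvc_train_binary(Xi, as.integer(yi), nu, gamma, eps)
    list(pair = pr, sv = Xi[fit$sv_index, , drop = FALSE], coef = fit$coef,
         b = fit$b, n_sv = fit$n_sv, iterations = fit$iterations,
         converged = fit$converged)
  })
  structure(list(levels = lev, models = models, nu = nu, gamma = gamma),
            class = "nusvm_model")
}

#' Predict classes with a trained nu-SVM
#'
#' One-vs-one voting; ties are broken toward the most severe class (the
#' highest factor level, e.g. `high` > `medium` > `low`).
#'
#' @param object a `nusvm_model`
#' @param newdata feature matrix
#' @param ... unused
#' @return factor of predicted labels with the training levels
#' @export
predict.nusvm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  votes <- matrix(0L, nrow(newdata), length(object$levels),
                  dimnames = list(NULL, object$levels))
  for (m in object$models) {
    dec <- .rbf_decision(m$sv, m$coef, m$b, object$gamma, newdata)
    win <- ifelse(dec > 0, m$pair[1], m$pair[2])
    for (lv in m$pair) votes[, lv] <- votes[, lv] + (win == lv)
  }
  # ties broken toward the most severe (right-most) level
  pick <- apply(votes, 1, function(v) rev(which(v == max(v)))[1])
  factor(object$levels[pick], levels = object$levels)
}

# ---------------------------------------------------------------------------
# Metrics

#' F1 score from precision and recall
#'
#' The harmonic mean `F1 = 2 P R / (P + R)`; 0 when both are 0.
#'
#' @param p,r precision and recall in `[0, 1]`
#' @return F1
#' @export
f1_score <- function(p, r) ifelse(p + r == 0, 0, 2 * p * r / (p + r))

#' Pixel-weighted harmonic mean
#'
#' `sum(w) / sum(w / x)`: the aggregation used for the totals row of the
#' per-class metric table.
#'
#' @param x per-class values (all > 0)
#' @param w per-class pixel counts
#' @return weighted harmonic mean
#' @export
weighted_harmonic <- function(x, w) sum(w) / sum(w / x)

#' Evaluate predictions against true labels
#'
#' Per-class one-vs-rest true/false positive and false negative fractions,
#' precision, recall and F1, plus a totals row using pixel-count-weighted
#' harmonic means of the per-class precision and recall (total F1 is the
#' harmonic mean of those two totals). Classes absent from the truth are
#' omitted from the table.
#'
#' @param predictions factor of predicted labels
#' @param truth factor of true labels on the same level set
#' @return object of class `classification_report`: `per_class` data.frame
#'   (class, pixels, t_p, f_p, f_n, precision, recall, f1) and `total`
#' @export
evaluate <- function(predictions, truth) {
  predictions <- as.factor(predictions); truth <- as.factor(truth)
  if (!all(levels(truth) %in% levels(predictions)) &&
      !all(levels(predictions) %in% levels(truth)))
    stop("prediction and truth label sets do not match")
  lev <- levels(truth)
  predictions <- factor(as.character(predictions), levels = lev)
  n <- length(truth)
  rows <- lapply(lev, function(k) {
    n_k <- sum(truth == k)
    if (n_k == 0) return(NULL)          # metrics undefined: reported absent
    tp <- sum(predictions == k & truth == k) / n
    fp <- sum(predictions == k & truth != k) / n
    fn <- sum(predictions != k & truth == k) / n
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- tp / (tp + fn)
    data.frame(class = k, pixels = n_k, t_p = tp, f_p = fp, f_n = fn,
               precision = p, recall = r, f1 = f1_score(p, r))
  })
  per_class <- do.call(rbind, rows)
  p_tot <- weighted_harmonic(per_class$precision, per_class$pixels)
  r_tot <- weighted_harmonic(per_class$recall, per_class$pixels)
  total <- data.frame(pixels = sum(per_class$pixels), precision = p_tot,
                      recall = r_tot, f1 = f1_score(p_tot, r_tot),
                      accuracy = mean(predictions == truth))
  structure(list(per_class = per_class, total = total),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, digits = 2, ...) {
  df <- x$per_class[, c("class", "pixels", "precision", "recall", "f1")]
  df[3:5] <- round(df[3:5], digits)
  print(df, row.names = FALSE)
  cat(sprintf("Total/avg: %d pixels, P = %.2f, R = %.2f, F1 = %.2f (accuracy %.2f)\n",
              x$total$pixels, x$total$precision, x$total$recall, x$total$f1,
              x$total$accuracy))
  invisible(x)
}

#' Write a metric table as CSV (2-decimal, half-up rounding)
#'
#' @param reports named list of `classification_report`s (names = morphs)
#' @param path output CSV
#' @return `path`, invisibly
#' @export
report_write <- function(reports, path) {
  half_up <- function(x) floor(x * 100 + 0.5) / 100
  rows <- lapply(names(reports), function(m) {
    r <- reports[[m]]
    pc <- data.frame(color_morph = m, exposure = r$per_class$class,
                     pixels = r$per_class$pixels,
                     P = half_up(r$per_class$precision),
                     R = half_up(r$per_class$recall),
                     F1 = half_up(r$per_class$f1))
    tot <- data.frame(color_morph = m, exposure = "Total/avg",
                      pixels = r$total$pixels, P = half_up(r$total$precision),
                      R = half_up(r$total$recall), F1 = half_up(r$total$f1))
    rbind(pc, tot)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Majority vote and splits

#' Per-sample majority vote over pixel predictions
#'
#' Assigns each coral sample the exposure category predicted for the
#' plurality of its pixels. Ties are broken toward the more severe category
#' with a warning. Samples listed in `all_samples` but without any pixel are
#' reported unclassified (`NA`).
#'
#' @param predictions factor of per-pixel predicted categories
#' @param sample_id sample identifier per pixel
#' @param all_samples optional vector of sample ids that must appear
#' @return data.frame with `sample_id`, `label` and one tally column per
#'   category level
#' @export
majority_vote <- function(predictions, sample_id, all_samples = NULL) {
  predictions <- as.factor(predictions)
  lev <- levels(predictions)
  ids <- unique(sample_id)
  if (!is.null(all_samples)) {
    missing <- setdiff(all_samples, ids)
    if (length(missing) > 0)
      warning("samples without pixels left unclassified: ",
              paste(missing, collapse = ", "))
    ids <- union(ids, all_samples)
  }
  rows <- lapply(ids, function(id) {
    tab <- table(factor(predictions[sample_id == id], levels = lev))
    if (sum(tab) == 0) {
      lab <- NA_character_
    } else {
      winners <- which(tab == max(tab))
      if (length(winners) > 1)
        warning("tie for sample ", id, "; broken toward the more severe category")
      lab <- lev[max(winners)]       # levels ordered low < medium < high
    }
    cbind(data.frame(sample_id = id, label = lab), as.data.frame(t(as.matrix(tab))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratified train/test split
#'
#' Samples `frac` of the rows of every class for training (rounded to the
#' nearest integer per class), the rest for testing; seed-reproducible.
#'
#' @param y class labels
#' @param frac training fraction (default 0.8)
#' @param seed integer seed
#' @return list with integer vectors `train` and `test`
#' @export
stratified_split <- function(y, frac = 0.8, seed = 1L) {
  y <- as.factor(y)
  with_seed(seed, {
    train <- unlist(lapply(levels(y), function(k) {
      idx <- which(y == k)
      if (length(idx) == 0) return(integer(0))
      sample(idx, round(frac * length(idx)))
    }))
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(y), train))
  })
}

# ---------------------------------------------------------------------------
# Cross-validation for the latent-variable count

#' Cross-validated classification error over latent-variable counts
#'
#' 5-fold stratified cross-validation of the full standardize -> PLS ->
#' nu-SVM chain. Because NIPALS scores are nested, one PLS fit per fold
#' serves every candidate.
#'
#' @param X raw (uncentred) spectra matrix
#' @param Y_h raw response block (concentration, mortality)
#' @param y_c class labels
#' @param candidates latent-variable counts to evaluate
#' @param k number of folds (default 5)
#' @param seed integer seed for fold assignment
#' @param nu,gamma SVM parameters (gamma default: scale heuristic per fold)
#' @return data.frame with `n_latent` and mean CV `error`
#' @export
cv_latent_error <- function(X, Y_h, y_c, candidates = 1:25, k = 5, seed = 1L,
                            nu = 0.1, gamma = NULL) {
  y_c <- droplevels(as.factor(y_c))
  n <- nrow(X)
  if (min(table(y_c)) < k)
    stop("fewer rows than folds in at least one class")
  folds <- with_seed(seed, {
    f <- integer(n)
    for (lv in levels(y_c)) {
      idx <- sample(which(y_c == lv))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  a_max <- max(candidates)
  err <- matrix(NA_real_, k, length(candidates))
  for (fold in seq_len(k)) {
    tr <- folds != fold; te <- !tr
    sx <- fit_standardizer(X[tr, , drop = FALSE])
    sy <- fit_standardizer(as.matrix(Y_h)[tr, , drop = FALSE])
    Xtr <- apply_standardizer(sx, X[tr, , drop = FALSE])
    Ytr <- apply_standardizer(sy, as.matrix(Y_h)[tr, , drop = FALSE])
    pls <- fit_pls(Xtr, Ytr, a_max)
    Xte <- apply_standardizer(sx, X[te, , drop = FALSE])
    for (ci in seq_along(candidates)) {
      nc <- candidates[ci]
      str <- pls_scores(pls, Xtr, nc)
      ste <- pls_scores(pls, Xte, nc)
      svm <- fit_svm(str, y_c[tr], nu = nu, gamma = gamma)
      err[fold, ci] <- mean(predict(svm, ste) != y_c[te])
    }
  }
  data.frame(n_latent = candidates, error = colMeans(err))
}

#' Select the latent-variable count by stratified cross-validation
#'
#' Returns the candidate with the smallest cross-validated downstream
#' classification error; ties are broken toward fewer components.
#'
#' @inheritParams cv_latent_error
#' @return integer: the selected number of latent variables
#' @export
select_n_latent <- function(X, Y_h, y_c, candidates = 1:25, k = 5, seed = 1L,
                            nu = 0.1, gamma = NULL) {
  candidates <- sort(unique(candidates))
  if (length(candidates) == 1) return(candidates)
  cv <- cv_latent_error(X, Y_h, y_c, candidates, k, seed, nu, gamma)
  cv$n_latent[which.min(cv$error)]
}

# ---------------------------------------------------------------------------
# Per-morph pipeline

#' Train the full classification pipeline on one morph's spectra
#'
#' Stratified 80/20 pixel split, standardisation of X and Y_h on the
#' training set, PLS to `n_latent` latent variables, nu-SVM on the training
#' scores, evaluation on the held-out test pixels, and per-sample majority
#' vote over the test pixels.
#'
#' @param table an annotated, cropped [spectra_table] containing a single
#'   colour morph
#' @param n_latent latent variables (default 10)
#' @param nu nu-SVM parameter (default 0.1)
#' @param gamma RBF width (default: scale heuristic on the training scores)
#' @param split_frac training fraction (default 0.8)
#' @param seed split seed
#' @return object of class `classifier_bundle`
#' @export
train_pipeline <- function(table, n_latent = 10, nu = 0.1, gamma = NULL,
                           split_frac = 0.8, seed = 1L) {
  stopifnot(inherits(table, "spectra_table"), !is.null(table$y_c))
  morphs <- unique(table$meta$morph)
  if (length(morphs) != 1)
    stop("train_pipeline expects a single-morph table; use train_morph_pipelines")
  y <- droplevels(table$y_c)
  sp <- stratified_split(y, split_frac, seed)
  Xtr <- table$X[sp$train, , drop = FALSE]
  std_x <- fit_standardizer(Xtr)
  std_y <- fit_standardizer(as.matrix(table$y_h)[sp$train, , drop = FALSE])
  Ztr <- apply_standardizer(std_x, Xtr)
  Ytr <- apply_standardizer(std_y, as.matrix(table$y_h)[sp$train, , drop = FALSE])
  pls <- fit_pls(Ztr, Ytr, n_latent)
  scores_tr <- pls_scores(pls, Ztr)
  svm <- fit_svm(scores_tr, y[sp$train], nu = nu, gamma = gamma)
  bundle <- structure(list(
    morph = morphs, standardizer_x = std_x, standardizer_y = std_y,
    pls = pls, svm = svm, wavelengths = table$wavelengths,
    split = list(frac = split_frac, seed = seed, train = sp$train,
                 test = sp$test),
    config = list(n_latent = n_latent, nu = nu, gamma = svm$gamma)),
    class = "classifier_bundle")
  test_pred <- predict_pipeline(bundle, table$X[sp$test, , drop = FALSE])
  bundle$report <- evaluate(test_pred, factor(as.character(y[sp$test]),
                                              levels = levels(table$y_c)))
  bundle$test_votes <- majority_vote(test_pred,
                                     table$meta$sample_id[sp$test])
  truth_map <- tapply(as.character(table$y_c), table$meta$sample_id,
                      function(v) v[1])
  bundle$test_votes$true_label <-
    as.character(truth_map[bundle$test_votes$sample_id])
  bundle
}

#' Predict pixel categories with a trained bundle
#'
#' @param bundle a `classifier_bundle`
#' @param X raw (uncentred) spectra matrix on the bundle's wavelength grid
#' @return factor of predicted categories
#' @export
predict_pipeline <- function(bundle, X) {
  stopifnot(inherits(bundle, "classifier_bundle"))
  Z <- apply_standardizer(bundle$standardizer_x, X)
  predict(bundle$svm, pls_scores(bundle$pls, Z))
}

#' Train one pipeline per colour morph
#'
#' White and orange pipelines share no fitted state.
#'
#' @param table an annotated, cropped [spectra_table] with both morphs
#' @param ... passed to [train_pipeline()]
#' @return named list of `classifier_bundle`s
#' @export
train_morph_pipelines <- function(table, ...) {
  lapply(split_by_morph(table), train_pipeline, ...)
}

#' Evaluate trained pipelines on a healthy reference hold-out group
#'
#' Reference corals were never exposed, so the correct category for every
#' reference pixel is `low`. Reports precision and recall of the `low` class
#' per morph and the per-sample majority-vote outcome.
#'
#' @param bundles named list of `classifier_bundle`s (per morph)
#' @param ref_table a cropped [spectra_table] of reference spectra (not used
#'   in training)
#' @return list per morph with `precision`, `recall`, `votes`
#' @export
evaluate_reference_group <- function(bundles, ref_table) {
  stopifnot(inherits(ref_table, "spectra_table"))
  if (n_spectra(ref_table) == 0) stop("reference set contains zero pixels")
  out <- list()
  for (m in unique(ref_table$meta$morph)) {
    if (is.null(bundles[[m]]))
      stop("no trained model for morph: ", m)
    sub <- subset_spectra(ref_table, ref_table$meta$morph == m)
    pred <- predict_pipeline(bundles[[m]], sub$X)
    tp <- sum(pred == "low")           # every reference truth is "low"
    p <- if (tp > 0) 1 else NaN        # tp / n_predicted_low
    r <- tp / length(pred)
    votes <- majority_vote(pred, sub$meta$sample_id)
    out[[m]] <- list(precision = p, recall = r, votes = votes,
                     n_pixels = length(pred))
  }
  out
}

#' Write a per-pixel classification map as PNG + JSON legend
#'
#' Classified coral pixels are painted with the category palette (low =
#' orange, medium = red, high = dark red by default); unclassified pixels
#' are black.
#'
#' @param shape image `(rows, cols)`
#' @param px_row,px_col pixel positions of the predictions
#' @param predictions factor of categories
#' @param path output path without extension (writes `.png` and `.json`)
#' @param palette named vector of hex colours per category
#' @return `path`, invisibly
#' @export
write_classification_map <- function(shape, px_row, px_col, predictions, path,
                                     palette = c(low = "#E69F00",
                                                 medium = "#D62728",
                                                 high = "#67000D")) {
  img <- array(0, c(shape[1], shape[2], 3))
  rgb_of <- grDevices::col2rgb(palette) / 255
  for (k in seq_along(levels(predictions))) {
    lv <- levels(predictions)[k]
    sel <- which(predictions == lv)
    for (ch in 1:3)
      img[cbind(px_row[sel], px_col[sel], ch)] <- rgb_of[ch, lv]
  }
  png::writePNG(img, paste0(path, ".png"))
  jsonlite::write_json(as.list(palette), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}
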