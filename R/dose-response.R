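# Concentration--mortality modelling. The fraction of dead polyps per coral
# sample is related to the beaker's mean 2-methylnaphthalene concentration
# by a binomial model with a logit link on log-concentration:
#
#     logit(p) = beta0 + beta1 * log(C)
#
# The log-dose parameterisation forces p -> 0 as C -> 0 ("through the
# origin") without an improper link. Lethal concentrations LC5/LC25 are the
# closed-form inverse of the link; confidence intervals come from case
# resampling of coral samples.

#' Exposure-category rule
#'
#' Concentration thresholds separating the low / medium / high exposure
#' categories. Defaults are the LC5 and LC25 levels of the study's fitted
#' dose-response curve: 1.25 and 2.30 mg/L.
#'
#' @param lc5,lc25 thresholds in mg/L; `0 < lc5 < lc25`
#' @return object of class `category_rule`
#' @export
category_rule <- function(lc5 = 1.25, lc25 = 2.30) {
  if (!(0 < lc5 && lc5 < lc25)) stop("need 0 < lc5 < lc25")
  structure(list(lc5 = lc5, lc25 = lc25), class = "category_rule")
}

#' Assign exposure categories to concentrations
#'
#' Boundary convention: low if `C <= lc5`; medium if `lc5 < C <= lc25`;
#' high if `C > lc25`.
#'
#' @param concentration numeric vector, mg/L, non-negative
#' @param rule a [category_rule()]
#' @return factor with levels `low`, `medium`, `high`
#' @export
assign_category <- function(concentration, rule = category_rule()) {
  if (any(concentration < 0)) stop("concentration must be >= 0")
  out <- ifelse(concentration <= rule$lc5, "low",
                ifelse(concentration <= rule$lc25, "medium", "high"))
  factor(out, levels = c("low", "medium", "high"))
}

.validate_records <- function(records) {
  need <- c("polyps_alive_before", "polyps_dead_after", "beaker_mean_mg_l")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  if (any(records$polyps_alive_before < 1)) stop("alive_before must be >= 1")
  if (any(records$polyps_dead_after < 0 |
            records$polyps_dead_after > records$polyps_alive_before))
    stop("dead counts must lie in [0, alive_before]")
  records
}

#' Fit the concentration--mortality dose-response curve
#'
#' Binomial GLM with logit link on log-concentration. "Binarised" polyp
#' outcomes (each polyp one Bernoulli trial) are expressed as the equivalent
#' aggregated binomial counts per sample. Zero-concentration records cannot
#' enter the log-dose likelihood; they are summarised as a goodness check
#' (their observed mortality, which the origin-constrained curve predicts to
#' be 0).
#'
#' @param records data.frame with columns `polyps_alive_before`,
#'   `polyps_dead_after`, `beaker_mean_mg_l` (one row per coral sample)
#' @param binarize `"polyp"` (default: dead/alive per polyp) or `"sample"`
#'   (any-death vs no-death per sample)
#' @return object of class `dose_response_fit`: coefficients `beta0`,
#'   `beta1`, `pseudo_r2` (McFadden), the fitted `glm`, and the control
#'   goodness check
#' @export
fit_dose_response <- function(records, binarize = c("polyp", "sample")) {
  binarize <- match.arg(binarize)
  records <- .validate_records(records)
  pos <- records[records$beaker_mean_mg_l > 0, ]
  if (length(unique(pos$beaker_mean_mg_l)) < 2)
    stop("need >= 2 distinct positive concentrations")
  if (sum(records$polyps_dead_after) == 0)
    stop("no deaths observed at any dose: dose-response cannot be fitted")
  if (binarize == "polyp") {
    resp <- cbind(pos$polyps_dead_after,
                  pos$polyps_alive_before - pos$polyps_dead_after)
  } else {
    any_death <- as.integer(pos$polyps_dead_after > 0)
    resp <- cbind(any_death, 1L - any_death)
  }
  logc <- log(pos$beaker_mean_mg_l)
  fit <- suppressWarnings(glm(resp ~ logc, family = binomial()))
  null <- suppressWarnings(glm(resp ~ 1, family = binomial()))
  b <- coef(fit)
  ctrl <- records[records$beaker_mean_mg_l == 0, ]
  ctrl_mort <- if (nrow(ctrl) > 0)
    sum(ctrl$polyps_dead_after) / sum(ctrl$polyps_alive_before) else NA_real_
  structure(list(beta0 = unname(b[1]), beta1 = unname(b[2]),
                 pseudo_r2 = 1 - as.numeric(logLik(fit) / logLik(null)),
                 glm = fit, binarize = binarize,
                 n_samples = nrow(records), n_positive = nrow(pos),
                 control_mortality = ctrl_mort),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> logit(p) = %.3f + %.3f log(C); McFadden R2 = %.3f\n",
              x$beta0, x$beta1, x$pseudo_r2))
  if (x$beta1 > 0)
    cat(sprintf("  LC5 = %.3f mg/L, LC25 = %.3f mg/L\n",
                invert_lc(x, 0.05), invert_lc(x, 0.25)))
  invisible(x)
}

#' Predict mortality at given concentrations
#'
#' @param fit a `dose_response_fit` (or a list with `beta0`, `beta1`)
#' @param concentration mg/L, vectorised; returns 0 at C = 0
#' @return predicted mortality fraction
#' @export
predict_mortality <- function(fit, concentration) {
  ifelse(concentration <= 0, 0,
         plogis(fit$beta0 + fit$beta1 * log(concentration)))
}

#' Invert the fitted curve at a mortality level
#'
#' Closed-form inverse of the logit link:
#' `C_p = exp((logit(p) - beta0) / beta1)`.
#'
#' @param fit a `dose_response_fit`
#' @param p mortality fraction, `0 < p < 1`
#' @return concentration in mg/L
#' @export
invert_lc <- function(fit, p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  if (fit$beta1 <= 0)
    stop("fitted curve is non-increasing (beta1 <= 0); LC undefined")
  exp((qlogis(p) - fit$beta0) / fit$beta1)
}

#' Bootstrap confidence intervals for the dose-response curve and LC levels
#'
#' Case resampling of coral samples (not polyps), preserving each sample's
#' beaker concentration. Percentile intervals; resamples on which the fit
#' fails (e.g. no deaths drawn) are counted and reported, and the run fails
#' if fewer than `min_success` of resamples succeed.
#'
#' @param records as for [fit_dose_response()]
#' @param n_boot number of resamples (default 10^4)
#' @param level confidence level (default 0.95)
#' @param seed integer seed
#' @param lc_levels mortality fractions whose LCs are tracked
#' @param binarize passed to [fit_dose_response()]
#' @param min_success minimum fraction of successful resamples
#' @return object of class `dose_response_boot`: point `fit`, `lc` table
#'   with point estimates and CIs, coefficient CIs, failure count
#' @export
bootstrap_ci <- function(records, n_boot = 1e4, level = 0.95, seed = 1L,
                         lc_levels = c(0.05, 0.25),
                         binarize = c("polyp", "sample"),
                         min_success = 0.8) {
  binarize <- match.arg(binarize)
  records <- .validate_records(records)
  fit <- fit_dose_response(records, binarize)
  n <- nrow(records)
  stats <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, 2 + length(lc_levels))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      fb <- tryCatch(fit_dose_response(records[idx, ], binarize),
                     error = function(e) NULL)
      if (is.null(fb) || fb$beta1 <= 0) next
      out[b, ] <- c(fb$beta0, fb$beta1,
                    vapply(lc_levels, function(p) invert_lc(fb, p), 0))
    }
    out
  })
  ok <- stats::complete.cases(stats)
  if (mean(ok) < min_success)
    stop(sprintf("only %.0f%% of bootstrap resamples produced a valid fit",
                 100 * mean(ok)))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(stats[ok, , drop = FALSE], 2, quantile, probs = probs)
  lc_point <- vapply(lc_levels, function(p) invert_lc(fit, p), 0)
  lc <- data.frame(level = lc_levels, estimate = lc_point,
                   lower = qs[1, -(1:2)], upper = qs[2, -(1:2)])
  structure(list(fit = fit, lc = lc,
                 coef_ci = data.frame(coef = c("beta0", "beta1"),
                                      lower = qs[1, 1:2], upper = qs[2, 1:2]),
                 n_boot = n_boot, n_failed = sum(!ok), level = level,
                 seed = seed), class = "dose_response_boot")
}

#' @export
print.dose_response_boot <- function(x, ...) {
  print(x$fit)
  for (i in seq_len(nrow(x$lc)))
    cat(sprintf("  LC%.0f = %.3f mg/L  [%.3f, %.3f] (%.0f%% CI, N = %d, %d failed)\n",
                100 * x$lc$level[i], x$lc$estimate[i], x$lc$lower[i],
                x$lc$upper[i], 100 * x$level, x$n_boot, x$n_failed))
  invisible(x)
}

#' Serialise a bootstrap dose-response report to JSON
#'
#' @param boot a `dose_response_boot`
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
dose_response_report <- function(boot, path) {
  jsonlite::write_json(list(
    beta0 = boot$fit$beta0, beta1 = boot$fit$beta1,
    pseudo_r2 = boot$fit$pseudo_r2, binarize = boot$fit$binarize,
    lc = boot$lc, coef_ci = boot$coef_ci,
    n_boot = boot$n_boot, n_failed = boot$n_failed,
    level = boot$level, seed = boot$seed,
    control_mortality = boot$fit$control_mortality),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
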