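# Summaries of measured 2-methylnaphthalene concentrations in stock bottles
# and exposure beakers. The long-format chemistry table has one row per
# water-sample measurement: group (C0..), replicate (R1.. or "stock"),
# phase ("beaker", or stock-bottle phases "A_after_replacement" /
# "B_before_replacement"), time_h, duplicate (I/II) and concentration.

#' Limits of the analytical chemistry
#'
#' Limit of quantification (LOQ, 0.1 mg/L) and limit of detection
#' (LOD, 0.033 mg/L) of the GC-MS workflow; measurements below the LOQ are
#' flagged in summaries but enter at their measured value.
#' @export
chem_limits <- list(loq_mg_l = 0.1, lod_mg_l = 0.033)

#' Read / write a long-format chemistry table
#'
#' @param path CSV with columns `group`, `replicate`, `phase`, `time_h`,
#'   `duplicate`, `concentration_mg_l`
#' @return data.frame
#' @export
chemistry_read <- function(path) {
  df <- read.csv(path)
  need <- c("group", "replicate", "phase", "time_h", "concentration_mg_l")
  if (!all(need %in% names(df)))
    stop("chemistry table needs columns: ", paste(need, collapse = ", "))
  if (any(df$concentration_mg_l < 0)) stop("concentrations must be >= 0")
  df
}

#' @rdname chemistry_read
#' @param table chemistry data.frame
#' @export
chemistry_write <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

.chem_cell <- function(x) {
  data.frame(avg = mean(x), std_dev = if (length(x) > 1) sd(x) else 0,
             min = min(x), max = max(x), n = length(x),
             n_below_loq = sum(x < chem_limits$loq_mg_l))
}

#' Summarise measured concentrations
#'
#' Arithmetic mean, standard deviation, minimum and maximum over time points
#' and duplicate water samples.
#'
#' * `level = "stock"`: one row per group over the stock-bottle phases.
#' * `level = "beaker"`: one row per (group, replicate) over beaker
#'   measurements.
#' * `level = "group"`: one row per group; the average is the mean of the
#'   replicate beaker means, the standard deviation either pools all beaker
#'   measurements (default) or is taken over the four beaker means.
#'
#' @param table long-format chemistry data.frame
#' @param level `"stock"`, `"beaker"` or `"group"`
#' @param sd_method for `level = "group"`: `"pooled"` (default) or
#'   `"beaker_means"`
#' @return data.frame of summary rows; cells without measurements are
#'   absent, not zero
#' @export
summarize_chemistry <- function(table, level = c("beaker", "group", "stock"),
                                sd_method = c("pooled", "beaker_means")) {
  level <- match.arg(level); sd_method <- match.arg(sd_method)
  if (level == "stock") {
    sub <- table[table$replicate == "stock", ]
    if (nrow(sub) == 0) stop("no stock measurements present")
    out <- do.call(rbind, lapply(split(sub, sub$group), function(g)
      cbind(data.frame(group = g$group[1]), .chem_cell(g$concentration_mg_l))))
  } else {
    sub <- table[table$phase == "beaker", ]
    if (nrow(sub) == 0) stop("no beaker measurements present")
    if (level == "beaker") {
      out <- do.call(rbind, lapply(
        split(sub, list(sub$group, sub$replicate), drop = TRUE), function(g)
          cbind(data.frame(group = g$group[1], replicate = g$replicate[1]),
                .chem_cell(g$concentration_mg_l))))
      out <- out[order(out$group, out$replicate), ]
    } else {
      out <- do.call(rbind, lapply(split(sub, sub$group), function(g) {
        bm <- tapply(g$concentration_mg_l, g$replicate, mean)
        sdv <- if (sd_method == "pooled") {
          if (nrow(g) > 1) sd(g$concentration_mg_l) else 0
        } else if (length(bm) > 1) sd(bm) else 0
        data.frame(group = g$group[1], avg = mean(bm), std_dev = sdv,
                   min = min(g$concentration_mg_l),
                   max = max(g$concentration_mg_l),
                   n = nrow(g),
                   n_below_loq = sum(g$concentration_mg_l < chem_limits$loq_mg_l))
      }))
    }
  }
  rownames(out) <- NULL
  out
}

#' Group averages of already-summarised beaker means
#'
#' Averages printed per-beaker means into the group-level figure (the
#' "Beakers 1--4 (avg)" row convention): plain arithmetic mean, reported to
#' one decimal like the concentration tables.
#'
#' @param beaker_means numeric vector of per-beaker average concentrations
#' @param digits decimals for the reported value (default 1); use `Inf` for
#'   the unrounded value
#' @return the group average concentration
#' @export
group_average <- function(beaker_means, digits = 1) {
  m <- mean(beaker_means)
  if (is.finite(digits)) round(m, digits) else m
}

#' Express group or beaker means as a percentage of nominal
#'
#' @param summary data.frame with columns `group`, `avg` (and optionally
#'   `replicate`), e.g. from [summarize_chemistry()]
#' @param nominal named numeric vector of nominal concentrations per group
#' @param low_floor fraction of nominal below which an exposed row is
#'   flagged as an outlier (default 0.10, catching e.g. a faulty pump
#'   delivering 2% of nominal)
#' @return the summary with added `percent_of_nominal` (NA for zero-nominal
#'   groups, which are excluded with a note column) and `flagged_low`
#' @export
percent_of_nominal <- function(summary, nominal, low_floor = 0.10) {
  nom <- nominal[as.character(summary$group)]
  if (any(is.na(nom))) stop("nominal concentration missing for some groups")
  pct <- ifelse(nom > 0, 100 * summary$avg / nom, NA_real_)
  summary$percent_of_nominal <- pct
  summary$note <- ifelse(nom > 0, "", "excluded: zero nominal")
  summary$flagged_low <- !is.na(pct) & pct < 100 * low_floor
  summary
}
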