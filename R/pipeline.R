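# Batch extraction, group summaries and reliability reporting.

#' Extract features for every row of a study design table
#'
#' The design CSV keys each recorded frame to its tendon, group, evaluator,
#' visit and image replicate, and names the image and ROI files.  Rows that
#' fail (missing file, corrupt image, view mismatch, degenerate ROI) are
#' logged and skipped; the run continues and the failures are returned so a
#' caller (e.g. the CLI) can exit non-zero.
#'
#' @param design data.frame or CSV path with columns `tendon_id`, `group`,
#'   `evaluator`, `visit`, `image`, `view`, `image_path`, `roi_path`.
#' @param image_dir,roi_dir directories the path columns are relative to
#'   (default `"."`).
#' @param config a [qus_config()].
#' @param calibration a [pixel_calibration()].
#' @return list of class `"qus_extraction"`: `features` (long data.frame:
#'   design columns + `feature`, `value`, `undefined_flag`) and `failures`
#'   (data.frame of failed rows with the error message).
#' @export
run_extract <- function(design, image_dir = ".", roi_dir = ".",
                        config = qus_config(),
                        calibration = pixel_calibration()) {
  if (is.character(design)) design <- read.csv(design, stringsAsFactors = FALSE)
  need <- c("tendon_id", "group", "evaluator", "visit", "image", "view",
            "image_path", "roi_path")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(design) == 0L) stop("empty design table")
  feats <- list(); fails <- list()
  for (k in seq_len(nrow(design))) {
    row <- design[k, ]
    res <- tryCatch({
      img <- load_image(file.path(image_dir, row$image_path),
                        calibration = calibration, view = row$view)
      roi <- read_roi(file.path(roi_dir, row$roi_path))
      fs <- extract_features(img, roi, config)
      features_to_rows(fs, meta = row[c("tendon_id", "group", "evaluator",
                                        "visit", "image")])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message("row ", k, " (", row$image_path, ") failed: ",
              conditionMessage(res))
      fails[[length(fails) + 1L]] <- cbind(row, error = conditionMessage(res))
    } else {
      feats[[length(feats) + 1L]] <- res
    }
  }
  structure(list(features = if (length(feats)) do.call(rbind, feats)
                            else data.frame(),
                 failures = if (length(fails)) do.call(rbind, fails)
                            else data.frame()),
            class = "qus_extraction")
}

#' Per-group summary of extracted features
#'
#' The analysis unit is the tendon: each tendon's repeated images are first
#' averaged, then the mean, SD (sample, n - 1) and confidence interval are
#' computed over tendons, per feature x view x group, plus the overall
#' (all-tendon) statistics and the percent difference between the
#' symptomatic and asymptomatic group means.
#'
#' @param features long feature data.frame (from [run_extract()] or
#'   [simulate_feature_study()]); undefined-flagged rows are dropped with a
#'   message.
#' @param ci_method `"normal"` (mean +/- 1.96 SD/sqrt(n); default) or
#'   `"t"` (t quantile).
#' @param conf confidence level (default 0.95).
#' @param groups the two groups compared, `c(symptomatic, asymptomatic)`
#'   order for the percent difference.
#' @return data.frame of class `"group_summary"`: one row per feature x
#'   view x group (plus group `"all"`), columns `mean`, `sd`, `ci_lower`,
#'   `ci_upper`, `n`, `pct_difference` (on symptomatic rows; percent).
#' @export
group_summary <- function(features, ci_method = c("normal", "t"),
                          conf = 0.95,
                          groups = c("symptomatic", "asymptomatic")) {
  ci_method <- match.arg(ci_method)
  df <- features
  if ("undefined_flag" %in% names(df) && any(df$undefined_flag)) {
    message("dropping ", sum(df$undefined_flag), " undefined-flagged rows")
    df <- df[!df$undefined_flag, ]
  }
  per_tendon <- aggregate(value ~ tendon_id + group + view + feature,
                          data = df, FUN = mean)
  summarize <- function(sub, label) {
    n <- nrow(sub)
    m <- mean(sub$value); s <- if (n > 1) sd(sub$value) else NA_real_
    q <- if (ci_method == "normal") qnorm(1 - (1 - conf) / 2)
         else qt(1 - (1 - conf) / 2, df = n - 1)
    half <- q * s / sqrt(n)
    data.frame(view = sub$view[1], feature = sub$feature[1], group = label,
               n = n, mean = m, sd = s,
               ci_lower = m - half, ci_upper = m + half,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (vw in unique(per_tendon$view)) for (ft in unique(per_tendon$feature)) {
    sub <- per_tendon[per_tendon$view == vw & per_tendon$feature == ft, ]
    if (!nrow(sub)) next
    out[[length(out) + 1L]] <- summarize(sub, "all")
    for (g in unique(sub$group)) {
      out[[length(out) + 1L]] <- summarize(sub[sub$group == g, ], g)
    }
  }
  res <- do.call(rbind, out)
  res$pct_difference <- NA_real_
  for (vw in unique(res$view)) for (ft in unique(res$feature)) {
    sel <- res$view == vw & res$feature == ft
    ms <- res$mean[sel & res$group == groups[1]]
    ma <- res$mean[sel & res$group == groups[2]]
    if (length(ms) == 1L && length(ma) == 1L && ma != 0) {
      res$pct_difference[sel & res$group == groups[1]] <-
        percent_difference(ms, ma)
    }
  }
  class(res) <- c("group_summary", class(res))
  res
}

#' Percent difference between two group means
#'
#' `100 * (mean_symptomatic - mean_asymptomatic) / mean_asymptomatic`.
#'
#' @param mean_symptomatic,mean_asymptomatic the two group means; the
#'   asymptomatic (reference) mean must be non-zero.
#' @return percent difference (numeric).
#' @export
percent_difference <- function(mean_symptomatic, mean_asymptomatic) {
  if (any(mean_asymptomatic == 0)) stop("reference mean must be non-zero")
  100 * (mean_symptomatic - mean_asymptomatic) / mean_asymptomatic
}

#' Full reliability report: G-study + D-study per feature x view x group
#'
#' For every feature x view x group cell with a balanced complete design
#' and no undefined-flagged values: estimates the 15 variance components,
#' their percentages of total variance, and the single-evaluator D-study
#' grid (V in 1:2 crossed with I in 1:3) with Phi, SEM, the normalized
#' minimal detectable change and the verbal reliability label.  Cells that
#' cannot be analysed (undefined values, unbalanced) are skipped with the
#' reason recorded.
#'
#' @param features long feature data.frame with design columns.
#' @param z confidence multiplier for the MDC (default 1.65).
#' @param visits,images D-study protocol levels.
#' @return list of class `"reliability_report"`: `analyses` (one entry per
#'   analysed cell: `feature`, `view`, `group`, `components`,
#'   `proportions`, `grid`, `group_mean`), `skipped` (data.frame with
#'   reasons).
#' @export
reliability_report <- function(features, z = 1.65, visits = 1:2,
                               images = 1:3) {
  analyses <- list(); skipped <- list()
  cells <- unique(features[, c("feature", "view", "group")])
  for (k in seq_len(nrow(cells))) {
    ft <- cells$feature[k]; vw <- cells$view[k]; g <- cells$group[k]
    sub <- features[features$feature == ft & features$view == vw &
                      features$group == g, ]
    res <- tryCatch({
      vc <- estimate_variance_components(sub)
      gm <- mean(sub$value)
      list(feature = ft, view = vw, group = g,
           components = vc, proportions = variance_proportions(vc),
           grid = protocol_grid(vc, group_mean = gm, visits = visits,
                                images = images, z = z),
           group_mean = gm)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(feature = ft, view = vw, group = g,
                   reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      analyses[[length(analyses) + 1L]] <- res
    }
  }
  structure(list(analyses = analyses,
                 skipped = if (length(skipped)) do.call(rbind, skipped)
                           else data.frame()),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> %d analyses, %d skipped\n",
              length(x$analyses), nrow(x$skipped)))
  invisible(x)
}

#' Write a reliability report bundle to disk
#'
#' Emits `variance_proportions.csv` (one row per analysed cell, the 15
#' component percentages), `dstudy_grid.csv` (one row per cell x protocol)
#' and `report.json` (everything, including raw components).
#'
#' @param report a [reliability_report()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  props <- do.call(rbind, lapply(report$analyses, function(a) {
    cbind(data.frame(feature = a$feature, view = a$view, group = a$group,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(round(a$proportions, 4))))
  }))
  grids <- do.call(rbind, lapply(report$analyses, function(a) {
    cbind(data.frame(feature = a$feature, view = a$view, group = a$group,
                     stringsAsFactors = FALSE), a$grid)
  }))
  write.csv(props, file.path(out_dir, "variance_proportions.csv"),
            row.names = FALSE)
  write.csv(grids, file.path(out_dir, "dstudy_grid.csv"), row.names = FALSE)
  js <- lapply(report$analyses, function(a) {
    list(feature = a$feature, view = a$view, group = a$group,
         group_mean = a$group_mean,
         components_raw = as.list(a$components$raw),
         components = as.list(a$components$clamped),
         proportions = as.list(a$proportions),
         dstudy = a$grid)
  })
  jsonlite::write_json(list(analyses = js, skipped = report$skipped),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}
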