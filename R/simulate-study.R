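# Simulated measurement studies over the crossed S x E x V x I design.
#
# Linear mode draws one independent zero-mean Gaussian effect per realized
# level combination of each of the 15 effects, with the requested component
# variances, and sums them plus the grand mean -- the textbook random-model
# generator, so that estimate_variance_components() is expected to recover
# the components.  Imaging mode renders an actual phantom per design cell
# (evaluator gain + ROI-placement jitter, visit gain, fresh speckle per
# image) and extracts features, mapping the reliability facets onto
# image-formation causes.

#' Parameters of a simulated measurement study
#'
#' @param n_s subjects (tendons) per group.
#' @param n_e,n_v,n_i evaluators, visits, images per visit (defaults 2, 2,
#'   2 -- the crossed design the package's reliability analysis targets).
#' @param components named 15-vector of true variance components (see
#'   [gtheory_effects()]); missing names default to 0.  Used by linear
#'   mode.
#' @param grand_mean grand mean of the simulated feature (linear mode).
#' @param groups group labels; one grand mean per group may be supplied as
#'   a named vector in `grand_mean`.
#' @param evaluator_gain_sd imaging mode: SD of the per-(subject,
#'   evaluator) multiplicative intensity gain (default 0.03).
#' @param visit_gain_sd imaging mode: SD of the per-(subject, visit)
#'   multiplicative gain (default 0.015).
#' @param roi_jitter_px imaging mode: SD (pixels) of the vertical
#'   ROI-placement error drawn per (subject, evaluator) (default 3).
#' @param subject_echo_sd imaging mode: SD of the per-subject mean echo
#'   level (default 8).
#' @param subject_thickness_sd imaging mode: SD (cm) of the per-subject
#'   thickness (default 0.08).
#' @param view imaging mode: view to render (default longitudinal).
#' @param condition imaging mode: phantom condition (default healthy).
#' @return list of class `"study_sim_params"`.
#' @export
study_sim_params <- function(n_s = 20L, n_e = 2L, n_v = 2L, n_i = 2L,
                             components = c(S = 1, SEVI = 0.2),
                             grand_mean = 10, groups = "asymptomatic",
                             evaluator_gain_sd = 0.03,
                             visit_gain_sd = 0.015,
                             roi_jitter_px = 3,
                             subject_echo_sd = 8,
                             subject_thickness_sd = 0.08,
                             view = "longitudinal",
                             condition = "healthy") {
  stopifnot(n_s >= 1, n_e >= 1, n_v >= 1, n_i >= 1,
            all(components >= 0), evaluator_gain_sd >= 0,
            visit_gain_sd >= 0, roi_jitter_px >= 0)
  full <- setNames(numeric(15), gtheory_effects())
  bad <- setdiff(names(components), names(full))
  if (length(bad)) stop("unknown effect name(s): ", paste(bad, collapse = ", "))
  full[names(components)] <- components
  structure(list(n_s = as.integer(n_s), n_e = as.integer(n_e),
                 n_v = as.integer(n_v), n_i = as.integer(n_i),
                 components = full, grand_mean = grand_mean,
                 groups = groups,
                 evaluator_gain_sd = evaluator_gain_sd,
                 visit_gain_sd = visit_gain_sd,
                 roi_jitter_px = roi_jitter_px,
                 subject_echo_sd = subject_echo_sd,
                 subject_thickness_sd = subject_thickness_sd,
                 view = view, condition = condition),
            class = "study_sim_params")
}

.expand_effect <- function(draws, dims_present, n) {
  # draws: array over the facets present in the effect; replicate to the
  # full S x E x V x I grid (long order: S fastest, then E, V, I)
  grid <- expand.grid(S = seq_len(n[1]), E = seq_len(n[2]),
                      V = seq_len(n[3]), I = seq_len(n[4]))
  if (length(dims_present) == 0L) return(rep(draws, nrow(grid)))
  idx <- as.matrix(grid[, dims_present, drop = FALSE])
  draws[idx]
}

#' Simulate a balanced feature table with known variance components
#'
#' @param params a [study_sim_params()].
#' @param mode `"linear"` (direct draws from the random model) or
#'   `"imaging"` (render a phantom per cell and extract features).
#' @param seed integer seed for full reproducibility.
#' @param feature feature to extract in imaging mode (default
#'   `"echogenicity"`); linear-mode tables are labelled with this name too.
#' @param config a [qus_config()] for imaging mode.
#' @return data.frame with columns `tendon_id`, `group`, `evaluator`,
#'   `visit`, `image`, `view`, `feature`, `value` (imaging mode: one block
#'   of rows per extracted feature), balanced and complete by
#'   construction.
#' @export
simulate_feature_study <- function(params = study_sim_params(),
                                   mode = c("linear", "imaging"),
                                   seed = NULL, feature = "echogenicity",
                                   config = qus_config()) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "linear") {
    out <- lapply(seq_along(params$groups), function(gi) {
      g <- params$groups[gi]
      gm <- if (!is.null(names(params$grand_mean)) &&
                g %in% names(params$grand_mean)) params$grand_mean[[g]]
            else params$grand_mean[[min(gi, length(params$grand_mean))]]
      tab <- .simulate_linear_group(params, gm)
      tab$group <- g
      tab$tendon_id <- sprintf("%s_t%03d", substr(g, 1, 1), tab$S)
      tab
    })
    df <- do.call(rbind, out)
    df$view <- params$view
    df$feature <- feature
    df[, c("tendon_id", "group", "S", "E", "V", "I",
           "evaluator", "visit", "image", "view", "feature", "value")]
  } else {
    .simulate_imaging(params, feature, config)
  }
}

.simulate_linear_group <- function(params, grand_mean) {
  n <- c(S = params$n_s, E = params$n_e, V = params$n_v, I = params$n_i)
  grid <- expand.grid(S = seq_len(n[1]), E = seq_len(n[2]),
                      V = seq_len(n[3]), I = seq_len(n[4]))
  value <- rep(grand_mean, nrow(grid))
  for (e in gtheory_effects()) {
    s2 <- params$components[[e]]
    fac <- strsplit(e, "")[[1]]
    if (s2 <= 0) next
    dims <- n[fac]
    draws <- array(rnorm(prod(dims), sd = sqrt(s2)), dim = dims)
    value <- value + .expand_effect(draws, fac, n)
  }
  grid$value <- value
  grid$evaluator <- grid$E; grid$visit <- grid$V; grid$image <- grid$I
  grid
}

.simulate_imaging <- function(params, feature, config) {
  n_s <- params$n_s; n_e <- params$n_e; n_v <- params$n_v; n_i <- params$n_i
  rows <- list()
  for (g in params$groups) {
    # subject-level true anatomy; evaluator and visit gains are main
    # effects (shared across subjects), the ROI placement jitter is the
    # subject x evaluator interplay (each evaluator re-places the tracing
    # differently on each tendon)
    echo0 <- rnorm(n_s, 0, params$subject_echo_sd)
    thick0 <- rnorm(n_s, 0, params$subject_thickness_sd)
    gain_e <- rnorm(n_e, 1, params$evaluator_gain_sd)
    jitter <- matrix(rnorm(n_s * n_e, 0, params$roi_jitter_px), n_s, n_e)
    gain_v <- rnorm(n_v, 1, params$visit_gain_sd)
    for (s in seq_len(n_s)) {
      base <- tendon_image_params(view = params$view,
                                  condition = params$condition)
      p <- tendon_image_params(
        view = params$view, condition = params$condition,
        thickness_cm = max(base$thickness_cm + thick0[s], 0.2),
        mean_echo = min(max(base$mean_echo + echo0[s], 20), 240))
      for (e in seq_len(n_e)) for (v in seq_len(n_v)) for (i in seq_len(n_i)) {
        sim <- simulate_tendon_image(p)      # fresh speckle each image
        img <- sim$image
        px <- pmin(pmax(round(img$pixels * gain_e[e] * gain_v[v]),
                        0L), 255L)
        img <- us_image(px, img$calibration, view = img$view, id = img$id)
        roi <- .shift_roi(sim$roi, dy = jitter[s, e], dim(img))
        fs <- extract_features(img, roi, config)
        rows[[length(rows) + 1L]] <- features_to_rows(
          fs, meta = list(tendon_id = sprintf("%s_t%03d", substr(g, 1, 1), s),
                          group = g, evaluator = e, visit = v, image = i))
      }
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(feature)) df <- df[df$feature %in% feature, , drop = FALSE]
  rownames(df) <- NULL
  df
}

.shift_roi <- function(roi, dy, dims) {
  if (dy == 0) return(roi)
  if (roi$kind == "band") {
    up <- roi$upper_edge; lo <- roi$lower_edge
    up[, 2] <- pmin(pmax(up[, 2] + dy, 0), dims[1])
    lo[, 2] <- pmin(pmax(lo[, 2] + dy, 0), dims[1])
    roi_band(up, lo, view = roi$view)
  } else {
    v <- roi$contour
    v[, 2] <- pmin(pmax(v[, 2] + dy, 0), dims[1])
    roi_contour(v, view = roi$view)
  }
}
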