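# Generalizability theory for the fully crossed S x E x V x I random model
# with one observation per cell.
#
# The G-study estimates the 15 variance components (4 main effects, 6
# two-way, 4 three-way interactions, and the four-way term which is
# confounded with residual error) by the method of moments: balanced ANOVA
# mean squares equated to their expected values (Cornfield-Tukey rule for a
# fully random crossed design) and the triangular system solved from the
# highest-order term down.  The D-study then projects the components onto
# hypothetical protocols that average over n_e' evaluators, n_v' visits and
# n_i' images.

.facets <- c("S", "E", "V", "I")

#' Canonical names of the 15 variance components
#'
#' Order: main effects S, E, V, I; two-way SE..VI; three-way SEV..EVI;
#' four-way SEVI (residual).
#' @return character vector of length 15.
#' @export
gtheory_effects <- function() {
  subs <- .effect_subsets()
  vapply(subs, paste, collapse = "", character(1))
}

.effect_subsets <- function() {
  subs <- list()
  for (k in 1:4) {
    cmb <- utils::combn(.facets, k, simplify = FALSE)
    subs <- c(subs, cmb)
  }
  # combn on c(S,E,V,I) already yields the canonical order
  subs
}

.canon_table <- function(table, value_col = "value") {
  df <- as.data.frame(table)
  alias <- c(S = "tendon_id", E = "evaluator", V = "visit", I = "image")
  for (f in .facets) {
    if (!f %in% names(df)) {
      if (alias[[f]] %in% names(df)) df[[f]] <- df[[alias[[f]]]]
      else stop("measurement table lacks facet column ", f,
                " (or ", alias[[f]], ")")
    }
  }
  if (!value_col %in% names(df)) stop("no '", value_col, "' column")
  if ("undefined_flag" %in% names(df) && any(df$undefined_flag)) {
    stop("table contains undefined-flagged values; drop that feature/group ",
         "analysis instead of estimating from it")
  }
  if (anyNA(df[[value_col]])) stop("missing values in measurement table")
  df
}

#' Estimate G-study variance components
#'
#' Method-of-moments (expected-mean-squares) estimation for the balanced,
#' fully crossed, all-random S x E x V x I design with one observation per
#' cell.  The four-way component SEVI is the residual: it absorbs the
#' highest-order mean square and cannot be separated from measurement
#' error.
#'
#' Facets with a single level in the data yield structurally zero
#' components for every effect they take part in (their degrees of freedom
#' are zero); at least 2 subjects are required.
#'
#' @param table data.frame with facet columns `S`, `E`, `V`, `I` (or
#'   `tendon_id`, `evaluator`, `visit`, `image`) and a value column; must
#'   be balanced and complete (every cell exactly once) and contain no
#'   undefined-flagged values.
#' @param value_col name of the value column (default `"value"`).
#' @return Object of class `"variance_components"`: list with `raw`
#'   (possibly negative estimates), `clamped` (`pmax(raw, 0)`), `n` (facet
#'   sizes), `mean_squares`, `df`, `grand_mean`.
#' @export
estimate_variance_components <- function(table, value_col = "value") {
  df <- .canon_table(table, value_col)
  lev <- lapply(.facets, function(f) sort(unique(df[[f]])))
  names(lev) <- .facets
  n <- vapply(lev, length, integer(1))
  if (n["S"] < 2L) stop("at least 2 subjects are required")
  if (nrow(df) != prod(n)) {
    stop("unbalanced design: expected ", prod(n), " cells, got ", nrow(df))
  }
  idx <- lapply(.facets, function(f) match(df[[f]], lev[[f]]))
  cell <- ((idx[[1]] - 1L) +
             n["S"] * ((idx[[2]] - 1L) +
                         n["E"] * ((idx[[3]] - 1L) + n["V"] * (idx[[4]] - 1L)))) + 1L
  if (anyDuplicated(cell)) stop("duplicated cells in measurement table")
  y <- array(NA_real_, dim = n)
  y[cell] <- df[[value_col]]

  subs <- .effect_subsets()
  eff <- vapply(subs, paste, collapse = "", character(1))
  N <- prod(n)
  gmean <- mean(y)

  # uncorrected sums of squared marginal means, scaled to observation count
  t_of <- function(f) {
    if (length(f) == 0L) return(N * gmean^2)
    dims <- match(f, .facets)
    marg <- apply(y, dims, mean)
    prod(n[setdiff(.facets, f)]) * sum(marg^2)
  }
  all_subs <- c(list(character(0)), subs)
  tvals <- setNames(vapply(all_subs, t_of, numeric(1)),
                    c("0", eff))

  ss <- df_ <- setNames(numeric(15), eff)
  for (k in seq_along(subs)) {
    f <- subs[[k]]
    tot <- 0
    for (g in all_subs) {
      if (all(g %in% f)) {
        tot <- tot + (-1)^(length(f) - length(g)) *
          tvals[[if (length(g)) paste(g, collapse = "") else "0"]]
      }
    }
    ss[k] <- tot
    df_[k] <- prod(n[f] - 1L)
  }
  ms <- ifelse(df_ > 0, ss / df_, NA_real_)

  # EMS coefficient of sigma^2_g in EMS(f), g containing f: prod of sizes of
  # facets absent from g.  Solve from the four-way term down.
  raw <- setNames(numeric(15), eff)
  ord <- order(vapply(subs, length, integer(1)), decreasing = TRUE)
  for (k in ord) {
    f <- subs[[k]]
    if (df_[k] == 0) { raw[k] <- 0; next }   # structurally zero
    contrib <- 0
    for (m in seq_along(subs)) {
      g <- subs[[m]]
      if (length(g) > length(f) && all(f %in% g) && df_[m] > 0) {
        contrib <- contrib + prod(n[setdiff(.facets, g)]) * raw[m]
      }
    }
    raw[k] <- (ms[k] - contrib) / prod(n[setdiff(.facets, f)])
  }
  structure(list(raw = raw, clamped = pmax(raw, 0), n = n,
                 mean_squares = ms, df = df_, grand_mean = gmean),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> design %s\n",
              paste(sprintf("%s=%d", .facets, x$n), collapse = " ")))
  print(round(rbind(raw = x$raw, clamped = x$clamped), 6))
  invisible(x)
}

#' Variance components as percentages of total
#'
#' Each zero-clamped component divided by the sum of all clamped
#' components, times 100.
#'
#' @param vc a [estimate_variance_components()] result.
#' @return named numeric vector of 15 percentages summing to 100.
#' @export
variance_proportions <- function(vc) {
  tot <- sum(vc$clamped)
  if (tot <= 0) stop("all variance components are zero")
  100 * vc$clamped / tot
}

#' Dependability of a measurement protocol (D-study)
#'
#' Projects the G-study components onto a protocol that averages the
#' measurements of `n_e` evaluators, `n_v` visits and `n_i` images.  The
#' absolute error variance divides each non-subject component by the
#' number of averaged levels of the facets it involves, e.g.
#' `sigma2_SEI / (n_e * n_i)`; the dependability coefficient is
#' `Phi = sigma2_S / (sigma2_S + sigma2_abs)` and the standard error of
#' measurement is `SEM = sqrt(sigma2_abs)`.
#'
#' The relative (norm-referenced) error variance — only the interactions
#' involving the subject — and the corresponding generalizability
#' coefficient are reported alongside, since the two can differ
#' appreciably when evaluator or visit main effects are large.
#'
#' @param vc a [estimate_variance_components()] result (or a named
#'   15-vector of non-negative components).
#' @param n_e,n_v,n_i protocol sizes (>= 1).
#' @param group_mean mean used to normalize the minimal detectable change;
#'   `NULL` to skip MDC.
#' @param z confidence multiplier for the MDC (default 1.65, i.e. 90%).
#' @return Object of class `"dstudy_result"`: list with `phi`, `sem`,
#'   `error_variance`, `rel_coefficient`, `rel_error_variance`,
#'   `mdc_abs`, `mdc_norm`, `label`, protocol sizes, `group_mean`, `z`.
#' @export
dstudy <- function(vc, n_e = 1L, n_v = 1L, n_i = 1L,
                   group_mean = NULL, z = 1.65) {
  comp <- if (inherits(vc, "variance_components")) vc$clamped else vc
  eff <- gtheory_effects()
  if (is.null(names(comp)) || !all(eff %in% names(comp))) {
    stop("components must be named with the 15 canonical effects")
  }
  comp <- pmax(comp[eff], 0)
  if (any(c(n_e, n_v, n_i) < 1)) stop("protocol sizes must be >= 1")
  sizes <- c(E = n_e, V = n_v, I = n_i)
  divisor <- function(e) {
    fac <- strsplit(e, "")[[1]]
    prod(sizes[intersect(fac, names(sizes))])
  }
  err_abs <- sum(vapply(setdiff(eff, "S"),
                        function(e) comp[[e]] / divisor(e), numeric(1)))
  rel_eff <- setdiff(eff[grepl("S", eff)], "S")
  err_rel <- sum(vapply(rel_eff,
                        function(e) comp[[e]] / divisor(e), numeric(1)))
  if (comp[["S"]] + err_abs <= 0) stop("Phi undefined: no variance at all")
  phi <- comp[["S"]] / (comp[["S"]] + err_abs)
  rho <- if (comp[["S"]] + err_rel > 0) comp[["S"]] / (comp[["S"]] + err_rel)
         else NA_real_
  sem <- sqrt(err_abs)
  res <- list(n_e = n_e, n_v = n_v, n_i = n_i, phi = phi, sem = sem,
              error_variance = err_abs, rel_coefficient = rho,
              rel_error_variance = err_rel, label = phi_label(phi),
              group_mean = group_mean, z = z,
              mdc_abs = NA_real_, mdc_norm = NA_real_)
  if (!is.null(group_mean)) {
    m <- mdc(sem, group_mean, z = z)
    res$mdc_abs <- m[["mdc_abs"]]
    res$mdc_norm <- m[["mdc_norm"]]
  }
  structure(res, class = "dstudy_result")
}

#' @export
print.dstudy_result <- function(x, ...) {
  cat(sprintf("<dstudy> E=%d V=%d I=%d  Phi=%.3f (%s)  SEM=%.4g",
              x$n_e, x$n_v, x$n_i, x$phi, x$label, x$sem))
  if (!is.na(x$mdc_norm)) cat(sprintf("  MDC90=%.4g (%.2f%%)", x$mdc_abs, x$mdc_norm))
  cat("\n")
  invisible(x)
}

#' Minimal detectable change
#'
#' `MDC_abs = z * sqrt(2) * SEM`; `MDC_norm = 100 * MDC_abs / group_mean`.
#'
#' @param sem standard error of measurement (>= 0).
#' @param group_mean the group average used for normalization (non-zero).
#' @param z confidence multiplier (default 1.65 for 90% confidence).
#' @return named vector `c(mdc_abs = , mdc_norm = )`; `mdc_norm` in percent.
#' @export
mdc <- function(sem, group_mean, z = 1.65) {
  if (sem < 0) stop("sem must be >= 0")
  if (group_mean == 0) stop("group_mean must be non-zero")
  abs_ <- z * sqrt(2) * sem
  c(mdc_abs = abs_, mdc_norm = 100 * abs_ / group_mean)
}

#' Verbal interpretation of a dependability coefficient
#'
#' poor `< 0.50`; moderate `[0.50, 0.75)`; good `[0.75, 0.90)`; excellent
#' `>= 0.90`.
#'
#' @param phi numeric vector of coefficients in `[0, 1]`.
#' @return character vector of labels.
#' @export
phi_label <- function(phi) {
  cut(phi, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf),
      labels = c("poor", "moderate", "good", "excellent"),
      right = FALSE) |> as.character()
}

#' D-study grid over the standard single-evaluator protocols
#'
#' One [dstudy()] per protocol, default the six single-evaluator designs
#' `V in {1, 2}` crossed with `I in {1, 2, 3}`, ordered I within V.
#'
#' @param vc a [estimate_variance_components()] result or named 15-vector.
#' @param group_mean mean for MDC normalization (optional).
#' @param n_e evaluators per protocol (default 1).
#' @param visits,images protocol levels (defaults `1:2` and `1:3`).
#' @param z confidence multiplier (default 1.65).
#' @return data.frame with one row per protocol: `n_e`, `n_v`, `n_i`,
#'   `phi`, `label`, `sem`, `mdc_abs`, `mdc_norm`, `rel_coefficient`.
#' @export
protocol_grid <- function(vc, group_mean = NULL, n_e = 1L,
                          visits = 1:2, images = 1:3, z = 1.65) {
  rows <- list()
  for (v in visits) for (i in images) {
    d <- dstudy(vc, n_e = n_e, n_v = v, n_i = i,
                group_mean = group_mean, z = z)
    rows[[length(rows) + 1L]] <-
      data.frame(n_e = n_e, n_v = v, n_i = i, phi = d$phi, label = d$label,
                 sem = d$sem, mdc_abs = d$mdc_abs, mdc_norm = d$mdc_norm,
                 rel_coefficient = d$rel_coefficient,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
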