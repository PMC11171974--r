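#' Spatial fraction of area-level variation
#'
#' The share of area-level variation attributable to spatial structure:
#' `phi = var(u) / (var(u) + var(v))`.  Given draw matrices, the empirical
#' across-area variance (`J - 1` denominator) is computed per draw and
#' `var(u)`, `var(v)` are its posterior means; given scalars they are used
#' directly.
#'
#' @param u draws-by-areas matrix of structured effects, or scalar `var(u)`.
#' @param v draws-by-areas matrix of heterogeneity effects, or scalar
#'   `var(v)`.
#' @return list of class `spatial_fraction` with `var_u`, `var_v`, `phi`.
#' @examples
#' phi_statistic(0.807, 0.223)   # 0.78
#' @export
phi_statistic <- function(u, v) {
  draw_var <- function(x) {
    if (is.matrix(x)) {
      stopifnot(ncol(x) >= 2L)
      mean(apply(x, 1L, stats::var))
    } else {
      stopifnot(length(x) == 1L, x >= 0)
      as.numeric(x)
    }
  }
  if (is.matrix(u) && is.matrix(v) &&
      (nrow(u) != nrow(v) || ncol(u) != ncol(v)))
    stop("u and v draw matrices must be aligned")
  var_u <- draw_var(u); var_v <- draw_var(v)
  if (var_u + var_v <= 0) stop("total area-level variance is zero")
  structure(list(var_u = var_u, var_v = var_v,
                 phi = var_u / (var_u + var_v)),
            class = "spatial_fraction")
}

#' @export
print.spatial_fraction <- function(x, ...) {
  cat(sprintf("var(u) = %.3f, var(v) = %.3f, spatial fraction = %.2f\n",
              x$var_u, x$var_v, x$phi))
  invisible(x)
}

#' Observed/expected relative-risk table by area and year
#'
#' For each area-year cell: the observed poor-outcome count `O`, the
#' expected count `E = n_cell * pooled prevalence`, and `RR = O / E`.  By
#' construction the table is globally calibrated: `sum(O) = sum(E)`.
#' Cells with no patients are omitted.
#'
#' @param records data.frame with area, year and binary outcome columns.
#' @param area_field,year_field,outcome_field column names.
#' @return data.frame: area_id, year, n_patients, observed, expected, rr.
#' @export
rr_table <- function(records, area_field = "area_id", year_field = "year",
                     outcome_field = "poor_qol") {
  stopifnot(all(c(area_field, year_field, outcome_field) %in% names(records)))
  y <- as.integer(records[[outcome_field]])
  prev <- mean(y)
  if (prev == 0) stop("overall prevalence is zero; relative risks undefined")
  key <- interaction(records[[area_field]], records[[year_field]], drop = TRUE)
  n_cell <- tapply(y, key, length)
  o_cell <- tapply(y, key, sum)
  parts <- strsplit(names(n_cell), ".", fixed = TRUE)
  out <- data.frame(
    area_id = vapply(parts, function(p) paste(p[-length(p)], collapse = "."), ""),
    year = vapply(parts, function(p) p[length(p)], ""),
    n_patients = as.integer(n_cell),
    observed = as.integer(o_cell),
    stringsAsFactors = FALSE, row.names = NULL)
  out$expected <- out$n_patients * prev
  out$rr <- out$observed / out$expected
  out[order(out$area_id, out$year), , drop = FALSE]
}

#' Percent coefficient change between two weight-matrix fits
#'
#' Sensitivity of the posterior mean log-odds coefficients to the choice of
#' spatial weight matrix: per coefficient,
#' `100 * |m_dist - m_adj| / |m_adj|`.  A near-zero adjacency-based
#' coefficient makes the ratio undefined; such terms are flagged (`NA`)
#' rather than erroring, and a sign flip between the fits triggers a
#' warning.
#'
#' @param summary_adjacency,summary_distance data.frames from
#'   [posterior_summaries()] covering the same terms.
#' @return data.frame: term, mean_adjacency, mean_distance, or_adjacency,
#'   or_distance, pct_change, undefined.
#' @export
coefficient_percent_change <- function(summary_adjacency, summary_distance) {
  a <- summary_adjacency; d <- summary_distance
  if (!setequal(a$term, d$term))
    stop("the two summaries must cover the same coefficient set")
  d <- d[match(a$term, d$term), ]
  undefined <- abs(a$mean) < 1e-12
  pct <- ifelse(undefined, NA_real_, 100 * abs(d$mean - a$mean) / abs(a$mean))
  flipped <- !undefined & sign(a$mean) * sign(d$mean) < 0
  if (any(flipped))
    warning("coefficient sign flip between weight matrices: ",
            paste(a$term[flipped], collapse = ", "))
  data.frame(term = a$term,
             mean_adjacency = a$mean, mean_distance = d$mean,
             or_adjacency = exp(a$mean), or_distance = exp(d$mean),
             pct_change = pct, undefined = undefined,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Prevalence crosstab with chi-square test
#'
#' Counts and row percentages of the binary outcome by the levels of one
#' categorical covariate, with the Pearson chi-square statistic (no
#' continuity correction) and its degrees of freedom.
#'
#' @param records patient data.frame.
#' @param covariate name of the categorical column.
#' @param outcome_field name of the binary outcome column.
#' @param levels optional explicit level order.
#' @return list: `table` (level, poor, good, total, poor_pct, good_pct),
#'   `statistic`, `df`, `p_value`.
#' @export
crosstab_prevalence <- function(records, covariate, outcome_field = "poor_qol",
                                levels = NULL) {
  stopifnot(all(c(covariate, outcome_field) %in% names(records)))
  x <- as.character(records[[covariate]])
  if (is.null(levels)) levels <- unique(x)
  if (!all(x %in% levels)) stop("values outside the declared levels")
  y <- as.integer(records[[outcome_field]])
  poor <- vapply(levels, function(l) sum(y[x == l] == 1L), 0L)
  good <- vapply(levels, function(l) sum(y[x == l] == 0L), 0L)
  tab <- data.frame(level = levels, poor = poor, good = good,
                    total = poor + good, stringsAsFactors = FALSE,
                    row.names = NULL)
  tab$poor_pct <- 100 * tab$poor / tab$total
  tab$good_pct <- 100 * tab$good / tab$total
  m <- cbind(tab$poor, tab$good)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin in the crosstab; chi-square undefined")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(table = tab, statistic = unname(ct$statistic),
       df = unname(ct$parameter), p_value = unname(ct$p.value))
}

#' Published descriptive crosstab counts
#'
#' Poor/good outcome counts by covariate level as published in the
#' descriptive tables of the study the package emulates (transcribed
#' fixture).  Useful for exercising [crosstab_prevalence()] on real
#' registry margins without access to patient-level data.
#'
#' @return data.frame with columns variable, level, poor, good.
#' @export
study_crosstab_counts <- function() {
  path <- system.file("extdata", "qol_crosstab_counts.csv",
                      package = "bymlogit", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Expand aggregated outcome counts to patient-level records
#'
#' @param counts data.frame with columns level, poor, good (one covariate).
#' @param covariate name to give the covariate column.
#' @return data.frame with one row per patient (`poor_qol`, covariate).
#' @export
counts_to_records <- function(counts, covariate = "level") {
  out <- data.frame(
    level = rep(counts$level, counts$poor + counts$good),
    poor_qol = unlist(lapply(seq_len(nrow(counts)), function(i)
      rep(c(1L, 0L), c(counts$poor[i], counts$good[i])))),
    stringsAsFactors = FALSE)
  names(out)[1] <- covariate
  out
}
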