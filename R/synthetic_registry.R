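#' Default covariate frequency table
#'
#' Marginal category frequencies used by the synthetic registry generator,
#' shipped as a plain-text fixture mirroring the descriptive statistics of
#' the study population the package emulates (e.g. 40.3% of patients aged
#' 56--65, 77.5% with PSA <= 10, 70.6% treated in metropolitan hospitals).
#'
#' @return named list: `individual` and `area` are named lists of named
#'   probability vectors; `year` is a named probability vector.
#' @export
default_covariate_freqs <- function() {
  path <- system.file("extdata", "covariate_frequencies.csv",
                      package = "bymlogit", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  split_scope <- function(scope) {
    sub <- df[df$scope == scope, ]
    out <- lapply(split(sub, sub$covariate), function(s)
      stats::setNames(s$prob, s$level))
    out[unique(sub$covariate)]
  }
  list(individual = split_scope("individual"),
       area = split_scope("area"),
       year = stats::setNames(df$prob[df$scope == "year"],
                              df$level[df$scope == "year"]))
}

#' Default ground-truth effects for the generator
#'
#' Log odds ratios per non-reference covariate level, matching the adjusted
#' odds ratios the emulated study reports for its distance-band model
#' (e.g. public institution OR 1.35, age 76--85 OR 2.90, highly accessible
#' OR 0.60); covariates outside that model get null effects.
#'
#' @return named list of named numeric vectors (log-odds scale).
#' @export
default_true_beta <- function() {
  list(
    age_group = c("56-65" = log(1.08), "66-75" = log(1.70),
                  "76-85" = log(2.90)),
    nccn = c("Intermediate risk" = log(0.68), "High risk" = log(0.97),
             "Very high risk/Metastatic" = log(1.22)),
    psa = c("10.1-20.0" = log(1.33), ">20" = log(0.87)),
    institution = c("Public" = log(1.35)),
    remoteness = c("Moderately accessible" = log(0.53),
                   "Highly accessible" = log(0.60)))
}

#' Simulation configuration
#'
#' Bundles everything the synthetic registry generator needs: lattice
#' dimensions (8 x 10 unit cells by default, matching the 80 areal units of
#' the emulated registry), cohort size, calendar years, covariate
#' frequencies, ground-truth regression effects, the quadratic time trend
#' and the BYM precision parameters.
#'
#' @param n_rows,n_cols lattice dimensions; areas = `n_rows * n_cols`.
#' @param cell_km lattice cell size in km.
#' @param n_patients cohort size.
#' @param years inclusive calendar-year range of surgery.
#' @param covariate_freqs as returned by [default_covariate_freqs()].
#' @param true_alpha intercept on the log-odds scale.  The default is
#'   calibrated so that, with the default effects and frequencies and no
#'   area/time contribution, overall prevalence of the poor outcome is near
#'   36.4%.
#' @param true_beta named list of per-level log odds ratios.
#' @param true_delta1,true_delta2 linear and quadratic coefficients of the
#'   centred year index.
#' @param tau_u,tau_v precisions of the structured (ICAR) and unstructured
#'   area effects.
#' @param area_probs optional area assignment probabilities (uniform if
#'   `NULL`).
#' @param seed integer seed governing the whole simulation.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_rows = 8L, n_cols = 10L, cell_km = 20,
                       n_patients = 5238L, years = 2015:2021,
                       covariate_freqs = default_covariate_freqs(),
                       true_alpha = -0.306,
                       true_beta = default_true_beta(),
                       true_delta1 = 0.06, true_delta2 = -0.02,
                       tau_u = 2, tau_v = 4,
                       area_probs = NULL, seed = 1L) {
  stopifnot(n_rows >= 1L, n_cols >= 1L, n_patients >= 1L,
            length(years) >= 1L, tau_u > 0, tau_v > 0)
  for (grp in c("individual", "area")) {
    for (cv in names(covariate_freqs[[grp]])) {
      p <- covariate_freqs[[grp]][[cv]]
      if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
        stop("probabilities for '", cv, "' must be nonnegative and sum to 1")
    }
  }
  if (abs(sum(covariate_freqs$year) - 1) > 1e-6)
    stop("year probabilities must sum to 1")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_km = cell_km, n_patients = as.integer(n_patients),
                 years = as.integer(years), covariate_freqs = covariate_freqs,
                 true_alpha = true_alpha, true_beta = true_beta,
                 true_delta1 = true_delta1, true_delta2 = true_delta2,
                 tau_u = tau_u, tau_v = tau_v, area_probs = area_probs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Build a rectangular lattice of square areas
#'
#' Stands in for a real areal geography: `n_rows * n_cols` square cells of
#' side `cell_km`, with centroids at cell centres.  The 8 x 10 default gives
#' 80 areas.
#'
#' @param n_rows,n_cols lattice dimensions.
#' @param cell_km cell side length in km.
#' @return list of [area_geometry()] objects with ids `"a001"`, `"a002"`, ...
#'   in row-major order.
#' @export
make_lattice <- function(n_rows, n_cols, cell_km = 1) {
  if (n_rows < 1L || n_cols < 1L || cell_km <= 0)
    stop("lattice dimensions and cell size must be positive")
  areas <- vector("list", n_rows * n_cols)
  idx <- 0L
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      idx <- idx + 1L
      x0 <- (c - 1L) * cell_km; y0 <- (r - 1L) * cell_km
      ring <- rbind(c(x0, y0), c(x0 + cell_km, y0),
                    c(x0 + cell_km, y0 + cell_km), c(x0, y0 + cell_km),
                    c(x0, y0))
      areas[[idx]] <- area_geometry(sprintf("a%03d", idx), list(ring))
    }
  }
  areas
}

#' Simulate BYM area effects
#'
#' Draws the spatially structured effect `u` from the intrinsic CAR
#' distribution with precision `tau_u`, exactly on its proper subspace: the
#' graph Laplacian `L = D - W` is spectrally decomposed, the null direction
#' (constant vector) is excluded, and `u = sum_k e_k z_k / sqrt(tau_u
#' lambda_k)`, which enforces `sum(u) = 0`.  The heterogeneity effect `v` is
#' iid Normal(0, 1/tau_v).
#'
#' @param W a connected `weight_matrix`.
#' @param tau_u,tau_v positive precisions.
#' @param seed optional integer seed.
#' @return list with numeric vectors `u` and `v` (named by area id).
#' @export
simulate_area_effects <- function(W, tau_u, tau_v, seed = NULL) {
  stopifnot(inherits(W, "weight_matrix"), tau_u > 0, tau_v > 0)
  comp <- connected_components(W)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop("weight matrix is disconnected (", max(comp), " components of sizes ",
         paste(sizes, collapse = ", "), "); the ICAR draw requires a single ",
         "component. Smallest component: ",
         paste(W$ids[comp == which.min(sizes)], collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  Wm <- as_dense_matrix(W)
  L <- diag(rowSums(Wm)) - Wm
  eg <- eigen(L, symmetric = TRUE)
  keep <- seq_len(W$n - 1L)        # drop the zero eigenvalue (constant vector)
  lambda <- eg$values[keep]
  z <- stats::rnorm(W$n - 1L)
  u <- as.numeric(eg$vectors[, keep, drop = FALSE] %*%
                    (z / sqrt(tau_u * lambda)))
  u <- u - mean(u)                 # exact numerical sum-to-zero
  v <- stats::rnorm(W$n, 0, 1 / sqrt(tau_v))
  list(u = stats::setNames(u, W$ids), v = stats::setNames(v, W$ids))
}

sample_levels <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Centred year index
#'
#' @param year integer years.
#' @param years the full inclusive year range of the study.
#' @return numeric vector `year - midpoint(range)`.
#' @export
centred_year <- function(year, years = sort(unique(year))) {
  year - mean(range(years))
}

#' Simulate a synthetic patient registry
#'
#' Samples individual covariates independently from the configured
#' frequencies, assigns each area a socio-economic quartile and remoteness
#' category, allocates patients to areas, and draws the binary poor-QoL
#' outcome from the logistic model
#' `logit P(y=1) = alpha + x'beta + delta1 t + delta2 t^2 + u_j + v_j`
#' with `t` the centred year index.
#'
#' @param config a [sim_config()].
#' @param areas list of [area_geometry()]; defaults to the config lattice.
#' @param u,v area effect vectors aligned with `areas`.
#' @return data.frame of patient records with attribute `"truth"` echoing
#'   the generating parameters.
#' @export
simulate_patients <- function(config, areas, u, v) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  J <- length(areas)
  if (length(u) != J || length(v) != J)
    stop("u and v must align with areas")
  fr <- config$covariate_freqs
  ids <- area_ids(areas)

  rec <- data.frame(patient_id = sprintf("p%06d", seq_len(n)),
                    stringsAsFactors = FALSE)
  ap <- config$area_probs
  if (is.null(ap)) ap <- rep(1 / J, J)
  if (length(ap) != J || any(ap < 0) || abs(sum(ap) - 1) > 1e-6)
    stop("area_probs must be a probability vector over the areas")
  aidx <- sample.int(J, n, replace = TRUE, prob = ap)
  rec$area_id <- ids[aidx]
  rec$year <- as.integer(sample_levels(n, fr$year))

  for (cv in names(fr$individual)) rec[[cv]] <- sample_levels(n, fr$individual[[cv]])
  # area-level covariates: one category per area, inherited by its patients
  area_cov <- lapply(fr$area, function(p) sample_levels(J, p))
  for (cv in names(area_cov)) rec[[cv]] <- area_cov[[cv]][aidx]

  tt <- centred_year(rec$year, config$years)
  eta <- config$true_alpha + config$true_delta1 * tt +
    config$true_delta2 * tt^2 + u[aidx] + v[aidx]
  for (cv in names(config$true_beta)) {
    if (!cv %in% names(rec)) stop("true_beta names unknown covariate '", cv, "'")
    b <- config$true_beta[[cv]]
    eta <- eta + ifelse(rec[[cv]] %in% names(b),
                        b[match(rec[[cv]], names(b))], 0)
  }
  rec$poor_qol <- stats::rbinom(n, 1L, stats::plogis(eta))
  attr(rec, "truth") <- list(alpha = config$true_alpha,
                             beta = config$true_beta,
                             delta1 = config$true_delta1,
                             delta2 = config$true_delta2,
                             tau_u = config$tau_u, tau_v = config$tau_v,
                             u = u, v = v)
  rec
}

#' One-call synthetic registry
#'
#' Convenience wrapper: builds the lattice, both the queen weight matrix (to
#' draw the ICAR effect the config asks for, unless a matrix is supplied),
#' the area effects, and the patient table, all under `config$seed`.
#'
#' @param config a [sim_config()].
#' @param W optional `weight_matrix` defining the spatial structure the
#'   truth is drawn from; defaults to queen contiguity on the lattice.
#' @return list with `areas`, `W`, `effects` (u, v) and `patients`.
#' @export
simulate_registry <- function(config = sim_config(), W = NULL) {
  areas <- make_lattice(config$n_rows, config$n_cols, config$cell_km)
  if (is.null(W)) W <- queen_contiguity(areas)
  set.seed(config$seed)
  eff <- simulate_area_effects(W, config$tau_u, config$tau_v)
  patients <- simulate_patients(config, areas, eff$u, eff$v)
  list(areas = areas, W = W, effects = eff, patients = patients)
}

#' Simulate EPIC-26-style domain scores consistent with an outcome label
#'
#' Attaches five bounded domain scores to each record such that re-running
#' the scoring pipeline (cohort quartiles, composite, median split)
#' reproduces the record's `poor_qol` label with high probability.
#'
#' Quartile binning fixes the mass of every bin at one quarter of the
#' cohort, so with poor prevalence near 36% a naive two-cluster score model
#' cannot keep the median split faithful: the lowest-scoring "good" patients
#' inevitably fall below the composite median.  The generator therefore
#' builds the scores from narrow score bands with a deliberate per-patient
#' band composition: poor patients draw five independent very-low scores
#' (composite well below the median); good patients come in two profiles,
#' one with a single weaker domain (composite 16) and one with two weaker
#' domains drawn from a lower sub-band (an atom at composite 15 that anchors
#' the cohort median), with a "flex" band absorbing quartile-boundary
#' spillover so misclassification is confined to Gaussian band tails.
#'
#' @param records data.frame carrying `poor_qol`.
#' @param seed optional integer seed.
#' @return `records` with the five domain score columns appended.
#' @export
simulate_domain_scores <- function(records, seed = NULL) {
  stopifnot(is.data.frame(records), "poor_qol" %in% names(records))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  poor <- records$poor_qol == 1L
  domain_cols <- c("urinary_incontinence", "urinary_irritative",
                   "bowel", "sexual", "hormonal")
  band <- function(m, mu, sd) 100 * stats::plogis(stats::rnorm(m, mu, sd))
  sc <- matrix(0, n, 5L)
  for (d in 1:5) sc[poor, d] <- band(sum(poor), -2.2, 0.55)
  g <- which(!poor)
  two_weak <- stats::runif(length(g)) < 0.3
  for (k in seq_along(g)) {
    i <- g[k]
    perm <- sample.int(5L)
    if (two_weak[k]) {          # two weak domains (lower sub-band), atom at 15
      sc[i, perm[1:2]] <- band(2L, -0.45, 0.12)
      sc[i, perm[3L]] <- band(1L, 0.90, 0.18)
      sc[i, perm[4:5]] <- band(2L, 2.80, 0.35)
    } else {                    # one weak domain, composite 16
      sc[i, perm[1L]] <- band(1L, 0.05, 0.12)
      sc[i, perm[2:3]] <- band(2L, 0.90, 0.18)
      sc[i, perm[4L]] <- band(1L, 1.80, 0.15)
      sc[i, perm[5L]] <- band(1L, 2.80, 0.35)
    }
  }
  for (d in 1:5) records[[domain_cols[d]]] <- pmin(100, pmax(0, sc[, d]))
  records
}
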