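#' Model specification
#'
#' Declares the categorical covariates of the multilevel logistic model with
#' their level sets; the first level of each is the reference and gets no
#' coefficient.  `include_time` adds the centred year index and its square
#' as fixed effects.
#'
#' @param covariates named list; each element is a character vector of
#'   levels, reference first.
#' @param include_time include `t + t^2` temporal terms?
#' @param area_field,year_field column bindings in the patient table.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(covariates = default_model_covariates(),
                       include_time = TRUE,
                       area_field = "area_id", year_field = "year") {
  stopifnot(is.list(covariates))
  for (cv in names(covariates))
    if (length(covariates[[cv]]) < 2L)
      stop("covariate '", cv, "' needs at least two levels")
  structure(list(covariates = covariates, include_time = include_time,
                 area_field = area_field, year_field = year_field),
            class = "model_spec")
}

#' Default covariate set of the full model
#'
#' The five covariates retained by the emulated study's sequential WAIC
#' selection: age group, NCCN risk group, PSA category, treating institution
#' and remoteness (accessibility), with their conventional reference levels.
#'
#' @return named list of level vectors, reference level first.
#' @export
default_model_covariates <- function() {
  list(age_group = c("<=55", "56-65", "66-75", "76-85"),
       nccn = c("Low risk", "Intermediate risk", "High risk",
                "Very high risk/Metastatic"),
       psa = c("<=10", "10.1-20.0", ">20"),
       institution = c("Private", "Public"),
       remoteness = c("Accessible", "Moderately accessible",
                      "Highly accessible"))
}

#' Coefficient prior and precision hyperpriors
#'
#' Fixed-effect coefficients get independent Normal(0, `coef_precision`)
#' priors on the log-odds scale; the default precision 0.725 places 95%
#' prior mass of each odds ratio inside (0.1, 10).  The intercept gets a
#' weakly informative Normal(0, `intercept_precision`).  The ICAR and
#' heterogeneity precisions get Gamma(shape, rate) hyperpriors.
#'
#' @param coef_precision prior precision of the slope coefficients.
#' @param intercept_precision prior precision of the intercept.
#' @param tau_u_prior,tau_v_prior length-2 `c(shape, rate)` Gamma
#'   hyperparameters.
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(coef_precision = 0.725,
                       intercept_precision = 0.01,
                       tau_u_prior = c(0.5, 0.0005),
                       tau_v_prior = c(0.5, 0.0005)) {
  stopifnot(coef_precision > 0, intercept_precision > 0,
            all(tau_u_prior > 0), all(tau_v_prior > 0))
  structure(list(coef_precision = coef_precision,
                 intercept_precision = intercept_precision,
                 tau_u_prior = tau_u_prior, tau_v_prior = tau_v_prior),
            class = "prior_spec")
}

#' Normal precision putting a given prior mass on an odds-ratio interval
#'
#' Solves for the precision of a mean-zero Normal prior on a log odds ratio
#' such that the central `mass` of the implied odds ratio lies in
#' `(lower, upper)`; the interval must be symmetric on the log scale.  With
#' the defaults this reproduces the conventional 0.725.
#'
#' @param lower,upper odds-ratio interval bounds.
#' @param mass central prior mass.
#' @return precision (1/variance) on the log-odds scale.
#' @export
or_interval_precision <- function(lower = 0.1, upper = 10, mass = 0.95) {
  stopifnot(lower > 0, upper > lower, mass > 0, mass < 1)
  if (abs(log(lower) + log(upper)) > 1e-8)
    stop("interval must be symmetric about 1 on the log scale")
  z <- stats::qnorm(1 - (1 - mass) / 2)
  (z / log(upper))^2
}

#' MCMC run configuration
#'
#' @param n_iter total iterations per chain.
#' @param burn_in discarded warm-up iterations; proposal-step adaptation
#'   stops here.
#' @param thin retain every `thin`-th post-burn-in draw.
#' @param n_chains number of independent chains.
#' @param seeds one integer seed per chain (distinct).
#' @param target_accept target acceptance rate of the adaptive random-walk
#'   blocks.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 100000L, burn_in = 50000L, thin = 2L,
                        n_chains = 2L, seeds = NULL, target_accept = 0.35) {
  stopifnot(burn_in < n_iter, thin >= 1L, n_chains >= 1L,
            target_accept > 0, target_accept < 1)
  if (is.null(seeds)) seeds <- seq_len(n_chains)
  if (length(seeds) != n_chains || anyDuplicated(seeds))
    stop("'seeds' must provide one distinct seed per chain")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seeds = as.integer(seeds), target_accept = target_accept),
            class = "mcmc_config")
}

#' Build the design of the multilevel logistic model
#'
#' Dummy-encodes the declared covariates against their reference levels and
#' centres the year index at the midpoint of the year range.
#'
#' @param records patient data.frame.
#' @param spec a [model_spec()].
#' @param W optional `weight_matrix`; if given, area ids are mapped into it
#'   (unknown areas are an error).
#' @param years year range used for centring; defaults to the range present.
#' @return list: `y` (binary outcome), `X` (design matrix, no intercept
#'   column), `area` (1-based index into `W$ids` or the sorted area ids),
#'   `t` (centred year), `n`, `p`, `J`, `terms` (column names).
#' @export
build_design <- function(records, spec = model_spec(), W = NULL,
                         years = NULL) {
  stopifnot(is.data.frame(records), inherits(spec, "model_spec"))
  if (!"poor_qol" %in% names(records))
    stop("records must carry the binary outcome column 'poor_qol'")
  y <- as.integer(records$poor_qol)
  if (any(!y %in% 0:1)) stop("poor_qol must be binary 0/1")
  n <- nrow(records)

  cols <- list(); nm <- character(0)
  for (cv in names(spec$covariates)) {
    lev <- spec$covariates[[cv]]
    if (!cv %in% names(records)) stop("covariate column '", cv, "' not found")
    xs <- as.character(records[[cv]])
    unseen <- setdiff(unique(xs), lev)
    if (length(unseen) > 0L)
      stop("unseen level(s) for covariate '", cv, "': ",
           paste(unseen, collapse = ", "))
    for (lv in lev[-1L]) {
      cols[[length(cols) + 1L]] <- as.numeric(xs == lv)
      nm <- c(nm, paste0(cv, "=", lv))
    }
  }
  X <- if (length(cols) > 0L) do.call(cbind, cols) else matrix(0, n, 0L)
  colnames(X) <- nm

  area_levels <- if (is.null(W)) sort(unique(as.character(records[[spec$area_field]])))
                 else W$ids
  area <- match(as.character(records[[spec$area_field]]), area_levels)
  if (anyNA(area))
    stop("area id(s) not in the weight matrix: ",
         paste(unique(records[[spec$area_field]][is.na(area)]), collapse = ", "))

  yr <- records[[spec$year_field]]
  if (is.null(years)) years <- range(yr)
  tt <- centred_year(yr, years)

  list(y = y, X = X, area = area, t = tt, n = n, p = ncol(X),
       J = length(area_levels), terms = nm, area_levels = area_levels)
}

#' Bernoulli log likelihood of the logistic model
#'
#' `sum_i [y_i eta_i - log(1 + exp(eta_i))]`, evaluated with overflow-safe
#' `log1p`/`exp` branching so it is accurate for |eta| up to 700 and beyond.
#'
#' @param y binary outcome vector.
#' @param eta linear predictor vector.
#' @return list with `total` and `pointwise` log-likelihood.
#' @export
log_likelihood <- function(y, eta) {
  stopifnot(length(y) == length(eta))
  if (any(!is.finite(eta))) stop("nonfinite linear predictor")
  l1pe <- ifelse(eta > 18, eta + exp(-pmin(eta, 700)), log1p(exp(pmin(eta, 18))))
  pw <- y * eta - l1pe
  list(total = sum(pw), pointwise = pw)
}

#' Log kernel of the intrinsic CAR prior
#'
#' `((n - c)/2) log(tau_u) - (tau_u/2) sum_{j<k} w_jk (u_j - u_k)^2`, with
#' `c` the number of connected components of the graph (the improper ICAR
#' normalizes over the rank of the Laplacian).
#'
#' @param u effect vector (should sum to ~0 within each component).
#' @param W a symmetric `weight_matrix`.
#' @param tau_u positive precision.
#' @return scalar log kernel.
#' @export
car_log_kernel <- function(u, W, tau_u) {
  stopifnot(inherits(W, "weight_matrix"), length(u) == W$n, tau_u > 0)
  cc <- max(connected_components(W))
  ss <- 0
  for (j in seq_len(W$n)) {
    nb <- W$neighbours[[j]]
    if (length(nb) > 0L)
      ss <- ss + sum(W$weights[[j]] * (u[j] - u[nb])^2)
  }
  ss <- ss / 2                      # each unordered pair counted twice
  0.5 * (W$n - cc) * log(tau_u) - 0.5 * tau_u * ss
}

#' Shape and rate of the precision full conditionals
#'
#' The Gibbs full conditionals used by the sampler:
#' `tau_u | u ~ Gamma(a_u + (J - c)/2, b_u + (1/2) sum_{j<k} w_jk (u_j-u_k)^2)`
#' and `tau_v | v ~ Gamma(a_v + J/2, b_v + (1/2) sum v_j^2)`.
#'
#' @param u,v current effect vectors.
#' @param W the `weight_matrix`.
#' @param priors a [prior_spec()].
#' @return list with `tau_u = c(shape, rate)` and `tau_v = c(shape, rate)`.
#' @export
tau_full_conditionals <- function(u, v, W, priors = prior_spec()) {
  cc <- max(connected_components(W))
  ss_u <- 0
  for (j in seq_len(W$n)) {
    nb <- W$neighbours[[j]]
    if (length(nb) > 0L)
      ss_u <- ss_u + sum(W$weights[[j]] * (u[j] - u[nb])^2)
  }
  ss_u <- ss_u / 2
  list(tau_u = c(shape = priors$tau_u_prior[1] + (W$n - cc) / 2,
                 rate = priors$tau_u_prior[2] + ss_u / 2),
       tau_v = c(shape = priors$tau_v_prior[1] + W$n / 2,
                 rate = priors$tau_v_prior[2] + sum(v^2) / 2))
}

#' Fit the BYM spatio-temporal multilevel logistic model
#'
#' Metropolis-within-Gibbs sampler: adaptive Gaussian random-walk updates
#' for the intercept, each slope and the two temporal coefficients;
#' single-site random-walk updates for each structured effect `u_j`
#' (likelihood plus ICAR full conditional, with re-centring of `u` to sum
#' zero each sweep, the mean being absorbed into the intercept) and each
#' heterogeneity effect `v_j`; conjugate Gibbs draws for `tau_u`, `tau_v`.
#' Proposal steps adapt only during burn-in, so the post-burn-in kernel is a
#' fixed, valid Metropolis-Hastings kernel.  Chains are fully deterministic
#' given their seeds.
#'
#' @param records patient data.frame with outcome, covariates, area, year.
#' @param W `weight_matrix` over the areas.
#' @param spec a [model_spec()].
#' @param priors a [prior_spec()].
#' @param mcmc an [mcmc_config()].
#' @param spatial include the BYM area effects? `FALSE` fits a plain
#'   logistic model (useful as a baseline and for exact small-case checks).
#' @param store_loglik keep the draws-by-patients pointwise log-likelihood
#'   matrix (needed by matrix-based [waic()]; streaming WAIC accumulators
#'   are always kept).
#' @param likelihood_weight multiplier on the log likelihood; 0 samples the
#'   prior.
#' @param allow_isolated fit despite isolated areas (their `u_j` is pinned
#'   at zero)?
#' @param fix_u,fix_v optional vectors freezing the area effects at given
#'   values (diagnostic use, e.g. checking the `tau` full conditionals).
#' @param years year range for centring `t`; defaults to the data range.
#' @return object of class `bym_fit`.
#' @export
run_mcmc <- function(records, W, spec = model_spec(), priors = prior_spec(),
                     mcmc = mcmc_config(), spatial = TRUE,
                     store_loglik = FALSE, likelihood_weight = 1,
                     allow_isolated = FALSE, fix_u = NULL, fix_v = NULL,
                     years = NULL) {
  stopifnot(inherits(W, "weight_matrix"), inherits(priors, "prior_spec"),
            inherits(mcmc, "mcmc_config"))
  if (nrow(records) == 0L) stop("no patient records")
  des <- build_design(records, spec, W, years = years)

  iso <- which(lengths(W$neighbours) == 0L)
  if (spatial && length(iso) > 0L && !allow_isolated)
    stop("weight matrix has isolated area(s): ",
         paste(W$ids[iso], collapse = ", "),
         "; widen the band or set allow_isolated = TRUE")

  # full design: intercept | slopes | t | t^2
  Xf <- cbind(`(Intercept)` = 1, des$X)
  prec <- c(priors$intercept_precision, rep(priors$coef_precision, des$p))
  if (spec$include_time) {
    Xf <- cbind(Xf, t = des$t, `t^2` = des$t^2)
    prec <- c(prec, rep(priors$coef_precision, 2L))
  }
  terms <- colnames(Xf)
  p_all <- ncol(Xf)

  comp <- connected_components(W)
  nb0 <- lapply(W$neighbours, function(x) as.integer(x - 1L))
  prev <- mean(des$y)
  prev <- min(max(prev, 1e-3), 1 - 1e-3)

  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    # distinct starting values per chain: chain 1 at data-informed neutral
    # values, later chains offset and overdispersed
    off <- 0.5 * (ch - 1L)
    init_coef <- c(stats::qlogis(prev) + off, rep(off, p_all - 1L))
    init_tau <- if (ch == 1L) 1 else 10
    u0 <- if (is.null(fix_u)) rep(0, W$n) else as.numeric(fix_u)
    v0 <- if (is.null(fix_v)) rep(0, W$n) else as.numeric(fix_v)
    set.seed(mcmc$seeds[ch])
    raw <- bym_mcmc_cpp(des$y, Xf, as.integer(des$area - 1L), nb0, W$weights,
                        max(comp), prec,
                        priors$tau_u_prior[1], priors$tau_u_prior[2],
                        priors$tau_v_prior[1], priors$tau_v_prior[2],
                        mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                        init_coef, init_tau, init_tau, u0, v0,
                        likelihood_weight, spatial, store_loglik,
                        is.null(fix_u), is.null(fix_v), mcmc$target_accept)
    colnames(raw$coef) <- terms
    if (spatial) { colnames(raw$u) <- W$ids; colnames(raw$v) <- W$ids }
    colnames(raw$tau) <- c("tau_u", "tau_v")
    chains[[ch]] <- raw
  }

  structure(list(chains = chains, terms = terms, spec = spec,
                 priors = priors, mcmc = mcmc, spatial = spatial,
                 area_ids = W$ids, W_kind = W$kind, n = des$n, J = des$J,
                 p = p_all, y = des$y, seeds = mcmc$seeds,
                 n_retained = nrow(chains[[1L]]$coef)),
            class = "bym_fit")
}

#' @export
print.bym_fit <- function(x, ...) {
  cat("BYM spatio-temporal logistic fit (", x$W_kind, " weights): ",
      x$n, " patients, ", x$J, " areas, ", length(x$chains), " chain(s) x ",
      x$n_retained, " retained draws\n", sep = "")
  invisible(x)
}

#' Pool a named parameter across chains of a fit
#'
#' @param fit a `bym_fit`.
#' @param what one of `"coef"`, `"u"`, `"v"`, `"tau"`.
#' @return matrix of pooled draws (rows = draws across all chains).
#' @export
pooled_draws <- function(fit, what = "coef") {
  stopifnot(inherits(fit, "bym_fit"))
  do.call(rbind, lapply(fit$chains, `[[`, what))
}

#' Posterior odds-ratio summaries
#'
#' Per coefficient: posterior mean and median on the log-odds scale, the
#' odds ratio `exp(median)`, and the 95% credible interval from the 2.5 and
#' 97.5 empirical percentiles of the draws.  Reference levels are reported
#' with OR 1.
#'
#' @param fit a `bym_fit`, or a matrix of coefficient draws (columns named).
#' @param include_reference append OR = 1 rows for declared reference
#'   levels (only when `fit` is a `bym_fit`).
#' @return data.frame with columns term, mean, median, or, lower, upper.
#' @export
posterior_summaries <- function(fit, include_reference = FALSE) {
  draws <- if (inherits(fit, "bym_fit")) pooled_draws(fit, "coef") else fit
  stopifnot(is.matrix(draws), nrow(draws) >= 1L)
  qs <- apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  out <- data.frame(term = colnames(draws),
                    mean = colMeans(draws),
                    median = apply(draws, 2L, stats::median),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$or <- exp(out$median)
  out$lower <- exp(qs[1L, ])
  out$upper <- exp(qs[2L, ])
  if (include_reference && inherits(fit, "bym_fit")) {
    for (cv in names(fit$spec$covariates)) {
      ref <- fit$spec$covariates[[cv]][1L]
      out <- rbind(out, data.frame(term = paste0(cv, "=", ref, " (ref)"),
                                   mean = 0, median = 0, or = 1,
                                   lower = 1, upper = 1))
    }
  }
  out
}
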