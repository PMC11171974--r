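#' Gelman--Rubin potential scale reduction factor
#'
#' Classic split-free PSRF for one parameter from two or more equal-length
#' chains: with `W` the mean within-chain sample variance and
#' `B = n_ret * var(chain means)`,
#' `PSRF = sqrt(((n_ret - 1)/n_ret * W + B/n_ret) / W)`.
#' Values near 1 indicate convergence.
#'
#' @param chains list of numeric vectors (one per chain, equal length
#'   `>= 2`), or a matrix with one column per chain.
#' @return list with `psrf`, `B`, `W` and `n_ret`.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(k) chains[, k])
  if (!is.list(chains) || length(chains) < 2L)
    stop("at least two chains are required")
  n_ret <- unique(lengths(chains))
  if (length(n_ret) != 1L) stop("chains must have equal length")
  if (n_ret < 2L) stop("chains must have length >= 2")
  Ww <- mean(vapply(chains, stats::var, 0))
  B <- n_ret * stats::var(vapply(chains, mean, 0))
  psrf <- sqrt(((n_ret - 1) / n_ret * Ww + B / n_ret) / Ww)
  list(psrf = psrf, B = B, W = Ww, n_ret = n_ret)
}

#' PSRF report for a fitted model
#'
#' Computes the Gelman--Rubin factor for every fixed-effect coefficient and
#' both precision parameters of a multi-chain [run_mcmc()] fit.
#'
#' @param fit a `bym_fit` with at least two chains.
#' @return data.frame with columns parameter, psrf, B, W.
#' @export
psrf_report <- function(fit) {
  stopifnot(inherits(fit, "bym_fit"))
  if (length(fit$chains) < 2L) stop("at least two chains are required")
  grab <- function(what, k) lapply(fit$chains, function(ch) ch[[what]][, k])
  pars <- fit$terms
  rows <- lapply(seq_along(pars), function(k) {
    g <- gelman_rubin(grab("coef", k))
    data.frame(parameter = pars[k], psrf = g$psrf, B = g$B, W = g$W)
  })
  if (fit$spatial) {
    for (k in 1:2) {
      g <- gelman_rubin(grab("tau", k))
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = c("tau_u", "tau_v")[k],
                   psrf = g$psrf, B = g$B, W = g$W)
    }
  }
  do.call(rbind, rows)
}

logmeanexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Watanabe--Akaike information criterion
#'
#' From a draws-by-patients pointwise log-likelihood matrix:
#' `lppd = sum_i log mean_s exp(ll_si)` (log-sum-exp stabilized),
#' `p_waic = sum_i var_s(ll_si)` (sample variance over draws), and
#' `waic = -2 (lppd - p_waic)`.  Lower WAIC indicates better fit.
#'
#' @param x pointwise log-likelihood matrix (rows = draws, columns =
#'   patients), or a `bym_fit` (uses the stored matrix when present, the
#'   streaming accumulators otherwise).
#' @return list of class `waic_report`: `lppd`, `p_waic`, `waic`, and
#'   per-patient `pointwise` contributions.
#' @export
waic <- function(x) UseMethod("waic")

#' @export
waic.default <- function(x) {
  ll <- as.matrix(x)
  stopifnot(nrow(ll) >= 1L, ncol(ll) >= 1L)
  if (any(is.na(ll))) stop("pointwise log-likelihood contains NA")
  allneg <- which(apply(ll, 2L, function(col) all(col == -Inf)))
  if (length(allneg) > 0L)
    stop("all-draw zero likelihood for patient(s): ",
         paste(allneg, collapse = ", "))
  lppd_i <- apply(ll, 2L, logmeanexp)
  p_i <- if (nrow(ll) > 1L) apply(ll, 2L, stats::var) else rep(0, ncol(ll))
  res <- list(lppd = sum(lppd_i), p_waic = sum(p_i),
              waic = -2 * (sum(lppd_i) - sum(p_i)),
              pointwise = data.frame(lppd = lppd_i, p_waic = p_i))
  class(res) <- "waic_report"
  res
}

#' @export
waic.bym_fit <- function(x) {
  has_ll <- !is.null(x$chains[[1L]]$loglik)
  if (has_ll)
    return(waic.default(do.call(rbind, lapply(x$chains, `[[`, "loglik"))))
  # streaming accumulators: exact same quantities without storing the matrix
  S <- sum(vapply(x$chains, function(ch) ch$waic_acc$n_draws, 0L))
  sum_p <- Reduce(`+`, lapply(x$chains, function(ch) ch$waic_acc$sum_p))
  sum_ll <- Reduce(`+`, lapply(x$chains, function(ch) ch$waic_acc$sum_ll))
  sum_ll2 <- Reduce(`+`, lapply(x$chains, function(ch) ch$waic_acc$sum_ll2))
  if (any(sum_p == 0)) stop("all-draw zero likelihood for patient(s): ",
                            paste(which(sum_p == 0), collapse = ", "))
  lppd_i <- log(sum_p / S)
  p_i <- if (S > 1L) pmax(0, (sum_ll2 - sum_ll^2 / S) / (S - 1)) else
    rep(0, length(sum_p))
  res <- list(lppd = sum(lppd_i), p_waic = sum(p_i),
              waic = -2 * (sum(lppd_i) - sum(p_i)),
              pointwise = data.frame(lppd = lppd_i, p_waic = p_i))
  class(res) <- "waic_report"
  res
}

#' @export
print.waic_report <- function(x, ...) {
  cat(sprintf("WAIC %.2f (lppd %.2f, p_waic %.2f)\n",
              x$waic, x$lppd, x$p_waic))
  invisible(x)
}

#' Rank models by WAIC
#'
#' @param reports named list of `waic_report` objects (or bare WAIC
#'   numbers); names are the model labels.
#' @return data.frame sorted by ascending WAIC with `delta` versus the best
#'   model; ties keep their original order.
#' @export
compare_models <- function(reports) {
  stopifnot(length(reports) >= 2L)
  vals <- vapply(reports, function(r)
    if (inherits(r, "waic_report")) r$waic else as.numeric(r), 0)
  labs <- names(reports)
  if (is.null(labs)) labs <- paste0("model", seq_along(vals))
  ord <- order(vals)                     # stable: ties keep input order
  out <- data.frame(label = labs[ord], waic = vals[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$delta <- out$waic - out$waic[1L]
  out
}

#' Sequential covariate addition by WAIC
#'
#' Refits the model for each prefix of a user-given covariate order and
#' tabulates the WAIC per step, mirroring forward model building where each
#' covariate is added only if it improves fit.  The order is the user's;
#' no search is performed.
#'
#' @param records patient data.frame.
#' @param W `weight_matrix`.
#' @param covariate_order character vector of covariate names (must appear
#'   in `covariates`).
#' @param covariates full named list of level sets (see [model_spec()]).
#' @param priors,mcmc passed to [run_mcmc()].
#' @param ... further arguments to [run_mcmc()].
#' @return data.frame with columns model (formula-style label) and waic.
#' @export
sequential_waic <- function(records, W, covariate_order,
                            covariates = default_model_covariates(),
                            priors = prior_spec(), mcmc = mcmc_config(),
                            ...) {
  stopifnot(all(covariate_order %in% names(covariates)))
  rows <- lapply(seq_along(covariate_order), function(k) {
    cvs <- covariates[covariate_order[seq_len(k)]]
    fit <- run_mcmc(records, W, model_spec(cvs), priors, mcmc, ...)
    data.frame(model = paste(covariate_order[seq_len(k)], collapse = " + "),
               waic = waic(fit)$waic, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
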