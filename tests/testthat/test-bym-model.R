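test_that("design building encodes dummies against references and centres time", {
  rec <- data.frame(patient_id = 1:3, area_id = c("a001", "a002", "a001"),
                    year = c(2015, 2018, 2021),
                    grp = c("other", "ref", "other"), poor_qol = c(1L, 0L, 1L))
  sp <- model_spec(list(grp = c("ref", "other")))
  des <- build_design(rec, sp)
  expect_equal(unname(des$X[, 1]), c(1, 0, 1))
  expect_equal(des$t, c(-3, 0, 3))
  expect_identical(des$terms, "grp=other")

  # full study covariate set: 11 slopes
  cfg <- sim_config(n_patients = 200, seed = 8)
  reg <- simulate_registry(cfg)
  des2 <- build_design(reg$patients, model_spec(), reg$W)
  expect_identical(des2$p, 11L)
  expect_identical(des2$J, 80L)
  expect_setequal(unique(des2$t), -3:3)
  expect_setequal(unique(des2$t^2), c(0, 1, 4, 9))

  rec_bad <- rec; rec_bad$grp[2] <- "mystery"
  expect_error(build_design(rec_bad, sp), "mystery")
  W <- weight_matrix(c("b1", "b2"), list(2L, 1L))
  expect_error(build_design(rec, sp, W), "not in the weight matrix")
})

test_that("the Bernoulli log likelihood is exact and numerically stable", {
  r <- log_likelihood(c(1L, 0L), c(0, 0))
  expect_equal(r$total, 2 * log(0.5), tolerance = 1e-12)
  # limits: large eta with y = 1 contributes ~0
  expect_equal(log_likelihood(1L, 700)$pointwise, 0, tolerance = 1e-12)
  expect_lt(log_likelihood(0L, 700)$pointwise, -699)
  # random small instance against the direct pmf product oracle
  set.seed(19)
  for (rep in 1:10) {
    eta <- rnorm(7, 0, 2); y <- rbinom(7, 1, 0.5)
    oracle <- sum(dbinom(y, 1, plogis(eta), log = TRUE))
    expect_equal(log_likelihood(y, eta)$total, oracle, tolerance = 1e-10)
  }
  expect_error(log_likelihood(1L, NaN), "nonfinite")
})

test_that("the ICAR log kernel equals the Laplacian quadratic form", {
  W2 <- weight_matrix(c("a", "b"), list(2L, 1L))
  a <- 0.7
  expect_equal(car_log_kernel(c(a, -a), W2, 1), -2 * a^2, tolerance = 1e-12)
  expect_equal(car_log_kernel(rep(0, 2), W2, 3), 0.5 * log(3))
  # random graphs n <= 10: pairwise form vs u' (D - W) u
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(3:10, 1)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- rbinom(n * (n - 1) / 2, 1, 0.5)
    m <- m + t(m)
    nb <- lapply(seq_len(n), function(j) which(m[j, ] == 1))
    W <- weight_matrix(sprintf("g%02d", 1:n), nb)
    u <- rnorm(n); u <- u - mean(u)
    tau <- runif(1, 0.5, 3)
    L <- diag(rowSums(m)) - m
    cc <- max(connected_components(W))
    oracle <- 0.5 * (n - cc) * log(tau) -
      0.5 * tau * as.numeric(t(u) %*% L %*% u)
    expect_equal(car_log_kernel(u, W, tau), oracle, tolerance = 1e-10)
  }
})

test_that("prior precision 0.725 corresponds to 95% OR mass in (0.1, 10)", {
  expect_equal(round(or_interval_precision(0.1, 10, 0.95), 3), 0.725)
  expect_error(or_interval_precision(0.2, 10), "symmetric")
})

test_that("prior-only sampling recovers the coefficient prior sd", {
  rec <- tiny_records(50)
  W <- queen_contiguity(make_lattice(2, 2))
  sp <- model_spec(list(institution = c("Private", "Public")))
  # 50,000 retained draws of the pure prior
  fit <- run_mcmc(rec, W, sp,
                  mcmc = mcmc_config(110000, 10000, 2, 1, seeds = 5),
                  likelihood_weight = 0, spatial = FALSE)
  draws <- pooled_draws(fit, "coef")
  target <- 1 / sqrt(0.725)
  for (term in c("institution=Public", "t", "t^2")) {
    expect_lt(abs(sd(draws[, term]) - target) / target, 0.05, label = term)
    expect_lt(abs(mean(draws[, term])), 0.05)
  }
})

test_that("every retained structured-effect draw sums to zero", {
  cfg <- sim_config(n_rows = 3, n_cols = 4, n_patients = 600, seed = 15)
  reg <- simulate_registry(cfg)
  fit <- run_mcmc(reg$patients, reg$W,
                  model_spec(list(institution = c("Private", "Public"))),
                  mcmc = mcmc_config(1200, 600, 2, 1, seeds = 3))
  u <- pooled_draws(fit, "u")
  expect_lt(max(abs(rowSums(u))), 1e-8)
})

test_that("extending a chain leaves its common prefix identical", {
  cfg <- sim_config(n_rows = 2, n_cols = 3, n_patients = 300, seed = 16)
  reg <- simulate_registry(cfg)
  sp <- model_spec(list(institution = c("Private", "Public")))
  mc1 <- mcmc_config(1000, 400, 2, 1, seeds = 9)
  mc2 <- mcmc_config(1600, 400, 2, 1, seeds = 9)
  f1 <- run_mcmc(reg$patients, reg$W, sp, mcmc = mc1)
  f2 <- run_mcmc(reg$patients, reg$W, sp, mcmc = mc2)
  n1 <- f1$n_retained
  expect_identical(f1$chains[[1]]$coef, f2$chains[[1]]$coef[seq_len(n1), ])
  expect_identical(f1$chains[[1]]$tau, f2$chains[[1]]$tau[seq_len(n1), ])
})

test_that("tau draws follow their Gamma full conditionals at fixed effects", {
  cfg <- sim_config(n_rows = 3, n_cols = 4, n_patients = 400, seed = 18)
  reg <- simulate_registry(cfg)
  W <- reg$W
  set.seed(18)
  u_fix <- simulate_area_effects(W, 1, 1)$u
  u_fix <- u_fix - mean(u_fix)
  v_fix <- rnorm(W$n, 0, 0.5)
  fit <- run_mcmc(reg$patients, W,
                  model_spec(list(institution = c("Private", "Public"))),
                  mcmc = mcmc_config(4000, 1000, 1, 1, seeds = 2),
                  fix_u = u_fix, fix_v = v_fix)
  fc <- tau_full_conditionals(u_fix, v_fix, W, prior_spec())
  tu <- pooled_draws(fit, "tau")[, "tau_u"]
  tv <- pooled_draws(fit, "tau")[, "tau_v"]
  pp <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  # QQ agreement against the analytic Gamma quantiles
  expect_equal(unname(quantile(tu, pp)),
               qgamma(pp, fc$tau_u["shape"], fc$tau_u["rate"]),
               tolerance = 0.06, ignore_attr = TRUE)
  expect_equal(unname(quantile(tv, pp)),
               qgamma(pp, fc$tau_v["shape"], fc$tau_v["rate"]),
               tolerance = 0.06, ignore_attr = TRUE)
})

test_that("the MCMC intercept posterior matches dense grid integration", {
  # 2 areas, 10 patients, intercept-only non-spatial model: the posterior
  # over alpha is one-dimensional and can be integrated on a grid
  rec <- data.frame(patient_id = 1:10,
                    area_id = rep(c("x1", "x2"), 5),
                    year = 2018,
                    poor_qol = c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L))
  W <- weight_matrix(c("x1", "x2"), list(2L, 1L))
  sp <- model_spec(covariates = list(), include_time = FALSE)
  fit <- run_mcmc(rec, W, sp,
                  mcmc = mcmc_config(210000, 10000, 1, 1, seeds = 44),
                  spatial = FALSE)
  a <- pooled_draws(fit, "coef")[, 1]

  grid <- seq(-6, 6, by = 0.01)
  logpost <- sapply(grid, function(g)
    sum(dbinom(rec$poor_qol, 1, plogis(g), log = TRUE))) +
    dnorm(grid, 0, 1 / sqrt(0.01), log = TRUE)
  post <- exp(logpost - max(logpost)); post <- post / sum(post)

  breaks <- seq(-6, 6, by = 0.25)
  mcmc_hist <- hist(a[a > -6 & a < 6], breaks = breaks, plot = FALSE)$counts
  mcmc_p <- mcmc_hist / sum(mcmc_hist)
  grid_p <- sapply(seq_len(length(breaks) - 1), function(b)
    sum(post[grid > breaks[b] & grid <= breaks[b + 1]]))
  expect_lt(0.5 * sum(abs(mcmc_p - grid_p)), 0.05)
})

test_that("posterior summaries expose OR medians, intervals and references", {
  draws <- cbind("(Intercept)" = rep(0, 101),
                 "institution=Public" = rep(0, 101))
  s <- posterior_summaries(draws)
  expect_equal(s$or, c(1, 1)); expect_equal(s$lower, c(1, 1))
  draws2 <- cbind(b = rnorm(5000, log(2), 1e-6))
  expect_equal(posterior_summaries(draws2)$or, 2, tolerance = 1e-4)
  # quantiles match a brute-force sort-and-interpolate on 101 draws
  set.seed(33)
  x <- rnorm(101)
  s3 <- posterior_summaries(cbind(b = x))
  xs <- sort(x)
  bf_q <- function(p) {                 # linear interpolation of order stats
    h <- (101 - 1) * p + 1
    xs[floor(h)] + (h - floor(h)) * (xs[floor(h) + 1] - xs[floor(h)])
  }
  expect_equal(s3$lower, exp(bf_q(0.025)), tolerance = 1e-12)
  expect_equal(s3$upper, exp(bf_q(0.975)), tolerance = 1e-12)
  expect_equal(s3$median, bf_q(0.5), tolerance = 1e-12)
})

test_that("isolated areas are refused unless explicitly allowed", {
  rec <- tiny_records(30)
  rec$area_id <- sample(c("i1", "i2", "i3"), 30, TRUE)
  W <- weight_matrix(c("i1", "i2", "i3"), list(2L, 1L, integer(0)))
  sp <- model_spec(list(institution = c("Private", "Public")))
  expect_error(run_mcmc(rec, W, sp), "isolated")
  fit <- run_mcmc(rec, W, sp, mcmc = mcmc_config(400, 200, 1, 1, seeds = 1),
                  allow_isolated = TRUE)
  expect_s3_class(fit, "bym_fit")
  expect_true(all(is.finite(pooled_draws(fit, "u"))))
})
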