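test_that("lattice construction gives closed square cells with centred centroids", {
  two <- make_lattice(1, 2, 1)
  expect_length(two, 2)
  expect_equal(sqrt(sum((two[[1]]$centroid - two[[2]]$centroid)^2)), 1)
  expect_length(make_lattice(8, 10, 20), 80)
  expect_identical(lengths(queen_contiguity(make_lattice(3, 3))$neighbours),
                   c(3L, 5L, 3L, 5L, 8L, 5L, 3L, 5L, 3L))
  expect_error(make_lattice(0, 3), "positive")
})

test_that("ICAR draws are centred, seeded and scale as 1/tau", {
  W <- queen_contiguity(make_lattice(4, 5))
  for (s in 1:5) {
    eff <- simulate_area_effects(W, tau_u = 2, tau_v = 4, seed = s)
    expect_lt(abs(sum(eff$u)), 1e-10)
  }
  e1 <- simulate_area_effects(W, 2, 4, seed = 42)
  e2 <- simulate_area_effects(W, 2, 4, seed = 42)
  expect_identical(e1, e2)

  # iid component: sample sd near 1/sqrt(tau_v) over a large batch.
  # (u is drawn on a small graph; v is what the batch size is for)
  chain_w <- function(m) weight_matrix(
    sprintf("c%05d", seq_len(m)),
    lapply(seq_len(m), function(j)
      intersect(c(j - 1L, j + 1L), seq_len(m))))
  set.seed(9)
  v_draws <- replicate(125, simulate_area_effects(chain_w(80), 1, 4)$v)
  expect_gt(sd(v_draws), 0.49); expect_lt(sd(v_draws), 0.51)

  # ICAR quadratic-form identity on a chain graph:
  # E[sum_{j<k} w_jk (u_j-u_k)^2] = (n - 1)/tau_u
  Wchain <- chain_w(30)
  set.seed(101)
  qf <- replicate(400, {
    u <- simulate_area_effects(Wchain, tau_u = 2, tau_v = 1)$u
    sum(sapply(seq_len(29), function(j) (u[j] - u[j + 1])^2))
  })
  expect_equal(mean(qf) / 29, 1 / 2, tolerance = 0.1)
})

test_that("disconnected graphs are refused for the ICAR draw", {
  W <- weight_matrix(letters[1:4], list(2L, 1L, 4L, 3L))
  expect_error(simulate_area_effects(W, 1, 1), "disconnected")
})

test_that("outcome prevalence follows the linear predictor", {
  areas <- make_lattice(2, 2)
  u <- rep(0, 4); v <- rep(0, 4)
  null_beta <- list(institution = c(Public = 0))
  cfg0 <- sim_config(n_rows = 2, n_cols = 2, n_patients = 10000,
                     true_alpha = 0, true_beta = null_beta,
                     true_delta1 = 0, true_delta2 = 0, seed = 5)
  set.seed(5)
  rec <- simulate_patients(cfg0, areas, u, v)
  expect_equal(mean(rec$poor_qol), 0.5, tolerance = 3 * 0.5 / sqrt(10000))

  # cohort-rate intercept reproduces the 36.4% prevalence
  cfg1 <- sim_config(n_rows = 2, n_cols = 2, n_patients = 10000,
                     true_alpha = qlogis(0.3639), true_beta = null_beta,
                     true_delta1 = 0, true_delta2 = 0, seed = 6)
  set.seed(6)
  rec1 <- simulate_patients(cfg1, areas, u, v)
  expect_lt(abs(mean(rec1$poor_qol) - 0.3639),
            3.5 * sqrt(0.3639 * 0.6361 / 10000))

  # a single log(1.35) institution effect shows up as the crude OR
  cfg2 <- sim_config(n_rows = 2, n_cols = 2, n_patients = 50000,
                     true_alpha = 0,
                     true_beta = list(institution = c(Public = log(1.35))),
                     true_delta1 = 0, true_delta2 = 0, seed = 7)
  set.seed(7)
  rec2 <- simulate_patients(cfg2, areas, u, v)
  tab <- table(rec2$institution, rec2$poor_qol)
  crude_or <- (tab["Public", "1"] * tab["Private", "0"]) /
    (tab["Public", "0"] * tab["Private", "1"])
  expect_equal(log(crude_or), log(1.35), tolerance = 3 * sqrt(sum(1 / tab)))
})

test_that("prevalence is monotone in the intercept", {
  areas <- make_lattice(2, 2)
  u <- v <- rep(0, 4)
  prev <- sapply(c(-2, -1, 0, 1), function(a) {
    set.seed(31)
    cfg <- sim_config(n_rows = 2, n_cols = 2, n_patients = 4000,
                      true_alpha = a, seed = 31)
    mean(simulate_patients(cfg, areas, u, v)$poor_qol)
  })
  expect_true(all(diff(prev) > 0))
})

test_that("covariate margins match the configured frequencies", {
  cfg <- sim_config(n_patients = 100000, seed = 12)
  areas <- make_lattice(8, 10, 20)
  set.seed(12)
  rec <- simulate_patients(cfg, areas, rep(0, 80), rep(0, 80))
  fr <- cfg$covariate_freqs
  for (cv in names(fr$individual)) {
    obs <- table(factor(rec[[cv]], levels = names(fr$individual[[cv]])))
    p <- chisq.test(obs, p = fr$individual[[cv]])$p.value
    expect_gt(p, 0.001, label = paste("GOF", cv))
  }
  obs_y <- table(factor(rec$year, levels = names(fr$year)))
  expect_gt(chisq.test(obs_y, p = fr$year)$p.value, 0.001)
})

test_that("the registry is fully deterministic given the seed", {
  cfg <- sim_config(n_patients = 500, seed = 77)
  r1 <- simulate_registry(cfg)
  r2 <- simulate_registry(cfg)
  expect_identical(r1$patients, r2$patients)
  expect_identical(r1$effects, r2$effects)
  s1 <- simulate_domain_scores(r1$patients, seed = 78)
  s2 <- simulate_domain_scores(r2$patients, seed = 78)
  expect_identical(s1, s2)
})

test_that("domain scores are bounded and reproduce the outcome label", {
  cfg <- sim_config(n_patients = 5238, seed = 4)
  reg <- simulate_registry(cfg)
  rec <- simulate_domain_scores(reg$patients, seed = 14)
  dom <- c("urinary_incontinence", "urinary_irritative", "bowel",
           "sexual", "hormonal")
  sc <- as.matrix(rec[, dom])
  expect_true(all(sc >= 0 & sc <= 100))
  out <- derive_poor_qol(rec)
  agree <- mean(out$outcomes$poor_qol == rec$poor_qol)
  expect_gte(agree, 0.9)
  # agreement holds among the poor-labelled records specifically
  poor_idx <- rec$poor_qol == 1
  expect_gte(mean(out$outcomes$poor_qol[poor_idx] == 1), 0.9)
})

test_that("malformed probability vectors are rejected", {
  fr <- default_covariate_freqs()
  fr$individual$psa <- c("<=10" = 0.5, "10.1-20.0" = 0.2, ">20" = 0.2)
  expect_error(sim_config(covariate_freqs = fr), "sum to 1")
})
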