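test_that("Wald ratio arithmetic, signs and degenerate numerator", {
  rec <- tibble::tibble(
    variant_id = "s", gamma = 0.1, sigma_x = 0.001, Gamma = 0.05, sigma_y = 0.01
  )
  est <- mr_wald_ratio(rec)
  expect_equal(est$beta_hat, 0.5)
  expect_equal(est$se, 0.1)
  expect_equal(mr_wald_ratio(dplyr::mutate(rec, gamma = -0.1))$beta_hat, -0.5)
  expect_equal(mr_wald_ratio(dplyr::mutate(rec, Gamma = 0))$beta_hat, 0)
  expect_error(
    mr_wald_ratio(dplyr::mutate(rec, gamma = 0)),
    class = "mrpipe_undefined_ratio_error"
  )
})

test_that("IVW reproduces the worked example and its degenerate cases", {
  d <- worked_data()
  est <- mr_ivw(d)
  expect_equal(est$beta_hat, 127.5 / 525, tolerance = 1e-12)
  expect_equal(1 / sqrt(525), 0.043644, tolerance = 1e-4)
  # Q/(n-1) < 1 here, so the random-effects floor leaves the fixed SE
  expect_equal(est$se, 1 / sqrt(525), tolerance = 1e-12)
  expect_equal(mr_ivw(d, model = "fixed")$se, 1 / sqrt(525), tolerance = 1e-12)

  single <- mr_ivw(d[1, ], model = "fixed")
  wald <- mr_wald_ratio(d[1, ])
  expect_equal(single$beta_hat, wald$beta_hat)
  expect_equal(single$se, wald$se)

  # all per-SNP ratios equal: Q = 0 and the floor applies
  eq <- dplyr::mutate(d, Gamma = 0.4 * gamma)
  est_eq <- mr_ivw(eq)
  expect_equal(est_eq$beta_hat, 0.4, tolerance = 1e-12)
  expect_equal(est_eq$cochran_q$statistic, 0, tolerance = 1e-20)
  expect_equal(est_eq$se, mr_ivw(eq, model = "fixed")$se)

  expect_error(mr_ivw(d[0, ]), class = "mrpipe_insufficient_instruments_error")
})

test_that("IVW equals weighted regression through the origin on random data", {
  for (seed in 1:20) {
    rec <- random_mr_records(sample(3:30, 1), seed)
    est <- mr_ivw(rec, model = "fixed")
    fit <- lm(Gamma ~ 0 + gamma, data = rec, weights = 1 / rec$sigma_y^2)
    expect_equal(est$beta_hat, unname(coef(fit)["gamma"]), tolerance = 1e-10)
    # lm scales its SE by the residual sd; undo it to get the fixed-effect SE
    se_lm <- summary(fit)$coefficients["gamma", "Std. Error"] / summary(fit)$sigma
    expect_equal(est$se, unname(se_lm), tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact linear relationship and matches lm", {
  d <- worked_data()
  exact <- dplyr::mutate(d, Gamma = 0.01 + 0.5 * gamma, sigma_y = 0.01)
  est <- mr_egger(exact)
  expect_equal(est$beta_hat, 0.5, tolerance = 1e-10)
  expect_equal(est$intercept$estimate, 0.01, tolerance = 1e-10)

  for (seed in 1:20) {
    rec <- random_mr_records(sample(3:30, 1), seed)
    flip <- sign(rec$gamma)
    g <- rec$gamma * flip
    G <- rec$Gamma * flip
    fit <- lm(G ~ g, weights = 1 / rec$sigma_y^2)
    est <- mr_egger(rec)
    expect_equal(est$beta_hat, unname(coef(fit)["g"]), tolerance = 1e-10)
    expect_equal(est$intercept$estimate, unname(coef(fit)["(Intercept)"]),
      tolerance = 1e-10
    )
    # with the multiplicative floor, SEs match lm's when overdispersion > 1
    if (summary(fit)$sigma > 1) {
      expect_equal(est$se, summary(fit)$coefficients["g", "Std. Error"],
        tolerance = 1e-8
      )
    }
  }
  expect_error(mr_egger(worked_data()[1:2, ]),
    class = "mrpipe_insufficient_instruments_error"
  )
  flat <- dplyr::mutate(worked_data(), gamma = 0.1)
  expect_error(mr_egger(flat), class = "mrpipe_degenerate_design_error")
})

test_that("weighted median interpolates at the 50% weight midpoint", {
  d <- worked_data() # ratios (0.2, 0.25, 0.3), weights prop. (100, 400, 25)
  est <- mr_weighted_median(d, n_boot = 200, seed = 4)
  expect_equal(est$beta_hat, 0.2425, tolerance = 1e-4)
  expect_equal(
    est$beta_hat,
    weighted_median_oracle(c(0.2, 0.25, 0.3), c(100, 400, 25)),
    tolerance = 1e-12
  )
  expect_gt(est$se, 0)

  # equal weights and odd n reduce to the plain median ratio
  eqw <- tibble::tibble(
    variant_id = c("a", "b", "c"), gamma = 0.1, sigma_x = 0.001,
    Gamma = c(0.01, 0.03, 0.07), sigma_y = 0.01
  )
  expect_equal(mr_weighted_median(eqw, n_boot = 50, seed = 1)$beta_hat, 0.3)

  # bootstrap SE is reproducible under the seed
  e1 <- mr_weighted_median(d, n_boot = 100, seed = 9)
  e2 <- mr_weighted_median(d, n_boot = 100, seed = 9)
  expect_identical(e1$se, e2$se)
})

test_that("weighted mode tracks the dominant cluster and the dense-grid oracle", {
  same <- tibble::tibble(
    variant_id = letters[1:4], gamma = 0.1, sigma_x = 0.001,
    Gamma = 0.04, sigma_y = 0.01
  )
  expect_equal(mr_weighted_mode(same, n_boot = 50, seed = 1)$beta_hat, 0.4)

  cl <- tibble::tibble(
    variant_id = letters[1:4], gamma = 0.1, sigma_x = 0.001,
    Gamma = c(0.02, 0.021, 0.022, 0.09), sigma_y = 0.01
  )
  est <- mr_weighted_mode(cl, n_boot = 50, seed = 1)
  expect_gte(est$beta_hat, 0.2 - 0.02)
  expect_lte(est$beta_hat, 0.22 + 0.02)
  expect_lt(abs(est$beta_hat - 0.21), abs(est$beta_hat - 0.9))

  # coarse-grid argmax within one coarse step of a 10x finer scan
  rec <- random_mr_records(15, 3)
  b <- rec$Gamma / rec$gamma
  w <- rec$gamma^2 / rec$sigma_y^2
  w <- w / sum(w)
  h <- 0.9 * min(sd(b), IQR(b) / 1.349) * length(b)^(-0.2)
  coarse <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 512)
  fine <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 5120)
  dens <- function(x) sum(w * dnorm((x - b) / h)) / h
  fine_mode <- fine[which.max(vapply(fine, dens, numeric(1)))]
  est2 <- mr_weighted_mode(rec, n_boot = 50, seed = 2)
  expect_lt(abs(est2$beta_hat - fine_mode), diff(coarse[1:2]) + 1e-12)
})

test_that("run_all applies exactly the methods the SNP count admits", {
  d <- worked_data()
  res1 <- mr_all(d[1, ], n_boot = 50)
  expect_setequal(names(res1$estimates), c("wald", "ivw"))
  expect_setequal(res1$skipped$method, c("egger", "weighted_median", "weighted_mode"))

  sim <- simulate_two_sample(scenario_preset("afb_like", seed = 13))
  res <- mr_all(sim_instrument_data(sim), n_boot = 100, seed = 2)
  expect_setequal(
    names(res$estimates),
    c("ivw", "egger", "weighted_median", "weighted_mode")
  )
  td <- tidy(res)
  expect_equal(nrow(td), 4)
  # consistent data: every estimator lands near the simulated truth on its
  # own uncertainty scale (Egger is far noisier than IVW at 10 SNPs)
  truth <- attr(sim$truth, "causal_beta")
  expect_true(all(abs(td$estimate - truth) < 4 * td$std_error))
  expect_false(is.na(td$q_statistic[td$method == "ivw_re"]))
})

test_that("estimators are scale- and sign-equivariant, Q permutation-invariant", {
  rec <- random_mr_records(12, 8)
  base <- mr_ivw(rec)
  scaled <- dplyr::mutate(rec, Gamma = Gamma * 3, sigma_y = sigma_y * 3)
  est_s <- mr_ivw(scaled)
  expect_equal(est_s$beta_hat, 3 * base$beta_hat, tolerance = 1e-12)
  expect_equal(est_s$se, 3 * base$se, tolerance = 1e-12)

  neg <- dplyr::mutate(rec, Gamma = -Gamma)
  expect_equal(mr_ivw(neg)$beta_hat, -base$beta_hat, tolerance = 1e-12)
  eg <- mr_egger(rec)
  eg_n <- mr_egger(neg)
  expect_equal(eg_n$beta_hat, -eg$beta_hat, tolerance = 1e-12)
  expect_equal(eg_n$intercept$pvalue, eg$intercept$pvalue, tolerance = 1e-12)

  perm <- rec[sample(nrow(rec)), ]
  expect_equal(mr_ivw(perm)$cochran_q$statistic, base$cochran_q$statistic,
    tolerance = 1e-12
  )

  wm <- mr_weighted_median(rec, n_boot = 50, seed = 3)
  wm_s <- mr_weighted_median(scaled, n_boot = 50, seed = 3)
  expect_equal(wm_s$beta_hat, 3 * wm$beta_hat, tolerance = 1e-12)
})

test_that("confidence bounds bracket the estimate at 1.96 standard errors", {
  for (seed in 1:5) {
    est <- mr_ivw(random_mr_records(10, seed))
    expect_lt(est$ci_low, est$beta_hat)
    expect_gt(est$ci_high, est$beta_hat)
    expect_equal(est$ci_high - est$beta_hat, qnorm(0.975) * est$se, tolerance = 1e-12)
  }
})
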