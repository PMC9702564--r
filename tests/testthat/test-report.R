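test_that("Bonferroni threshold arithmetic and domain errors", {
  expect_equal(bonferroni_threshold(3, 4), 0.05 / 12, tolerance = 1e-12)
  expect_equal(round(bonferroni_threshold(3, 4), 3), 0.004)
  expect_equal(bonferroni_threshold(1, 1), 0.05)
  expect_equal(bonferroni_threshold(2, 5, 0.1), 0.01)
  expect_error(bonferroni_threshold(0, 4), class = "mrpipe_domain_error")
})

test_that("odds-ratio conversion exponentiates the estimate and its CI", {
  est0 <- mr_wald_ratio(tibble::tibble(
    variant_id = "s", gamma = 0.1, sigma_x = 0.001, Gamma = 0, sigma_y = 0.01
  ))
  or0 <- to_odds_ratio(est0)
  expect_equal(or0$or, 1)
  expect_equal(or0$ci_low * or0$ci_high, 1, tolerance = 1e-12)

  est <- structure(
    list(beta_hat = -0.2231, se = 0.05),
    class = "mr_estimate"
  )
  or <- to_odds_ratio(est)
  expect_equal(or$or, 0.800, tolerance = 1e-3)
  expect_equal(or$ci_low, 0.725, tolerance = 1e-3)
  expect_equal(or$ci_high, 0.883, tolerance = 1e-3)

  est_neg <- structure(list(beta_hat = 0.2231, se = 0.05), class = "mr_estimate")
  expect_equal(to_odds_ratio(est)$or * to_odds_ratio(est_neg)$or, 1, tolerance = 1e-12)
})

test_that("report rows satisfy the significance ordering invariant", {
  sim <- simulate_two_sample(scenario_preset("afb_like", seed = 2))
  res <- mr_all(sim_instrument_data(sim), n_boot = 100)
  rows <- report_rows(res, "AFB", "overall_oa",
    mean_f = 36,
    p_bonferroni = 0.05 / 12
  )
  expect_true(all(rows$CI_low < rows$OR & rows$OR < rows$CI_high))
  expect_true(all(!rows$significant_bonferroni | rows$significant_nominal))
  expect_lte(sum(rows$significant_bonferroni), sum(rows$significant_nominal))
})

grid_config <- function(seed = 1) {
  # a 3-exposure x 4-outcome grid built from three simulated scenarios whose
  # variants are disjoint; every outcome table carries all three variant sets
  relabel <- function(tbl, prefix) {
    tbl <- tibble::as_tibble(tbl)
    tbl$variant_id <- paste0(prefix, tbl$variant_id)
    tbl
  }
  sims <- lapply(1:3, function(i) {
    simulate_two_sample(sim_config(
      n_instruments = 8, n_null_snps = 20, n_exposure = 2e5, n_outcome = 3e5,
      causal_beta = c(-0.2, 0, 0.1)[i], gamma_mean = 0.025, gamma_sd = 0.003,
      seed = seed + i
    ))
  })
  exposures <- setNames(
    lapply(1:3, function(i) relabel(sims[[i]]$exposure, paste0("e", i, "_"))),
    c("E1", "E2", "E3")
  )
  shared_outcome <- dplyr::bind_rows(
    lapply(1:3, function(i) relabel(sims[[i]]$outcome, paste0("e", i, "_")))
  )
  outcomes <- setNames(
    rep(list(shared_outcome), 4),
    c("O1", "O2", "O3", "O4")
  )
  mr_config(
    exposures = exposures, outcomes = outcomes,
    p_instrument = 5e-8, n_boot = 20, n_sim = 50, seed = seed
  )
}

test_that("a 3x4 grid yields 12 primary rows flagged at alpha/12", {
  res <- run_mr_pipeline(grid_config(seed = 101))
  ivw <- res$results[res$results$method == "ivw_re", ]
  expect_equal(nrow(ivw), 12)
  expect_equal(res$p_bonferroni, 0.05 / 12, tolerance = 1e-12)
  expect_true(all(ivw$significant_bonferroni == (ivw$pvalue < 0.05 / 12)))
  expect_equal(nrow(forest_table(ivw, methods = "ivw_re")), 12)
})

test_that("the pipeline runs an exposure-by-outcome grid deterministically", {
  sim <- simulate_two_sample(scenario_preset("afb_like", seed = 6))
  cfg <- mr_config(
    exposures = list(AFB = sim$exposure),
    outcomes = list(overall_oa = sim$outcome),
    ld = sim$ld, n_boot = 50, n_sim = 100, seed = 7
  )
  res <- run_mr_pipeline(cfg)
  expect_s3_class(res$results, "tbl_df")
  expect_setequal(
    res$results$method,
    c("ivw_re", "egger", "weighted_median", "weighted_mode")
  )
  expect_equal(unique(res$results$exposure), "AFB")
  # the genome-wide screen keeps at most the 10 planted instruments; a few
  # borderline ones (true z near the threshold) are lost to sampling noise
  expect_true(all(res$results$n_snp <= 10 & res$results$n_snp >= 5))
  expect_equal(res$p_bonferroni, 0.05)
  expect_false(is.null(res$diagnostics[["AFB -> overall_oa"]]$presso))

  # same config, same seed: identical outputs (to the byte, via the TSV)
  res2 <- run_mr_pipeline(cfg)
  p1 <- tempfile()
  p2 <- tempfile()
  write_results(dplyr::rename(res$results, mean_F = mean_F), p1)
  write_results(res2$results, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("confounder pruning appends rows with fewer or equal instruments", {
  sim <- simulate_two_sample(scenario_preset("confounded_bmi", seed = 19))
  cfg <- mr_config(
    exposures = list(AFB = sim$exposure),
    outcomes = list(hip_knee_oa = sim$outcome),
    confounders = list(BMI = sim$confounder),
    ld = sim$ld, n_boot = 50, n_sim = 100, seed = 3
  )
  res <- run_mr_pipeline(cfg)
  primary <- res$results[res$results$exposure == "AFB", ]
  pruned <- res$results[res$results$exposure == "AFB no BMI", ]
  expect_gt(nrow(pruned), 0)
  expect_true(all(pruned$n_snp <= max(primary$n_snp)))
  # pruning the confounded instruments moves the IVW estimate materially
  or_raw <- primary$OR[primary$method == "ivw_re"]
  or_pruned <- pruned$OR[pruned$method == "ivw_re"]
  expect_gt(abs(log(or_raw) - log(or_pruned)), 0.02)
  # and the pruned estimate is closer to the simulated truth
  truth <- attr(sim$truth, "causal_beta")
  expect_lt(abs(log(or_pruned) - truth), abs(log(or_raw) - truth))
})

test_that("forest tables group rows, mark significance, and plots render", {
  sim <- simulate_two_sample(scenario_preset("afb_like", seed = 23))
  res <- mr_all(sim_instrument_data(sim), n_boot = 50)
  rows <- dplyr::bind_rows(
    report_rows(res, "AFB", "overall_oa", p_bonferroni = 0.004),
    report_rows(res, "AFB", "knee_oa", p_bonferroni = 0.004)
  )
  ft <- forest_table(rows, methods = "ivw_re")
  expect_equal(nrow(ft), 2)
  expect_true(all(ft$marker %in% c("", "*", "**")))
  wide <- ft[ft$CI_low < 1 & ft$CI_high > 1, ]
  expect_true(all(wide$marker == ""))

  p <- plot_forest(rows, methods = "ivw_re")
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(funnel_data(res$data)), "ggplot")
  expect_s3_class(autoplot(mr_leave_one_out(res$data)), "ggplot")
})

test_that("configs validate and round-trip through YAML", {
  expect_error(
    mr_config(exposures = list(tibble::tibble()), outcomes = list(a = 1)),
    class = "mrpipe_config_error"
  )
  dir <- tempfile()
  dir.create(dir)
  exp_path <- file.path(dir, "exp.tsv")
  readr::write_tsv(tiny_sumstats(), exp_path)
  out_path <- file.path(dir, "out.tsv")
  readr::write_tsv(tiny_sumstats(), out_path)
  yml <- file.path(dir, "config.yaml")
  writeLines(c(
    "exposures:",
    paste0("  E: {path: ", exp_path, "}"),
    "outcomes:",
    paste0("  O: {path: ", out_path, "}"),
    "p_instrument: 1.0e-6",
    "seed: 5"
  ), yml)
  cfg <- read_mr_config(yml)
  expect_s3_class(cfg, "mr_config")
  expect_equal(cfg$p_instrument, 1e-6)
  expect_equal(cfg$seed, 5L)
})
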