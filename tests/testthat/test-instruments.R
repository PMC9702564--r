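test_that("genome-wide screen keeps exactly the sub-threshold records in p order", {
  df <- tiny_sumstats()
  df$pvalue <- c(1e-9, 4e-8, 6e-8)
  tbl <- as_sumstats(df, "x", "exposure", quiet = TRUE)
  sel <- select_genome_wide(tbl)
  expect_equal(sel$variant_id, c("rs1", "rs2"))

  df$pvalue <- rep(0.5, 3)
  expect_equal(
    nrow(select_genome_wide(as_sumstats(df, "x", "exposure", quiet = TRUE), quiet = TRUE)),
    0
  )
})

test_that("screen recovers roughly the planted instruments among many nulls", {
  # oracle: direct count of p-values below threshold in the generated table
  sim <- simulate_two_sample(sim_config(
    n_instruments = 15, n_null_snps = 1000,
    gamma_mean = 0.03, gamma_sd = 0.003, seed = 7
  ))
  sel <- select_genome_wide(sim$exposure, quiet = TRUE)
  expect_equal(nrow(sel), sum(sim$exposure$pvalue < 5e-8))
  # z near 8 for gamma_mean 0.03 at n = 251k: nearly all planted SNPs pass
  expect_gte(nrow(sel), 12)
  expect_lte(nrow(sel), 18)
})

test_that("clumping follows the greedy smallest-p rule", {
  cand <- tibble::tibble(
    variant_id = c("s1", "s2", "s3"),
    pvalue = c(1e-12, 1e-10, 1e-9)
  )
  ld <- ld_table(tibble::tibble(a = "s1", b = "s2", r2 = 0.5))
  kept <- clump_variants(cand, ld)
  expect_setequal(kept$variant_id, c("s1", "s3"))

  # independent pairs: identity
  ld0 <- ld_table(tibble::tibble(a = character(), b = character(), r2 = numeric()))
  expect_equal(nrow(clump_variants(cand, ld0)), 3)
})

test_that("clumping matches a brute-force oracle and ignores input order", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 50
    cand <- tibble::tibble(
      variant_id = sprintf("c%02d", 1:n),
      pvalue = runif(n, 1e-12, 1e-6)
    )
    pair_idx <- t(combn(n, 2))
    take <- sample(nrow(pair_idx), 120)
    pairs <- tibble::tibble(
      a = cand$variant_id[pair_idx[take, 1]],
      b = cand$variant_id[pair_idx[take, 2]],
      r2 = runif(120)
    )
    ld <- ld_table(pairs)
    kept <- clump_variants(cand, ld, r2_threshold = 0.01)
    expect_equal(sort(kept$variant_id), clump_oracle(cand, pairs, 0.01))
    shuffled <- cand[sample(n), ]
    expect_equal(
      sort(clump_variants(shuffled, ld, r2_threshold = 0.01)$variant_id),
      sort(kept$variant_id)
    )
  }
})

test_that("strength formula matches its printed form, worked value and simplification", {
  s <- compute_strength(0.1, 0.02, 0.3, 1e4)
  expect_equal(s$r2_explained, 0.01 / (0.01 + 0.02^2 * 1e4), tolerance = 1e-12)
  expect_equal(s$f_stat, 25.0, tolerance = 1e-2)
  # F ~ (beta/se)^2 for small R^2
  expect_equal(s$f_stat, (0.1 / 0.02)^2, tolerance = 2e-3)

  # printed form == simplified beta^2 / (beta^2 + se^2 n) to 1e-12
  set.seed(11)
  for (i in 1:200) {
    beta <- rnorm(1, 0, 0.2)
    se <- runif(1, 1e-4, 0.1)
    eaf <- runif(1, 0.01, 0.99)
    n <- sample(100:1e6, 1)
    got <- compute_strength(beta, se, eaf, n)
    expect_equal(got$r2_explained, beta^2 / (beta^2 + se^2 * n), tolerance = 1e-12)
  }

  expect_equal(compute_strength(0, 0.02, 0.3, 1e4)$f_stat, 0)
  expect_equal(
    compute_strength(0.1, 0.02, 0.3, 1e4),
    compute_strength(0.1, 0.02, 0.7, 1e4)
  )
  expect_error(compute_strength(0.1, 0.02, 0.3, 2), class = "mrpipe_domain_error")
})

test_that("F is monotone in |beta|, n and 1/se", {
  base <- compute_strength(0.1, 0.02, 0.3, 1e4)$f_stat
  expect_gt(compute_strength(0.15, 0.02, 0.3, 1e4)$f_stat, base)
  expect_gt(compute_strength(0.1, 0.02, 0.3, 2e4)$f_stat, base)
  expect_lt(compute_strength(0.1, 0.04, 0.3, 1e4)$f_stat, base)
})

test_that("weak-instrument filtering splits at F = 10 and recomputes mean F", {
  instr <- tibble::tibble(
    variant_id = c("a", "b", "c"),
    f_stat = c(25, 9.9, 40), r2_explained = c(0.001, 0.0005, 0.002)
  )
  set <- filter_weak(instr, exposure_name = "x")
  expect_equal(nrow(set$retained), 2)
  expect_equal(set$mean_f, 32.5)
  expect_equal(set$excluded$excluded_reason, "weak_instrument")
  # partition is conserved
  expect_equal(nrow(set$retained) + nrow(set$excluded), nrow(instr))

  all_strong <- filter_weak(dplyr::mutate(instr, f_stat = c(25, 11, 40)),
    exposure_name = "x"
  )
  expect_equal(nrow(all_strong$retained), 3)
})

test_that("proxy search takes the strongest-LD proxy with stated tie-breaks", {
  out <- tiny_sumstats()
  out$variant_id <- c("p1", "p2", "p3")
  out <- as_sumstats(out, "oa", "outcome", quiet = TRUE)
  ld <- ld_table(tibble::tibble(
    a = c("miss", "miss"), b = c("p1", "p2"), r2 = c(0.85, 0.95)
  ))
  expect_equal(find_proxy("miss", out, ld)$variant_id, "p2")

  weak <- ld_table(tibble::tibble(a = "miss", b = "p1", r2 = 0.7))
  expect_null(find_proxy("miss", out, weak))

  tied <- ld_table(tibble::tibble(
    a = c("miss", "miss"), b = c("p1", "p2"), r2 = c(0.9, 0.9)
  ))
  out2 <- tibble::as_tibble(out)
  out2$pvalue <- c(1e-2, 1e-4, 0.5)
  expect_equal(find_proxy("miss", out2, tied)$variant_id, "p2")
})

test_that("confounder pruning excludes associated SNPs and keeps absent ones", {
  instr <- add_strength(tiny_sumstats())
  set <- filter_weak(instr, f_min = 0, exposure_name = "x")
  conf <- tibble::tibble(
    variant_id = c("rs1", "rs9"), chrom = "1", pos = 1L,
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = 0.1, se = 0.01, pvalue = c(1e-9, 1e-9), n = 5e5
  )
  pruned <- prune_confounder(set, as_sumstats(conf, "bmi", "confounder", quiet = TRUE))
  expect_false("rs1" %in% pruned$retained$variant_id)
  expect_true(all(c("rs2", "rs3") %in% pruned$retained$variant_id))
  expect_equal(
    pruned$excluded$excluded_reason[pruned$excluded$variant_id == "rs1"],
    "confounder_associated"
  )
  expect_equal(nrow(pruned$retained) + nrow(pruned$excluded), 3)
})

test_that("pruning two confounded instruments from ten leaves eight", {
  sim <- simulate_two_sample(scenario_preset("confounded_bmi", seed = 5))
  instr <- tibble::as_tibble(sim$exposure)[sim$truth$is_instrument, ]
  set <- filter_weak(add_strength(instr), f_min = 0, exposure_name = "afb")
  pruned <- prune_confounder(set, sim$confounder)
  expect_equal(nrow(set$retained), 10)
  expect_equal(nrow(pruned$retained), 8)
})
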