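# Synthetic two-sample GWAS generator with known ground truth. Trait
# variances are normalized to 1, so the per-variant sampling variance is
# 1 / (2 f (1-f) N) and the analytic R^2 / F formulas hold in expectation.

NON_PALINDROMIC_PAIRS <- matrix(
  c(
    "A", "C", "A", "G", "C", "A", "C", "T",
    "G", "A", "G", "T", "T", "C", "T", "G"
  ),
  ncol = 2, byrow = TRUE
)
PALINDROMIC_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
  ncol = 2, byrow = TRUE
)

#' Configuration for the two-sample summary-statistics generator
#'
#' @param n_instruments True instruments (non-zero exposure effect).
#' @param n_null_snps Null variants (zero effect), organised into LD blocks
#'   so clumping is exercised.
#' @param n_exposure,n_outcome GWAS sample sizes of the two (non-overlapping)
#'   samples.
#' @param causal_beta True causal effect of the exposure on the outcome
#'   (log-odds per exposure unit for a case-control outcome).
#' @param gamma_mean,gamma_sd Mean and SD of the absolute true instrument
#'   effects (trait-SD units per allele); signs are random.
#' @param eaf_min,eaf_max Uniform bounds for effect-allele frequencies.
#' @param pleiotropy One of `"none"`, `"balanced"`, `"directional"`,
#'   `"confounded"`.
#' @param mu_alpha,tau_alpha Mean and SD of the direct (pleiotropic) outcome
#'   effects of invalid instruments.
#' @param prop_invalid Fraction of instruments with a pleiotropic path.
#' @param confounder_beta_x,confounder_beta_y Shared-confounder path
#'   coefficients: the confounder's effect on exposure and its direct effect
#'   on outcome (used when `pleiotropy = "confounded"`).
#' @param n_confounder Sample size of the confounder GWAS.
#' @param palindrome_fraction Fraction of instruments given A/T or G/C
#'   alleles.
#' @param missing_in_outcome_fraction Fraction of instruments absent from the
#'   outcome GWAS.
#' @param proxy_fraction Fraction of the missing instruments for which an LD
#'   proxy (r-squared 0.9) is present in the outcome.
#' @param n_outliers,outlier_sigma Number of instruments given an additional
#'   direct outcome effect of `outlier_sigma` outcome standard errors
#'   (pleiotropic outliers for the PRESSO tests).
#' @param ld_block_size,ld_block_r2 Size and within-block r-squared of the
#'   null-variant LD blocks.
#' @param seed Integer seed; generation is byte-identical under it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_instruments = 10, n_null_snps = 500,
                       n_exposure = 251151, n_outcome = 450000,
                       causal_beta = log(0.80),
                       gamma_mean = 0.019, gamma_sd = 0.003,
                       eaf_min = 0.1, eaf_max = 0.9,
                       pleiotropy = c("none", "balanced", "directional", "confounded"),
                       mu_alpha = 0, tau_alpha = 0, prop_invalid = 0,
                       confounder_beta_x = 0.4, confounder_beta_y = 0.3,
                       n_confounder = 806834,
                       palindrome_fraction = 0, missing_in_outcome_fraction = 0,
                       proxy_fraction = 0.5,
                       n_outliers = 0, outlier_sigma = 10,
                       ld_block_size = 5, ld_block_r2 = 0.5,
                       seed = 1) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(
    n_instruments >= 1, n_null_snps >= 0,
    n_exposure > 2, n_outcome > 2,
    gamma_mean > 0, gamma_sd >= 0, tau_alpha >= 0,
    eaf_min > 0.05 - 1e-9, eaf_max < 0.95 + 1e-9, eaf_min < eaf_max,
    prop_invalid >= 0, prop_invalid <= 1,
    palindrome_fraction >= 0, palindrome_fraction <= 1,
    missing_in_outcome_fraction >= 0, missing_in_outcome_fraction <= 1,
    proxy_fraction >= 0, proxy_fraction <= 1,
    n_outliers >= 0, ld_block_size >= 2,
    ld_block_r2 >= 0, ld_block_r2 <= 1
  )
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("A single integer seed is required", class = "mrpipe_config_error")
  }
  structure(
    list(
      n_instruments = as.integer(n_instruments),
      n_null_snps = as.integer(n_null_snps),
      n_exposure = n_exposure, n_outcome = n_outcome,
      causal_beta = causal_beta,
      gamma_mean = gamma_mean, gamma_sd = gamma_sd,
      eaf_min = eaf_min, eaf_max = eaf_max,
      pleiotropy = pleiotropy, mu_alpha = mu_alpha, tau_alpha = tau_alpha,
      prop_invalid = prop_invalid,
      confounder_beta_x = confounder_beta_x,
      confounder_beta_y = confounder_beta_y,
      n_confounder = n_confounder,
      palindrome_fraction = palindrome_fraction,
      missing_in_outcome_fraction = missing_in_outcome_fraction,
      proxy_fraction = proxy_fraction,
      n_outliers = as.integer(n_outliers), outlier_sigma = outlier_sigma,
      ld_block_size = as.integer(ld_block_size), ld_block_r2 = ld_block_r2,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Preset simulation scenarios
#'
#' Fully specified configurations mirroring the scale of the pipeline's
#' motivating analyses of hormonal reproductive exposures on osteoarthritis
#' risk:
#' * `afb_like` - 10 instruments at the age-at-first-birth GWAS scale
#'   (n = 251,151), true odds ratio 0.80 per year, mean F near 36.
#' * `aam_like` - 349 instruments at the age-at-menarche scale
#'   (n = 329,345, mean F near 64), with palindromic and outcome-missing
#'   instruments injected so harmonization sheds a handful of SNPs.
#' * `anm_like` - 54 instruments at the age-at-natural-menopause scale
#'   (n = 69,360, mean F near 68), null causal effect.
#' * `confounded_bmi` - the afb_like scenario with 2 of 10 instruments
#'   acting through a BMI-like shared confounder (and a confounder GWAS,
#'   n = 806,834, in which they reach genome-wide significance), so that
#'   confounder pruning materially changes the IVW estimate.
#' * `directional_pleiotropy` - 20 instruments, 30% with strong directional
#'   pleiotropy, for robust-estimator comparisons.
#' * `outlier_injection` - 20 instruments with one 10-sigma pleiotropic
#'   outlier, for the PRESSO outlier test.
#'
#' @param name Preset name.
#' @param seed Seed stored in the returned configuration.
#' @return A `sim_config`.
#' @export
scenario_preset <- function(name, seed = 1) {
  presets <- list(
    afb_like = function() {
      sim_config(
        n_instruments = 10, n_null_snps = 500,
        n_exposure = 251151, n_outcome = 450000,
        causal_beta = log(0.80), gamma_mean = 0.019, gamma_sd = 0.003,
        seed = seed
      )
    },
    aam_like = function() {
      sim_config(
        n_instruments = 349, n_null_snps = 500,
        n_exposure = 329345, n_outcome = 450000,
        causal_beta = log(0.91), gamma_mean = 0.025, gamma_sd = 0.005,
        palindrome_fraction = 0.06, missing_in_outcome_fraction = 0.02,
        proxy_fraction = 0.5, seed = seed
      )
    },
    anm_like = function() {
      sim_config(
        n_instruments = 54, n_null_snps = 500,
        n_exposure = 69360, n_outcome = 450000,
        causal_beta = 0, gamma_mean = 0.049, gamma_sd = 0.008,
        seed = seed
      )
    },
    confounded_bmi = function() {
      sim_config(
        n_instruments = 10, n_null_snps = 500,
        n_exposure = 251151, n_outcome = 450000,
        causal_beta = log(0.80), gamma_mean = 0.019, gamma_sd = 0.003,
        pleiotropy = "confounded", prop_invalid = 0.2,
        confounder_beta_x = 0.4, confounder_beta_y = 0.3,
        n_confounder = 806834, seed = seed
      )
    },
    directional_pleiotropy = function() {
      sim_config(
        n_instruments = 20, n_null_snps = 200,
        n_exposure = 251151, n_outcome = 450000,
        causal_beta = log(0.80), gamma_mean = 0.019, gamma_sd = 0.003,
        pleiotropy = "directional", prop_invalid = 0.3,
        mu_alpha = 0.02, tau_alpha = 0.004, seed = seed
      )
    },
    outlier_injection = function() {
      sim_config(
        n_instruments = 20, n_null_snps = 200,
        n_exposure = 251151, n_outcome = 450000,
        causal_beta = log(0.80), gamma_mean = 0.019, gamma_sd = 0.003,
        n_outliers = 1, outlier_sigma = 10, seed = seed
      )
    }
  )
  if (!name %in% names(presets)) {
    abort(paste0(
      "Unknown preset '", name, "'. Available: ",
      paste(names(presets), collapse = ", ")
    ), class = "mrpipe_config_error")
  }
  presets[[name]]()
}

draw_alleles <- function(n_pal, n_total) {
  idx_np <- sample.int(nrow(NON_PALINDROMIC_PAIRS), n_total - n_pal, replace = TRUE)
  idx_p <- sample.int(nrow(PALINDROMIC_PAIRS), n_pal, replace = TRUE)
  ea <- c(PALINDROMIC_PAIRS[idx_p, 1], NON_PALINDROMIC_PAIRS[idx_np, 1])
  oa <- c(PALINDROMIC_PAIRS[idx_p, 2], NON_PALINDROMIC_PAIRS[idx_np, 2])
  list(ea = ea, oa = oa, palindrome = c(rep(TRUE, n_pal), rep(FALSE, n_total - n_pal)))
}

pvalue_from_z <- function(z) pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Draws, per variant: an effect-allele frequency; a true exposure effect
#' (zero for nulls); a true outcome effect `causal_beta * gamma + alpha`
#' (plus a shared-confounder path for confounded instruments); and
#' independent sampling noise in each sample with variance
#' `1 / (2 f (1-f) N)`. Palindromic alleles, outcome missingness with LD
#' proxies, outcome-side allele/strand re-labelling, LD-correlated null
#' blocks, and pleiotropic outliers are injected per the configuration.
#'
#' @param cfg A `sim_config` (see [sim_config()], [scenario_preset()]).
#' @return A list: `exposure`, `outcome`, `confounder` (`sumstats`; the
#'   confounder only for the confounded scenario), `ld` (`ld_table`), and
#'   `truth` (tibble of per-variant ground-truth parameters plus the
#'   scenario's `causal_beta` attribute).
#' @export
simulate_two_sample <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  n_i <- cfg$n_instruments
  n_0 <- cfg$n_null_snps
  n <- n_i + n_0
  id <- sprintf("rs%05d", seq_len(n))
  is_instrument <- c(rep(TRUE, n_i), rep(FALSE, n_0))
  eaf <- runif(n, cfg$eaf_min, cfg$eaf_max)
  var_g <- 2 * eaf * (1 - eaf)
  sigma_x <- 1 / sqrt(var_g * cfg$n_exposure)
  sigma_y <- 1 / sqrt(var_g * cfg$n_outcome)

  # instruments are coded on the exposure-increasing allele (the standard
  # summary-statistic convention); directional pleiotropy is then a
  # consistent-sign shift of the per-SNP ratio estimates
  gamma_true <- numeric(n)
  gamma_true[is_instrument] <- abs(rnorm(n_i, cfg$gamma_mean, cfg$gamma_sd))

  # pleiotropic direct effects
  alpha <- numeric(n)
  lambda <- numeric(n)
  n_invalid <- round(cfg$prop_invalid * n_i)
  invalid <- rep(FALSE, n)
  if (n_invalid > 0) {
    inv_idx <- sample(seq_len(n_i), n_invalid)
    invalid[inv_idx] <- TRUE
    if (cfg$pleiotropy == "balanced") {
      alpha[inv_idx] <- rnorm(n_invalid, 0, cfg$tau_alpha)
    } else if (cfg$pleiotropy == "directional") {
      alpha[inv_idx] <- rnorm(n_invalid, cfg$mu_alpha, cfg$tau_alpha)
    } else if (cfg$pleiotropy == "confounded") {
      # the confounded SNPs act on a shared confounder, strongly enough to
      # reach genome-wide significance in the confounder GWAS
      sigma_c <- 1 / sqrt(var_g[inv_idx] * cfg$n_confounder)
      lambda[inv_idx] <- rnorm(n_invalid, 10, 1) * sigma_c *
        sample(c(-1, 1), n_invalid, replace = TRUE)
    }
  }
  gamma_total <- gamma_true + cfg$confounder_beta_x * lambda
  Gamma_true <- cfg$causal_beta * gamma_total + alpha +
    cfg$confounder_beta_y * lambda

  outlier <- rep(FALSE, n)
  if (cfg$n_outliers > 0) {
    out_idx <- setdiff(seq_len(n_i), which(invalid))[seq_len(cfg$n_outliers)]
    outlier[out_idx] <- TRUE
    Gamma_true[out_idx] <- Gamma_true[out_idx] + cfg$outlier_sigma * sigma_y[out_idx]
  }

  gamma_hat <- rnorm(n, gamma_total, sigma_x)
  Gamma_hat <- rnorm(n, Gamma_true, sigma_y)

  n_pal <- round(cfg$palindrome_fraction * n_i)
  al_i <- draw_alleles(n_pal, n_i)
  al_0 <- draw_alleles(0, max(n_0, 0))
  ea <- c(al_i$ea, al_0$ea)
  oa <- c(al_i$oa, al_0$oa)
  palindrome <- c(al_i$palindrome, al_0$palindrome)

  chrom <- as.character(sample.int(22, n, replace = TRUE))
  pos <- sample.int(2.5e8, n, replace = TRUE)

  exposure <- tibble(
    variant_id = id, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = gamma_hat, se = sigma_x,
    pvalue = pvalue_from_z(gamma_hat / sigma_x), n = cfg$n_exposure
  )

  # outcome side: random allele/strand re-labelling per SNP
  rep_form <- sample.int(4, n, replace = TRUE) # 1 same, 2 swap, 3 comp, 4 comp+swap
  swap <- rep_form %in% c(2, 4)
  comp <- rep_form %in% c(3, 4)
  ea_y <- ifelse(swap, oa, ea)
  oa_y <- ifelse(swap, ea, oa)
  ea_y <- ifelse(comp, allele_complement(ea_y), ea_y)
  oa_y <- ifelse(comp, allele_complement(oa_y), oa_y)
  beta_y <- ifelse(swap, -Gamma_hat, Gamma_hat)
  eaf_y <- ifelse(swap, 1 - eaf, eaf)

  outcome <- tibble(
    variant_id = id, chrom = chrom, pos = pos,
    effect_allele = ea_y, other_allele = oa_y, eaf = eaf_y,
    beta = beta_y, se = sigma_y,
    pvalue = pvalue_from_z(beta_y / sigma_y), n = cfg$n_outcome
  )

  # outcome missingness and LD proxies
  n_missing <- round(cfg$missing_in_outcome_fraction * n_i)
  missing <- rep(FALSE, n)
  proxy_id <- rep(NA_character_, n)
  ld_entries <- list()
  if (n_missing > 0) {
    miss_idx <- sample(seq_len(n_i), n_missing)
    missing[miss_idx] <- TRUE
    n_proxy <- round(cfg$proxy_fraction * n_missing)
    proxy_idx <- miss_idx[seq_len(n_proxy)]
    if (n_proxy > 0) {
      r <- sqrt(0.9)
      proxy_rows <- outcome[proxy_idx, ]
      proxy_rows$variant_id <- paste0(id[proxy_idx], "_p")
      # a proxy tags the causal variant at r^2 = 0.9: its effect attenuates
      # by r, with its own sampling noise
      proxy_rows$beta <- rnorm(
        n_proxy, r * ifelse(swap[proxy_idx], -Gamma_true[proxy_idx], Gamma_true[proxy_idx]),
        sigma_y[proxy_idx]
      )
      proxy_rows$pvalue <- pvalue_from_z(proxy_rows$beta / proxy_rows$se)
      proxy_id[proxy_idx] <- proxy_rows$variant_id
      ld_entries[["proxy"]] <- tibble(
        a = id[proxy_idx], b = proxy_rows$variant_id, r2 = 0.9
      )
      outcome <- bind_rows(outcome, proxy_rows)
    }
    outcome <- outcome[!outcome$variant_id %in% id[miss_idx], ]
  }

  # LD blocks among null SNPs
  if (n_0 >= cfg$ld_block_size && cfg$ld_block_r2 > 0) {
    null_ids <- id[!is_instrument]
    k <- cfg$ld_block_size
    n_blocks <- length(null_ids) %/% k
    cmb <- utils::combn(k, 2)
    offset <- rep((seq_len(n_blocks) - 1) * k, each = ncol(cmb))
    ld_entries[["blocks"]] <- tibble(
      a = null_ids[offset + rep(cmb[1, ], n_blocks)],
      b = null_ids[offset + rep(cmb[2, ], n_blocks)],
      r2 = cfg$ld_block_r2
    )
  }
  ld <- if (length(ld_entries) > 0) {
    ld_table(bind_rows(ld_entries))
  } else {
    ld_table(tibble(a = character(), b = character(), r2 = numeric()))
  }

  confounder <- NULL
  if (cfg$pleiotropy == "confounded") {
    sigma_c <- 1 / sqrt(var_g * cfg$n_confounder)
    beta_c <- rnorm(n, lambda, sigma_c)
    confounder <- as_sumstats(
      tibble(
        variant_id = id, chrom = chrom, pos = pos,
        effect_allele = ea, other_allele = oa, eaf = eaf,
        beta = beta_c, se = sigma_c,
        pvalue = pvalue_from_z(beta_c / sigma_c), n = cfg$n_confounder
      ),
      trait_name = "confounder", trait_type = "confounder", quiet = TRUE
    )
  }

  truth <- tibble(
    variant_id = id, is_instrument = is_instrument,
    gamma = gamma_total, alpha = alpha, lambda = lambda,
    Gamma = Gamma_true, sigma_x = sigma_x, sigma_y = sigma_y,
    eaf = eaf, valid = is_instrument & !invalid & !outlier,
    invalid = invalid, outlier = outlier,
    palindrome = palindrome, missing_in_outcome = missing,
    proxy_id = proxy_id
  )
  attr(truth, "causal_beta") <- cfg$causal_beta

  list(
    exposure = as_sumstats(exposure,
      trait_name = "exposure", trait_type = "exposure", quiet = TRUE
    ),
    outcome = as_sumstats(outcome,
      trait_name = "outcome", trait_type = "outcome", quiet = TRUE
    ),
    confounder = confounder,
    ld = ld,
    truth = truth,
    config = cfg
  )
}

#' Harmonized data for a simulation's true instruments
#'
#' Convenience accessor used throughout the validation suite: harmonizes the
#' generated instruments (bypassing the significance screen, which would
#' superimpose winner's-curse selection effects on estimator checks) against
#' the simulated outcome.
#'
#' @param sim Output of [simulate_two_sample()].
#' @param ... Passed to [harmonize_set()].
#' @return An `mr_data`.
#' @export
sim_instrument_data <- function(sim, ...) {
  instr <- as_tibble(sim$exposure)[sim$truth$is_instrument[
    match(sim$exposure$variant_id, sim$truth$variant_id)
  ], ]
  harmonize_set(instr, sim$outcome, ld = sim$ld, ...)
}
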