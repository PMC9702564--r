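# Causal-effect estimators on harmonized two-sample summary data: per-SNP
# Wald ratios, inverse-variance weighted (fixed / multiplicative random
# effects), MR-Egger, weighted median and weighted mode.

Z95 <- stats::qnorm(0.975)

new_mr_estimate <- function(method, beta_hat, se, n_snp,
                            intercept = NULL, cochran_q = NULL,
                            n_boot = NULL, seed = NULL) {
  p <- 2 * pnorm(-abs(beta_hat / se))
  structure(
    list(
      method = method, beta_hat = beta_hat, se = se,
      ci_low = beta_hat - Z95 * se, ci_high = beta_hat + Z95 * se,
      pvalue = max(p, .Machine$double.xmin), n_snp = n_snp,
      intercept = intercept, cochran_q = cochran_q,
      n_boot = n_boot, seed = seed
    ),
    class = "mr_estimate"
  )
}

ratio_inputs <- function(data, require_nonzero_gamma = TRUE) {
  rec <- as_mr_records(data)
  if (require_nonzero_gamma && any(rec$gamma == 0)) {
    abort("Wald ratios are undefined where the exposure effect is exactly 0",
      class = "mrpipe_undefined_ratio_error"
    )
  }
  rec
}

check_n_snp <- function(n, minimum, method) {
  if (n < minimum) {
    abort(paste0(
      method, " requires at least ", minimum, " SNPs; got ", n
    ), class = "mrpipe_insufficient_instruments_error")
  }
}

#' Wald ratio estimate for a single variant
#'
#' The per-SNP causal estimate: outcome effect divided by exposure effect,
#' with first-order standard error `sigma_y / |gamma|` (exposure-side noise
#' ignored; the no-measurement-error approximation).
#'
#' @param rec A one-row harmonized record (columns `gamma`, `sigma_x`,
#'   `Gamma`, `sigma_y`), or an `mr_data` with a single record.
#' @return An `mr_estimate` with method `"wald"`.
#' @export
mr_wald_ratio <- function(rec) {
  rec <- ratio_inputs(rec)
  check_n_snp(nrow(rec), 1, "Wald ratio")
  rec <- rec[1, ]
  new_mr_estimate("wald", rec$Gamma / rec$gamma, rec$sigma_y / abs(rec$gamma), 1L)
}

#' Inverse-variance weighted estimate
#'
#' Combines per-SNP Wald ratios with weights `gamma^2 / sigma_y^2`,
#' equivalently a weighted regression of outcome on exposure effects through
#' the origin with weights `1 / sigma_y^2`. Under the default multiplicative
#' random-effects model the fixed-effect standard error is inflated by
#' `max(1, sqrt(Q / (n - 1)))` where Q is Cochran's heterogeneity statistic;
#' `model = "fixed"` reports the unscaled error. Q, its degrees of freedom
#' and chi-squared p-value are attached to the estimate.
#'
#' @param data Harmonized records (`mr_data` or data frame with `gamma`,
#'   `sigma_x`, `Gamma`, `sigma_y`).
#' @param model `"random"` (default) or `"fixed"`.
#' @return An `mr_estimate` with method `"ivw_re"` or `"ivw_fe"`.
#' @export
mr_ivw <- function(data, model = c("random", "fixed")) {
  model <- match.arg(model)
  rec <- ratio_inputs(data, require_nonzero_gamma = FALSE)
  n <- nrow(rec)
  check_n_snp(n, if (model == "random") 2 else 1, "IVW")
  w <- 1 / rec$sigma_y^2
  beta <- sum(w * rec$gamma * rec$Gamma) / sum(w * rec$gamma^2)
  se_fixed <- 1 / sqrt(sum(w * rec$gamma^2))
  q <- sum(w * (rec$Gamma - beta * rec$gamma)^2)
  q_df <- n - 1L
  cochran <- list(
    statistic = q, df = q_df,
    pvalue = if (q_df > 0) pchisq(q, q_df, lower.tail = FALSE) else NA_real_
  )
  se <- if (model == "random" && n >= 2) {
    se_fixed * max(1, sqrt(q / q_df))
  } else {
    se_fixed
  }
  new_mr_estimate(
    if (model == "random") "ivw_re" else "ivw_fe",
    beta, se, as.integer(n),
    cochran_q = cochran
  )
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with a
#' free intercept, weights `1 / sigma_y^2`, after orienting all exposure
#' effects non-negative (flipping the sign of both effects where needed).
#' The slope is the causal estimate; a non-zero intercept indicates
#' directional horizontal pleiotropy (valid under the InSIDE assumption,
#' instrument strength independent of direct effects). Standard errors carry
#' a multiplicative overdispersion factor floored at 1; p-values use normal
#' quantiles.
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate` with method `"egger"` and an `intercept`
#'   component (`estimate`, `se`, `pvalue`).
#' @export
mr_egger <- function(data) {
  rec <- ratio_inputs(data, require_nonzero_gamma = FALSE)
  n <- nrow(rec)
  check_n_snp(n, 3, "MR-Egger")
  flip <- sign(rec$gamma)
  flip[flip == 0] <- 1
  g <- rec$gamma * flip
  G <- rec$Gamma * flip
  w <- 1 / rec$sigma_y^2
  # weighted normal equations for [intercept, slope]
  sw <- sum(w)
  sx <- sum(w * g)
  sxx <- sum(w * g^2)
  sy <- sum(w * G)
  sxy <- sum(w * g * G)
  det <- sw * sxx - sx^2
  if (det <= .Machine$double.eps * sw * sxx) {
    abort("MR-Egger requires variation in the exposure effects",
      class = "mrpipe_degenerate_design_error"
    )
  }
  slope <- (sw * sxy - sx * sy) / det
  alpha <- (sxx * sy - sx * sxy) / det
  rss <- sum(w * (G - alpha - slope * g)^2)
  phi <- max(1, rss / (n - 2))
  se_slope <- sqrt(phi * sw / det)
  se_alpha <- sqrt(phi * sxx / det)
  new_mr_estimate(
    "egger", slope, se_slope, as.integer(n),
    intercept = list(
      estimate = alpha, se = se_alpha,
      pvalue = 2 * pnorm(-abs(alpha / se_alpha))
    )
  )
}

weighted_median_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) {
    return(b[1])
  }
  n <- length(b)
  if (0.5 >= s[n]) {
    return(b[n])
  }
  k <- max(which(s <= 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

boot_draws <- function(rec, n_boot, seed, statistic) {
  n <- nrow(rec)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    g_star <- matrix(rnorm(n * n_boot, rec$gamma, rec$sigma_x), nrow = n)
    G_star <- matrix(rnorm(n * n_boot, rec$Gamma, rec$sigma_y), nrow = n)
    vapply(seq_len(n_boot), function(i) {
      statistic(g_star[, i], G_star[, i])
    }, numeric(1))
  })
}

#' Weighted median estimate
#'
#' Orders the per-SNP Wald ratios and takes the value at which 50% of the
#' inverse-variance weight is accumulated, interpolating linearly between the
#' bracketing ratios at midpoint ranks. Consistent when at least half of the
#' total instrument weight comes from valid instruments. The standard error
#' is a seeded parametric bootstrap: exposure and outcome effects are
#' redrawn from their estimated sampling distributions and the weighted
#' median recomputed.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap replicates for the standard error (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = 1) {
  rec <- ratio_inputs(data)
  n <- nrow(rec)
  check_n_snp(n, 3, "Weighted median")
  w <- rec$gamma^2 / rec$sigma_y^2
  est <- weighted_median_point(rec$Gamma / rec$gamma, w)
  boots <- boot_draws(rec, n_boot, seed, function(g, G) {
    g[g == 0] <- .Machine$double.eps
    weighted_median_point(G / g, g^2 / rec$sigma_y^2)
  })
  new_mr_estimate("weighted_median", est, sd(boots), as.integer(n),
    n_boot = n_boot, seed = seed
  )
}

mode_bandwidth <- function(b, phi) {
  s <- sd(b)
  iqr <- stats::IQR(b)
  phi * 0.9 * min(s, iqr / 1.349) * length(b)^(-1 / 5)
}

weighted_mode_point <- function(b, w, phi = 1, grid_n = 512) {
  h <- mode_bandwidth(b, phi)
  if (!is.finite(h) || h <= 0) {
    return(b[which.max(w)])
  }
  w <- w / sum(w)
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = grid_n)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm((x - b) / h)) / h, numeric(1))
  grid[which.max(dens)]
}

#' Weighted mode estimate
#'
#' Takes the mode of the inverse-variance-weighted kernel-smoothed density of
#' the per-SNP Wald ratios (normal kernel; modified Silverman bandwidth
#' `phi * 0.9 * min(sd, IQR/1.349) * n^(-1/5)`), evaluated on a fine grid
#' spanning the ratios plus/minus three bandwidths. Consistent when the
#' largest group of instruments sharing a causal effect is valid. Standard
#' error by the same seeded parametric bootstrap as [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @param phi Bandwidth multiplier (default 1).
#' @return An `mr_estimate` with method `"weighted_mode"`.
#' @export
mr_weighted_mode <- function(data, phi = 1, n_boot = 1000, seed = 1) {
  rec <- ratio_inputs(data)
  n <- nrow(rec)
  check_n_snp(n, 3, "Weighted mode")
  w <- rec$gamma^2 / rec$sigma_y^2
  est <- weighted_mode_point(rec$Gamma / rec$gamma, w, phi = phi)
  boots <- boot_draws(rec, n_boot, seed, function(g, G) {
    g[g == 0] <- .Machine$double.eps
    weighted_mode_point(G / g, g^2 / rec$sigma_y^2, phi = phi)
  })
  new_mr_estimate("weighted_mode", est, sd(boots), as.integer(n),
    n_boot = n_boot, seed = seed
  )
}

#' Run all applicable MR estimators
#'
#' Applies the Wald ratio (single-SNP data), IVW, MR-Egger, weighted median
#' and weighted mode to harmonized data; methods whose minimum SNP count is
#' not met are reported as skipped rather than raising errors.
#'
#' @inheritParams mr_ivw
#' @param seed Integer seed for the bootstrap-based estimators.
#' @param ivw_model `"random"` or `"fixed"` (see [mr_ivw()]).
#' @param n_boot Bootstrap replicates.
#' @param phi Weighted-mode bandwidth multiplier.
#' @return An object of class `mr_result` holding the data, a list of
#'   `mr_estimate`s, and a tibble of skipped methods. Use [tidy()] for the
#'   estimate table and [autoplot()] for a scatter plot with fitted slopes.
#' @export
mr_all <- function(data, seed = 1, ivw_model = "random", n_boot = 1000, phi = 1) {
  rec <- as_mr_records(data)
  n <- nrow(rec)
  estimates <- list()
  skipped <- list()
  try_method <- function(label, min_n, fun) {
    if (n < min_n) {
      skipped[[label]] <<- tibble(
        method = label, reason = paste0("requires >= ", min_n, " SNPs (", n, " available)")
      )
    } else {
      estimates[[label]] <<- fun()
    }
  }
  if (n == 1) try_method("wald", 1, function() mr_wald_ratio(rec))
  # a single SNP still admits fixed-effect IVW (it reduces to the Wald ratio)
  try_method("ivw", 1, function() {
    mr_ivw(rec, model = if (n >= 2) ivw_model else "fixed")
  })
  try_method("egger", 3, function() mr_egger(rec))
  try_method("weighted_median", 3, function() mr_weighted_median(rec, n_boot = n_boot, seed = seed))
  try_method("weighted_mode", 3, function() mr_weighted_mode(rec, phi = phi, n_boot = n_boot, seed = seed))
  structure(
    list(
      data = if (inherits(data, "mr_data")) data else mr_data(rec),
      estimates = estimates,
      skipped = bind_rows(skipped)
    ),
    class = "mr_result"
  )
}

#' @method tidy mr_estimate
#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble(
    method = x$method, n_snp = x$n_snp,
    estimate = x$beta_hat, std_error = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$pvalue,
    intercept = x$intercept$estimate %||% NA_real_,
    intercept_se = x$intercept$se %||% NA_real_,
    intercept_p = x$intercept$pvalue %||% NA_real_,
    q_statistic = x$cochran_q$statistic %||% NA_real_,
    q_df = x$cochran_q$df %||% NA_integer_,
    q_p = x$cochran_q$pvalue %||% NA_real_
  )
}

#' @method glance mr_estimate
#' @export
glance.mr_estimate <- function(x, ...) {
  tibble(method = x$method, n_snp = x$n_snp, estimate = x$beta_hat, p_value = x$pvalue)
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat("<mr_estimate> ", x$method, ": beta = ",
    formatC(x$beta_hat, digits = 4, format = "fg"),
    " (SE ", formatC(x$se, digits = 4, format = "fg"),
    "), p = ", format(x$pvalue, digits = 3), ", nSNP = ", x$n_snp, "\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, ...) {
  bind_rows(lapply(x$estimates, tidy))
}

#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  ivw <- x$estimates[["ivw"]]
  tibble(
    exposure = x$data$exposure_name, outcome = x$data$outcome_name,
    n_snp = nrow(x$data$records),
    n_methods = length(x$estimates),
    ivw_estimate = ivw$beta_hat %||% NA_real_,
    ivw_p = ivw$pvalue %||% NA_real_,
    q_statistic = ivw$cochran_q$statistic %||% NA_real_,
    q_p = ivw$cochran_q$pvalue %||% NA_real_
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat("<mr_result> ", x$data$exposure_name, " -> ", x$data$outcome_name,
    " (", nrow(x$data$records), " SNPs)\n",
    sep = ""
  )
  print(tidy(x))
  invisible(x)
}
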