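# Pleiotropy and robustness diagnostics: MR-PRESSO global / outlier /
# distortion tests, leave-one-out influence analysis, and funnel-plot data.

loo_slopes <- function(g, G, w) {
  # leave-one-out IVW slopes via running totals: O(n) for all n slopes
  A <- sum(w * g * G)
  B <- sum(w * g^2)
  (A - w * g * G) / (B - w * g^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Resampling test for horizontal pleiotropy in the IVW regression. For each
#' SNP the leave-one-out IVW slope predicts its outcome effect; the weighted
#' residual sum of squares (RSS) over all SNPs is compared with its
#' distribution under `n_sim` parametric simulations (outcome effects redrawn
#' around the leave-one-out predictions, exposure effects around their
#' estimates) to give the global test p-value. Per-SNP observed weighted
#' squared residuals against their simulated distributions give the outlier
#' test, Bonferroni-corrected over SNPs. When outliers are flagged, the
#' distortion test compares the change in the IVW estimate after their
#' removal with the distribution of changes under random removal of equally
#' many SNPs.
#'
#' @inheritParams mr_ivw
#' @param n_sim Simulated datasets for the global/outlier tests (p-value
#'   resolution 1/(n_sim + 1)).
#' @param outlier_alpha Family-wise level for outlier flagging (Bonferroni
#'   over SNPs).
#' @param seed Integer seed; results are exactly reproducible under it.
#' @param n_distortion Random re-assignments for the distortion test.
#' @return An object of class `mr_presso`: `rss_observed`, `global_p`,
#'   `per_snp` (tibble of per-SNP statistics and p-values), `outliers`
#'   (variant ids), `beta_raw` and `beta_corrected` (`mr_estimate`s),
#'   `distortion_p` (`NA` when no outliers), `n_sim`, `seed`.
#' @export
mr_presso <- function(data, n_sim = 1000, outlier_alpha = 0.05, seed = 1,
                      n_distortion = 1000) {
  rec <- as_mr_records(data)
  n <- nrow(rec)
  check_n_snp(n, 4, "MR-PRESSO")
  w <- 1 / rec$sigma_y^2
  slopes <- loo_slopes(rec$gamma, rec$Gamma, w)
  resid <- rec$Gamma - slopes * rec$gamma
  t_obs <- w * resid^2
  rss_obs <- sum(t_obs)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  g_star <- matrix(rnorm(n * n_sim, rec$gamma, rec$sigma_x), nrow = n)
  G_star <- matrix(rnorm(n * n_sim, slopes * rec$gamma, rec$sigma_y), nrow = n)
  wg <- w * g_star
  A <- colSums(wg * G_star)
  B <- colSums(wg * g_star)
  slope_star <- (rep(A, each = n) - wg * G_star) /
    (rep(B, each = n) - wg * g_star)
  dim(slope_star) <- c(n, n_sim)
  r_star <- G_star - slope_star * g_star
  t_star <- w * r_star^2
  rss_star <- colSums(t_star)

  global_p <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)
  per_snp_p <- (1 + rowSums(t_star >= t_obs)) / (n_sim + 1)
  outlier_flag <- per_snp_p < outlier_alpha / n
  outliers <- rec$variant_id[outlier_flag]

  beta_raw <- mr_ivw(rec)
  beta_corrected <- NULL
  distortion_p <- NA_real_
  if (length(outliers) > 0 && n - length(outliers) >= 2) {
    keep <- !outlier_flag
    beta_corrected <- mr_ivw(rec[keep, ])
    d_obs <- beta_raw$beta_hat - beta_corrected$beta_hat
    k <- length(outliers)
    d_null <- vapply(seq_len(n_distortion), function(b) {
      drop_idx <- sample.int(n, k)
      sub <- rec[-drop_idx, ]
      wv <- 1 / sub$sigma_y^2
      beta_raw$beta_hat - sum(wv * sub$gamma * sub$Gamma) / sum(wv * sub$gamma^2)
    }, numeric(1))
    distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_distortion + 1)
  }

  structure(
    list(
      rss_observed = rss_obs, global_p = global_p, n_sim = n_sim,
      per_snp = tibble(
        variant_id = rec$variant_id, statistic = t_obs,
        pvalue = per_snp_p, outlier = outlier_flag
      ),
      outliers = outliers,
      beta_raw = beta_raw, beta_corrected = beta_corrected,
      distortion_p = distortion_p, seed = seed
    ),
    class = "mr_presso"
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat("<mr_presso> global p = ", format(x$global_p, digits = 3),
    " (RSS = ", formatC(x$rss_observed, digits = 4, format = "fg"),
    ", ", x$n_sim, " simulations); ",
    length(x$outliers), " outlier(s)",
    if (length(x$outliers) > 0) paste0(": ", paste(x$outliers, collapse = ", ")) else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy mr_presso
#' @export
tidy.mr_presso <- function(x, ...) x$per_snp

#' @method glance mr_presso
#' @export
glance.mr_presso <- function(x, ...) {
  tibble(
    rss_observed = x$rss_observed, global_p = x$global_p,
    n_outliers = length(x$outliers),
    beta_raw = x$beta_raw$beta_hat,
    beta_corrected = x$beta_corrected$beta_hat %||% NA_real_,
    distortion_p = x$distortion_p, n_sim = x$n_sim
  )
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW causal effect with each instrument omitted in turn,
#' to reveal whether the association is driven disproportionately by any
#' single SNP. The attribute `max_abs_deviation` records the largest absolute
#' departure of any leave-one-out estimate from the full-data estimate.
#'
#' @inheritParams mr_ivw
#' @param model IVW model for the re-fits (see [mr_ivw()]).
#' @return A tibble of class `mr_loo` with one row per omitted variant
#'   (estimate, standard error, CI, p), plus attributes `full` (the full-data
#'   `mr_estimate`) and `max_abs_deviation`.
#' @export
mr_leave_one_out <- function(data, model = "random") {
  rec <- as_mr_records(data)
  n <- nrow(rec)
  check_n_snp(n, 2, "Leave-one-out")
  sub_model <- if (n - 1 >= 2) model else "fixed"
  rows <- lapply(seq_len(n), function(j) {
    est <- mr_ivw(rec[-j, ], model = sub_model)
    tibble(
      omitted_variant_id = rec$variant_id[j],
      estimate = est$beta_hat, std_error = est$se,
      ci_low = est$ci_low, ci_high = est$ci_high,
      p_value = est$pvalue, n_snp = est$n_snp
    )
  })
  out <- bind_rows(rows)
  full <- mr_ivw(rec, model = if (n >= 2) model else "fixed")
  structure(out,
    full = full,
    max_abs_deviation = max(abs(out$estimate - full$beta_hat)),
    class = c("mr_loo", class(out))
  )
}

#' Funnel-plot data
#'
#' Per-SNP Wald ratios against their precisions (1 / ratio standard error =
#' |gamma| / sigma_y). Under balanced pleiotropy the ratios scatter
#' symmetrically about the combined estimate; the attached `symmetry`
#' statistic is the inverse-variance weighted mean of the sign of each
#' ratio's departure from the full estimate, which is approximately 0 under
#' symmetry and +/-1 when every ratio lies on one side.
#'
#' @inheritParams mr_ivw
#' @param full_estimate Reference `mr_estimate`; default the IVW fit on
#'   `data`.
#' @return A tibble of class `mr_funnel` with columns `variant_id`, `ratio`,
#'   `precision`; attributes `symmetry` and `full`.
#' @export
funnel_data <- function(data, full_estimate = NULL) {
  rec <- ratio_inputs(data)
  if (is.null(full_estimate)) {
    full_estimate <- mr_ivw(rec, model = if (nrow(rec) >= 2) "random" else "fixed")
  }
  ratio <- rec$Gamma / rec$gamma
  precision <- abs(rec$gamma) / rec$sigma_y
  w <- rec$gamma^2 / rec$sigma_y^2
  dev_sign <- sign(ratio - full_estimate$beta_hat)
  structure(
    tibble(variant_id = rec$variant_id, ratio = ratio, precision = precision),
    symmetry = sum(w * dev_sign) / sum(w),
    full = full_estimate,
    class = c("mr_funnel", class(tibble()))
  )
}
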