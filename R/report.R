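# Reporting: odds-ratio conversion, Bonferroni correction over the
# exposure-by-outcome grid, full-pipeline orchestration, and forest-plot
# tables.

#' Bonferroni-corrected significance threshold
#'
#' Family-wise level divided by the number of primary tests (exposures times
#' outcomes); with 3 exposures and 4 outcomes at alpha = 0.05 this is
#' 0.05/12, conventionally reported as 0.004.
#'
#' @param n_exposures,n_outcomes Counts of exposures and outcomes.
#' @param alpha Family-wise error level (default 0.05).
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(n_exposures, n_outcomes, alpha = 0.05) {
  if (n_exposures < 1 || n_outcomes < 1) {
    abort("Exposure and outcome counts must be at least 1",
      class = "mrpipe_domain_error"
    )
  }
  alpha / (n_exposures * n_outcomes)
}

#' Convert a log-odds causal estimate to the odds-ratio scale
#'
#' @param est An `mr_estimate` whose `beta_hat` is on the log-odds scale
#'   (outcome from a case-control GWAS).
#' @return A one-row tibble with `or`, `ci_low`, `ci_high`.
#' @export
to_odds_ratio <- function(est) {
  tibble(
    or = exp(est$beta_hat),
    ci_low = exp(est$beta_hat - Z95 * est$se),
    ci_high = exp(est$beta_hat + Z95 * est$se)
  )
}

#' Assemble report rows from an estimator run
#'
#' Converts each estimate in an `mr_result` to the odds-ratio scale and flags
#' nominal and Bonferroni significance.
#'
#' @param result An `mr_result` from [mr_all()].
#' @param exposure,outcome Labels for the pair.
#' @param mean_f Mean F-statistic of the instruments used.
#' @param p_bonferroni Bonferroni-corrected threshold (see
#'   [bonferroni_threshold()]).
#' @param alpha Nominal level (default 0.05).
#' @return Tibble of report rows (columns `exposure`, `outcome`, `method`,
#'   `n_snp`, `mean_F`, `OR`, `CI_low`, `CI_high`, `pvalue`,
#'   `significant_nominal`, `significant_bonferroni`).
#' @export
report_rows <- function(result, exposure, outcome, mean_f = NA_real_,
                        p_bonferroni = 0.05, alpha = 0.05) {
  est <- tidy(result)
  tibble(
    exposure = exposure, outcome = outcome,
    method = est$method, n_snp = est$n_snp, mean_F = mean_f,
    OR = exp(est$estimate),
    CI_low = exp(est$ci_low), CI_high = exp(est$ci_high),
    pvalue = est$p_value,
    significant_nominal = est$p_value < alpha,
    significant_bonferroni = est$p_value < p_bonferroni
  )
}

resolve_source <- function(src, name, trait_type) {
  if (inherits(src, "sumstats")) {
    return(src)
  }
  if (is.data.frame(src)) {
    return(as_sumstats(src, trait_name = name, trait_type = trait_type, quiet = TRUE))
  }
  if (is.character(src)) {
    return(read_sumstats(src, trait_name = name, trait_type = trait_type, quiet = TRUE))
  }
  if (is.list(src) && !is.null(src$path)) {
    return(read_sumstats(src$path,
      column_map = src$column_map, trait_name = name,
      trait_type = trait_type, quiet = TRUE
    ))
  }
  abort(paste0("Cannot interpret source for '", name, "'"),
    class = "mrpipe_config_error"
  )
}

#' Build a pipeline configuration
#'
#' @param exposures,outcomes Named lists of summary-statistic sources: each
#'   element a `sumstats` object, a data frame, a file path, or a list with
#'   `path` and optional `column_map`.
#' @param confounders Optional named list of confounder sources; when given,
#'   the analysis is repeated with confounder-pruned instrument sets labelled
#'   `"<exposure> no <confounder>"`.
#' @param ld An `ld_table`, a path to one, or `NULL` (no LD information).
#' @param p_instrument,r2_clump,r2_proxy,f_min,p_confounder,window_bp,
#'   eaf_ambiguity Selection and harmonization thresholds (see the stage
#'   functions for semantics and defaults).
#' @param ivw_model,n_boot,phi,n_sim Estimator and diagnostic settings.
#' @param alpha Family-wise level for the Bonferroni correction.
#' @param seed Integer seed governing every stochastic component.
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(exposures, outcomes, confounders = NULL, ld = NULL,
                      p_instrument = 5e-8, r2_clump = 0.01, r2_proxy = 0.8,
                      f_min = 10, p_confounder = 5e-8, window_bp = NULL,
                      eaf_ambiguity = c(0.42, 0.58),
                      ivw_model = "random", n_boot = 1000, phi = 1,
                      n_sim = 1000, alpha = 0.05, seed = 1) {
  stopifnot(is.list(exposures), is.list(outcomes))
  if (is.null(names(exposures)) || is.null(names(outcomes))) {
    abort("Exposures and outcomes must be named", class = "mrpipe_config_error")
  }
  stopifnot(
    p_instrument > 0, p_instrument <= 1, r2_clump >= 0, r2_clump <= 1,
    r2_proxy >= 0, r2_proxy <= 1, f_min >= 0, alpha > 0, alpha < 1,
    length(eaf_ambiguity) == 2, eaf_ambiguity[1] <= eaf_ambiguity[2]
  )
  if (!is.numeric(seed) || length(seed) != 1) {
    abort("A single integer seed is required", class = "mrpipe_config_error")
  }
  structure(
    list(
      exposures = exposures, outcomes = outcomes, confounders = confounders,
      ld = ld, p_instrument = p_instrument, r2_clump = r2_clump,
      r2_proxy = r2_proxy, f_min = f_min, p_confounder = p_confounder,
      window_bp = window_bp, eaf_ambiguity = eaf_ambiguity,
      ivw_model = ivw_model, n_boot = n_boot, phi = phi, n_sim = n_sim,
      alpha = alpha, seed = as.integer(seed)
    ),
    class = "mr_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [mr_config()]: named `exposures` / `outcomes` /
#' `confounders` blocks (each with `path` and optional `column_map`), an `ld`
#' path, and scalar settings.
#'
#' @param path Path to a YAML file.
#' @return An `mr_config`.
#' @export
read_mr_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("exposures", "outcomes", "confounders", "ld"))]
  if (!is.null(args$eaf_ambiguity)) args$eaf_ambiguity <- as.numeric(args$eaf_ambiguity)
  do.call(mr_config, c(
    list(
      exposures = y$exposures, outcomes = y$outcomes,
      confounders = y$confounders, ld = y$ld
    ),
    args
  ))
}

pair_mean_f <- function(data, instruments) {
  ids <- ifelse(data$records$is_proxy %||% FALSE,
    data$records$proxy_of, data$records$variant_id
  )
  idx <- match(ids, instruments$retained$variant_id)
  f <- instruments$retained$f_stat[idx]
  mean(f, na.rm = TRUE)
}

run_one_block <- function(instr_sets, outcomes, cfg, p_bonf, label_suffix = "") {
  ld <- cfg$ld
  rows <- list()
  diagnostics <- list()
  for (exp_name in names(instr_sets)) {
    set <- instr_sets[[exp_name]]
    label <- paste0(exp_name, label_suffix)
    for (out_name in names(outcomes)) {
      pair <- paste(label, out_name, sep = " -> ")
      data <- tryCatch(
        harmonize_set(set, outcomes[[out_name]],
          ld = ld,
          eaf_ambiguity = cfg$eaf_ambiguity, r2_proxy = cfg$r2_proxy
        ),
        mrpipe_empty_data_error = function(e) {
          warn(paste0("Skipping ", pair, ": ", conditionMessage(e)))
          NULL
        }
      )
      if (is.null(data)) next
      data$exposure_name <- label
      result <- mr_all(data,
        seed = cfg$seed, ivw_model = cfg$ivw_model,
        n_boot = cfg$n_boot, phi = cfg$phi
      )
      mean_f <- pair_mean_f(data, set)
      rows[[pair]] <- report_rows(result, label, out_name,
        mean_f = mean_f,
        p_bonferroni = p_bonf, alpha = cfg$alpha
      )
      n <- nrow(data$records)
      diagnostics[[pair]] <- list(
        data = data,
        result = result,
        presso = if (n >= 4) {
          mr_presso(data, n_sim = cfg$n_sim, seed = cfg$seed)
        },
        leave_one_out = if (n >= 2) mr_leave_one_out(data, model = cfg$ivw_model),
        funnel = if (n >= 1 && all(data$records$gamma != 0)) funnel_data(data)
      )
    }
  }
  list(rows = bind_rows(rows), diagnostics = diagnostics)
}

#' Run the full two-sample MR pipeline
#'
#' For every exposure-outcome pair: genome-wide selection, LD clumping,
#' strength computation and weak-instrument rejection, harmonization with
#' proxy substitution, all four estimators, and pleiotropy diagnostics
#' (MR-PRESSO, leave-one-out, funnel data). When confounders are configured,
#' the analysis is repeated with confounder-pruned instrument sets appended
#' as `"<exposure> no <confounder>"` rows. Deterministic given the
#' configuration and its seed.
#'
#' @param config An `mr_config` (see [mr_config()], [read_mr_config()]).
#' @return A list of class `mr_pipeline_result`: `results` (tibble of report
#'   rows), `instruments` (per-exposure `instrument_set`s), `diagnostics`
#'   (per-pair list), `p_bonferroni`, `config`.
#' @export
run_mr_pipeline <- function(config) {
  stopifnot(inherits(config, "mr_config"))
  cfg <- config
  if (is.character(cfg$ld)) cfg$ld <- read_ld_table(cfg$ld)
  if (is.null(cfg$ld)) {
    cfg$ld <- ld_table(tibble(a = character(), b = character(), r2 = numeric()))
  }
  exposures <- purrr::imap(cfg$exposures, ~ resolve_source(.x, .y, "exposure"))
  outcomes <- purrr::imap(cfg$outcomes, ~ resolve_source(.x, .y, "outcome"))
  confounders <- if (!is.null(cfg$confounders)) {
    purrr::imap(cfg$confounders, ~ resolve_source(.x, .y, "confounder"))
  }
  p_bonf <- bonferroni_threshold(length(exposures), length(outcomes), cfg$alpha)

  instr_sets <- purrr::imap(exposures, function(stats, name) {
    select_instruments(stats, cfg$ld,
      p_threshold = cfg$p_instrument,
      r2_clump = cfg$r2_clump, f_min = cfg$f_min, window_bp = cfg$window_bp
    )
  })
  primary <- run_one_block(instr_sets, outcomes, cfg, p_bonf)
  rows <- primary$rows
  diagnostics <- primary$diagnostics

  if (!is.null(confounders)) {
    for (conf_name in names(confounders)) {
      pruned_sets <- purrr::map(instr_sets, prune_confounder,
        confounder = confounders[[conf_name]], p_threshold = cfg$p_confounder
      )
      block <- run_one_block(
        pruned_sets, outcomes, cfg, p_bonf,
        label_suffix = paste0(" no ", conf_name)
      )
      rows <- bind_rows(rows, block$rows)
      diagnostics <- c(diagnostics, block$diagnostics)
    }
  }
  structure(
    list(
      results = rows, instruments = instr_sets, diagnostics = diagnostics,
      p_bonferroni = p_bonf, config = config
    ),
    class = "mr_pipeline_result"
  )
}

#' @export
print.mr_pipeline_result <- function(x, ...) {
  cat("<mr_pipeline_result> ", nrow(x$results), " report rows; Bonferroni p < ",
    format(x$p_bonferroni, digits = 3), "\n",
    sep = ""
  )
  print(x$results)
  invisible(x)
}

#' @method tidy mr_pipeline_result
#' @export
tidy.mr_pipeline_result <- function(x, ...) x$results

#' Forest-plot-ready table
#'
#' Orders report rows for a forest plot: grouped by exposure, one labelled
#' entry per outcome (and method), with odds ratio, CI, p-value and
#' significance markers.
#'
#' @param rows Report rows (see [report_rows()]); typically the IVW rows of a
#'   pipeline result.
#' @param methods Methods to keep (default `"ivw"`).
#' @return A tibble of class `mr_forest` ordered for plotting, with a `label`
#'   column and a `marker` column (`""`, `"*"` nominal, `"**"` Bonferroni).
#' @export
forest_table <- function(rows, methods = "ivw") {
  rows <- as_tibble(rows)
  if (!is.null(methods)) rows <- rows[rows$method %in% methods, ]
  if (nrow(rows) == 0) {
    abort("No rows to tabulate", class = "mrpipe_validation_error")
  }
  rows <- rows %>%
    arrange(.data$exposure, .data$outcome, .data$method) %>%
    mutate(
      label = paste0(.data$exposure, ": ", .data$outcome),
      marker = dplyr::case_when(
        .data$significant_bonferroni ~ "**",
        .data$significant_nominal ~ "*",
        TRUE ~ ""
      )
    )
  structure(rows, class = c("mr_forest", class(tibble())))
}
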