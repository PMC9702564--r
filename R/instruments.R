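# Instrument selection: genome-wide significance screen, LD clumping,
# strength (R^2 / F) computation, weak-instrument rejection, proxy lookup
# and confounder pruning.

#' Genome-wide significance screen
#'
#' Returns the variants whose association p-value falls strictly below the
#' threshold, ordered by ascending p-value. An empty selection is permitted
#' (and reported).
#'
#' @param stats A `sumstats` tibble (exposure trait).
#' @param p_threshold Significance threshold; default the conventional
#'   genome-wide 5e-8.
#' @param quiet Suppress the empty-selection message.
#' @return Tibble of selected variant records sorted by p-value.
#' @export
select_genome_wide <- function(stats, p_threshold = 5e-8, quiet = FALSE) {
  sel <- as_tibble(stats) %>%
    filter(.data$pvalue < p_threshold) %>%
    arrange(.data$pvalue)
  if (!quiet && nrow(sel) == 0) {
    inform(paste0("No variants reached p < ", format(p_threshold), "."))
  }
  sel
}

#' Greedy LD clumping
#'
#' Reduces a candidate set to quasi-independent variants: repeatedly retain
#' the smallest-p remaining candidate and discard every remaining candidate
#' in LD with it above `r2_threshold` (and, when positions are available and
#' `window_bp` is set, any candidate within `window_bp` of it on the same
#' chromosome). The retained set has pairwise r-squared at or below the
#' threshold; the result depends only on p-values and LD, not input order.
#'
#' @param candidates Tibble of variant records with a `pvalue` column.
#' @param ld An `ld_table` (absent pairs mean r2 = 0).
#' @param r2_threshold Maximum tolerated pairwise r-squared (default 0.01).
#' @param window_bp Optional physical clumping window in base pairs; ignored
#'   for candidates lacking `chrom`/`pos`. `NULL` disables it.
#' @return Tibble of retained variant records, smallest p first.
#' @export
clump_variants <- function(candidates, ld, r2_threshold = 0.01, window_bp = NULL) {
  candidates <- as_tibble(candidates) %>%
    arrange(.data$pvalue, .data$variant_id)
  if (nrow(candidates) <= 1) {
    return(candidates)
  }
  alive <- rep(TRUE, nrow(candidates))
  keep <- logical(nrow(candidates))
  has_pos <- !is.null(window_bp) &&
    all(c("chrom", "pos") %in% names(candidates))
  for (i in seq_len(nrow(candidates))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    rest <- which(alive)
    if (length(rest) == 0) break
    r2 <- ld_lookup(ld, candidates$variant_id[i], candidates$variant_id[rest])
    drop <- r2 > r2_threshold
    if (has_pos && !is.na(candidates$pos[i]) && !is.na(candidates$chrom[i])) {
      near <- !is.na(candidates$pos[rest]) &
        candidates$chrom[rest] == candidates$chrom[i] &
        abs(candidates$pos[rest] - candidates$pos[i]) <= window_bp
      near[is.na(near)] <- FALSE
      drop <- drop | near
    }
    alive[rest[drop]] <- FALSE
  }
  candidates[keep, ]
}

#' Instrument strength: variance explained and F-statistic
#'
#' Computes, per variant, the proportion of exposure variance explained
#' \deqn{R^2 = \frac{2\beta^2 f(1-f)}{2\beta^2 f(1-f) + 2\,SE^2 N f(1-f)}}
#' and the instrument F-statistic \eqn{F = R^2 (N-2)/(1-R^2)}, where f is the
#' effect-allele frequency and N the GWAS sample size. The common factor
#' 2f(1-f) cancels, so R-squared is symmetric in f vs 1-f.
#'
#' @param beta,se,eaf,n Per-variant effect size, standard error,
#'   effect-allele frequency and sample size (vectorized).
#' @return Tibble with columns `r2_explained` and `f_stat`.
#' @export
compute_strength <- function(beta, se, eaf, n) {
  if (any(n <= 2)) {
    abort("Sample size must exceed 2 to compute an F-statistic",
      class = "mrpipe_domain_error"
    )
  }
  if (any(se <= 0) || any(eaf <= 0 | eaf >= 1)) {
    abort("compute_strength requires se > 0 and 0 < eaf < 1",
      class = "mrpipe_domain_error"
    )
  }
  v <- 2 * beta^2 * eaf * (1 - eaf)
  r2 <- v / (v + 2 * se^2 * n * eaf * (1 - eaf))
  f <- r2 * (n - 2) / (1 - r2)
  tibble(r2_explained = r2, f_stat = f)
}

#' Attach strength columns to a variant table
#'
#' @param variants Tibble with `beta`, `se`, `eaf`, `n` columns.
#' @return The table with `r2_explained` and `f_stat` columns appended.
#' @export
add_strength <- function(variants) {
  s <- compute_strength(variants$beta, variants$se, variants$eaf, variants$n)
  variants$r2_explained <- s$r2_explained
  variants$f_stat <- s$f_stat
  variants
}

new_instrument_set <- function(exposure_name, retained, excluded) {
  retained <- as_tibble(retained)
  excluded <- as_tibble(excluded)
  structure(
    list(
      exposure_name = exposure_name,
      retained = retained,
      excluded = excluded,
      mean_f = if (nrow(retained) > 0) mean(retained$f_stat) else NA_real_
    ),
    class = "instrument_set"
  )
}

#' Reject weak instruments
#'
#' Splits instruments at the conventional weak-instrument boundary: variants
#' with `f_stat >= f_min` are retained, the rest are excluded with reason
#' `weak_instrument`. The set's mean F is the arithmetic mean over retained
#' instruments only.
#'
#' @param instruments Tibble of variant records carrying `f_stat` (see
#'   [add_strength()]).
#' @param f_min Minimum F-statistic for retention (default 10).
#' @param exposure_name Label for the exposure the instruments tag.
#' @return An `instrument_set`: list with `exposure_name`, `retained`,
#'   `excluded` (with `excluded_reason`), and `mean_f`.
#' @export
filter_weak <- function(instruments, f_min = 10,
                        exposure_name = attr(instruments, "trait_name") %||% "exposure") {
  instruments <- as_tibble(instruments)
  if (!"f_stat" %in% names(instruments)) instruments <- add_strength(instruments)
  weak <- instruments$f_stat < f_min
  excluded <- instruments[weak, ]
  if (nrow(excluded) > 0) excluded$excluded_reason <- "weak_instrument"
  if (nrow(excluded) == 0) excluded$excluded_reason <- character()
  new_instrument_set(exposure_name, instruments[!weak, ], excluded)
}

#' Find a proxy variant in the outcome GWAS
#'
#' For an instrument absent from the outcome table, searches the outcome's
#' variants for the one in strongest LD with it, requiring r-squared strictly
#' above `r2_min` (default 0.8). Ties on r-squared are broken by the smaller
#' outcome p-value, then lexicographically by identifier.
#'
#' @param missing_id Identifier of the instrument missing from the outcome.
#' @param outcome A `sumstats` tibble for the outcome trait.
#' @param ld An `ld_table`.
#' @param r2_min LD threshold a proxy must exceed.
#' @return A one-row tibble (the proxy's outcome record, with an `r2_proxy`
#'   column), or `NULL` when no adequate proxy exists.
#' @export
find_proxy <- function(missing_id, outcome, ld, r2_min = 0.8) {
  outcome <- as_tibble(outcome)
  pool <- outcome[outcome$variant_id != missing_id, ]
  if (nrow(pool) == 0) {
    return(NULL)
  }
  r2 <- ld_lookup(ld, missing_id, pool$variant_id)
  ok <- r2 > r2_min
  if (!any(ok)) {
    return(NULL)
  }
  pool <- pool[ok, ]
  r2 <- r2[ok]
  ord <- order(-r2, pool$pvalue, pool$variant_id)
  best <- pool[ord[1], ]
  best$r2_proxy <- r2[ord[1]]
  best
}

#' Prune confounder-associated instruments
#'
#' Moves retained instruments that reach genome-wide significance in a
#' confounder GWAS (e.g. BMI) to the excluded set with reason
#' `confounder_associated`. Instruments absent from the confounder table are
#' kept: pruning keys on exact identifier match.
#'
#' @param instruments An `instrument_set`.
#' @param confounder A `sumstats` tibble for the confounder trait.
#' @param p_threshold Confounder-association threshold (default 5e-8).
#' @return A pruned `instrument_set`.
#' @export
prune_confounder <- function(instruments, confounder, p_threshold = 5e-8) {
  stopifnot(inherits(instruments, "instrument_set"))
  confounder <- as_tibble(confounder)
  idx <- match(instruments$retained$variant_id, confounder$variant_id)
  conf_p <- confounder$pvalue[idx]
  assoc <- !is.na(conf_p) & conf_p < p_threshold
  pruned <- instruments$retained[assoc, ]
  if (nrow(pruned) > 0) pruned$excluded_reason <- "confounder_associated"
  excluded <- bind_rows(instruments$excluded, pruned)
  new_instrument_set(instruments$exposure_name, instruments$retained[!assoc, ], excluded)
}

#' Select instruments end-to-end
#'
#' Composes the selection stages: genome-wide screen, greedy LD clumping,
#' strength computation and weak-instrument rejection, and (optionally)
#' confounder pruning.
#'
#' @param stats Exposure `sumstats` tibble.
#' @param ld An `ld_table`.
#' @param p_threshold Genome-wide screen threshold.
#' @param r2_clump Clumping r-squared threshold.
#' @param f_min Weak-instrument F floor.
#' @param window_bp Optional physical clumping window (see [clump_variants()]).
#' @param confounder Optional confounder `sumstats` for pruning.
#' @param p_confounder Confounder-association threshold.
#' @return An `instrument_set`.
#' @export
select_instruments <- function(stats, ld, p_threshold = 5e-8, r2_clump = 0.01,
                               f_min = 10, window_bp = NULL,
                               confounder = NULL, p_confounder = 5e-8) {
  exposure_name <- attr(stats, "trait_name") %||% "exposure"
  candidates <- select_genome_wide(stats, p_threshold, quiet = TRUE)
  clumped <- clump_variants(candidates, ld, r2_threshold = r2_clump, window_bp = window_bp)
  dropped_ld <- candidates[!candidates$variant_id %in% clumped$variant_id, ]
  set <- filter_weak(add_strength(clumped), f_min = f_min, exposure_name = exposure_name)
  if (nrow(dropped_ld) > 0) {
    dropped_ld <- add_strength(dropped_ld)
    dropped_ld$excluded_reason <- "ld_pruned"
    set$excluded <- bind_rows(set$excluded, dropped_ld)
  }
  if (!is.null(confounder)) {
    set <- prune_confounder(set, confounder, p_threshold = p_confounder)
  }
  set
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("<instrument_set> exposure '", x$exposure_name, "': ",
    nrow(x$retained), " retained (mean F = ",
    formatC(x$mean_f, digits = 4, format = "fg"), "), ",
    nrow(x$excluded), " excluded\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy instrument_set
#' @export
tidy.instrument_set <- function(x, ...) {
  ret <- x$retained
  if (nrow(ret) > 0) ret$status <- "retained"
  exc <- x$excluded
  if (nrow(exc) > 0) exc$status <- "excluded"
  bind_rows(ret, exc)
}
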