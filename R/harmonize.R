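# Allele harmonization: align exposure and outcome effect estimates to a
# common effect allele, resolving allele swaps, strand flips and palindromic
# ambiguity. The exposure table's allele convention is the reference; the
# outcome side is flipped to it.

allele_complement <- function(x) chartr("ACGT", "TGCA", x)

is_palindromic <- function(effect, other) other == allele_complement(effect)

#' Construct harmonized exposure/outcome data
#'
#' @param records Tibble with columns `variant_id`, `gamma` (exposure effect),
#'   `sigma_x`, `Gamma` (outcome effect on the same effect allele), `sigma_y`,
#'   and optionally `eaf_exposure`, `eaf_outcome`, `action`, `is_proxy`,
#'   `proxy_of`.
#' @param exposure_name,outcome_name Trait labels.
#' @param dropped Tibble of `(variant_id, reason)` for instruments lost in
#'   harmonization.
#' @return An object of class `mr_data`.
#' @export
mr_data <- function(records, exposure_name = "exposure", outcome_name = "outcome",
                    dropped = tibble(variant_id = character(), reason = character())) {
  records <- as_tibble(records)
  needed <- c("variant_id", "gamma", "sigma_x", "Gamma", "sigma_y")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Harmonized records need column(s): ", paste(missing_cols, collapse = ", ")
    ), class = "mrpipe_validation_error")
  }
  if (any(records$sigma_x <= 0) || any(records$sigma_y <= 0)) {
    abort("Harmonized records require positive standard errors",
      class = "mrpipe_validation_error"
    )
  }
  structure(
    list(
      exposure_name = exposure_name, outcome_name = outcome_name,
      records = records, dropped = as_tibble(dropped)
    ),
    class = "mr_data"
  )
}

as_mr_records <- function(data) {
  if (inherits(data, "mr_data")) {
    return(data$records)
  }
  as_tibble(data)
}

#' Harmonize one exposure/outcome variant pair
#'
#' Aligns the outcome record's effect to the exposure record's effect allele.
#' Four resolvable configurations exist: identical alleles (no action),
#' swapped alleles (negate the outcome effect, complement its frequency),
#' strand-complement alleles (relabel only), and strand-complement swapped
#' (relabel and negate). Palindromic variants (A/T or G/C) cannot be resolved
#' from alleles alone: orientation is inferred from effect-allele frequency
#' side-agreement, and the pair is dropped as `palindromic_ambiguous` when
#' either frequency falls inside the ambiguity window or is missing.
#'
#' @param exp_rec,out_rec One-row data frames (or lists) with fields
#'   `variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`.
#' @param eaf_ambiguity Frequency window, default `c(0.42, 0.58)`, inside
#'   which a palindromic variant's strand cannot be called.
#' @return A list with `record` (one-row harmonized tibble, or `NULL`) and
#'   `reason` (`NA` on success; otherwise `palindromic_ambiguous` or
#'   `invalid_alleles`).
#' @export
harmonize_pair <- function(exp_rec, out_rec, eaf_ambiguity = c(0.42, 0.58)) {
  h <- harmonize_pair_core(exp_rec, out_rec, eaf_ambiguity)
  if (is.null(h$record)) {
    return(h)
  }
  list(record = as_tibble(h$record), reason = h$reason)
}

# row-level harmonization returning a plain list, so set-level callers can
# assemble one tibble at the end instead of one per SNP
harmonize_pair_core <- function(exp_rec, out_rec, eaf_ambiguity) {
  ea_x <- toupper(exp_rec$effect_allele)
  oa_x <- toupper(exp_rec$other_allele)
  ea_y <- toupper(out_rec$effect_allele)
  oa_y <- toupper(out_rec$other_allele)
  bases <- c("A", "C", "G", "T")
  if (!all(c(ea_x, oa_x, ea_y, oa_y) %in% bases)) {
    return(list(record = NULL, reason = "invalid_alleles"))
  }

  drop <- function(reason) list(record = NULL, reason = reason)
  done <- function(Gamma, eaf_out, action) {
    list(
      record = list(
        variant_id = exp_rec$variant_id,
        gamma = exp_rec$beta, sigma_x = exp_rec$se,
        Gamma = Gamma, sigma_y = out_rec$se,
        eaf_exposure = exp_rec$eaf, eaf_outcome = eaf_out,
        action = action, is_proxy = FALSE, proxy_of = NA_character_
      ),
      reason = NA_character_
    )
  }

  if (is_palindromic(ea_x, oa_x)) {
    # outcome must carry the same base pair (its complement equals its swap)
    if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
      return(drop("invalid_alleles"))
    }
    fx <- exp_rec$eaf
    fy <- out_rec$eaf
    if (is.na(fx) || is.na(fy)) {
      return(drop("palindromic_ambiguous"))
    }
    ambiguous <- function(f) f >= eaf_ambiguity[1] & f <= eaf_ambiguity[2]
    if (ambiguous(fx) || ambiguous(fy)) {
      return(drop("palindromic_ambiguous"))
    }
    # frequency of the exposure's effect-allele *letter* on the outcome side
    f_same <- if (ea_y == ea_x) fy else 1 - fy
    letters_match <- ea_y == ea_x
    if (sign(fx - 0.5) == sign(f_same - 0.5)) {
      # letter orientation agrees with frequency
      if (letters_match) {
        return(done(out_rec$beta, fy, "none"))
      }
      return(done(-out_rec$beta, 1 - fy, "allele_flip"))
    }
    # frequencies disagree: the outcome is reported on the opposite strand,
    # which for a palindrome toggles the allele assignment
    if (letters_match) {
      return(done(-out_rec$beta, 1 - fy, "strand_flip_and_allele_flip"))
    }
    done(out_rec$beta, fy, "strand_flip")
  } else {
    if (ea_y == ea_x && oa_y == oa_x) {
      return(done(out_rec$beta, out_rec$eaf, "none"))
    }
    if (ea_y == oa_x && oa_y == ea_x) {
      return(done(-out_rec$beta, 1 - out_rec$eaf, "allele_flip"))
    }
    cea <- allele_complement(ea_y)
    coa <- allele_complement(oa_y)
    if (cea == ea_x && coa == oa_x) {
      return(done(out_rec$beta, out_rec$eaf, "strand_flip"))
    }
    if (cea == oa_x && coa == ea_x) {
      return(done(-out_rec$beta, 1 - out_rec$eaf, "strand_flip_and_allele_flip"))
    }
    drop("invalid_alleles")
  }
}

#' Harmonize an instrument set against an outcome GWAS
#'
#' For every retained instrument: a direct identifier match in the outcome is
#' harmonized with [harmonize_pair()]; an instrument missing from the outcome
#' is substituted by its strongest LD proxy (r-squared > `r2_proxy`, see
#' [find_proxy()]) with the original exposure effect retained, or dropped as
#' `missing_in_outcome` when no proxy exists. Every instrument appears
#' exactly once, in the harmonized records or among the drops.
#'
#' @param instruments An `instrument_set` (or tibble of exposure-side variant
#'   records).
#' @param outcome A `sumstats` tibble for the outcome.
#' @param ld An `ld_table`, used for proxy search.
#' @param eaf_ambiguity Palindrome ambiguity window (see [harmonize_pair()]).
#' @param r2_proxy Minimum LD for proxy substitution (default 0.8).
#' @return An `mr_data` object.
#' @export
harmonize_set <- function(instruments, outcome, ld = NULL,
                          eaf_ambiguity = c(0.42, 0.58), r2_proxy = 0.8) {
  if (inherits(instruments, "instrument_set")) {
    exposure_name <- instruments$exposure_name
    instr <- instruments$retained
  } else {
    exposure_name <- attr(instruments, "trait_name") %||% "exposure"
    instr <- as_tibble(instruments)
  }
  outcome_name <- attr(outcome, "trait_name") %||% "outcome"
  outcome <- as_tibble(outcome)
  if (is.null(ld)) ld <- ld_table(tibble(a = character(), b = character(), r2 = numeric()))

  instr_rows <- purrr::transpose(as.list(instr[c(
    "variant_id", "effect_allele", "other_allele", "eaf", "beta", "se"
  )]))
  out_idx <- match(instr$variant_id, outcome$variant_id)
  out_rows <- purrr::transpose(as.list(outcome[c(
    "variant_id", "effect_allele", "other_allele", "eaf", "beta", "se"
  )]))

  records <- vector("list", nrow(instr))
  drop_id <- character()
  drop_reason <- character()
  for (i in seq_len(nrow(instr))) {
    exp_rec <- instr_rows[[i]]
    j <- out_idx[i]
    proxy_of <- NA_character_
    if (is.na(j)) {
      proxy <- find_proxy(exp_rec$variant_id, outcome, ld, r2_min = r2_proxy)
      if (is.null(proxy)) {
        drop_id <- c(drop_id, exp_rec$variant_id)
        drop_reason <- c(drop_reason, "missing_in_outcome")
        next
      }
      out_rec <- as.list(proxy[c(
        "variant_id", "effect_allele", "other_allele", "eaf", "beta", "se"
      )])
      proxy_of <- exp_rec$variant_id
    } else {
      out_rec <- out_rows[[j]]
    }
    h <- harmonize_pair_core(exp_rec, out_rec, eaf_ambiguity)
    if (is.null(h$record)) {
      drop_id <- c(drop_id, exp_rec$variant_id)
      drop_reason <- c(drop_reason, h$reason)
    } else {
      rec <- h$record
      if (!is.na(proxy_of)) {
        rec$is_proxy <- TRUE
        rec$proxy_of <- proxy_of
        rec$variant_id <- out_rec$variant_id
      }
      records[[i]] <- rec
    }
  }
  records <- bind_rows(records)
  dropped <- tibble(variant_id = drop_id, reason = drop_reason)
  if (nrow(records) == 0) {
    abort(paste0(
      "No instruments survived harmonization for '", exposure_name,
      "' against '", outcome_name, "'"
    ), class = "mrpipe_empty_data_error")
  }
  mr_data(records,
    exposure_name = exposure_name, outcome_name = outcome_name,
    dropped = dropped
  )
}

#' @export
print.mr_data <- function(x, ...) {
  cat("<mr_data> ", x$exposure_name, " -> ", x$outcome_name, ": ",
    nrow(x$records), " harmonized SNPs, ", nrow(x$dropped), " dropped\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy mr_data
#' @export
tidy.mr_data <- function(x, ...) x$records
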