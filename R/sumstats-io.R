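# Reading and validating GWAS summary-statistic tables, LD tables, and
# pipeline result tables.

SUMSTATS_FIELDS <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pvalue", "n"
)
SUMSTATS_REQUIRED <- setdiff(SUMSTATS_FIELDS, c("chrom", "pos"))

#' Construct a validated summary-statistics table
#'
#' Coerces a data frame of per-variant GWAS association records into the
#' canonical `sumstats` tibble used throughout the pipeline. Rows violating
#' the per-variant invariants (missing required fields, `se <= 0`, `eaf`
#' outside (0, 1), `pvalue` outside (0, 1], non-SNP alleles) are dropped with
#' an informative count; duplicated variant identifiers are an error.
#'
#' @param x Data frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n` (and optionally
#'   `chrom`, `pos`).
#' @param trait_name Name of the trait the associations describe.
#' @param trait_type One of `"exposure"`, `"outcome"`, `"confounder"`.
#' @param quiet Suppress the dropped-row message.
#'
#' @return A tibble of class `sumstats` with attributes `trait_name`,
#'   `trait_type` and `n_dropped` (rows removed during validation).
#' @export
as_sumstats <- function(x, trait_name, trait_type = c("exposure", "outcome", "confounder"),
                        quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  x <- as_tibble(x)
  missing_cols <- setdiff(SUMSTATS_REQUIRED, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Summary-statistics table for '", trait_name, "' is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "mrpipe_config_error")
  }
  if (!"chrom" %in% names(x)) x$chrom <- NA_character_
  if (!"pos" %in% names(x)) x$pos <- NA_integer_
  x <- x[SUMSTATS_FIELDS]

  x$variant_id <- as.character(x$variant_id)
  x$chrom <- as.character(x$chrom)
  x$pos <- suppressWarnings(as.integer(x$pos))
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue")) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }
  x$n <- suppressWarnings(as.numeric(x$n))

  n_in <- nrow(x)
  complete <- !(is.na(x$variant_id) | x$variant_id == "" |
    is.na(x$effect_allele) | is.na(x$other_allele) |
    is.na(x$eaf) | is.na(x$beta) | is.na(x$se) | is.na(x$pvalue) | is.na(x$n))
  snp_alleles <- x$effect_allele %in% c("A", "C", "G", "T") &
    x$other_allele %in% c("A", "C", "G", "T") &
    x$effect_allele != x$other_allele
  in_range <- x$eaf > 0 & x$eaf < 1 & x$se > 0 &
    x$pvalue > 0 & x$pvalue <= 1 & x$n > 0
  keep <- complete & !is.na(snp_alleles) & snp_alleles & !is.na(in_range) & in_range
  keep[is.na(keep)] <- FALSE
  n_dropped <- n_in - sum(keep)
  x <- x[keep, ]

  dup <- x$variant_id[duplicated(x$variant_id)]
  if (length(dup) > 0) {
    abort(paste0(
      "Duplicate variant_id in '", trait_name, "': ",
      paste(unique(head(dup, 10)), collapse = ", ")
    ), class = "mrpipe_validation_error")
  }
  if (!quiet && n_dropped > 0) {
    inform(paste0(
      "Removed ", n_dropped, " of ", n_in, " rows with missing or invalid ",
      "information from '", trait_name, "'."
    ))
  }
  structure(x,
    trait_name = trait_name, trait_type = trait_type, n_dropped = n_dropped,
    class = c("sumstats", class(x))
  )
}

#' Read a GWAS summary-statistics file
#'
#' Reads a tab- or comma-delimited file (delimiter auto-detected from the
#' header line, tab preferred) and maps its columns onto the canonical
#' per-variant fields via `column_map`. Validation and row-dropping rules are
#' those of [as_sumstats()].
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical field names
#'   (`variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`, `n`, optionally `chrom`, `pos`) to the file's column names.
#'   Fields whose name matches the file column can be omitted.
#' @inheritParams as_sumstats
#'
#' @return A `sumstats` tibble (see [as_sumstats()]).
#' @export
read_sumstats <- function(path, column_map = NULL, trait_name = basename(path),
                          trait_type = c("exposure", "outcome", "confounder"),
                          quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "mrpipe_io_error")
  }
  delim <- detect_delim(path)
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src) > 0) {
      abort(paste0(
        "Column(s) named in column_map not present in ", path, ": ",
        paste(missing_src, collapse = ", ")
      ), class = "mrpipe_config_error")
    }
    for (canon in names(column_map)) {
      raw[[canon]] <- raw[[column_map[[canon]]]]
    }
  }
  as_sumstats(raw, trait_name = trait_name, trait_type = trait_type, quiet = quiet)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) {
    abort(paste0("Empty file: ", path), class = "mrpipe_io_error")
  }
  if (grepl("\t", header)) "\t" else ","
}

#' Read a pairwise linkage-disequilibrium table
#'
#' Reads a three-column pair list (`variant_id_a`, `variant_id_b`, `r2`) from
#' a delimited text file, with or without a header. Lookups through
#' [ld_lookup()] are symmetric, self-LD is implicitly 1, and an absent pair
#' is treated as r-squared 0. Duplicate pairs with conflicting r-squared
#' values are an error.
#'
#' @param path Path to the pair list.
#' @return A tibble of class `ld_table` with columns `a`, `b`, `r2`.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "mrpipe_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(ld_table(tibble(a = character(), b = character(), r2 = numeric())))
  }
  first <- strsplit(lines[[1]], "[\t,]")[[1]]
  has_header <- length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[[3]])))
  delim <- if (grepl("\t", lines[[1]])) "\t" else ","
  tbl <- readr::read_delim(path,
    delim = delim, col_names = has_header,
    col_types = readr::cols(), progress = FALSE, show_col_types = FALSE
  )
  if (ncol(tbl) < 3) {
    abort("LD table must have three columns: id_a, id_b, r2",
      class = "mrpipe_validation_error"
    )
  }
  tbl <- tbl[, 1:3]
  names(tbl) <- c("a", "b", "r2")
  tbl$a <- as.character(tbl$a)
  tbl$b <- as.character(tbl$b)
  tbl$r2 <- as.numeric(tbl$r2)
  ld_table(tbl)
}

#' Build an LD table from a data frame of variant pairs
#'
#' @param pairs Data frame with columns `a`, `b`, `r2`.
#' @return A tibble of class `ld_table`.
#' @export
ld_table <- function(pairs) {
  pairs <- as_tibble(pairs)[, c("a", "b", "r2")]
  if (any(is.na(pairs$r2)) || any(pairs$r2 < 0 | pairs$r2 > 1)) {
    abort("LD r2 values must lie in [0, 1]", class = "mrpipe_validation_error")
  }
  # canonical unordered-pair key so lookup is symmetric by construction
  key <- paste(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b), sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(pairs$r2, key, function(v) diff(range(v)))
    bad <- names(agg)[agg > 1e-12]
    if (length(bad) > 0) {
      abort(paste0(
        "Conflicting r2 for pair(s): ",
        paste(gsub("\r", "/", head(bad, 5)), collapse = ", ")
      ), class = "mrpipe_validation_error")
    }
    keep <- !duplicated(key)
    pairs <- pairs[keep, ]
    key <- key[keep]
  }
  structure(pairs, pair_key = key, class = c("ld_table", class(pairs)))
}

#' Symmetric LD lookup
#'
#' @param ld An `ld_table`.
#' @param a,b Variant identifier vectors (recycled to a common length).
#' @return Numeric vector of r-squared values; 1 where `a == b`, 0 for pairs
#'   absent from the table.
#' @export
ld_lookup <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_table"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  idx <- match(key, attr(ld, "pair_key"))
  out <- ifelse(is.na(idx), 0, ld$r2[idx])
  out[a == b] <- 1
  out
}

#' Write pipeline result rows to TSV
#'
#' Emits the study-level result grid: one row per exposure/outcome/method
#' with instrument count, mean F-statistic, odds ratio, 95% CI and p-value.
#' Values round-trip losslessly at 6 significant digits.
#'
#' @param rows Data frame of report rows (see [report_rows()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path) {
  cols <- c(
    "exposure", "outcome", "method", "n_snp", "mean_F",
    "OR", "CI_low", "CI_high", "pvalue"
  )
  rows <- as_tibble(rows)
  missing_cols <- setdiff(cols, names(rows))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Result rows missing column(s): ", paste(missing_cols, collapse = ", ")
    ), class = "mrpipe_validation_error")
  }
  readr::write_tsv(rows[cols], path)
  invisible(path)
}

#' Read a results TSV written by [write_results()]
#'
#' @param path Path to the TSV.
#' @return Tibble with the result columns.
#' @export
read_results <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      exposure = readr::col_character(), outcome = readr::col_character(),
      method = readr::col_character(), n_snp = readr::col_integer(),
      .default = readr::col_double()
    ), progress = FALSE
  )
}

#' @export
print.sumstats <- function(x, ...) {
  cat(
    "<sumstats> trait '", attr(x, "trait_name"), "' (",
    attr(x, "trait_type"), "), ", nrow(x), " variants\n",
    sep = ""
  )
  NextMethod()
}
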