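# Shared fixtures and independent oracles used across the suite.

# the three-SNP harmonized dataset used in several worked examples
worked_data <- function() {
  tibble::tibble(
    variant_id = c("s1", "s2", "s3"),
    gamma = c(0.1, 0.2, 0.1), sigma_x = c(0.001, 0.001, 0.001),
    Gamma = c(0.02, 0.05, 0.03), sigma_y = c(0.01, 0.01, 0.02)
  )
}

# random harmonized data for property tests
random_mr_records <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    variant_id = sprintf("v%03d", seq_len(n)),
    gamma = rnorm(n, 0.05, 0.02) * sample(c(-1, 1), n, replace = TRUE),
    sigma_x = runif(n, 0.002, 0.01),
    Gamma = rnorm(n, 0.02, 0.02),
    sigma_y = runif(n, 0.005, 0.02)
  )
}

# a tiny valid sumstats data frame
tiny_sumstats <- function() {
  tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3"),
    chrom = c("1", "2", "3"), pos = c(1000L, 2000L, 3000L),
    effect_allele = c("A", "C", "G"), other_allele = c("G", "T", "A"),
    eaf = c(0.3, 0.5, 0.7), beta = c(0.1, -0.05, 0.02),
    se = c(0.01, 0.02, 0.01), pvalue = c(1e-20, 0.012, 0.05),
    n = c(10000, 10000, 10000)
  )
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path)
  path
}

# independent greedy-clumping oracle: dense r2 matrix + explicit loop over
# every remaining candidate, no shared code with clump_variants
clump_oracle <- function(candidates, ld_pairs, r2_threshold) {
  ids <- candidates$variant_id[order(candidates$pvalue, candidates$variant_id)]
  r2 <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(nrow(ld_pairs))) {
    a <- ld_pairs$a[k]
    b <- ld_pairs$b[k]
    if (a %in% ids && b %in% ids) {
      r2[a, b] <- ld_pairs$r2[k]
      r2[b, a] <- ld_pairs$r2[k]
    }
  }
  retained <- character()
  remaining <- ids
  while (length(remaining) > 0) {
    pick <- remaining[1]
    retained <- c(retained, pick)
    remaining <- remaining[-1]
    if (length(remaining) > 0) {
      remaining <- remaining[r2[pick, remaining] <= r2_threshold]
    }
  }
  sort(retained)
}

# independent weighted-median oracle: direct evaluation of the midpoint-rank
# interpolation formula
weighted_median_oracle <- function(b, w) {
  o <- order(b)
  b <- b[o]
  wp <- w[o] / sum(w)
  s <- cumsum(wp) - wp / 2
  stats::approx(s, b, xout = 0.5, rule = 2, ties = "ordered")$y
}
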