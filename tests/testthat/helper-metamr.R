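# Shared fixture builders. All fixtures are constructed in code.

# Minimal well-formed summary-statistic data.frame; fields overridable.
make_sumstats_df <- function(.rows = 3, ...) {
  z <- seq_len(.rows) / 2
  df <- data.frame(
    snp_id = sprintf("rs%d", seq_len(.rows)),
    chrom = "1",
    pos = seq_len(.rows) * 100000L,
    effect_allele = "A",
    other_allele = "G",
    eaf = 0.3,
    beta = z * 0.05,
    se = 0.05,
    p = 2 * pnorm(-abs(z)),
    n = 1000L,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

write_tsv_fixture <- function(df, path, header = names(df)) {
  names(df) <- header
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Canonical-header file version of make_sumstats_df.
make_sumstats_file <- function(path, .rows = 3, ...) {
  df <- make_sumstats_df(.rows, ...)
  names(df) <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Meta-analysis-shaped data.frame straight from p-values/positions.
make_meta_df <- function(p, pos = seq_along(p) * 100000L,
                         chrom = rep("1", length(p)),
                         snp_id = sprintf("rs%d", seq_along(p)),
                         k = 2L) {
  m <- length(p)
  z <- qnorm(p / 2, lower.tail = FALSE)
  data.frame(snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
             effect_allele = rep_len("A", m), other_allele = rep_len("G", m),
             eaf = rep_len(0.3, m), beta_meta = z * 0.05,
             se_meta = rep_len(0.05, m), z_meta = z, p_meta = p,
             k = rep_len(k, m), n = rep_len(10000L, m),
             lambda_gc = rep_len(1, m), stringsAsFactors = FALSE)
}

# Instrument table with exact effect values.
make_instruments_df <- function(beta_x, beta_y, se_y, se_x = 0.01) {
  data.frame(snp_id = sprintf("iv%d", seq_along(beta_x)),
             beta_x = beta_x, se_x = rep_len(se_x, length(beta_x)),
             beta_y = beta_y, se_y = rep_len(se_y, length(beta_x)),
             stringsAsFactors = FALSE)
}

# Random positive-definite r-squared matrix with unit diagonal.
random_r2_matrix <- function(ids) {
  m <- length(ids)
  a <- matrix(rnorm(m * m), m)
  r <- cov2cor(crossprod(a) + diag(m))
  r2 <- r^2
  diag(r2) <- 1
  dimnames(r2) <- list(ids, ids)
  r2
}
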