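# Inverse-variance-weighted fixed-effect meta-analysis across cohorts, with
# genomic control and QQ-plot data.

CHISQ1_MEDIAN <- 0.4549364  # qchisq(0.5, df = 1)

#' Fixed-effect inverse-variance-weighted pooling for one SNP
#'
#' With weights \eqn{w_i = 1/se_i^2}, the pooled effect is
#' \eqn{\sum w_i \beta_i / \sum w_i} with standard error
#' \eqn{(\sum w_i)^{-1/2}}; this equals the generalized-least-squares
#' solution of an intercept-only weighted regression. The two-sided p-value
#' comes from the standard normal distribution.
#'
#' @param beta,se numeric vectors of per-cohort effects and standard errors.
#' @return list with `beta_meta`, `se_meta`, `z_meta`, `p_meta` and `k`
#'   (number of contributing studies).
#' @export
ivw_fixed_effect_meta <- function(beta, se) {
  if (length(beta) == 0) stopf("no cohort effects supplied")
  stopifnot(length(beta) == length(se), all(se > 0))
  w <- 1 / se^2
  beta_meta <- sum(w * beta) / sum(w)
  se_meta <- 1 / sqrt(sum(w))
  z <- beta_meta / se_meta
  list(beta_meta = beta_meta, se_meta = se_meta, z_meta = z,
       p_meta = two_sided_p(z), k = length(beta))
}

#' Meta-analyze harmonized cohort tables SNP by SNP
#'
#' SNPs present in only a subset of cohorts are pooled over the cohorts that
#' carry them; the number of contributing studies is recorded per SNP in `k`.
#' Tables must already share an allele orientation (see
#' [harmonize_alleles()]).
#'
#' @param tables list of harmonized cohort tables for one trait.
#' @return data.frame with columns `snp_id, chrom, pos, effect_allele,
#'   other_allele, eaf, beta_meta, se_meta, z_meta, p_meta, k, n, lambda_gc`
#'   (`lambda_gc = 1` until [genomic_control()] is applied; `eaf` and `n` are
#'   the sample-size-weighted frequency and the summed n).
#' @export
meta_analyze <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (!length(tables)) stopf("no cohort tables supplied")
  long <- do.call(rbind, lapply(tables, function(t) as.data.frame(t)[SUMSTAT_COLS]))
  w <- 1 / long$se^2
  g <- factor(long$snp_id, levels = unique(long$snp_id))
  sw <- rowsum(w, g)[, 1]
  swb <- rowsum(w * long$beta, g)[, 1]
  k <- rowsum(rep(1L, nrow(long)), g)[, 1]
  n_tot <- rowsum(as.numeric(long$n), g)[, 1]
  eaf_w <- rowsum(long$eaf * long$n, g)[, 1] / n_tot
  first <- long[!duplicated(long$snp_id), ]
  beta_meta <- swb / sw
  se_meta <- 1 / sqrt(sw)
  z <- beta_meta / se_meta
  out <- data.frame(
    snp_id = first$snp_id, chrom = first$chrom, pos = first$pos,
    effect_allele = first$effect_allele, other_allele = first$other_allele,
    eaf = unname(eaf_w), beta_meta = unname(beta_meta),
    se_meta = unname(se_meta), z_meta = unname(z),
    p_meta = two_sided_p(unname(z)), k = unname(as.integer(k)),
    n = unname(as.integer(n_tot)), lambda_gc = 1,
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$snp_id), ]
  rownames(out) <- NULL
  out
}

#' Apply genomic control to meta-analysis statistics
#'
#' The inflation factor is \eqn{\lambda = median(z^2) / 0.4549364}, the ratio
#' of the observed median association chi-square to the null median of
#' \eqn{\chi^2_1}. When \eqn{\lambda > 1}, z-scores are divided by
#' \eqn{\sqrt\lambda}, standard errors multiplied by \eqn{\sqrt\lambda}, and
#' p-values recomputed; deflation (\eqn{\lambda \le 1}) never rescales, the
#' standard convention. `lambda_gc` records the measured \eqn{\lambda} on
#' every row either way. The same correction can be applied per cohort before
#' pooling by passing a cohort table through `genomic_control_table()`.
#'
#' @param meta data.frame from [meta_analyze()].
#' @return The corrected data.frame.
#' @export
genomic_control <- function(meta) {
  if (!nrow(meta)) stopf("no meta-analysis records supplied")
  lambda <- median(meta$z_meta^2) / CHISQ1_MEDIAN
  meta$lambda_gc <- lambda
  if (lambda > 1) {
    s <- sqrt(lambda)
    meta$z_meta <- meta$z_meta / s
    meta$se_meta <- meta$se_meta * s
    meta$p_meta <- two_sided_p(meta$z_meta)
  }
  meta
}

#' @rdname genomic_control
#' @param table a cohort table; its z is taken as `beta/se`.
#' @export
genomic_control_table <- function(table) {
  if (!nrow(table)) stopf("no records supplied")
  z <- table$beta / table$se
  lambda <- median(z^2) / CHISQ1_MEDIAN
  if (lambda > 1) {
    s <- sqrt(lambda)
    table$se <- table$se * s
    table$p <- two_sided_p(z / s)
  }
  attr(table, "lambda_gc") <- lambda
  table
}

#' Expected vs observed -log10 p for a quantile-quantile plot
#'
#' Observed p-values are sorted ascending and paired with the uniform
#' quantiles \eqn{(i - 0.5)/n}.
#'
#' @param meta data.frame with a `p_meta` (or `p`) column.
#' @return data.frame with columns `expected` and `observed` (-log10 scale).
#' @export
qq_data <- function(meta) {
  p <- meta$p_meta %||% meta$p
  if (is.null(p) || !length(p)) stopf("no p-values supplied")
  p <- sort(p)
  n <- length(p)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n), observed = -log10(p))
}

#' Write a meta-analysis table as tab-separated text
#'
#' Columns: SNP, CHR, POS, EA, OA, EAF, BETA_META, SE_META, Z, P, K, N,
#' LAMBDA_GC; full double precision for exact round-trips.
#'
#' @param meta data.frame from [meta_analyze()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meta <- function(meta, path) {
  out <- data.frame(SNP = meta$snp_id, CHR = meta$chrom, POS = meta$pos,
                    EA = meta$effect_allele, OA = meta$other_allele,
                    EAF = sprintf("%.17g", meta$eaf),
                    BETA_META = sprintf("%.17g", meta$beta_meta),
                    SE_META = sprintf("%.17g", meta$se_meta),
                    Z = sprintf("%.17g", meta$z_meta),
                    P = sprintf("%.17g", meta$p_meta),
                    K = meta$k, N = meta$n,
                    LAMBDA_GC = sprintf("%.17g", meta$lambda_gc),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a meta-analysis table written by [write_meta()]
#' @param path path to the TSV.
#' @return data.frame in [meta_analyze()] layout.
#' @export
read_meta <- function(path) {
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
  out <- data.frame(
    snp_id = raw$SNP, chrom = raw$CHR, pos = as.integer(raw$POS),
    effect_allele = raw$EA, other_allele = raw$OA, eaf = as.numeric(raw$EAF),
    beta_meta = as.numeric(raw$BETA_META), se_meta = as.numeric(raw$SE_META),
    z_meta = as.numeric(raw$Z), p_meta = as.numeric(raw$P),
    k = as.integer(raw$K), n = as.integer(raw$N),
    lambda_gc = as.numeric(raw$LAMBDA_GC), stringsAsFactors = FALSE)
  out
}
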