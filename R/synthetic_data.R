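# Summary-level simulation with known causal structure. The generator works
# directly on Z scores: per locus, cohort Z vectors are drawn from a
# multivariate normal whose covariance is the locus LD matrix (AR(1),
# R_ij = rho^|i-j|) and whose mean is the LD-propagated signal of one causal
# SNP, scaled by sqrt(n_k / n_total) so the stated causal_z is the
# non-centrality of the *meta-analyzed* Z. Betas are back-computed from
# beta = z * se with se = 1/sqrt(2 n maf (1-maf)); allele frequencies are
# shared across cohorts. Simulating at the summary level is deliberate: the
# pipeline consumes only summary statistics.

#' Simulation configuration
#'
#' All randomness in the simulators flows from `seed`; re-running with the
#' same config is bit-identical.
#'
#' @param seed integer master seed.
#' @param n_cohorts number of cohorts.
#' @param n_per_cohort per-cohort sample sizes (recycled to `n_cohorts`);
#'   defaults 2741 and 15061, the two-cohort sizes of a white-blood-cell
#'   count meta-analysis.
#' @param n_loci number of loci.
#' @param snps_per_locus SNPs per locus; default 50 (10 kb spacing, so a
#'   locus spans the same +/-250 kb window the pipeline analyzes).
#' @param ld_rho AR(1) LD parameter in `[0, 1)`.
#' @param causal_fraction fraction of loci that carry one causal SNP.
#' @param causal_z non-centrality of the causal SNP's meta-analysis Z.
#' @param maf_range range effect-allele frequencies are drawn from.
#' @param mr_true_theta true causal effect of the exposure on the outcome.
#' @param mr_n_instruments number of MR instruments.
#' @param mr_pleiotropy_fraction fraction of instruments with a direct
#'   (pleiotropic) outcome effect.
#' @param mr_pleiotropy_mean mean of the planted per-SNP direct effects
#'   (sd fixed at 0.01).
#' @param mr_n_exposure exposure-side sample size (sets `se_x`);
#'   default 17802.
#' @param mr_n_outcome outcome-side sample size (sets `se_y`);
#'   default 200000, a large consortium outcome study, sized so instruments
#'   of the simulated effect scale carry informative Wald ratios.
#' @param trait trait label stamped on simulated tables.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_cohorts = 2, n_per_cohort = c(2741, 15061),
                       n_loci = 20, snps_per_locus = 50, ld_rho = 0.5,
                       causal_fraction = 0.5, causal_z = 8,
                       maf_range = c(0.1, 0.4), mr_true_theta = 0.2,
                       mr_n_instruments = 50, mr_pleiotropy_fraction = 0,
                       mr_pleiotropy_mean = 0.02, mr_n_exposure = 17802,
                       mr_n_outcome = 200000, trait = "WBCc") {
  cfg <- list(seed = as.integer(seed), n_cohorts = as.integer(n_cohorts),
              n_per_cohort = as.integer(rep_len(n_per_cohort, n_cohorts)),
              n_loci = as.integer(n_loci),
              snps_per_locus = as.integer(snps_per_locus),
              ld_rho = ld_rho, causal_fraction = causal_fraction,
              causal_z = causal_z, maf_range = maf_range,
              mr_true_theta = mr_true_theta,
              mr_n_instruments = as.integer(mr_n_instruments),
              mr_pleiotropy_fraction = mr_pleiotropy_fraction,
              mr_pleiotropy_mean = mr_pleiotropy_mean,
              mr_n_exposure = as.integer(mr_n_exposure),
              mr_n_outcome = as.integer(mr_n_outcome), trait = trait)
  with(cfg, {
    if (n_cohorts < 1 || n_loci < 1 || snps_per_locus < 1 ||
        mr_n_instruments < 1 || any(n_per_cohort < 1))
      stopf("all counts in a simulation config must be positive")
    if (ld_rho < 0 || ld_rho >= 1) stopf("ld_rho must be in [0, 1)")
    if (causal_fraction < 0 || causal_fraction > 1 ||
        mr_pleiotropy_fraction < 0 || mr_pleiotropy_fraction > 1)
      stopf("fractions must be in [0, 1]")
    if (maf_range[1] <= 0 || maf_range[2] >= 1 || maf_range[1] > maf_range[2])
      stopf("maf_range must satisfy 0 < low <= high < 1")
  })
  structure(cfg, class = c("sim_config", "list"))
}

ar1_corr <- function(m, rho) rho^abs(outer(seq_len(m), seq_len(m), "-"))

se_from_n <- function(n, eaf) 1 / sqrt(2 * n * eaf * (1 - eaf))

#' Simulate multi-cohort GWAS summary statistics with known causal SNPs
#'
#' @param config a [sim_config()].
#' @return list with `cohorts` (list of cohort tables), `truth` (data.frame
#'   `locus, causal_snp, causal_z`; `causal_snp` is `NA` for null loci),
#'   `ld` (per-locus LD correlation matrices, dimnames = SNP ids; exactly
#'   the matrices used for generation) and `config`.
#' @export
simulate_cohort_sumstats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    m <- config$snps_per_locus
    L <- config$n_loci
    R <- ar1_corr(m, config$ld_rho)
    cR <- chol(R)
    n_total <- sum(config$n_per_cohort)
    n_causal <- round(config$causal_fraction * L)
    causal_loci <- if (n_causal > 0) sort(sample.int(L, n_causal)) else integer()
    causal_idx <- rep(NA_integer_, L)
    causal_idx[causal_loci] <- sample.int(m, n_causal, replace = TRUE)

    snp_ids <- sprintf("snp_%03d_%03d", rep(seq_len(L), each = m),
                       rep(seq_len(m), L))
    pos <- rep((seq_len(L) - 1L) * 1000000L, each = m) +
      (rep(seq_len(m), L) - 1L) * 10000L + 1L
    eaf <- runif(L * m, config$maf_range[1], config$maf_range[2])
    alleles <- matrix(c("A", "G"), nrow = L * m, ncol = 2, byrow = TRUE)

    ld <- lapply(seq_len(L), function(l) {
      dimnames(R) <- list(snp_ids[(l - 1) * m + seq_len(m)],
                          snp_ids[(l - 1) * m + seq_len(m)])
      R
    })
    names(ld) <- sprintf("locus_%03d", seq_len(L))

    cohorts <- lapply(seq_len(config$n_cohorts), function(k) {
      n_k <- config$n_per_cohort[k]
      scale_k <- sqrt(n_k / n_total)
      z <- unlist(lapply(seq_len(L), function(l) {
        mu <- if (is.na(causal_idx[l])) rep(0, m) else
          R[, causal_idx[l]] * config$causal_z * scale_k
        mu + drop(crossprod(cR, rnorm(m)))
      }))
      se <- se_from_n(n_k, eaf)
      df <- data.frame(snp_id = snp_ids, chrom = "1", pos = pos,
                       effect_allele = alleles[, 1], other_allele = alleles[, 2],
                       eaf = eaf, beta = z * se, se = se, p = two_sided_p(z),
                       n = n_k, stringsAsFactors = FALSE)
      cohort_table(df, cohort_name = sprintf("cohort_%d", k),
                   trait = config$trait, validate = FALSE)
    })
    truth <- data.frame(
      locus = names(ld),
      causal_snp = ifelse(is.na(causal_idx), NA_character_,
                          snp_ids[(seq_len(L) - 1) * m + causal_idx]),
      causal_z = ifelse(is.na(causal_idx), 0, config$causal_z),
      stringsAsFactors = FALSE)
    list(cohorts = cohorts, truth = truth, ld = ld, config = config)
  })
}

#' Simulate a two-sample MR dataset with known causal effect
#'
#' Exposure effects are half-normal magnitudes (|N(0, 0.05^2)|, redrawn while
#' below 0.01 to keep Wald ratios stable), oriented to the
#' exposure-increasing allele. Outcome effects are
#' `beta_y = theta * beta_x + alpha + N(0, se_y^2)` where `alpha = 0` for
#' valid instruments and `alpha ~ N(mr_pleiotropy_mean, 0.01^2)` for the
#' pleiotropic fraction (independent of `beta_x`, so the InSIDE assumption
#' holds). Standard errors follow `1/sqrt(2 n maf (1-maf))` on each side.
#' Instruments are mutually unlinked (identity LD) and placed 1 Mb apart.
#' A random half of the outcome rows have their allele orientation swapped
#' (with the corresponding sign/frequency flip), so harmonization is
#' exercised end-to-end.
#'
#' @param config a [sim_config()].
#' @return list with `exposure` and `outcome` cohort tables, `ld` (identity
#'   r-squared matrix over the instruments), and `truth` (list: `theta`,
#'   `valid` logical vector named by SNP, `alpha` planted direct effects,
#'   `seed`).
#' @export
simulate_mr_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    J <- config$mr_n_instruments
    bx <- abs(rnorm(J, 0, 0.05))
    while (any(bx <= 0.01)) bx[bx <= 0.01] <- abs(rnorm(sum(bx <= 0.01), 0, 0.05))
    eaf <- runif(J, config$maf_range[1], config$maf_range[2])
    se_x <- se_from_n(config$mr_n_exposure, eaf)
    se_y <- se_from_n(config$mr_n_outcome, eaf)
    n_pleio <- round(config$mr_pleiotropy_fraction * J)
    pleio <- seq_len(J) <= n_pleio  # first block; order is random anyway
    alpha <- ifelse(pleio, rnorm(J, config$mr_pleiotropy_mean, 0.01), 0)
    by <- config$mr_true_theta * bx + alpha + rnorm(J, 0, se_y)

    snp_ids <- sprintf("ivsnp_%03d", seq_len(J))
    pos <- seq_len(J) * 1000000L
    exposure <- cohort_table(data.frame(
      snp_id = snp_ids, chrom = "1", pos = pos,
      effect_allele = "A", other_allele = "G", eaf = eaf,
      beta = bx, se = se_x, p = two_sided_p(bx / se_x),
      n = config$mr_n_exposure, stringsAsFactors = FALSE),
      cohort_name = "exposure", trait = config$trait, validate = FALSE)

    swap <- runif(J) < 0.5
    outcome <- cohort_table(data.frame(
      snp_id = snp_ids, chrom = "1", pos = pos,
      effect_allele = ifelse(swap, "G", "A"),
      other_allele = ifelse(swap, "A", "G"),
      eaf = ifelse(swap, 1 - eaf, eaf),
      beta = ifelse(swap, -by, by), se = se_y,
      p = two_sided_p(by / se_y), n = config$mr_n_outcome,
      stringsAsFactors = FALSE),
      cohort_name = "outcome", trait = "asthma", validate = FALSE)

    ld <- diag(J)
    dimnames(ld) <- list(snp_ids, snp_ids)
    list(exposure = exposure, outcome = outcome, ld = ld,
         truth = list(theta = config$mr_true_theta,
                      valid = setNames(!pleio, snp_ids),
                      alpha = setNames(alpha, snp_ids),
                      seed = config$seed))
  })
}

#' Write an LD (r-squared) matrix as TSV with SNP-id header row and column
#' @param ld square matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(SNP = rownames(ld),
                   apply(ld, 2, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("SNP", colnames(ld))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LD matrix written by [write_ld_matrix()]
#' @param path input path.
#' @return numeric matrix with SNP-id dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- raw[[1]]
  m
}
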