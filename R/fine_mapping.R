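# Bayesian fine-mapping under a single-causal-variant model: per-SNP Bayes
# factors from meta-analysis Z scores, posterior probabilities normalized
# within a locus, and 99% credible sets.
#
# The Bayes factor is BF = exp((Z^2 - log K)/2) with K the number of studies
# contributing to the SNP. Note this form carries no prior-variance
# shrinkage term; it grows without bound in |Z|, so posterior probabilities
# are always computed in log space (see posterior_probabilities).

#' Per-SNP Bayes factor from a meta-analysis Z score
#'
#' \eqn{BF = e^{(Z^2 - \log K)/2}}, with K the number of contributing
#' studies and the logarithm natural by default. `log = TRUE` returns
#' \eqn{\log BF}, which stays finite for |Z| far beyond the ~37.6 at which
#' the plain value overflows double precision.
#'
#' @param z meta-analysis Z score (vectorized).
#' @param k number of studies contributing to each SNP (scalar or vector).
#' @param log return the natural logarithm of the Bayes factor.
#' @param log_base base of the `log K` penalty; natural log by default.
#' @return Bayes factor(s), or their natural log.
#' @export
bayes_factor <- function(z, k, log = FALSE, log_base = exp(1)) {
  if (any(k < 1)) stopf("k must be >= 1 (number of contributing studies)")
  lbf <- (z^2 - base::log(k, base = log_base)) / 2
  if (log) lbf else exp(lbf)
}

#' Posterior probability of driving the association, per SNP at a locus
#'
#' Under a single-causal-variant assumption, each SNP's posterior probability
#' is its Bayes factor normalized by the sum of Bayes factors over all SNPs
#' at the locus: \eqn{PP_i = BF_i / \sum_j BF_j}. The computation subtracts
#' the maximum of \eqn{Z^2} inside the exponent before normalizing, which
#' leaves the result unchanged but avoids overflow for large |Z|. Ranking
#' ties on pp break by |z| descending then snp_id ascending, so output is
#' deterministic across input row orders.
#'
#' @param snp_id character vector of SNP ids at the locus.
#' @param z their meta-analysis Z scores.
#' @param k number of contributing studies per SNP (recycled if scalar).
#' @return data.frame sorted by rank: `snp_id, z, k, bf, pp, rank` (`bf` may
#'   be `Inf` for |z| beyond double range; `pp` is always finite and sums
#'   to 1).
#' @export
posterior_probabilities <- function(snp_id, z, k = 1) {
  if (!length(z)) stopf("no SNPs supplied for the locus")
  stopifnot(length(snp_id) == length(z))
  k <- rep_len(k, length(z))
  lbf <- bayes_factor(z, k, log = TRUE)
  m <- max(lbf)
  pp <- exp(lbf - m)
  pp <- pp / sum(pp)
  ord <- order(-pp, -abs(z), snp_id)
  out <- data.frame(snp_id = snp_id, z = z, k = k, bf = exp(lbf), pp = pp,
                    stringsAsFactors = FALSE)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Credible set of SNPs at a locus
#'
#' SNPs are sorted by posterior probability from highest to lowest and
#' counted until the cumulative posterior probability reaches `level`
#' (greater than or equal, with 1e-12 slack for floating error). The set is
#' minimal by construction: dropping its last member falls below `level`.
#' A locus is high-confidence when its top SNP alone carries more than 50%
#' of the posterior probability (strict).
#'
#' @param records data.frame from [posterior_probabilities()].
#' @param level credible level in (0, 1); default 0.99.
#' @return list with `members` (SNP ids in pp-descending order), `size`,
#'   `cumulative_pp`, `high_confidence`, `level`.
#' @export
credible_set <- function(records, level = 0.99) {
  if (level <= 0 || level >= 1) stopf("credible level must be in (0, 1)")
  tot <- sum(records$pp)
  if (abs(tot - 1) > 1e-6)
    stopf("posterior probabilities must sum to 1 (got %.6f)", tot)
  ord <- order(-records$pp, -abs(records$z), records$snp_id)
  pp <- records$pp[ord]
  cum <- cumsum(pp)
  size <- which(cum >= level - 1e-12)[1]
  list(members = records$snp_id[ord][seq_len(size)],
       size = size,
       cumulative_pp = cum[size],
       high_confidence = pp[1] > 0.5,
       level = level)
}

#' Is a credible set anchored by a high-confidence index SNP?
#'
#' True when the top SNP accounts for more than 50% of the posterior
#' probability of driving the association (strict inequality: exactly 50%
#' does not qualify).
#'
#' @param set list from [credible_set()].
#' @return logical scalar.
#' @export
is_high_confidence <- function(set) {
  if (!length(set$members)) stopf("empty credible set")
  isTRUE(set$high_confidence)
}

#' Fine-map every locus of a meta-analysis
#'
#' For each locus, takes all meta-analysis SNPs (genome-wide-significant or
#' not) within `window` of the lead SNP on the same chromosome, computes
#' posterior probabilities and the credible set.
#'
#' @param meta data.frame from [meta_analyze()] (after [genomic_control()] if
#'   used).
#' @param loci data.frame from [define_loci()].
#' @param window half-width around the lead SNP; default 250000.
#' @param level credible level; default 0.99.
#' @return list with `snps` (per-SNP data.frame across loci, with `locus_id`
#'   and `in_credible_set`) and `summary` (per-locus data.frame with
#'   `locus_id, n_snps, set_size, cumulative_pp, high_confidence, top_snp,
#'   top_pp`).
#' @export
finemap_loci <- function(meta, loci, window = 250000, level = 0.99) {
  per_snp <- list()
  per_locus <- list()
  for (i in seq_len(nrow(loci))) {
    sel <- meta$chrom == loci$chrom[i] &
      abs(meta$pos - loci$lead_pos[i]) <= window
    sub <- meta[sel, ]
    fm <- posterior_probabilities(sub$snp_id, sub$z_meta, sub$k)
    cs <- credible_set(fm, level = level)
    fm$in_credible_set <- fm$snp_id %in% cs$members
    fm <- cbind(locus_id = loci$locus_id[i], fm, stringsAsFactors = FALSE)
    per_snp[[i]] <- fm
    per_locus[[i]] <- data.frame(
      locus_id = loci$locus_id[i], n_snps = nrow(fm), set_size = cs$size,
      cumulative_pp = cs$cumulative_pp,
      high_confidence = cs$high_confidence,
      top_snp = fm$snp_id[1], top_pp = fm$pp[1], stringsAsFactors = FALSE)
  }
  list(snps = do.call(rbind, per_snp), summary = do.call(rbind, per_locus))
}
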