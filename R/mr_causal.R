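# Two-sample Mendelian randomization from exposure and outcome summary
# statistics: LD-clumped instrument selection, proxy substitution,
# exposure/outcome harmonization, and causal estimation by IVW, MR-Egger and
# weighted median with Cochran's Q heterogeneity and pleiotropy exclusion.
#
# Instrument tables ("instruments") are data.frames with columns
#   snp_id, beta_x, se_x, beta_y, se_y [, proxy_of]
# harmonized so beta_x and beta_y refer to the same effect allele.
# All first-order weights are w_j = (beta_x_j / se_y_j)^2, i.e. the inverse
# variance of the Wald ratio ignoring exposure-side uncertainty.

mr_result <- function(method, estimate, se, n_instruments, ...) {
  z <- estimate / se
  c(list(method = method, estimate = estimate, se = se,
         ci_lower = estimate - Z975 * se, ci_upper = estimate + Z975 * se,
         p = two_sided_p(z), n_instruments = n_instruments), list(...))
}

#' Select independent instruments by LD clumping
#'
#' Greedy p-ranked clumping: the most significant remaining SNP is accepted;
#' every remaining significant SNP that is both in LD with it
#' (`r^2 >= r2_max`) and within `window` base pairs on the same chromosome is
#' discarded; repeat. Accepted SNPs are therefore pairwise either below the
#' r-squared threshold or farther apart than the window.
#'
#' @param meta exposure meta-analysis data.frame (see [meta_analyze()]).
#' @param ld square symmetric matrix of r-squared values with unit diagonal,
#'   dimnames keyed by SNP id. SNPs absent from `ld` are treated as unlinked
#'   (r-squared 0) with a warning.
#' @param alpha instrument significance threshold; default `5e-9`.
#' @param r2_max LD threshold; default 0.001.
#' @param window clumping distance in base pairs; default 250000.
#' @return Character vector of accepted SNP ids, in acceptance order.
#' @export
clump_instruments <- function(meta, ld, alpha = 5e-9, r2_max = 0.001,
                              window = 250000) {
  sig <- select_significant(meta, alpha)
  if (!nrow(sig)) return(character())
  sig <- sig[order(sig$p_meta, sig$chrom, sig$pos), ]
  missing_ld <- setdiff(sig$snp_id, rownames(ld))
  if (length(missing_ld))
    warnf("%d SNP(s) absent from the LD matrix treated as unlinked (r2 = 0): %s",
          length(missing_ld), paste(utils::head(missing_ld, 5), collapse = ", "))
  r2_of <- function(a, b) {
    if (a %in% rownames(ld) && b %in% colnames(ld)) ld[a, b] else 0
  }
  accepted <- character()
  while (nrow(sig)) {
    lead <- sig[1, ]
    accepted <- c(accepted, lead$snp_id)
    r2 <- vapply(sig$snp_id, r2_of, numeric(1), b = lead$snp_id)
    near <- sig$chrom == lead$chrom & abs(sig$pos - lead$pos) <= window
    drop <- (r2 >= r2_max & near) | sig$snp_id == lead$snp_id
    sig <- sig[!drop, , drop = FALSE]
  }
  accepted
}

#' Substitute proxies for instruments missing from the outcome
#'
#' Instruments present in the outcome are used unchanged; an instrument
#' absent from the outcome is replaced by its highest-r-squared proxy that is
#' present (subject to `r2_min`); instruments with no eligible proxy are
#' dropped with a logged reason.
#'
#' @param instruments character vector of instrument SNP ids.
#' @param outcome outcome cohort table.
#' @param proxy_table data.frame with columns `snp_id`, `proxy`, `r2` (a
#'   user-supplied LD-proxy lookup).
#' @param r2_min minimum proxy r-squared; default 0.8.
#' @return data.frame with columns `snp_id`, `used_id` (`NA` when dropped),
#'   `proxy_r2` and `status` (`direct` / `proxy` / `dropped_no_proxy`).
#' @export
substitute_proxies <- function(instruments, outcome, proxy_table = NULL,
                               r2_min = 0.8) {
  res <- lapply(instruments, function(s) {
    if (s %in% outcome$snp_id)
      return(data.frame(snp_id = s, used_id = s, proxy_r2 = NA_real_,
                        status = "direct", stringsAsFactors = FALSE))
    cand <- if (is.null(proxy_table)) NULL else
      proxy_table[proxy_table$snp_id == s & proxy_table$r2 >= r2_min &
                    proxy_table$proxy %in% outcome$snp_id, , drop = FALSE]
    if (!is.null(cand) && nrow(cand)) {
      best <- cand[which.max(cand$r2), ]
      data.frame(snp_id = s, used_id = best$proxy, proxy_r2 = best$r2,
                 status = "proxy", stringsAsFactors = FALSE)
    } else {
      data.frame(snp_id = s, used_id = NA_character_, proxy_r2 = NA_real_,
                 status = "dropped_no_proxy", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}

#' Build harmonized exposure/outcome instrument records
#'
#' Harmonizes the outcome table to the exposure's allele orientation (see
#' [harmonize_alleles()]; the exposure is the reference), applies proxy
#' substitution for instruments missing from the outcome, and assembles the
#' instrument table used by the MR estimators. Proxy records take the
#' outcome effect of the proxy SNP as-is (the proxy lookup is assumed to
#' report alleles aligned to the instrument).
#'
#' @param exposure exposure meta-analysis data.frame (effects `beta_meta`,
#'   `se_meta`) or cohort table (effects `beta`, `se`).
#' @param outcome outcome cohort table.
#' @param instruments character vector of instrument SNP ids (e.g. from
#'   [clump_instruments()]).
#' @param proxy_table,r2_min see [substitute_proxies()].
#' @return Instrument data.frame (`snp_id, beta_x, se_x, beta_y, se_y,
#'   proxy_of`); the proxy log is attached as `attr(, "proxy_log")`.
#' @export
make_instruments <- function(exposure, outcome, instruments,
                             proxy_table = NULL, r2_min = 0.8) {
  bx <- exposure$beta_meta %||% exposure$beta
  sx <- exposure$se_meta %||% exposure$se
  exp_idx <- match(instruments, exposure$snp_id)
  if (anyNA(exp_idx))
    stopf("instrument(s) missing from the exposure table: %s",
          paste(instruments[is.na(exp_idx)], collapse = ", "))
  out_h <- harmonize_alleles(outcome, reference = exposure)
  plan <- substitute_proxies(instruments, out_h, proxy_table, r2_min)
  keep <- plan$status != "dropped_no_proxy"
  out_idx <- match(plan$used_id[keep], out_h$snp_id)
  dat <- data.frame(
    snp_id = plan$snp_id[keep],
    beta_x = bx[exp_idx[keep]], se_x = sx[exp_idx[keep]],
    beta_y = out_h$beta[out_idx], se_y = out_h$se[out_idx],
    proxy_of = ifelse(plan$status[keep] == "proxy", plan$snp_id[keep],
                      NA_character_),
    stringsAsFactors = FALSE)
  dat$snp_id[plan$status[keep] == "proxy"] <-
    plan$used_id[keep][plan$status[keep] == "proxy"]
  attr(dat, "proxy_log") <- plan
  dat
}

#' Inverse-variance-weighted causal estimate
#'
#' Fixed-effect, first-order weights:
#' \eqn{\hat\theta = \sum \beta_{Xj}\beta_{Yj}/se_{Yj}^2 \big/
#'   \sum \beta_{Xj}^2/se_{Yj}^2}, with
#' \eqn{se(\hat\theta) = (\sum \beta_{Xj}^2/se_{Yj}^2)^{-1/2}}. This equals
#' the slope of a weighted through-origin regression of outcome on exposure
#' effects. A single instrument degenerates to the Wald ratio
#' \eqn{\beta_Y/\beta_X} (returned with a warning).
#'
#' @param instruments instrument data.frame.
#' @param dispersion `"fixed"` (default) or `"multiplicative"`: the latter
#'   inflates the standard error by the root mean square of the weighted
#'   residuals when overdispersed (never deflates).
#' @return list: `method, estimate, se, ci_lower, ci_upper, p,
#'   n_instruments`, plus `q_stat, q_df, q_p` when J >= 2.
#' @export
mr_ivw <- function(instruments, dispersion = c("fixed", "multiplicative")) {
  dispersion <- match.arg(dispersion)
  J <- nrow(instruments)
  if (is.null(J) || J == 0) stopf("no instruments supplied")
  bx <- instruments$beta_x; by <- instruments$beta_y; sy <- instruments$se_y
  if (J == 1) {
    if (bx == 0) stopf("single instrument with beta_x = 0: Wald ratio undefined")
    warnf("single instrument: IVW degenerates to the Wald ratio")
    return(mr_result("IVW", by / bx, abs(sy / bx), 1L))
  }
  w <- 1 / sy^2
  est <- sum(w * bx * by) / sum(w * bx^2)
  se <- 1 / sqrt(sum(w * bx^2))
  q <- cochran_q(instruments, est)
  if (dispersion == "multiplicative") {
    phi <- max(1, q$q_stat / q$q_df)
    se <- se * sqrt(phi)
  }
  mr_result("IVW", est, se, J, q_stat = q$q_stat, q_df = q$q_df, q_p = q$q_p)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' intercept, weights \eqn{1/se_Y^2}, after orienting all exposure effects
#' non-negative (both betas flip sign together, which leaves ratios
#' unchanged). The slope is the causal estimate; the intercept, with its
#' standard error and p-value, is the directional-pleiotropy test. Standard
#' errors are model-based fixed-effect (no residual-dispersion scaling) by
#' default, matching the IVW convention.
#'
#' @inheritParams mr_ivw
#' @return list as in [mr_ivw()] plus `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_p`.
#' @export
mr_egger <- function(instruments, dispersion = c("fixed", "multiplicative")) {
  dispersion <- match.arg(dispersion)
  J <- nrow(instruments)
  if (is.null(J) || J < 3) stopf("MR-Egger needs at least 3 instruments")
  flip <- instruments$beta_x < 0
  bx <- ifelse(flip, -instruments$beta_x, instruments$beta_x)
  by <- ifelse(flip, -instruments$beta_y, instruments$beta_y)
  w <- 1 / instruments$se_y^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  coefs <- solve(XtWX, crossprod(X, w * by))
  vc <- solve(XtWX)
  if (dispersion == "multiplicative") {
    resid <- by - X %*% coefs
    phi <- max(1, sum(w * resid^2) / (J - 2))
    vc <- vc * phi
  }
  a <- coefs[1]; b <- coefs[2]
  se_a <- sqrt(vc[1, 1]); se_b <- sqrt(vc[2, 2])
  mr_result("Egger", b, se_b, J,
            egger_intercept = a, egger_intercept_se = se_a,
            egger_intercept_p = two_sided_p(a / se_a))
}

# Weight-interpolated median of Wald ratios; standardized cumulative weights
# s_j = (cum_j - w_j/2) / sum(w), linear interpolation at s = 0.5.
weighted_median_point <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(r[1])
  n <- length(r)
  if (s[n] <= 0.5) return(r[n])
  j <- max(which(s <= 0.5))
  if (s[j] == 0.5) r[j] else
    r[j] + (0.5 - s[j]) / (s[j + 1] - s[j]) * (r[j + 1] - r[j])
}

#' Weighted median causal estimate
#'
#' Per-instrument Wald ratios \eqn{\beta_Y/\beta_X} with weights
#' \eqn{(\beta_X/se_Y)^2}; the estimate interpolates the ratio at
#' standardized cumulative weight 0.5 and is consistent when valid
#' instruments carry more than half the weight. The standard error is a
#' seeded parametric bootstrap: exposure and outcome effects are resampled
#' from normal distributions centred on their estimates with their standard
#' errors, and the standard deviation of the replicate estimates is reported.
#'
#' @param instruments instrument data.frame.
#' @param n_boot bootstrap replicates; default 1000. `n_boot = 0` skips the
#'   bootstrap (`se`, `ci` and `p` are `NA`).
#' @param seed integer seed for the bootstrap.
#' @return list as in [mr_ivw()].
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = 1) {
  J <- nrow(instruments)
  if (is.null(J) || J < 3) stopf("weighted median needs at least 3 instruments")
  bx <- instruments$beta_x; by <- instruments$beta_y
  sx <- instruments$se_x; sy <- instruments$se_y
  est <- weighted_median_point(by / bx, (bx / sy)^2)
  if (n_boot <= 0)
    return(c(list(method = "WeightedMedian", estimate = est, se = NA_real_,
                  ci_lower = NA_real_, ci_upper = NA_real_, p = NA_real_,
                  n_instruments = J)))
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bxb <- rnorm(J, bx, sx)
      byb <- rnorm(J, by, sy)
      weighted_median_point(byb / bxb, (bxb / sy)^2)
    }, numeric(1))
  })
  mr_result("WeightedMedian", est, stats::sd(boots), J)
}

#' Cochran's Q heterogeneity statistic for instrument ratios
#'
#' \eqn{Q = \sum_j w_j (ratio_j - \theta)^2} with
#' \eqn{w_j = (\beta_{Xj}/se_{Yj})^2}, df = J - 1, upper-tail chi-square
#' p-value.
#'
#' @param instruments instrument data.frame (J >= 2).
#' @param theta the pooled causal estimate the ratios are compared against
#'   (typically the IVW estimate).
#' @return list with `q_stat`, `q_df`, `q_p`.
#' @export
cochran_q <- function(instruments, theta) {
  J <- nrow(instruments)
  if (is.null(J) || J < 2) stopf("Cochran's Q needs at least 2 instruments")
  ratio <- instruments$beta_y / instruments$beta_x
  w <- (instruments$beta_x / instruments$se_y)^2
  q <- sum(w * (ratio - theta)^2)
  df <- J - 1L
  list(q_stat = q, q_df = df, q_p = pchisq(q, df, lower.tail = FALSE))
}

#' Exclude pleiotropic outlier instruments by Q contribution
#'
#' One pass: each instrument's contribution to Cochran's Q about the IVW
#' estimate, \eqn{q_j = w_j (ratio_j - \hat\theta_{IVW})^2}, is compared to
#' the upper \eqn{\alpha/J} quantile of \eqn{\chi^2_1} (Bonferroni);
#' instruments exceeding it are excluded and the IVW estimate is refit once
#' on the retained set. A single pass avoids iterative outlier chasing.
#'
#' @param instruments instrument data.frame (J >= 3).
#' @param q_alpha family-wise error rate for the outlier test; default 0.05.
#' @return list with `instruments` (retained rows), `excluded` (SNP ids),
#'   `result` (IVW refit on the retained set), `q_contrib` (per-SNP
#'   contributions), `cutoff`.
#' @export
exclude_pleiotropic <- function(instruments, q_alpha = 0.05) {
  J <- nrow(instruments)
  if (is.null(J) || J < 3) stopf("pleiotropy exclusion needs at least 3 instruments")
  theta <- mr_ivw(instruments)$estimate
  ratio <- instruments$beta_y / instruments$beta_x
  w <- (instruments$beta_x / instruments$se_y)^2
  qj <- w * (ratio - theta)^2
  cutoff <- qchisq(1 - q_alpha / J, df = 1)
  out <- qj > cutoff
  if (all(out)) stopf("pleiotropy exclusion would remove every instrument")
  retained <- instruments[!out, , drop = FALSE]
  rownames(retained) <- NULL
  list(instruments = retained, excluded = instruments$snp_id[out],
       result = mr_ivw(retained), q_contrib = setNames(qj, instruments$snp_id),
       cutoff = cutoff)
}

#' Two-sided p-value implied by a reported estimate and 95% CI
#'
#' Recovers the Wald standard error from the confidence-interval width,
#' \eqn{se = (upper - lower) / (2 \times 1.959964)}, and returns
#' \eqn{p = 2\Phi(-|estimate|/se)}. Useful for checking the internal
#' consistency of published estimate/CI/p triples. Warns when the estimate
#' is not the CI midpoint (beyond 1e-3).
#'
#' @param estimate reported point estimate.
#' @param ci_lower,ci_upper reported 95% confidence bounds.
#' @return implied two-sided p-value.
#' @export
implied_wald_p <- function(estimate, ci_lower, ci_upper) {
  if (ci_upper <= ci_lower) stopf("ci_upper must exceed ci_lower")
  if (abs(estimate - (ci_lower + ci_upper) / 2) > 1e-3)
    warnf("estimate is not the midpoint of the CI (off by %.4g)",
          abs(estimate - (ci_lower + ci_upper) / 2))
  se <- (ci_upper - ci_lower) / (2 * Z975)
  two_sided_p(estimate / se)
}

#' Run all MR estimators and diagnostics on one instrument set
#'
#' @param instruments instrument data.frame (J >= 3 for the full panel).
#' @param n_boot,seed bootstrap controls for the weighted median.
#' @return data.frame with one row per method (IVW, Egger, WeightedMedian):
#'   `method, estimate, se, ci_lower, ci_upper, p, n_instruments, q_stat,
#'   q_df, q_p, egger_intercept, egger_intercept_se, egger_intercept_p`.
#' @export
mr_report <- function(instruments, n_boot = 1000, seed = 1) {
  res <- list(mr_ivw(instruments), mr_egger(instruments),
              mr_weighted_median(instruments, n_boot = n_boot, seed = seed))
  cols <- c("method", "estimate", "se", "ci_lower", "ci_upper", "p",
            "n_instruments", "q_stat", "q_df", "q_p", "egger_intercept",
            "egger_intercept_se", "egger_intercept_p")
  rows <- lapply(res, function(r) {
    vals <- lapply(cols, function(cn) r[[cn]] %||% NA)
    setNames(as.data.frame(vals, stringsAsFactors = FALSE), cols)
  })
  do.call(rbind, rows)
}
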