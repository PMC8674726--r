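test_that("clumping enforces the joint r2-and-distance rule", {
  m <- make_meta_df(p = c(1e-12, 1e-10), pos = c(1e6, 1.1e6))
  ld <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(m$snp_id, m$snp_id))

  # linked and nearby -> one instrument, the better p
  expect_equal(clump_instruments(m, ld), "rs1")

  # r2 below threshold passes even within the window
  ld2 <- ld; ld2[1, 2] <- ld2[2, 1] <- 0.0005
  expect_equal(clump_instruments(m, ld2), c("rs1", "rs2"))

  # linked but far apart (different chromosomes) -> both kept
  m2 <- make_meta_df(p = c(1e-12, 1e-10), pos = c(1e6, 1e6),
                     chrom = c("1", "2"))
  ld0 <- diag(2); dimnames(ld0) <- list(m2$snp_id, m2$snp_id)
  expect_equal(clump_instruments(m2, ld0), c("rs1", "rs2"))

  # SNP missing from the LD matrix: warned, treated as unlinked
  expect_warning(got <- clump_instruments(m, ld[1, 1, drop = FALSE]),
                 "absent from the LD matrix")
  expect_equal(got, c("rs1", "rs2"))
})

test_that("accepted instruments are pairwise unlinked or distant", {
  set.seed(88)
  for (i in 1:20) {
    n <- 25
    m <- make_meta_df(p = 10^runif(n, -15, -9),
                      pos = sort(sample.int(3e6, n)),
                      chrom = sample(c("1", "2"), n, replace = TRUE))
    ld <- random_r2_matrix(m$snp_id)
    acc <- clump_instruments(m, ld)
    pos <- setNames(m$pos, m$snp_id)
    chr <- setNames(m$chrom, m$snp_id)
    for (a in acc) for (b in acc) if (a != b) {
      far <- chr[a] != chr[b] || abs(pos[a] - pos[b]) > 250000
      expect_true(ld[a, b] < 0.001 || far)
    }
  }
})

test_that("proxy substitution keeps direct hits, takes the best eligible proxy, drops the rest", {
  outcome <- cohort_table(make_sumstats_df(3))  # rs1..rs3 present
  proxies <- data.frame(snp_id = c("rs9", "rs9", "rs8"),
                        proxy = c("rs2", "rs3", "rs3"),
                        r2 = c(0.85, 0.95, 0.5), stringsAsFactors = FALSE)
  got <- substitute_proxies(c("rs1", "rs9", "rs8"), outcome, proxies)
  expect_equal(got$status, c("direct", "proxy", "dropped_no_proxy"))
  expect_equal(got$used_id, c("rs1", "rs3", NA))  # best proxy by r2
  expect_equal(got$proxy_r2[2], 0.95)
})

test_that("IVW matches the closed form, the Wald ratio, and a through-origin WLS oracle", {
  one <- suppressWarnings(mr_ivw(make_instruments_df(0.2, 0.05, 0.01)))
  expect_equal(one$estimate, 0.25)
  expect_warning(mr_ivw(make_instruments_df(0.2, 0.05, 0.01)), "Wald")
  expect_error(mr_ivw(make_instruments_df(0, 0.05, 0.01)))
  expect_error(mr_ivw(make_instruments_df(numeric(), numeric(), numeric())))

  two <- mr_ivw(make_instruments_df(c(0.1, 0.2), c(0.02, 0.05), 0.01))
  expect_equal(two$estimate, 0.24)
  expect_equal(two$se, 1 / sqrt(500))
  expect_equal(two$ci_lower, two$estimate - 1.959964 * two$se)

  # shared ratio r -> exactly r with zero heterogeneity
  cons <- mr_ivw(make_instruments_df(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3) * 0.4,
                                     c(0.01, 0.02, 0.03)))
  expect_equal(cons$estimate, 0.4)
  expect_equal(cons$q_stat, 0)
  expect_equal(cons$q_p, 1)

  set.seed(99)
  for (i in 1:20) {
    J <- sample(3:30, 1)
    dat <- make_instruments_df(rnorm(J, 0, 0.1), rnorm(J, 0, 0.05),
                               runif(J, 0.005, 0.05))
    fit <- lm(beta_y ~ 0 + beta_x, weights = 1 / se_y^2, data = dat)
    got <- mr_ivw(dat)
    expect_equal(got$estimate, unname(coef(fit)[1]), tolerance = 1e-12)
  }
})

test_that("MR-Egger fits a weighted line with intercept after orienting exposures positive", {
  exact <- mr_egger(make_instruments_df(c(0.1, 0.2, 0.3), c(0.03, 0.05, 0.07),
                                        0.01))
  expect_equal(exact$estimate, 0.2, tolerance = 1e-12)
  expect_equal(exact$egger_intercept, 0.01, tolerance = 1e-12)

  null <- mr_egger(make_instruments_df(c(0.1, 0.2, 0.3), c(0, 0, 0), 0.01))
  expect_equal(null$estimate, 0)
  expect_equal(null$egger_intercept, 0)

  # constraining the intercept to zero recovers IVW (WLS algebra)
  dat <- make_instruments_df(c(0.05, 0.1, 0.22, 0.3), c(0.01, 0.03, 0.04, 0.06),
                             c(0.01, 0.02, 0.01, 0.03))
  fit0 <- lm(beta_y ~ 0 + beta_x, weights = 1 / se_y^2, data = dat)
  expect_equal(mr_ivw(dat)$estimate, unname(coef(fit0)[1]), tolerance = 1e-12)

  # orientation: flipping the sign of both betas of some instruments is a no-op
  flip <- dat
  flip$beta_x[c(1, 3)] <- -flip$beta_x[c(1, 3)]
  flip$beta_y[c(1, 3)] <- -flip$beta_y[c(1, 3)]
  expect_equal(mr_egger(flip)$estimate, mr_egger(dat)$estimate)
  expect_equal(mr_egger(flip)$egger_intercept, mr_egger(dat)$egger_intercept)

  expect_error(mr_egger(make_instruments_df(c(0.1, 0.2), c(0.1, 0.2), 0.01)))
})

test_that("weighted median interpolates standardized cumulative weights", {
  # equal weights, outlier-robust
  dat <- make_instruments_df(c(0.1, 0.1, 0.1), c(0.1, 0.2, 1.0), 0.01)
  expect_equal(mr_weighted_median(dat, n_boot = 0)$estimate, 2)

  # weights (0.6, 0.2, 0.2) on ratios (1, 2, 3): s = (0.3, 0.7, 0.9)
  w <- c(0.6, 0.2, 0.2)
  bx <- sqrt(w) * 0.01  # se_y = 0.01 -> w = (bx/se_y)^2 proportional to w
  dat2 <- make_instruments_df(bx, bx * c(1, 2, 3), 0.01)
  expect_equal(mr_weighted_median(dat2, n_boot = 0)$estimate, 1.5,
               tolerance = 1e-12)

  # equal weights and odd J: the simple median of ratios
  set.seed(7)
  r <- rnorm(7)
  dat3 <- make_instruments_df(rep(0.1, 7), 0.1 * r, 0.01)
  expect_equal(mr_weighted_median(dat3, n_boot = 0)$estimate, median(r))

  # degenerate limit: shared ratio, vanishing uncertainty
  dat4 <- make_instruments_df(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3) * 0.7,
                              1e-6, se_x = 1e-6)
  wm <- mr_weighted_median(dat4, n_boot = 200, seed = 42)
  expect_equal(wm$estimate, 0.7, tolerance = 1e-6)
  expect_lt(wm$se, 1e-3)

  # bootstrap se is reproducible under a fixed seed
  dat5 <- make_instruments_df(c(0.1, 0.15, 0.3), c(0.02, 0.04, 0.05), 0.01)
  expect_equal(mr_weighted_median(dat5, n_boot = 100, seed = 3)$se,
               mr_weighted_median(dat5, n_boot = 100, seed = 3)$se)

  expect_error(mr_weighted_median(make_instruments_df(0.1, 0.1, 0.01)))
})

test_that("Cochran's Q measures weighted ratio dispersion about theta", {
  cons <- make_instruments_df(c(0.1, 0.2), c(0.05, 0.1), 0.01)
  q0 <- cochran_q(cons, 0.5)
  expect_equal(q0$q_stat, 0)
  expect_equal(q0$q_p, 1)

  # weights 100 each, ratios (0.2, 0.3) about theta = 0.25 -> Q = 0.5
  dat <- make_instruments_df(c(0.1, 0.1), c(0.02, 0.03), 0.01)
  q <- cochran_q(dat, 0.25)
  expect_equal(q$q_stat, 0.5)
  expect_equal(q$q_df, 1)
  expect_equal(q$q_p, pchisq(0.5, 1, lower.tail = FALSE))

  expect_error(cochran_q(make_instruments_df(0.1, 0.1, 0.01), 1))
})

test_that("pleiotropy exclusion removes only Bonferroni-significant Q outliers, once", {
  # homogeneous: nothing excluded
  hom <- make_instruments_df(c(0.1, 0.2, 0.3, 0.15), c(0.1, 0.2, 0.3, 0.15) * 0.3,
                             0.01)
  ex <- exclude_pleiotropic(hom)
  expect_equal(length(ex$excluded), 0)
  expect_equal(nrow(ex$instruments), 4)

  # one planted outlier (ratio 2 vs 0.2 elsewhere, i.e. 10x) is excluded and
  # the estimate refit on the clean set
  bx <- c(0.2, 0.25, 0.3, 0.15, 0.1, 0.22, 0.28, 0.18, 0.26, 0.12)
  by <- 0.2 * bx
  by[5] <- 2 * bx[5]
  out <- exclude_pleiotropic(make_instruments_df(bx, by, 0.01))
  expect_equal(out$excluded, "iv5")
  expect_equal(out$result$estimate, 0.2, tolerance = 1e-12)

  # three equally, mildly discordant instruments survive Bonferroni
  theta <- 0.2
  bx3 <- c(0.1, 0.1, 0.1)
  dev <- 0.005  # q_j = (0.1/0.01)^2 * (dev/bx)^2 = 0.25 << chi2 cutoff
  by3 <- theta * bx3 + c(-dev, 0, dev)
  ex3 <- exclude_pleiotropic(make_instruments_df(bx3, by3, 0.01))
  expect_equal(length(ex3$excluded), 0)

  expect_error(exclude_pleiotropic(hom[1:2, ]))
})

test_that("implied Wald p reproduces reported MR consistency checks", {
  expect_equal(implied_wald_p(-0.079, -0.779, 0.621), 0.825, tolerance = 1e-3)
  expect_lt(implied_wald_p(0.38, 0.221, 0.539), 0.001)
  expect_equal(implied_wald_p(0, -1.959964, 1.959964), 1.0)
  expect_error(implied_wald_p(0, 1, 1))
  expect_warning(implied_wald_p(0.5, 0, 0.8), "midpoint")
})

test_that("harmonized instrument assembly flips outcome effects to the exposure orientation", {
  mr <- simulate_mr_dataset(sim_config(seed = 13, mr_n_instruments = 20))
  exp_meta <- meta_analyze(list(mr$exposure))
  dat <- make_instruments(exp_meta, mr$outcome, rownames(mr$ld))
  expect_equal(nrow(dat), 20)
  # after harmonization the ratio structure matches the planted effects:
  # beta_y - theta*beta_x has mean ~0 under no pleiotropy
  expect_lt(abs(mean(dat$beta_y - 0.2 * dat$beta_x)), 0.005)
  # proxies: drop an instrument from the outcome and route through a proxy
  out2 <- mr$outcome[mr$outcome$snp_id != "ivsnp_001", ]
  proxies <- data.frame(snp_id = "ivsnp_001", proxy = "ivsnp_002", r2 = 0.9)
  dat2 <- make_instruments(exp_meta, out2, c("ivsnp_001", "ivsnp_003"),
                           proxy_table = proxies)
  expect_equal(dat2$proxy_of[dat2$snp_id == "ivsnp_002"], "ivsnp_001")
})

test_that("mr_report returns one row per estimator with heterogeneity and pleiotropy columns", {
  mr <- simulate_mr_dataset(sim_config(seed = 29, mr_n_instruments = 30))
  dat <- make_instruments(meta_analyze(list(mr$exposure)), mr$outcome,
                          rownames(mr$ld))
  rep <- mr_report(dat, n_boot = 50, seed = 1)
  expect_equal(rep$method, c("IVW", "Egger", "WeightedMedian"))
  expect_true(all(rep$n_instruments == 30))
  expect_false(is.na(rep$q_p[1]))
  expect_false(is.na(rep$egger_intercept_p[2]))
})
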