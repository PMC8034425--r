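test_that("alteration frequency matches counts, headline and planted rates", {
  calls <- cbind(EGFR = c(rep(1, 821), rep(0, 10967 - 821)),
                 OTHER = rep(0, 10967))
  rownames(calls) <- sprintf("S%05d", 1:10967)
  m <- alteration_matrix(calls, rep(c("GBM", "LUAD"), length.out = 10967))
  f <- alteration_frequency(m, "EGFR")
  expect_equal(f$altered, 821)
  expect_equal(f$pct, 7)  # 821/10967 rounds to the printed headline
  expect_equal(alteration_frequency(m, "OTHER")$pct, 0)
  expect_error(alteration_frequency(m, "NOPE"), "unknown gene")

  # planted 12% rate recovered within a point at n = 5000
  gm <- gen_alteration_matrix(n_samples = 5000,
                              gene_base_rates = c(EGFR = 0.12, G2 = 0.05),
                              index_gene = "EGFR",
                              planted_odds_ratios = c(G2 = 1), seed = 8)
  f2 <- alteration_frequency(gm$matrix, "EGFR", by_cancer_type = TRUE)
  expect_lt(abs(f2$pct - 12), 1.01)
  expect_true(all(c("cancer_type", "pct") %in% names(f2$by_type)))
})

test_that("two-sided Fisher p matches enumeration, including conventions", {
  expect_equal(fisher_exact(0, 10, 10, 0), 2 / choose(20, 10),
               tolerance = 1e-10)
  expect_equal(fisher_exact(5, 5, 5, 5), 1)
  expect_equal(fisher_exact(3, 1, 1, 3), 34 / 70, tolerance = 1e-10)
  expect_equal(fisher_exact(0, 0, 0, 0), 1)  # all-zero convention
  # sweep all tables with small margins against the enumeration oracle
  for (a in 0:4) for (b in 0:3) for (c in 0:3) for (d in 0:4) {
    if (a + b + c + d == 0) next
    expect_equal(fisher_exact(a, b, c, d), oracle_fisher2(a, b, c, d),
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment is step-up and monotone with q in [p, 1]", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(3)
  p <- runif(50)^2
  q <- bh_fdr(p)
  expect_equal(q, oracle_bh(p))
  expect_true(all(q >= p & q <= 1))
  expect_false(is.unsorted(q[order(p)]))          # monotone in sorted p
  # constant vectors are fixed points of the adjustment
  expect_equal(bh_fdr(rep(0.2, 8)), rep(0.2, 8))
})

test_that("co-occurrence enrichment reproduces printed log-ratio semantics", {
  # the printed-percentage convention
  expect_equal(log_ratio_pct(8.85, 1.69), 2.39)
  expect_equal(log_ratio_pct(7.91, 1.34), 2.56)
  expect_equal(log_ratio_pct(4.69, 7.51), -0.68)

  gm <- gen_alteration_matrix(n_samples = 10000, seed = 13)
  enr <- cooccurrence_enrichment(gm$matrix, "EGFR")
  planted <- gm$truth$gene[gm$truth$planted_or > 1]
  expect_true(all(enr$log_ratio[enr$gene %in% planted] > 1.5))
  expect_true(all(enr$enriched_in[enr$gene %in% planted] == "altered"))
  expect_true(all(enr$q >= enr$p - 1e-12))
  expect_true(all(enr$q[enr$gene %in% planted] < 0.01))

  # identical frequencies in both groups
  calls <- cbind(IDX = rep(c(1, 0), each = 10), G = rep(c(1, 0), 10))
  rownames(calls) <- paste0("s", 1:20)
  e0 <- cooccurrence_enrichment(alteration_matrix(calls, rep("T", 20)), "IDX")
  expect_equal(e0$log_ratio, 0)
  expect_equal(e0$p, 1)
  expect_equal(e0$enriched_in, "neither")
})

test_that("label shuffling yields near-uniform enrichment p-values", {
  set.seed(21)
  n <- 2000; n_genes <- 200
  calls <- cbind(IDX = rbinom(n, 1, 0.1),
                 matrix(rbinom(n * n_genes, 1, 0.08), n,
                        dimnames = list(NULL, paste0("G", 1:n_genes))))
  rownames(calls) <- paste0("s", 1:n)
  enr <- cooccurrence_enrichment(alteration_matrix(calls, rep("T", n)), "IDX")
  ks <- suppressWarnings(ks.test(enr$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Wilcoxon comparison: exact small-sample p and power at a shift", {
  expect_equal(wilcoxon_ranksum(1:3, 10:12, alternative = "less")$p, 0.05)
  same <- wilcoxon_ranksum(c(1, 3, 5, 9), c(1, 3, 5, 9))
  expect_gt(same$p, 0.9)  # identical groups: no evidence of a shift
  # delta = 2 sd, n = 50/50: essentially always detected
  set.seed(17)
  rej <- mean(replicate(100, {
    wilcoxon_ranksum(rnorm(50), rnorm(50, 2))$p < 0.001
  }))
  expect_gte(rej, 0.95)
})

test_that("median split sends ties to the low group", {
  x <- setNames(1:10, paste0("s", 1:10))
  sp <- median_split(x)
  expect_length(sp$high, 5); expect_length(sp$low, 5)
  sp2 <- median_split(setNames(c(1, 2, 2, 3), paste0("s", 1:4)))
  expect_equal(sp2$high, "s4")
  expect_setequal(sp2$low, c("s1", "s2", "s3"))
  expect_warning(median_split(setNames(rep(2, 4), paste0("s", 1:4))),
                 "degenerate")
})

test_that("KM estimator matches the hand product-limit and empirical survival", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored: flat at 1
  km2 <- km_curve(c(4, 5, 6), c(0, 0, 0))
  expect_true(all(km_surv_at(km2, c(0, 5, 10)) == 1))
  # no censoring: equals the empirical survival function
  set.seed(31)
  t <- rexp(80, 0.1)
  km3 <- km_curve(t, rep(1, 80))
  emp <- vapply(km3$times, function(u) mean(t > u), 1)
  expect_equal(km3$surv, emp, tolerance = 1e-12)
  # with censoring: matches the hand oracle
  ev <- rbinom(80, 1, 0.7)
  km4 <- km_curve(t, ev)
  orc <- oracle_km(t, ev)
  expect_equal(km_surv_at(km4, orc$times), orc$surv, tolerance = 1e-12)
})

test_that("synthetic exponential survival recovers its median", {
  gs <- gen_survival(n_per_group = 500, baseline_rate = 0.02,
                     hazard_ratio = 1, censor_rate = 0, seed = 7)
  km <- km_curve(gs$records$time_months, gs$records$event)
  expect_lt(abs(km$median - log(2) / 0.02) / (log(2) / 0.02), 0.1)
})

test_that("log-rank test recovers a planted hazard ratio with a sane CI", {
  gs <- gen_survival(n_per_group = 300, hazard_ratio = 2,
                     censor_rate = 0.005, seed = 7)
  lr <- logrank_test(gs$records$time_months, gs$records$event,
                     gs$records$group)
  expect_gt(lr$hr, 1.6); expect_lt(lr$hr, 2.5)
  expect_lt(lr$p, 1e-6)
  expect_true(lr$hr_ci[1] < lr$hr && lr$hr < lr$hr_ci[2])

  # identical groups: no signal
  t <- rep(c(2, 4, 6, 8), 2); e <- rep(1, 8)
  g <- rep(c("A", "B"), each = 4)
  lr0 <- logrank_test(t, e, g)
  expect_lt(lr0$chi2, 1e-8)
  expect_equal(lr0$hr, 1, tolerance = 1e-6)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("A", "B")), "no events")
})
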