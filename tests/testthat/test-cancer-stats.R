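test_that("Pearson correlation matches hand computation and cor.test", {
  r1 <- pearson_with_test(1:10, 1:10)
  expect_equal(r1$r, 1)
  expect_false(r1$weak_flag)

  # hand computation: r = 3 / sqrt(28/3)
  r2 <- pearson_with_test(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r2$r, 3 / sqrt(28 / 3), tolerance = 1e-12)
  expect_equal(round(r2$r, 4), 0.982)

  expect_error(pearson_with_test(rep(1, 5), 1:5), "zero variance")

  set.seed(73)
  for (k in 1:100) {
    n <- sample(5:50, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- pearson_with_test(x, y)
    # direct covariance formula
    r_direct <- mean((x - mean(x)) * (y - mean(y))) /
      (sd(x) * sd(y)) * n / (n - 1)
    expect_equal(got$r, r_direct, tolerance = 1e-12)
    ct <- cor.test(x, y)
    expect_equal(got$p, ct$p.value, tolerance = 1e-12)
    expect_equal(got$t, unname(ct$statistic), tolerance = 1e-10)
    expect_identical(got$weak_flag, got$r > -0.5 & got$r < 0.5)
  }

  # bivariate normal rho = 0.7 at n = 500 recovered within 0.1
  set.seed(79)
  x <- rnorm(500); y <- 0.7 * x + sqrt(1 - 0.49) * rnorm(500)
  expect_lt(abs(pearson_with_test(x, y)$r - 0.7), 0.1)
})

test_that("Fisher-z intervals cover the true correlation at 95%", {
  hits <- vapply(1:1000, function(k) {
    set.seed(k)
    x <- rnorm(100)
    y <- 0.5 * x + sqrt(0.75) * rnorm(100)
    ci <- pearson_with_test(x, y)
    ci$ci_lo <= 0.5 && 0.5 <= ci$ci_hi
  }, logical(1))
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("per-cancer-type correlation table reflects the cohort structure", {
  cfg <- sim_config(seed = 83, expression = list(
    n_tumor = 200L, n_control = 200L, r_tumor = 0.1, r_control = 0.9))
  ex <- simulate_expression_pair(cfg, "CTA")
  tab <- correlate_by_cancer(ex)
  ctrl <- tab[tab$cohort == "control", ]
  tum <- tab[tab$cohort == "tumor", ]
  expect_gt(ctrl$r, tum$r)
  expect_true(tum$weak_flag)
  expect_false(ctrl$weak_flag)

  # two cancer types -> 4 rows in deterministic order
  ex2 <- rbind(ex, {
    e <- simulate_expression_pair(sim_config(seed = 84), "CTB"); e
  })
  tab2 <- correlate_by_cancer(ex2, adjust = TRUE)
  expect_equal(nrow(tab2), 4L)
  expect_identical(tab2$cancer_type, c("CTA", "CTA", "CTB", "CTB"))
  expect_identical(tab2$cohort, rep(c("control", "tumor"), 2))
  expect_true(all(tab2$p_bh >= tab2$p))

  # missing cohort -> warning, single row
  solo <- ex[ex$cohort == "tumor", ]
  expect_warning(tab3 <- correlate_by_cancer(solo), "fewer than 3")
  expect_equal(nrow(tab3), 1L)
})

test_that("KS statistic equals the brute-force ECDF gap (exhaustive)", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$D, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")

  # every pair of multisets of sizes <= 8 over 3 values, exhaustively
  sets <- unlist(lapply(1:8, multisets3), recursive = FALSE)
  for (x in sets[seq(1, length(sets), 2)]) {
    for (y in sets[seq(1, length(sets), 3)]) {
      expect_equal(ks_two_sample(x, y)$D, brute_ks_D(x, y))
    }
  }
})

test_that("KS asymptotic p agrees with stats::ks.test on untied samples", {
  set.seed(89)
  for (k in 1:25) {
    x <- rnorm(sample(20:120, 1))
    y <- rnorm(sample(20:120, 1), mean = runif(1, -1, 1))
    got <- ks_two_sample(x, y)
    ref <- stats::ks.test(x, y, exact = FALSE)
    expect_equal(got$D, unname(ref$statistic), tolerance = 1e-12)
    # same asymptotic Kolmogorov formula; series evaluation differs in
    # truncation, so agreement is to ~1e-4
    expect_equal(got$p, ref$p.value, tolerance = 1e-3)
  }
  # exact small-sample path
  x <- c(0.1, 0.5, 0.9); y <- c(0.2, 0.6, 1.4)
  expect_equal(ks_two_sample(x, y, exact = TRUE)$p,
               stats::ks.test(x, y, exact = TRUE)$p.value)
})

test_that("median split sends ties low and rejects degenerate input", {
  expect_identical(median_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_identical(median_split(c(5, 5, 5, 9)), c("low", "low", "low", "high"))
  expect_error(median_split(rep(2, 6)), "degenerate")
  expect_error(median_split(c(1, 2)), "length")
  set.seed(97)
  for (k in 1:20) {
    v <- sample(1:8, 20, replace = TRUE)
    grp <- median_split(v)
    ties <- sum(v == stats::median(v))
    imbalance <- abs(sum(grp == "high") - sum(grp == "low"))
    # with c values tied at the cut and a below it, the imbalance is
    # 2(a + c) - n <= 2c - 2 for even n; without ties the split is exact
    if (ties == 0) expect_equal(imbalance, 0) else
      expect_lte(imbalance, 2 * ties)
  }
})

test_that("KM estimates match closed-form product-limit values", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  kc <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(kc$surv == 1))

  # times [1, 2+, 3]: S(1) = 2/3, S(3) = 0 (risk set 1 at t = 3)
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)

  # no censoring: KM equals the empirical survival function
  set.seed(101)
  tt <- rexp(40, 0.1)
  km3 <- km_estimate(tt, rep(1, 40))
  expect_equal(km3$surv, vapply(km3$time, function(v) mean(tt > v),
                                numeric(1)))
  # monotone non-increasing always
  expect_true(all(diff(km3$surv) <= 0))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "time")
})

test_that("log-rank matches the hand hypergeometric table", {
  lr0 <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                      rep(c("a", "b"), each = 3))
  expect_equal(lr0$chisq, 0)
  expect_equal(lr0$p, 1)

  # A: events at 1, 2; B: events at 3, 4
  # t=1: O=1 E=1/2 V=1/4; t=2: O=1 E=1/3 V=2/9; t>=3: no A at risk
  # chisq = (2 - 5/6)^2 / (1/4 + 2/9) = 49/17
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$chisq, 49 / 17, tolerance = 1e-10)
  expect_equal(lr$p, pchisq(49 / 17, 1, lower.tail = FALSE))

  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "no events")

  # power: hazard ratio 3 at n = 200/group detected in >= 95% of 200 reps
  hits <- vapply(1:200, function(k) {
    set.seed(200 + k)
    tA <- rexp(200, 0.03); tB <- rexp(200, 0.01)
    logrank_test(c(tA, tB), rep(1, 400), rep(c("A", "B"), each = 200))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("subgroup survival isolates a disomy-3-only expression effect", {
  # effect present only in disomy 3: monosomy 3 hazards are equalized
  cfg <- sim_config(seed = 103, survival = list(
    n_cases = 400L, frac_monosomy3 = 0.5, hazard_low = 0.05,
    hazard_high = 0.01, hazard_low_m3 = 0.03, hazard_high_m3 = 0.03,
    censor_time = 80))
  co <- simulate_survival_cohort(cfg)
  d3 <- subgroup_survival(co, "disomy3")
  expect_lt(d3$logrank$p, 0.05)
  expect_true(all(c("high", "low") %in% names(d3$km)))

  # the monosomy 3 stratum is null: its log-rank p is calibrated
  ps <- vapply(1:500, function(k) {
    cfgk <- sim_config(seed = 5000 + k, survival = list(
      n_cases = 160L, frac_monosomy3 = 0.5, hazard_low = 0.05,
      hazard_high = 0.01, hazard_low_m3 = 0.03, hazard_high_m3 = 0.03,
      censor_time = 80))
    subgroup_survival(simulate_survival_cohort(cfgk), "monosomy3")$logrank$p
  }, numeric(1))
  expect_gte(mean(ps < 0.05), 0.035)
  expect_lte(mean(ps < 0.05), 0.065)

  # smoke on a 4-case cohort and empty-filter error
  tiny <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 1, 0),
                     expression = c(1, 2, 3, 4),
                     chr3_class = rep("disomy3", 4))
  expect_s3_class(subgroup_survival(tiny, "all")$logrank, "data.frame")
  expect_error(subgroup_survival(tiny, "monosomy3"), "too small")
})

test_that("UVM-style cohort summaries count classes and SF3B1 by group", {
  set.seed(107)
  co <- simulate_survival_cohort(sim_config(seed = 107))
  co$sf3b1_mut <- 0L
  d3 <- which(co$chr3_class == "disomy3")
  grp <- median_split(co$expression[d3])
  co$sf3b1_mut[d3[grp == "high"][1:3]] <- 1L
  co$sf3b1_mut[d3[grp == "low"][1]] <- 1L
  s <- summarize_uvm_cohort(co)
  expect_equal(s$n_cases, 80)
  expect_equal(s$n_disomy3 + s$n_monosomy3, 80)
  expect_equal(s$sf3b1_high_expr, 3)
  expect_equal(s$sf3b1_low_expr, 1)
})
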