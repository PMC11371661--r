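test_that("Lilliefors Monte-Carlo null is calibrated and detects non-normality", {
  # scaled-down calibration: n = 100, 300-replicate null, 300 trials
  set.seed(51)
  rej <- mean(replicate(300, {
    ks_normality(rnorm(100), mc_reps = 300)$p < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.08)
  power <- mean(replicate(30, {
    ks_normality(runif(500), mc_reps = 300)$p < 0.01
  }))
  expect_gte(power, 0.95)
  expect_error(ks_normality(rep(1, 10)), "zero variance")
  expect_error(ks_normality(rnorm(3)), "at least 4")
})

test_that("Lilliefors statistic and p agree with the nortest reference", {
  set.seed(52)
  x <- rnorm(80, 3, 2)
  got <- ks_normality(x, mc_reps = 4000)
  ref <- nortest::lillie.test(x)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 0.06)
  # the naive K-S p is anticonservative-side: never smaller family error
  expect_gte(got$p_naive, got$p - 0.05)
})

test_that("one-way ANOVA matches the textbook decomposition", {
  set.seed(53)
  y <- rnorm(60); g <- rep(c("a", "b", "c"), each = 20)
  got <- anova_oneway(y, g)
  # textbook oracle
  N <- 60; k <- 3
  gm <- mean(y)
  ssb <- sum(tapply(y, g, length) * (tapply(y, g, mean) - gm)^2)
  ssw <- sum((y - ave(y, g))^2)
  F_o <- (ssb / (k - 1)) / (ssw / (N - k))
  expect_equal(got$F, F_o, tolerance = 1e-12)
  expect_equal(got$df, c(2, 57))
  expect_equal(got$p, pf(F_o, 2, 57, lower.tail = FALSE), tolerance = 1e-12)
  # identical group values -> F = 0, p = 1
  same <- anova_oneway(rep(c(1, 2, 3, 4), 3),
                       rep(c("a", "b", "c"), each = 4))
  expect_equal(same$F, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
})

test_that("two-group ANOVA F equals the squared pooled t", {
  set.seed(54)
  y <- c(rnorm(12, 0), rnorm(15, 0.8))
  g <- rep(c("a", "b"), c(12, 15))
  got <- anova_oneway(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(got$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(got$p, tt$p.value, tolerance = 1e-12)
})

test_that("summary-statistic ANOVA is exact against raw-data ANOVA", {
  set.seed(55)
  for (rep in 1:10) {
    y <- rnorm(50, sd = runif(1, 0.5, 3))
    g <- sample(c("a", "b", "c"), 50, replace = TRUE)
    if (any(table(g) < 2)) next
    raw <- anova_oneway(y, g)
    smry <- anova_oneway_summary(n = tapply(y, g, length),
                                 mean = tapply(y, g, mean),
                                 sd = tapply(y, g, sd))
    expect_equal(smry$F, raw$F, tolerance = 1e-10)
    expect_equal(smry$p, raw$p, tolerance = 1e-10)
  }
  expect_equal(anova_oneway_summary(c(5, 5), c(2, 2), c(1, 1))$F, 0)
  expect_error(anova_oneway_summary(c(1, 5), c(2, 2), c(1, 1)), "n >= 2")
})

test_that("published cognitive summaries reproduce the printed significance", {
  # three-group processing-speed, memory and inhibition summaries
  sdmt <- anova_oneway_summary(c(54, 106, 79), c(26.18, 32.18, 40.42),
                               c(11.85, 12.43, 14.33))
  avlt <- anova_oneway_summary(c(54, 106, 79), c(54.96, 61.25, 64.00),
                               c(13.29, 12.55, 12.36))
  scwt <- anova_oneway_summary(c(54, 106, 79), c(179.8, 146.21, 133.53),
                               c(58.93, 44.79, 37.93))
  expect_lt(sdmt$p, 0.001)
  expect_lt(avlt$p, 0.001)
  expect_lt(scwt$p, 0.001)
})

test_that("LSD post hoc equals the pooled two-sample t for two groups", {
  set.seed(56)
  y <- c(rnorm(10), rnorm(14, 0.5)); g <- rep(c("a", "b"), c(10, 14))
  got <- lsd_posthoc(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(got$p["a", "b"], tt$p.value, tolerance = 1e-12)
  expect_equal(got$df, 22)
  same <- lsd_posthoc(n = c(8, 8), mean = c(1, 1), sd = c(0.5, 0.5))
  expect_equal(same$p[1, 2], 1)
})

test_that("chi-square recomputes the published clinical-marker p-values", {
  diabetes <- rbind(yes = c(24, 49, 29), no = c(30, 57, 50))
  expect_equal(round(chi_square_independence(diabetes)$p, 3), 0.414)
  smoking <- rbind(yes = c(16, 26, 22), no = c(38, 80, 57))
  expect_equal(round(chi_square_independence(smoking)$p, 3), 0.762)
  flat <- rbind(c(10, 20), c(20, 40))
  got <- chi_square_independence(flat)
  expect_equal(got$chi2, 0, tolerance = 1e-12)
  expect_equal(got$p, 1)
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "margin")
  expect_warning(chi_square_independence(rbind(c(2, 3), c(50, 60))),
                 "below 5")
})

test_that("covariate-free ANCOVA reduces exactly to one-way ANOVA", {
  set.seed(57)
  y <- rnorm(45); g <- rep(c("a", "b", "c"), each = 15)
  fit <- ancova_group_test(y, g, NULL)
  av <- anova_oneway(y, g)
  expect_equal(fit$F, av$F, tolerance = 1e-10)
  expect_equal(fit$p, av$p, tolerance = 1e-10)
  expect_equal(unname(fit$df), unname(av$df))
  # adjusted means equal raw means without covariates
  expect_equal(sort(fit$adjusted_means), sort(tapply(y, g, mean)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # and the post hoc equals classic LSD
  lsd <- lsd_posthoc(y, g)
  expect_equal(fit$posthoc$p["a", "b"], lsd$p["a", "b"], tolerance = 1e-10)
})

test_that("ANCOVA agrees with car type-II F and emmeans adjusted means", {
  set.seed(58)
  n <- 90
  g <- factor(rep(c("p1", "p2", "ctrl"), each = 30),
              levels = c("p1", "p2", "ctrl"))
  age <- rnorm(n, 60, 8); motion <- rnorm(n, 0.12, 0.04)
  y <- 0.3 + 0.02 * (g == "p1") - 0.01 * age + 0.5 * motion + rnorm(n, 0, 0.05)
  fit <- ancova_group_test(y, g, data.frame(age = age, motion = motion))
  ref <- lm(y ~ age + motion + g)
  ca <- car::Anova(ref, type = 2)
  expect_equal(fit$F, ca["g", "F value"], tolerance = 1e-10)
  expect_equal(fit$p, ca["g", "Pr(>F)"], tolerance = 1e-10)
  em <- as.data.frame(emmeans::emmeans(ref, "g"))
  expect_equal(unname(fit$adjusted_means[as.character(em$g)]),
               em$emmean, tolerance = 1e-8)
  pairsp <- as.data.frame(emmeans::emmeans(ref, pairwise ~ g,
                                           adjust = "none")$contrasts)
  for (i in seq_len(nrow(pairsp))) {
    gs <- strsplit(as.character(pairsp$contrast[i]), " - ")[[1]]
    expect_equal(fit$posthoc$p[gs[1], gs[2]], pairsp$p.value[i],
                 tolerance = 1e-8)
  }
})

test_that("ANCOVA unmasks a group effect hidden by a confounder", {
  set.seed(59)
  g <- factor(rep(c("pat", "ctrl"), each = 40))
  conf <- rnorm(80) + 1.5 * (g == "pat")
  y <- -0.5 * (g == "pat") + 0.5 * conf + rnorm(80, 0, 0.3)
  raw_p <- anova_oneway(y, g)$p
  adj_p <- ancova_group_test(y, g, data.frame(conf = conf))$p
  expect_lt(adj_p, 1e-6)
  expect_gt(raw_p, adj_p)
})

test_that("partial correlation matches the inverse-correlation-matrix oracle", {
  set.seed(60)
  for (rep in 1:10) {
    n <- 40
    Z <- matrix(rnorm(n * 3), n)
    x <- rnorm(n) + Z %*% c(0.5, -0.2, 0.1)
    y <- rnorm(n) + Z %*% c(-0.3, 0.4, 0.2) + 0.3 * x
    got <- partial_correlation(x, y, as.data.frame(Z))
    R <- cor(cbind(x, y, Z))
    P <- solve(R)
    oracle <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    expect_equal(got$r, oracle, tolerance = 1e-10)
    expect_equal(got$df, n - 2 - 3)
  }
})

test_that("partial correlation nests Pearson and handles exact dependence", {
  set.seed(61)
  x <- rnorm(30); y <- 0.6 * x + rnorm(30)
  got <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)
  z <- rnorm(30)
  y2 <- x + 2 * z - 1
  got2 <- partial_correlation(x, y2, data.frame(z = z))
  expect_equal(got2$r, 1, tolerance = 1e-10)
  # missing scores are excluded pairwise
  y3 <- y; y3[c(2, 9)] <- NA
  expect_equal(partial_correlation(x, y3)$n, 28)
})

test_that("BH adjustment matches the literal step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5),
               tolerance = 1e-14)
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  set.seed(62)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_equal(bh_fdr(q), bh_oracle(q), tolerance = 1e-12)  # idempotent-compatible
    expect_true(all(q[order(p)] == cummax(q[order(p)])))      # monotone
    expect_true(all(q <= 1 & q >= p - 1e-15))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
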