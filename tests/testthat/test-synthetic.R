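test_that("base SC is symmetric, nonnegative, with stronger within-module edges", {
  part <- toy_partition(6)
  set.seed(41)
  within_means <- between_means <- numeric(100)
  for (r in 1:100) {
    sc <- generate_base_sc(6, part)
    m <- unclass(sc)
    memb <- part$module[region_labels(sc)]
    ut <- which(upper.tri(m), arr.ind = TRUE)
    within <- memb[ut[, 1]] == memb[ut[, 2]]
    within_means[r] <- mean(m[ut][within])
    between_means[r] <- mean(m[ut][!within])
    expect_true(all(m >= 0))
    expect_equal(m, t(m), tolerance = 1e-15)
  }
  expect_gt(mean(within_means), mean(between_means))
  set.seed(99); a <- generate_base_sc(6, part)
  set.seed(99); b <- generate_base_sc(6, part)
  expect_identical(unclass(a), unclass(b))
  expect_error(generate_base_sc(2), ">= 3")
})

test_that("high latent loading yields near-perfect estimated coupling, zero yields none", {
  part <- default_partition()
  set.seed(42)
  hi <- mean(replicate(3, {
    sc <- generate_base_sc(90, part)
    fc_hi <- generate_fc_from_sc(sc, 0.99, noise_sd = 0.05, partition = part)
    coupling_profile(fc_hi, sc, part)$auc[["whole_brain"]]
  }))
  expect_gt(hi, 0.9)
  sc <- generate_base_sc(90, part)
  fc_null <- generate_fc_from_sc(sc, 0, partition = part)
  net <- threshold_proportional(fc_null, 0.6)
  E <- attr(net, "k")
  expect_lt(abs(as.numeric(whole_brain_coupling(net, sc))), 3 / sqrt(E))
})

test_that("module-specific loadings produce correctly ordered modular couplings", {
  set.seed(43)
  part <- toy_partition(40)
  sch <- threshold_scheme(values = seq(0.2, 0.8, 0.2))
  ordered <- replicate(100, {
    sc <- generate_base_sc(40, part)
    fc <- generate_fc_from_sc(sc, c(A = 0.2, B = 0.8, whole_brain = 0.5),
                              partition = part)
    auc <- coupling_profile(fc, sc, part, sch)$auc
    auc[["A"]] < auc[["B"]]
  })
  expect_gte(mean(ordered), 0.95)
})

test_that("estimated coupling increases with the latent loading", {
  set.seed(44)
  part <- toy_partition(30)
  grid <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  est <- sapply(grid, function(a) {
    mean(replicate(5, {
      sc <- generate_base_sc(30, part)
      fc <- generate_fc_from_sc(sc, a, partition = part)
      coupling_profile(fc, sc, part)$auc[["whole_brain"]]
    }))
  })
  expect_true(all(diff(est) > 0))
})

test_that("degenerate SC and out-of-range targets are rejected", {
  part <- toy_partition(6)
  flat <- connectivity_matrix(
    {m <- matrix(0.4, 6, 6); diag(m) <- 0
     dimnames(m) <- list(paste0("R", 1:6), paste0("R", 1:6)); m},
    "structural")
  expect_error(generate_fc_from_sc(flat, 0.5, partition = part), "degenerate")
  sc <- {set.seed(1); generate_base_sc(6, part)}
  expect_error(generate_fc_from_sc(sc, 1.0, partition = part), "\\(-1, 1\\)")
  expect_error(generate_fc_from_sc(sc, 0.5, noise_sd = 0, partition = part),
               "positive")
})

test_that("latent_loading is monotone, odd, and inverts near the design points", {
  x <- seq(-0.9, 0.9, by = 0.05)
  a <- latent_loading(x)
  expect_true(all(diff(a) > 0))
  expect_equal(latent_loading(-0.3), -latent_loading(0.3), tolerance = 1e-12)
  expect_equal(latent_loading(0), 0)
  expect_lte(max(abs(a)), 0.995)
  # the design knot: estimated 0.2835 came from latent 0.50
  expect_equal(latent_loading(0.2835), 0.50, tolerance = 1e-6)
})

test_that("time series reproduce a pairwise target correlation", {
  set.seed(45)
  w <- matrix(c(0, 0.9, 0.9, 0), 2, 2)
  # minimal 2-region FC; relax class checks by building a 3-region target
  w3 <- matrix(0, 3, 3)
  w3[1, 2] <- w3[2, 1] <- 0.9
  fc <- connectivity_matrix(w3, "functional")
  ts <- generate_time_series(fc, 10000)
  emp <- cor(ts[1, ], ts[2, ])
  expect_gte(emp, 0.88)
  expect_lte(emp, 0.92)
})

test_that("null target gives |r| at the analytic null magnitude", {
  # for independent normal series, E|r| = sqrt(2 / (pi * T))
  set.seed(46)
  Tlen <- 400
  fc <- connectivity_matrix(
    {m <- matrix(0, 10, 10)
     dimnames(m) <- list(paste0("R", 1:10), paste0("R", 1:10)); m},
    "functional")
  mean_abs <- mean(replicate(10, {
    ts <- generate_time_series(fc, Tlen)
    cm <- abs(cor(t(unclass(ts))))
    mean(cm[upper.tri(cm)])
  }))
  expect_equal(mean_abs, sqrt(2 / (pi * Tlen)), tolerance = 0.08)
})

test_that("time-series generation is deterministic and validates T", {
  fc <- connectivity_matrix(
    {m <- matrix(0, 4, 4); m[1, 2] <- m[2, 1] <- 0.5
     dimnames(m) <- list(paste0("R", 1:4), paste0("R", 1:4)); m},
    "functional")
  set.seed(7); a <- generate_time_series(fc, 50)
  set.seed(7); b <- generate_time_series(fc, 50)
  expect_identical(unclass(a), unclass(b))
  expect_error(generate_time_series(fc, 2), "T must be")
  expect_warning(generate_time_series(fc, 4), "rank deficient")
})

test_that("nearest_correlation: fixed points and grid-search optimality", {
  expect_equal(nearest_correlation(diag(3)), diag(3), tolerance = 1e-12)
  set.seed(47)
  # a guaranteed-PD correlation matrix is (numerically) a fixed point
  A <- cov2cor(crossprod(matrix(rnorm(25), 5)) + diag(5))
  expect_equal(nearest_correlation(A), A, tolerance = 1e-8)
  # indefinite 3x3 with off-diagonals (a, a, b)
  M <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.3, 0.9, -0.3, 1), 3)
  expect_lt(min(eigen(M, symmetric = TRUE)$values), 0)
  got <- nearest_correlation(M)
  expect_equal(diag(got), rep(1, 3), tolerance = 1e-9)
  expect_gte(min(eigen(got, symmetric = TRUE)$values), -1e-9)
  dist_got <- sqrt(sum((got - M)^2))
  # brute-force grid over the same symmetric (x, x, y) family
  grid <- seq(-0.999, 0.999, by = 0.004)
  best <- Inf
  for (x in grid) for (y in grid) {
    C <- matrix(c(1, x, x, x, 1, y, x, y, 1), 3)
    # PSD iff both eigenvalue branches nonnegative: evals are
    # 1 - y, and roots of (1-l)^2 + (1-l)(... ) -- use closed-form check
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 0) next
    dd <- sqrt(sum((C - M)^2))
    if (dd < best) best <- dd
  }
  expect_lte(dist_got, best + 1e-3)
  expect_error(nearest_correlation(matrix(c(1, 0.2, 0.5, 1), 2)), "symmetric")
})

test_that("cohort generation honors counts, records truth, reproduces bytes", {
  part <- toy_partition(12)
  cfg <- sim_config(
    n_regions = 12, partition = part,
    group_n = c("CSVD-s" = 3L, "CSVD-m" = 4L, "HC" = 3L),
    coupling_targets = list(
      "CSVD-s" = c(whole_brain = 0.25, A = 0.2, B = 0.3),
      "CSVD-m" = c(whole_brain = 0.28, A = 0.22, B = 0.32),
      "HC" = c(whole_brain = 0.30, A = 0.25, B = 0.35)),
    seed = 5L)
  coh <- generate_cohort(cfg)
  expect_length(coh$subjects, 10)
  expect_equal(unname(table(coh$cohort$group)), c(3L, 4L, 3L),
               ignore_attr = TRUE)
  expect_identical(unique(coh$truth$scope), c("whole_brain", "A", "B"))
  expect_equal(nrow(coh$truth), 30)
  # scores present and tied to covariates/coupling
  expect_true(all(c("MoCA", "AVLT", "SCWT", "SDMT", "TMT") %in%
                    names(coh$cohort)))
  # matrices satisfy the full validation invariants by reconstruction
  for (s in coh$subjects[1:2]) {
    expect_s3_class(connectivity_matrix(unclass(s$fc), "functional"),
                    "connectivity_matrix")
    expect_s3_class(connectivity_matrix(unclass(s$sc), "structural"),
                    "connectivity_matrix")
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_cohort(generate_cohort(cfg), d1)
  write_synthetic_cohort(generate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("efficiency shift orders group-mean global efficiency", {
  part <- toy_partition(24)
  tg <- c(whole_brain = 0.3, A = 0.3, B = 0.3)
  cfg <- sim_config(
    n_regions = 24, partition = part,
    group_n = c(lo = 5L, mid = 5L, hi = 5L),
    coupling_targets = list(lo = tg, mid = tg, hi = tg),
    efficiency_shift = c(lo = -0.4, mid = 0, hi = 0.4),
    cognition_model = NULL, seed = 11L)
  coh <- generate_cohort(cfg)
  sch <- threshold_scheme(values = seq(0.2, 0.6, 0.1))
  eg <- vapply(coh$subjects, function(s)
    topology_profile(s$fc, sch)$auc[["Eglob"]], 0)
  mns <- tapply(eg, coh$cohort$group, mean)
  expect_lt(mns[["lo"]], mns[["mid"]])
  expect_lt(mns[["mid"]], mns[["hi"]])
})

test_that("sim_config validates its invariants", {
  part <- toy_partition(6)
  tg <- list(g1 = c(whole_brain = 0.3, A = 0.2, B = 0.3),
             g2 = c(whole_brain = 0.3, A = 0.2, B = 0.3))
  expect_error(sim_config(n_regions = 5, partition = part,
                          group_n = c(g1 = 3L, g2 = 3L),
                          coupling_targets = tg), "disagrees")
  expect_error(sim_config(n_regions = 6, partition = part,
                          group_n = c(g1 = 1L, g2 = 3L),
                          coupling_targets = tg), ">= 2")
  bad <- tg; bad$g1[["whole_brain"]] <- 1.2
  expect_error(sim_config(n_regions = 6, partition = part,
                          group_n = c(g1 = 3L, g2 = 3L),
                          coupling_targets = bad), "\\(-1, 1\\)")
  expect_error(sim_config(n_regions = 6, partition = part,
                          group_n = c(g1 = 3L, g2 = 3L),
                          coupling_targets = tg, T = 10), "n_regions \\+ 10")
})
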