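test_that("rank-sum handles the canonical small cases", {
  expect_equal(rank_sum_exact(c(1, 4), c(2, 3))$p_value, 1)   # symmetric
  expect_equal(rank_sum_exact(c(1, 2), c(3, 4, 5))$p_value, 0.2)  # 2/C(5,2)
  expect_equal(rank_sum_exact(c(2, 2), c(2, 2, 2))$p_value, 1)    # degenerate
})

test_that("exact rank-sum equals brute-force enumeration on tied data", {
  set.seed(301)
  for (i in 1:200) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    vals <- sample(1:4, n + m, replace = TRUE)   # heavy ties
    x <- vals[seq_len(n)]; y <- vals[-seq_len(n)]
    expect_equal(rank_sum_exact(x, y)$p_value, oracle_rank_sum_p(x, y))
  }
})

test_that("exact rank-sum matches the reference implementation without ties", {
  set.seed(302)
  for (i in 1:50) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    expect_equal(rank_sum_exact(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("signed-rank handles the canonical small cases", {
  expect_equal(signed_rank_paired(c(2, 3, 4), c(1, 1, 1))$p_value, 0.25)  # 2/8
  r <- signed_rank_paired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p_value, 1)
  expect_match(r$flag, "all differences zero")
})

test_that("exact signed-rank equals the 2^n sign-flip oracle", {
  set.seed(303)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    d <- sample(-3:3, n, replace = TRUE)
    a <- d + 10; b <- rep(10, n)
    expect_equal(signed_rank_paired(a, b)$p_value, oracle_signed_rank_p(a, b))
  }
})

test_that("rank tests are invariant to monotone relabeling and label swap", {
  set.seed(304)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(5, 0.5)
    p0 <- rank_sum_exact(x, y)$p_value
    expect_equal(rank_sum_exact(exp(x), exp(y))$p_value, p0)   # monotone map
    expect_equal(rank_sum_exact(y, x)$p_value, p0)             # two-sided symmetry
  }
})

test_that("large-sample rank-sum approximation tracks the reference", {
  set.seed(305)
  x <- rnorm(12); y <- rnorm(14, 0.8)
  p <- rank_sum_exact(x, y)$p_value
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(p, ref, tolerance = 1e-9)
})

test_that("LME collapses to OLS with one section per brain at zero ratio", {
  set.seed(306)
  brain <- 1:12; grp <- rep(0:1, each = 6)
  y <- 5 + 3 * grp + rnorm(12)
  at0 <- rabiestrace:::lme_random_intercept_at(y, brain, grp, 0)
  ols <- stats::lm(y ~ grp)
  expect_equal(as.numeric(at0$beta), unname(stats::coef(ols)), tolerance = 1e-10)
})

test_that("LME ML estimates are unbiased in a parameter-recovery simulation", {
  set.seed(307)
  b1 <- vapply(1:500, function(r) {
    brain <- rep(1:10, each = 2); grp <- rep(c(0, 1), each = 10)
    y <- 1000 + 200 * grp + rnorm(10, 0, 50)[brain] + rnorm(20, 0, 60)
    lme_random_intercept(y, brain, grp)$beta[2]
  }, numeric(1))
  expect_lt(abs(mean(b1) - 200), 3 * sd(b1) / sqrt(length(b1)))
})

test_that("the profiled ML solution dominates a 100-point grid oracle", {
  set.seed(308)
  for (r in 1:5) {
    brain <- rep(1:8, each = 2); grp <- rep(c(0, 1), each = 8)
    y <- 100 + 30 * grp + rnorm(8, 0, 20)[brain] + rnorm(16, 0, 15)
    fit <- lme_random_intercept(y, brain, grp)
    grid <- lme_profile_grid(y, brain, grp, c(0, exp(seq(log(1e-6), log(100),
                                                         length.out = 99))))
    expect_gte(fit$loglik + 1e-6, max(grid))
  }
})

test_that("LME matches the reference mixed-model library under ML", {
  skip_if_not_installed("lme4")
  set.seed(309)
  brain <- rep(1:10, times = sample(1:3, 10, replace = TRUE))
  grp <- as.numeric(brain > 5)
  y <- 1000 + 150 * grp + rnorm(10, 0, 40)[brain] + rnorm(length(brain), 0, 50)
  fit <- lme_random_intercept(y, brain, grp)
  ref <- lme4::lmer(y ~ grp + (1 | brain), REML = FALSE)
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_equal(fit$sigma2, stats::sigma(ref)^2, tolerance = 1e-3)
})

test_that("LME is scale-equivariant and its Wald p is scale-free", {
  set.seed(310)
  brain <- rep(1:10, each = 2); grp <- rep(c(0, 1), each = 10)
  y <- 100 + 20 * grp + rnorm(10, 0, 10)[brain] + rnorm(20, 0, 12)
  f1 <- lme_random_intercept(y, brain, grp)
  f2 <- lme_random_intercept(7 * y, brain, grp)
  expect_equal(f2$beta, 7 * f1$beta, tolerance = 1e-6)
  expect_equal(f2$sigma2, 49 * f1$sigma2, tolerance = 1e-4)
  expect_equal(f2$sigma_b2, 49 * f1$sigma_b2, tolerance = 1e-3)
  expect_equal(f2$p_group, f1$p_group, tolerance = 1e-8)
})

test_that("significance stars follow the alpha conventions", {
  expect_equal(p_stars(c(0.2, 0.04, 0.009, 0.0009, 0.00009)),
               c("ns", "*", "**", "***", "****"))
})

test_that("compare_groups emits the planned bookkeeping and skips tiny groups", {
  sim <- simulate_study(default_cohort_config(), seed = 6)
  conn <- connectivity_table(sim$animals, sim$counts)
  keys <- c("MS_DB", "CA1_Or_ipsi", "CA3_Py_ipsi")
  plan <- default_comparison_plan(keys)
  plan$sex_split <- FALSE
  res <- compare_groups(conn, plan)
  # 4 contrasts x (3 regions x 2 metrics + 1 overall)
  expect_equal(nrow(res), 4 * (length(keys) * 2 + 1))
  expect_equal(attr(res, "n_tests"), nrow(res))
  # drop one group to n = 1 -> its contrasts are skipped with a flag
  small <- conn[conn$group != "WT_young" | conn$animal_id == conn$animal_id[1], ]
  res2 <- compare_groups(small, plan)
  expect_true(any(grepl("skipped", res2$flag)))
  expect_true(all(is.na(res2$p_value[res2$flag != ""])))
})

test_that("the cross-check mode agrees with the reference on untied contrasts", {
  sim <- simulate_study(default_cohort_config(), seed = 16)
  conn <- connectivity_table(sim$animals, sim$counts)
  plan <- default_comparison_plan(c("MS_DB", "CA3_Py_ipsi"))
  plan$sex_split <- FALSE
  cc <- cross_check_contrasts(conn, plan)
  expect_gt(cc$n_untied, 0)
  expect_lt(cc$max_abs_dp_untied, 1e-9)
})

test_that("a planted MS-DB deficit is detected at study scale with high power", {
  cfg <- default_cohort_config()
  set.seed(311)
  seeds <- sample.int(2^31 - 6000000L, 200)
  rej <- 0
  for (i in seq_len(200)) {
    a <- simulate_cohort(cfg, "WT_young", seeds[i])
    b <- simulate_cohort(cfg, "APP_KI_young", seeds[i] + 5000000L)
    ca <- a$counts[a$counts$key == "MS_DB", ]
    cb <- b$counts[b$counts$key == "MS_DB", ]
    va <- ca$count / a$animals$S[match(ca$animal_id, a$animals$animal_id)]
    vb <- cb$count / b$animals$S[match(cb$animal_id, b$animals$animal_id)]
    if (rank_sum_exact(va, vb)$p_value <= 0.05) rej <- rej + 1
  }
  expect_gte(rej / 200, 0.8)
})

test_that("paired AP-curve comparison drops both-zero bins and detects shifts", {
  a <- list(ap = seq(-1, 1, 0.1), mean = c(rep(0, 5), 1:6, rep(0, 10)))
  b <- list(ap = seq(-1, 1, 0.1), mean = c(rep(0, 5), (1:6) * 0.3, rep(0, 10)))
  r <- compare_ap_curves(a, b)
  expect_lt(r$p_value, 0.05)
  z <- list(ap = seq(-1, 1, 0.1), mean = rep(0, 21))
  expect_equal(compare_ap_curves(z, z)$p_value, 1)
})
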