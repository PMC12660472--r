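make_minimal_cohort <- function(n_per_group = 6, post_equals_pre = FALSE,
                                seed = 1) {
  set.seed(seed)
  coh <- suppressMessages(simulate_cohort(cohort_config(
    n_per_group = n_per_group, seed = seed)))
  if (post_equals_pre) {
    for (t in 1:6) {
      coh[[paste0("sms_mind_post_t", t)]] <- coh[[paste0("sms_mind_pre_t",
                                                         t)]]
    }
  }
  coh
}

test_that("residualizing post scores on a perfect predictor yields zero
           residuals", {
  coh <- make_minimal_cohort(post_equals_pre = TRUE)
  res <- residualize_sms(coh, "mind")
  expect_lt(max(abs(res$residual)), 1e-8)
})

test_that("pooled residualization recovers the generator's covariate
           effects", {
  ce <- list(pre = 0.4, sss = -1.0, age = 0.05, sex = 0.5)
  coh <- suppressMessages(simulate_cohort(
    cohort_config(n_per_group = 300, seed = 4), covariate_effects = ce))
  long <- do.call(rbind, lapply(1:6, function(t) data.frame(
    post = coh[[paste0("sms_mind_post_t", t)]],
    pre = coh[[paste0("sms_mind_pre_t", t)]],
    sss = coh[[paste0("sss_t", t)]], age = coh$age, sex = coh$sex)))
  fit <- summary(lm(post ~ pre + sss + age + sex, long))$coefficients
  for (v in names(ce)) {
    expect_lt(abs(fit[v, "Estimate"] - ce[[v]]),
              3 * fit[v, "Std. Error"] + 0.02)
  }
})

test_that("subjects with incomplete data are dropped listwise and constant
           covariates are removed with a warning", {
  coh <- make_minimal_cohort(n_per_group = 5)
  coh$sms_mind_post_t3[1] <- NA
  expect_message(res <- residualize_sms(coh, "mind"), "listwise")
  expect_equal(length(unique(res$subject_id)), 9)
  coh2 <- make_minimal_cohort(n_per_group = 5)
  coh2$age <- 30
  expect_warning(residualize_sms(coh2, "mind"), "constant covariate")
})

test_that("per-subject slopes are exact on linear data and the balanced
           fast path agrees with per-subject regression", {
  days <- c(0, 3, 4, 5, 6, 7)
  res <- data.frame(subject_id = rep(c("a", "b"), each = 6),
                    group = rep(c("experimental", "control"), each = 6),
                    timepoint = rep(1:6, 2), day = rep(days, 2),
                    residual = c(0.2 * days, rep(1, 6)))
  s <- fit_subject_slopes(res)
  expect_equal(s$slope[s$subject_id == "a"], 0.2)
  expect_equal(s$slope[s$subject_id == "b"], 0)

  set.seed(5)
  res$residual <- rnorm(12)
  s_fast <- fit_subject_slopes(res)
  res_unbal <- res[-3, ]                      # breaks the balanced path
  s_slow <- fit_subject_slopes(res_unbal)
  b_lm <- unname(coef(lm(residual ~ day, res[res$subject_id == "b", ]))[2])
  expect_equal(s_fast$slope[s_fast$subject_id == "b"], b_lm,
               tolerance = 1e-10)
  expect_equal(s_slow$slope[s_slow$subject_id == "b"], b_lm,
               tolerance = 1e-10)
  res_short <- res[res$subject_id == "a", ][1:2, ]
  expect_message(out <- fit_subject_slopes(res_short), "excluded")
  expect_null(out)
})

test_that("slope ANOVA matches a sums-of-squares oracle and handles the
           degenerate cases", {
  for (s in 1:20) {
    set.seed(s)
    n1 <- sample(5:15, 1); n2 <- sample(5:15, 1)
    slopes <- data.frame(
      subject_id = seq_len(n1 + n2),
      group = rep(c("control", "experimental"), c(n1, n2)),
      slope = rnorm(n1 + n2))
    r <- compare_slopes(slopes)
    # textbook one-way ANOVA from the SS decomposition
    g <- factor(slopes$group)
    gm <- mean(slopes$slope)
    ssb <- sum(tapply(slopes$slope, g, function(v)
      length(v) * (mean(v) - gm)^2))
    ssw <- sum(tapply(slopes$slope, g, function(v)
      sum((v - mean(v))^2)))
    F_oracle <- (ssb / 1) / (ssw / (n1 + n2 - 2))
    expect_equal(r$statistic, F_oracle, tolerance = 1e-10)
    expect_equal(r$p, pf(F_oracle, 1, n1 + n2 - 2, lower.tail = FALSE),
                 tolerance = 1e-10)
    d_expected <- sign(mean(slopes$slope[g == "experimental"]) -
                         mean(slopes$slope[g == "control"])) *
      sqrt(F_oracle) * sqrt(1 / n1 + 1 / n2)
    expect_equal(r$effect_size, d_expected, tolerance = 1e-10)
  }
  same <- data.frame(subject_id = 1:6,
                     group = rep(c("a", "b"), each = 3),
                     slope = rep(c(1, 2, 3), 2))
  r <- compare_slopes(same)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)
  degen <- data.frame(subject_id = 1:6, group = rep(c("a", "b"), each = 3),
                      slope = rep(5, 6))
  expect_equal(compare_slopes(degen)$p, 1)
})

test_that("difference-score ANCOVA nests to the two-sample t-test when
           covariates are null", {
  set.seed(6)
  n <- 20000
  g <- rep(c("control", "experimental"), each = n / 2)
  diff <- rnorm(n) + 0.04 * (g == "experimental")
  age <- runif(n, 19, 50); sex <- rep_len(0:1, n)
  r <- ancova_difference_scores(diff, g, age, sex)
  tt <- t.test(diff[g == "experimental"], diff[g == "control"],
               var.equal = TRUE)
  # chance group-covariate correlation perturbs t by O(1/sqrt(n))
  expect_lt(abs(r$p - tt$p.value), 0.01)
  expect_equal(sign(r$statistic), sign(unname(tt$statistic)))
  expect_error(ancova_difference_scores(diff, g, age, age),
               "singular|collinear")
  expect_equal(ancova_difference_scores(rep(2, 40),
                                        rep(c("a", "b"), each = 20),
                                        runif(40), rep_len(0:1, 40))$p, 1)
})

test_that("ANCOVA type-I error is calibrated under the null", {
  rejections <- vapply(seq_len(500), function(s) {
    set.seed(s)
    g <- rep(c("control", "experimental"), each = 19)
    ancova_difference_scores(rnorm(38), g, runif(38, 19, 50),
                             rep_len(0:1, 38))$p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 1.96 * sqrt(0.05 * 0.95 / 500) + 0.005)
})

test_that("rank-sum exact p-values match enumeration, including ties", {
  r <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)
  expect_equal(ranksum_test(c(2, 2, 2), c(2, 2, 2))$p, 1)
  for (s in 1:10) {
    set.seed(s)
    x <- sample(0:5, 5, replace = TRUE)
    y <- sample(0:5, 5, replace = TRUE)
    expect_equal(ranksum_test(x, y)$p, enumerate_ranksum_p(x, y))
  }
  # tie-free exact mode agrees with the classical exact distribution
  for (s in 1:5) {
    set.seed(100 + s)
    x <- sample(1:100, 4); y <- setdiff(sample(1:100, 12), x)[1:5]
    wt <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ranksum_test(x, y)$p, wt$p.value, tolerance = 1e-10)
  }
})

test_that("large-sample rank-sum uses the tie-corrected normal
           approximation", {
  set.seed(7)
  x <- sample(0:5, 30, replace = TRUE)
  y <- sample(0:5, 25, replace = TRUE)
  r <- ranksum_test(x, y)
  wt <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(r$p, wt$p.value, tolerance = 1e-10)
})

test_that("BH step-up adjustment reproduces the five-endpoint arithmetic
           and the reference implementation", {
  adj <- bh_fdr(c(0.019, 0.025, 0.033, 0.001, 0.50))
  expect_equal(round(adj, 3), c(0.041, 0.041, 0.041, 0.005, 0.500))
  expect_equal(bh_fdr(0.05, m = 1), 0.05)
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  set.seed(8)
  for (i in 1:200) {
    p <- runif(sample(2:12, 1))
    expect_equal(bh_fdr(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
})

test_that("BH adjustment is permutation-equivariant, order-preserving and
           never below the raw p", {
  set.seed(9)
  for (i in 1:20) {
    p <- runif(8)
    perm <- sample(8)
    adj <- bh_fdr(p)
    expect_equal(adj[perm], bh_fdr(p[perm]))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("partial correlation equals the two-stage regression oracle and
           plain Pearson with no covariates", {
  set.seed(10)
  n <- 40
  z <- matrix(rnorm(2 * n), n)
  x <- 0.5 * z[, 1] + rnorm(n)
  y <- -0.3 * z[, 2] + 0.4 * x + rnorm(n)
  r <- partial_correlation(x, y, z)
  rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
  expect_equal(r$effect_size, cor(rx, ry), tolerance = 1e-10)
  expect_equal(r$df, n - 4)
  r0 <- partial_correlation(x, y)
  expect_equal(r0$effect_size, cor(x, y), tolerance = 1e-12)
  expect_error(partial_correlation(rnorm(4), rnorm(4),
                                   matrix(rnorm(12), 4)), "df")
})

test_that("one-sample t follows the closed form, the t.test oracle, and
           translation invariance", {
  r <- one_sample_t(c(-1, 0, 1))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  r5 <- one_sample_t(1:5)
  tt <- t.test(1:5)
  expect_equal(r5$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r5$p, tt$p.value, tolerance = 1e-10)
  expect_equal(r5$effect_size, 3 / sd(1:5))
  shifted <- one_sample_t(1:5 + 7, mu0 = 7)
  expect_equal(shifted$statistic, r5$statistic)
  expect_error(one_sample_t(rep(2, 5)), "zero variance")
})

test_that("the endpoint table has five rows with monotone BH-adjusted
           p-values and refuses tiny groups", {
  coh <- make_minimal_cohort(n_per_group = 19, seed = 12)
  tab <- suppressMessages(run_endpoints(coh))
  expect_s3_class(tab, "nf_endpoint_table")
  expect_equal(nrow(tab), 5)
  expect_setequal(tab$test_kind, c("anova_on_slopes", "ancova_diff",
                                   "ranksum"))
  expect_true(all(tab$bh_p >= tab$raw_p - 1e-12))
  expect_true(all(tab$bh_p <= 1))
  tiny <- coh[c(1:2, 20:21), ]
  expect_error(suppressMessages(run_endpoints(tiny)), "fewer than 3")
})

test_that("the null SMS-Body endpoint stays non-significant in most
           cohorts", {
  hits <- vapply(seq_len(200), function(s) {
    coh <- suppressMessages(simulate_cohort(cohort_config(seed = 5000 + s)))
    slopes <- fit_subject_slopes(residualize_sms(coh, "body"))
    compare_slopes(slopes)$p >= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a sham session log yields a blinding-check summary", {
  donor_runs <- lapply(1:3, function(r)
    simulate_roi_run(default_design, default_acq, quiet_truth(seed = 30 + r)))
  recip_runs <- lapply(1:3, function(r)
    simulate_roi_run(default_design, default_acq, quiet_truth(seed = 40 + r)))
  donor_log <- run_nf_session(donor_runs, nf_config())
  log <- run_nf_session(recip_runs, nf_config(mode = "sham"),
                        sham_schedule("d", donor_log))
  coh <- make_minimal_cohort(n_per_group = 10, seed = 13)
  tab <- suppressMessages(run_endpoints(coh, nf_log = log))
  bl <- attr(tab, "blinding_check")
  expect_true(is.numeric(bl$r) && abs(bl$r) <= 1)
  expect_equal(bl$n, 18)
})
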