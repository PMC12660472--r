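#' Residualize post-meditation SMS scores
#'
#' Pools all subject-timepoints and regresses the post-meditation score on
#' the pre-meditation score, the session's sleepiness rating (SSS), age and
#' sex, returning per-subject per-timepoint residuals. Subjects with
#' incomplete 6-timepoint data are dropped (listwise) with a message;
#' constant covariates are dropped with a warning.
#'
#' @param cohort an \code{nf_cohort} data frame from [simulate_cohort()] or
#'   [read_cohort_csv()].
#' @param subscale \code{"mind"} or \code{"body"}.
#' @return data frame: subject_id, group, timepoint, day, residual.
#' @export
residualize_sms <- function(cohort, subscale = c("mind", "body")) {
  subscale <- match.arg(subscale)
  days <- attr(cohort, "session_days")
  if (is.null(days)) days <- c(0, 3, 4, 5, 6, 7)
  pre_cols <- paste0("sms_", subscale, "_pre_t", 1:6)
  post_cols <- paste0("sms_", subscale, "_post_t", 1:6)
  sss_cols <- paste0("sss_t", 1:6)
  need <- c(pre_cols, post_cols, sss_cols, "age", "sex")
  complete <- stats::complete.cases(cohort[, need])
  if (any(!complete)) {
    message(sprintf("listwise deletion: dropped %d subject(s) with %s",
                    sum(!complete), "incomplete timepoint data"))
  }
  coh <- cohort[complete, , drop = FALSE]
  long <- do.call(rbind, lapply(1:6, function(t) {
    data.frame(subject_id = coh$subject_id, group = coh$group,
               timepoint = t, day = days[t],
               post = coh[[post_cols[t]]], pre = coh[[pre_cols[t]]],
               sss = coh[[sss_cols[t]]], age = coh$age, sex = coh$sex)
  }))
  covs <- c("pre", "sss", "age", "sex")
  keep <- covs[vapply(covs, function(v) stats::sd(long[[v]]) > 0,
                      logical(1))]
  if (length(keep) < length(covs)) {
    warning("dropped constant covariate(s): ",
            paste(setdiff(covs, keep), collapse = ", "))
  }
  X <- cbind(1, as.matrix(long[, keep, drop = FALSE]))
  long$residual <- stats::lm.fit(X, long$post)$residuals
  long[, c("subject_id", "group", "timepoint", "day", "residual")]
}

#' Per-subject slopes of residual scores over days
#'
#' @param residuals output of [residualize_sms()].
#' @return data frame: subject_id, group, slope, intercept, n_timepoints.
#'   Subjects with fewer than 3 timepoints are excluded with a message.
#' @export
fit_subject_slopes <- function(residuals) {
  cnt <- table(residuals$subject_id)
  n_tp <- length(unique(residuals$day))
  if (n_tp >= 3 && all(cnt == n_tp)) {
    # balanced case: one closed-form least-squares pass for all subjects
    o <- order(residuals$subject_id, residuals$day)
    ids <- unique(residuals$subject_id[o])
    R <- matrix(residuals$residual[o], nrow = n_tp)
    day <- residuals$day[o][seq_len(n_tp)]
    dc <- day - mean(day)
    slope <- as.numeric(crossprod(dc, R) / sum(dc^2))
    res <- data.frame(subject_id = ids,
                      group = residuals$group[o][seq(1, length(o), n_tp)],
                      slope = slope,
                      intercept = colMeans(R) - slope * mean(day),
                      n_timepoints = n_tp)
    return(res)
  }
  out <- lapply(split(residuals, residuals$subject_id), function(d) {
    if (nrow(d) < 3) return(NULL)
    fit <- stats::lm.fit(cbind(1, d$day), d$residual)
    data.frame(subject_id = d$subject_id[1], group = d$group[1],
               slope = fit$coefficients[2], intercept = fit$coefficients[1],
               n_timepoints = nrow(d))
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped > 0) {
    message(sprintf("excluded %d subject(s) with < 3 timepoints", dropped))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

stat_result <- function(statistic, df, p, effect_size = NA_real_,
                        test_kind, tail = "two") {
  list(statistic = statistic, df = df, p = p, effect_size = effect_size,
       test_kind = test_kind, tail = tail)
}

#' One-way ANOVA on per-subject slopes
#'
#' Cohen's d is derived from the equivalent two-sample comparison:
#' d = t * sqrt(1/n1 + 1/n2) with t = sqrt(F) signed by the direction of the
#' group-mean difference. Direction convention throughout the endpoint
#' tests: second factor level minus first (alphabetically, experimental
#' minus control for the default labels).
#'
#' @param slopes data frame from [fit_subject_slopes()].
#' @return a StatResult list (F statistic, df, p, Cohen's d).
#' @export
compare_slopes <- function(slopes) {
  g <- factor(slopes$group)
  stopifnot(nlevels(g) == 2, all(table(g) >= 2))
  means <- tapply(slopes$slope, g, mean)
  if (stats::var(slopes$slope) == 0) {
    return(stat_result(0, c(1, length(g) - 2), 1, 0, "anova_on_slopes"))
  }
  fit <- stats::aov(slope ~ group, data = slopes)
  tab <- summary(fit)[[1]]
  Fv <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  tv <- sign(means[2] - means[1]) * sqrt(Fv)
  d <- tv * sqrt(1 / n1 + 1 / n2)
  stat_result(Fv, tab$Df, p, unname(d), "anova_on_slopes")
}

#' ANCOVA on difference scores
#'
#' Linear model \code{diff ~ group + age + sex}; reports the group-effect t,
#' its df and p, and Cohen's d = t * sqrt(1/n1 + 1/n2).
#'
#' @param diff_scores numeric difference scores (follow-up minus baseline).
#' @param group two-level factor/character.
#' @param age,sex covariates.
#' @return a StatResult list.
#' @export
ancova_difference_scores <- function(diff_scores, group, age, sex) {
  g <- factor(group)
  stopifnot(nlevels(g) == 2)
  dat <- data.frame(diff = diff_scores, group = g,
                    age = as.numeric(scale(age)),
                    sex = as.numeric(scale(sex)))
  X <- stats::model.matrix(~ group + age + sex, dat)
  if (qr(X)$rank < ncol(X)) {
    stop("singular model matrix: collinear covariates in the ANCOVA")
  }
  if (stats::var(diff_scores) == 0) {
    return(stat_result(0, length(diff_scores) - 4, 1, 0, "ancova_diff"))
  }
  fit <- stats::lm(diff ~ group + age + sex, data = dat)
  co <- summary(fit)$coefficients
  row <- grep("^group", rownames(co))
  tv <- co[row, "t value"]    # sign: second factor level minus first
  p <- co[row, "Pr(>|t|)"]
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  stat_result(tv, fit$df.residual, p, tv * sqrt(1 / n1 + 1 / n2),
              "ancova_diff")
}

#' Wilcoxon rank-sum test with exact enumeration for small samples
#'
#' For combined n at or below \code{exact_max} the two-sided p-value is
#' computed by full enumeration of all group-label assignments on the pooled
#' midranks (ties handled naturally); otherwise the normal approximation
#' with tie correction is used. The two-sided exact p is the fraction of
#' assignments whose rank-sum deviates from its null mean at least as much
#' as observed.
#'
#' @param x,y numeric samples (each of size >= 3 for endpoint use; smaller
#'   sizes are allowed for the enumeration itself).
#' @param exact_max largest combined n for which enumeration is used.
#' @return a StatResult list (W statistic = rank sum of \code{x}).
#' @export
ranksum_test <- function(x, y, exact_max = 12) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)                          # midranks under ties
  W <- sum(r[seq_len(n1)])
  EW <- n1 * (N + 1) / 2
  if (length(unique(pooled)) == 1) {
    return(stat_result(W, NA, 1, 0, "ranksum"))
  }
  if (N <= exact_max) {
    combs <- utils::combn(N, n1)
    Ws <- colSums(matrix(r[combs], nrow = n1))
    p <- mean(abs(Ws - EW) >= abs(W - EW) - 1e-12)
  } else {
    ties <- table(r)
    varW <- n1 * n2 / 12 *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (W - EW) / sqrt(varW)
    p <- 2 * stats::pnorm(-abs(z))
  }
  r_eff <- (W - EW) / sqrt(n1 * n2 * (N + 1) / 12) / sqrt(N)
  stat_result(W, NA, min(p, 1), r_eff, "ranksum")
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Sorts ascending, multiplies p(i) by m/i, enforces monotonicity from the
#' largest rank down, caps at 1, and returns the values in the input order.
#'
#' @param raw_p p-values in [0, 1].
#' @param m number of tests in the family (defaults to
#'   \code{length(raw_p)}).
#' @return adjusted p-values in input order.
#' @export
bh_fdr <- function(raw_p, m = length(raw_p)) {
  if (any(raw_p < 0 | raw_p > 1 | !is.finite(raw_p))) {
    stop("p-values must lie in [0, 1]")
  }
  stopifnot(m >= length(raw_p))
  k <- length(raw_p)
  ord <- order(raw_p)
  stepped <- raw_p[ord] * m / seq_len(k)
  adj <- rev(cummin(rev(stepped)))
  adj <- pmin(adj, 1)
  out <- numeric(k)
  out[ord] <- adj
  out
}

#' Partial correlation by the residual method
#'
#' Correlates the residuals of \code{x} and \code{y} after regressing each on
#' the covariates; df = n - 2 - k and the p-value comes from
#' t = r * sqrt(df / (1 - r^2)).
#'
#' @param x,y numeric vectors.
#' @param covariates optional matrix/data frame of covariates (k columns).
#' @param tail \code{"two"} (default), \code{"greater"} or \code{"less"}.
#' @return a StatResult list with the partial r as effect size.
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n - 2 - k <= 0) stop("not enough observations: df <= 0")
  if (k > 0) {
    Z <- cbind(1, as.matrix(covariates))
    x <- stats::lm.fit(Z, x)$residuals
    y <- stats::lm.fit(Z, y)$residuals
  }
  r <- stats::cor(x, y)
  df <- n - 2 - k
  p <- correlation_p(r, df, tail)
  stat_result(r * sqrt(df / (1 - r^2)), df, p, r, "partial_correlation",
              tail)
}

#' p-value of a (partial) correlation coefficient
#'
#' @param r correlation; @param df degrees of freedom (n - 2 - k).
#' @param tail \code{"two"}, \code{"greater"} or \code{"less"}.
#' @return the p-value from the t transform t = r * sqrt(df / (1 - r^2)).
#' @export
correlation_p <- function(r, df, tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  tv <- r * sqrt(df / (1 - r^2))
  switch(tail,
         two = 2 * stats::pt(-abs(tv), df),
         greater = stats::pt(tv, df, lower.tail = FALSE),
         less = stats::pt(tv, df))
}

#' One-sample t-test
#'
#' @param values numeric sample (n >= 2, nonzero variance).
#' @param mu0 null mean.
#' @param tail \code{"two"}, \code{"greater"} or \code{"less"}.
#' @return a StatResult list with Cohen's d = (mean - mu0) / sd.
#' @export
one_sample_t <- function(values, mu0 = 0,
                         tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  n <- length(values)
  stopifnot(n >= 2)
  s <- stats::sd(values)
  if (s == 0) stop("zero variance")
  tv <- (mean(values) - mu0) / (s / sqrt(n))
  df <- n - 1
  p <- switch(tail,
              two = 2 * stats::pt(-abs(tv), df),
              greater = stats::pt(tv, df, lower.tail = FALSE),
              less = stats::pt(tv, df))
  stat_result(tv, df, p, (mean(values) - mu0) / s, "one_sample_t", tail)
}

#' Run the five behavioural endpoints with BH-FDR control
#'
#' Executes, in order: (1) SMS-Mind slope ANOVA, (2) SMS-Body slope ANOVA,
#' (3) DASS-21 change ANCOVA, (4) BCT task-accuracy change ANCOVA, (5) BCT
#' probe-accuracy change rank-sum test; then adjusts the five raw p-values by
#' Benjamini-Hochberg at m = 5. If an NF session log with sham replay is
#' supplied, a blinding-check summary (correlation between displayed sham
#' scores and the recipients' actual scores) is attached as an attribute.
#'
#' @param cohort an \code{nf_cohort} data frame.
#' @param nf_log optional \code{nf_session_log} from a sham session.
#' @return data frame of class \code{nf_endpoint_table} with exactly five
#'   rows: endpoint, test_kind, statistic, df, raw_p, bh_p, cohen_d.
#' @export
run_endpoints <- function(cohort, nf_log = NULL) {
  if (any(table(cohort$group) < 3)) {
    stop("refusing: fewer than 3 subjects per group")
  }
  slopes_mind <- fit_subject_slopes(residualize_sms(cohort, "mind"))
  slopes_body <- fit_subject_slopes(residualize_sms(cohort, "body"))
  r_mind <- compare_slopes(slopes_mind)
  r_body <- compare_slopes(slopes_body)

  dass_diff <- cohort$dass_followup - cohort$dass_baseline
  r_dass <- ancova_difference_scores(dass_diff, cohort$group, cohort$age,
                                     cohort$sex)
  task_diff <- cohort$bct_task_followup - cohort$bct_task_baseline
  r_task <- ancova_difference_scores(task_diff, cohort$group, cohort$age,
                                     cohort$sex)
  probe_diff <- cohort$bct_probe_followup - cohort$bct_probe_baseline
  g <- factor(cohort$group)
  # rank-sum direction matches the others: second level minus first
  r_probe <- ranksum_test(probe_diff[g == levels(g)[2]],
                          probe_diff[g == levels(g)[1]])

  rows <- list(`SMS-Mind slope` = r_mind, `SMS-Body slope` = r_body,
               `DASS change` = r_dass, `BCT task change` = r_task,
               `BCT probe change` = r_probe)
  tab <- data.frame(endpoint = names(rows),
                    test_kind = vapply(rows, `[[`, "", "test_kind"),
                    statistic = vapply(rows, function(r)
                      r$statistic[1], numeric(1)),
                    df = vapply(rows, function(r)
                      as.numeric(r$df[length(r$df)]), numeric(1)),
                    raw_p = vapply(rows, `[[`, numeric(1), "p"),
                    cohen_d = vapply(rows, `[[`, numeric(1), "effect_size"))
  tab$bh_p <- bh_fdr(tab$raw_p, m = 5)
  tab <- tab[, c("endpoint", "test_kind", "statistic", "df", "raw_p",
                 "bh_p", "cohen_d")]
  rownames(tab) <- NULL
  if (!is.null(nf_log)) {
    # single-log approximation: partial out run and block-position effects
    # (the shared task profile); see sham_blinding_pvalues() for the
    # ensemble version
    Z <- stats::model.matrix(~ factor(nf_log$block) +
                               factor(nf_log$run))[, -1]
    blind <- partial_correlation(nf_log$displayed_psc,
                                 nf_log$residual_psc, Z)
    attr(tab, "blinding_check") <- list(r = blind$effect_size,
                                        p = blind$p, n = nrow(nf_log))
  }
  class(tab) <- c("nf_endpoint_table", "data.frame")
  tab
}
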