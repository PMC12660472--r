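#' Offline block GLM for one run
#'
#' Fits voxel-wise least squares with HRF-convolved condition regressors
#' (rest is the implicit baseline), an intercept, a linear trend, and any
#' nuisance columns. The meditation coefficient is rescaled by each voxel's
#' fitted rest baseline (intercept plus mid-run trend), giving the
#' meditation-vs-rest contrast in percent-signal-change units (negative =
#' deactivation); t-statistics are scale-free and come from the raw fit.
#'
#' @param Y voxels-by-volumes data matrix (raw intensities), or an
#'   \code{nf_roi_run} (its target ROI is used).
#' @param design an [make_block_design()] result.
#' @param tr_seconds repetition time, seconds.
#' @param conditions condition regressors to model.
#' @param nuisance optional volumes-by-k matrix of nuisance columns.
#' @return an object of class \code{nf_glm_fit}: \code{beta} (columns by
#'   voxel), \code{contrast} (meditation - rest), \code{t}, \code{sigma2},
#'   \code{df}.
#' @export
fit_block_glm <- function(Y, design, tr_seconds,
                          conditions = c("meditation", "cue", "feedback"),
                          nuisance = NULL) {
  if (inherits(Y, "nf_roi_run")) {
    tr_seconds <- Y$acquisition$tr_seconds
    design <- Y$design
    Y <- Y$target
  }
  nv <- ncol(Y)
  X <- build_design_matrix(design, nv, tr_seconds, conditions)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design: collinear column(s) ",
         paste(dropped, collapse = ", "))
  }
  Yt <- t(Y)                                 # volumes x voxels
  beta <- qr.coef(qrX, Yt)
  res <- Yt - X %*% beta
  df <- nv - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  j <- match("meditation", colnames(X))
  se <- sqrt(sigma2 * XtXinv[j, j])
  # rest baseline per voxel: intercept plus the trend at mid-run
  baseline <- beta["intercept", ] +
    if ("trend" %in% colnames(X)) 0.5 * beta["trend", ] else 0
  if (any(baseline <= 0)) {
    stop("degenerate intensities: non-positive fitted baseline")
  }
  contrast <- 100 * beta[j, ] / baseline
  structure(list(beta = beta, contrast = contrast,
                 t = ifelse(se > 0, beta[j, ] / se, NA_real_),
                 sigma2 = sigma2, df = df, columns = colnames(X)),
            class = "nf_glm_fit")
}

#' Generalized psychophysiological interaction (gPPI) fit
#'
#' First-level model per voxel: intercept, trend, condition regressors, the
#' (mean-centred) seed time course, and the PPI regressor seed x centred
#' meditation regressor. The PPI coefficient gamma estimates the
#' meditation-vs-rest modulation of seed-voxel coupling; negative gamma means
#' stronger negative coupling during meditation. No deconvolution is applied
#' (block design); set \code{deconvolve} for future extension (not
#' implemented).
#'
#' @param Y voxels-by-volumes data matrix.
#' @param seed_series seed ROI time course, length = volumes.
#' @param design an [make_block_design()] result.
#' @param tr_seconds repetition time, seconds.
#' @param nuisance optional volumes-by-k nuisance matrix.
#' @param kappa_max condition-number guard: gamma is NA where the model is
#'   numerically collinear.
#' @return an object of class \code{nf_gppi_fit} with \code{gamma}, \code{t},
#'   \code{df} per voxel.
#' @export
fit_gppi <- function(Y, seed_series, design, tr_seconds, nuisance = NULL,
                     kappa_max = 1e8) {
  nv <- ncol(Y)
  stopifnot(length(seed_series) == nv)
  med <- condition_regressor(design$events, "meditation", nv, tr_seconds)
  if (stats::sd(med) < .Machine$double.eps * 100) {
    stop("collinearity: constant meditation regressor (no rest or no ",
         "meditation volumes)")
  }
  med_c <- med - mean(med)                   # centred before the product
  seed_c <- seed_series - mean(seed_series)
  ppi <- seed_c * med_c
  X <- cbind(intercept = 1, trend = seq(0, 1, length.out = nv),
             meditation = med, seed = seed_c, ppi = ppi)
  if (!is.null(nuisance)) X <- cbind(X, as.matrix(nuisance))
  if (kappa(X, exact = TRUE) > kappa_max) {
    stop("collinearity: gPPI design exceeds the condition-number guard")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("collinearity: rank-deficient gPPI design")
  Yt <- t(Y)
  beta <- qr.coef(qrX, Yt)
  res <- Yt - X %*% beta
  df <- nv - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  j <- match("ppi", colnames(X))
  se <- sqrt(sigma2 * XtXinv[j, j])
  gamma <- beta[j, ]
  structure(list(gamma = gamma, t = ifelse(se > 0, gamma / se, NA_real_),
                 df = df, beta = beta), class = "nf_gppi_fit")
}

#' Permutation-test configuration
#'
#' @param n_permutations number of label permutations (>= 100).
#' @param cluster_forming_p uncorrected voxel threshold for cluster forming.
#' @param fwe_alpha family-wise error level across clusters.
#' @param tail \code{"one"} (upper tail of the group-A-minus-group-B t map)
#'   or \code{"two"}.
#' @param statistic cluster statistic: extent (voxel count) or mass (summed
#'   t above threshold).
#' @param seed RNG seed for the permutations.
#' @return an object of class \code{nf_perm_config}.
#' @export
perm_config <- function(n_permutations = 1000, cluster_forming_p = 0.005,
                        fwe_alpha = 0.05, tail = c("one", "two"),
                        statistic = c("extent", "mass"), seed = 1L) {
  tail <- match.arg(tail)
  statistic <- match.arg(statistic)
  if (n_permutations < 100) {
    stop("refusing n_permutations < 100: the permutation tail is unstable")
  }
  stopifnot(cluster_forming_p > 0, cluster_forming_p < fwe_alpha,
            fwe_alpha <= 1)
  structure(list(n_permutations = as.integer(n_permutations),
                 cluster_forming_p = cluster_forming_p,
                 fwe_alpha = fwe_alpha, tail = tail, statistic = statistic,
                 seed = as.integer(seed)),
            class = "nf_perm_config")
}

two_sample_t_maps <- function(M, Msq, Stot, Qtot, g1_idx) {
  n <- nrow(M)
  n1 <- length(g1_idx); n2 <- n - n1
  S1 <- colSums(M[g1_idx, , drop = FALSE])
  Q1 <- colSums(Msq[g1_idx, , drop = FALSE])
  S2 <- Stot - S1
  Q2 <- Qtot - Q1
  ss1 <- Q1 - S1^2 / n1
  ss2 <- Q2 - S2^2 / n2
  sp <- (ss1 + ss2) / (n1 + n2 - 2)
  (S1 / n1 - S2 / n2) / sqrt(sp * (1 / n1 + 1 / n2))
}

#' Cluster-level permutation test of a group difference
#'
#' Residualizes the per-subject maps against any covariates, forms the
#' pooled-variance two-sample t map for group A minus group B, thresholds it
#' at the cluster-forming p, labels 6-connected clusters, and compares each
#' observed cluster statistic with the permutation distribution of the
#' maximum cluster statistic under random relabelling. FWE p-values use the
#' (b + 1) / (B + 1) convention so they are valid at any B.
#'
#' @param maps subjects-by-voxels matrix of statistic maps (e.g. gPPI gamma).
#' @param group factor/character of length subjects with two levels; the
#'   first level (or \code{levels[1]}) is group A.
#' @param dims grid dimensions \code{c(nx, ny, nz)} with
#'   \code{prod(dims) == ncol(maps)}.
#' @param config an [perm_config()].
#' @param covariates optional subjects-by-k matrix residualized out of the
#'   maps before permutation.
#' @return list with \code{cluster_table} (id, size, mass, peak_t, fwe_p),
#'   \code{significant_mask} (logical, length voxels), \code{t_map},
#'   \code{threshold}, \code{perm_max}.
#' @export
group_permutation_test <- function(maps, group, dims, config = perm_config(),
                                   covariates = NULL) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2, nrow(maps) == length(group),
            prod(dims) == ncol(maps), all(table(group) >= 2))
  if (!is.null(covariates)) {
    Xc <- cbind(1, as.matrix(covariates))
    maps <- stats::lm.fit(Xc, maps)$residuals
  }
  n <- nrow(maps)
  g1 <- which(group == levels(group)[1])
  df <- n - 2
  thr_t <- stats::qt(1 - if (config$tail == "one") config$cluster_forming_p
                     else config$cluster_forming_p / 2, df)
  mass <- config$statistic == "mass"

  maps_sq <- maps^2
  Stot <- colSums(maps)
  Qtot <- colSums(maps_sq)
  stat_map <- function(idx1) {
    t_map <- two_sample_t_maps(maps, maps_sq, Stot, Qtot, idx1)
    if (config$tail == "two") abs(t_map) else t_map
  }
  obs <- stat_map(g1)
  labels <- label_clusters6(obs > thr_t, dims[1], dims[2], dims[3])
  n_clust <- max(labels)
  set.seed(config$seed)
  B <- config$n_permutations
  perm_max <- numeric(B)
  for (b in seq_len(B)) {
    idx1 <- sample.int(n, length(g1))
    perm_max[b] <- max_cluster_stat(stat_map(idx1), thr_t,
                                    dims[1], dims[2], dims[3], mass)
  }
  if (n_clust == 0) {
    tab <- data.frame(cluster = integer(0), size = integer(0),
                      mass = numeric(0), peak_t = numeric(0),
                      fwe_p = numeric(0))
    return(list(cluster_table = tab,
                significant_mask = rep(FALSE, ncol(maps)),
                t_map = obs, threshold = thr_t, perm_max = perm_max))
  }
  size <- tabulate(labels, n_clust)
  cmass <- vapply(seq_len(n_clust),
                  function(k) sum(obs[labels == k]), numeric(1))
  peak <- vapply(seq_len(n_clust),
                 function(k) max(obs[labels == k]), numeric(1))
  cstat <- if (mass) cmass else size
  fwe_p <- vapply(cstat, function(s) (sum(perm_max >= s) + 1) / (B + 1),
                  numeric(1))
  tab <- data.frame(cluster = seq_len(n_clust), size = size, mass = cmass,
                    peak_t = peak, fwe_p = fwe_p)
  tab <- tab[order(tab$size, decreasing = TRUE), ]
  rownames(tab) <- NULL
  sig <- labels %in% tab$cluster[tab$fwe_p <= config$fwe_alpha]
  list(cluster_table = tab, significant_mask = sig, t_map = obs,
       threshold = thr_t, perm_max = perm_max)
}

#' Baseline-to-transfer functional-connectivity change
#'
#' Pearson correlation between seed and cluster mean series in the baseline
#' and transfer tasks, and their difference (transfer minus baseline).
#'
#' @param seed_baseline,cluster_baseline baseline-task series (equal length).
#' @param seed_transfer,cluster_transfer transfer-task series (equal length).
#' @return list with \code{baseline_r}, \code{transfer_r}, \code{delta}.
#' @export
fc_change <- function(seed_baseline, cluster_baseline,
                      seed_transfer, cluster_transfer) {
  stopifnot(length(seed_baseline) == length(cluster_baseline),
            length(seed_transfer) == length(cluster_transfer))
  sds <- c(stats::sd(seed_baseline), stats::sd(cluster_baseline),
           stats::sd(seed_transfer), stats::sd(cluster_transfer))
  if (any(sds == 0)) {
    stop("undefined correlation: zero-variance series")
  }
  b <- stats::cor(seed_baseline, cluster_baseline)
  t <- stats::cor(seed_transfer, cluster_transfer)
  list(baseline_r = b, transfer_r = t, delta = t - b)
}
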