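#' Significance stars
#'
#' Convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001, `ns` otherwise (alpha 0.05).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star labels.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

stat_result <- function(comparison, test, statistic, p, mean_a, se_a, n_a,
                        mean_b, se_b, n_b, flag = "") {
  data.frame(comparison = comparison, test = test,
             statistic = statistic, p_value = p, stars = p_stars(p),
             mean_a = mean_a, se_a = se_a, n_a = n_a,
             mean_b = mean_b, se_b = se_b, n_b = n_b,
             flag = flag, stringsAsFactors = FALSE)
}

group_mean_se <- function(x) {
  c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
}

# distribution of the sum of n_pick values drawn without replacement from
# `vals` (integers): count[k, s] of subsets of size k with sum s
subset_sum_counts <- function(vals, n_pick) {
  smax <- sum(vals)
  f <- matrix(0, nrow = n_pick + 1, ncol = smax + 1)
  f[1, 1] <- 1
  for (v in vals) {
    kmax <- n_pick  # iterate k downward so each value is used at most once
    for (k in seq(kmax, 1)) {
      nz <- which(f[k, ] > 0)
      if (length(nz)) f[k + 1, nz + v] <- f[k + 1, nz + v] + f[k, nz]
    }
  }
  f[n_pick + 1, ]
}

#' Exact tie-aware Wilcoxon rank-sum test
#'
#' Two-sided two-sample rank test on midranks. For `n + m <= exact_max`
#' (default 14) the null distribution of the first sample's rank sum is
#' computed exactly by counting all `choose(n+m, n)` group assignments of
#' the observed (possibly tied) values via a subset-sum recursion; the
#' two-sided p doubles the smaller tail probability, capped at 1. Larger
#' samples use the normal approximation with tie correction and continuity
#' correction. Degenerate data (all values identical) give p = 1.
#'
#' @param x,y Numeric samples (each of length >= 1).
#' @param exact_max Largest `n + m` for which full enumeration is used.
#' @return One-row data frame (`StatResult`): test name, rank-sum statistic
#'   of `x`, p-value, per-group mean and SE, star label.
#' @export
rank_sum_exact <- function(x, y, exact_max = 14) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))              # midranks
  W <- sum(r[seq_len(n)])
  ma <- group_mean_se(x); mb <- group_mean_se(y)
  done <- function(p, flag = "") {
    stat_result("x vs y", "Wilcoxon rank-sum (exact, tie-aware)", W,
                min(1, p), ma["mean"], ma["se"], n, mb["mean"], mb["se"], m, flag)
  }
  if (length(unique(c(x, y))) == 1) return(done(1, "degenerate: all values equal"))
  if (N <= exact_max) {
    d <- as.integer(round(2 * r))  # doubled midranks are integers
    cnt <- subset_sum_counts(d, n)
    tot <- sum(cnt)
    w2 <- as.integer(round(2 * W))
    s <- seq_along(cnt) - 1
    p_le <- sum(cnt[s <= w2]) / tot
    p_ge <- sum(cnt[s >= w2]) / tot
    return(done(2 * min(p_le, p_ge)))
  }
  mu <- n * (N + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / ((N) * (N - 1))
  v <- n * m / 12 * ((N + 1) - tie_term)
  if (v <= 0) return(done(1, "degenerate: zero variance"))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(v)
  done(2 * stats::pnorm(-abs(z)))
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired rank test. Zero differences are dropped; midranks of
#' the absolute differences are signed by the difference. For `n <=
#' exact_max` remaining pairs (default 15) the null distribution of the
#' positive-rank sum is computed exactly over all `2^n` sign assignments
#' via a generating-function convolution; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' All-zero differences give p = 1 with a flag.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @param exact_max Largest number of nonzero pairs for full enumeration.
#' @return One-row `StatResult` data frame; the statistic is the
#'   positive-rank sum W+.
#' @export
signed_rank_paired <- function(a, b, exact_max = 15) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  d <- a - b
  ma <- group_mean_se(a); mb <- group_mean_se(b)
  nz <- d != 0
  done <- function(W, p, flag = "") {
    stat_result("a vs b (paired)", "Wilcoxon signed-rank (exact, tie-aware)",
                W, min(1, p), ma["mean"], ma["se"], length(a),
                mb["mean"], mb["se"], length(b), flag)
  }
  if (!any(nz)) return(done(0, 1, "degenerate: all differences zero"))
  d <- d[nz]
  n <- length(d)
  r <- rank(abs(d))
  Wp <- sum(r[d > 0])
  if (n <= exact_max) {
    dd <- as.integer(round(2 * r))
    # g[s+1] = number of sign patterns with doubled positive-rank sum s
    g <- c(1, rep(0, sum(dd)))
    for (v in dd) {
      nzv <- which(g > 0)
      g2 <- g  # value taken negative contributes 0 to W+
      g2[nzv + v] <- g2[nzv + v] + g[nzv]
      g <- g2
    }
    tot <- 2^n
    s <- seq_along(g) - 1
    w2 <- as.integer(round(2 * Wp))
    p_le <- sum(g[s <= w2]) / tot
    p_ge <- sum(g[s >= w2]) / tot
    return(done(Wp, 2 * min(p_le, p_ge)))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (v <= 0) return(done(Wp, 1, "degenerate: zero variance"))
  z <- (Wp - mu - sign(Wp - mu) * 0.5) / sqrt(v)
  done(Wp, 2 * stats::pnorm(-abs(z)))
}

#' Random-intercept linear mixed model by profile maximum likelihood
#'
#' Fits `y_ij = beta0 + beta1 * group_i + b_i + e_ij` with
#' `b_i ~ N(0, sigma_b^2)` per brain and `e_ij ~ N(0, sigma^2)`, by
#' maximum likelihood: the variance ratio `lambda = sigma_b^2 / sigma^2`
#' is profiled (1-D optimization on the log scale, with the boundary
#' `lambda = 0` always considered), with closed-form GLS for the fixed
#' effects and residual variance at each ratio. The group effect is tested
#' with a Wald z statistic.
#'
#' @param y Numeric observations (e.g. per-section plaque intensity).
#' @param brain Grouping factor (one level per brain).
#' @param group Fixed-effect factor or numeric covariate (two-level factors
#'   are coded 0/1).
#' @return Object of class `lme_fit`: list with `beta` (named), `se`,
#'   `sigma_b2`, `sigma2`, `loglik`, `lambda`, `p_group` (Wald, two-sided),
#'   `z_group`, `n`, `n_brains`.
#' @export
lme_random_intercept <- function(y, brain, group) {
  brain <- as.factor(brain)
  if (is.character(group)) group <- as.factor(group)
  g <- if (is.factor(group)) as.numeric(group) - 1 else as.numeric(group)
  X <- cbind(`(Intercept)` = 1, group = g)
  n <- length(y)
  stopifnot(length(brain) == n, length(g) == n)
  if (nlevels(brain) < 2) stop("need at least 2 brains")
  idx <- split(seq_len(n), brain)

  prof <- function(lambda) {
    # V_i = I + lambda J; V_i^{-1} = I - lambda/(1+n_i lambda) J
    XtVX <- matrix(0, 2, 2); XtVy <- numeric(2)
    for (ii in idx) {
      Xi <- X[ii, , drop = FALSE]; yi <- y[ii]; ni <- length(ii)
      a <- lambda / (1 + ni * lambda)
      XtVX <- XtVX + crossprod(Xi) - a * tcrossprod(colSums(Xi))
      XtVy <- XtVy + crossprod(Xi, yi) - a * colSums(Xi) * sum(yi)
    }
    beta <- solve(XtVX, XtVy)
    rss <- 0; logdet <- 0
    for (ii in idx) {
      ri <- y[ii] - X[ii, , drop = FALSE] %*% beta
      ni <- length(ii)
      a <- lambda / (1 + ni * lambda)
      rss <- rss + sum(ri^2) - a * sum(ri)^2
      logdet <- logdet + log1p(ni * lambda)
    }
    sigma2 <- rss / n
    ll <- -n / 2 * log(2 * pi * sigma2) - logdet / 2 - n / 2
    list(beta = beta, sigma2 = sigma2, loglik = ll, XtVX = XtVX)
  }

  obj <- function(loglam) -prof(exp(loglam))$loglik
  opt <- stats::optimize(obj, c(log(1e-8), log(1e4)))
  cand <- c(0, exp(opt$minimum))
  fits <- lapply(cand, prof)
  best <- which.max(vapply(fits, `[[`, numeric(1), "loglik"))
  lambda <- cand[best]
  fit <- fits[[best]]
  if (!is.finite(fit$loglik)) stop("LME did not converge: non-finite log-likelihood")
  vb <- fit$sigma2 * solve(fit$XtVX)
  se <- sqrt(diag(vb))
  z <- fit$beta[2] / se[2]
  structure(list(beta = stats::setNames(as.numeric(fit$beta), colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 sigma_b2 = lambda * fit$sigma2, sigma2 = fit$sigma2,
                 lambda = lambda, loglik = fit$loglik,
                 z_group = as.numeric(z),
                 p_group = 2 * stats::pnorm(-abs(as.numeric(z))),
                 n = n, n_brains = nlevels(brain)),
            class = "lme_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat("Random-intercept LME (ML)\n")
  cat(sprintf("  n = %d observations, %d brains\n", x$n, x$n_brains))
  cat(sprintf("  beta: intercept %.4g, group %.4g (SE %.4g)\n",
              x$beta[1], x$beta[2], x$se[2]))
  cat(sprintf("  sigma_b^2 = %.4g, sigma^2 = %.4g, logLik = %.4f\n",
              x$sigma_b2, x$sigma2, x$loglik))
  cat(sprintf("  Wald group test: z = %.3f, p = %.5g %s\n",
              x$z_group, x$p_group, p_stars(x$p_group)))
  invisible(x)
}

#' Profile log-likelihood of the random-intercept LME on a ratio grid
#'
#' Evaluates the profiled log-likelihood on a grid of variance ratios
#' (used as an independent check that the optimizer's solution dominates).
#'
#' @inheritParams lme_random_intercept
#' @param lambdas Grid of variance ratios `sigma_b^2 / sigma^2`.
#' @return Numeric vector of log-likelihoods.
#' @export
lme_profile_grid <- function(y, brain, group, lambdas) {
  vapply(lambdas, function(l) {
    f <- lme_random_intercept_at(y, brain, group, l)
    f$loglik
  }, numeric(1))
}

# fixed-ratio fit (internal; shares the profiling machinery)
lme_random_intercept_at <- function(y, brain, group, lambda) {
  brain <- as.factor(brain)
  if (is.character(group)) group <- as.factor(group)
  g <- if (is.factor(group)) as.numeric(group) - 1 else as.numeric(group)
  X <- cbind(1, g)
  n <- length(y)
  idx <- split(seq_len(n), brain)
  XtVX <- matrix(0, 2, 2); XtVy <- numeric(2)
  for (ii in idx) {
    Xi <- X[ii, , drop = FALSE]; ni <- length(ii)
    a <- lambda / (1 + ni * lambda)
    XtVX <- XtVX + crossprod(Xi) - a * tcrossprod(colSums(Xi))
    XtVy <- XtVy + crossprod(Xi, y[ii]) - a * colSums(Xi) * sum(y[ii])
  }
  beta <- solve(XtVX, XtVy)
  rss <- 0; logdet <- 0
  for (ii in idx) {
    ri <- y[ii] - X[ii, , drop = FALSE] %*% beta
    ni <- length(ii)
    a <- lambda / (1 + ni * lambda)
    rss <- rss + sum(ri^2) - a * sum(ri)^2
    logdet <- logdet + log1p(ni * lambda)
  }
  sigma2 <- rss / n
  list(beta = beta, sigma2 = sigma2,
       loglik = -n / 2 * log(2 * pi * sigma2) - logdet / 2 - n / 2)
}
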