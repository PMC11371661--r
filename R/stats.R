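# Lilliefors statistic: KS distance of a sample against the normal with
# parameters estimated from the sample itself
lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  i <- seq_len(n)
  max(max(i / n - p), max(p - (i - 1) / n))
}

#' Kolmogorov-Smirnov normality test with estimated parameters
#'
#' Tests a sample against normality with mean and sd estimated from the
#' data. Because estimating the parameters makes the classical K-S null
#' distribution anticonservative, the reference p-value is obtained from a
#' Monte-Carlo null of the Lilliefors statistic (parameter-free under
#' location-scale invariance); the naive one-sample K-S p-value is also
#' reported for comparison, with that caveat.
#'
#' @param x numeric sample, n >= 4, nonzero variance.
#' @param mc_reps Monte-Carlo replicates for the null (default 10000). Uses
#'   the current RNG stream; seed with [set.seed()] for reproducibility.
#' @return list with `statistic` (Lilliefors D), `p` (Monte-Carlo),
#'   `p_naive` (classical K-S with estimated parameters), `n`, `mc_reps`.
#' @export
ks_normality <- function(x, mc_reps = 10000L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) < .Machine$double.eps)
    stop("zero variance sample", call. = FALSE)
  d <- lilliefors_stat(x)
  null_d <- lilliefors_null(n, mc_reps)
  p_mc <- (sum(null_d >= d) + 1) / (mc_reps + 1)
  p_naive <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  list(statistic = d, p = p_mc, p_naive = p_naive, n = n, mc_reps = mc_reps)
}

# simulated null distribution of the Lilliefors statistic at sample size n
lilliefors_null <- function(n, reps) {
  m <- matrix(stats::rnorm(n * reps), n, reps)
  m <- scale(m)  # per-column standardization; D is location-scale invariant
  i <- seq_len(n)
  apply(m, 2L, function(col) {
    p <- stats::pnorm(sort(col))
    max(max(i / n - p), max(p - (i - 1) / n))
  })
}

as_group_data <- function(values, groups) {
  if (is.list(values) && is.null(groups)) {
    groups <- factor(rep(names(values), lengths(values)),
                     levels = names(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- droplevels(as.factor(groups))
  keep <- is.finite(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 observations", call. = FALSE)
  list(y = values, g = groups)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition with the omnibus F test, plus the
#' pooled within-group mean square needed for LSD post hoc contrasts.
#'
#' @param values numeric vector, or a named list of per-group vectors.
#' @param groups factor of group labels (ignored when `values` is a list).
#' @return list with `F`, `df` (length 2), `p`, per-group `n`/`mean`/`sd`,
#'   and `msw` (within-group mean square).
#' @export
anova_oneway <- function(values, groups = NULL) {
  d <- as_group_data(values, groups)
  fit <- stats::oneway.test(d$y ~ d$g, var.equal = TRUE)
  ns <- tapply(d$y, d$g, length)
  sds <- tapply(d$y, d$g, stats::sd)
  msw <- sum((ns - 1) * sds^2) / (length(d$y) - nlevels(d$g))
  list(F = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value),
       n = ns, mean = tapply(d$y, d$g, mean), sd = sds, msw = msw)
}

#' One-way ANOVA from published group summaries
#'
#' Recomputes the omnibus F test from per-group sample sizes, means and
#' standard deviations alone, enabling exact re-analysis of printed
#' demographic tables: `SSB` from the means and sizes, `SSW = sum((n_i - 1)
#' * sd_i^2)`. Identical to [anova_oneway()] when the summaries come from
#' the raw data.
#'
#' @param n,mean,sd equal-length numeric vectors of per-group summaries
#'   (all `n >= 2`, `sd >= 0`).
#' @return list with `F`, `df`, `p` and `msw`.
#' @export
anova_oneway_summary <- function(n, mean, sd) {
  if (length(unique(c(length(n), length(mean), length(sd)))) != 1L)
    stop("summary vectors must have equal length", call. = FALSE)
  if (any(n < 2L)) stop("every group needs n >= 2", call. = FALSE)
  if (any(sd < 0)) stop("sd must be nonnegative", call. = FALSE)
  g <- length(n)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)
  N <- sum(n)
  gm <- sum(n * mean) / N
  ssb <- sum(n * (mean - gm)^2)
  ssw <- sum((n - 1) * sd^2)
  df <- c(g - 1, N - g)
  msw <- ssw / df[2L]
  F <- (ssb / df[1L]) / msw
  list(F = F, df = df, p = stats::pf(F, df[1L], df[2L], lower.tail = FALSE),
       msw = msw)
}

#' Least-significant-difference pairwise post hoc tests
#'
#' Unadjusted pairwise t tests using the pooled within-group variance of
#' the omnibus ANOVA: `t = (m_i - m_j) / sqrt(MSW (1/n_i + 1/n_j))` on
#' `N - g` degrees of freedom. No multiplicity correction (the LSD
#' convention).
#'
#' @param values,groups as in [anova_oneway()]; alternatively pass
#'   summary vectors `n`, `mean`, `sd` directly.
#' @param n,mean,sd per-group summaries (named vectors name the output).
#' @return list with symmetric matrices `p`, `t` and `diff` over group
#'   pairs, and `df`.
#' @export
lsd_posthoc <- function(values = NULL, groups = NULL,
                        n = NULL, mean = NULL, sd = NULL) {
  if (!is.null(values)) {
    d <- as_group_data(values, groups)
    n <- tapply(d$y, d$g, length)
    mean <- tapply(d$y, d$g, base::mean)
    sd <- tapply(d$y, d$g, stats::sd)
  }
  g <- length(n)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)
  labels <- names(n)
  if (is.null(labels)) labels <- paste0("g", seq_len(g))
  N <- sum(n)
  df <- N - g
  msw <- sum((n - 1) * sd^2) / df
  pm <- tm <- dm <- matrix(NA_real_, g, g, dimnames = list(labels, labels))
  for (i in seq_len(g - 1)) for (j in seq(i + 1, g)) {
    se <- sqrt(msw * (1 / n[i] + 1 / n[j]))
    tv <- (mean[i] - mean[j]) / se
    pv <- 2 * stats::pt(abs(tv), df, lower.tail = FALSE)
    dm[i, j] <- dm[j, i] <- mean[i] - mean[j]
    tm[i, j] <- tv; tm[j, i] <- -tv
    pm[i, j] <- pm[j, i] <- pv
  }
  list(p = pm, t = tm, diff = dm, df = df, msw = msw)
}

#' Pearson chi-square test of independence
#'
#' For contingency tables of counts (e.g. sex ratio or binary clinical
#' markers by group). No continuity correction; expected counts from the
#' margins; `df = (r - 1)(c - 1)`. A warning is issued when any expected
#' count falls below 5.
#'
#' @param table r x c matrix of nonnegative integer counts with at least
#'   two nonzero rows and columns.
#' @return list with `chi2`, `df`, `p` and `expected`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin", call. = FALSE)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("need at least a 2 x 2 table", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(ht$expected < 5))
    warning("expected count(s) below 5; chi-square approximation is rough")
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), expected = ht$expected)
}

#' ANCOVA group comparison with covariate adjustment
#'
#' The study's main group test: a linear model of the metric on the group
#' factor plus continuous/binary nuisance covariates (head motion, age,
#' sex, education in the reference analysis). Reports the omnibus partial F
#' for the group block, covariate-adjusted (least-squares) group means
#' evaluated at the covariate means, and LSD-style unadjusted pairwise
#' contrasts from the model's residual variance. With no covariates this
#' reduces exactly to the one-way ANOVA.
#'
#' @param y numeric metric values, one per subject.
#' @param group factor (or coercible) of group labels; the *last* level is
#'   used as the dummy-coding reference (put the control group last).
#' @param covariates data.frame of numeric covariates (or `NULL`).
#' @return object of class `"scfc_ancova"`: `F`, `df`, `p`,
#'   `adjusted_means` (+- `adjusted_se`), `posthoc` (matrices `p`, `t`,
#'   `diff`; residual df), `covariates`, `n`.
#' @export
ancova_group_test <- function(y, group, covariates = NULL) {
  group <- droplevels(as.factor(group))
  g <- nlevels(group)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) < 2L))
    stop("every group needs at least 2 subjects", call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(y))
      stop("covariates and y lengths differ", call. = FALSE)
  }
  keep <- is.finite(y)
  if (!is.null(covariates))
    keep <- keep & stats::complete.cases(covariates)
  y <- y[keep]; group <- droplevels(group[keep])
  # last level (control) as dummy reference
  group <- stats::relevel(group, ref = levels(group)[nlevels(group)])
  dat <- data.frame(.y = y, .g = group)
  cnames <- character(0)
  if (!is.null(covariates) && ncol(covariates)) {
    covariates <- covariates[keep, , drop = FALSE]
    cnames <- names(covariates)
    dat <- cbind(dat, covariates)
  }
  nc <- length(cnames)
  if (length(y) <= g + nc + 1L)
    stop("too few subjects for the requested model", call. = FALSE)
  rhs_cov <- if (nc) paste(cnames, collapse = " + ") else "1"
  full <- stats::lm(stats::as.formula(paste("`.y` ~", rhs_cov, "+ .g")),
                    data = dat)
  if (any(is.na(stats::coef(full))))
    stop("rank-deficient design (collinear covariates?)", call. = FALSE)
  reduced <- stats::lm(stats::as.formula(paste("`.y` ~", rhs_cov)), data = dat)
  cmp <- stats::anova(reduced, full)
  F <- cmp$F[2L]
  df <- c(cmp$Df[2L], cmp$Res.Df[2L])
  p <- cmp$`Pr(>F)`[2L]

  lev <- levels(group)
  newdata <- data.frame(.g = factor(lev, levels = lev))
  if (nc) for (cn in cnames) newdata[[cn]] <- base::mean(dat[[cn]])
  pr <- stats::predict(full, newdata = newdata, se.fit = TRUE)
  adj <- stats::setNames(pr$fit, lev)
  adj_se <- stats::setNames(pr$se.fit, lev)

  # pairwise LSD-style contrasts on the adjusted means
  X <- stats::model.matrix(stats::delete.response(stats::terms(full)), newdata)
  V <- stats::vcov(full)
  beta <- stats::coef(full)
  rdf <- full$df.residual
  pm <- tm <- dm <- matrix(NA_real_, g, g, dimnames = list(lev, lev))
  for (i in seq_len(g - 1)) for (j in seq(i + 1, g)) {
    cvec <- X[i, ] - X[j, ]
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tv <- est / se
    dm[i, j] <- est; dm[j, i] <- -est
    tm[i, j] <- tv; tm[j, i] <- -tv
    pm[i, j] <- pm[j, i] <- 2 * stats::pt(abs(tv), rdf, lower.tail = FALSE)
  }
  structure(list(F = F, df = df, p = p,
                 adjusted_means = adj, adjusted_se = adj_se,
                 posthoc = list(p = pm, t = tm, diff = dm, df = rdf),
                 covariates = cnames, n = table(group)),
            class = "scfc_ancova")
}

#' @export
print.scfc_ancova <- function(x, ...) {
  cat(sprintf("<scfc_ancova> F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1L], x$df[2L], x$F, x$p))
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  cat("  adjusted means:\n")
  for (g in names(x$adjusted_means))
    cat(sprintf("    %-10s %8.4f (se %.4f, n = %d)\n", g,
                x$adjusted_means[[g]], x$adjusted_se[[g]], x$n[[g]]))
  invisible(x)
}

#' Partial correlation with covariate adjustment
#'
#' Pearson correlation between the residuals of `x` and `y` after each is
#' regressed on an intercept plus the covariates; the test statistic is
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - 2 - c`. With no
#' covariates this is the ordinary Pearson correlation test. Incomplete
#' cases are dropped pairwise.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame of numeric covariates, or `NULL`.
#' @return list with `r`, `df`, `p`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- keep & stats::complete.cases(covariates)
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  nc <- if (is.null(covariates)) 0L else ncol(covariates)
  df <- n - 2L - nc
  if (df < 1L) stop("too few complete cases for the covariate set",
                    call. = FALSE)
  if (nc) {
    Z <- cbind(1, as.matrix(covariates[keep, , drop = FALSE]))
    if (qr(Z)$rank < ncol(Z))
      stop("rank-deficient covariate matrix", call. = FALSE)
    x <- stats::lm.fit(Z, x)$residuals
    y <- stats::lm.fit(Z, y)$residuals
  }
  if (stats::var(x) < .Machine$double.eps ||
      stats::var(y) < .Machine$double.eps)
    stop("zero residual variance", call. = FALSE)
  r <- stats::cor(x, y)
  tv <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * stats::pt(abs(tv), df, lower.tail = FALSE),
       n = n)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values: monotone, bounded by 1, controlling the FDR
#' across the supplied family of p-values.
#'
#' @param pvalues numeric vector in \[0, 1\] (NA passed through).
#' @return adjusted q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}
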