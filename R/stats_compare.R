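## Group-comparison statistics with exact small-sample formulas and a
## deterministic contract: pooled-variance Student's t (the named test,
## not Welch), one-way ANOVA with Tukey or Dunnett post-tests, Pearson
## correlation. All p-values are two-sided. Degenerate zero-variance
## inputs are flagged rather than allowed to crash pipelines running on
## flat synthetic data.

comparison_result <- function(kind, statistic, df, p_value, means, sems,
                              degenerate = FALSE, posthoc = NULL) {
  structure(list(kind = kind, statistic = statistic, df = df,
                 p_value = p_value, means = means, sems = sems,
                 degenerate = degenerate, posthoc = posthoc),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, df = %s, p = %.4g%s\n", x$kind,
              x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value, if (x$degenerate) " [degenerate]" else ""))
  if (!is.null(x$means))
    cat("  group means +/- SEM:",
        paste(sprintf("%.4g +/- %.4g", x$means, x$sems), collapse = ", "), "\n")
  if (!is.null(x$posthoc)) { cat("  post-hoc:\n"); print(x$posthoc) }
  invisible(x)
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Student's t-test (pooled variance), paired or unpaired
#'
#' Two-sided Student's t-test. The unpaired form uses the pooled-variance
#' statistic with `n1 + n2 - 2` degrees of freedom. When every difference
#' (paired) or both samples (unpaired, equal means) carry zero variance,
#' the result is flagged degenerate with statistic 0 and p = 1.
#'
#' @param a,b numeric samples; equal lengths when `paired`.
#' @param paired logical.
#' @return a `comparison_result`.
#' @export
t_test2 <- function(a, b, paired = FALSE) {
  if (paired) {
    if (length(a) != length(b)) stopf("paired samples must have equal length")
    if (length(a) < 2) stopf("paired test needs n >= 2")
    d <- a - b
    n <- length(d)
    if (stats::sd(d) == 0) {
      return(comparison_result("t_paired", 0, n - 1, 1,
                               c(mean(a), mean(b)), c(sem(a), sem(b)),
                               degenerate = TRUE))
    }
    t <- mean(d) / (stats::sd(d) / sqrt(n))
    return(comparison_result("t_paired", t, n - 1, 2 * stats::pt(-abs(t), n - 1),
                             c(mean(a), mean(b)), c(sem(a), sem(b))))
  }
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stopf("each sample needs n >= 2")
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (mean(a) == mean(b))
      return(comparison_result("t_unpaired", 0, n1 + n2 - 2, 1,
                               c(mean(a), mean(b)), c(sem(a), sem(b)),
                               degenerate = TRUE))
    stopf("zero variance with unequal means: t undefined")
  }
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  comparison_result("t_unpaired", t, n1 + n2 - 2,
                    2 * stats::pt(-abs(t), n1 + n2 - 2),
                    c(mean(a), mean(b)), c(sem(a), sem(b)))
}

## Two-sided Dunnett many-to-one p-values via the equicoordinate
## multivariate t distribution (correlations r_ij = sqrt(li * lj),
## l_i = n_i / (n_i + n0)).
dunnett_p <- function(tstats, n, df, control = 1L) {
  ns <- n[-control]
  lam <- sqrt(ns / (ns + n[control]))
  R <- outer(lam, lam)
  diag(R) <- 1
  # pmvt's quasi-Monte-Carlo integrator consumes the R RNG; pin it locally
  # so results are deterministic and callers' streams are untouched
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20231230L)
  vapply(abs(tstats), function(q) {
    pr <- mvtnorm::pmvt(lower = rep(-q, length(ns)), upper = rep(q, length(ns)),
                        df = as.integer(df), corr = R,
                        algorithm = mvtnorm::GenzBretz(abseps = 1e-6,
                                                       maxpts = 1e5))
    max(0, 1 - as.numeric(pr))
  }, 0)
}

#' One-way ANOVA with optional post-hoc comparisons
#'
#' Fixed-effects one-way analysis of variance, F with `(k-1, N-k)` df.
#' Two groups delegate to the unpaired pooled-variance t-test (F = t^2).
#' Post-hoc options: Tukey HSD (studentized-range p-values over all
#' pairs) or Dunnett many-to-one versus a control group (multivariate-t
#' adjusted, two-sided). Groups that are all identical constants yield a
#' degenerate 0/0 F, reported as no difference (p = 1).
#'
#' @param groups named (or unnamed) list of numeric vectors, each n >= 2.
#' @param posthoc `"none"`, `"tukey"` or `"dunnett"`.
#' @param control index or name of the control group for Dunnett.
#' @return a `comparison_result`; post-hoc table (comparison, estimate,
#'   statistic, p_adj) in `$posthoc`.
#' @export
one_way_anova <- function(groups, posthoc = c("none", "tukey", "dunnett"),
                          control = 1L) {
  posthoc <- match.arg(posthoc)
  if (length(groups) < 2) stopf("need >= 2 groups")
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  nm[nm == ""] <- paste0("g", which(nm == ""))
  names(groups) <- nm
  ns <- lengths(groups)
  small <- ns < 2
  if (any(small)) stopf("group(s) with n < 2: %s",
                        paste(nm[small], collapse = ", "))
  if (length(groups) == 2 && posthoc == "none") {
    tt <- t_test2(groups[[1]], groups[[2]], paired = FALSE)
    return(comparison_result("anova_as_t", tt$statistic^2,
                             c(1, tt$df), tt$p_value, tt$means, tt$sems,
                             degenerate = tt$degenerate))
  }
  k <- length(groups); N <- sum(ns)
  means <- vapply(groups, mean, 0)
  gm <- sum(unlist(groups)) / N
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  if (ssw == 0 && ssb == 0) {
    return(comparison_result("anova", NaN, c(k - 1, N - k), 1, means,
                             vapply(groups, sem, 0), degenerate = TRUE))
  }
  if (ssw == 0) stopf("zero within-group variance with unequal means")
  mse <- ssw / (N - k)
  f <- (ssb / (k - 1)) / mse
  p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  ph <- NULL
  if (posthoc == "tukey") {
    pairs <- utils::combn(k, 2)
    est <- means[pairs[1, ]] - means[pairs[2, ]]
    se <- sqrt(mse * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
    q <- abs(est) / se * sqrt(2)
    ph <- data.frame(comparison = paste(nm[pairs[1, ]], "-", nm[pairs[2, ]]),
                     estimate = unname(est), statistic = unname(q),
                     p_adj = stats::ptukey(q, k, N - k, lower.tail = FALSE),
                     row.names = NULL, stringsAsFactors = FALSE)
  } else if (posthoc == "dunnett") {
    if (is.character(control)) control <- match(control, nm)
    others <- setdiff(seq_len(k), control)
    est <- means[others] - means[control]
    se <- sqrt(mse * (1 / ns[others] + 1 / ns[control]))
    tstat <- est / se
    ph <- data.frame(comparison = paste(nm[others], "-", nm[control]),
                     estimate = unname(est), statistic = unname(tstat),
                     p_adj = dunnett_p(tstat, ns, N - k, control),
                     row.names = NULL, stringsAsFactors = FALSE)
  }
  comparison_result("anova", f, c(k - 1, N - k), p, means,
                    vapply(groups, sem, 0), posthoc = ph)
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation; p from the t-transform
#' `t = r * sqrt((n-2) / (1-r^2))` with `n - 2` degrees of freedom. For
#' |r| = 1 the p-value is 0 by continuity.
#'
#' @param x,y numeric vectors, length >= 3, each with nonzero variance.
#' @return list `r`, `p_value`, `n`, `statistic`, `df` of class
#'   `comparison_result`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3) stopf("Pearson correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero variance: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    t <- Inf * sign(r); p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  out <- comparison_result("pearson", t, n - 2, p, NULL, NULL)
  out$r <- r; out$n <- n
  out
}
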