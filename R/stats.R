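# Group-comparison statistics for MEA endpoints: Brown-Forsythe variance
# check deciding between one-way ANOVA + Dunnett and Welch ANOVA +
# Games-Howell.

#' Compare treatment groups the MEA way
#'
#' Implements the branching analysis used for well-level MEA endpoints.
#' The Brown-Forsythe test (Levene's test on absolute deviations from group
#' medians) checks whether the group standard deviations differ at
#' `alpha`.  If not, a one-way ANOVA is followed by Dunnett's many-to-one
#' comparisons against the control group; if they do, a Welch ANOVA is
#' followed by Games-Howell all-pairs comparisons.
#'
#' @param values Numeric response vector.
#' @param group Grouping factor (or coercible); the control group is the
#'   first level unless given.
#' @param control Control-group level for the Dunnett branch (default: first
#'   level of `group`).
#' @param alpha Significance level of the Brown-Forsythe branch decision
#'   (default 0.05).
#' @return Object of class `mea_group_test`: list with `branch`
#'   (`"homoscedastic"` or `"heteroscedastic"`), `brown_forsythe` (statistic,
#'   df, p), `omnibus` (ANOVA or Welch ANOVA), and `posthoc` (data frame of
#'   comparisons with estimates and adjusted p-values).
#' @examples
#' set.seed(1)
#' compare_groups(c(rnorm(8), rnorm(8, 2), rnorm(8, 0)),
#'                rep(c("ctrl", "a", "b"), each = 8), control = "ctrl")
#' @export
compare_groups <- function(values, group, control = NULL, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2) stop_config("need at least 2 groups")
  if (any(table(group) < 2)) stop_config("every group needs >= 2 values")
  if (!is.null(control)) group <- stats::relevel(group, ref = control)
  zero_var <- tapply(values, group, stats::sd) == 0 & table(group) == 2
  if (any(zero_var))
    warning("group(s) with zero variance and n = 2: ",
            paste(names(zero_var)[zero_var], collapse = ", "),
            "; results are unreliable", call. = FALSE)
  bf <- car::leveneTest(values ~ group, center = stats::median)
  bf_p <- bf[["Pr(>F)"]][1]
  if (bf_p >= alpha) {
    branch <- "homoscedastic"
    fit <- stats::aov(values ~ group)
    omni <- summary(fit)[[1]]
    glht <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    s <- summary(glht)
    posthoc <- data.frame(
      comparison = names(s$test$coefficients),
      estimate = as.numeric(s$test$coefficients),
      statistic = as.numeric(s$test$tstat),
      p_adjusted = as.numeric(s$test$pvalues),
      method = "Dunnett", stringsAsFactors = FALSE)
    omnibus <- list(statistic = omni[["F value"]][1],
                    df = c(omni[["Df"]][1], omni[["Df"]][2]),
                    p = omni[["Pr(>F)"]][1], method = "one-way ANOVA")
  } else {
    branch <- "heteroscedastic"
    w <- stats::oneway.test(values ~ group, var.equal = FALSE)
    posthoc <- games_howell(values, group)
    posthoc$method <- "Games-Howell"
    omnibus <- list(statistic = unname(w$statistic),
                    df = unname(w$parameter), p = w$p.value,
                    method = "Welch ANOVA")
  }
  structure(list(branch = branch,
                 brown_forsythe = list(statistic = bf[["F value"]][1],
                                       df = c(bf[["Df"]][1], bf[["Df"]][2]),
                                       p = bf_p),
                 omnibus = omnibus, posthoc = posthoc, alpha = alpha),
            class = "mea_group_test")
}

#' @export
print.mea_group_test <- function(x, ...) {
  cat("MEA group comparison\n")
  cat(sprintf("  Brown-Forsythe: F = %.3f, p = %.4g -> %s branch\n",
              x$brown_forsythe$statistic, x$brown_forsythe$p, x$branch))
  cat(sprintf("  %s: statistic = %.3f, p = %.4g\n",
              x$omnibus$method, x$omnibus$statistic, x$omnibus$p))
  cat(sprintf("  post hoc (%s):\n", x$posthoc$method[1]))
  print.data.frame(x$posthoc[, c("comparison", "estimate", "p_adjusted")],
                   digits = 4)
  invisible(x)
}

#' Games-Howell all-pairs comparisons
#'
#' Pairwise comparisons for unequal variances: each pair's statistic is the
#' mean difference over the Welch standard error, referred to the studentized
#' range distribution with `k` groups and the pair's Welch-Satterthwaite
#' degrees of freedom.
#'
#' @param values Numeric response vector.
#' @param group Grouping factor.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return Data frame `comparison`, `estimate`, `statistic` (Welch t), `df`,
#'   `p_adjusted`, `conf_low`, `conf_high`.
#' @export
games_howell <- function(values, group, conf_level = 0.95) {
  group <- factor(group)
  k <- nlevels(group)
  m <- tapply(values, group, mean)
  v <- tapply(values, group, stats::var)
  n <- tapply(values, group, length)
  pairs <- utils::combn(levels(group), 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se2 <- v[a] / n[a] + v[b] / n[b]
    df <- se2^2 / ((v[a] / n[a])^2 / (n[a] - 1) +
                     (v[b] / n[b])^2 / (n[b] - 1))
    tt <- (m[b] - m[a]) / sqrt(se2)
    p <- stats::ptukey(sqrt(2) * abs(tt), k, df, lower.tail = FALSE)
    hw <- stats::qtukey(conf_level, k, df) / sqrt(2) * sqrt(se2)
    data.frame(comparison = paste(b, "-", a),
               estimate = unname(m[b] - m[a]), statistic = unname(tt),
               df = unname(df), p_adjusted = unname(p),
               conf_low = unname(m[b] - m[a] - hw),
               conf_high = unname(m[b] - m[a] + hw),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Dunnett two-sided critical value
#'
#' Critical value of the balanced many-to-one (Dunnett) comparison: the
#' `1 - alpha` two-sided equicoordinate quantile of `k - 1` equicorrelated
#' (rho = 0.5) t variates on the pooled error degrees of freedom.
#'
#' @param k Number of groups including the control.
#' @param n Per-group sample size (balanced).
#' @param alpha Familywise error rate (default 0.05).
#' @return The critical |t| value.
#' @export
dunnett_critical <- function(k, n, alpha = 0.05) {
  stopifnot(k >= 2, n >= 2)
  df <- k * (n - 1)
  R <- matrix(0.5, k - 1, k - 1)
  diag(R) <- 1
  # qmvt seeds the global RNG for its quasi-Monte-Carlo integration;
  # evaluate under a local RNG state so callers' streams are untouched
  with_local_seed(1L,
                  mvtnorm::qmvt(1 - alpha, tail = "both.tails", df = df,
                                corr = R, seed = 1)$quantile)
}
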