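#' Kolmogorov-Smirnov normality screen with log-transform policy
#'
#' Computes the one-sample K-S distance between the empirical CDF and a
#' normal CDF with mean and SD estimated from the sample (the Lilliefors
#' statistic), with its p-value obtained by seeded Monte-Carlo simulation
#' under the estimated-parameter null. When normality is rejected at
#' `alpha`, a logarithmic transformation is recommended, mirroring the
#' analysis policy of normalizing skewed outcome variables before ANOVA.
#'
#' @param x Numeric sample, n >= 4.
#' @param alpha Rejection level driving the transform recommendation
#'   (default 0.05).
#' @param mc_reps Monte-Carlo replicates for the p-value (default 10^4).
#' @param seed Seed for the Monte-Carlo draw (default 1).
#' @return A `rehab_ks` list: `statistic` (D), `p_value`, `n`,
#'   `transform_recommended`.
#' @export
ks_normality <- function(x, alpha = 0.05, mc_reps = 1e4, seed = 1) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) stop_rehab("need at least 4 observations", "rehabpose_parameter_error")
  D <- lilliefors_d(x)
  Dsim <- local({
    set.seed(seed)
    vapply(seq_len(mc_reps), function(i) lilliefors_d(stats::rnorm(n)), numeric(1))
  })
  p <- (1 + sum(Dsim >= D)) / (mc_reps + 1)
  structure(list(statistic = D, p_value = p, n = n,
                 transform_recommended = p < alpha,
                 method = "K-S (Lilliefors) with Monte-Carlo p"),
            class = "rehab_ks")
}

# sup |ECDF - fitted normal CDF|, evaluated at the jump points
lilliefors_d <- function(x) {
  n <- length(x)
  z <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  max(seq_len(n) / n - z, z - (seq_len(n) - 1) / n)
}

#' @export
print.rehab_ks <- function(x, ...) {
  cat(sprintf("K-S normality: D = %.4f, Monte-Carlo p = %.4f (n = %d)%s\n",
              x$statistic, x$p_value, x$n,
              if (x$transform_recommended) "; log transform recommended" else ""))
  invisible(x)
}

#' Log-transform a positive sample
#'
#' The normalization applied when the K-S screen rejects; refuses
#' non-positive values rather than producing -Inf/NaN.
#'
#' @param x Numeric vector, strictly positive.
#' @return `log(x)`.
#' @export
log_transform <- function(x) {
  if (any(x <= 0, na.rm = TRUE)) {
    stop_rehab("log transform requested for non-positive values",
               "rehabpose_transform_error")
  }
  log(x)
}

#' One-way (single-factor) analysis of variance
#'
#' Classical between/within decomposition via [stats::aov()].
#'
#' @param data Either a list of `k` numeric samples, or a data frame with
#'   `value` and `group` columns.
#' @return Tibble with `F`, `df1`, `df2`, `p`, `partial_eta_sq`.
#' @export
oneway_anova <- function(data) {
  if (is.data.frame(data)) {
    df <- tibble(value = data$value, group = factor(data$group))
  } else {
    df <- imap(data, ~ tibble(value = .x, group = as.character(.y))) |> list_rbind()
    df$group <- factor(df$group)
  }
  sizes <- table(df$group)
  if (length(sizes) < 2) stop_rehab("need at least 2 groups", "rehabpose_parameter_error")
  if (any(sizes < 2)) {
    stop_rehab("every group needs at least 2 observations", "rehabpose_degeneracy_error")
  }
  tab <- stats::anova(stats::aov(value ~ group, data = df))
  F <- tab$`F value`[1]
  tibble(F = F, df1 = tab$Df[1], df2 = tab$Df[2], p = tab$`Pr(>F)`[1],
         partial_eta_sq = partial_eta_from_f(F, tab$Df[1], tab$Df[2]))
}

#' Partial eta-squared from an F statistic
#'
#' `F * df1 / (F * df1 + df2)`, the effect-size measure
#' SS_effect / (SS_effect + SS_error) re-expressed through the reported F
#' and its degrees of freedom.
#'
#' @param F F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @param digits Optional rounding.
#' @return Partial eta-squared in \[0, 1\].
#' @export
#' @examples
#' partial_eta_from_f(6.219, 4, 134, digits = 3)  # 0.157
partial_eta_from_f <- function(F, df1, df2, digits = NULL) {
  check_number(F, "F", lo = 0)
  check_number(df1, "df1", lo = 0, strict_lo = TRUE)
  check_number(df2, "df2", lo = 0, strict_lo = TRUE)
  out <- F * df1 / (F * df1 + df2)
  if (!is.null(digits)) out <- round(out, digits) else out
}

# ---- mixed repeated-measures ANOVA -----------------------------------------

# complete-case wide matrix: rows subjects, cols timepoints, plus group factor
rm_wide <- function(data, measure) {
  stopifnot(all(c("subject", "group", "time", "measure", "value") %in% names(data)))
  d <- data |> filter(.data$measure == !!measure)
  if (nrow(d) == 0) stop_rehab(sprintf("no rows for measure '%s'", measure),
                               "rehabpose_design_error")
  times <- if (is.factor(d$time)) levels(droplevels(d$time)) else unique(as.character(d$time))
  m <- length(times)
  if (m < 2) stop_rehab("need at least 2 timepoints", "rehabpose_design_error")
  if (anyDuplicated(d[, c("subject", "time")]) > 0) {
    stop_rehab("duplicated (subject, timepoint) rows", "rehabpose_design_error")
  }
  wide <- d |>
    mutate(time = factor(as.character(.data$time), levels = times)) |>
    pivot_wider(id_cols = c("subject", "group"), names_from = "time",
                values_from = "value")
  complete <- stats::complete.cases(wide[, times])
  dropped <- sum(!complete)
  if (dropped > 0) {
    warn(sprintf("%d incomplete subject(s) dropped listwise", dropped))
  }
  wide <- wide[complete, ]
  list(Y = as.matrix(wide[, times]), g = factor(wide$group), times = times,
       m = m, dropped = dropped)
}

# orthonormal within-subject contrast matrix (m x (m-1))
orthonormal_contrasts <- function(m) {
  C <- stats::contr.helmert(m)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# general linear hypothesis SSCP for L %*% B = 0 in the mlm Z = X B + E
glh_sscp <- function(X, B, XtXinv, L) {
  LB <- L %*% B
  t(LB) %*% solve(L %*% XtXinv %*% t(L), LB)
}

pillai_f <- function(H, E, df_h, df_e, p) {
  V <- sum(diag(H %*% solve(H + E)))
  s <- min(p, df_h)
  mm <- (abs(p - df_h) - 1) / 2
  nn <- (df_e - p - 1) / 2
  df1 <- s * (2 * mm + s + 1)
  df2 <- s * (2 * nn + s + 1)
  F <- (df2 / df1) * (V / (s - V))
  list(statistic = V, F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

#' Mixed-design repeated-measures ANOVA
#'
#' Three-way inference for a groups x timepoints design with subjects
#' nested in groups: the between-group effect (tested on subject means),
#' the within-subject time effect, and the group x time interaction.
#' Within-subject inference is built on orthonormalized contrast scores.
#' Mauchly's sphericity test is applied to the pooled contrast covariance;
#' when it rejects at `sphericity_alpha`, the within and interaction
#' effects are reported through the Pillai's-trace MANOVA F approximation
#' instead of the sphericity-assumed univariate test. The between effect is
#' always univariate. Partial eta-squared accompanies every effect.
#' Incomplete subjects are dropped listwise with a warning.
#'
#' @param data Long-format trial data: columns `subject`, `group`, `time`,
#'   `measure`, `value`.
#' @param measure Which measure to analyse.
#' @param sphericity_alpha Mauchly rejection level triggering the Pillai
#'   path (default 0.05).
#' @return A `rehab_rm_anova` object; see [tidy()]/[glance()] methods.
#' @export
rm_anova <- function(data, measure, sphericity_alpha = 0.05) {
  w <- rm_wide(data, measure)
  Y <- w$Y; g <- w$g; m <- w$m
  N <- nrow(Y); k <- nlevels(g)
  if (N < k + 1) stop_rehab("too few complete subjects", "rehabpose_design_error")
  p <- m - 1

  # between-group effect on subject means (the m factor cancels)
  btab <- stats::anova(stats::lm(rowMeans(Y) ~ g))
  Fb <- btab$`F value`[1]
  between <- tibble(effect = "group", F = Fb, df1 = btab$Df[1], df2 = btab$Df[2],
                    p = btab$`Pr(>F)`[1],
                    partial_eta_sq = safe_eta(Fb, btab$Df[1], btab$Df[2]),
                    path = "univariate")

  # contrast-space general linear model with sum-to-zero group coding
  C <- orthonormal_contrasts(m)
  Z <- Y %*% C
  X <- stats::model.matrix(~g, data = data.frame(g = g),
                           contrasts.arg = list(g = "contr.sum"))
  XtXinv <- solve(crossprod(X))
  B <- XtXinv %*% crossprod(X, Z)
  R <- Z - X %*% B
  E <- crossprod(R)
  df_e <- N - k

  mauchly <- mauchly_sphericity(E, df_e, p)
  use_pillai <- is.finite(mauchly$p) && mauchly$p < sphericity_alpha

  within_effect <- function(label, L, df_h) {
    H <- glh_sscp(X, B, XtXinv, L)
    if (sum(diag(H)) < 1e-12) {
      return(tibble(effect = label, F = 0, df1 = df_h * p, df2 = df_e * p,
                    p = 1, partial_eta_sq = 0, path = "univariate"))
    }
    if (use_pillai) {
      pt <- pillai_f(H, E, df_h, df_e, p)
      tibble(effect = label, F = pt$F, df1 = pt$df1, df2 = pt$df2, p = pt$p,
             partial_eta_sq = safe_eta(pt$F, pt$df1, pt$df2),
             path = "pillai_trace")
    } else {
      F <- (sum(diag(H)) / df_h) / (sum(diag(E)) / df_e)
      df1 <- df_h * p; df2 <- df_e * p
      tibble(effect = label, F = F, df1 = df1, df2 = df2,
             p = stats::pf(F, df1, df2, lower.tail = FALSE),
             partial_eta_sq = safe_eta(F, df1, df2),
             path = "univariate")
    }
  }
  ncoef <- ncol(X)
  L_time <- matrix(c(1, rep(0, ncoef - 1)), nrow = 1)
  L_int <- cbind(matrix(0, k - 1, 1), diag(k - 1))

  effects <- bind_rows(between,
                       within_effect("time", L_time, 1),
                       within_effect("group:time", L_int, k - 1))
  structure(
    list(effects = effects, mauchly = mauchly,
         path = if (use_pillai) "pillai_trace" else "sphericity_assumed",
         n = N, k = k, m = m, times = w$times, measure = measure,
         dropped = w$dropped),
    class = "rehab_rm_anova")
}

# partial eta-squared tolerating degenerate (zero-error) decompositions
safe_eta <- function(F, df1, df2) {
  if (!is.finite(F)) return(if (is.nan(F)) NA_real_ else 1)
  F * df1 / (F * df1 + df2)
}

mauchly_sphericity <- function(E, df_e, p) {
  if (p < 2) {
    return(list(W = 1, chisq = 0, df = 0, p = NA_real_))
  }
  S <- E / df_e
  W <- det(S) / (sum(diag(S)) / p)^p
  fcorr <- 1 - (2 * p^2 + p + 2) / (6 * p * df_e)
  chisq <- -fcorr * df_e * log(W)
  df <- p * (p + 1) / 2 - 1
  list(W = W, chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' @export
print.rehab_rm_anova <- function(x, ...) {
  cat(sprintf("Mixed RM-ANOVA of '%s': %d subjects, %d groups x %d timepoints\n",
              x$measure, x$n, x$k, x$m))
  cat(sprintf("Mauchly W = %.4f (p = %s); within-subject path: %s\n",
              x$mauchly$W, format.pval(x$mauchly$p), x$path))
  print(as.data.frame(x$effects), row.names = FALSE)
  invisible(x)
}

#' Pairwise mean differences with confidence intervals
#'
#' Within-group time contrasts (paired) and between-group contrasts at each
#' timepoint (independent), both using the pooled within-group covariance
#' of the repeated measures (error df N - k). The default follows the
#' unadjusted (LSD) convention; Bonferroni adjustment is available.
#'
#' @inheritParams rm_anova
#' @param adjust `"none"` (LSD) or `"bonferroni"`.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble of contrasts: `type` (within/between), `group` or `time`
#'   context, `lhs`, `rhs`, `difference` (lhs - rhs), `se`, `df`, `lower`,
#'   `upper`, `p`.
#' @export
pairwise_differences <- function(data, measure, adjust = c("none", "bonferroni"),
                                 conf_level = 0.95) {
  adjust <- match.arg(adjust)
  w <- rm_wide(data, measure)
  Y <- w$Y; g <- w$g; times <- w$times
  N <- nrow(Y); k <- nlevels(g); m <- w$m
  df_err <- N - k
  if (df_err < 1) stop_rehab("no error degrees of freedom", "rehabpose_design_error")
  # pooled within-group covariance of the m repeated measures
  S <- Reduce(`+`, lapply(levels(g), function(gl) {
    Yg <- Y[g == gl, , drop = FALSE]
    if (nrow(Yg) < 2) matrix(0, m, m) else (nrow(Yg) - 1) * stats::cov(Yg)
  })) / df_err

  rows <- list()
  # within-group: time t2 vs t1 inside each group (paired contrast)
  for (gl in levels(g)) {
    Yg <- Y[g == gl, , drop = FALSE]
    ng <- nrow(Yg)
    for (i1 in seq_len(m - 1)) for (i2 in seq((i1 + 1), m)) {
      d <- mean(Yg[, i2]) - mean(Yg[, i1])
      se <- sqrt((S[i1, i1] + S[i2, i2] - 2 * S[i1, i2]) / ng)
      rows[[length(rows) + 1]] <- tibble(
        type = "within", context = gl, lhs = times[i2], rhs = times[i1],
        difference = d, se = se, df = df_err)
    }
  }
  # between-group at each timepoint (independent contrast)
  gls <- levels(g)
  for (it in seq_len(m)) {
    for (i1 in seq_len(max(k - 1, 0))) for (i2 in seq(min(i1 + 1, k), k)) {
      if (i1 >= i2) next
      n1 <- sum(g == gls[i1]); n2 <- sum(g == gls[i2])
      d <- mean(Y[g == gls[i1], it]) - mean(Y[g == gls[i2], it])
      se <- sqrt(S[it, it] * (1 / n1 + 1 / n2))
      rows[[length(rows) + 1]] <- tibble(
        type = "between", context = times[it], lhs = gls[i1], rhs = gls[i2],
        difference = d, se = se, df = df_err)
    }
  }
  out <- list_rbind(rows) |>
    mutate(t = .data$difference / .data$se,
           p = 2 * stats::pt(abs(.data$t), .data$df, lower.tail = FALSE))
  nc <- if (adjust == "bonferroni") {
    ifelse(out$type == "within", choose(m, 2), choose(k, 2))
  } else 1
  alpha <- (1 - conf_level) / nc
  out |>
    mutate(p = pmin(1, .data$p * nc),
           lower = .data$difference - stats::qt(1 - alpha / 2, .data$df) * .data$se,
           upper = .data$difference + stats::qt(1 - alpha / 2, .data$df) * .data$se) |>
    select("type", "context", "lhs", "rhs", "difference", "se", "df",
           "lower", "upper", "p")
}

# ---- power analysis ---------------------------------------------------------

#' Specify a power analysis
#'
#' Parameters of the noncentral-F power calculation for a one-way or
#' repeated-measures between-factors ANOVA: Cohen's effect size f measured
#' against total (between + within subject) SD, the type-I level, target
#' power, group count `k`, number of repeated measurements `m`, and the
#' common correlation `rho` between repeated measures.
#'
#' @param f Effect size f (> 0).
#' @param alpha Type-I error level in (0, 1).
#' @param power Target power in (0, 1).
#' @param k Number of groups (>= 2).
#' @param m Number of repeated measurements (>= 2 for `rm_between`).
#' @param rho Repeated-measures correlation in (0, 1).
#' @param design `"rm_between"` (between-group effect of a repeated-measures
#'   design) or `"oneway"`.
#' @return A `rehab_power_spec` list.
#' @export
power_spec <- function(f = 0.4, alpha = 0.05, power = 0.90, k = 3, m = 3,
                       rho = 0.5, design = c("rm_between", "oneway")) {
  design <- match.arg(design)
  check_number(f, "f", lo = 0, strict_lo = TRUE)
  check_number(alpha, "alpha", lo = 0, hi = 1, strict_lo = TRUE)
  if (alpha >= 1) stop_rehab("alpha must be in (0,1)", "rehabpose_parameter_error")
  check_number(power, "power", lo = 0, hi = 1, strict_lo = TRUE)
  check_number(k, "k", lo = 2)
  check_number(rho, "rho", lo = 0, hi = 1, strict_lo = TRUE)
  if (design == "rm_between") check_number(m, "m", lo = 2)
  structure(list(f = f, alpha = alpha, power = power, k = k, m = m,
                 rho = rho, design = design),
            class = "rehab_power_spec")
}

#' Power of the between-group test at a given total sample size
#'
#' Noncentral-F power: the between-group effect has df1 = k - 1 and
#' df2 = N - k; for the repeated-measures design the noncentrality is
#' lambda = f^2 N m / (1 + (m - 1) rho) -- averaging over m correlated
#' measurements shrinks the subject-level error -- and for the one-way
#' design lambda = f^2 N. Power is P(F' > F_crit(alpha)).
#'
#' @param spec A [power_spec()].
#' @param N Total sample size across the `k` equal groups.
#' @return Power in (0, 1).
#' @export
power_rm_between <- function(spec, N) {
  stopifnot(inherits(spec, "rehab_power_spec"))
  check_number(N, "N", lo = spec$k + 1)
  lambda <- if (spec$design == "rm_between") {
    spec$f^2 * N * spec$m / (1 + (spec$m - 1) * spec$rho)
  } else {
    spec$f^2 * N
  }
  df1 <- spec$k - 1
  df2 <- N - spec$k
  crit <- stats::qf(1 - spec$alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Solve for the minimum sample size
#'
#' Smallest equal-group total N (stepping by `k`) whose noncentral-F power
#' reaches the target.
#'
#' @param spec A [power_spec()].
#' @param n_max Per-group search ceiling (default 10000).
#' @return A `rehab_sample_size` list: `n_per_group`, `N`,
#'   `achieved_power`, the `spec`, and the noncentrality convention used.
#' @export
solve_sample_size <- function(spec, n_max = 1e4) {
  stopifnot(inherits(spec, "rehab_power_spec"))
  for (n in 2:n_max) {
    N <- n * spec$k
    pw <- power_rm_between(spec, N)
    if (pw >= spec$power) {
      return(structure(
        list(n_per_group = n, N = N, achieved_power = pw, spec = spec,
             convention = "lambda = f^2 * N * m / (1 + (m-1) rho); df2 = N - k"),
        class = "rehab_sample_size"))
    }
  }
  stop_rehab("no sample size below the search ceiling reaches the target power",
             "rehabpose_parameter_error")
}

#' @export
print.rehab_sample_size <- function(x, ...) {
  cat(sprintf("minimum n = %d per group (N = %d), achieved power %.3f\n",
              x$n_per_group, x$N, x$achieved_power))
  invisible(x)
}

#' Inflate a per-group sample size for expected dropout
#'
#' `ceiling(n * (1 + rate))`.
#'
#' @param n Per-group size (>= 1).
#' @param rate Expected dropout fraction in \[0, 1).
#' @return Inflated per-group size.
#' @export
#' @examples
#' inflate_dropout(17, 0.20)  # 21
inflate_dropout <- function(n, rate) {
  check_number(n, "n", lo = 1)
  check_number(rate, "rate", lo = 0, hi = 1 - 1e-12)
  ceiling(n * (1 + rate))
}
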