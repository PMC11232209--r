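test_that("the K-S statistic equals a brute-force ECDF supremum", {
  set.seed(8)
  x <- rnorm(10, 5, 2)
  rep <- ks_normality(x, mc_reps = 200, seed = 1)
  # independent oracle: scan |ECDF - fitted normal CDF| just before and at
  # every jump of the empirical CDF
  xs <- sort(x)
  mu <- mean(x); s <- sd(x)
  sup <- max(vapply(seq_along(xs), function(i) {
    Fx <- pnorm(xs[i], mu, s)
    max(abs(i / 10 - Fx), abs((i - 1) / 10 - Fx))
  }, numeric(1)))
  expect_equal(rep$statistic, sup, tolerance = 1e-12)
})

test_that("the K-S statistic matches the Lilliefors reference implementation", {
  skip_if_not_installed("nortest")
  set.seed(9)
  for (n in c(20, 57)) {
    x <- rexp(n)
    expect_equal(ks_normality(x, mc_reps = 50, seed = 1)$statistic,
                 unname(nortest::lillie.test(x)$statistic), tolerance = 1e-12)
  }
})

test_that("Monte-Carlo p-values track the Lilliefors reference and reject at the nominal rate", {
  skip_if_not_installed("nortest")
  set.seed(31)
  for (i in 1:3) {
    x <- rnorm(80)
    expect_lt(abs(ks_normality(x, seed = 2, mc_reps = 4000)$p_value -
                    min(1, nortest::lillie.test(x)$p.value)), 0.05)
  }
  y <- rexp(80)
  expect_lt(ks_normality(y, seed = 2, mc_reps = 1000)$p_value, 0.05)
  expect_lt(nortest::lillie.test(y)$p.value, 0.05)
  # size calibration: normal data rejected at about alpha = 0.05
  set.seed(17)
  rejections <- sum(vapply(1:200, function(i) {
    ks_normality(rnorm(50), seed = i, mc_reps = 400)$p_value < 0.05
  }, logical(1)))
  expect_gte(rejections / 200, 0.01)
  expect_lte(rejections / 200, 0.10)
})

test_that("log-normal samples trigger the transform policy and pass after transform", {
  set.seed(33)
  y <- exp(rnorm(100, sd = 1.2))
  repy <- ks_normality(y, seed = 2, mc_reps = 2000)
  expect_lt(repy$p_value, 0.05)
  expect_true(repy$transform_recommended)
  repl <- ks_normality(log_transform(y), seed = 2, mc_reps = 2000)
  expect_gt(repl$p_value, 0.05)
  expect_false(repl$transform_recommended)
  expect_error(log_transform(c(1, 0, 2)), class = "rehabpose_transform_error")
  expect_error(ks_normality(c(1, 2, 3)), class = "rehabpose_parameter_error")
})

test_that("one-way ANOVA matches hand- and matrix-computed sums of squares", {
  expect_equal(oneway_anova(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))$F, 0)
  out <- oneway_anova(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6)))
  expect_equal(out$F, 13.5)
  expect_equal(out$df1, 1)
  expect_equal(out$df2, 4)
  set.seed(12)
  d <- tibble(value = rnorm(60), group = rep(letters[1:3], each = 20))
  got <- oneway_anova(d)
  # independent matrix-algebra oracle: projection onto group indicators
  X <- model.matrix(~ 0 + factor(d$group))
  P <- X %*% solve(crossprod(X)) %*% t(X)
  yc <- d$value - mean(d$value)
  ssb <- sum((P %*% yc)^2)
  ssw <- sum((yc - P %*% yc)^2)
  expect_equal(got$F, (ssb / 2) / (ssw / 57), tolerance = 1e-9)
  expect_error(oneway_anova(list(a = 1, b = c(1, 2))),
               class = "rehabpose_degeneracy_error")
})

test_that("partial eta-squared reproduces the trial's printed effect sizes", {
  expect_equal(partial_eta_from_f(6.219, 4, 134, digits = 3), 0.157)
  expect_equal(partial_eta_from_f(0.537, 4, 134, digits = 3), 0.016)
  expect_equal(partial_eta_from_f(0.304, 4, 134, digits = 3), 0.009)
  expect_equal(partial_eta_from_f(0.107, 4, 134, digits = 3), 0.003)
  expect_equal(partial_eta_from_f(0, 4, 134), 0)
})

make_trial <- function(seed = 42, sizes = c(10, 10, 10)) {
  spec <- cohort_spec(
    group_sizes = sizes, time_effects = c(0, 0.3, 0.6),
    interaction = matrix(c(0, 0, 0, 0, 0.2, 0.4, 0, -0.2, -0.4), 3, 3, byrow = TRUE))
  generate_cohort(spec, seed = seed)
}

test_that("the univariate RM-ANOVA path matches the aov error-stratum oracle", {
  d <- make_trial()
  fit <- rm_anova(d, "outcome")
  expect_equal(fit$path, "sphericity_assumed")
  dd <- d |> mutate(subject = factor(subject))
  a <- summary(stats::aov(value ~ group * time + Error(subject / time), data = dd))
  btab <- a$`Error: subject`[[1]]
  wtab <- a$`Error: subject:time`[[1]]
  eff <- tidy(fit)
  expect_equal(eff$F[eff$effect == "group"], btab$`F value`[1], tolerance = 1e-9)
  expect_equal(eff$F[eff$effect == "time"], wtab$`F value`[1], tolerance = 1e-9)
  expect_equal(eff$F[eff$effect == "group:time"], wtab$`F value`[2], tolerance = 1e-9)
  expect_equal(eff$p[eff$effect == "group:time"], wtab$`Pr(>F)`[2], tolerance = 1e-9)
  expect_equal(eff$df1, c(2, 2, 4))
  expect_equal(eff$df2, c(27, 54, 54))
})

test_that("Mauchly and the Pillai fallback match the multivariate lm oracle", {
  d <- make_trial(seed = 77)
  w <- d |> tidyr::pivot_wider(id_cols = c(subject, group),
                               names_from = time, values_from = value)
  Y <- as.matrix(w[, c("pre", "mid", "post")])
  ml <- stats::lm(Y ~ group, data = w)
  idata <- data.frame(time = factor(c("pre", "mid", "post"),
                                    levels = c("pre", "mid", "post")))
  mt <- stats::mauchly.test(ml, M = ~time, X = ~1, idata = idata)
  fit <- rm_anova(d, "outcome")
  expect_equal(fit$mauchly$W, unname(mt$statistic), tolerance = 1e-9)
  expect_equal(fit$mauchly$p, mt$p.value, tolerance = 1e-9)
  # force the multivariate path and compare Pillai F approximations
  fit2 <- rm_anova(d, "outcome", sphericity_alpha = 1)
  pt <- stats::anova(ml, M = ~time, X = ~1, idata = idata, test = "Pillai")
  eff <- tidy(fit2)
  i_time <- which(rownames(pt) == "(Intercept)")
  i_int <- which(rownames(pt) == "group")
  expect_equal(eff$F[eff$effect == "time"], pt$`approx F`[i_time], tolerance = 1e-9)
  expect_equal(eff$F[eff$effect == "group:time"], pt$`approx F`[i_int], tolerance = 1e-9)
  expect_equal(eff$p[eff$effect == "group:time"], pt$`Pr(>F)`[i_int], tolerance = 1e-9)
  expect_equal(eff$df1[eff$effect == "group:time"], pt$`num Df`[i_int])
  expect_equal(eff$df2[eff$effect == "group:time"], pt$`den Df`[i_int])
})

test_that("an AR(1)-violated covariance routes inference through Pillai's trace", {
  # strong AR(1) with heterogeneous variances breaks sphericity
  set.seed(5)
  n <- 40; m <- 3
  L <- chol(outer(1:m, 1:m, function(i, j) 0.9^abs(i - j)) * outer(c(1, 2, 4), c(1, 2, 4)))
  Y <- matrix(rnorm(n * m), n, m) %*% L
  d <- tibble(subject = rep(sprintf("s%02d", 1:n), each = m),
              group = rep(rep(c("a", "b"), each = n / 2 * m), length.out = n * m),
              time = factor(rep(c("pre", "mid", "post"), n),
                            levels = c("pre", "mid", "post")),
              measure = "outcome", value = as.vector(t(Y)))
  fit <- rm_anova(d, "outcome")
  expect_lt(fit$mauchly$p, 0.05)
  expect_equal(fit$path, "pillai_trace")
  eff <- tidy(fit)
  expect_equal(unique(eff$path[eff$effect != "group"]), "pillai_trace")
  expect_equal(eff$path[eff$effect == "group"], "univariate")
})

test_that("partial eta-squared is internally consistent for every effect and path", {
  for (seed in c(42, 77)) {
    for (al in c(0.05, 1)) {
      eff <- tidy(rm_anova(make_trial(seed = seed), "outcome", sphericity_alpha = al))
      expect_equal(eff$partial_eta_sq,
                   eff$F * eff$df1 / (eff$F * eff$df1 + eff$df2), tolerance = 1e-6)
    }
  }
})

test_that("degenerate designs are handled: zero interaction, dropouts, few timepoints", {
  # identical group profiles with pure subject offsets: interaction F = 0
  d0 <- tidyr::expand_grid(subject = sprintf("s%02d", 1:12),
                           time = factor(c("pre", "mid", "post"),
                                         levels = c("pre", "mid", "post"))) |>
    mutate(group = c("a", "b", "c")[(match(subject, unique(subject)) - 1) %/% 4 + 1],
           measure = "outcome",
           value = as.numeric(factor(time, levels = levels(time))) +
             0.5 * match(subject, unique(subject)))
  fit0 <- rm_anova(d0, "outcome")
  eff0 <- tidy(fit0)
  expect_equal(eff0$F[eff0$effect == "group:time"], 0)
  expect_equal(eff0$partial_eta_sq[eff0$effect == "group:time"], 0)
  # incomplete subjects are dropped listwise with a warning
  d <- make_trial()
  d_miss <- d |> filter(!(subject == "s001" & time == "post"))
  expect_warning(fit <- rm_anova(d_miss, "outcome"), "dropped")
  expect_equal(fit$n, 29)
  # single timepoint is a design error
  d1 <- d |> filter(time == "pre")
  expect_error(rm_anova(d1, "outcome"), class = "rehabpose_design_error")
})

test_that("pairwise differences reduce to exact t intervals on subcases", {
  # paired subcase: one group, the within contrast equals a paired t test
  spec1 <- cohort_spec(group_sizes = 12, time_effects = c(0, 0.5, 1),
                       interaction = matrix(0, 1, 3))
  d1 <- generate_cohort(spec1, seed = 3)
  pw <- pairwise_differences(d1, "outcome")
  w <- d1 |> tidyr::pivot_wider(id_cols = subject, names_from = time,
                                values_from = value)
  tt <- t.test(w$mid, w$pre, paired = TRUE)
  row <- pw |> filter(type == "within", lhs == "mid", rhs == "pre")
  expect_equal(row$difference, unname(tt$estimate), tolerance = 1e-9)
  expect_equal(c(row$lower, row$upper), as.vector(tt$conf.int), tolerance = 1e-9)
  expect_equal(row$p, tt$p.value, tolerance = 1e-9)
  # independent subcase: two groups at one timepoint equal a pooled t test
  spec2 <- cohort_spec(group_sizes = c(9, 14), group_effects = c(0, 0.4),
                       interaction = matrix(0, 2, 3))
  d2 <- generate_cohort(spec2, seed = 4)
  pw2 <- pairwise_differences(d2, "outcome")
  w2 <- d2 |> tidyr::pivot_wider(id_cols = c(subject, group),
                                 names_from = time, values_from = value)
  tt2 <- t.test(w2$post[w2$group == "group_1"], w2$post[w2$group == "group_2"],
                var.equal = TRUE)
  row2 <- pw2 |> filter(type == "between", context == "post")
  expect_equal(row2$difference, unname(diff(rev(tt2$estimate))), tolerance = 1e-9)
  expect_equal(c(row2$lower, row2$upper), as.vector(tt2$conf.int), tolerance = 1e-9)
  expect_equal(row2$p, tt2$p.value, tolerance = 1e-9)
})

test_that("identical groups give zero differences with symmetric intervals", {
  d <- tidyr::expand_grid(subject = sprintf("s%02d", 1:9),
                          time = factor(c("pre", "mid", "post"),
                                        levels = c("pre", "mid", "post"))) |>
    mutate(group = rep(c("a", "b", "c"), 9)[match(subject, unique(subject))],
           measure = "outcome",
           value = rep(c(1, 2, 3), 9))  # same profile for everyone
  pw <- pairwise_differences(d, "outcome")
  between <- pw |> filter(type == "between")
  expect_true(all(between$difference == 0))
  expect_equal(between$lower, -between$upper)
})

test_that("bonferroni adjustment widens intervals and inflates p-values", {
  d <- make_trial()
  lsd <- pairwise_differences(d, "outcome", adjust = "none")
  bon <- pairwise_differences(d, "outcome", adjust = "bonferroni")
  expect_true(all(bon$p >= lsd$p - 1e-12))
  expect_true(all(bon$upper - bon$lower > lsd$upper - lsd$lower - 1e-12))
})

test_that("pairwise post-contrast coverage attains its nominal level", {
  delta <- 0.6
  spec <- cohort_spec(group_sizes = c(10, 10),
                      interaction = matrix(c(0, 0, 0, 0, 0, delta), 2, 3,
                                           byrow = TRUE))
  hits <- 0
  for (i in 1:500) {
    d <- generate_cohort(spec, seed = 1000 + i)
    pw <- pairwise_differences(d, "outcome") |>
      filter(type == "between", context == "post")
    true_diff <- -delta  # group_1 - group_2 at post
    if (pw$lower <= true_diff && true_diff <= pw$upper) hits <- hits + 1
  }
  expect_gte(hits / 500, 0.93)
})

test_that("noncentral-F power behaves at its analytic limits and monotonically", {
  sp <- power_spec(f = 5, alpha = 0.05, power = 0.9, k = 3, m = 3, rho = 0.5)
  expect_gt(power_rm_between(sp, 6), 0.999)
  sp0 <- power_spec(f = 1e-9, alpha = 0.05, power = 0.9, k = 3, m = 3, rho = 0.5)
  expect_equal(power_rm_between(sp0, 30), 0.05, tolerance = 1e-4)
  # monotone in f and N
  pws <- sapply(c(0.1, 0.2, 0.4), function(f)
    power_rm_between(power_spec(f = f), 45))
  expect_true(all(diff(pws) > 0))
  pwN <- sapply(c(30, 45, 60), function(N) power_rm_between(power_spec(), N))
  expect_true(all(diff(pwN) > 0))
  # the repeated-measures multiplier m/(1+(m-1)rho) = 1.5 exactly at m=3, rho=0.5
  N <- 45
  direct <- pf(qf(0.95, 2, N - 3), 2, N - 3, ncp = 0.4^2 * N * 1.5,
               lower.tail = FALSE)
  expect_equal(power_rm_between(power_spec(), N), direct, tolerance = 1e-12)
  oneway <- pf(qf(0.95, 2, N - 3), 2, N - 3, ncp = 0.4^2 * N, lower.tail = FALSE)
  expect_equal(power_rm_between(power_spec(design = "oneway"), N), oneway,
               tolerance = 1e-12)
})

test_that("the sample-size solver meets the trial's planning chain", {
  sol <- solve_sample_size(power_spec(f = 0.4, alpha = 0.05, power = 0.90,
                                      k = 3, m = 3, rho = 0.5))
  expect_gte(sol$n_per_group, 17)
  expect_gte(sol$achieved_power, 0.90)
  # one per-group step below the solution the target power is not reached
  expect_lt(power_rm_between(sol$spec, sol$N - 3), 0.90)
  # a lower target needs fewer subjects
  sol50 <- solve_sample_size(power_spec(f = 0.4, alpha = 0.05, power = 0.50,
                                        k = 3, m = 3, rho = 0.5))
  expect_lt(sol50$n_per_group, sol$n_per_group)
  # the repeated-measures design needs fewer subjects than one-way at rho = 0.5
  sol1 <- solve_sample_size(power_spec(f = 0.4, alpha = 0.05, power = 0.90,
                                       k = 3, design = "oneway"))
  expect_gt(sol1$n_per_group, sol$n_per_group)
})

test_that("dropout inflation rounds up from the planned minimum", {
  expect_equal(inflate_dropout(17, 0.20), 21)
  expect_equal(inflate_dropout(10, 0), 10)
  expect_equal(inflate_dropout(10, 0.25), 13)  # ceil(12.5)
  expect_error(inflate_dropout(17, 1), class = "rehabpose_parameter_error")
})

test_that("power specs validate their parameter ranges", {
  expect_error(power_spec(f = 0), class = "rehabpose_parameter_error")
  expect_error(power_spec(alpha = 0), class = "rehabpose_parameter_error")
  expect_error(power_spec(rho = 1.2), class = "rehabpose_parameter_error")
  expect_error(power_spec(k = 1), class = "rehabpose_parameter_error")
  expect_error(power_rm_between(power_spec(), 3), class = "rehabpose_parameter_error")
})
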