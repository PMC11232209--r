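#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the effect table of a mixed RM-ANOVA
#'
#' @param x A [rm_anova()] result.
#' @param ... Unused.
#' @return Tibble with one row per effect: `effect`, `F`, `df1`, `df2`,
#'   `p`, `partial_eta_sq`, `path`.
#' @method tidy rehab_rm_anova
#' @export
tidy.rehab_rm_anova <- function(x, ...) {
  x$effects
}

#' One-row summary of a mixed RM-ANOVA
#'
#' @param x A [rm_anova()] result.
#' @param ... Unused.
#' @return One-row tibble: design shape, Mauchly statistics, reporting
#'   path, subjects dropped.
#' @method glance rehab_rm_anova
#' @export
glance.rehab_rm_anova <- function(x, ...) {
  tibble(measure = x$measure, n = x$n, k = x$k, m = x$m,
         mauchly_w = x$mauchly$W, mauchly_p = x$mauchly$p,
         path = x$path, dropped = x$dropped)
}

#' @method tidy rehab_ks
#' @export
tidy.rehab_ks <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, n = x$n,
         transform_recommended = x$transform_recommended)
}

#' @method tidy rehab_session_report
#' @export
tidy.rehab_session_report <- function(x, ...) {
  x$findings
}

#' @method glance rehab_session_report
#' @export
glance.rehab_session_report <- function(x, ...) {
  tibble(overall = x$overall, segments = nrow(x$segments),
         findings = nrow(x$findings))
}

#' @method tidy rehab_sample_size
#' @export
tidy.rehab_sample_size <- function(x, ...) {
  tibble(n_per_group = x$n_per_group, N = x$N,
         achieved_power = x$achieved_power,
         f = x$spec$f, alpha = x$spec$alpha, target_power = x$spec$power,
         k = x$spec$k, m = x$spec$m, rho = x$spec$rho, design = x$spec$design)
}
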