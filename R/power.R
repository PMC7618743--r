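#' Required sample size for a pairwise comparison
#'
#' Per-group n for a two-sided two-sample t-test detecting a
#' standardised effect of Cohen's f (d = 2f for two equal groups),
#' solved through the noncentral-t power equation, then inflated for
#' anticipated non-compliance and expanded to the trial's allocation
#' ratio (control : interventions).
#'
#' @param f Cohen's f effect size (> 0).
#' @param power target power in (0, 1).
#' @param alpha two-sided significance level in (0, 1).
#' @param noncompliance_rate anticipated non-compliance fraction; group
#'   sizes are inflated by `1 / (1 - rate)`.
#' @param allocation randomisation ratio, control first (default
#'   1:5:5:5:5).
#' @return list with `n_per_group` (uninflated, per comparison group),
#'   `n_per_group_inflated`, `n_control`, `n_total`.
#' @export
#' @examples
#' required_sample_size(f = 0.1)$n_per_group # 527
required_sample_size <- function(f, power = 0.9, alpha = 0.05,
                                 noncompliance_rate = 0.2,
                                 allocation = c(1, 5, 5, 5, 5)) {
  if (!is.numeric(f) || f <= 0) abort("f must be > 0")
  if (!is_prob(power) || power <= 0 || power >= 1) abort("power must be in (0, 1)")
  if (!is_prob(alpha) || alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (!is_prob(noncompliance_rate) || noncompliance_rate >= 1)
    abort("noncompliance_rate must be in [0, 1)")
  if (length(allocation) < 2 || any(allocation <= 0))
    abort("allocation needs a control weight and >= 1 intervention weights")
  n <- power.t.test(delta = 2 * f, sd = 1, sig.level = alpha,
                    power = power, type = "two.sample",
                    alternative = "two.sided")$n
  n_group <- ceiling(n)
  n_infl <- ceiling(n_group / (1 - noncompliance_rate))
  plan <- plan_allocation(n_infl, allocation)
  list(n_per_group = n_group, n_per_group_inflated = n_infl,
       n_control = plan$n_control, n_total = plan$n_total)
}

#' Expand a per-intervention-group size to the full allocation
#'
#' Given the planned size of each (equal) intervention group and the
#' randomisation ratio, returns the control group size (scaled by the
#' ratio, rounded up) and the study total.
#'
#' @param n_intervention planned participants per intervention group.
#' @param allocation randomisation ratio, control first.
#' @return list with `n_control`, `n_intervention`,
#'   `n_intervention_groups`, `n_total`.
#' @export
#' @examples
#' plan_allocation(633) # control 127, total 2659
plan_allocation <- function(n_intervention, allocation = c(1, 5, 5, 5, 5)) {
  if (!is_count(n_intervention) || n_intervention < 1)
    abort("n_intervention must be a positive count")
  k <- length(allocation) - 1L
  n_control <- ceiling(n_intervention * allocation[1] / allocation[2])
  list(n_control = n_control, n_intervention = n_intervention,
       n_intervention_groups = k,
       n_total = n_control + k * n_intervention)
}
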