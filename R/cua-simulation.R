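# Ten-year two-arm cost-utility simulation. A hypothetical treatment applied
# to the lower utility tertile closes a configurable fraction of each
# patient's gap to the target utility (the middle-tertile mean), ramping
# linearly over the first year; both arms age at a fixed annual utility
# decrement, annual utilities are discounted, and QALYs accumulate over the
# horizon. Willingness-to-pay tables convert QALY gains into the maximum
# constant annual treatment cost at a given cost-effectiveness threshold.

#' Simulation configuration
#'
#' @param horizon_years simulation horizon (years, default 10).
#' @param discount_rate annual discount rate applied to utilities and costs
#'   (default 0.035, the health-technology-assessment reference rate).
#' @param attainment fraction of each patient's potential improvement reached
#'   by the end of year 1 (base case 0.75).
#' @param sensitivity_grid attainment fractions for sensitivity analysis.
#' @param target_utility utility the treatment moves patients toward
#'   (default 0.745, the observed middle-tertile mean).
#' @param aging_decrement utility lost per year of ageing in both arms
#'   (default 0.005, the observed utility-on-age regression slope magnitude).
#' @param utility_bounds interval utilities are clamped to during
#'   trajectories; defaults to the England value-set range `[-0.285, 1]`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(horizon_years = 10L, discount_rate = 0.035,
                       attainment = 0.75,
                       sensitivity_grid = c(0.55, 0.65, 0.75, 0.85, 0.95),
                       target_utility = 0.745, aging_decrement = 0.005,
                       utility_bounds = c(-0.285, 1)) {
  stopifnot(horizon_years >= 1, discount_rate >= 0, discount_rate < 1,
            attainment > 0, attainment <= 1,
            all(sensitivity_grid > 0), all(sensitivity_grid <= 1),
            length(utility_bounds) == 2, utility_bounds[1] < utility_bounds[2])
  if (target_utility < utility_bounds[1] || target_utility > utility_bounds[2]) {
    stop("target utility must lie within the utility bounds")
  }
  structure(list(
    horizon_years = as.integer(horizon_years), discount_rate = discount_rate,
    attainment = attainment, sensitivity_grid = sensitivity_grid,
    target_utility = target_utility, aging_decrement = aging_decrement,
    utility_bounds = utility_bounds
  ), class = "sim_config")
}

#' Annuity (discount) factor
#'
#' Sum of discount weights over annual cycles `t = 0, ..., years - 1`, the
#' first cycle undiscounted: `sum((1 + rate)^-t)`.
#'
#' @param rate annual discount rate in `[0, 1)`.
#' @param years number of annual cycles, at least 1.
#' @return The annuity factor; equals `years` when `rate = 0`.
#' @examples
#' annuity_factor(0.035, 10)  # 8.60769
#' @export
annuity_factor <- function(rate, years) {
  stopifnot(years >= 1, rate >= 0, rate < 1)
  if (rate == 0) return(as.numeric(years))
  v <- 1 / (1 + rate)
  (1 - v^years) / (1 - v)
}

#' Potential improvement of a patient
#'
#' The gap between baseline utility and the target utility, floored at zero:
#' patients already at or above the target have nothing to gain.
#'
#' @param u0 baseline utility (vectorised).
#' @param target target utility.
#' @return `pmax(0, target - u0)`.
#' @export
potential_improvement <- function(u0, target) {
  pmax(0, target - u0)
}

# per-cycle discount weights and clamped control-arm utility path
.disc_weights <- function(cfg) (1 + cfg$discount_rate)^-(0:(cfg$horizon_years - 1))

.clamp <- function(u, bounds) pmin(pmax(u, bounds[1]), bounds[2])

#' Discounted QALYs for one patient
#'
#' Control arm: utility starts at `u0` and declines by the ageing decrement
#' each year, clamped to the utility bounds; annual utilities are discounted
#' and summed over the horizon. Treatment arm: the same trajectory plus the
#' treatment effect, which ramps linearly from 0 to `attainment x potential
#' improvement` over the first year (contributing half the full effect in
#' cycle 0) and stays at the full effect thereafter.
#'
#' @param u0 baseline utility (vectorised).
#' @param arm `"treatment"` or `"control"`.
#' @param cfg a [sim_config()].
#' @return Discounted QALY total(s) over the horizon.
#' @export
person_qalys <- function(u0, arm = c("treatment", "control"), cfg = sim_config()) {
  arm <- match.arg(arm)
  if (any(u0 < cfg$utility_bounds[1] - 1e-12 | u0 > cfg$utility_bounds[2] + 1e-12)) {
    stop("baseline utility outside the configured bounds")
  }
  w <- .disc_weights(cfg)
  t <- 0:(cfg$horizon_years - 1)
  base <- outer(u0, t, function(u, tt) u - cfg$aging_decrement * tt)
  base <- .clamp(base, cfg$utility_bounds)
  qaly <- as.numeric(base %*% w)
  if (arm == "treatment") {
    delta <- cfg$attainment * potential_improvement(u0, cfg$target_utility)
    effect <- c(0.5, rep(1, cfg$horizon_years - 1))  # linear first-year ramp
    qaly <- qaly + delta * sum(effect * w)
  }
  qaly
}

#' Run the two-arm QALY simulation on a treatment group
#'
#' Computes per-person treated and untreated discounted QALYs and their
#' difference (the QALY gain), plus aggregates: arm totals and means, mean
#' gain, the gain SD, and the dispersion interval `mean +/- 1.96 SD` as
#' reported alongside the study's mean gain.
#'
#' @param patients cohort data frame (typically the lower tertile) with a
#'   `utility` column, or a bare numeric vector of baseline utilities.
#' @param cfg a [sim_config()].
#' @return List of class `cua_result` with `per_person` (data frame) and
#'   `aggregate` (list).
#' @examples
#' res <- simulate_cua(rep(0.3386, 15))
#' res$aggregate$total_untreated  # about 41 QALYs
#' @export
simulate_cua <- function(patients, cfg = sim_config()) {
  u0 <- if (is.numeric(patients)) patients else patients$utility
  id <- if (is.numeric(patients)) as.character(seq_along(u0)) else patients$id
  if (length(u0) == 0) stop("treatment group is empty")
  treated <- person_qalys(u0, "treatment", cfg)
  untreated <- person_qalys(u0, "control", cfg)
  gain <- treated - untreated
  per_person <- data.frame(
    id = id, baseline_utility = u0,
    potential_improvement = potential_improvement(u0, cfg$target_utility),
    qalys_treated = treated, qalys_untreated = untreated, qaly_gain = gain,
    stringsAsFactors = FALSE
  )
  n <- length(u0)
  sd_gain <- if (n > 1) stats::sd(gain) else 0
  aggregate <- list(
    n = n,
    total_treated = sum(treated), total_untreated = sum(untreated),
    mean_treated = mean(treated), mean_untreated = mean(untreated),
    mean_gain = mean(gain), sd_gain = sd_gain,
    interval95 = mean(gain) + c(-1, 1) * 1.96 * sd_gain
  )
  structure(list(per_person = per_person, aggregate = aggregate, config = cfg),
            class = "cua_result")
}

#' @export
print.cua_result <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("Cost-utility simulation over %d years (n = %d, attainment %.0f%%)\n",
              x$config$horizon_years, a$n, 100 * x$config$attainment))
  cat(sprintf("  treated:   %.1f QALYs total (%.2f per person)\n",
              a$total_treated, a$mean_treated))
  cat(sprintf("  untreated: %.1f QALYs total (%.2f per person)\n",
              a$total_untreated, a$mean_untreated))
  cat(sprintf("  gain: %.2f QALYs per person (SD %.2f, interval %.2f to %.2f)\n",
              a$mean_gain, a$sd_gain, a$interval95[1], a$interval95[2]))
  invisible(x)
}

#' Mean QALY gain across attainment fractions
#'
#' Reruns [simulate_cua()] at each attainment in the grid. Absent clamping,
#' the gain is exactly proportional to the attainment fraction.
#'
#' @param patients treatment group (see [simulate_cua()]).
#' @param cfg a [sim_config()].
#' @param grid attainment fractions; defaults to `cfg$sensitivity_grid`.
#' @return Data frame with columns `attainment` and `mean_gain`.
#' @export
sensitivity_gains <- function(patients, cfg = sim_config(),
                              grid = cfg$sensitivity_grid) {
  stopifnot(length(grid) >= 1)
  gains <- vapply(grid, function(a) {
    cfg_a <- cfg
    cfg_a$attainment <- a
    simulate_cua(patients, cfg_a)$aggregate$mean_gain
  }, numeric(1))
  data.frame(attainment = grid, mean_gain = gains)
}

#' Maximum cost-effective annual treatment cost
#'
#' The constant annual cost whose discounted 10-year total, divided by the
#' QALY gain, equals the willingness-to-pay threshold:
#' `threshold x gain / annuity_factor(rate, horizon)`. Rounding to whole
#' currency units is left to presentation.
#'
#' @param threshold willingness-to-pay threshold (currency per QALY).
#' @param gain per-person QALY gain over the horizon.
#' @param cfg a [sim_config()].
#' @return Maximum annual cost (currency per year).
#' @examples
#' round(wtp_annual(50000, 2.4712))  # 14355
#' @export
wtp_annual <- function(threshold, gain, cfg = sim_config()) {
  stopifnot(all(threshold >= 0), all(gain >= 0))
  threshold * gain / annuity_factor(cfg$discount_rate, cfg$horizon_years)
}

#' Willingness-to-pay table over thresholds and attainments
#'
#' Grid of maximum cost-effective annual treatment costs: thresholds in rows,
#' attainment fractions (through their simulated QALY gains) in columns.
#' Cells are exact; the print method rounds to whole currency units.
#'
#' @param gains data frame `attainment, mean_gain` from [sensitivity_gains()],
#'   or a named numeric vector of gains.
#' @param thresholds willingness-to-pay thresholds (currency per QALY).
#' @param cfg a [sim_config()].
#' @return Numeric matrix of class `wtp_table`.
#' @export
build_wtp_table <- function(gains, thresholds = seq(20000, 100000, by = 10000),
                            cfg = sim_config()) {
  if (is.data.frame(gains)) {
    g <- setNames(gains$mean_gain, sprintf("%.0f%%", 100 * gains$attainment))
  } else {
    g <- gains
    if (is.null(names(g))) names(g) <- sprintf("gain%d", seq_along(g))
  }
  if (any(g <= 0)) stop("QALY gains must be positive to price a treatment")
  cells <- outer(thresholds, g, function(th, gg) wtp_annual(th, gg, cfg))
  dimnames(cells) <- list(format(thresholds, scientific = FALSE, trim = TRUE),
                          names(g))
  structure(cells, class = c("wtp_table", "matrix"), thresholds = thresholds)
}

#' @export
print.wtp_table <- function(x, ...) {
  cat("Maximum annual treatment cost to be cost-effective\n")
  cat("(thresholds per QALY in rows; attainment fraction in columns)\n")
  m <- round(unclass(x))
  attr(m, "thresholds") <- NULL
  print(m)
  invisible(x)
}

#' Empirical middle-tertile mean utility
#'
#' Helper reproducing the original target-setting procedure on user data:
#' the mean utility of the middle tertile of a group. The packaged default
#' target (0.745) is a fixed constant; use this to derive a target from your
#' own cohort instead.
#'
#' @param patients cohort data frame with `utility` and `id`.
#' @return Mean utility of the middle tertile.
#' @export
middle_tertile_target <- function(patients) {
  mean(split_tertiles(patients)$middle$utility)
}
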