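# Behavioral probes that recover the pipeline's decision constants from the
# outside: each constant is measured by bisecting the input at which the
# corresponding public function changes behavior, never by reading a default.

.bisect <- function(f, lo, hi, iter = 60) {
  flo <- f(lo)
  if (f(hi) == flo) stop("probe bisection: no behavior change in [lo, hi]")
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) == flo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

.probe_shells <- function(isig2, compl2) {
  data.table::data.table(shell = 1:2, d_max = c(3.9, 3.0),
                         d_min = c(3.0, 2.5),
                         mean_i_over_sigma = c(20, isig2),
                         completeness = c(99, compl2))
}

# flat calibration table whose Wilson fit is exact (all intensities equal)
.probe_wilson_table <- function() {
  cell <- unit_cell(10, 11, 12)
  uniq <- enumerate_unique(cell, sym_group("P1"), d_min = 2.5)
  list(cell = cell,
       table = reflection_table(uniq$h, uniq$k, uniq$l,
                                intensity = 1000, sigma = 10))
}

# Friedel-separate table whose every pair has amplitude difference x and an
# exactly computable sigma(d'')
.probe_anom_table <- function(x, f0 = 100, sigma_i = 200) {
  cell <- unit_cell(12, 13, 14)
  uniq <- utils::head(enumerate_unique(cell, sym_group("P1"), d_min = 4), 25)
  n <- nrow(uniq)
  reflection_table(h = c(uniq$h, -uniq$h), k = c(uniq$k, -uniq$k),
                   l = c(uniq$l, -uniq$l),
                   intensity = c(rep((f0 + x / 2)^2, n),
                                 rep((f0 - x / 2)^2, n)),
                   sigma = sigma_i)
}

#' Measure the pipeline's decision constants behaviorally
#'
#' Recovers every decision constant by probing the public functions from the
#' outside: the I/sigma retention cutoff and completeness branch threshold
#' by bisecting synthetic shell tables fed to
#' [determine_resolution_limit()], the Wilson rejection threshold by
#' bisecting a probe reflection against an exactly calibrated flat fit, the
#' anomalous trigger level by bisecting constructed Friedel differences, the
#' assumed solvent fraction by inverting the default MW estimate, the
#' success-flag thresholds by bisecting [assess_solution()], and the wedge
#' geometry constants from emitted [plan_spot_wedges()] plans.
#'
#' @param seed seed for the (deterministic) probes, kept for interface
#'   symmetry with stochastic checks
#' @return named list `t1` .. `t11`:
#'   `t1` I/sigma cutoff, `t2` completeness cutoff (%), `t3` Wilson Z
#'   threshold, `t4` anomalous trigger level, `t5` assumed solvent content
#'   (%), `t6` SAD trial count, `t7` success CC threshold (%), `t8` success
#'   fragment-length threshold (residues), `t9` ideal wedge separation
#'   (deg), `t10` separation fallback decrement (deg), `t11` initial spot
#'   wedge width (images)
#' @export
probe_decision_constants <- function(seed = 1L) {
  set.seed(seed)
  out <- list()

  # t1: largest shell I/sigma at which the loop stops retaining the shell
  out$t1 <- .bisect(function(v)
    determine_resolution_limit(.probe_shells(v, 99))$rule == "all_retained",
    lo = 0.2, hi = 19)

  # t2: completeness at which the failing shell switches branch
  out$t2 <- .bisect(function(cc)
    determine_resolution_limit(.probe_shells(1, cc))$rule == "interpolated",
    lo = 1, hi = 99.5)

  # t3: probe intensity (in units of the Wilson mean) at which rejection fires
  pw <- .probe_wilson_table()
  fit <- fit_wilson(pw$table, pw$cell, n_shells = 5)
  out$t3 <- .bisect(function(v) {
    probe <- rbind(pw$table,
                   reflection_table(1, 0, 0, intensity = v * 1000, sigma = 10))
    reject_wilson_outliers(probe, fit, pw$cell)$n_rejected > 0
  }, lo = 1.5, hi = 50)

  # t4: shell <d''/sigma(d'')> at which the trigger fires, read off the
  # summary at the bisected flip point
  cell_anom <- unit_cell(12, 13, 14)
  trig <- function(x) anomalous_signal(.probe_anom_table(x), cell_anom,
                                       sym_group("P1"), n_shells = 2)
  x_flip <- .bisect(function(x) trig(x)$trigger, lo = 0.05, hi = 20)
  out$t4 <- max(trig(x_flip)$shells$danom_over_sigma, na.rm = TRUE)

  # t5: solvent fraction assumed by the default MW estimate, inverted
  # through the Matthews-style relation (%)
  cell <- unit_cell(40, 50, 60)
  g <- sym_group("P212121")
  mw <- estimate_mw(cell, g)
  out$t5 <- 100 * (1 - mw * length(g$rotations) * 1.23 / cell_volume(cell))

  # t6: number of SAD trials actually planned
  out$t6 <- nrow(build_trial_plan(cell, g)$trials)

  # t7/t8: success-flag thresholds
  out$t7 <- .bisect(function(cc) assess_solution(cc, 15)$success,
                    lo = 0, hi = 100)
  out$t8 <- .bisect(function(fl) assess_solution(50, fl)$success,
                    lo = 0, hi = 100)

  # t9-t11: wedge geometry constants from emitted plans
  ample <- plan_spot_wedges(n_images = 2000, oscillation_range = 1)
  out$t9 <- ample$achieved_separation
  # 95 images: the ideal separation misses by one step
  out$t10 <- out$t9 - plan_spot_wedges(95, oscillation_range = 1)$achieved_separation
  out$t11 <- diff(ample$wedges[[1]]) + 1

  lapply(out, as.numeric)
}
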