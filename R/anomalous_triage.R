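# Anomalous-signal triage and SAD trial planning: per-shell <d''/sigma(d'')>
# strength, the submission trigger, the Matthews-style MW estimate, the
# solvent/enantiomorph trial grid and the solved-structure flag.

#' Per-shell anomalous-signal strength
#'
#' The table is canonicalized with Friedel mates kept separate; each mate
#' side of each unique index is inverse-variance merged.  For unique
#' indices with both mates the anomalous amplitude difference is
#' d'' = |F+ - F-| with F = sqrt(max(I, 0)) and sigma_F propagated as
#' sigma_I / (2 * max(F, sqrt(sigma_I))) — the max() guards the propagation
#' against blow-up for weak or negative intensities (a proper
#' intensity-to-amplitude conversion is out of scope).  The per-shell
#' statistic is mean(d'') / mean(sigma_d'') (ratio of means; the
#' mean-of-ratios variant is available via `method`).  The trigger fires
#' when any shell's statistic strictly exceeds `threshold` (default 1.3).
#' With pure noise the statistic sits near sqrt(2/pi) ~ 0.8.
#'
#' @param table reflection table with Friedel mates present (unmerged)
#' @param cell a [unit_cell()]
#' @param group a [sym_group()]
#' @param n_shells number of resolution shells, default 10
#' @param edges optional explicit shell edges (d, decreasing)
#' @param threshold trigger level on the shell statistic, default 1.3
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"`
#' @return list of class `anomalous_summary`: `shells` (d_max, d_min,
#'   n_pairs, danom_over_sigma — NA, never 0, where no pairs exist),
#'   `trigger`, `threshold`
#' @export
anomalous_signal <- function(table, cell, group, n_shells = 10, edges = NULL,
                             threshold = 1.3,
                             method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  table <- as_reflection_table(table)
  H <- as.matrix(table[, c("h", "k", "l")])
  cn <- canonicalize(H, group, friedel_merged = FALSE)
  dt <- data.table::data.table(ch = cn$hkl[, 1], ck = cn$hkl[, 2],
                               cl = cn$hkl[, 3], sign = cn$sign,
                               intensity = table$intensity,
                               sigma = table$sigma)
  merged <- dt[, .(i = sum(intensity / sigma^2) / sum(1 / sigma^2),
                   s = sqrt(1 / sum(1 / sigma^2))),
               by = .(ch, ck, cl, sign)]
  sides <- data.table::dcast(merged, ch + ck + cl ~ sign,
                             value.var = c("i", "s"))
  if (!all(c("i_1", "i_-1") %in% names(sides)) ||
      !any(stats::complete.cases(sides[, c("i_1", "i_-1")])))
    stop("undefined anomalous signal: no unique index has both Friedel mates")
  pairs <- sides[stats::complete.cases(sides[, c("i_1", "i_-1")])]
  famp <- function(i) sqrt(pmax(i, 0))
  fsig <- function(i, s) s / (2 * pmax(famp(i), sqrt(s)))
  pairs[, `:=`(fp = famp(i_1), fm = famp(`i_-1`),
               sp = fsig(i_1, s_1), sm = fsig(`i_-1`, `s_-1`))]
  pairs[, `:=`(danom = abs(fp - fm), sdanom = sqrt(sp^2 + sm^2))]
  pairs[, d := d_spacing(as.matrix(pairs[, c("ch", "ck", "cl")]), cell)]
  if (is.null(edges)) edges <- shell_edges(max(pairs$d), min(pairs$d), n_shells)
  pairs[, bin := shell_bin(d, edges)]
  n <- length(edges) - 1
  stat <- rep(NA_real_, n)
  npairs <- integer(n)
  for (b in seq_len(n)) {
    p <- pairs[bin == b]
    npairs[b] <- nrow(p)
    if (nrow(p))
      stat[b] <- if (method == "ratio_of_means") mean(p$danom) / mean(p$sdanom)
                 else mean(p$danom / p$sdanom)
  }
  shells <- data.table::data.table(shell = seq_len(n),
                                   d_max = edges[-(n + 1)], d_min = edges[-1],
                                   n_pairs = npairs, danom_over_sigma = stat)
  structure(list(shells = shells,
                 trigger = any(stat > threshold, na.rm = TRUE),
                 threshold = threshold),
            class = "anomalous_summary")
}

#' Tentative molecular-weight estimate from cell volume
#'
#' Matthews-style relation at an assumed solvent fraction (default 47%, the
#' typical protein crystal):
#' MW = V_cell * (1 - solvent_fraction) / (Z * nu), with Z the number of
#' symmetry copies in the cell (taken as the group's rotation count;
#' registry groups are primitive settings) and nu = 1.23 A^3/Da the protein
#' partial specific volume.
#'
#' @param cell a [unit_cell()]
#' @param group a [sym_group()]
#' @param solvent_fraction assumed solvent fraction in (0, 1), default 0.47
#' @param nu partial specific volume, A^3/Da, default 1.23
#' @return estimated molecular weight in Da
#' @export
estimate_mw <- function(cell, group, solvent_fraction = 0.47, nu = 1.23) {
  if (!is.finite(solvent_fraction) || solvent_fraction <= 0 ||
      solvent_fraction >= 1)
    stop("solvent_fraction must be in (0, 1)")
  z <- length(group$rotations)
  cell_volume(cell) * (1 - solvent_fraction) / (z * nu)
}

#' Build the SAD trial plan
#'
#' The deterministic trial grid run when the anomalous trigger fires: three
#' solvent-content values (37, 47 and 57%) crossed with both enantiomorph
#' hands — six trials — plus the tentative MW at the assumed 47% solvent.
#'
#' @param cell a [unit_cell()]
#' @param group a [sym_group()]
#' @param solvent_fractions solvent contents to try, default
#'   `c(0.37, 0.47, 0.57)`
#' @return list of class `trial_plan`: `estimated_mw`, `solvent_fractions`,
#'   `hands`, `trials` (data.table, solvent ascending, original hand first)
#' @export
build_trial_plan <- function(cell, group,
                             solvent_fractions = c(0.37, 0.47, 0.57)) {
  hands <- c("original", "inverted")
  trials <- data.table::CJ(solvent_fraction = sort(solvent_fractions),
                           hand = factor(hands, levels = hands),
                           sorted = TRUE)
  trials[, hand := as.character(hand)]
  structure(list(estimated_mw = estimate_mw(cell, group, 0.47),
                 solvent_fractions = sort(solvent_fractions),
                 hands = hands, trials = trials[]),
            class = "trial_plan")
}

#' Flag a successful SAD structure determination
#'
#' Success requires both a partial-model correlation coefficient strictly
#' above 25% and a mean traced fragment length strictly above 10 residues —
#' a deliberately high bar that trades recall for a low false-positive rate.
#'
#' @param cc_partial CC of the partial model, percent, in \[-100, 100\]
#' @param mean_fragment_length mean fragment length in residues, >= 0
#' @param cc_threshold default 25 (percent)
#' @param length_threshold default 10 (residues)
#' @return list of class `solution_assessment`: `cc_partial`,
#'   `mean_fragment_length`, `success`
#' @export
assess_solution <- function(cc_partial, mean_fragment_length,
                            cc_threshold = 25, length_threshold = 10) {
  if (any(cc_partial < -100 | cc_partial > 100))
    stop("cc_partial must be in [-100, 100]")
  if (any(mean_fragment_length < 0))
    stop("mean_fragment_length must be >= 0")
  structure(list(cc_partial = cc_partial,
                 mean_fragment_length = mean_fragment_length,
                 success = cc_partial > cc_threshold &
                   mean_fragment_length > length_threshold),
            class = "solution_assessment")
}
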