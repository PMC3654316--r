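# Automatic high-resolution-limit determination: low->high shell-retention
# loop with linear I/sigma interpolation at the failing shell.

#' Cutoff parameters for the resolution-limit loop
#'
#' Defaults are the pipeline's decision constants: retain shells while mean
#' I/sigma exceeds 2; the completeness branch threshold is 80%.
#'
#' @param i_sigma_cutoff mean I/sigma retention cutoff (> 0), default 2
#' @param completeness_cutoff completeness branch threshold in percent,
#'   in (0, 100], default 80
#' @return list of class `cutoff_parameters`
#' @export
cutoff_parameters <- function(i_sigma_cutoff = 2, completeness_cutoff = 80) {
  if (!is.finite(i_sigma_cutoff) || i_sigma_cutoff <= 0)
    stop("i_sigma_cutoff must be > 0")
  if (!is.finite(completeness_cutoff) || completeness_cutoff <= 0 ||
      completeness_cutoff > 100)
    stop("completeness_cutoff must be in (0, 100]")
  structure(list(i_sigma_cutoff = i_sigma_cutoff,
                 completeness_cutoff = completeness_cutoff),
            class = "cutoff_parameters")
}

#' Interpolate the resolution limit between two shells
#'
#' Linear interpolation of resolution against mean I/sigma between the last
#' shell above the cutoff (`prev`) and the first shell below it (`outer`),
#' using each shell's high-resolution edge (its `d_min`):
#'
#'   d_new = d_prev + (d_outer - d_prev) * (I_prev - I_cutoff) / (I_prev - I_outer)
#'
#' The result lies strictly between the two edges; at the boundaries
#' I_prev -> cutoff gives d_prev and I_outer -> cutoff gives d_outer.  The
#' linearity of I/sigma in d is an assumption, known to slightly
#' overestimate the attainable resolution.
#'
#' @param prev shell (one row of [compute_shell_stats()] output, or any list
#'   with `d_min` and `mean_i_over_sigma`) with I/sigma above the cutoff
#' @param outer shell with I/sigma below the cutoff, at higher resolution
#' @param i_cutoff the I/sigma cutoff
#' @return new high-resolution limit in Angstrom
#' @export
interpolate_resolution <- function(prev, outer, i_cutoff = 2) {
  i_prev <- prev$mean_i_over_sigma
  i_outer <- outer$mean_i_over_sigma
  d_prev <- prev$d_min
  d_outer <- outer$d_min
  if (!(i_prev > i_cutoff && i_cutoff > i_outer))
    stop("contract error: need I_prev > cutoff > I_outer (got ",
         i_prev, ", ", i_cutoff, ", ", i_outer, ")")
  if (!(d_prev > d_outer))
    stop("contract error: prev shell must be at lower resolution than outer")
  d_prev + (d_outer - d_prev) * (i_prev - i_cutoff) / (i_prev - i_outer)
}

#' Determine the high-resolution limit from shell statistics
#'
#' Walks shells from low to high resolution, retaining each shell whose mean
#' I/sigma is strictly greater than the cutoff.  At the first failing shell:
#' if completeness is also below its threshold, the limit is the previous
#' shell's high-resolution edge (`rule = "both_below_boundary"`); if
#' completeness holds, the limit is interpolated between the previous and
#' failing shells (`rule = "interpolated"`).  If no shell fails the limit is
#' the innermost edge (`rule = "all_retained"`).  If the very first shell
#' already fails, the low-resolution edge is returned with a warning flag
#' rather than an abort, so very weak data still yield a report.
#'
#' @param shells output of [compute_shell_stats()] (ordered low -> high
#'   resolution, i.e. decreasing d)
#' @param params a [cutoff_parameters()]
#' @return list of class `cutoff_result`: `d_min_new` (A),
#'   `retained_shells` (indices), `rule`, `no_usable_data` flag
#' @export
determine_resolution_limit <- function(shells, params = cutoff_parameters()) {
  shells <- data.table::as.data.table(shells)
  if (!nrow(shells)) stop("need at least one shell")
  if (is.unsorted(rev(shells$d_min)))
    stop("shells must be ordered low -> high resolution (decreasing d_min)")
  isig <- shells$mean_i_over_sigma
  comp <- shells$completeness
  res <- function(d, retained, rule, warn = FALSE)
    structure(list(d_min_new = d, retained_shells = retained, rule = rule,
                   no_usable_data = warn), class = "cutoff_result")

  for (i in seq_len(nrow(shells))) {
    if (isig[i] > params$i_sigma_cutoff) next
    if (i == 1L)  # degenerate: nothing retained
      return(res(shells$d_max[1], integer(0), "both_below_boundary",
                 warn = TRUE))
    below_comp <- !is.na(comp[i]) && comp[i] < params$completeness_cutoff
    if (below_comp)
      return(res(shells$d_min[i - 1], seq_len(i - 1), "both_below_boundary"))
    if (isig[i] == params$i_sigma_cutoff)  # flat hit: no interpolation room
      return(res(shells$d_min[i], seq_len(i - 1), "interpolated"))
    return(res(interpolate_resolution(shells[i - 1], shells[i],
                                      params$i_sigma_cutoff),
               seq_len(i - 1), "interpolated"))
  }
  res(shells$d_min[nrow(shells)], seq_len(nrow(shells)), "all_retained")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("resolution limit %.3f A (%s, %d shells retained%s)\n",
              x$d_min_new, x$rule, length(x$retained_shells),
              if (x$no_usable_data) ", no usable data at cutoff" else ""))
  invisible(x)
}
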