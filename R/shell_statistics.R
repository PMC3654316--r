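# Resolution binning and per-shell merging statistics.

#' Assign reflections to resolution shells
#'
#' Bins are equal-volume in reciprocal space, i.e. equally spaced in 1/d^3,
#' between the lowest- and highest-resolution observation (a convention for
#' the "bins chosen by the integration program", which are approximately
#' equal-volume).
#'
#' @param table reflection table
#' @param cell a [unit_cell()]
#' @param n_shells number of shells (>= 1)
#' @return list with `edges` (d in A, strictly decreasing, length
#'   `n_shells + 1`) and `bin` (integer shell label per reflection, 1 =
#'   lowest resolution)
#' @export
assign_shells <- function(table, cell, n_shells = 10) {
  table <- as_reflection_table(table)
  if (!nrow(table)) stop("cannot assign shells: empty reflection table")
  if (n_shells < 1) stop("n_shells must be >= 1")
  d <- d_spacing(as.matrix(table[, c("h", "k", "l")]), cell)
  edges <- shell_edges(max(d), min(d), n_shells)
  list(edges = edges, bin = shell_bin(d, edges), d = d)
}

# equal 1/d^3 spacing from d_max down to d_min
shell_edges <- function(d_max, d_min, n_shells) {
  if (d_max == d_min) d_max <- d_max * (1 + 1e-9)  # degenerate single-d table
  v <- seq(1 / d_max^3, 1 / d_min^3, length.out = n_shells + 1)
  edges <- v^(-1 / 3)
  edges[1] <- d_max            # pin ends: v^(-1/3) reintroduces float error
  edges[n_shells + 1] <- d_min
  edges
}

shell_bin <- function(d, edges) {
  n <- length(edges) - 1
  # work in 1/d^3 so edges are increasing; clamp for boundary float noise
  b <- findInterval(1 / d^3, 1 / edges^3, rightmost.closed = TRUE)
  pmin(pmax(b, 1L), n)
}

#' Per-shell data-quality statistics
#'
#' For each resolution shell: observation and unique counts, theoretical
#' unique count (from [enumerate_unique()]), completeness (%),
#' mean unmerged I/sigma, R-merge, R-meas and multiplicity.
#'
#' R-merge = sum_h sum_i |I_hi - <I_h>| / sum_h sum_i I_hi over canonical
#' groups with >= 2 observations; R-meas applies the per-group factor
#' sqrt(n_h / (n_h - 1)).  Negative intensities are retained in all sums.
#' A shell with no theoretically possible reflections gets completeness NA
#' (flagged, never silently 0).
#'
#' @param table reflection table
#' @param cell a [unit_cell()]
#' @param group a [sym_group()]
#' @param friedel_merged merge Friedel mates when grouping equivalents?
#' @param edges shell edges in d (decreasing); defaults to
#'   [assign_shells()] with `n_shells`
#' @param n_shells used when `edges` is NULL
#' @param merged_i_over_sigma also report mean I/sigma of inverse-variance
#'   merged intensities (`mean_i_over_sigma_merged` column)?
#' @return data.table with one row per shell (class `resolution_shells`)
#' @export
compute_shell_stats <- function(table, cell, group, friedel_merged = TRUE,
                                edges = NULL, n_shells = 10,
                                merged_i_over_sigma = FALSE) {
  table <- as_reflection_table(table)
  if (!nrow(table)) stop("empty reflection table")
  d <- d_spacing(as.matrix(table[, c("h", "k", "l")]), cell)
  if (is.null(edges)) edges <- shell_edges(max(d), min(d), n_shells)
  bin <- shell_bin(d, edges)
  key <- canonical_key(as.matrix(table[, c("h", "k", "l")]), group,
                       friedel_merged)

  obs <- data.table::data.table(bin = bin, ckey = key,
                                intensity = table$intensity,
                                sigma = table$sigma)
  n <- length(edges) - 1

  # theoretical unique count per shell, one global enumeration
  theo <- enumerate_unique(cell, group, d_min = min(edges), d_max = max(edges),
                           friedel_merged = friedel_merged)
  theo_bin <- shell_bin(theo$d, edges)
  n_theo <- tabulate(theo_bin, nbins = n)

  per_group <- obs[, .(n_h = .N, ibar = mean(intensity),
                       dev = sum(abs(intensity - mean(intensity))),
                       isum = sum(intensity),
                       w = sum(1 / sigma^2),
                       iw = sum(intensity / sigma^2)),
                   by = .(bin, ckey)]

  shell_of <- function(b) {
    g <- per_group[bin == b]
    o <- obs[bin == b]
    multi <- g[n_h >= 2L]
    denom <- sum(multi$isum)
    list(n_obs = nrow(o),
         n_unique = nrow(g),
         r_merge = if (nrow(multi) && denom != 0) sum(multi$dev) / denom else 0,
         r_meas = if (nrow(multi) && denom != 0)
           sum(sqrt(multi$n_h / (multi$n_h - 1)) * multi$dev) / denom else 0,
         mean_i_over_sigma = mean(o$intensity / o$sigma),
         mean_i_over_sigma_merged = mean((g$iw / g$w) * sqrt(g$w)))
  }

  rows <- lapply(seq_len(n), function(b) {
    s <- shell_of(b)
    data.table::data.table(
      shell = b, d_max = edges[b], d_min = edges[b + 1],
      n_obs = s$n_obs, n_unique = s$n_unique, n_theoretical = n_theo[b],
      completeness = if (n_theo[b] > 0) 100 * s$n_unique / n_theo[b] else NA_real_,
      mean_i_over_sigma = if (s$n_obs) s$mean_i_over_sigma else NA_real_,
      mean_i_over_sigma_merged =
        if (merged_i_over_sigma && s$n_unique) s$mean_i_over_sigma_merged else NA_real_,
      r_merge = s$r_merge, r_meas = s$r_meas,
      multiplicity = if (s$n_unique) s$n_obs / s$n_unique else NA_real_)
  })
  out <- data.table::rbindlist(rows)
  if (!merged_i_over_sigma) out[, mean_i_over_sigma_merged := NULL]
  data.table::setattr(out, "class",
                      c("resolution_shells", class(out)))
  out
}

#' Overall statistics across all shells
#'
#' Recomputed from the pooled observations (not averaged shell values), over
#' the resolution range spanned by the given shell edges.
#'
#' @inheritParams compute_shell_stats
#' @param edges the shell edges the per-shell table used
#' @return one-row data.table with the same columns as
#'   [compute_shell_stats()]
#' @export
overall_stats <- function(table, cell, group, friedel_merged = TRUE,
                          edges = NULL) {
  table <- as_reflection_table(table)
  if (is.null(edges)) {
    d <- d_spacing(as.matrix(table[, c("h", "k", "l")]), cell)
    edges <- c(max(d), min(d))
  }
  out <- compute_shell_stats(table, cell, group, friedel_merged,
                             edges = c(max(edges), min(edges)))
  out[, shell := NA_integer_]
  out
}

#' Write per-shell statistics as TSV
#' @param shells output of [compute_shell_stats()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_shell_stats <- function(shells, path) {
  data.table::fwrite(shells, path, sep = "\t")
  invisible(path)
}
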