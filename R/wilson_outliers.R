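# Wilson-plot fit and Z-score outlier rejection (the REMOVE.HKL-style
# mechanism), with a single rejection-and-re-merge cycle.

#' Fit a Wilson model to shell mean intensities
#'
#' Least-squares line through (s^2, ln <I>_shell) with s = 1/(2d):
#' slope = -2B, intercept = log of the scale.  Shells with non-positive mean
#' intensity are excluded; at least three usable shells are required.  All
#' reflections are treated as acentric (exponential intensity law).
#'
#' @param table reflection table
#' @param cell a [unit_cell()]
#' @param n_shells number of Wilson shells (default 20 for a stable fit)
#' @param edges optional explicit shell edges (d, decreasing)
#' @return list of class `wilson_fit`: `log_scale`, `b_factor` (A^2),
#'   `shells` (data.table of s2, mean intensity, expected mean)
#' @export
fit_wilson <- function(table, cell, n_shells = 20, edges = NULL) {
  table <- as_reflection_table(table)
  d <- d_spacing(as.matrix(table[, c("h", "k", "l")]), cell)
  if (is.null(edges)) edges <- shell_edges(max(d), min(d), n_shells)
  bin <- shell_bin(d, edges)
  dt <- data.table::data.table(bin = bin, intensity = table$intensity, d = d)
  sh <- dt[, .(mean_i = mean(intensity), mean_d = mean(d), n = .N), by = bin]
  sh <- sh[mean_i > 0]
  if (nrow(sh) < 3)
    stop("Wilson fit error: fewer than 3 shells with positive mean intensity")
  sh[, s2 := 1 / (2 * mean_d)^2]
  fit <- stats::lm(log(mean_i) ~ s2, data = sh)
  cf <- stats::coef(fit)
  if (any(!is.finite(cf))) stop("Wilson fit error: non-finite coefficients")
  sh[, expected := exp(cf[1] + cf[2] * s2)]
  structure(list(log_scale = unname(cf[1]),
                 b_factor = unname(-cf[2] / 2),
                 shells = sh[order(bin)]),
            class = "wilson_fit")
}

#' @export
print.wilson_fit <- function(x, ...) {
  cat(sprintf("Wilson fit: B = %.2f A^2, scale = %.4g (%d shells)\n",
              x$b_factor, exp(x$log_scale), nrow(x$shells)))
  invisible(x)
}

# Wilson-expected mean intensity at resolution d (A)
wilson_expected <- function(fit, d) {
  s2 <- 1 / (2 * d)^2
  exp(fit$log_scale - 2 * fit$b_factor * s2)
}

#' Reject reflections not obeying the Wilson distribution
#'
#' Z is the observed intensity over the Wilson-expected mean intensity at
#' that resolution (for acentric reflections the expected distribution is
#' exponential, so under the model P(Z > z) = exp(-z)).  Rows with
#' Z strictly greater than `z_threshold` (default 10) are removed; the
#' removal list mirrors a REMOVE.HKL file, and downstream statistics are
#' recomputed on the clean table (the "re-merge" pass).  A single cycle
#' only: the pass is not iterated to convergence.
#'
#' @param table reflection table
#' @param fit a [fit_wilson()] result
#' @param cell a [unit_cell()]
#' @param z_threshold rejection threshold on Z (strict >), default 10
#' @return list with `clean` (reflection table), `rejected` (data.table of
#'   the removed rows plus `z_score` and `reason`), and `n_rejected`
#' @export
reject_wilson_outliers <- function(table, fit, cell, z_threshold = 10) {
  table <- as_reflection_table(table)
  d <- d_spacing(as.matrix(table[, c("h", "k", "l")]), cell)
  z <- table$intensity / wilson_expected(fit, d)
  bad <- z > z_threshold
  rejected <- data.table::copy(table[bad])
  if (nrow(rejected)) {
    rejected[, z_score := z[bad]]
    rejected[, reason := "wilson_z_exceeds_threshold"]
  } else {
    rejected[, `:=`(z_score = numeric(0), reason = character(0))]
  }
  list(clean = table[!bad], rejected = rejected, n_rejected = sum(bad))
}

#' Write a REMOVE.HKL-style rejection file
#'
#' One line per rejected reflection: `h k l z_score`.
#'
#' @param rejected the `rejected` table from [reject_wilson_outliers()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_remove_hkl <- function(rejected, path) {
  lines <- sprintf("%5d %5d %5d %12.4f",
                   rejected$h, rejected$k, rejected$l, rejected$z_score)
  writeLines(lines, path)
  invisible(path)
}
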