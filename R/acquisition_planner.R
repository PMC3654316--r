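# Spot-wedge acquisition planning: an initial wedge for indexing plus a
# second wedge ideally 90 degrees from the starting angle, relaxed in 5
# degree decrements until it fits in the collected images.

#' Plan spot-picking image wedges
#'
#' Wedge 1 covers the first `first_width` images (or all of them if fewer
#' exist).  Wedge 2 is `second_width` images starting at the image whose
#' start angle is `starting_angle + sep`, where `sep` is the largest value
#' in `target_sep, target_sep - decrement, ...` such that the whole wedge
#' exists and does not overlap wedge 1.  If no separation of at least one
#' oscillation step admits a valid wedge, the plan contains wedge 1 only
#' and `achieved_separation` is NA.
#'
#' @param n_images number of images collected, >= 1
#' @param starting_angle degrees (enters only via image arithmetic)
#' @param oscillation_range degrees per image, > 0
#' @param first_width images in the initial wedge, default 20
#' @param second_width images in the second wedge, default 10
#' @param target_sep ideal angular separation (deg), default 90
#' @param decrement fallback step (deg), default 5
#' @return list of class `wedge_plan`: `wedges` (list of inclusive
#'   1-based `c(first, last)` ranges), `achieved_separation` (deg or NA),
#'   `requested_separation`
#' @export
plan_spot_wedges <- function(n_images, starting_angle = 0,
                             oscillation_range = 1, first_width = 20,
                             second_width = 10, target_sep = 90,
                             decrement = 5) {
  if (!is.finite(oscillation_range) || oscillation_range <= 0)
    stop("oscillation_range must be > 0")
  if (n_images < 1) stop("n_images must be >= 1")
  wedge1 <- c(1L, as.integer(min(first_width, n_images)))
  sep <- target_sep
  wedge2 <- NULL
  achieved <- NA_real_
  while (sep >= oscillation_range) {
    first <- as.integer(floor(sep / oscillation_range)) + 1L
    last <- first + as.integer(second_width) - 1L
    if (last <= n_images && first > wedge1[2]) {
      wedge2 <- c(first, last)
      achieved <- sep
      break
    }
    sep <- sep - decrement
  }
  structure(list(wedges = if (is.null(wedge2)) list(wedge1)
                          else list(wedge1, wedge2),
                 achieved_separation = achieved,
                 requested_separation = target_sep),
            class = "wedge_plan")
}

#' @export
print.wedge_plan <- function(x, ...) {
  cat(sprintf("wedge plan: %s (separation %s deg of %g requested)\n",
              paste(vapply(x$wedges, function(w)
                sprintf("[%d..%d]", w[1], w[2]), ""), collapse = " "),
              if (is.na(x$achieved_separation)) "none"
              else format(x$achieved_separation),
              x$requested_separation))
  invisible(x)
}

#' Format a wedge plan as SPOT_RANGE-style lines
#' @param plan a [plan_spot_wedges()] result
#' @return character vector, one `SPOT_RANGE= first last` line per wedge
#' @export
format_spot_ranges <- function(plan) {
  vapply(plan$wedges,
         function(w) sprintf("SPOT_RANGE= %d %d", w[1], w[2]), character(1))
}
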