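#' @import data.table
#' @importFrom stats lm coef rexp rnorm runif cor setNames
#' @importFrom utils head tail
NULL

# package-level cache for the symmetry registry
.reflexio_env <- new.env(parent = emptyenv())

#' Construct a crystallographic unit cell
#'
#' Cell lengths are in Angstrom, angles in degrees.  The constructor
#' validates that the metric tensor is positive definite (i.e. the cell
#' encloses a positive volume).
#'
#' @param a,b,c cell edge lengths (Angstrom), > 0
#' @param alpha,beta,gamma cell angles (degrees), strictly in (0, 180)
#' @return an object of class `unit_cell`
#' @examples
#' unit_cell(40, 50, 60)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("invalid cell: all lengths must be finite and > 0")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("invalid cell: all angles must lie strictly in (0, 180) degrees")
  cell <- structure(list(a = a, b = b, c = c,
                         alpha = alpha, beta = beta, gamma = gamma),
                    class = "unit_cell")
  G <- cell_metric_tensor(cell)
  if (det(G) <= 0)
    stop("invalid cell: metric tensor is not positive definite")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

# real-space metric tensor G (A^2); reciprocal metric is solve(G)
cell_metric_tensor <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta  * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  with(cell, matrix(c(a * a,      a * b * cg, a * c * cb,
                      a * b * cg, b * b,      b * c * ca,
                      a * c * cb, b * c * ca, c * c), 3, 3))
}

#' Unit-cell volume in cubic Angstrom
#' @param cell a [unit_cell()]
#' @return volume (A^3)
#' @export
cell_volume <- function(cell) {
  sqrt(det(cell_metric_tensor(cell)))
}

#' d-spacing of reflections
#'
#' Resolution d (Angstrom) of Miller indices under a unit cell, via the
#' reciprocal metric tensor: 1/d^2 = h' G* h.  For an orthogonal cell this
#' reduces to 1/d^2 = h^2/a^2 + k^2/b^2 + l^2/c^2.
#'
#' @param hkl integer vector of length 3, or an n x 3 matrix of indices
#' @param cell a [unit_cell()]
#' @return numeric vector of d (A), one per reflection
#' @examples
#' d_spacing(c(1, 0, 0), unit_cell(10, 10, 10))  # 10 A
#' @export
d_spacing <- function(hkl, cell) {
  H <- as_hkl_matrix(hkl)
  if (any(rowSums(H != 0L) == 0L))
    stop("invalid reflection: (0,0,0) has no d-spacing")
  Gstar <- solve(cell_metric_tensor(cell))
  inv_d2 <- rowSums((H %*% Gstar) * H)
  1 / sqrt(inv_d2)
}

as_hkl_matrix <- function(hkl) {
  if (is.matrix(hkl)) {
    stopifnot(ncol(hkl) == 3)
    H <- hkl
  } else {
    stopifnot(length(hkl) == 3)
    H <- matrix(hkl, 1, 3)
  }
  storage.mode(H) <- "double"
  H
}

# ---- symmetry registry -----------------------------------------------------

#' Load the symmetry-group registry
#'
#' The registry is a plain-text file shipping one block per group: the
#' Hermann-Mauguin-style symbol, the Bravais-lattice symbol, the rotation
#' matrices (9 integers, row-major) and the indexing-ambiguity operators.
#' Point-group machinery only: screw axes and centring translations do not
#' act on (h,k,l), so e.g. P212121 shares its rotations with P222.
#'
#' @param path registry file; defaults to the file shipped with the package
#' @return named list of symmetry groups (see [sym_group()])
#' @export
load_symmetry_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "symmetry_groups.txt", package = "reflexio",
                        mustWork = TRUE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  registry <- list()
  cur <- NULL
  parse_mat <- function(line) {
    v <- as.integer(strsplit(line, "\\s+")[[1]][-1])
    stopifnot(length(v) == 9)
    matrix(v, 3, 3, byrow = TRUE)
  }
  for (ln in lines) {
    if (startsWith(ln, "group ")) {
      cur <- list(symbol = sub("^group\\s+", "", ln),
                  rotations = list(), ambiguity_ops = list())
    } else if (startsWith(ln, "bravais ")) {
      cur$bravais_lattice <- sub("^bravais\\s+", "", ln)
    } else if (startsWith(ln, "rot ")) {
      cur$rotations <- c(cur$rotations, list(parse_mat(ln)))
    } else if (startsWith(ln, "ambig ")) {
      cur$ambiguity_ops <- c(cur$ambiguity_ops, list(parse_mat(ln)))
    } else if (ln == "end") {
      registry[[cur$symbol]] <- .finish_group(cur)
      cur <- NULL
    } else {
      stop("malformed registry line: ", ln)
    }
  }
  registry
}

.op_key <- function(x) paste(as.integer(x), collapse = ",")

.mat_closure <- function(ops) {
  out <- list(diag(3))
  names(out) <- .op_key(diag(3))
  queue <- ops
  while (length(queue)) {
    g <- queue[[1]]; queue <- queue[-1]
    if (is.null(out[[.op_key(g)]])) {
      out[[.op_key(g)]] <- g
      for (h in out) queue <- c(queue, list(g %*% h, h %*% g))
      queue <- c(queue, ops)
    }
  }
  unname(out)
}

.finish_group <- function(g) {
  stopifnot(length(g$rotations) >= 1)
  dets <- vapply(g$rotations, det, 0)
  if (any(abs(abs(dets) - 1) > 1e-9))
    stop("registry group ", g$symbol, ": operator determinant not +/-1")
  keys <- vapply(g$rotations, .op_key, "")
  if (!(.op_key(diag(3)) %in% keys))
    stop("registry group ", g$symbol, ": identity missing")
  for (a in g$rotations) for (b in g$rotations)
    if (!(.op_key(a %*% b) %in% keys))
      stop("registry group ", g$symbol, ": rotations not closed")
  g$laue_ops <- .mat_closure(c(g$rotations, list(-diag(3))))
  laue_keys <- vapply(g$laue_ops, .op_key, "")
  for (t in g$ambiguity_ops)
    if (.op_key(t) %in% laue_keys)
      stop("registry group ", g$symbol, ": ambiguity op already in Laue group")
  class(g) <- "sym_group"
  g
}

#' Fetch a symmetry group from the registry
#'
#' @param symbol group symbol, e.g. `"P212121"`
#' @param registry optional registry list; defaults to the shipped registry
#'   (cached after first load)
#' @return a `sym_group`: `symbol`, `bravais_lattice`, `rotations`
#'   (3x3 integer matrices acting on column hkl), `laue_ops` (closure under
#'   inversion), `ambiguity_ops`
#' @export
sym_group <- function(symbol, registry = NULL) {
  if (is.null(registry)) {
    if (is.null(.reflexio_env$registry))
      .reflexio_env$registry <- load_symmetry_registry()
    registry <- .reflexio_env$registry
  }
  g <- registry[[symbol]]
  if (is.null(g))
    stop("unknown symmetry group '", symbol, "'; registry has: ",
         paste(names(registry), collapse = ", "))
  g
}

#' @export
print.sym_group <- function(x, ...) {
  cat(sprintf("symmetry group %s (%s): %d rotations, %d Laue ops, %d ambiguity ops\n",
              x$symbol, x$bravais_lattice, length(x$rotations),
              length(x$laue_ops), length(x$ambiguity_ops)))
  invisible(x)
}

# ---- canonical indices -----------------------------------------------------

# encode rows of an integer n x 3 matrix as one sortable double per row
.lex_key <- function(H) {
  off <- max(abs(H), 1)
  base <- 2 * off + 2
  ((H[, 1] + off) * base + (H[, 2] + off)) * base + (H[, 3] + off)
}

.lex_reduce <- function(H, ops) {
  best <- H %*% t(ops[[1]])
  if (length(ops) == 1) return(best)
  # shared offset so keys are comparable across candidates
  off <- max(abs(H)) * 3 + 1
  base <- 2 * off + 2
  keyf <- function(M) ((M[, 1] + off) * base + (M[, 2] + off)) * base + (M[, 3] + off)
  bk <- keyf(best)
  for (R in ops[-1]) {
    cand <- H %*% t(R)
    ck <- keyf(cand)
    imp <- ck > bk
    if (any(imp)) {
      best[imp, ] <- cand[imp, , drop = FALSE]
      bk[imp] <- ck[imp]
    }
  }
  best
}

#' Canonicalize Miller indices under a symmetry group
#'
#' Maps each reflection to a deterministic representative of its symmetry
#' orbit: the lexicographically greatest (h,k,l) over all symmetry mates
#' (including Friedel mates -h,-k,-l when `friedel_merged = TRUE`).  When
#' Friedel mates are kept separate the canonical index is still the shared
#' Friedel-merged representative and `friedel_sign` tells the two mates
#' apart (+1 for the mate whose rotation-only representative equals the
#' merged one, -1 for its Friedel partner).  Centric reflections, whose
#' rotation orbit already contains -hkl, always carry sign +1.
#'
#' @param hkl length-3 vector or n x 3 matrix of integer indices
#' @param group a [sym_group()]
#' @param friedel_merged merge Friedel mates (anomalous pairs) into one index?
#' @return a list with `hkl` (n x 3 canonical indices) and `sign`
#'   (integer +/-1 when `friedel_merged = FALSE`, otherwise `NA`)
#' @export
canonicalize <- function(hkl, group, friedel_merged = TRUE) {
  H <- as_hkl_matrix(hkl)
  if (!nrow(H))
    return(list(hkl = H, sign = integer(0)))
  merged <- .lex_reduce(H, group$laue_ops)
  if (friedel_merged)
    return(list(hkl = merged, sign = rep(NA_integer_, nrow(H))))
  rot <- .lex_reduce(H, group$rotations)
  sgn <- ifelse(rowSums(rot != merged) == 0L, 1L, -1L)
  list(hkl = merged, sign = sgn)
}

# single sortable key per reflection: canonical index (+ sign when separate)
canonical_key <- function(hkl, group, friedel_merged = TRUE) {
  cn <- canonicalize(hkl, group, friedel_merged)
  key <- paste(cn$hkl[, 1], cn$hkl[, 2], cn$hkl[, 3], sep = ",")
  if (!friedel_merged) key <- paste0(key, ";", cn$sign)
  key
}

#' Enumerate unique reflections in a resolution range
#'
#' All integer triples with d in `[d_min, d_max]` reduced to one canonical
#' representative each.  Systematic absences are not removed (documented
#' convention: the registry carries point-group machinery only, and the
#' resulting bias in theoretical completeness denominators is small).
#'
#' @param cell a [unit_cell()]
#' @param group a [sym_group()]
#' @param d_min,d_max resolution range in Angstrom, `0 < d_min < d_max`
#' @param friedel_merged merge Friedel mates?
#' @return data.table with columns h, k, l (canonical unique indices), d,
#'   and sign when `friedel_merged = FALSE`
#' @export
enumerate_unique <- function(cell, group, d_min, d_max = Inf,
                             friedel_merged = TRUE) {
  if (!is.finite(d_min) || d_min <= 0)
    stop("invalid range: d_min must be finite and > 0")
  if (d_min >= d_max) stop("invalid range: d_min must be < d_max")
  # |h_i| <= |a_i| / d_min exactly (h = x . a with |x| <= 1/d_min)
  hmax <- ceiling(cell$a / d_min)
  kmax <- ceiling(cell$b / d_min)
  lmax <- ceiling(cell$c / d_min)
  grid <- data.table::CJ(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  grid <- grid[h != 0L | k != 0L | l != 0L]
  H <- as.matrix(grid)
  d <- d_spacing(H, cell)
  keep <- d >= d_min & d <= d_max
  H <- H[keep, , drop = FALSE]
  d <- d[keep]
  cn <- canonicalize(H, group, friedel_merged)
  dt <- data.table::data.table(h = as.integer(cn$hkl[, 1]),
                               k = as.integer(cn$hkl[, 2]),
                               l = as.integer(cn$hkl[, 3]), d = d)
  if (!friedel_merged) {
    dt[, sign := cn$sign]
    unique(dt, by = c("h", "k", "l", "sign"))
  } else {
    unique(dt, by = c("h", "k", "l"))
  }
}

# ---- reflection tables -----------------------------------------------------

#' Construct a reflection table
#'
#' The unmerged-observation container every pipeline stage consumes: one row
#' per measured reflection with Miller indices, intensity on an arbitrary
#' linear scale, its standard deviation, the image the observation came from
#' and a dataset label.
#'
#' @param h,k,l integer Miller indices
#' @param intensity observed intensities (arbitrary linear scale)
#' @param sigma standard deviations, must be > 0
#' @param image 1-based image numbers
#' @param dataset_id dataset label (recycled)
#' @return a `data.table` of class `reflection_table`
#' @export
reflection_table <- function(h, k, l, intensity, sigma, image = 1L,
                             dataset_id = "ds1") {
  dt <- data.table::data.table(h = as.integer(h), k = as.integer(k),
                               l = as.integer(l),
                               intensity = as.numeric(intensity),
                               sigma = as.numeric(sigma),
                               image = as.integer(image),
                               dataset_id = as.character(dataset_id))
  validate_reflection_table(dt)
  dt
}

#' Validate reflection-table invariants
#'
#' Checks sigma > 0, no (0,0,0) rows, image >= 1 and column presence.
#' @param table a reflection table (data.frame)
#' @return the table, invisibly
#' @export
validate_reflection_table <- function(table) {
  need <- c("h", "k", "l", "intensity", "sigma", "image", "dataset_id")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("reflection table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(table)) {
    if (any(table$sigma <= 0)) stop("reflection table: sigma must be > 0")
    if (any(table$h == 0L & table$k == 0L & table$l == 0L))
      stop("reflection table: (0,0,0) row not allowed")
    if (any(table$image < 1L)) stop("reflection table: image must be >= 1")
  }
  invisible(table)
}

as_reflection_table <- function(table) {
  dt <- data.table::as.data.table(table)
  validate_reflection_table(dt)
  dt
}
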