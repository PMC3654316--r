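# Independent oracles: everything here is deliberately written from first
# principles (direct lattice vectors, explicit orbit enumeration, plain
# loops) and shares no code path with the package implementation.

# d-spacing via explicit direct/reciprocal lattice vectors (cross products),
# not the metric-tensor route the package uses
oracle_d_spacing <- function(hkl, a, b, c, alpha = 90, beta = 90, gamma = 90) {
  deg <- pi / 180
  ca <- cos(alpha * deg); cb <- cos(beta * deg)
  cg <- cos(gamma * deg); sg <- sin(gamma * deg)
  av <- c(a, 0, 0)
  bv <- c(b * cg, b * sg, 0)
  cx <- c * cb
  cy <- c * (ca - cb * cg) / sg
  cv <- c(cx, cy, sqrt(c^2 - cx^2 - cy^2))
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  vol <- sum(av * cross(bv, cv))
  astar <- cross(bv, cv) / vol
  bstar <- cross(cv, av) / vol
  cstar <- cross(av, bv) / vol
  q <- hkl[1] * astar + hkl[2] * bstar + hkl[3] * cstar
  1 / sqrt(sum(q^2))
}

# explicit orbit of one hkl under a list of ops (+ Friedel mates if merged)
oracle_orbit <- function(hkl, rotations, friedel_merged = TRUE) {
  mats <- rotations
  orb <- unique(t(vapply(mats, function(R) as.integer(R %*% hkl),
                         integer(3))))
  if (friedel_merged) orb <- unique(rbind(orb, -orb))
  orb
}

# lexicographically greatest member of the orbit, by direct comparison
oracle_canonical <- function(hkl, rotations, friedel_merged = TRUE) {
  orb <- oracle_orbit(hkl, rotations, friedel_merged)
  best <- orb[1, ]
  for (i in seq_len(nrow(orb))) {
    x <- orb[i, ]
    if (x[1] > best[1] ||
        (x[1] == best[1] && x[2] > best[2]) ||
        (x[1] == best[1] && x[2] == best[2] && x[3] > best[3]))
      best <- x
  }
  best
}

# brute-force unique-reflection count in [d_min, d_max] by exhaustive loop
oracle_unique_count <- function(cellpar, rotations, d_min, d_max,
                                friedel_merged = TRUE) {
  hm <- ceiling(cellpar[1] / d_min)
  km <- ceiling(cellpar[2] / d_min)
  lm <- ceiling(cellpar[3] / d_min)
  seen <- new.env(parent = emptyenv())
  for (h in -hm:hm) for (k in -km:km) for (l in -lm:lm) {
    if (h == 0 && k == 0 && l == 0) next
    d <- oracle_d_spacing(c(h, k, l), cellpar[1], cellpar[2], cellpar[3],
                          cellpar[4], cellpar[5], cellpar[6])
    if (d < d_min || d > d_max) next
    cn <- oracle_canonical(c(h, k, l), rotations, friedel_merged)
    assign(paste(cn, collapse = ","), TRUE, envir = seen)
  }
  length(ls(seen))
}

# precomputed exhaustive enumeration (canonical key + d per grid triple),
# reusable across shells/tables for the same cell and group
oracle_enum_cache <- function(cellpar, rotations, d_min_floor,
                              friedel_merged = TRUE) {
  hm <- ceiling(cellpar[1] / d_min_floor)
  km <- ceiling(cellpar[2] / d_min_floor)
  lm <- ceiling(cellpar[3] / d_min_floor)
  keys <- character(0)
  ds <- numeric(0)
  for (h in -hm:hm) for (k in -km:km) for (l in -lm:lm) {
    if (h == 0 && k == 0 && l == 0) next
    d <- oracle_d_spacing(c(h, k, l), cellpar[1], cellpar[2], cellpar[3],
                          cellpar[4], cellpar[5], cellpar[6])
    if (d < d_min_floor) next
    cn <- oracle_canonical(c(h, k, l), rotations, friedel_merged)
    keys <- c(keys, paste(cn, collapse = ","))
    ds <- c(ds, d)
  }
  list(keys = keys, d = ds)
}

# brute-force shell statistics on a reflection table: plain loops, own
# canonicalization, own d-spacing
oracle_shell_stats <- function(table, cellpar, rotations, friedel_merged,
                               edges, enum_cache = NULL) {
  n <- length(edges) - 1
  cp <- cellpar
  d <- vapply(seq_len(nrow(table)), function(i)
    oracle_d_spacing(c(table$h[i], table$k[i], table$l[i]),
                     cp[1], cp[2], cp[3], cp[4], cp[5], cp[6]), 0)
  keys <- vapply(seq_len(nrow(table)), function(i) {
    cn <- oracle_canonical(c(table$h[i], table$k[i], table$l[i]),
                           rotations, friedel_merged)
    key <- paste(cn, collapse = ",")
    if (!friedel_merged) {
      cr <- oracle_canonical(c(table$h[i], table$k[i], table$l[i]),
                             rotations, friedel_merged = FALSE)
      key <- paste0(key, if (all(cr == cn)) "+" else "-")
    }
    key
  }, "")
  # bin: first shell whose [d_min, d_max] contains d (clamped at the ends)
  bin <- vapply(d, function(x) {
    b <- which(x <= edges[-length(edges)] * (1 + 1e-12) &
               x >= edges[-1] * (1 - 1e-12))[1]
    if (is.na(b)) if (x > edges[1]) 1L else n else as.integer(b)
  }, integer(1))

  out <- list()
  for (b in seq_len(n)) {
    rows <- which(bin == b)
    ib <- table$intensity[rows]
    sb <- table$sigma[rows]
    kb <- keys[rows]
    num_m <- num_me <- den <- 0
    for (kk in unique(kb)) {
      ii <- ib[kb == kk]
      if (length(ii) >= 2) {
        dev <- sum(abs(ii - mean(ii)))
        num_m <- num_m + dev
        num_me <- num_me + sqrt(length(ii) / (length(ii) - 1)) * dev
        den <- den + sum(ii)
      }
    }
    nun <- length(unique(kb))
    theo <- if (!is.null(enum_cache)) {
      inb <- enum_cache$d >= edges[b + 1] & enum_cache$d <= edges[b]
      length(unique(enum_cache$keys[inb]))
    } else {
      oracle_unique_count(cp, rotations, edges[b + 1], edges[b],
                          friedel_merged)
    }
    out[[b]] <- list(
      n_obs = length(rows), n_unique = nun, n_theoretical = theo,
      completeness = if (theo > 0) 100 * nun / theo else NA_real_,
      mean_i_over_sigma = if (length(rows)) mean(ib / sb) else NA_real_,
      r_merge = if (den != 0) num_m / den else 0,
      r_meas = if (den != 0) num_me / den else 0,
      multiplicity = if (nun) length(rows) / nun else NA_real_)
  }
  out
}

# true Wilson mean at each observation's resolution, from generator truth
approx_true_mean <- function(ds, cell) {
  d <- d_spacing(as.matrix(ds$table[, c("h", "k", "l")]), cell)
  ds$truth$scale * exp(-2 * ds$truth$b_factor / (2 * d)^2)
}

# shared small fixtures --------------------------------------------------

tiny_table <- function() {
  reflection_table(h = c(1, 2, 0, 1, -3), k = c(0, 1, 3, 1, 2),
                   l = c(2, -1, 1, 0, 2),
                   intensity = c(100.25, 50.5, 75.125, 200.0625, 12.5),
                   sigma = c(10.5, 5.25, 7.0625, 20.125, 2.5),
                   image = c(1L, 2L, 3L, 4L, 5L))
}

# random small reflection table exercising symmetry-equivalent groups
random_table <- function(group, n = 60, idx_max = 4) {
  H <- matrix(sample(seq(-idx_max, idx_max), 3 * n, replace = TRUE), n, 3)
  H <- H[rowSums(H != 0) > 0, , drop = FALSE]
  reflection_table(h = H[, 1], k = H[, 2], l = H[, 3],
                   intensity = stats::rnorm(nrow(H), 100, 30),
                   sigma = stats::runif(nrow(H), 1, 10),
                   image = sample(1:10, nrow(H), replace = TRUE))
}
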