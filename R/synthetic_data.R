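# Synthetic reflection-data generator: Wilson-distributed intensities with
# B-factor falloff, counting-statistics noise, injected non-Wilson outliers,
# injected Friedel differences, and multi-position sub-datasets.

# deterministic per-stage sub-seed from the one global seed, so adding a
# stage never perturbs another stage's draws
derive_seed <- function(seed, label) {
  cp <- utf8ToInt(label)
  h <- sum(cp * seq_along(cp))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Configuration of the synthetic-data generator
#'
#' The stated world every test runs in: acentric Wilson (exponential)
#' intensities with mean `scale * exp(-2 * b_factor * s^2)`, s = 1/(2d);
#' per-observation Gaussian noise with sigma = sqrt(max(I,0) +
#' noise_floor^2) approximating counting statistics; optional non-Wilson
#' outliers at `outlier_z` times the Wilson mean; optional Friedel
#' amplitude differences of relative size `anomalous_delta`.
#'
#' @param cell a [unit_cell()]
#' @param group_symbol registry symmetry symbol
#' @param d_min high-resolution limit of generated indices (A)
#' @param b_factor Wilson B (A^2), default 20
#' @param scale overall intensity scale, default 1000
#' @param noise_floor additive noise floor in sigma units, default 5
#' @param multiplicity observations generated per unique reflection (per
#'   Friedel mate when `friedel = "separate"`), default 4
#' @param outlier_fraction fraction of observations replaced by outliers
#' @param outlier_z intensity of injected outliers in units of the Wilson
#'   mean at their resolution, default 100
#' @param anomalous_fraction fraction of unique reflections carrying an
#'   injected Friedel difference, default 0
#' @param anomalous_delta relative amplitude difference |F+ - F-| / F for
#'   injected reflections, default 0
#' @param friedel `"merged"` (one mate per unique) or `"separate"` (both
#'   mates generated)
#' @param n_images,oscillation_range,starting_angle acquisition metadata
#' @param dataset_id dataset label
#' @param seed global seed; fixes the entire output stream
#' @return list of class `synthetic_config`
#' @export
synthetic_config <- function(cell, group_symbol = "P1", d_min = 2,
                             b_factor = 20, scale = 1000, noise_floor = 5,
                             multiplicity = 4, outlier_fraction = 0,
                             outlier_z = 100, anomalous_fraction = 0,
                             anomalous_delta = 0,
                             friedel = c("merged", "separate"),
                             n_images = 100L, oscillation_range = 1,
                             starting_angle = 0, dataset_id = "synth1",
                             seed = 1L) {
  friedel <- match.arg(friedel)
  stopifnot(d_min > 0, scale > 0, multiplicity >= 1,
            outlier_fraction >= 0, outlier_fraction <= 1,
            anomalous_fraction >= 0, anomalous_fraction <= 1,
            anomalous_delta >= 0, noise_floor >= 0)
  structure(as.list(environment()), class = "synthetic_config")
}

# the shared ground truth: unique indices, Wilson means, true intensities,
# per-mate true intensities after anomalous injection
.synth_truth <- function(config) {
  cell <- config$cell
  group <- sym_group(config$group_symbol)
  uniq <- enumerate_unique(cell, group, d_min = config$d_min,
                           friedel_merged = TRUE)
  data.table::setorder(uniq, -d, h, k, l)
  nu <- nrow(uniq)
  s2 <- 1 / (2 * uniq$d)^2
  mean_i <- config$scale * exp(-2 * config$b_factor * s2)

  set.seed(derive_seed(config$seed, "true_intensities"))
  true_i <- stats::rexp(nu) * mean_i

  set.seed(derive_seed(config$seed, "anomalous"))
  anom <- rep(FALSE, nu)
  if (config$anomalous_fraction > 0 && config$anomalous_delta > 0)
    anom[sample.int(nu, round(config$anomalous_fraction * nu))] <- TRUE
  f <- sqrt(true_i)
  list(group = group, uniq = uniq, nu = nu, mean_i = mean_i,
       true_i = true_i, anom = anom,
       i_plus = (f * ifelse(anom, 1 + config$anomalous_delta / 2, 1))^2,
       i_minus = (f * ifelse(anom, 1 - config$anomalous_delta / 2, 1))^2)
}

# emit noisy observations for a subset of the truth's unique reflections;
# seed_label names this emission's random stream
.emit_observations <- function(truth, config, subset, seed_label,
                               scale_factor = 1, dataset_id = config$dataset_id) {
  m <- as.integer(config$multiplicity)
  sides <- if (config$friedel == "separate") c(1L, -1L) else 1L
  obs <- data.table::rbindlist(lapply(sides, function(sg) {
    i_side <- if (sg == 1L) truth$i_plus[subset] else truth$i_minus[subset]
    data.table::data.table(u = rep(subset, each = m), sign = sg,
                           i_true = rep(i_side, each = m))
  }))

  # carry each observation on a random symmetry mate of its canonical index
  set.seed(derive_seed(config$seed, paste0(seed_label, ":mates")))
  H <- as.matrix(truth$uniq[obs$u, c("h", "k", "l")])
  ops <- truth$group$rotations
  if (length(ops) > 1) {
    op_idx <- sample.int(length(ops), nrow(obs), replace = TRUE)
    for (j in seq_along(ops)[-1]) {
      w <- op_idx == j
      if (any(w)) H[w, ] <- H[w, , drop = FALSE] %*% t(ops[[j]])
    }
  }
  H <- H * obs$sign

  set.seed(derive_seed(config$seed, paste0(seed_label, ":noise")))
  sig <- sqrt(pmax(obs$i_true, 0) + config$noise_floor^2)
  i_obs <- obs$i_true + stats::rnorm(nrow(obs)) * sig

  set.seed(derive_seed(config$seed, paste0(seed_label, ":outliers")))
  n_out <- round(config$outlier_fraction * nrow(obs))
  out_rows <- if (n_out > 0) sort(sample.int(nrow(obs), n_out)) else integer(0)
  if (length(out_rows))
    i_obs[out_rows] <- config$outlier_z * truth$mean_i[obs$u[out_rows]]

  table <- reflection_table(
    h = H[, 1], k = H[, 2], l = H[, 3],
    intensity = i_obs * scale_factor, sigma = sig * scale_factor,
    image = ((seq_len(nrow(obs)) - 1L) %% config$n_images) + 1L,
    dataset_id = dataset_id)
  list(table = table, outlier_rows = out_rows)
}

#' Generate a synthetic reflection dataset
#'
#' Enumerates unique indices to `d_min`, draws per-reflection true
#' intensities from the acentric Wilson law, emits `multiplicity` noisy
#' observations per unique index (each observation carried on a randomly
#' chosen symmetry mate so canonicalization is exercised), assigns
#' observations to images cyclically, and optionally injects Friedel
#' differences and non-Wilson outliers.  Fully deterministic given
#' `config$seed`.
#'
#' @param config a [synthetic_config()]
#' @return list: `header` ([dataset_header()]), `table` (reflection table),
#'   `truth` (generator bookkeeping: model parameters, per-unique true
#'   intensities, injected outlier row ids, injected anomalous unique ids,
#'   the written intensity sum)
#' @export
generate_dataset <- function(config) {
  tr <- .synth_truth(config)
  em <- .emit_observations(tr, config, seq_len(tr$nu), "main")
  header <- dataset_header(config$cell, config$group_symbol,
                           oscillation_range = config$oscillation_range,
                           starting_angle = config$starting_angle,
                           n_images = config$n_images,
                           dataset_id = config$dataset_id)
  truth <- list(b_factor = config$b_factor, scale = config$scale,
                noise_floor = config$noise_floor,
                n_unique = tr$nu,
                unique_hkl = tr$uniq[, c("h", "k", "l", "d")],
                true_intensity = tr$true_i,
                wilson_mean = tr$mean_i,
                anomalous_unique = which(tr$anom),
                anomalous_delta = config$anomalous_delta,
                outlier_rows = em$outlier_rows,
                sum_intensity = sum(em$table$intensity))
  list(header = header, table = em$table, truth = truth)
}

#' Generate grouped sub-datasets from one underlying truth
#'
#' Emulates multiple small wedges collected at different positions: all
#' sub-datasets share one set of true intensities (one structure), and only
#' the measurement noise, coverage, scale and indexing convention differ.
#' `"disjoint_wedges"` partitions the unique reflections into k
#' pairwise-disjoint index-space sectors, so merged completeness strictly
#' increases as sub-datasets are added; `"random"` gives each sub-dataset
#' an overlapping random subset (`subset_fraction` of the uniques), the
#' regime where indexing-ambiguity resolution has common reflections to
#' work with.  Each sub-dataset gets its own multiplicative scale factor
#' and, optionally, an indexing-ambiguity operator applied to all its
#' indices (recorded in the truth).
#'
#' @param config a [synthetic_config()]
#' @param k number of sub-datasets, >= 1
#' @param coverage_scheme `"disjoint_wedges"` or `"random"`
#' @param scale_factors per-dataset scale factors (length k, default 1)
#' @param applied_ops integer vector (length k): 0 = identity, j > 0 = the
#'   group's j-th ambiguity operator, applied to that sub-dataset's indices
#' @param subset_fraction fraction of uniques per sub-dataset under the
#'   random scheme, default 0.6
#' @return list: `subs` (list of [sub_dataset()] in collection order),
#'   `truth` (shared dataset truth plus per-dataset membership, scales and
#'   applied operators)
#' @export
generate_subdatasets <- function(config, k,
                                 coverage_scheme = c("disjoint_wedges", "random"),
                                 scale_factors = rep(1, k),
                                 applied_ops = rep(0L, k),
                                 subset_fraction = 0.6) {
  coverage_scheme <- match.arg(coverage_scheme)
  stopifnot(k >= 1, length(scale_factors) == k, length(applied_ops) == k)
  tr <- .synth_truth(config)
  nu <- tr$nu
  if (coverage_scheme == "disjoint_wedges" && k > nu)
    stop("k exceeds available sectors: ", k, " > ", nu, " unique reflections")

  membership <- vector("list", k)
  if (coverage_scheme == "disjoint_wedges") {
    # index-space sectors: block split of the (h,k,l)-sorted unique list
    ord <- order(tr$uniq$h, tr$uniq$k, tr$uniq$l)
    membership <- lapply(unname(split(ord, ceiling(seq_len(nu) * k / nu))),
                         sort)
  } else {
    set.seed(derive_seed(config$seed, "coverage"))
    for (i in seq_len(k))
      membership[[i]] <- sort(sample.int(nu, max(1, round(subset_fraction * nu))))
  }

  subs <- vector("list", k)
  for (i in seq_len(k)) {
    id <- if (k == 1L) config$dataset_id
          else sprintf("%s_pos%02d", config$dataset_id, i)
    # a single sub-dataset IS the dataset: reuse the main stream so k = 1
    # reproduces generate_dataset() exactly
    em <- .emit_observations(tr, config, membership[[i]],
                             seed_label = if (k == 1L) "main"
                                          else sprintf("sub%d", i),
                             scale_factor = scale_factors[i],
                             dataset_id = id)
    tab <- em$table
    if (applied_ops[i] > 0L)
      tab <- apply_operator(tab, tr$group$ambiguity_ops[[applied_ops[i]]])
    subs[[i]] <- sub_dataset(id, tab, config$cell,
                             lattice_symbol = tr$group$bravais_lattice,
                             position = sprintf("position %d", i))
  }
  truth <- list(b_factor = config$b_factor, scale = config$scale,
                n_unique = nu, unique_hkl = tr$uniq[, c("h", "k", "l", "d")],
                true_intensity = tr$true_i,
                membership = membership,
                scale_factors = scale_factors, applied_ops = applied_ops,
                coverage_scheme = coverage_scheme)
  list(subs = subs, truth = truth)
}
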