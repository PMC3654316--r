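mk_sub <- function(id, cell, lattice, group_symbol = "P2", seed = 1) {
  cfg <- synthetic_config(cell, group_symbol, d_min = 3, multiplicity = 2,
                          dataset_id = id, seed = seed)
  sub_dataset(id, generate_dataset(cfg)$table, cell, lattice)
}

test_that("lattice consistency verdicts follow the symbol + metric rule", {
  cell <- unit_cell(20, 25, 30, beta = 105)
  g <- sym_group("P2")  # mP
  subs <- list(mk_sub("a", cell, "mP"),
               mk_sub("b", unit_cell(20.1, 25.05, 29.9, beta = 104.5), "mP"),
               mk_sub("c", cell, "mP"))
  expect_equal(check_lattice_consistency(subs, g, cell),
               rep("matched", 3))
  # an aP-labelled sub-dataset among mP consensus is re-integrated
  subs[[2]]$lattice_symbol <- "aP"
  expect_equal(check_lattice_consistency(subs, g, cell)[2], "re_integrated")
  # 15% edge mismatch is excluded outright
  subs[[3]]$cell <- unit_cell(23, 25, 30, beta = 105)
  expect_equal(check_lattice_consistency(subs, g, cell)[3], "excluded")
})

test_that("choose_reference takes the first matched, then first usable", {
  subs <- list(list(dataset_id = "d1"), list(dataset_id = "d2"),
               list(dataset_id = "d3"))
  expect_equal(choose_reference(subs, c("re_integrated", "matched", "matched")),
               "d2")
  expect_equal(choose_reference(subs, c("matched", "matched", "matched")),
               "d1")
  expect_equal(choose_reference(subs, c("re_integrated", "excluded",
                                        "re_integrated")), "d1")
  expect_error(choose_reference(subs, rep("excluded", 3)), "no reference")
})

test_that("resolve_indexing recovers applied ambiguity operators", {
  cell <- unit_cell(22, 22, 30)
  g <- sym_group("P4")
  cfg <- synthetic_config(cell, "P4", d_min = 2.6, scale = 5000,
                          noise_floor = 4, multiplicity = 2, seed = 17)
  # sub 2 carries the tetragonal twofold (k, h, -l); recover it
  gs <- generate_subdatasets(cfg, 2, "random", applied_ops = c(0L, 1L))
  r <- resolve_indexing(gs$subs[[2]], gs$subs[[1]], g)
  expect_identical(r$operator, g$ambiguity_ops[[1]])
  expect_gt(r$correlation, 0.9)
  # identity-indexed copy resolves to identity
  r0 <- resolve_indexing(gs$subs[[1]], gs$subs[[1]], g)
  expect_identical(r0$operator, diag(3))
  expect_equal(r0$correlation, 1)
  # a group without ambiguity operators always returns identity
  g222 <- sym_group("P222")
  cfg2 <- synthetic_config(unit_cell(18, 20, 24), "P222", d_min = 3, seed = 18)
  gs2 <- generate_subdatasets(cfg2, 2, "random")
  r2 <- resolve_indexing(gs2$subs[[2]], gs2$subs[[1]], g222)
  expect_identical(r2$operator, diag(3))
  # insufficient overlap is an error
  expect_error(resolve_indexing(gs$subs[[2]]$table[1:3],
                                gs$subs[[1]]$table[1:3], g,
                                min_overlap = 10),
               "insufficient overlap")
})

test_that("apply-and-recover succeeds across all ambiguous registry groups", {
  reg <- load_symmetry_registry()
  ambiguous <- names(reg)[vapply(reg, function(g)
    length(g$ambiguity_ops) > 0, logical(1))]
  expect_true(length(ambiguous) >= 4)
  cells <- list(tP = unit_cell(20, 20, 28), hP = unit_cell(20, 20, 28, gamma = 120),
                cP = unit_cell(22, 22, 22))
  for (sym in ambiguous) {
    g <- reg[[sym]]
    cell <- cells[[g$bravais_lattice]]
    for (opi in seq_along(g$ambiguity_ops)) {
      cfg <- synthetic_config(cell, sym, d_min = 3, scale = 8000,
                              noise_floor = 3, multiplicity = 2,
                              seed = 100 + opi)
      gs <- generate_subdatasets(cfg, 2, "random",
                                 applied_ops = c(0L, opi))
      r <- resolve_indexing(gs$subs[[2]], gs$subs[[1]], g)
      expect_identical(r$operator, g$ambiguity_ops[[opi]])
    }
  }
})

test_that("merging k copies keeps completeness, multiplies multiplicity", {
  cell <- unit_cell(16, 18, 20)
  g <- sym_group("P1")
  cfg <- synthetic_config(cell, "P1", d_min = 3, seed = 19)
  ds <- generate_dataset(cfg)
  k <- 3
  subs <- lapply(seq_len(k), function(i)
    sub_dataset(paste0("c", i), ds$table, cell, "aP"))
  mg <- merge_grouped(subs, g, cell, n_shells = 4)
  first <- mg$increments[[1]]$overall
  last <- mg$increments[[k]]$overall
  expect_equal(last$completeness, first$completeness)
  expect_equal(last$multiplicity, k * first$multiplicity)
  expect_equal(mg$reference_id, "c1")
  expect_identical(mg$datasets$operator[[1]], diag(3))
})

test_that("disjoint wedges give strictly increasing completeness", {
  cell <- unit_cell(18, 20, 22)
  g <- sym_group("P1")
  cfg <- synthetic_config(cell, "P1", d_min = 2.6, seed = 20)
  gs <- generate_subdatasets(cfg, 5, "disjoint_wedges")
  mg <- merge_grouped(gs$subs, g, cell, n_shells = 5)
  compl <- vapply(mg$increments, function(i) i$overall$completeness, 0)
  mult <- vapply(mg$increments, function(i) i$overall$multiplicity, 0)
  expect_length(compl, 5)
  expect_true(all(diff(compl) > 0))
  expect_true(all(diff(mult) >= -1e-12))
  expect_equal(compl[5], 100)
})

test_that("a single sub-dataset yields one increment equal to its own stats", {
  cell <- unit_cell(16, 18, 20)
  g <- sym_group("P1")
  cfg <- synthetic_config(cell, "P1", d_min = 3, seed = 21)
  gs <- generate_subdatasets(cfg, 1, "disjoint_wedges")
  mg <- merge_grouped(gs$subs, g, cell, n_shells = 4)
  expect_length(mg$increments, 1)
  direct <- compute_shell_stats(gs$subs[[1]]$table, cell, g, TRUE,
                                edges = mg$edges)
  expect_equal(mg$increments[[1]]$shells$r_merge, direct$r_merge)
  expect_equal(mg$increments[[1]]$shells$completeness, direct$completeness)
})

test_that("final merged statistics are order-invariant", {
  cell <- unit_cell(18, 20, 22)
  g <- sym_group("P1")
  cfg <- synthetic_config(cell, "P1", d_min = 2.8, seed = 22)
  gs <- generate_subdatasets(cfg, 3, "random")
  # rescale off: the estimated scale depends on which dataset is the
  # reference, which would break exact order invariance
  mg1 <- merge_grouped(gs$subs, g, cell, n_shells = 4, rescale = FALSE)
  mg2 <- merge_grouped(gs$subs[c(3, 1, 2)], g, cell, n_shells = 4,
                       edges = mg1$edges, rescale = FALSE)
  f1 <- mg1$increments[[3]]$overall
  f2 <- mg2$increments[[3]]$overall
  expect_equal(f1$r_merge, f2$r_merge, tolerance = 1e-9)
  expect_equal(f1$completeness, f2$completeness, tolerance = 1e-9)
  expect_equal(f1$multiplicity, f2$multiplicity, tolerance = 1e-9)
})

test_that("per-dataset scale factors are undone by reference rescaling", {
  cell <- unit_cell(18, 20, 22)
  g <- sym_group("P1")
  cfg <- synthetic_config(cell, "P1", d_min = 2.8, scale = 4000,
                          noise_floor = 3, seed = 23)
  gs <- generate_subdatasets(cfg, 3, "random", scale_factors = c(1, 5, 0.2))
  mg <- merge_grouped(gs$subs, g, cell, n_shells = 4)
  expect_equal(mg$datasets$scale[1], 1)
  expect_equal(mg$datasets$scale[2], 1 / 5, tolerance = 0.1)
  expect_equal(mg$datasets$scale[3], 1 / 0.2, tolerance = 0.1)
  # merged r_merge stays at the noise level, not at the scale mismatch
  expect_lt(mg$increments[[3]]$overall$r_merge, 0.15)
})
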