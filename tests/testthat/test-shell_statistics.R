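test_that("assign_shells produces equal reciprocal-volume bins", {
  cell <- unit_cell(30, 30, 30)
  tab <- tiny_table()
  one <- assign_shells(tab, cell, n_shells = 1)
  expect_true(all(one$bin == 1L))
  expect_length(one$edges, 2)

  # 10 shells between 1.5 and 30 A: constant 1/d^3 increments
  edges <- reflexio:::shell_edges(30, 1.5, 10)
  incr <- diff(1 / edges^3)
  expect_equal(incr, rep(incr[1], 10), tolerance = 1e-9)
  expect_true(all(diff(edges) < 0))
  expect_error(assign_shells(tab[0], cell), "empty")
})

test_that("uniform-in-volume reflections fill shells evenly", {
  # a complete enumeration is (asymptotically) uniform in reciprocal volume
  cell <- unit_cell(40, 40, 40)
  uniq <- enumerate_unique(cell, sym_group("P1"), d_min = 2.5)
  tab <- reflection_table(uniq$h, uniq$k, uniq$l,
                          intensity = 1, sigma = 1)
  sh <- assign_shells(tab, cell, n_shells = 8)
  counts <- tabulate(sh$bin, 8)
  expected <- nrow(tab) / 8
  # multinomial-scale tolerance (generous: shell edges quantize the lattice)
  expect_true(all(abs(counts - expected) < 6 * sqrt(expected)))
})

test_that("r_merge and r_meas match hand computation", {
  cell <- unit_cell(10, 10, 10)
  g <- sym_group("P1")
  # one group of two equal intensities
  tab <- reflection_table(c(1, -1), c(2, -2), c(3, -3), c(50, 50), c(5, 5))
  sh <- compute_shell_stats(tab, cell, g, TRUE, n_shells = 1)
  expect_equal(sh$r_merge, 0)
  expect_equal(sh$r_meas, 0)
  expect_equal(sh$multiplicity, 2)
  # I = {10, 20}: r_merge = 1/3, r_meas = sqrt(2)/3
  tab2 <- reflection_table(c(1, -1), c(2, -2), c(3, -3), c(10, 20), c(1, 2))
  sh2 <- compute_shell_stats(tab2, cell, g, TRUE, n_shells = 1)
  expect_equal(sh2$r_merge, 1 / 3)
  expect_equal(sh2$r_meas, sqrt(2) / 3)
  # the lone-group singleton contributes to neither numerator nor denominator
  tab3 <- rbind(tab2, reflection_table(2, 0, 0, 99, 1))
  sh3 <- compute_shell_stats(tab3, cell, g, TRUE, n_shells = 1)
  expect_equal(sh3$r_merge, 1 / 3)
})

test_that("full-sphere synthetic data is 100% complete in every shell", {
  cfg <- synthetic_config(unit_cell(18, 20, 22), "P1", d_min = 2.0, seed = 2)
  ds <- generate_dataset(cfg)
  sh <- compute_shell_stats(ds$table, cfg$cell, sym_group("P1"), TRUE,
                            n_shells = 10)
  expect_equal(sh$completeness, rep(100, 10))
  expect_true(all(sh$r_meas >= sh$r_merge))
  expect_true(all(sh$r_merge >= 0))
  expect_true(all(sh$multiplicity >= 1))
})

test_that("duplicating every observation fixes r_merge, doubles multiplicity", {
  set.seed(11)
  cell <- unit_cell(8, 9, 10)
  g <- sym_group("P2")
  # every canonical group multiply-observed (r_merge denominator convention
  # counts only such groups, so singletons entering it would shift r_merge)
  half <- random_table(g)
  jit <- data.table::copy(half)
  jit$intensity <- jit$intensity + rnorm(nrow(jit), 0, 5)
  tab <- rbind(half, jit)
  sh1 <- compute_shell_stats(tab, cell, g, TRUE, n_shells = 2)
  sh2 <- compute_shell_stats(rbind(tab, tab), cell, g, TRUE,
                             edges = c(sh1$d_max[1], sh1$d_min))
  expect_equal(sh2$r_merge, sh1$r_merge, tolerance = 1e-12)
  expect_equal(sh2$completeness, sh1$completeness)
  expect_equal(sh2$multiplicity, 2 * sh1$multiplicity)
})

test_that("completeness is monotone in added observations", {
  cfg <- synthetic_config(unit_cell(15, 16, 18), "P1", d_min = 2.5, seed = 9)
  ds <- generate_dataset(cfg)
  g <- sym_group("P1")
  full <- compute_shell_stats(ds$table, cfg$cell, g, TRUE, n_shells = 4)
  part <- compute_shell_stats(ds$table[seq_len(nrow(ds$table) %/% 3)],
                              cfg$cell, g, TRUE,
                              edges = c(full$d_max[1], full$d_min))
  expect_true(all(part$completeness <= full$completeness + 1e-12))
})

test_that("I/sigma falls with resolution on B-damped data", {
  cfg <- synthetic_config(unit_cell(20, 22, 25), "P1", d_min = 2.0,
                          b_factor = 25, scale = 4000, noise_floor = 6,
                          seed = 4)
  ds <- generate_dataset(cfg)
  sh <- compute_shell_stats(ds$table, cfg$cell, sym_group("P1"), TRUE,
                            n_shells = 10)
  # strong monotone trend: rank correlation near -1
  expect_lt(cor(sh$shell, sh$mean_i_over_sigma, method = "spearman"), -0.9)
  expect_gt(sh$mean_i_over_sigma[1], 2 * sh$mean_i_over_sigma[10])
})

test_that("overall stats are recomputed from pooled observations", {
  set.seed(21)
  cell <- unit_cell(8, 9, 10)
  g <- sym_group("P222")
  tab <- random_table(g)
  sh <- compute_shell_stats(tab, cell, g, TRUE, n_shells = 3)
  ov <- overall_stats(tab, cell, g, TRUE, edges = c(sh$d_max[1], sh$d_min[3]))
  expect_equal(ov$n_obs, sum(sh$n_obs))
  # pooled r_merge equals a single-shell computation on the full table
  direct <- compute_shell_stats(tab, cell, g, TRUE,
                                edges = c(sh$d_max[1], sh$d_min[3]))
  expect_equal(ov$r_merge, direct$r_merge, tolerance = 1e-15)
  expect_true(is.na(ov$shell))
  # with one shell, overall equals that shell
  sh1 <- compute_shell_stats(tab, cell, g, TRUE, n_shells = 1)
  expect_equal(ov$r_merge, sh1$r_merge, tolerance = 1e-15)
})
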