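test_that("d_spacing matches axis geometry and rejects bad input", {
  cubic <- unit_cell(10, 10, 10)
  expect_equal(d_spacing(c(1, 0, 0), cubic), 10)
  expect_equal(d_spacing(c(0, 2, 0), cubic), 5)
  expect_error(d_spacing(c(0, 0, 0), cubic), "no d-spacing")
  expect_error(unit_cell(10, -1, 10), "lengths")
  expect_error(unit_cell(10, 10, 10, alpha = 0), "angles")
  # degenerate metric: angle combination with non-positive volume
  expect_error(unit_cell(10, 10, 10, alpha = 45, beta = 45, gamma = 120),
               "positive definite")
})

test_that("d_spacing agrees with direct-lattice-vector oracle on triclinic", {
  cell <- unit_cell(10, 12, 15, alpha = 85, beta = 95, gamma = 100)
  for (hkl in list(c(1, 2, 3), c(-2, 1, 4), c(3, -3, 1), c(0, 0, 5))) {
    expect_equal(d_spacing(hkl, cell),
                 oracle_d_spacing(hkl, 10, 12, 15, 85, 95, 100),
                 tolerance = 1e-12)
  }
})

test_that("registry groups satisfy the group axioms", {
  reg <- load_symmetry_registry()
  expect_true(length(reg) >= 10)
  for (g in reg) {
    keys <- vapply(g$rotations, function(m) paste(m, collapse = ","), "")
    expect_true(paste(diag(3), collapse = ",") %in% keys)
    for (a in g$rotations) for (b in g$rotations)
      expect_true(paste(a %*% b, collapse = ",") %in% keys)
    for (m in c(g$rotations, g$laue_ops, g$ambiguity_ops))
      expect_equal(abs(det(m)), 1)
    # ambiguity ops sit outside the Laue group
    lkeys <- vapply(g$laue_ops, function(m) paste(m, collapse = ","), "")
    for (t in g$ambiguity_ops)
      expect_false(paste(t, collapse = ",") %in% lkeys)
  }
})

test_that("d_spacing is invariant under every registry rotation", {
  cellpars <- list(P1 = unit_cell(10, 12, 15, 85, 95, 100),
                   P2 = unit_cell(10, 12, 15, beta = 102),
                   P222 = unit_cell(10, 12, 15),
                   P4 = unit_cell(10, 10, 15),
                   P3 = unit_cell(10, 10, 15, gamma = 120),
                   P6 = unit_cell(10, 10, 15, gamma = 120),
                   P23 = unit_cell(10, 10, 10))
  triples <- list(c(1, 2, 3), c(-1, 3, 2), c(2, 0, -1))
  for (sym in names(cellpars)) {
    g <- sym_group(sym)
    cell <- cellpars[[sym]]
    for (hkl in triples) for (R in g$rotations)
      expect_equal(d_spacing(as.integer(R %*% hkl), cell),
                   d_spacing(hkl, cell), tolerance = 1e-12)
  }
})

test_that("canonicalize collapses Friedel pairs and symmetry orbits", {
  p1 <- sym_group("P1")
  cm <- canonicalize(rbind(c(1, 2, 3), c(-1, -2, -3)), p1, friedel_merged = TRUE)
  expect_equal(cm$hkl[1, ], cm$hkl[2, ])
  cs <- canonicalize(rbind(c(1, 2, 3), c(-1, -2, -3)), p1, friedel_merged = FALSE)
  expect_equal(cs$hkl[1, ], cs$hkl[2, ])
  expect_equal(sort(cs$sign), c(-1L, 1L))

  # full orbit of (1,2,3) in P222 collapses to one representative that
  # matches explicit matrix enumeration
  g <- sym_group("P222")
  orb <- oracle_orbit(c(1, 2, 3), g$rotations, friedel_merged = TRUE)
  expect_equal(nrow(orb), 8)
  cn <- canonicalize(orb, g, friedel_merged = TRUE)
  expect_equal(nrow(unique(cn$hkl)), 1)
  expect_equal(cn$hkl[1, ], oracle_canonical(c(1, 2, 3), g$rotations, TRUE))
})

test_that("canonicalization is idempotent and deterministic across groups", {
  set.seed(42)
  H <- matrix(sample(-6:6, 300, replace = TRUE), ncol = 3)
  H <- H[rowSums(H != 0) > 0, ]
  for (sym in c("P1", "P2", "P222", "P4", "P422", "P3", "P321", "P6", "P23")) {
    g <- sym_group(sym)
    for (fm in c(TRUE, FALSE)) {
      c1 <- canonicalize(H, g, fm)
      c2 <- canonicalize(c1$hkl, g, fm)
      expect_equal(c1$hkl, c2$hkl)
      if (!fm) expect_true(all(c2$sign == 1L))  # representatives are + side
    }
    # every orbit member maps to the oracle representative
    for (i in sample(nrow(H), 5)) {
      want <- oracle_canonical(H[i, ], g$rotations, TRUE)
      got <- canonicalize(H[i, , drop = FALSE], g, TRUE)$hkl[1, ]
      expect_equal(got, want)
    }
  }
})

test_that("enumerate_unique matches the exhaustive-loop oracle", {
  cubic <- unit_cell(10, 10, 10)
  p1 <- sym_group("P1")
  # 5-10 A shell on a 10 A cube: all |h|,|k|,|l| <= 2
  got <- enumerate_unique(cubic, p1, d_min = 5, d_max = 10)
  expect_equal(nrow(got),
               oracle_unique_count(c(10, 10, 10, 90, 90, 90),
                                   p1$rotations, 5, 10))
  # shell excluding every reflection (axes have d = 10 at most)
  expect_equal(nrow(enumerate_unique(cubic, p1, d_min = 11, d_max = 20)), 0)
  expect_error(enumerate_unique(cubic, p1, d_min = -1, d_max = 5),
               "invalid range")
  expect_error(enumerate_unique(cubic, p1, d_min = 5, d_max = 5),
               "invalid range")
  # higher symmetry collapses orbits: count(P2) <= count(P1)
  p2 <- sym_group("P2")
  expect_lte(nrow(enumerate_unique(cubic, p2, d_min = 3)),
             nrow(enumerate_unique(cubic, p1, d_min = 3)))
  # oracle agreement down to 3 A for a symmetric group too
  expect_equal(nrow(enumerate_unique(cubic, p2, d_min = 3, d_max = 10)),
               oracle_unique_count(c(10, 10, 10, 90, 90, 90),
                                   p2$rotations, 3, 10))
})

test_that("reflection_table enforces its invariants", {
  expect_error(reflection_table(0, 0, 0, 10, 1), "0,0,0")
  expect_error(reflection_table(1, 0, 0, 10, 0), "sigma")
  expect_error(reflection_table(1, 0, 0, 10, 1, image = 0), "image")
  tab <- tiny_table()
  expect_equal(nrow(tab), 5)
  expect_silent(validate_reflection_table(tab))
})
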