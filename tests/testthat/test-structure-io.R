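test_that("CIF write/read round-trips coordinates, elements and cell", {
  s <- build_pair("UU_mWW_(23)(32)")
  f <- withr::local_tempfile(fileext = ".cif")
  write_structure(s, f)
  s2 <- read_structure(f)
  expect_equal(s2$atoms$element, s$atoms$element)
  expect_lt(max(abs(coords(s2) - coords(s))), 1e-3)
  expect_false(is.null(s2$cell))  # dummy P1 cell emitted for cell-less input

  p1 <- build_pair_p1bar("UU_mWW_(34)(43)")
  f2 <- withr::local_tempfile(fileext = ".cif")
  write_structure(p1, f2)
  p2 <- read_structure(f2)
  expect_equal(p2$cell$a, p1$cell$a, tolerance = 1e-6)
  expect_equal(length(p2$cell$symops), 2)
  expect_lt(max(abs(coords(p2) - coords(p1))), 1e-3)
})

test_that("PDB write/read round-trips, and CRYST1 is optional", {
  s <- build_pair("AA_mHH_(67)(76)")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f)
  expect_equal(s2$atoms$element, s$atoms$element)
  expect_lt(max(abs(coords(s2) - coords(s))), 1e-3)
  expect_null(s2$cell)  # no CRYST1 written for a cell-less structure
})

test_that("symmetry operator strings parse to fractional matrices", {
  op <- parse_symop("-x, y+1/2, -z+1/2")
  expect_equal(op$R, diag(c(-1, 1, -1)))
  expect_equal(op$t, c(0, 0.5, 0.5))
  expect_equal(parse_symop("x,y,z")$R, diag(3))
  expect_error(parse_symop("x; y; z"))
})

test_that("disorder keeps the highest-occupancy group", {
  f <- withr::local_tempfile(fileext = ".cif")
  disorder_cif(f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 2)
  expect_setequal(s$atoms$label, c("C1", "N1A"))
})

test_that("bond inference follows covalent radii plus tolerance", {
  at <- data.frame(label = c("C1", "N1", "N2"), element = c("C", "N", "N"),
                   x = c(0, 1.34, 4.24), y = 0, z = 0)
  s <- infer_bonds(crystal_structure("t", at))
  # C-N at 1.34 <= 0.76 + 0.71 + 0.4; N...N at 2.9 is far beyond 1.82
  expect_equal(nrow(s$bonds), 1)
  expect_setequal(as.vector(s$bonds), c(1, 2))

  at2 <- rbind(at, data.frame(label = "H9", element = "H", x = 9, y = 0, z = 0))
  expect_warning(s2 <- infer_bonds(crystal_structure("t2", at2)),
                 "orphan hydrogen")
  expect_equal(nrow(s2$atoms), 3)  # orphan H dropped
})

test_that("explicit CIF bond tables take precedence over inference", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_explicit",
    "_cell_length_a 20", "_cell_length_b 20", "_cell_length_c 20",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "C1 C 0.1 0.1 0.1", "N1 N 0.167 0.1 0.1", "O1 O 0.4 0.4 0.4",
    "loop_", "_geom_bond_atom_site_label_1", "_geom_bond_atom_site_label_2",
    "C1 N1"), f)
  s <- read_structure(f)
  expect_true(s$meta$bonds_explicit)
  s <- infer_bonds(s)
  expect_equal(nrow(s$bonds), 1)
})

test_that("symmetry expansion finds translational and inversion mates", {
  # single base in a tight P1 cell: brute-force count of images in range
  b <- ideal_base("C", "free", "1H 3")
  cell <- list(a = 8, b = 9, c = 10, alpha = 90, beta = 90, gamma = 90)
  s <- crystal_structure("p1", b$atoms, cell = cell)
  e <- expand_symmetry(s, radius = 6)
  n_au <- sum(!e$atoms$is_mate)
  expect_equal(n_au, nrow(b$atoms))
  # oracle: count +-2 cell translations bringing any atom within 6 A
  xyz <- coords(s)
  cnt <- 0
  for (i in -2:2) for (j in -2:2) for (k in -2:2) {
    if (i == 0 && j == 0 && k == 0) next
    shifted <- sweep(xyz, 2, c(i * 8, j * 9, k * 10), "+")
    dmin <- min(pairdex:::.cross_dist(shifted, xyz))
    if (dmin <= 6) cnt <- cnt + 1
  }
  expect_equal(sum(e$atoms$is_mate) / nrow(b$atoms), cnt)
  # idempotence: expanding again adds nothing
  e2 <- expand_symmetry(e, radius = 6)
  expect_equal(nrow(e2$atoms), nrow(e$atoms))
  # radius zero: no mates
  e0 <- expand_symmetry(s, radius = 0)
  expect_false(any(e0$atoms$is_mate))
  expect_error(expand_symmetry(build_pair("AA_mWW_(12)(21)")), "no unit cell")
})

test_that("an inversion-wrapped half pair is regenerated and deduplicated", {
  for (nm in c("AA_mWW_(16)(61)", "CC_mSS_(12)(21)")) {
    s <- build_pair_p1bar(nm)
    prs <- detect_pairs(s)
    expect_length(prs, 1)
    expect_true(same_pair_name(prs[[1]]$name, parse_name(nm)))
    expect_true(prs[[1]]$symmetry_generated)
  }
})
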