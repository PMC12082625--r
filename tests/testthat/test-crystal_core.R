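test_that("unit cell validates its parameters and computes the metric", {
  cl <- unit_cell(10, 20, 30, 90, 90, 90)
  expect_equal(cl$volume, 6000)
  tric <- unit_cell(10, 12, 14, 80, 95, 103)
  ca <- cos(80 * pi / 180); cb <- cos(95 * pi / 180); cg <- cos(103 * pi / 180)
  expect_equal(tric$volume,
               10 * 12 * 14 * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
  expect_error(unit_cell(-1, 2, 3), "positive")
  expect_error(unit_cell(1, 2, 3, alpha = 190), "angles")
  # frac <-> cart inverse
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(frac_to_cart(cart_to_frac(x, tric), tric), x)
  # d-spacing of axial reflections in an orthorhombic cell
  expect_equal(d_spacing(rbind(c(1, 0, 0), c(0, 2, 0)), cl), c(10, 10))
})

test_that("a minimal one-atom PDB parses to the expected model", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 P 1",
    "HETATM    1 FE   SF4 A   1       0.000   0.000   0.000  1.00 20.00          FE",
    "END"), f)
  m <- read_model(f)
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$element, "Fe")
  expect_equal(unlist(m$atoms[, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))
  expect_equal(m$atoms$occ, 1)
  expect_equal(m$atoms$b_iso, 20)
})

test_that("model write/read round trips through PDB and mmCIF", {
  m <- tiny_model(3)
  # quantize to the PDB field precision so the round trip is exact
  m$atoms$x <- round(m$atoms$x, 3); m$atoms$y <- round(m$atoms$y, 3)
  m$atoms$z <- round(m$atoms$z, 3); m$atoms$b_iso <- round(m$atoms$b_iso, 2)
  fp <- withr::local_tempfile(fileext = ".pdb")
  write_model(m, fp)
  m2 <- read_model(fp)
  for (col in c("name", "element", "resname", "resid", "chain")) {
    expect_identical(m2$atoms[[col]], m$atoms[[col]])
  }
  for (col in c("x", "y", "z", "occ", "b_iso")) {
    expect_equal(unname(m2$atoms[[col]]), unname(m$atoms[[col]]))
  }
  expect_identical(is.na(m2$atoms$u11), is.na(m$atoms$u11))
  expect_lt(max(abs(m2$atoms$u11 - m$atoms$u11), na.rm = TRUE), 1e-4)
  expect_equal(unlist(m2$cell[1:6]), unlist(m$cell[1:6]))
  # independent reader agrees on the coordinates
  pb <- bio3d::read.pdb(fp)
  expect_equal(pb$atom$x, unname(m$atoms$x))
  expect_equal(pb$atom$b, unname(m$atoms$b_iso))
  fc <- withr::local_tempfile(fileext = ".cif")
  write_model(m, fc)
  m3 <- read_model(fc)
  expect_equal(unname(m3$atoms$x), unname(m$atoms$x), tolerance = 1e-4)
  expect_lt(max(abs(m3$atoms$u23 - m$atoms$u23), na.rm = TRUE), 1e-5)
  expect_identical(m3$atoms$name, m$atoms$name)
})

test_that("mmCIF anisotropic U entries populate Ueq = trace/3", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_test",
    "_cell.length_a 20", "_cell.length_b 20", "_cell.length_c 20",
    "_cell.angle_alpha 90", "_cell.angle_beta 90", "_cell.angle_gamma 90",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_comp_id",
    "_atom_site.label_asym_id", "_atom_site.label_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "HETATM 1 FE FE1 SF4 A 1 1.0 2.0 3.0 1.0 15.0",
    "loop_",
    "_atom_site_anisotrop.id", "_atom_site_anisotrop.type_symbol",
    "_atom_site_anisotrop.U[1][1]", "_atom_site_anisotrop.U[2][2]",
    "_atom_site_anisotrop.U[3][3]", "_atom_site_anisotrop.U[1][2]",
    "_atom_site_anisotrop.U[1][3]", "_atom_site_anisotrop.U[2][3]",
    "1 FE 0.030 0.020 0.010 0.005 -0.002 0.001"), f)
  m <- read_model(f)
  ueq <- (m$atoms$u11 + m$atoms$u22 + m$atoms$u33) / 3
  expect_equal(ueq, (0.030 + 0.020 + 0.010) / 3)  # hand sum
  ad <- adp_eigen(m)
  expect_equal(ad$ueq, 0.02)
})

test_that("structure factors obey origin-atom and centrosymmetry phases", {
  cl <- unit_cell(12, 12, 12)
  at <- tibble::tibble(name = "C1", element = "C", x = 0, y = 0, z = 0,
                       occ = 1, b_iso = 0)
  fc <- calc_structure_factors(crystal_model(cl, at), 2.5)
  expect_true(all(abs(fc$phi) < 1e-8))
  expect_equal(fc$f, scattering_factor("C", 1 / fc$d), ignore_attr = TRUE)
  # two identical atoms at x and -x: centric, phases 0 or 180
  at2 <- tibble::tibble(name = c("C1", "C2"), element = "C",
                        x = c(1.7, -1.7), y = c(0.9, -0.9), z = c(2.3, -2.3),
                        occ = 1, b_iso = 5)
  fc2 <- calc_structure_factors(crystal_model(cl, at2), 2.5)
  expect_true(all(abs(fc2$phi) < 1e-6 | abs(abs(fc2$phi) - 180) < 1e-6))
})

test_that("amplitudes scale exactly linearly with occupancy", {
  m <- tiny_model(2)
  m$atoms$occ <- 0.4
  f1 <- calc_structure_factors(m, 2.2)
  m$atoms$occ <- 0.8
  f2 <- calc_structure_factors(m, 2.2)
  expect_equal(f2$f, 2 * f1$f)
  expect_equal(f2$phi, f1$phi)
})

test_that("map synthesis satisfies Parseval and locates the heaviest atom", {
  m <- tiny_model(1)
  fc <- tiny_fc(1)
  map <- synthesize_map(fc)
  # Parseval: mean rho^2 = sum over the full (Friedel-complete) set / V^2
  expect_equal(mean(map$values^2), 2 * sum(fc$f^2) / m$cell$volume^2,
               tolerance = 1e-10)
  # global maximum within one voxel of an Fe atom
  idx <- which(map$values == max(map$values), arr.ind = TRUE)[1, ]
  peak <- frac_to_cart((idx - 1) / map$dims, m$cell)
  fe <- as.matrix(m$atoms[m$atoms$element == "Fe", c("x", "y", "z")])
  dmin <- min(sqrt(rowSums(sweep(fe, 2, as.vector(peak))^2)))
  expect_lt(dmin, max(c(m$cell$a, m$cell$b, m$cell$c) / map$dims) * sqrt(3))
})

test_that("all-zero coefficients give a flat zero map", {
  cl <- unit_cell(15, 15, 15)
  coeffs <- complex_sf_set(c(1, 2, 0), c(0, 1, 2), c(0, 0, 1),
                           f = c(0, 0, 0), phi = c(0, 0, 0), cl)
  map <- synthesize_map(coeffs, grid_spacing = 1)
  expect_true(all(map$values == 0))
  expect_equal(map$sigma, 0)
})

test_that("coarse grids are rejected with a Nyquist message", {
  fc <- tiny_fc(1)
  expect_error(synthesize_map(fc, grid_spacing = 3), "Nyquist")
  expect_error(synthesize_map(fc, dims = c(8, 8, 8)), "Nyquist")
})

test_that("synthesis and numerical back-transform are mutually inverse", {
  fc <- tiny_fc(2)
  map <- synthesize_map(fc)
  fb <- map_structure_factors(map, fc[, c("h", "k", "l")])
  rel <- abs(Mod(fb) - fc$f) / pmax(fc$f, 1e-9)
  expect_lt(max(rel), 0.005)
  dphi <- abs(((Arg(fb) * 180 / pi - fc$phi + 180) %% 360) - 180)
  expect_lt(max(dphi[fc$f > stats::median(fc$f)]), 1e-6)
})

test_that("region masks behave at both radius extremes", {
  m <- tiny_model(1)
  map <- synthesize_map(tiny_fc(1))
  # small radius: at least the nearest voxel per selected atom
  tiny_mask <- make_region_mask(map, m, list(element = "Fe"), 0.05)
  expect_gte(length(tiny_mask), 1L)
  # huge radius saturates the whole grid
  all_mask <- make_region_mask(map, m, seq_len(nrow(m$atoms)), 30)
  expect_equal(length(all_mask), prod(map$dims))
  expect_error(make_region_mask(map, m, list(resname = "NOPE"), 2),
               "no atom")
})

test_that("sphere masks match the analytic sphere volume", {
  cl <- unit_cell(20, 20, 20)
  at <- tibble::tibble(name = c("C1", "C2"), element = "C",
                       x = c(5, 11), y = 10, z = 10, occ = 1, b_iso = 10)
  m <- crystal_model(cl, at)
  fc <- calc_structure_factors(m, 1.5)
  map <- synthesize_map(fc, grid_spacing = 0.5)
  r <- 3
  mask <- make_region_mask(map, m, 1:2, r)
  vox_vol <- cl$volume / prod(map$dims)
  expect_equal(length(mask) * vox_vol, 2 * 4 / 3 * pi * r^3,
               tolerance = 0.05)
})

test_that("CCP4 maps round trip through disk", {
  map <- synthesize_map(tiny_fc(1))
  f <- withr::local_tempfile(fileext = ".ccp4")
  write_ccp4(map, f)
  m2 <- read_ccp4(f)
  expect_equal(as.integer(m2$dims), as.integer(map$dims))
  expect_equal(m2$values, map$values, tolerance = 1e-6)
  expect_equal(unlist(m2$cell[1:6]), unlist(map$cell[1:6]), tolerance = 1e-5)
})

test_that("reflection TSV dialect is bit-stable and rejects duplicates", {
  fc <- tiny_fc(3, d_min = 3)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_reflections_tsv(fc, f1)
  rt <- read_reflections_tsv(f1)
  expect_s3_class(rt, "complex_sf_set")
  write_reflections_tsv(rt, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(reflection_set(c(1, 1), c(0, 0), c(0, 0), c(1, 1), c(0, 0),
                              attr(fc, "cell")),
               "duplicate")
  # observed set round trip preserves sigF
  rs <- reflection_set(fc$h, fc$k, fc$l, fc$f, fc$f * 0.05, attr(fc, "cell"))
  f3 <- withr::local_tempfile()
  write_reflections_tsv(rs, f3)
  rs2 <- read_reflections_tsv(f3)
  expect_equal(rs2$sigf, rs$sigf, tolerance = 1e-7)
})
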