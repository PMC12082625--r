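test_that("the flavin frame resolves rings, wings and the reference arm", {
  m <- tiny_model(5)
  fr <- flavin_frame(m, "FLV")
  nm <- function(i) m$atoms$name[i]
  expect_setequal(nm(fr$ring2), c("N5", "C5A", "C9A", "N10", "C10A", "C4A"))
  expect_true(all(c("C6", "C7", "C8", "C9", "C7M", "C8M") %in% nm(fr$wing_c)))
  expect_true(all(c("N1", "C2", "N3", "C4", "O2", "O4") %in% nm(fr$wing_n)))
  expect_identical(nm(fr$axis), c("N5", "N10"))
  # missing atom is named in the error
  m2 <- m
  m2$atoms$name[m2$atoms$name == "N5"] <- "XX"
  expect_error(flavin_frame(m2, "FLV"), "N5")
})

test_that("bending is a rigid wing rotation about the N5-N10 axis", {
  m <- tiny_model(5)
  fr <- flavin_frame(m, "FLV")
  # zero bend is the identity
  expect_identical(bend_flavin(m, fr, 0, 0)$atoms, m$atoms)
  b <- bend_flavin(m, fr, 10, 12)
  # N5, N10 and the ribityl reference do not move
  fixed <- c(fr$axis, fr$ref_atom)
  expect_equal(as.matrix(b$atoms[fixed, c("x", "y", "z")]),
               as.matrix(m$atoms[fixed, c("x", "y", "z")]))
  # all pairwise distances within each wing preserved exactly
  for (wing in list(fr$wing_c, fr$wing_n)) {
    d0 <- dist(as.matrix(m$atoms[wing, c("x", "y", "z")]))
    d1 <- dist(as.matrix(b$atoms[wing, c("x", "y", "z")]))
    expect_lt(max(abs(d0 - d1)), 1e-6)
  }
  # central-ring bond lengths preserved
  ring2 <- fr$ring2
  ring2_next <- ring2[c(2:6, 1)]
  bl <- function(mm) sqrt(rowSums((as.matrix(mm$atoms[ring2, c("x","y","z")]) -
                                   as.matrix(mm$atoms[ring2_next, c("x","y","z")]))^2))
  expect_equal(bl(b), bl(m), tolerance = 1e-9)
})

test_that("bend then measure round trips over a grid of angles", {
  m <- tiny_model(5)
  fr <- flavin_frame(m, "FLV")
  for (ang in list(c(10, 12), c(-6, 7.5), c(25, -18), c(0.4, 0.9))) {
    got <- butterfly_angles(bend_flavin(m, fr, ang[1], ang[2]), fr)
    expect_equal(unname(got), ang, tolerance = 0.2)
  }
})

test_that("butterfly angles are invariant under rigid motion", {
  m <- tiny_model(5)
  fr <- flavin_frame(m, "FLV")
  b <- bend_flavin(m, fr, 8, -4)
  set.seed(99)
  for (i in 1:20) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
                  2 * (q[2] * q[4] + q[1] * q[3]),
                  2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
                  2 * (q[3] * q[4] - q[1] * q[2]),
                  2 * (q[2] * q[4] - q[1] * q[3]),
                  2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
                3, 3, byrow = TRUE)
    shift <- rnorm(3, 0, 5)
    moved <- b
    xyz <- as.matrix(b$atoms[, c("x", "y", "z")]) %*% t(R)
    moved$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, shift, "+")
    expect_equal(unname(butterfly_angles(moved, fr)),
                 unname(butterfly_angles(b, fr)), tolerance = 1e-6)
  }
})

test_that("model difference maps vanish, negate and localize as expected", {
  m <- tiny_model(5)
  fr <- flavin_frame(m, "FLV")
  zero <- model_ded(m, m, d_min = 2.0)
  expect_true(all(zero$values == 0))
  b <- bend_flavin(m, fr, 15, 15)
  fwd <- model_ded(m, b, d_min = 2.0)
  bwd <- model_ded(b, m, d_min = 2.0)
  expect_equal(bwd$values, -fwd$values, tolerance = 1e-9)
  # strongest features within 2 A of wing atoms
  v <- fwd$values
  idx <- arrayInd(order(-abs(v))[1:5], dim(v)) - 1L
  pk <- frac_to_cart(sweep(idx, 2, dim(v), "/"), m$cell)
  wings <- as.matrix(m$atoms[c(fr$wing_c, fr$wing_n), c("x", "y", "z")])
  for (i in seq_len(nrow(pk))) {
    dmin <- min(sqrt(rowSums(sweep(wings, 2, pk[i, ])^2)))
    expect_lt(dmin, 2)
  }
})

test_that("dfocc refinement is exact on self-consistent noise-free input", {
  m <- tiny_model(5)
  fr <- flavin_frame(m, "FLV")
  obs <- model_ded(m, bend_flavin(m, fr, 6, 4), d_min = 2.0,
                   projection = "amplitude")
  br <- dfocc_refine(obs, m, fr, scan_bound = 8, step = 0.5, d_min = 2.0)
  expect_equal(br$rho_c, 6, tolerance = 0.5)
  expect_equal(br$rho_n, 4, tolerance = 0.5)
  expect_gt(br$dfocc, 0.99)
  # score surface has a single local maximum on the grid
  surf <- tidy(br)
  expect_equal(nrow(surf), 33^2)
  sc <- matrix(surf$dfocc, 33, 33)
  n_local_max <- 0
  for (i in 2:32) for (j in 2:32) {
    nb <- sc[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (is.finite(sc[i, j]) && sc[i, j] == max(nb, na.rm = TRUE)) {
      n_local_max <- n_local_max + 1
    }
  }
  expect_equal(n_local_max, 1L)
  expect_equal(glance(br)$dfocc, br$dfocc)
})

test_that("a signal-free observed map is rejected", {
  m <- tiny_model(5)
  fr <- flavin_frame(m, "FLV")
  flat <- model_ded(m, m, d_min = 2.0)
  expect_error(dfocc_refine(flat, m, fr, scan_bound = 4, step = 2,
                            d_min = 2.0), "no signal")
})
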