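test_that("minimum edge distance matches hand values and brute force", {
  cl <- unit_cell(40, 40, 40)
  at <- tibble::tibble(name = c("A", "B"), element = "C",
                       x = c(0, 3), y = c(0, 4), z = 0, occ = 1, b_iso = 10)
  m <- crystal_model(cl, at)
  expect_equal(min_edge_distance(m, 1, 2), 5)
  expect_equal(min_edge_distance(m, 1:2, 1:2), 0)
  # random selections vs a double loop
  set.seed(3)
  at2 <- tibble::tibble(name = paste0("X", 1:40), element = "C",
                        x = runif(40, 0, 30), y = runif(40, 0, 30),
                        z = runif(40, 0, 30), occ = 1, b_iso = 10)
  m2 <- crystal_model(cl, at2)
  selA <- 1:20; selB <- 21:40
  brute <- Inf
  for (i in selA) for (j in selB) {
    brute <- min(brute, sqrt(sum((unlist(at2[i, c("x", "y", "z")]) -
                                    unlist(at2[j, c("x", "y", "z")]))^2)))
  }
  expect_equal(min_edge_distance(m2, selA, selB), brute)
  # hydrogens are excluded
  at3 <- at; at3$element <- c("H", "C")
  expect_error(min_edge_distance(crystal_model(cl, at3), 1, 2),
               "no non-hydrogen")
})

test_that("an ideal helix returns its construction dihedrals", {
  m <- build_backbone(phi = rep(-62, 6), psi = rep(-41, 6))
  pp <- backbone_phipsi(m)
  expect_equal(pp$phi[2:6], rep(-62, 5), tolerance = 0.5)
  expect_equal(pp$psi[1:5], rep(-41, 5), tolerance = 0.5)
  # the oxidized-state backbone values print the same way
  m2 <- build_backbone(phi = c(-64, -64, -64), psi = c(-28.2, -28.2, -28.2))
  pp2 <- backbone_phipsi(m2)
  expect_equal(pp2$phi[2], -64, tolerance = 0.5)
  expect_equal(pp2$psi[2], -28.2, tolerance = 0.5)
})

test_that("dihedrals agree with an independent implementation", {
  set.seed(8)
  for (i in 1:25) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    ours <- redoxmap:::dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    ref <- bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4)
    expect_equal(ours, as.numeric(ref), tolerance = 1e-6)
  }
})

test_that("collinear backbone atoms raise a dihedral error", {
  expect_error(
    redoxmap:::dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
    "collinear")
})

test_that("a chain break omits the affected dihedral with a warning", {
  m <- build_backbone(phi = rep(-62, 4), psi = rep(-41, 4))
  broken <- m
  sel <- broken$atoms$resid >= 3
  broken$atoms[sel, c("x", "y", "z")] <-
    broken$atoms[sel, c("x", "y", "z")] + 10
  # both the psi before and the phi after the break warn
  expect_warning(expect_warning(pp <- backbone_phipsi(broken), "chain break"))
  expect_true(is.na(pp$phi[pp$resid == 3]))
  expect_false(is.na(pp$phi[pp$resid == 2]))
})

test_that("displacement profiles distinguish shifts from superposable motion", {
  m <- tiny_model(6)
  expect_true(all(displacement_profile(m, m)$displacement == 0))
  shifted <- m
  shifted$atoms[, c("x", "y", "z")] <- shifted$atoms[, c("x", "y", "z")] +
    matrix(rep(c(1.2, 0, 0), each = nrow(m$atoms)), ncol = 3)
  prof <- displacement_profile(m, shifted)
  expect_equal(prof$displacement, rep(1.2, nrow(m$atoms)))
  # symmetric in its arguments
  expect_equal(displacement_profile(shifted, m)$displacement,
               prof$displacement)
  # superposition removes the rigid shift
  sup <- displacement_profile(m, shifted, superpose = TRUE)
  expect_lt(max(sup$displacement), 1e-9)
  # unmatched atoms are excluded with a warning
  renamed <- m
  renamed$atoms$name[5] <- "ZZ"
  expect_warning(pr <- displacement_profile(m, renamed), "unmatched")
  expect_equal(nrow(pr), nrow(m$atoms) - 1L)
})

test_that("B-factor profiles correlate as expected", {
  m <- build_backbone(phi = rep(-62, 8), psi = rep(-41, 8))
  m$atoms$b_iso <- seq(10, 24, length.out = nrow(m$atoms))
  expect_equal(bfactor_profiles(m, m)$r, 1.0)
  affine <- m
  affine$atoms$b_iso <- 2 * affine$atoms$b_iso + 5
  expect_equal(bfactor_profiles(m, affine)$r, 1.0)
  # independent random profiles mostly decorrelate
  set.seed(12)
  rs <- replicate(40, {
    a <- m; b <- m
    a$atoms$b_iso <- runif(nrow(m$atoms), 10, 60)
    b$atoms$b_iso <- runif(nrow(m$atoms), 10, 60)
    bfactor_profiles(a, b)$r
  })
  expect_gt(mean(abs(rs) < 0.7), 0.9)
  two <- m
  two$atoms <- two$atoms[two$atoms$resid <= 2, ]
  expect_error(bfactor_profiles(two, two), "3 matched")
})

test_that("ADP eigen-analysis matches closed forms and a root-finder oracle", {
  iso <- list(diag(3) * 0.02)
  a1 <- adp_eigen(iso)
  expect_equal(unlist(a1[, c("lambda1", "lambda2", "lambda3")]),
               c(lambda1 = 0.02, lambda2 = 0.02, lambda3 = 0.02))
  expect_equal(a1$anisotropy, 1.0)
  expect_equal(a1$ueq, 0.02)
  a2 <- adp_eigen(list(diag(c(0.04, 0.02, 0.01))))
  expect_equal(a2$anisotropy, 0.25)
  # random SPD tensors: eigenvalues match the characteristic polynomial roots
  set.seed(4)
  for (i in 1:10) {
    B <- matrix(rnorm(9), 3, 3)
    U <- crossprod(B) / 50 + diag(3) * 0.01
    ev <- unlist(adp_eigen(list(U))[, c("lambda1", "lambda2", "lambda3")])
    # characteristic polynomial det(U - x I) = 0 via polyroot
    c0 <- -det(U)
    c1 <- (sum(diag(U))^2 - sum(diag(U %*% U))) / 2
    c2 <- -sum(diag(U))
    roots <- sort(Re(polyroot(c(c0, c1, c2, 1))), decreasing = TRUE)
    expect_equal(unname(ev), roots, tolerance = 1e-9)
  }
  asym <- matrix(c(0.02, 0.01, 0, 0, 0.02, 0, 0, 0, 0.02), 3, 3)
  expect_error(adp_eigen(list(asym)), "asymmetric")
})

test_that("the oxidation fraction inverts its own formula", {
  expect_equal(cluster_oxidation_fraction(0, 1), 0)
  # construct deltaA for a 6% fraction and invert
  frac <- 0.06
  dA <- frac * (8400 / 7500) * 0.5
  expect_equal(cluster_oxidation_fraction(dA, 0.5), 0.06)
  # equal absorbances: the ratio of the molar absorptivities
  expect_equal(cluster_oxidation_fraction(1, 1), 7500 / 8400)
  expect_warning(out <- cluster_oxidation_fraction(10, 0.1), "clamped")
  expect_equal(out, 1)
  expect_error(cluster_oxidation_fraction(0.1, 0), "positive")
  expect_error(cluster_oxidation_fraction(0.1, 1, delta_eps_470 = -5),
               "positive")
})
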