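make_ref <- function(seed = 2, d_min = 2.0) {
  fc <- tiny_fc(seed, d_min)
  reflection_set(fc$h, fc$k, fc$l, fc$f, rep(0, nrow(fc)), attr(fc, "cell"))
}

test_that("scaling recovers injected scale and relative B", {
  ref <- make_ref()
  # identity
  id <- scale_to_reference(ref, ref)$result
  expect_equal(id$k, 1, tolerance = 1e-6)
  expect_equal(id$b_rel, 0, tolerance = 1e-6)
  # pure scale: fo = 2 ref -> k = 0.5
  fo <- reflection_set(ref$h, ref$k, ref$l, 2 * ref$f, 0.02 * ref$f,
                       attr(ref, "cell"))
  sc <- scale_to_reference(fo, ref)
  expect_equal(sc$result$k, 0.5, tolerance = 1e-4)
  expect_equal(sc$scaled$f, ref$f, tolerance = 1e-6)
  expect_equal(sc$scaled$sigf, 0.01 * ref$f, tolerance = 1e-6)
  # pure B: fo = ref exp(-10 s^2/4) -> b_rel = -10
  s2 <- (1 / ref$d)^2
  fo2 <- reflection_set(ref$h, ref$k, ref$l, ref$f * exp(-10 * s2 / 4),
                        rep(0, nrow(ref)), attr(ref, "cell"))
  sc2 <- scale_to_reference(fo2, ref)$result
  expect_equal(sc2$b_rel, -10, tolerance = 0.1)
  expect_equal(sc2$k, 1, tolerance = 1e-3)
})

test_that("scaling refuses sparse overlap", {
  ref <- make_ref()
  few <- reflection_set(ref$h[1:20], ref$k[1:20], ref$l[1:20], ref$f[1:20],
                        rep(0, 20), attr(ref, "cell"))
  expect_error(scale_to_reference(few, ref), "at least 50")
})

test_that("q-weights are symmetric when all differences look alike", {
  ref <- make_ref(5)
  n <- nrow(ref)
  # equal |deltaF|, alternating sign, no sigma: w identical, dFo_WN = deltaF
  delta <- 0.5 * rep(c(1, -1), length.out = n)
  fx <- reflection_set(ref$h, ref$k, ref$l, ref$f + delta, rep(0, n),
                       attr(ref, "cell"))
  fd <- reflection_set(ref$h, ref$k, ref$l, ref$f, rep(0, n),
                       attr(ref, "cell"))
  wd <- qweight_differences(fx, fd, alpha = 1, n_shells = 10)
  expect_equal(length(unique(round(wd$w, 12))), 1L)
  expect_equal(wd$dfo_wn, wd$delta_f)
  # alpha = 0, equal sigF: w constant within each shell
  fx2 <- reflection_set(ref$h, ref$k, ref$l, ref$f + rnorm(n), rep(0.3, n),
                        attr(ref, "cell"))
  fd2 <- reflection_set(ref$h, ref$k, ref$l, ref$f, rep(0.4, n),
                        attr(ref, "cell"))
  wd2 <- qweight_differences(fx2, fd2, alpha = 0, n_shells = 8)
  spread <- tapply(wd2$w, wd2$shell, function(w) diff(range(w)))
  expect_true(all(spread < 1e-12))
})

test_that("an outlying difference is down-weighted within its shell", {
  ref <- make_ref(6)
  n <- nrow(ref)
  set.seed(1)
  delta <- rnorm(n, 0, 0.3)
  delta[7] <- 10 * sqrt(mean(delta^2))
  fx <- reflection_set(ref$h, ref$k, ref$l, pmax(0, ref$f + delta),
                       rep(0.1, n), attr(ref, "cell"))
  fd <- reflection_set(ref$h, ref$k, ref$l, ref$f, rep(0.1, n),
                       attr(ref, "cell"))
  wd <- qweight_differences(fx, fd, alpha = 1, n_shells = 5)
  out_row <- which(wd$h == ref$h[7] & wd$k == ref$k[7] & wd$l == ref$l[7])
  shell_w <- wd$w[wd$shell == wd$shell[out_row]]
  expect_lt(wd$w[out_row], stats::median(shell_w))
  # boundedness and monotone decrease in |deltaF| within a shell
  expect_true(all(wd$w > 0 & wd$w <= 1))
  for (sh in unique(wd$shell)) {
    rows <- wd[wd$shell == sh, ]
    expect_true(all(diff(rows$w[order(abs(rows$delta_f))]) <= 1e-12))
  }
})

test_that("weight normalization preserves shell scale", {
  fx <- scan_fixture(0.5, seed = 31)
  scd <- scale_to_reference(fx$fo_dark, fx$fc_dark)$scaled
  scm <- scale_to_reference(fx$fo_mix, fx$fc_dark)$scaled
  wd <- qweight_differences(scm, scd, alpha = 1, n_shells = 15)
  wm <- tapply(wd$w, wd$shell, mean)
  per_shell <- tapply(wd$dfo_wn / wd$delta_f, wd$shell, mean)
  # dfo_wn = w deltaF / <w>, so <w norm> = 1 per shell by construction
  expect_equal(as.numeric(tapply(wd$w / wm[as.character(wd$shell)], wd$shell,
                                 mean)),
               rep(1, 15), tolerance = 1e-12)
  expect_error(qweight_differences(scm, scd, n_shells = 1e6), "fewer shells")
})

test_that("identical states give an empty difference map", {
  fx <- scan_fixture(0.3, seed = 41, noise = 0)
  scd <- scale_to_reference(fx$fo_dark, fx$fc_dark)$scaled
  wd <- qweight_differences(scd, scd)
  expect_true(all(wd$delta_f == 0))
  ded <- fofo_map(wd, fx$fc_dark)
  expect_true(all(ded$map$values == 0))
  expect_equal(nrow(ded$peaks), 0L)
})

test_that("swapping the states negates the map voxel for voxel", {
  fx <- scan_fixture(0.6, seed = 42)
  scd <- scale_to_reference(fx$fo_dark, fx$fc_dark)$scaled
  scm <- scale_to_reference(fx$fo_mix, fx$fc_dark)$scaled
  fwd <- fofo_map(qweight_differences(scm, scd), fx$fc_dark)
  rev <- fofo_map(qweight_differences(scd, scm), fx$fc_dark)
  expect_lt(max(abs(fwd$map$values + rev$map$values)),
            1e-10 * max(abs(fwd$map$values)))
})

test_that("a noise-free single-displacement fixture localizes its peak pair", {
  pert <- perturbation_spec(displacement = list(
    selection = list(name = "SG1"), vector = c(0.6, 0, 0)))
  fx <- two_state_fixture(size_class = "tiny", n_true = 1, noise_frac = 0,
                          perturbation = pert, seed = 43)
  scd <- scale_to_reference(fx$fo_dark, fx$fc_dark)$scaled
  scm <- scale_to_reference(fx$fo_mix, fx$fc_dark)$scaled
  ded <- fofo_map(qweight_differences(scm, scd), fx$fc_dark,
                  model = fx$ground)
  neg <- ded$peaks[ded$peaks$height_sigma < 0, ][1, ]
  pos <- ded$peaks[ded$peaks$height_sigma > 0, ][1, ]
  old_pos <- unlist(fx$ground$atoms[fx$ground$atoms$name == "SG1",
                                    c("x", "y", "z")])
  new_pos <- unlist(fx$excited$atoms[fx$excited$atoms$name == "SG1",
                                     c("x", "y", "z")])
  voxel <- max(c(fx$ground$cell$a, fx$ground$cell$b, fx$ground$cell$c) /
                 ded$map$dims)
  expect_lt(sqrt(sum((c(neg$x, neg$y, neg$z) - old_pos)^2)),
            voxel * sqrt(3))
  # strongest positive peak displaced along the shift vector
  d_new <- sqrt(sum((c(pos$x, pos$y, pos$z) - new_pos)^2))
  d_old <- sqrt(sum((c(pos$x, pos$y, pos$z) - old_pos)^2))
  expect_lt(d_new, d_old)
})

test_that("missing phases are counted in the error", {
  fx <- scan_fixture(0.5, seed = 44)
  scd <- scale_to_reference(fx$fo_dark, fx$fc_dark)$scaled
  scm <- scale_to_reference(fx$fo_mix, fx$fc_dark)$scaled
  wd <- qweight_differences(scm, scd)
  short <- fx$fc_dark[-(1:5), ]
  attr(short, "cell") <- attr(fx$fc_dark, "cell")
  class(short) <- class(fx$fc_dark)
  expect_error(fofo_map(wd, short), "5 .*no dark phase")
})

test_that("region integration respects sign, threshold and saturation", {
  map <- synthesize_map(tiny_fc(1))
  zero <- map; zero$values[] <- 0; zero$sigma <- 0
  full_mask <- make_region_mask(map, tiny_model(1), seq_len(40), 30)
  expect_equal(integrate_region(zero, full_mask, "both", 0), 0)
  expect_equal(integrate_region(map, full_mask, "both", threshold_sigma = 0),
               sum(abs(map$values)))
  # a purely positive blob yields no negative integral
  pos_map <- map; pos_map$values <- abs(pos_map$values)
  expect_equal(integrate_region(pos_map, full_mask, "negative",
                                threshold_sigma = 0), 0)
  expect_equal(integrate_region(map, full_mask, "negative",
                                threshold_absolute = 1e9), 0)
})

test_that("map correlation behaves like Pearson correlation", {
  a <- synthesize_map(tiny_fc(1))
  expect_equal(map_correlation(a, a), 1.0)
  b <- a; b$values <- -b$values
  expect_equal(map_correlation(a, b), -1.0)
  flat <- a; flat$values[] <- 2
  expect_error(map_correlation(a, flat), "zero variance")
  # independent random maps decorrelate
  set.seed(7)
  r1 <- a; r1$values <- array(rnorm(1000), c(10, 10, 10)); r1$dims <- c(10, 10, 10)
  r2 <- a; r2$values <- array(rnorm(1000), c(10, 10, 10)); r2$dims <- c(10, 10, 10)
  expect_lt(abs(map_correlation(r1, r2)), 0.1)
})

test_that("difference peaks localize the perturbed atoms across seeds", {
  hits <- vapply(1:20, function(sd) {
    pert <- perturbation_spec(displacement = list(
      selection = list(name = "SG1"), vector = c(0.8, 0.6, 0)))
    fx <- two_state_fixture(size_class = "tiny", n_true = 0.5,
                            noise_frac = 0.04, perturbation = pert, seed = sd)
    scd <- scale_to_reference(fx$fo_dark, fx$fc_dark)$scaled
    scm <- scale_to_reference(fx$fo_mix, fx$fc_dark)$scaled
    ded <- fofo_map(qweight_differences(scm, scd), fx$fc_dark,
                    model = fx$ground)
    if (nrow(ded$peaks) == 0) return(FALSE)
    top <- ded$peaks[1, ]
    old_pos <- unlist(fx$ground$atoms[fx$ground$atoms$name == "SG1",
                                      c("x", "y", "z")])
    new_pos <- unlist(fx$excited$atoms[fx$excited$atoms$name == "SG1",
                                       c("x", "y", "z")])
    min(sqrt(sum((c(top$x, top$y, top$z) - old_pos)^2)),
        sqrt(sum((c(top$x, top$y, top$z) - new_pos)^2))) <= 1.5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
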