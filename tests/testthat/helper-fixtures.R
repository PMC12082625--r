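# Shared fixtures, cached across test files (all are pure functions of
# their seeds, so caching cannot leak state between tests).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_model <- function(seed = 1) {
  cached(paste0("tiny", seed), make_ground_model("tiny", seed = seed))
}

tiny_fc <- function(seed = 1, d_min = 2.0) {
  cached(paste0("fc", seed, "_", d_min),
         calc_structure_factors(tiny_model(seed), d_min))
}

# two S ligand atoms displaced well clear of their old sites: the
# linear-regime fixture used for occupancy recovery
scan_perturbation <- function() {
  perturbation_spec(displacement = list(
    selection = list(name = c("SG1", "SG2")), vector = c(1.2, 1.0, 0.6)))
}

scan_fixture <- function(n_true, seed, noise = 0.03, size = "small") {
  two_state_fixture(size_class = size, n_true = n_true, noise_frac = noise,
                    perturbation = scan_perturbation(), seed = seed)
}

# scale both observed sets, form sigma-weighted differences, scan
run_occupancy_scan <- function(fx, alpha = 0, roi_radius = 1.5) {
  scd <- scale_to_reference(fx$fo_dark, fx$fc_dark)$scaled
  scm <- scale_to_reference(fx$fo_mix, fx$fc_dark)$scaled
  dif <- qweight_differences(scm, scd, alpha = alpha)
  map0 <- synthesize_map(fx$fc_dark)
  roi <- make_region_mask(map0, fx$ground, list(name = c("SG1", "SG2")),
                          roi_radius)
  occupancy_scan(fx$fc_dark, dif, roi)
}

bend_fixture <- function(bend, seed, noise = 0.03) {
  two_state_fixture(size_class = "tiny", n_true = 1, noise_frac = noise,
                    perturbation = perturbation_spec(bend = bend),
                    d_min = 2.0, seed = seed)
}

observed_ded <- function(fx, alpha = 0) {
  scd <- scale_to_reference(fx$fo_dark, fx$fc_dark)$scaled
  scm <- scale_to_reference(fx$fo_mix, fx$fc_dark)$scaled
  dif <- qweight_differences(scm, scd, alpha = alpha)
  fofo_map(dif, fx$fc_dark)
}

# minimum interatomic distance under periodic boundaries (brute force)
min_pair_distance <- function(model) {
  fr <- cart_to_frac(as.matrix(model$atoms[, c("x", "y", "z")]), model$cell)
  A <- frac_to_cart_matrix(model$cell)
  best <- Inf
  for (i in seq_len(nrow(fr) - 1)) {
    df <- sweep(fr[(i + 1):nrow(fr), , drop = FALSE], 2, fr[i, ], "-")
    df <- df - round(df)
    best <- min(best, sqrt(min(rowSums((df %*% t(A))^2))))
  }
  best
}

demo_fixture_for_tests <- function(seed = 1) {
  redoxmap:::demo_fixture(seed = seed)
}
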