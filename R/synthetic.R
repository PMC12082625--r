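# run code with a private RNG stream, restoring the caller's state
local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# planar idealized isoalloxazine: three fused hexagons in the xy-plane,
# N5-N10 along +x, plus O2/O4 carbonyls, 7/8 methyls and the N10 link
# carbon. Uniform 1.5 A bonds (idealized; keeps every pair at or above
# the generator's 1.5 A contact floor).
flavin_template <- function() {
  R <- 1.5
  hexv <- function(centre, ang_deg) {
    cbind(centre[1] + R * cos(ang_deg * pi / 180),
          centre[2] + R * sin(ang_deg * pi / 180), 0)
  }
  c2 <- c(0, 0); c1 <- c(0, 2 * R * cos(pi / 6)); c3 <- c(0, -2 * R * cos(pi / 6))
  pos <- rbind(
    hexv(c2, 180), hexv(c2, 120), hexv(c2, 60),
    hexv(c2, 0), hexv(c2, -60), hexv(c2, -120),
    hexv(c1, 180), hexv(c1, 120), hexv(c1, 60), hexv(c1, 0),
    hexv(c3, 180), hexv(c3, -120), hexv(c3, -60), hexv(c3, 0))
  rownames(pos) <- c("N5", "C5A", "C9A", "N10", "C10A", "C4A",
                     "C6", "C7", "C8", "C9", "C4", "N3", "C2", "N1")
  sub_out <- function(at, centre, len) {
    v <- pos[at, 1:2] - centre
    pos[at, ] + c(len * v / sqrt(sum(v^2)), 0)
  }
  c1p <- sub_out("N10", c2, 1.50)
  # second ribityl carbon, off the N5-N10 axis but bend-invariant: it is
  # the in-plane reference that makes the rho_c/rho_n split observable
  c2p <- c1p + 1.5 * c(cos(pi / 3), sin(pi / 3), 0)
  pos <- rbind(pos,
               O2 = sub_out("C2", c3, 1.50), O4 = sub_out("C4", c3, 1.50),
               C7M = sub_out("C7", c1, 1.50), C8M = sub_out("C8", c1, 1.50),
               "C1'" = c1p, "C2'" = c2p)
  el <- c(N5 = "N", C5A = "C", C9A = "C", N10 = "N", C10A = "C", C4A = "C",
          C6 = "C", C7 = "C", C8 = "C", C9 = "C", C4 = "C", N3 = "N",
          C2 = "C", N1 = "N", O2 = "O", O4 = "O", C7M = "C", C8M = "C",
          "C1'" = "C", "C2'" = "C")
  list(xyz = pos, element = el[rownames(pos)])
}

# cubane 4Fe-4S cluster with four outward S ligands; bond 2.3 A
cluster_template <- function() {
  e <- 2.3
  verts <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * e
  parity <- rowSums(verts / e) %% 2
  fe <- verts[parity == 0, ]
  ss <- verts[parity == 1, ]
  centre <- colMeans(verts)
  sg <- t(apply(fe, 1, function(p) {
    v <- p - centre; p + 2.3 * v / sqrt(sum(v^2))
  }))
  xyz <- rbind(fe, ss, sg)
  rownames(xyz) <- c(paste0("FE", 1:4), paste0("S", 1:4), paste0("SG", 1:4))
  list(xyz = xyz,
       element = c(rep("Fe", 4), rep("S", 8)))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Synthetic ground-state crystal model
#'
#' Builds a deterministic pseudo-protein in a P1 cell: a planar mock
#' isoalloxazine (canonical atom names, residue FLV), a cubane
#' 4Fe-4S cluster with four S ligands (residues SF4/CYS, carrying mild
#' anisotropic U), and a random C/N/O/S scatter filling out the atom
#' count, with no interatomic contact closer than 1.5 Angstrom (under
#' periodic boundaries).
#'
#' @param size_class "tiny" (~40 atoms, 22 A cell) or "small" (~150
#'   atoms, 30 A cell).
#' @param seed RNG seed; the model is a pure function of
#'   (size_class, seed).
#' @return A [crystal_model()].
#' @export
make_ground_model <- function(size_class = c("tiny", "small"), seed = 1) {
  size_class <- match.arg(size_class)
  edge <- switch(size_class, tiny = 22, small = 30)
  n_target <- switch(size_class, tiny = 40, small = 150)
  cell <- unit_cell(edge, edge, edge * 1.05)
  local_seed(seed, {
    fl <- flavin_template()
    Rf <- random_rotation()
    fl_xyz <- fl$xyz %*% t(Rf)
    fl_xyz <- sweep(fl_xyz, 2, colMeans(fl_xyz))
    fl_xyz <- sweep(fl_xyz, 2, c(0.30, 0.30, 0.50) * c(edge, edge, edge * 1.05), "+")
    clu <- cluster_template()
    Rc <- random_rotation()
    clu_xyz <- clu$xyz %*% t(Rc)
    clu_xyz <- sweep(clu_xyz, 2, colMeans(clu_xyz))
    clu_xyz <- sweep(clu_xyz, 2, c(0.72, 0.72, 0.50) * c(edge, edge, edge * 1.05), "+")
    atoms <- tibble::tibble(
      name = c(rownames(fl$xyz), rownames(clu$xyz)),
      element = c(unname(fl$element), unname(clu$element)),
      resname = c(rep("FLV", nrow(fl_xyz)), rep("SF4", 8), rep("CYS", 4)),
      resid = c(rep(1L, nrow(fl_xyz)), rep(2L, 8), 3:6),
      chain = "A",
      x = c(fl_xyz[, 1], clu_xyz[, 1]),
      y = c(fl_xyz[, 2], clu_xyz[, 2]),
      z = c(fl_xyz[, 3], clu_xyz[, 3]),
      occ = 1,
      b_iso = c(rep(12, nrow(fl_xyz)), rep(10, nrow(clu_xyz))))
    for (u in c("u11", "u22", "u33", "u12", "u13", "u23")) {
      atoms[[u]] <- NA_real_
    }
    # mild anisotropy on the cluster heavy atoms
    clu_rows <- which(atoms$resname == "SF4")
    for (i in clu_rows) {
      Ru <- random_rotation()
      U <- Ru %*% diag(c(0.024, 0.016, 0.010)) %*% t(Ru)
      atoms[i, c("u11", "u22", "u33", "u12", "u13", "u23")] <-
        as.list(U[c(1, 5, 9, 4, 7, 8)])
    }
    # scatter atoms with clash rejection (min-image distance >= 1.5 A)
    n_scatter <- max(0, n_target - nrow(atoms))
    A <- frac_to_cart_matrix(cell)
    occupied <- cart_to_frac(as.matrix(atoms[, c("x", "y", "z")]), cell)
    els <- c("C", "N", "O", "S")
    placed <- 0L; rid <- 10L
    while (placed < n_scatter) {
      fr <- stats::runif(3)
      df <- sweep(occupied, 2, fr, "-")
      df <- df - round(df)
      if (min(rowSums((df %*% t(A))^2)) < 1.5^2) next
      cart <- as.vector(frac_to_cart(fr, cell))
      placed <- placed + 1L; rid <- rid + 1L
      atoms <- dplyr::bind_rows(atoms, tibble::tibble(
        name = paste0("X", placed),
        element = sample(els, 1, prob = c(0.55, 0.2, 0.2, 0.05)),
        resname = "SCT", resid = rid, chain = "A",
        x = cart[1], y = cart[2], z = cart[3],
        occ = 1, b_iso = stats::runif(1, 10, 30),
        u11 = NA_real_, u22 = NA_real_, u33 = NA_real_,
        u12 = NA_real_, u13 = NA_real_, u23 = NA_real_))
      occupied <- rbind(occupied, fr)
    }
    crystal_model(cell, atoms)
  })
}

#' Perturbation specification
#'
#' Describes the structural difference between the ground and the
#' perturbed state: a rigid displacement of a selection, an optional
#' additional cofactor shift, an elongated bond (the second atom is
#' moved along the bond direction to the requested length), and an
#' optional flavin butterfly bend.
#'
#' @param displacement `list(selection =, vector =)` rigid translation
#'   (Angstrom); magnitude must stay below 3 (isomorphism).
#' @param cofactor_shift Same shape as `displacement`.
#' @param elongate_bond `list(from =, to =, length =)`: single-atom
#'   selections; `to` is moved.
#' @param bend Length-2 numeric `(rho_c, rho_n)` in degrees.
#' @param bend_selection Selection naming the flavin (default residue
#'   FLV).
#' @return A `perturbation_spec`.
#' @export
perturbation_spec <- function(displacement = NULL, cofactor_shift = NULL,
                              elongate_bond = NULL, bend = NULL,
                              bend_selection = "FLV") {
  for (mv in list(displacement, cofactor_shift)) {
    if (!is.null(mv)) {
      stopifnot(is.list(mv), length(mv$vector) == 3)
      if (sqrt(sum(mv$vector^2)) >= 3) {
        stop("displacement magnitude must be < 3 A (isomorphism assumption)")
      }
    }
  }
  if (!is.null(bend)) stopifnot(length(bend) == 2)
  structure(list(displacement = displacement, cofactor_shift = cofactor_shift,
                 elongate_bond = elongate_bond, bend = bend,
                 bend_selection = bend_selection),
            class = "perturbation_spec")
}

#' Apply a perturbation to a model
#'
#' Returns a model differing from the input only at the atoms named in
#' the spec; requested displacements and bond lengths are achieved to
#' machine precision. Stages apply in the order displacement,
#' cofactor shift, bond elongation, bend.
#'
#' @param model A [crystal_model()].
#' @param spec A [perturbation_spec()].
#' @return The perturbed [crystal_model()].
#' @export
apply_perturbation <- function(model, spec) {
  stopifnot(inherits(spec, "perturbation_spec"))
  out <- model
  shift <- function(m, mv) {
    idx <- resolve_selection(m, mv$selection)
    xyz <- atom_xyz(m)
    xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2, mv$vector, "+")
    atom_xyz(m) <- xyz
    m
  }
  if (!is.null(spec$displacement)) out <- shift(out, spec$displacement)
  if (!is.null(spec$cofactor_shift)) out <- shift(out, spec$cofactor_shift)
  if (!is.null(spec$elongate_bond)) {
    eb <- spec$elongate_bond
    i <- resolve_selection(out, eb$from); j <- resolve_selection(out, eb$to)
    if (length(i) != 1L || length(j) != 1L) {
      stop("elongate_bond selections must each match exactly one atom")
    }
    xyz <- atom_xyz(out)
    v <- xyz[j, ] - xyz[i, ]
    len <- sqrt(sum(v^2))
    if (len < 1e-9) stop("bond atoms coincide")
    xyz[j, ] <- xyz[i, ] + v / len * eb$length
    atom_xyz(out) <- xyz
  }
  if (!is.null(spec$bend)) {
    fr <- flavin_frame(out, spec$bend_selection)
    out <- bend_flavin(out, fr, spec$bend[1], spec$bend[2])
  }
  out
}

#' Simulate observed two-state amplitudes
#'
#' The mixed crystal is static disorder at fractional occupancy
#' `n_true`, so the true mixed amplitude is the modulus of the complex
#' sum `(1 - n) F_ground + n F_excited`. Observed amplitudes get
#' additive Gaussian noise `sigma_h = noise_frac * F_true +
#' noise_floor`, truncated at zero, and carry `sigF = sigma_h`. The
#' dark calculated set `fc_dark` is noise-free.
#'
#' @param ground,excited Isomorphous [crystal_model()]s (same cell and
#'   atom order).
#' @param n_true Minor-state occupancy in [0, 1].
#' @param noise_frac,noise_floor Relative and absolute amplitude noise
#'   (>= 0).
#' @param d_min Resolution limit (Angstrom).
#' @param seed RNG seed.
#' @return List with `fo_dark`, `fo_mix` (`reflection_set`s) and
#'   `fc_dark` (`complex_sf_set`).
#' @export
simulate_observed <- function(ground, excited, n_true, noise_frac = 0.03,
                              noise_floor = 0, d_min = 1.8, seed = 1) {
  if (n_true < 0 || n_true > 1) stop("n_true must lie in [0, 1]")
  if (noise_frac < 0 || noise_floor < 0) stop("noise parameters must be >= 0")
  if (!cell_equal(ground$cell, excited$cell) ||
      n_atoms(ground) != n_atoms(excited)) {
    stop("states are not isomorphous (cell or atom count differs)")
  }
  fc_g <- calc_structure_factors(ground, d_min)
  fc_e <- calc_structure_factors(excited, d_min)
  zg <- sf_complex(fc_g); ze <- sf_complex(fc_e)
  f_dark_true <- Mod(zg)
  f_mix_true <- Mod((1 - n_true) * zg + n_true * ze)
  noisy <- function(f_true) {
    sig <- noise_frac * f_true + noise_floor
    f <- pmax(0, f_true + stats::rnorm(length(f_true), 0, 1) * sig)
    list(f = f, sig = sig)
  }
  local_seed(seed, {
    nd <- noisy(f_dark_true)
    nm <- noisy(f_mix_true)
    list(fo_dark = reflection_set(fc_g$h, fc_g$k, fc_g$l, nd$f, nd$sig,
                                  ground$cell),
         fo_mix = reflection_set(fc_g$h, fc_g$k, fc_g$l, nm$f, nm$sig,
                                 ground$cell),
         fc_dark = fc_g)
  })
}

#' Two-state crystal fixture with known ground truth
#'
#' Convenience wrapper: ground model, perturbed model, simulated
#' observed amplitude sets and a manifest recording every parameter,
#' so analysis stages can be validated against a recoverable target.
#'
#' @param size_class Passed to [make_ground_model()].
#' @param n_true Mixing occupancy of the perturbed state.
#' @param perturbation A [perturbation_spec()]; default: the demo
#'   scenario (0.6 A cluster shift, Fe4-SG4 bond set to 3.0 A).
#' @param noise_frac,noise_floor,d_min,seed See [simulate_observed()].
#' @return A `two_state_fixture` list: `ground`, `excited`, `n_true`,
#'   `noise_frac`, `noise_floor`, `seed`, `d_min`, `fo_dark`,
#'   `fo_mix`, `fc_dark`, `perturbation`, `manifest`.
#' @export
two_state_fixture <- function(size_class = "tiny", n_true = 0.3,
                              perturbation = NULL, noise_frac = 0.03,
                              noise_floor = 0, d_min = 1.8, seed = 1) {
  if (is.null(perturbation)) {
    perturbation <- perturbation_spec(
      displacement = list(selection = "SF4", vector = c(0.6, 0, 0) / 1),
      elongate_bond = list(from = list(name = "SG4"),
                           to = list(name = "FE4"), length = 3.0))
  }
  ground <- make_ground_model(size_class, seed = seed)
  excited <- apply_perturbation(ground, perturbation)
  sim <- simulate_observed(ground, excited, n_true, noise_frac, noise_floor,
                           d_min, seed = seed + 1000L)
  manifest <- list(size_class = size_class, n_true = n_true,
                   noise_frac = noise_frac, noise_floor = noise_floor,
                   d_min = d_min, seed = seed,
                   n_atoms = n_atoms(ground),
                   cell = unlist(ground$cell[1:6]))
  structure(c(list(ground = ground, excited = excited, n_true = n_true,
                   noise_frac = noise_frac, noise_floor = noise_floor,
                   seed = seed, d_min = d_min,
                   perturbation = perturbation, manifest = manifest),
              sim),
            class = "two_state_fixture")
}

#' Write a fixture bundle to disk
#'
#' Two PDB files (ground/excited), two reflection TSVs (dark and mixed
#' observed), the dark calculated set, and a JSON manifest holding all
#' generation parameters (the ground-truth record).
#'
#' @param fixture A [two_state_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model(fixture$ground, file.path(dir, "ground.pdb"))
  write_model(fixture$excited, file.path(dir, "excited.pdb"))
  write_reflections_tsv(fixture$fo_dark, file.path(dir, "fo_dark.tsv"))
  write_reflections_tsv(fixture$fo_mix, file.path(dir, "fo_mix.tsv"))
  write_reflections_tsv(fixture$fc_dark, file.path(dir, "fc_dark.tsv"))
  jsonlite::write_json(fixture$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
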