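flavin_ring_names <- list(
  ring1 = c("C5A", "C6", "C7", "C8", "C9", "C9A"),
  ring2 = c("N5", "C5A", "C9A", "N10", "C10A", "C4A"),
  ring3 = c("N1", "C2", "N3", "C4", "C4A", "C10A"))

#' Isoalloxazine frame
#'
#' Resolves the canonically named tricyclic ring atoms of a flavin
#' isoalloxazine within a model selection and partitions the selection
#' into the two butterfly wings: ring I (benzene side: C5a, C6-C9,
#' C9a) and ring III (pyrimidine side: N1, C2, N3, C4, C4a, C10a),
#' folding about the N5-N10 axis. Non-ring atoms in the selection
#' (O2, O4, methyls, the N10 link) are assigned to the wing of their
#' nearest ring atom; atoms nearest to N5/N10 stay fixed.
#'
#' @param model A [crystal_model()].
#' @param selection Selection covering the flavin (e.g. a residue
#'   name).
#' @return A `flavin_frame`: list of atom-index vectors `ring1`,
#'   `ring2`, `ring3`, `axis` (N5, N10), `wing_c`, `wing_n`, `all`.
#' @export
flavin_frame <- function(model, selection) {
  sel <- resolve_selection(model, selection)
  nm <- toupper(model$atoms$name[sel])
  need <- unique(unlist(flavin_ring_names))
  for (a in need) {
    if (sum(nm == a) == 0L) stop("flavin frame atom missing: ", a)
    if (sum(nm == a) > 1L) stop("flavin frame atom duplicated: ", a)
  }
  idx_of <- function(names) sel[match(names, nm)]
  ring1 <- idx_of(flavin_ring_names$ring1)
  ring2 <- idx_of(flavin_ring_names$ring2)
  ring3 <- idx_of(flavin_ring_names$ring3)
  axis <- idx_of(c("N5", "N10"))
  wing_c <- ring1
  wing_n <- ring3
  others <- setdiff(sel, unique(c(ring1, ring2, ring3)))
  if (length(others)) {
    ringidx <- unique(c(ring1, ring2, ring3))
    xyz <- atom_xyz(model)
    for (i in others) {
      d <- sqrt(colSums((t(xyz[ringidx, , drop = FALSE]) - xyz[i, ])^2))
      nearest <- ringidx[which.min(d)]
      if (nearest %in% setdiff(ring1, ring2)) {
        wing_c <- c(wing_c, i)
      } else if (nearest %in% setdiff(ring3, ring2)) {
        wing_n <- c(wing_n, i)
      } else if (nearest %in% setdiff(ring2, axis)) {
        # shared-edge atoms carry their wing
        if (nearest %in% ring1) wing_c <- c(wing_c, i)
        if (nearest %in% ring3) wing_n <- c(wing_n, i)
      } # nearest N5/N10: stays fixed
    }
  }
  # bend-invariant reference: the substituent hanging off the axis
  # (the N10 ribityl link, or an N5 substituent), which no wing rotation
  # moves; together with the N5-N10 axis it spans the reference plane
  # the wing angles are measured against.
  ref_atom <- NA_integer_
  if (length(others)) {
    ringidx <- unique(c(ring1, ring2, ring3))
    xyz <- atom_xyz(model)
    u <- xyz[axis[2], ] - xyz[axis[1], ]
    u <- u / sqrt(sum(u^2))
    best_perp <- 0.2  # need a clearly off-axis arm to define the frame
    for (i in others) {
      d <- sqrt(colSums((t(xyz[ringidx, , drop = FALSE]) - xyz[i, ])^2))
      if (!ringidx[which.min(d)] %in% axis) next
      w <- xyz[i, ] - xyz[axis[2], ]
      perp <- sqrt(sum(pracma_cross(u, w)^2)) / sqrt(sum(w^2))
      if (perp > best_perp) { ref_atom <- i; best_perp <- perp }
    }
  }
  structure(list(ring1 = ring1, ring2 = ring2, ring3 = ring3, axis = axis,
                 wing_c = unique(wing_c), wing_n = unique(wing_n),
                 ref_atom = ref_atom, all = sel),
            class = "flavin_frame")
}

rodrigues <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Butterfly-bend a flavin
#'
#' Rotates the benzene wing rigidly by `rho_c` and the pyrimidine wing
#' by `rho_n` about the N5-N10 axis, in opposite senses, so that
#' positive angles fold both wings toward the same face. N5 and N10 do
#' not move and every within-wing distance is preserved exactly (rigid
#' rotations).
#'
#' @param model A [crystal_model()].
#' @param frame A [flavin_frame()] for that model.
#' @param rho_c,rho_n Fold angles in degrees.
#' @return The model with bent flavin coordinates.
#' @export
bend_flavin <- function(model, frame, rho_c, rho_n) {
  stopifnot(inherits(frame, "flavin_frame"))
  xyz <- atom_xyz(model)
  p0 <- xyz[frame$axis[1], ]
  u <- xyz[frame$axis[2], ] - p0
  if (sqrt(sum(u^2)) < 1e-6) stop("degenerate N5-N10 axis")
  rot_about <- function(idx, theta) {
    if (abs(theta) < 1e-15 || length(idx) == 0L) return()
    R <- rodrigues(u, theta)
    moved <- sweep(sweep(xyz[idx, , drop = FALSE], 2, p0) %*% t(R), 2, p0, "+")
    xyz[idx, ] <<- moved
  }
  rot_about(setdiff(frame$wing_c, frame$axis), rho_c * pi / 180)
  rot_about(setdiff(frame$wing_n, frame$axis), -rho_n * pi / 180)
  atom_xyz(model) <- xyz
  model
}

ls_plane_normal <- function(pts) {
  pts <- sweep(pts, 2, colMeans(pts))
  e <- eigen(crossprod(pts), symmetric = TRUE)
  # collinear points: no unique plane
  if (e$values[2] < 1e-8 * max(e$values[1], 1e-12)) {
    stop("ring atoms are collinear: plane fit undefined")
  }
  e$vectors[, 3]
}

signed_plane_angle <- function(nA, nB, u) {
  u <- u / sqrt(sum(u^2))
  if (sum(nA * nB) < 0) nA <- -nA
  pa <- nA - sum(nA * u) * u
  pb <- nB - sum(nB * u) * u
  pa <- pa / sqrt(sum(pa^2)); pb <- pb / sqrt(sum(pb^2))
  atan2(sum(u * pracma_cross(pb, pa)), sum(pa * pb)) * 180 / pi
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

measure_bend_once <- function(model, frame) {
  xyz <- atom_xyz(model)
  u <- xyz[frame$axis[2], ] - xyz[frame$axis[1], ]
  u <- u / sqrt(sum(u^2))
  n2 <- ls_plane_normal(xyz[frame$ring2, , drop = FALSE])
  if (!is.na(frame$ref_atom)) {
    w <- xyz[frame$ref_atom, ] - xyz[frame$axis[2], ]
    nref <- pracma_cross(u, w)
    if (sqrt(sum(nref^2)) < 1e-8) {
      nref <- n2  # link atom on the axis: degenerate, fall back
    } else if (sum(nref * n2) < 0) {
      nref <- -nref  # orient with the central ring
    }
  } else {
    nref <- n2
  }
  n1 <- ls_plane_normal(xyz[frame$ring1, , drop = FALSE])
  n3 <- ls_plane_normal(xyz[frame$ring3, , drop = FALSE])
  c(rho_c = signed_plane_angle(n1, nref, u),
    rho_n = -signed_plane_angle(n3, nref, u))
}

#' Measure butterfly fold angles
#'
#' Least-squares planes are fitted to ring I, ring III and the central
#' ring; the fold angles are the signed plane-plane angles about the
#' N5-N10 axis, refined by a short fixed-point iteration (measure,
#' un-bend, re-measure) so that applying the inverse bend restores
#' ring coplanarity. The sign convention matches [bend_flavin()]:
#' positive angles fold both wings toward the same face.
#'
#' @param model A [crystal_model()].
#' @param frame A [flavin_frame()].
#' @param tol Convergence tolerance in degrees.
#' @return Named numeric `c(rho_c, rho_n)` in degrees.
#' @export
butterfly_angles <- function(model, frame, tol = 1e-5) {
  total <- c(rho_c = 0, rho_n = 0)
  work <- model
  for (it in 1:60) {
    m <- measure_bend_once(work, frame)
    total <- total + m
    if (max(abs(m)) < tol) break
    work <- bend_flavin(work, frame, -m[["rho_c"]], -m[["rho_n"]])
  }
  total
}

#' Model-calculated difference density
#'
#' Synthesizes the map of `Fc(perturbed model) - Fc(dark model)`; only
#' atoms whose coordinates differ contribute (the rest cancel
#' exactly), so the computation involves just the moved atoms.
#'
#' @param dark_model,bent_model Congruent [crystal_model()]s (same
#'   atom order).
#' @param d_min High-resolution limit (Angstrom).
#' @param low_cut Low-resolution cutoff (Angstrom), mirroring observed
#'   difference maps.
#' @param grid_spacing,dims Grid control, as in [synthesize_map()].
#' @param projection "complex" (default): the true difference density,
#'   coefficients `Fc(bent) - Fc(dark)` as complex numbers.
#'   "amplitude": mimic an observed Fo-Fo map by using the amplitude
#'   difference `|Fc(bent)| - |Fc(dark)|` phased with the dark phases
#'   -- the form to correlate against experimental DED maps, which
#'   carry the change only in that phase-projected form.
#' @return A sigma-scaled `map_grid` (an all-zero difference returns a
#'   zero map).
#' @export
model_ded <- function(dark_model, bent_model, d_min, low_cut = 10,
                      grid_spacing = NULL, dims = NULL,
                      projection = c("complex", "amplitude")) {
  projection <- match.arg(projection)
  if (n_atoms(dark_model) != n_atoms(bent_model)) {
    stop("models have different atom counts")
  }
  moved <- which(rowSums(abs(atom_xyz(dark_model) - atom_xyz(bent_model))) > 0)
  hkl <- miller_set(dark_model$cell, d_min)
  hkl <- hkl[hkl$d <= low_cut, ]
  if (length(moved)) {
    sub <- function(m) crystal_model(m$cell, m$atoms[moved, , drop = FALSE])
    fd <- sf_direct(sub(bent_model), hkl) - sf_direct(sub(dark_model), hkl)
  } else {
    fd <- complex(length.out = nrow(hkl))
  }
  if (projection == "complex") {
    coeffs <- complex_sf_set(hkl$h, hkl$k, hkl$l, Mod(fd), phase_deg(fd),
                             dark_model$cell)
  } else {
    f_full <- sf_direct(dark_model, hkl)
    damp <- Mod(f_full + fd) - Mod(f_full)
    coeffs <- complex_sf_set(hkl$h, hkl$k, hkl$l, abs(damp),
                             phase_deg(f_full) + ifelse(damp < 0, 180, 0),
                             dark_model$cell)
  }
  map <- synthesize_map(coeffs, grid_spacing = grid_spacing, dims = dims)
  sigma_scale(map)
}

#' Refine butterfly angles against an observed difference map
#'
#' Exhaustive grid search over (rho_c, rho_n): for each candidate the
#' flavin is bent, the model-calculated difference map is synthesized
#' on the observed grid, and the difference-map real-space correlation
#' coefficient (dFoCC) is computed inside a mask around the flavin.
#' The argmax is returned with the full score surface; ties are broken
#' toward the smaller total bend.
#'
#' @param obs_ded Observed difference map: a `ded_map` or sigma-scaled
#'   `map_grid`.
#' @param dark_model The dark [crystal_model()].
#' @param frame A [flavin_frame()] for `dark_model`.
#' @param scan_bound Half-width of the search square in degrees.
#' @param step Grid step in degrees.
#' @param mask_radius Mask radius around flavin atoms (Angstrom).
#' @param d_min High-resolution limit for model difference maps;
#'   defaults to the observed map's.
#' @param low_cut Low-resolution cutoff (Angstrom).
#' @param projection How the candidate model difference maps are
#'   built (see [model_ded()]). Default "amplitude": an observed Fo-Fo
#'   DED map carries the density change in dark-phase-projected form,
#'   so the model map must be projected the same way or the refined
#'   angles inherit a systematic shape mismatch.
#' @return A `bending_result`: `rho_c`, `rho_n`, `dfocc`, `surface`
#'   (tibble rho_c, rho_n, dfocc), `step`, `scan_bound`.
#' @export
dfocc_refine <- function(obs_ded, dark_model, frame, scan_bound = 30,
                         step = 0.5, mask_radius = 2.5, d_min = NULL,
                         low_cut = 10,
                         projection = c("amplitude", "complex")) {
  projection <- match.arg(projection)
  stopifnot(step > 0, scan_bound > 0)
  map <- if (inherits(obs_ded, "ded_map")) obs_ded$map else obs_ded
  stopifnot(inherits(map, "map_grid"))
  if (is.null(d_min)) d_min <- map$d_min
  if (is.null(d_min) || is.na(d_min)) stop("d_min unknown: supply it")
  mask <- make_region_mask(map, dark_model, frame$all, mask_radius)
  obs_v <- map$values[as.integer(mask)]
  if (stats::sd(obs_v) == 0) {
    stop("observed difference map is flat within the flavin mask: no signal")
  }
  hkl <- miller_set(dark_model$cell, d_min)
  hkl <- hkl[hkl$d <= low_cut, ]
  hm <- hkl_matrix(hkl)
  fl <- frame$all
  sub_dark <- crystal_model(dark_model$cell,
                            dark_model$atoms[fl, , drop = FALSE])
  f_dark <- sf_direct(sub_dark, hkl)
  f_full <- if (projection == "amplitude") sf_direct(dark_model, hkl) else NULL
  amp_full <- if (is.null(f_full)) NULL else Mod(f_full)
  phase_full <- if (is.null(f_full)) NULL else f_full / pmax(amp_full, 1e-12)
  # fixed per-atom reflection coefficients: occ * f(s) * DW
  at <- sub_dark$atoms
  s <- 1 / hkl$d
  f_el <- vapply(at$element, function(e) scattering_factor(e, s),
                 numeric(length(s)))
  dim(f_el) <- c(length(s), nrow(at))
  coef <- f_el * dw_factors(sub_dark, hkl) *
    matrix(at$occ, length(s), nrow(at), byrow = TRUE)
  B <- cart_to_frac_matrix(dark_model$cell)
  dims <- as.integer(map$dims)
  lin_mask <- as.integer(mask)
  vol <- dark_model$cell$volume
  grid <- seq(-scan_bound, scan_bound, by = step)
  cand <- expand.grid(rho_c = grid, rho_n = grid)
  scores <- rep(NA_real_, nrow(cand))
  base <- dark_model
  for (i in seq_len(nrow(cand))) {
    bent <- bend_flavin(base, frame, cand$rho_c[i], cand$rho_n[i])
    frac <- atom_xyz(bent)[fl, , drop = FALSE] %*% t(B)
    fb <- rowSums(coef * exp(2i * pi * (hm %*% t(frac))))
    fd <- fb - f_dark
    if (projection == "amplitude") {
      fd <- (Mod(f_full + fd) - amp_full) * phase_full
    }
    rho <- fourier_synthesis(hm, fd, dims, vol)
    mv <- rho[lin_mask]
    sdm <- stats::sd(mv)
    if (sdm > 0) scores[i] <- stats::cor(obs_v, mv)
  }
  if (all(is.na(scores))) stop("no candidate produced a non-flat model map")
  ord <- order(-scores, abs(cand$rho_c) + abs(cand$rho_n))
  best <- ord[1]
  structure(list(rho_c = cand$rho_c[best], rho_n = cand$rho_n[best],
                 dfocc = scores[best],
                 surface = tibble::tibble(rho_c = cand$rho_c,
                                          rho_n = cand$rho_n,
                                          dfocc = scores),
                 step = step, scan_bound = scan_bound,
                 mask_radius = mask_radius, d_min = d_min),
            class = "bending_result")
}

#' @export
print.bending_result <- function(x, ...) {
  cat(sprintf("<bending_result> rho_c = %.2f deg, rho_n = %.2f deg, dFoCC = %.4f (step %.2f deg)\n",
              x$rho_c, x$rho_n, x$dfocc, x$step))
  invisible(x)
}
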