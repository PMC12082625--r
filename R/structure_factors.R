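# Cromer-Mann 4-Gaussian scattering factors (International Tables C, 6.1.1.4),
# neutral atoms: f(s) = sum_i a_i exp(-b_i (s/2)^2) + c, s = 1/d.
cm_table <- local({
  m <- rbind(
    H  = c(0.493002, 0.322912, 0.140191, 0.040810, 10.5109, 26.1257, 3.14236, 57.7997, 0.003038),
    C  = c(2.310000, 1.020000, 1.588600, 0.865000, 20.8439, 10.2075, 0.56870, 51.6512, 0.215600),
    N  = c(12.21260, 3.132200, 2.012500, 1.166300, 0.00570, 9.89330, 28.9975, 0.58260, -11.52900),
    O  = c(3.048500, 2.286800, 1.546300, 0.867000, 13.2771, 5.70110, 0.32390, 32.9089, 0.250800),
    Mg = c(5.420400, 2.173500, 1.226900, 2.307300, 2.82750, 79.2611, 0.38080, 7.19370, 0.858400),
    P  = c(6.434500, 4.179100, 1.780000, 1.490800, 1.90670, 27.1570, 0.52600, 68.1645, 1.114900),
    S  = c(6.905300, 5.203400, 1.437900, 1.586300, 1.46790, 22.2151, 0.25360, 56.1720, 0.866900),
    Fe = c(11.76950, 7.357300, 3.522200, 2.304500, 4.76110, 0.30720, 15.3535, 76.8805, 1.036900))
  colnames(m) <- c(paste0("a", 1:4), paste0("b", 1:4), "c")
  m
})

#' Atomic scattering factor
#'
#' Cromer-Mann 4-Gaussian form factor for a neutral atom at scattering
#' vector length `s = 1/d`.
#'
#' @param element Element symbol (one of the built-in table's rows).
#' @param s Numeric vector, 1/d in 1/Angstrom.
#' @return Numeric vector of f (electrons).
#' @export
scattering_factor <- function(element, s) {
  if (!element %in% rownames(cm_table)) {
    stop("no form factor for element ", element, "; supported: ",
         paste(rownames(cm_table), collapse = ", "))
  }
  p <- cm_table[element, ]
  q2 <- (s / 2)^2
  p["a1"] * exp(-p["b1"] * q2) + p["a2"] * exp(-p["b2"] * q2) +
    p["a3"] * exp(-p["b3"] * q2) + p["a4"] * exp(-p["b4"] * q2) + p["c"]
}

#' Friedel-unique Miller indices to a resolution limit
#'
#' Enumerates the P1 half-set: all (h, k, l) with d >= d_min and
#' (h > 0) or (h = 0, k > 0) or (h = k = 0, l > 0). F(000) is excluded.
#'
#' @param cell A [unit_cell()].
#' @param d_min High-resolution limit (Angstrom).
#' @return Tibble with columns h, k, l, d.
#' @export
miller_set <- function(cell, d_min) {
  stopifnot(d_min > 0)
  hmax <- floor(cell$a / d_min) + 1L
  kmax <- floor(cell$b / d_min) + 1L
  lmax <- floor(cell$c / d_min) + 1L
  g <- expand.grid(h = 0:hmax, k = -kmax:kmax, l = -lmax:lmax)
  g <- g[g$h > 0 | (g$h == 0 & g$k > 0) | (g$h == 0 & g$k == 0 & g$l > 0), ]
  d <- d_spacing(g, cell)
  g <- g[d >= d_min, ]
  if (nrow(g) == 0L) {
    stop("d_min = ", d_min, " A admits no reflection for this cell")
  }
  out <- tibble::as_tibble(g)
  out$d <- d_spacing(out, cell)
  out[order(-out$d, out$h, out$k, out$l), ]
}

# Debye-Waller factors, one column per atom (n_refl x n_atom).
dw_factors <- function(model, hkl) {
  at <- model$atoms
  sv <- recip_vectors(hkl, model$cell)
  s2 <- rowSums(sv^2)
  dw <- matrix(0, nrow(sv), nrow(at))
  iso <- !has_aniso(at)
  if (any(iso)) {
    dw[, iso] <- exp(outer(-s2 / 4, at$b_iso[iso]))
  }
  for (j in which(!iso)) {
    u <- atom_u_matrix(at, j)
    q <- rowSums((sv %*% u) * sv)  # s^T U s
    dw[, j] <- exp(-2 * pi^2 * q)
  }
  dw
}

#' Calculate structure factors from a model
#'
#' Direct summation over atoms:
#' F(h) = sum_j occ_j f_j(s) T_j(h) exp(2 pi i h.x_j), with isotropic
#' Debye-Waller T = exp(-B s^2 / 4) or anisotropic
#' T = exp(-2 pi^2 s^T U s). The `fft` method samples Gaussian atomic
#' density on a fine grid (with an extra smearing B that is deconvolved
#' in reciprocal space) and Fourier-transforms it; it exists as an
#' independent route for cross-validation and large models.
#'
#' @param model A [crystal_model()]; all elements must be in the
#'   built-in form-factor table.
#' @param d_min High-resolution limit (Angstrom).
#' @param method "direct" (default) or "fft".
#' @return A `complex_sf_set`: tibble (h, k, l, f, phi, d) with the cell
#'   and resolution limits as attributes; phases in degrees in
#'   [-180, 180).
#' @export
calc_structure_factors <- function(model, d_min, method = c("direct", "fft")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "crystal_model"))
  if (nrow(model$atoms) == 0L) stop("empty model")
  hkl <- miller_set(model$cell, d_min)
  fvals <- if (method == "direct") {
    sf_direct(model, hkl)
  } else {
    sf_fft(model, hkl, d_min)
  }
  complex_sf_set(hkl$h, hkl$k, hkl$l, Mod(fvals),
                 phase_deg(fvals), model$cell)
}

sf_direct <- function(model, hkl) {
  at <- model$atoms
  hm <- hkl_matrix(hkl)
  s <- 1 / hkl$d
  frac <- cart_to_frac(atom_xyz(model), model$cell)
  # per-element form factors
  f_el <- vapply(at$element, function(e) scattering_factor(e, s),
                 numeric(length(s)))
  dim(f_el) <- c(length(s), nrow(at))
  coef <- f_el * dw_factors(model, hkl) *
    matrix(at$occ, length(s), nrow(at), byrow = TRUE)
  ph <- 2 * pi * (hm %*% t(frac))
  rowSums(coef * exp(1i * ph))
}

phase_deg <- function(z) {
  p <- Arg(z) * 180 / pi
  p[Mod(z) < 1e-12] <- 0
  ((p + 180) %% 360) - 180
}

# FFT route: sample sum-of-Gaussians density with extra smearing b_extra,
# forward-transform, deconvolve exp(+b_extra s^2/4).
sf_fft <- function(model, hkl, d_min, oversample = 4, b_extra = 20) {
  cell <- model$cell
  at <- model$atoms
  spacing <- d_min / oversample
  dims <- vapply(c(cell$a, cell$b, cell$c),
                 function(L) fft_friendly(ceiling(L / spacing)), integer(1))
  rho <- array(0, dims)
  A <- frac_to_cart_matrix(cell)
  frac <- cart_to_frac(atom_xyz(model), cell) %% 1
  # per-axis fractional half-width covering r_cut
  ax_len <- c(cell$a, cell$b, cell$c)
  for (j in seq_len(nrow(at))) {
    p <- cm_table[at$element[j], ]
    a_coef <- c(p[paste0("a", 1:4)], p["c"])
    b_coef <- c(p[paste0("b", 1:4)], 0)
    uj <- atom_u_matrix(at, j)
    bj <- if (is.null(uj)) at$b_iso[j] else 8 * pi^2 * max(eigen(uj)$values)
    b_eff <- b_coef + bj + b_extra
    r_cut <- sqrt(max(b_eff) * 20) / (2 * pi)
    nhw <- pmin(ceiling(r_cut / (ax_len / dims)) + 1L, floor((dims - 1) / 2))
    off <- expand.grid(dx = -nhw[1]:nhw[1], dy = -nhw[2]:nhw[2],
                       dz = -nhw[3]:nhw[3])
    centre <- round(frac[j, ] * dims)
    vox <- sweep(as.matrix(off), 2, centre, "+")
    dfrac <- sweep(sweep(vox, 2, dims, "/"), 2, frac[j, ], "-")
    dcart <- dfrac %*% t(A)
    r2 <- rowSums(dcart^2)
    dens <- numeric(length(r2))
    for (k in seq_along(a_coef)) {
      if (is.null(uj)) {
        bk <- b_coef[k] + at$b_iso[j] + b_extra
        dens <- dens + a_coef[k] * (4 * pi / bk)^1.5 *
          exp(-4 * pi^2 * r2 / bk)
      } else {
        # anisotropic Gaussian: F = a exp(-2 pi^2 s^T M s),
        # M = U + (b_k + b_extra)/(8 pi^2) I
        M <- uj + diag(3) * (b_coef[k] + b_extra) / (8 * pi^2)
        Mi <- solve(M)
        q <- rowSums((dcart %*% Mi) * dcart)
        dens <- dens + a_coef[k] * (2 * pi)^-1.5 / sqrt(det(M)) *
          exp(-q / 2)
      }
    }
    idx <- sweep(vox, 2, dims, "%%") + 1
    lin <- idx[, 1] + dims[1] * (idx[, 2] - 1) + dims[1] * dims[2] * (idx[, 3] - 1)
    acc <- rowsum(at$occ[j] * dens, lin)
    ii <- as.integer(rownames(acc))
    rho[ii] <- rho[ii] + acc[, 1]
  }
  Fgrid <- stats::fft(rho, inverse = TRUE) * (cell$volume / prod(dims))
  hm <- hkl_matrix(hkl)
  idx <- sweep(hm, 2, dims, "%%") + 1
  lin <- idx[, 1] + dims[1] * (idx[, 2] - 1) + dims[1] * dims[2] * (idx[, 3] - 1)
  Fgrid[lin] * exp(b_extra * (1 / hkl$d)^2 / 4)
}

fft_friendly <- function(n) {
  # next integer >= n whose prime factors are all <= 5 (fast mixed-radix FFT)
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}
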