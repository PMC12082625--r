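#' Fourier synthesis of an electron-density map
#'
#' Computes rho(x) = (1/V) sum_h F(h) exp(-2 pi i h.x) on a regular
#' grid, completing the Friedel-unique coefficient half-set with its
#' conjugate mates so the map is real. Values are on an e/A^3
#' -proportional scale; the mean and population sigma are cached.
#'
#' @param coeffs A `complex_sf_set`.
#' @param grid_spacing Target spacing (Angstrom); default `d_min / 3`.
#'   Must satisfy the Nyquist bound `<= d_min / 2`.
#' @param dims Optional explicit grid dimensions (length 3), overriding
#'   `grid_spacing`.
#' @return A `map_grid`: list with `values` (3D array), `dims`, `cell`,
#'   `mean`, `sigma`, `d_min`, `sigma_scaled`.
#' @export
synthesize_map <- function(coeffs, grid_spacing = NULL, dims = NULL) {
  stopifnot(inherits(coeffs, "complex_sf_set"))
  if (nrow(coeffs) == 0L) stop("empty coefficient set")
  cell <- refl_cell(coeffs)
  d_min <- attr(coeffs, "d_min")
  if (is.null(dims)) {
    if (is.null(grid_spacing)) grid_spacing <- d_min / 3
    if (grid_spacing > d_min / 2 + 1e-9) {
      stop(sprintf(paste0("grid spacing %.3f A is coarser than the Nyquist ",
                          "bound d_min/2 = %.3f A"), grid_spacing, d_min / 2))
    }
    dims <- vapply(c(cell$a, cell$b, cell$c),
                   function(L) fft_friendly(ceiling(L / grid_spacing)),
                   integer(1))
  }
  dims <- as.integer(dims)
  hm <- hkl_matrix(coeffs)
  hmax <- apply(abs(hm), 2, max)
  if (any(dims < 2L) || any(hmax >= dims / 2)) {
    stop(sprintf(paste0("grid %s cannot represent indices up to (%d %d %d): ",
                        "Nyquist bound violated"),
                 paste(dims, collapse = "x"), hmax[1], hmax[2], hmax[3]))
  }
  fv <- sf_complex(coeffs)
  vals <- fourier_synthesis(hm, fv, dims, cell$volume, check_real = TRUE)
  new_map_grid(vals, cell, d_min)
}

# Core synthesis: rho(n) = (1/V) sum_h F_h exp(-2 pi i h.n/N), Friedel
# mates added. `hm` is the unique half-set.
fourier_synthesis <- function(hm, fv, dims, volume, check_real = FALSE) {
  arr <- array(0 + 0i, dims)
  arr[hkl_linear(hm, dims)] <- fv
  arr[hkl_linear(-hm, dims)] <- Conj(fv)
  g <- stats::fft(arr)
  if (check_real) {
    imax <- max(abs(Im(g))); rmax <- max(abs(g))
    if (rmax > 0 && imax > 1e-8 * rmax) {
      stop("synthesized map is not real: Friedel completion failed")
    }
  }
  array(Re(g), dims) / volume
}

new_map_grid <- function(vals, cell, d_min, sigma_scaled = FALSE) {
  structure(list(values = vals, dims = dim(vals), cell = cell,
                 mean = mean(vals), sigma = stats::sd(as.vector(vals)) *
                   sqrt((length(vals) - 1) / length(vals)),
                 d_min = d_min, sigma_scaled = sigma_scaled),
            class = "map_grid")
}

#' @export
print.map_grid <- function(x, ...) {
  cat(sprintf("<map_grid> %s grid, cell %s\n  mean %.4g, sigma %.4g%s\n",
              paste(x$dims, collapse = "x"), format(x$cell),
              x$mean, x$sigma, if (x$sigma_scaled) " (sigma-scaled)" else ""))
  invisible(x)
}

hkl_linear <- function(hm, dims) {
  idx <- sweep(hm, 2, dims, "%%") + 1
  idx[, 1] + dims[1] * (idx[, 2] - 1) + dims[1] * dims[2] * (idx[, 3] - 1)
}

#' Rescale a map to sigma units
#'
#' Divides voxel values by the map sigma (a zero-sigma map is returned
#' unchanged but flagged scaled).
#'
#' @param map A `map_grid`.
#' @return A `map_grid` with `sigma_scaled = TRUE`.
#' @export
sigma_scale <- function(map) {
  if (map$sigma_scaled) return(map)
  vals <- if (map$sigma > 0) map$values / map$sigma else map$values
  out <- new_map_grid(vals, map$cell, map$d_min, sigma_scaled = TRUE)
  out
}

#' Numerical back-transform of a map
#'
#' Recovers complex structure factors F(h) = (V/Ngrid) sum_n rho(n)
#' exp(2 pi i h.n/N) at the requested indices; used to verify the
#' synthesis round trip.
#'
#' @param map A `map_grid`.
#' @param hkl Matrix or data frame of Miller indices.
#' @return Complex vector.
#' @export
map_structure_factors <- function(map, hkl) {
  hm <- hkl_matrix(hkl)
  Fg <- stats::fft(map$values, inverse = TRUE) *
    (map$cell$volume / prod(map$dims))
  Fg[hkl_linear(hm, map$dims)]
}

#' Voxel mask from atom-centred spheres
#'
#' Union of spheres of the given radius around the selected atoms,
#' mapped to voxel indices under periodic boundary conditions.
#'
#' @param grid A `map_grid` supplying dimensions and cell.
#' @param model A [crystal_model()] in the same cell.
#' @param selection Atom selection (see [atom_select()]); indices,
#'   logical mask, residue-name character vector, or filter list.
#' @param radius Sphere radius in Angstrom.
#' @return A `region_mask`: sorted unique linear voxel indices with
#'   grid dims and provenance attached.
#' @export
make_region_mask <- function(grid, model, selection, radius) {
  stopifnot(inherits(grid, "map_grid"), radius > 0)
  sel <- resolve_selection(model, selection)
  dims <- grid$dims
  cell <- grid$cell
  A <- frac_to_cart_matrix(cell)
  frac <- cart_to_frac(atom_xyz(model, sel), cell) %% 1
  ax_len <- c(cell$a, cell$b, cell$c)
  # conservative per-axis half-width: radius / smallest voxel extent
  nhw <- pmin(ceiling(radius / (ax_len / dims)) + 1L, floor(dims / 2))
  off <- as.matrix(expand.grid(-nhw[1]:nhw[1], -nhw[2]:nhw[2], -nhw[3]:nhw[3]))
  keep <- integer(0)
  for (j in seq_len(nrow(frac))) {
    centre <- round(frac[j, ] * dims)
    vox <- sweep(off, 2, centre, "+")
    dfrac <- sweep(sweep(vox, 2, dims, "/"), 2, frac[j, ], "-")
    dfrac <- dfrac - round(dfrac)  # minimum image
    r2 <- rowSums((dfrac %*% t(A))^2)
    inside <- vox[r2 <= radius^2, , drop = FALSE]
    if (nrow(inside) == 0L) inside <- matrix(round(frac[j, ] * dims), 1)
    keep <- c(keep, hkl_linear(inside, dims))
  }
  idx <- sort(unique(keep))
  structure(idx, dims = dims,
            provenance = list(selection = sel, radius = radius),
            class = "region_mask")
}

#' Integrate density in a masked region
#'
#' Sum of |rho| over masked voxels whose sign matches `sign` and whose
#' magnitude is at least `threshold_sigma` map sigmas.
#'
#' @param map A `map_grid`.
#' @param mask A `region_mask` on the same grid.
#' @param sign "negative", "positive" or "both".
#' @param threshold_sigma Magnitude threshold in map sigmas (default 3).
#' @param threshold_absolute Optional absolute magnitude threshold (map
#'   units) overriding `threshold_sigma`; use it to hold the threshold
#'   fixed across a series of maps.
#' @return Scalar sum of absolute density.
#' @export
integrate_region <- function(map, mask, sign = c("negative", "positive", "both"),
                             threshold_sigma = 3, threshold_absolute = NULL) {
  sign <- match.arg(sign)
  check_mask(map, mask)
  v <- map$values[as.integer(mask)]
  thr <- if (is.null(threshold_absolute)) {
    threshold_sigma * map$sigma
  } else {
    threshold_absolute
  }
  keep <- abs(v) >= thr
  keep <- keep & switch(sign, negative = v < 0, positive = v > 0, both = TRUE)
  sum(abs(v[keep]))
}

check_mask <- function(map, mask) {
  stopifnot(inherits(mask, "region_mask"))
  if (!identical(as.integer(attr(mask, "dims")), as.integer(map$dims))) {
    stop("mask grid dimensions do not match the map")
  }
  if (length(mask) == 0L) stop("empty region mask")
}

#' Correlation between two maps
#'
#' Pearson correlation of voxel values over a mask (or the whole grid).
#'
#' @param a,b `map_grid` objects on identical grids.
#' @param mask Optional `region_mask`; if given, must cover >= 10
#'   voxels.
#' @return Correlation in [-1, 1].
#' @export
map_correlation <- function(a, b, mask = NULL) {
  if (!identical(as.integer(a$dims), as.integer(b$dims))) {
    stop("maps are on different grids")
  }
  if (is.null(mask)) {
    va <- as.vector(a$values); vb <- as.vector(b$values)
  } else {
    check_mask(a, mask)
    if (length(mask) < 10L) stop("mask must cover at least 10 voxels")
    va <- a$values[as.integer(mask)]; vb <- b$values[as.integer(mask)]
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("map correlation undefined: zero variance")
  }
  stats::cor(va, vb)
}

# Local extrema above a sigma threshold; 26-neighbour comparison with
# periodic wrap. Returns a tibble sorted by |height| descending.
find_map_peaks <- function(map, threshold_sigma, model = NULL) {
  v <- map$values
  sg <- if (map$sigma_scaled) 1 else map$sigma
  if (sg == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                          height_sigma = numeric(0),
                          nearest_atom = character(0), distance = numeric(0)))
  }
  dims <- dim(v)
  is_max <- abs(v) >= threshold_sigma * sg
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, ]
  for (r in seq_len(nrow(shifts))) {
    sh <- shifts[r, ]
    w <- v[shift_index(dims[1], sh[1]), shift_index(dims[2], sh[2]),
           shift_index(dims[3], sh[3])]
    is_max <- is_max & (abs(v) >= abs(w))
    if (!any(is_max)) break
  }
  idx <- which(is_max)
  if (!length(idx)) {
    return(tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                          height_sigma = numeric(0),
                          nearest_atom = character(0), distance = numeric(0)))
  }
  ai <- arrayInd(idx, dims) - 1L
  frac <- sweep(ai, 2, dims, "/")
  cart <- frac_to_cart(frac, map$cell)
  out <- tibble::tibble(x = cart[, 1], y = cart[, 2], z = cart[, 3],
                        height_sigma = v[idx] / sg,
                        nearest_atom = NA_character_,
                        distance = NA_real_)
  if (!is.null(model)) {
    near <- nearest_atom_periodic(cart, model)
    out$nearest_atom <- near$label
    out$distance <- near$distance
  }
  out[order(-abs(out$height_sigma)), ]
}

shift_index <- function(n, s) ((seq_len(n) - 1 + s) %% n) + 1

nearest_atom_periodic <- function(cart, model) {
  fa <- cart_to_frac(atom_xyz(model), model$cell)
  fp <- cart_to_frac(cart, model$cell)
  A <- frac_to_cart_matrix(model$cell)
  lab <- paste0(model$atoms$resname, model$atoms$resid, "/", model$atoms$name)
  best_lab <- character(nrow(fp)); best_d <- numeric(nrow(fp))
  for (i in seq_len(nrow(fp))) {
    df <- sweep(fa, 2, fp[i, ], "-")
    df <- df - round(df)
    d <- sqrt(rowSums((df %*% t(A))^2))
    j <- which.min(d)
    best_lab[i] <- lab[j]; best_d[i] <- d[j]
  }
  list(label = best_lab, distance = best_d)
}
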