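#' Unit cell
#'
#' Construct a triclinic unit cell from edge lengths and angles. All
#' structure-factor and map arithmetic in the package goes through the
#' metric defined here.
#'
#' @param a,b,c Cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`: a named list with the six
#'   parameters plus the cached volume.
#' @examples
#' unit_cell(25, 25, 25)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  p <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(p))) stop("unit cell parameters must be finite")
  if (any(p[1:3] <= 0)) stop("cell lengths must be positive")
  if (any(p[4:6] <= 0 | p[4:6] >= 180)) {
    stop("cell angles must lie in (0, 180) degrees")
  }
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) stop("cell angles do not define a positive-definite metric")
  cell <- list(a = a, b = b, c = c, alpha = alpha, beta = beta,
               gamma = gamma, volume = a * b * c * sqrt(v2))
  structure(cell, class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' @export
format.unit_cell <- function(x, ...) {
  sprintf("%g %g %g %g %g %g", x$a, x$b, x$c, x$alpha, x$beta, x$gamma)
}

cell_equal <- function(a, b, tol = 1e-6) {
  all(abs(unlist(a[1:6]) - unlist(b[1:6])) < tol)
}

#' Orthogonalization matrix (fractional to Cartesian)
#'
#' Standard PDB convention: the first Cartesian axis lies along a, the
#' second in the a-b plane. Cartesian = M %*% fractional.
#'
#' @param cell A [unit_cell()].
#' @return 3x3 numeric matrix.
#' @export
frac_to_cart_matrix <- function(cell) {
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  v <- cell$volume / (cell$a * cell$b * cell$c)
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0, cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0, 0, cell$c * v / sg),
         nrow = 3, byrow = TRUE)
}

#' @rdname frac_to_cart_matrix
#' @export
cart_to_frac_matrix <- function(cell) solve(frac_to_cart_matrix(cell))

#' Convert coordinates between Cartesian and fractional
#'
#' @param xyz Numeric matrix (n x 3) or length-3 vector.
#' @param cell A [unit_cell()].
#' @return Matrix of the same shape.
#' @export
cart_to_frac <- function(xyz, cell) {
  xyz <- rbind3(xyz)
  t(cart_to_frac_matrix(cell) %*% t(xyz))
}

#' @rdname cart_to_frac
#' @export
frac_to_cart <- function(xyz, cell) {
  xyz <- rbind3(xyz)
  t(frac_to_cart_matrix(cell) %*% t(xyz))
}

rbind3 <- function(xyz) {
  if (is.null(dim(xyz))) matrix(xyz, ncol = 3) else as.matrix(xyz)
}

#' Resolution of reflections
#'
#' d-spacing of Miller indices in a given cell, via the reciprocal
#' metric tensor.
#'
#' @param hkl Integer matrix (n x 3) or a data frame with columns h, k, l.
#' @param cell A [unit_cell()].
#' @return Numeric vector of d (Angstrom).
#' @export
d_spacing <- function(hkl, cell) {
  hm <- hkl_matrix(hkl)
  s <- recip_vectors(hm, cell)
  1 / sqrt(rowSums(s^2))
}

# Cartesian reciprocal-space vectors (A^-1); |s| = 1/d.
recip_vectors <- function(hkl, cell) {
  hm <- hkl_matrix(hkl)
  hm %*% cart_to_frac_matrix(cell)  # rows: h . [a* b* c*] in Cartesian A^-1
}

hkl_matrix <- function(hkl) {
  if (is.data.frame(hkl)) hkl <- cbind(hkl$h, hkl$k, hkl$l)
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  storage.mode(hkl) <- "double"
  hkl
}
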