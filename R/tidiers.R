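#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an occupancy scan
#'
#' @param x An `occupancy_scan`.
#' @param ... Unused.
#' @return Tibble (n, neg_density, curvature).
#' @export
tidy.occupancy_scan <- function(x, ...) {
  tibble::tibble(n = x$n_grid, neg_density = x$neg_density,
                 curvature = x$curvature)
}

#' @rdname tidy.occupancy_scan
#' @export
glance.occupancy_scan <- function(x, ...) {
  tibble::tibble(n_est = x$n_est, n_trials = length(x$n_grid),
                 threshold_sigma = x$threshold_sigma)
}

#' Tidy a bending refinement
#'
#' @param x A `bending_result`.
#' @param ... Unused.
#' @return `tidy()`: the full (rho_c, rho_n, dfocc) score surface;
#'   `glance()`: one row with the refined angles and score.
#' @export
tidy.bending_result <- function(x, ...) x$surface

#' @rdname tidy.bending_result
#' @export
glance.bending_result <- function(x, ...) {
  tibble::tibble(rho_c = x$rho_c, rho_n = x$rho_n, dfocc = x$dfocc,
                 step = x$step, scan_bound = x$scan_bound)
}

#' @export
tidy.scale_result <- function(x, ...) {
  tibble::tibble(k = x$k, b_rel = x$b_rel, residual = x$residual,
                 n_common = x$n_common)
}

#' @export
tidy.bfactor_comparison <- function(x, ...) x$profile

#' @export
glance.bfactor_comparison <- function(x, ...) {
  tibble::tibble(r = x$r, n_residues = nrow(x$profile))
}

#' Plot an occupancy scan curve
#'
#' Integrated residual negative density against trial occupancy, with
#' the detected inflection marked.
#'
#' @param object An `occupancy_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.occupancy_scan <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$neg_density)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::geom_vline(xintercept = object$n_est, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "trial occupancy N",
                  y = "integrated residual negative density",
                  title = sprintf("occupancy scan: N_est = %.2f", object$n_est)) +
    ggplot2::theme_minimal()
}

#' Plot a dFoCC score surface
#'
#' @param object A `bending_result`.
#' @param ... Unused.
#' @return A ggplot raster of dFoCC over (rho_c, rho_n) with the
#'   optimum marked.
#' @export
autoplot.bending_result <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(x = .data$rho_c, y = .data$rho_n,
                               fill = .data$dfocc)) +
    ggplot2::geom_raster() +
    ggplot2::annotate("point", x = object$rho_c, y = object$rho_n,
                      shape = 4, size = 3, colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(rho[C] ~ "(deg)"),
                  y = expression(rho[N] ~ "(deg)"), fill = "dFoCC") +
    ggplot2::theme_minimal()
}

#' Plot difference-map peaks
#'
#' Peak heights (sigma) by nearest atom, signed.
#'
#' @param object A `ded_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ded_map <- function(object, ...) {
  pk <- object$peaks
  if (!nrow(pk)) stop("no peaks beyond the contour threshold")
  pk$rank <- seq_len(nrow(pk))
  ggplot2::ggplot(pk, ggplot2::aes(x = .data$rank, y = .data$height_sigma,
                                   fill = .data$height_sigma > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "forestgreen",
                                          `FALSE` = "firebrick")) +
    ggplot2::labs(x = "peak rank", y = "height (sigma)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
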