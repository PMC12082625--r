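#' Scale an observed amplitude set to a reference
#'
#' Fits a linear scale and relative isotropic B so that
#' `k * exp(-b_rel * s^2 / 4) * F` best matches the reference
#' amplitudes over the common Miller indices (least squares on
#' amplitudes, the classic isotropous scaling of isomorphous pairs).
#' Uncertainties are scaled identically.
#'
#' @param fo A `reflection_set` to be scaled.
#' @param ref A `reflection_set` or `complex_sf_set` providing reference
#'   amplitudes on (a superset of) the same indices.
#' @return List with `scaled` (the scaled `reflection_set`) and
#'   `result` (a `scale_result`: `k`, `b_rel`, `residual` = RMS
#'   relative misfit after scaling, `n_common`).
#' @export
scale_to_reference <- function(fo, ref) {
  stopifnot(inherits(fo, "reflection_set"))
  j <- join_hkl(fo, ref, suffix = c("_fo", "_ref"))
  j <- j[j$f_fo > 0 & j$f_ref > 0, ]
  if (nrow(j) < 50L) {
    stop("need at least 50 positive common reflections for scaling, have ",
         nrow(j))
  }
  s2 <- (1 / j$d_fo)^2
  # log-linear start: log(ref/fo) = log k - b s^2/4
  fit0 <- stats::lm(log(j$f_ref / j$f_fo) ~ I(-s2 / 4))
  par0 <- c(log_k = unname(stats::coef(fit0)[1]),
            b_rel = unname(stats::coef(fit0)[2]))
  obj <- function(p) {
    sum((j$f_ref - exp(p[1]) * exp(-p[2] * s2 / 4) * j$f_fo)^2)
  }
  opt <- stats::optim(par0, obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  k <- exp(opt$par[1]); b_rel <- opt$par[2]
  fac <- k * exp(-b_rel * (1 / fo$d)^2 / 4)
  scaled <- reflection_set(fo$h, fo$k, fo$l, fo$f * fac, fo$sigf * fac,
                           refl_cell(fo))
  pred <- k * exp(-b_rel * s2 / 4) * j$f_fo
  res <- sqrt(mean(((j$f_ref - pred) / pmax(j$f_ref, 1e-12))^2))
  result <- structure(list(k = unname(k), b_rel = unname(b_rel),
                           residual = res, n_common = nrow(j)),
                      class = "scale_result")
  list(scaled = scaled, result = result)
}

#' @export
print.scale_result <- function(x, ...) {
  cat(sprintf("<scale_result> k = %.6g, b_rel = %.4g A^2, RMS rel misfit = %.3g (n = %d)\n",
              x$k, x$b_rel, x$residual, x$n_common))
  invisible(x)
}

#' Bayesian-weighted normalized difference structure factors
#'
#' Forms per-reflection isomorphous differences
#' `deltaF = F_x - F_dark` on the common indices of two scaled sets and
#' down-weights noisy or outlying differences shell by shell:
#' `w = 1 / (1 + sig^2/<sig^2> + alpha * dF^2/<dF^2>)` with shell
#' averages over equal-count resolution shells, then renormalizes so
#' the weighted differences keep their shell-wise scale:
#' `dFo_WN = w * deltaF / <w>`.
#'
#' @param fo_x,fo_dark Scaled `reflection_set`s (perturbed and dark).
#' @param alpha Outlier-term weight (>= 0); 0 gives pure sigma
#'   weighting.
#' @param n_shells Number of equal-count resolution shells.
#' @return A `weighted_difference_set`: tibble (h, k, l, d, delta_f,
#'   sig_delta_f, w, dfo_wn, shell) with the cell and parameters as
#'   attributes.
#' @export
qweight_differences <- function(fo_x, fo_dark, alpha = 1, n_shells = 20) {
  stopifnot(alpha >= 0, n_shells >= 1)
  j <- join_hkl(fo_x, fo_dark, suffix = c("_x", "_dark"))
  if (nrow(j) < 50L) stop("need at least 50 common reflections, have ", nrow(j))
  if (nrow(j) < n_shells) {
    stop("a resolution shell would be empty: use fewer shells (have ",
         nrow(j), " reflections for ", n_shells, " shells)")
  }
  out <- tibble::tibble(h = j$h, k = j$k, l = j$l, d = j$d_x,
                        delta_f = j$f_x - j$f_dark,
                        sig_delta_f = sqrt(j$sigf_x^2 + j$sigf_dark^2))
  ord <- order(-out$d)
  shell <- integer(nrow(out))
  shell[ord] <- ceiling(seq_along(ord) / (length(ord) / n_shells))
  shell <- pmin(shell, n_shells)
  out$shell <- shell
  out <- out |>
    dplyr::group_by(.data$shell) |>
    dplyr::mutate(
      w = {
        ms <- mean(.data$sig_delta_f^2)
        md <- mean(.data$delta_f^2)
        t1 <- if (ms > 0) .data$sig_delta_f^2 / ms else 0
        t2 <- if (md > 0) alpha * .data$delta_f^2 / md else 0
        1 / (1 + t1 + t2)
      },
      dfo_wn = .data$w * .data$delta_f / mean(.data$w)) |>
    dplyr::ungroup()
  out <- out[, c("h", "k", "l", "d", "delta_f", "sig_delta_f", "w",
                 "dfo_wn", "shell")]
  attr(out, "cell") <- refl_cell(fo_x)
  attr(out, "alpha") <- alpha
  attr(out, "n_shells") <- n_shells
  attr(out, "d_min") <- min(out$d)
  class(out) <- c("weighted_difference_set", class(out))
  out
}

#' Observed-observed difference electron density map
#'
#' Fourier synthesis with coefficients `dFo_WN * exp(i * PHIc_dark)`,
#' i.e. weighted isomorphous differences phased with the dark model.
#' Reflections beyond the low-resolution cutoff (default 10 Angstrom)
#' are excluded; the map is sigma-scaled and peaks above the contour
#' threshold are listed.
#'
#' @param diffs A `weighted_difference_set`.
#' @param phic_dark A `complex_sf_set` providing phases for every
#'   difference index.
#' @param low_cut Low-resolution cutoff in Angstrom (reflections with
#'   d > low_cut are dropped).
#' @param grid_spacing,dims Passed to [synthesize_map()].
#' @param contour Peak-listing threshold in map sigmas.
#' @param model Optional [crystal_model()] used to annotate peaks with
#'   their nearest atom.
#' @return A `ded_map`: list with `map` (sigma-scaled `map_grid`),
#'   `peaks` (tibble: x, y, z, height_sigma, nearest_atom, distance),
#'   `contour`, `resolution` (c(low, high)).
#' @export
fofo_map <- function(diffs, phic_dark, low_cut = 10, grid_spacing = NULL,
                     dims = NULL, contour = 3.5, model = NULL) {
  stopifnot(inherits(diffs, "weighted_difference_set"))
  j <- dplyr::left_join(tibble::as_tibble(diffs),
                        tibble::as_tibble(phic_dark)[, c("h", "k", "l", "phi")],
                        by = c("h", "k", "l"))
  nmiss <- sum(is.na(j$phi))
  if (nmiss > 0) stop(nmiss, " difference reflections have no dark phase")
  j <- j[j$d <= low_cut, ]
  if (nrow(j) == 0L) stop("no reflections survive the low-resolution cutoff")
  # signed amplitude as amplitude+phase flip
  amp <- abs(j$dfo_wn)
  phi <- j$phi + ifelse(j$dfo_wn < 0, 180, 0)
  coeffs <- complex_sf_set(j$h, j$k, j$l, amp, phi, attr(diffs, "cell"))
  map <- synthesize_map(coeffs, grid_spacing = grid_spacing, dims = dims)
  smap <- sigma_scale(map)
  peaks <- find_map_peaks(smap, contour, model = model)
  structure(list(map = smap, peaks = peaks, contour = contour,
                 resolution = c(low = low_cut, high = min(j$d))),
            class = "ded_map")
}

#' @export
print.ded_map <- function(x, ...) {
  cat(sprintf("<ded_map> %s grid, %.1f-%.2f A, %d peaks beyond %.1f sigma\n",
              paste(x$map$dims, collapse = "x"), x$resolution[1],
              x$resolution[2], nrow(x$peaks), x$contour))
  if (nrow(x$peaks)) print(utils::head(x$peaks, 5))
  invisible(x)
}
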