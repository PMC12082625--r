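#' Minimum edge-to-edge distance between two selections
#'
#' Minimum Cartesian distance over all non-hydrogen atom pairs of the
#' two selections. By default no periodic images are considered
#' (intramolecular comparisons); set `periodic = TRUE` to search
#' minimum-image distances.
#'
#' @param model A [crystal_model()].
#' @param selA,selB Atom selections (see [atom_select()]).
#' @param periodic Use minimum-image convention.
#' @return Distance in Angstrom.
#' @export
min_edge_distance <- function(model, selA, selB, periodic = FALSE) {
  ia <- resolve_selection(model, selA)
  ib <- resolve_selection(model, selB)
  ia <- ia[model$atoms$element[ia] != "H"]
  ib <- ib[model$atoms$element[ib] != "H"]
  if (!length(ia) || !length(ib)) stop("selection contains no non-hydrogen atom")
  xa <- atom_xyz(model, ia); xb <- atom_xyz(model, ib)
  if (!periodic) {
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
    return(sqrt(max(0, min(d2))))
  }
  A <- frac_to_cart_matrix(model$cell)
  fa <- cart_to_frac(xa, model$cell); fb <- cart_to_frac(xb, model$cell)
  best <- Inf
  for (i in seq_len(nrow(fa))) {
    df <- sweep(fb, 2, fa[i, ], "-")
    df <- df - round(df)
    best <- min(best, sqrt(min(rowSums((df %*% t(A))^2))))
  }
  best
}

# standard dihedral about b2 = p3 - p2; IUPAC sign, degrees in [-180, 180)
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop("dihedral undefined: collinear atoms")
  }
  ang <- atan2(sqrt(sum(b2^2)) * sum(b1 * n2), sum(n1 * n2)) * 180 / pi
  ((ang + 180) %% 360) - 180
}

#' Backbone phi/psi dihedrals
#'
#' Standard IUPAC convention: phi = C(i-1)-N(i)-CA(i)-C(i), psi =
#' N(i)-CA(i)-C(i)-N(i+1). Residues must provide N, CA, C atoms; a
#' chain break (peptide C-N distance > 2.5 Angstrom) omits the
#' affected dihedral with a warning.
#'
#' @param model A [crystal_model()].
#' @param resid Optional residue numbers to report (default: all with
#'   computable angles).
#' @param chain Chain to use (default: first chain present).
#' @return Tibble (chain, resid, resname, phi, psi); angles in degrees
#'   in [-180, 180), `NA` where undefined.
#' @export
backbone_phipsi <- function(model, resid = NULL, chain = NULL) {
  a <- model$atoms
  if (is.null(chain)) chain <- a$chain[1]
  a <- a[a$chain == chain & toupper(a$name) %in% c("N", "CA", "C"), ]
  if (nrow(a) == 0L) stop("no backbone atoms (N, CA, C) in chain ", chain)
  res_ids <- sort(unique(a$resid))
  get_at <- function(rid, nm) {
    r <- a[a$resid == rid & toupper(a$name) == nm, ]
    if (nrow(r) != 1L) return(NULL)
    c(r$x, r$y, r$z)
  }
  resname_of <- function(rid) {
    r <- a[a$resid == rid, ]
    if (nrow(r)) r$resname[1] else NA_character_
  }
  bonded <- function(cpos, npos) {
    !is.null(cpos) && !is.null(npos) && sqrt(sum((npos - cpos)^2)) <= 2.5
  }
  rows <- purrr::map(res_ids, function(rid) {
    N <- get_at(rid, "N"); CA <- get_at(rid, "CA"); C <- get_at(rid, "C")
    phi <- psi <- NA_real_
    Cm <- get_at(rid - 1L, "C")
    Np <- get_at(rid + 1L, "N")
    if (!is.null(N) && !is.null(CA) && !is.null(C)) {
      if (!is.null(Cm)) {
        if (bonded(Cm, N)) {
          phi <- dihedral_angle(Cm, N, CA, C)
        } else {
          warning("chain break before residue ", rid, ": phi omitted")
        }
      }
      if (!is.null(Np)) {
        if (bonded(C, Np)) {
          psi <- dihedral_angle(N, CA, C, Np)
        } else {
          warning("chain break after residue ", rid, ": psi omitted")
        }
      }
    }
    tibble::tibble(chain = chain, resid = rid, resname = resname_of(rid),
                   phi = phi, psi = psi)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(resid)) out <- out[out$resid %in% resid, ]
  out
}

#' Per-atom displacement between two isomorphous states
#'
#' Atoms are matched by chain/residue/name; distances are computed in
#' the common crystal frame by default (no superposition), which is
#' the natural comparison for isomorphous pairs. Optionally a
#' least-squares (Kabsch) superposition on a stated selection is
#' applied first.
#'
#' @param stateA,stateB [crystal_model()]s with matching atoms.
#' @param selection Atoms to report (default all matched).
#' @param superpose Apply least-squares superposition first.
#' @param fit_selection Atoms (of `stateA`) defining the superposition
#'   fit; defaults to all matched atoms.
#' @return Tibble (name, resname, resid, chain, displacement) in
#'   Angstrom. Unmatched atoms are excluded with a warning.
#' @export
displacement_profile <- function(stateA, stateB, selection = NULL,
                                 superpose = FALSE, fit_selection = NULL) {
  keyA <- with(stateA$atoms, paste(chain, resid, name))
  keyB <- with(stateB$atoms, paste(chain, resid, name))
  pos <- match(keyA, keyB)
  un <- which(is.na(pos))
  if (length(un)) {
    warning(length(un), " unmatched atom(s) excluded: ",
            paste(utils::head(keyA[un], 5), collapse = ", "))
  }
  ia <- which(!is.na(pos)); ib <- pos[ia]
  xa <- atom_xyz(stateA, ia); xb <- atom_xyz(stateB, ib)
  if (superpose) {
    fit_ia <- if (is.null(fit_selection)) {
      seq_along(ia)
    } else {
      match(resolve_selection(stateA, fit_selection), ia)
    }
    fit_ia <- fit_ia[!is.na(fit_ia)]
    if (length(fit_ia) < 3L) stop("superposition needs >= 3 matched fit atoms")
    tr <- kabsch(xb[fit_ia, , drop = FALSE], xa[fit_ia, , drop = FALSE])
    xb <- sweep(xb, 2, tr$center_from) %*% tr$rotation
    xb <- sweep(xb, 2, tr$center_to, "+")
  }
  disp <- sqrt(rowSums((xa - xb)^2))
  out <- tibble::tibble(name = stateA$atoms$name[ia],
                        resname = stateA$atoms$resname[ia],
                        resid = stateA$atoms$resid[ia],
                        chain = stateA$atoms$chain[ia],
                        displacement = disp)
  if (!is.null(selection)) {
    keep <- ia %in% resolve_selection(stateA, selection)
    out <- out[keep, ]
  }
  out
}

# least-squares rotation carrying `from` onto `to` (row coordinate sets)
kabsch <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  H <- crossprod(sweep(from, 2, cf), sweep(to, 2, ct))
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(rotation = R, center_from = cf, center_to = ct)
}

#' Main-chain B-factor profiles and their correlation
#'
#' Per-residue mean main-chain (N, CA, C, O) isotropic B of two models
#' on their matched residues, with the Pearson correlation between the
#' two profiles.
#'
#' @param modelA,modelB [crystal_model()]s.
#' @param main_chain Atom names considered main chain.
#' @return A `bfactor_comparison`: list with `profile` (tibble chain,
#'   resid, b_a, b_b) and `r` (Pearson correlation).
#' @export
bfactor_profiles <- function(modelA, modelB,
                             main_chain = c("N", "CA", "C", "O")) {
  prof <- function(m) {
    a <- m$atoms
    keep <- if (any(toupper(a$name) %in% main_chain)) {
      toupper(a$name) %in% main_chain
    } else {
      rep(TRUE, nrow(a))  # non-peptide models: all atoms
    }
    a[keep, ] |>
      dplyr::group_by(.data$chain, .data$resid) |>
      dplyr::summarise(b = mean(.data$b_iso), .groups = "drop")
  }
  j <- dplyr::inner_join(prof(modelA), prof(modelB),
                         by = c("chain", "resid"), suffix = c("_a", "_b"))
  if (nrow(j) < 3L) stop("fewer than 3 matched residues")
  r <- stats::cor(j$b_a, j$b_b)
  structure(list(profile = j, r = r), class = "bfactor_comparison")
}

#' @export
print.bfactor_comparison <- function(x, ...) {
  cat(sprintf("<bfactor_comparison> %d residues, Pearson r = %.3f\n",
              nrow(x$profile), x$r))
  invisible(x)
}

#' Anisotropic displacement eigen-analysis
#'
#' Eigen-decomposes the Cartesian U tensor of every anisotropic atom:
#' principal displacements (descending), equivalent isotropic Ueq =
#' trace/3 and the anisotropy ratio lambda_min/lambda_max.
#' Non-positive-definite tensors are flagged, not dropped.
#'
#' @param model A [crystal_model()] (or a list of symmetric 3x3
#'   matrices).
#' @param selection Optional atom selection; default all anisotropic
#'   atoms.
#' @return Tibble (name, resname, resid, lambda1..lambda3, ueq,
#'   anisotropy, positive_definite).
#' @export
adp_eigen <- function(model, selection = NULL) {
  if (is.list(model) && !inherits(model, "crystal_model")) {
    tensors <- model
    labels <- tibble::tibble(name = paste0("U", seq_along(tensors)),
                             resname = NA_character_, resid = NA_integer_)
  } else {
    sel <- if (is.null(selection)) {
      which(has_aniso(model$atoms))
    } else {
      intersect(resolve_selection(model, selection),
                which(has_aniso(model$atoms)))
    }
    if (!length(sel)) stop("no atoms with anisotropic U in selection")
    tensors <- lapply(sel, function(i) atom_u_matrix(model$atoms, i))
    labels <- model$atoms[sel, c("name", "resname", "resid")]
  }
  rows <- purrr::imap(tensors, function(u, i) {
    u <- as.matrix(u)
    if (max(abs(u - t(u))) > 1e-8) stop("asymmetric U tensor for atom ", i)
    ev <- eigen((u + t(u)) / 2, symmetric = TRUE, only.values = TRUE)$values
    tibble::tibble(lambda1 = ev[1], lambda2 = ev[2], lambda3 = ev[3],
                   ueq = mean(ev),
                   anisotropy = if (ev[1] > 0) ev[3] / ev[1] else NA_real_,
                   positive_definite = ev[3] > 0)
  })
  dplyr::bind_cols(tibble::as_tibble(labels), dplyr::bind_rows(rows))
}

#' Fraction of oxidized iron-sulfur cluster from difference absorbance
#'
#' Estimates the [4Fe-4S]3+ fraction from the 470 nm difference
#' absorbance of the oxidized-minus-reduced spectrum, referenced to
#' the flavin's 470 nm absorbance:
#' `fraction = (deltaA470 / delta_eps_470) / (A470_fad / eps_470_fad)`.
#' Defaults use the HiPIP-derived difference molar absorptivity
#' (8400 / M / cm) and the oxidized-flavin absorptivity (7500 / M /
#' cm).
#'
#' @param deltaA470 Difference absorbance at 470 nm.
#' @param A470_fad Flavin absorbance at 470 nm (> 0).
#' @param delta_eps_470,eps_470_fad Molar absorptivities (1/M/cm, > 0).
#' @return Fraction in [0, 1]; values outside are clamped with a
#'   warning.
#' @export
cluster_oxidation_fraction <- function(deltaA470, A470_fad,
                                       delta_eps_470 = 8400,
                                       eps_470_fad = 7500) {
  if (delta_eps_470 <= 0 || eps_470_fad <= 0) {
    stop("molar absorptivities must be positive")
  }
  if (A470_fad <= 0) stop("A470_fad must be positive")
  frac <- (deltaA470 / delta_eps_470) / (A470_fad / eps_470_fad)
  if (frac < 0 || frac > 1) {
    warning(sprintf("oxidation fraction %.3g outside [0, 1]: clamped", frac))
    frac <- min(1, max(0, frac))
  }
  frac
}
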