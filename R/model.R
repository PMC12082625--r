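#' Crystal model
#'
#' A crystal model couples a unit cell with an ordered atom table. Atom
#' coordinates are Cartesian Angstrom externally; fractionalization
#' happens internally wherever reciprocal-space math needs it.
#'
#' The atom table is a tibble with columns `name`, `element`, `resname`,
#' `resid`, `chain`, `x`, `y`, `z`, `occ`, `b_iso` and the six Cartesian
#' anisotropic displacement components `u11, u22, u33, u12, u13, u23`
#' (all `NA` for isotropic atoms).
#'
#' @param cell A [unit_cell()].
#' @param atoms A data frame with at least `name`, `element`, `x`, `y`,
#'   `z`; missing `occ` defaults to 1, `b_iso` to 20, residue fields to
#'   a single residue "UNK 1".
#' @param spacegroup Space-group label; all synthetic work is P1.
#' @return An object of class `crystal_model`.
#' @export
crystal_model <- function(cell, atoms, spacegroup = "P1") {
  stopifnot(inherits(cell, "unit_cell"))
  atoms <- tibble::as_tibble(atoms)
  if (nrow(atoms) < 1L) stop("a crystal model needs at least one atom")
  need <- c("name", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  defaults <- list(occ = 1, b_iso = 20, resname = "UNK", resid = 1L,
                   chain = "A", u11 = NA_real_, u22 = NA_real_,
                   u33 = NA_real_, u12 = NA_real_, u13 = NA_real_,
                   u23 = NA_real_)
  for (col in names(defaults)) {
    if (!col %in% names(atoms)) atoms[[col]] <- defaults[[col]]
  }
  if (any(atoms$occ < 0 | atoms$occ > 1)) stop("occupancies must lie in [0, 1]")
  if (any(atoms$b_iso < 0)) stop("b_iso must be non-negative")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atom coordinates must be finite")
  }
  ueq <- (atoms$u11 + atoms$u22 + atoms$u33) / 3
  if (any(!is.na(ueq) & ueq < 0)) stop("anisotropic U has negative Ueq")
  bad <- setdiff(unique(atoms$element), rownames(cm_table))
  if (length(bad)) {
    stop("unknown element(s): ", paste(bad, collapse = ", "),
         "; supported: ", paste(rownames(cm_table), collapse = ", "))
  }
  structure(list(cell = cell, atoms = atoms, spacegroup = spacegroup),
            class = "crystal_model")
}

#' @export
print.crystal_model <- function(x, ...) {
  cat(sprintf("<crystal_model> %d atoms, %s, cell %s\n",
              nrow(x$atoms), x$spacegroup, format(x$cell)))
  invisible(x)
}

n_atoms <- function(model) nrow(model$atoms)

atom_xyz <- function(model, sel = NULL) {
  m <- as.matrix(model$atoms[, c("x", "y", "z")])
  if (!is.null(sel)) m <- m[sel, , drop = FALSE]
  m
}

`atom_xyz<-` <- function(model, sel = NULL, value) {
  if (is.null(sel)) sel <- seq_len(nrow(model$atoms))
  model$atoms[sel, c("x", "y", "z")] <- as.data.frame(value) |>
    stats::setNames(c("x", "y", "z"))
  model
}

#' Select atoms of a crystal model
#'
#' Returns the integer indices of atoms matching all given filters
#' (each filter is a vector of allowed values; `NULL` means no
#' constraint).
#'
#' @param model A [crystal_model()].
#' @param name,element,resname,resid,chain Optional filters.
#' @return Integer vector of atom indices, in model order.
#' @export
atom_select <- function(model, name = NULL, element = NULL, resname = NULL,
                        resid = NULL, chain = NULL) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  which(keep)
}

# Resolve a selection argument: integer indices, logical mask, a character
# vector of residue names, or a list of atom_select() filters.
resolve_selection <- function(model, selection) {
  n <- nrow(model$atoms)
  idx <- if (is.null(selection)) {
    seq_len(n)
  } else if (is.numeric(selection)) {
    as.integer(selection)
  } else if (is.logical(selection)) {
    which(selection)
  } else if (is.character(selection)) {
    atom_select(model, resname = selection)
  } else if (is.list(selection)) {
    do.call(atom_select, c(list(model), selection))
  } else {
    stop("unsupported selection type")
  }
  if (length(idx) == 0L) stop("selection matches no atom")
  if (any(idx < 1L | idx > n)) stop("selection index out of range")
  idx
}

# 3x3 U tensors (Cartesian A^2) for the selected atoms, NULL where isotropic
atom_u_matrix <- function(atoms, i) {
  u <- unlist(atoms[i, c("u11", "u22", "u33", "u12", "u13", "u23")])
  if (any(is.na(u))) return(NULL)
  matrix(c(u[1], u[4], u[5],
           u[4], u[2], u[6],
           u[5], u[6], u[3]), 3, 3)
}

has_aniso <- function(atoms) !is.na(atoms$u11)
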