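#' Read an atomic model
#'
#' Reads PDB (ATOM/HETATM/ANISOU/CRYST1 records) or a minimal mmCIF
#' (`atom_site` and `atom_site_anisotrop` loops plus `cell` items) into
#' a [crystal_model()]. Atoms keep file order; anisotropic displacement
#' records are attached to their atoms when present. ANISOU / mmCIF U
#' values are taken as Cartesian U (A^2).
#'
#' @param path Path to the file.
#' @param format "pdb" or "cif"; guessed from the extension by default.
#' @return A [crystal_model()].
#' @export
read_model <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  if (format == "pdb") read_pdb_model(path) else read_cif_model(path)
}

#' Write an atomic model
#'
#' @param model A [crystal_model()].
#' @param path Output path.
#' @param format "pdb" or "cif"; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  if (format == "pdb") write_pdb_model(model, path) else write_cif_model(model, path)
  invisible(path)
}

pdb_num <- function(line, lo, hi, what, ln) {
  s <- substr(line, lo, hi)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) {
    stop(sprintf("PDB parse error at line %d, field %s: %s", ln, what,
                 dQuote(trimws(s))))
  }
  v
}

read_pdb_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cell <- NULL
  atoms <- list()
  aniso <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    rec <- substr(line, 1, 6)
    if (rec == "CRYST1") {
      cell <- unit_cell(pdb_num(line, 7, 15, "a", ln), pdb_num(line, 16, 24, "b", ln),
                        pdb_num(line, 25, 33, "c", ln), pdb_num(line, 34, 40, "alpha", ln),
                        pdb_num(line, 41, 47, "beta", ln), pdb_num(line, 48, 54, "gamma", ln))
    } else if (rec %in% c("ATOM  ", "HETATM")) {
      el <- trimws(substr(line, 77, 78))
      if (el == "") el <- toupper(substr(trimws(substr(line, 13, 16)), 1, 1))
      el <- paste0(substr(el, 1, 1), tolower(substr(el, 2, 2)))
      atoms[[length(atoms) + 1L]] <- tibble::tibble(
        name = trimws(substr(line, 13, 16)),
        element = el,
        resname = trimws(substr(line, 18, 20)),
        resid = as.integer(pdb_num(line, 23, 26, "resSeq", ln)),
        chain = trimws(substr(line, 22, 22)),
        x = pdb_num(line, 31, 38, "x", ln),
        y = pdb_num(line, 39, 46, "y", ln),
        z = pdb_num(line, 47, 54, "z", ln),
        occ = pdb_num(line, 55, 60, "occupancy", ln),
        b_iso = pdb_num(line, 61, 66, "tempFactor", ln))
    } else if (rec == "ANISOU") {
      u <- vapply(seq_len(6), function(i) {
        pdb_num(line, 29 + 7 * (i - 1), 35 + 7 * (i - 1), paste0("U", i), ln)
      }, numeric(1)) / 1e4
      aniso[[length(aniso) + 1L]] <- c(idx = length(atoms), u)
    }
  }
  if (length(atoms) == 0L) stop("no ATOM/HETATM records in ", path)
  at <- dplyr::bind_rows(atoms)
  for (u in c("u11", "u22", "u33", "u12", "u13", "u23")) at[[u]] <- NA_real_
  for (an in aniso) {
    i <- an[["idx"]]
    if (i >= 1) at[i, c("u11", "u22", "u33", "u12", "u13", "u23")] <-
        as.list(unname(an[-1]))
  }
  if (is.null(cell)) stop("no CRYST1 record in ", path)
  crystal_model(cell, at)
}

write_pdb_model <- function(model, path) {
  cl <- model$cell
  out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                 cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma,
                 model$spacegroup)
  a <- model$atoms
  for (i in seq_len(nrow(a))) {
    nm <- a$name[i]
    nm <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
    out <- c(out, sprintf(
      "HETATM%5d %s %-3s%2s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i %% 100000L, nm, substr(a$resname[i], 1, 3), substr(a$chain[i], 1, 1),
      a$resid[i] %% 10000L, a$x[i], a$y[i], a$z[i], a$occ[i], a$b_iso[i],
      toupper(a$element[i])))
    if (has_aniso(a)[i]) {
      u <- round(unlist(a[i, c("u11", "u22", "u33", "u12", "u13", "u23")]) * 1e4)
      out <- c(out, sprintf(
        "ANISOU%5d %s %-3s%2s%4d  %7d%7d%7d%7d%7d%7d      %2s",
        i %% 100000L, nm, substr(a$resname[i], 1, 3), substr(a$chain[i], 1, 1),
        a$resid[i] %% 10000L, u[1], u[2], u[3], u[4], u[5], u[6],
        toupper(a$element[i])))
    }
  }
  writeLines(c(out, "END"), path)
}

cif_fields <- c("_atom_site.group_PDB", "_atom_site.id",
                "_atom_site.type_symbol", "_atom_site.label_atom_id",
                "_atom_site.label_comp_id", "_atom_site.label_asym_id",
                "_atom_site.label_seq_id", "_atom_site.Cartn_x",
                "_atom_site.Cartn_y", "_atom_site.Cartn_z",
                "_atom_site.occupancy", "_atom_site.B_iso_or_equiv")

write_cif_model <- function(model, path) {
  cl <- model$cell
  a <- model$atoms
  head <- c("data_redoxmap",
            sprintf("_cell.length_a %.4f", cl$a),
            sprintf("_cell.length_b %.4f", cl$b),
            sprintf("_cell.length_c %.4f", cl$c),
            sprintf("_cell.angle_alpha %.4f", cl$alpha),
            sprintf("_cell.angle_beta %.4f", cl$beta),
            sprintf("_cell.angle_gamma %.4f", cl$gamma),
            sprintf("_symmetry.space_group_name_H-M '%s'", model$spacegroup),
            "loop_", cif_fields)
  rows <- sprintf("HETATM %d %s %s %s %s %d %.4f %.4f %.4f %.4f %.4f",
                  seq_len(nrow(a)), toupper(a$element), a$name, a$resname,
                  a$chain, a$resid, a$x, a$y, a$z, a$occ, a$b_iso)
  out <- c(head, rows)
  wa <- which(has_aniso(a))
  if (length(wa)) {
    out <- c(out, "loop_",
             "_atom_site_anisotrop.id", "_atom_site_anisotrop.type_symbol",
             paste0("_atom_site_anisotrop.U[", c("1][1", "2][2", "3][3",
                                                 "1][2", "1][3", "2][3"), "]"),
             sprintf("%d %s %.6f %.6f %.6f %.6f %.6f %.6f",
                     wa, toupper(a$element[wa]), a$u11[wa], a$u22[wa],
                     a$u33[wa], a$u12[wa], a$u13[wa], a$u23[wa]))
  }
  writeLines(out, path)
}

cif_item <- function(lines, key) {
  hit <- grep(paste0("^", key, "\\b"), lines, value = TRUE)
  if (!length(hit)) stop("mmCIF item missing: ", key)
  as.numeric(strsplit(trimws(hit[[1]]), "\\s+")[[1]][2])
}

# Parse one loop_ whose header contains `tag`; returns a data frame of
# whitespace-separated tokens with the loop's column names.
cif_loop <- function(lines, tag) {
  starts <- which(trimws(lines) == "loop_")
  for (s in starts) {
    i <- s + 1L
    keys <- character()
    while (i <= length(lines) && grepl("^_", trimws(lines[i]))) {
      keys <- c(keys, trimws(lines[i])); i <- i + 1L
    }
    if (!any(grepl(tag, keys, fixed = TRUE))) next
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || grepl("^(_|loop_|data_|#)", ln)) break
      tok <- strsplit(ln, "\\s+")[[1]]
      if (length(tok) != length(keys)) {
        stop(sprintf("mmCIF parse error at line %d: %d tokens for %d columns",
                     i, length(tok), length(keys)))
      }
      rows[[length(rows) + 1L]] <- tok
      i <- i + 1L
    }
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- keys
    return(df)
  }
  NULL
}

read_cif_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cell <- unit_cell(cif_item(lines, "_cell.length_a"),
                    cif_item(lines, "_cell.length_b"),
                    cif_item(lines, "_cell.length_c"),
                    cif_item(lines, "_cell.angle_alpha"),
                    cif_item(lines, "_cell.angle_beta"),
                    cif_item(lines, "_cell.angle_gamma"))
  site <- cif_loop(lines, "_atom_site.Cartn_x")
  if (is.null(site)) stop("no atom_site loop in ", path)
  el <- site[["_atom_site.type_symbol"]]
  el <- paste0(substr(el, 1, 1), tolower(substr(el, 2, 2)))
  at <- tibble::tibble(
    name = site[["_atom_site.label_atom_id"]],
    element = el,
    resname = site[["_atom_site.label_comp_id"]],
    resid = as.integer(site[["_atom_site.label_seq_id"]]),
    chain = site[["_atom_site.label_asym_id"]],
    x = as.numeric(site[["_atom_site.Cartn_x"]]),
    y = as.numeric(site[["_atom_site.Cartn_y"]]),
    z = as.numeric(site[["_atom_site.Cartn_z"]]),
    occ = as.numeric(site[["_atom_site.occupancy"]]),
    b_iso = as.numeric(site[["_atom_site.B_iso_or_equiv"]]))
  for (u in c("u11", "u22", "u33", "u12", "u13", "u23")) at[[u]] <- NA_real_
  an <- cif_loop(lines, "_atom_site_anisotrop.U[1][1]")
  if (!is.null(an)) {
    idx <- as.integer(an[["_atom_site_anisotrop.id"]])
    ucols <- paste0("_atom_site_anisotrop.U[",
                    c("1][1", "2][2", "3][3", "1][2", "1][3", "2][3"), "]")
    at[idx, c("u11", "u22", "u33", "u12", "u13", "u23")] <-
      lapply(an[ucols], as.numeric)
  }
  crystal_model(cell, at)
}
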