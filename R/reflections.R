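#' Reflection sets
#'
#' `reflection_set()` holds observed amplitudes with uncertainties;
#' `complex_sf_set()` holds calculated amplitudes with phases. Both are
#' tibbles keyed by Miller index with the unit cell and resolution
#' limits attached as attributes.
#'
#' @param h,k,l Integer Miller indices (unique as triples).
#' @param f Amplitudes, non-negative.
#' @param sigf Standard uncertainties, non-negative.
#' @param phi Phases in degrees; stored wrapped to [-180, 180).
#' @param cell A [unit_cell()].
#' @return A tibble of class `reflection_set` (columns h, k, l, f,
#'   sigf, d) or `complex_sf_set` (columns h, k, l, f, phi, d).
#' @export
reflection_set <- function(h, k, l, f, sigf, cell) {
  check_hkl_unique(h, k, l)
  if (any(f < 0)) stop("amplitudes must be non-negative")
  if (any(sigf < 0)) stop("sigF must be non-negative")
  d <- d_spacing(cbind(h, k, l), cell)
  out <- tibble::tibble(h = as.integer(h), k = as.integer(k),
                        l = as.integer(l), f = as.numeric(f),
                        sigf = as.numeric(sigf), d = d)
  new_refl(out, cell, "reflection_set")
}

#' @rdname reflection_set
#' @export
complex_sf_set <- function(h, k, l, f, phi, cell) {
  check_hkl_unique(h, k, l)
  if (any(f < 0)) stop("amplitudes must be non-negative")
  d <- d_spacing(cbind(h, k, l), cell)
  out <- tibble::tibble(h = as.integer(h), k = as.integer(k),
                        l = as.integer(l), f = as.numeric(f),
                        phi = ((as.numeric(phi) + 180) %% 360) - 180, d = d)
  new_refl(out, cell, "complex_sf_set")
}

new_refl <- function(tbl, cell, cls) {
  attr(tbl, "cell") <- cell
  attr(tbl, "d_min") <- min(tbl$d)
  attr(tbl, "d_max") <- max(tbl$d)
  class(tbl) <- c(cls, class(tbl))
  tbl
}

check_hkl_unique <- function(h, k, l) {
  if (anyDuplicated(paste(h, k, l))) stop("duplicate Miller indices")
}

refl_cell <- function(x) attr(x, "cell")

sf_complex <- function(x) complex(modulus = x$f, argument = x$phi * pi / 180)

#' Read and write the plain-text reflection table dialect
#'
#' Tab-separated, one reflection per line, with a final header line
#' `# h k l F sigF` or `# h k l F phi`; a preceding `# cell a b c alpha
#' beta gamma` line carries the unit cell (if absent, `cell` must be
#' given). Duplicate indices are rejected.
#'
#' @param path File path.
#' @param cell Optional [unit_cell()] overriding the `# cell` line.
#' @param x A `reflection_set` or `complex_sf_set`.
#' @return `read_reflections_tsv()`: a `reflection_set` or
#'   `complex_sf_set`, depending on the header.
#' @export
read_reflections_tsv <- function(path, cell = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  cl <- grep("^# cell ", hdr, value = TRUE)
  if (is.null(cell)) {
    if (!length(cl)) stop("no '# cell' line and no cell supplied for ", path)
    v <- as.numeric(strsplit(trimws(sub("^# cell", "", cl[[1]])), "\\s+")[[1]])
    cell <- unit_cell(v[1], v[2], v[3], v[4], v[5], v[6])
  }
  colhdr <- grep("^# h\tk\tl", hdr, value = TRUE)
  if (!length(colhdr)) stop("missing '# h\tk\tl ...' header line in ", path)
  cols <- strsplit(sub("^# ", "", colhdr[[1]]), "\t")[[1]]
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) stop("no reflections in ", path)
  m <- utils::read.table(text = body, sep = "\t", col.names = cols,
                         colClasses = "numeric")
  if (identical(cols[4:5], c("F", "sigF"))) {
    reflection_set(m$h, m$k, m$l, m$F, m$sigF, cell)
  } else if (identical(cols[4:5], c("F", "phi"))) {
    complex_sf_set(m$h, m$k, m$l, m$F, m$phi, cell)
  } else {
    stop("unrecognized reflection columns: ", paste(cols, collapse = " "))
  }
}

#' @rdname read_reflections_tsv
#' @export
write_reflections_tsv <- function(x, path) {
  cell <- refl_cell(x)
  hdr <- sprintf("# cell %.6g %.6g %.6g %.6g %.6g %.6g",
                 cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma)
  if (inherits(x, "complex_sf_set")) {
    lines <- c(hdr, "# h\tk\tl\tF\tphi",
               sprintf("%d\t%d\t%d\t%.8g\t%.8g", x$h, x$k, x$l, x$f, x$phi))
  } else {
    lines <- c(hdr, "# h\tk\tl\tF\tsigF",
               sprintf("%d\t%d\t%d\t%.8g\t%.8g", x$h, x$k, x$l, x$f, x$sigf))
  }
  writeLines(lines, path)
  invisible(path)
}

# inner join of two reflection tables on hkl, suffixing value columns
join_hkl <- function(a, b, suffix = c("_a", "_b")) {
  dplyr::inner_join(tibble::as_tibble(a), tibble::as_tibble(b),
                    by = c("h", "k", "l"), suffix = suffix)
}
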