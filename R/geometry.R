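#' Construct a molecular geometry
#'
#' @param atoms character vector of element symbols.
#' @param coords numeric matrix (n x 3) of Cartesian positions in Angstrom.
#' @param charge integer total charge.
#' @param spin_multiplicity integer spin multiplicity (only 1, closed shell,
#'   is supported by the mean-field backend).
#' @return an object of class `geometry`.
#' @export
geometry <- function(atoms, coords, charge = 0L, spin_multiplicity = 1L) {
  coords <- as.matrix(coords)
  stopifnot(is.character(atoms), ncol(coords) == 3,
            length(atoms) == nrow(coords))
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!all(atoms %in% names(.element_numbers))) {
    stop("unknown element symbol(s): ",
         paste(setdiff(atoms, names(.element_numbers)), collapse = ", "))
  }
  structure(list(atoms = atoms,
                 coords = unname(coords),
                 charge = as.integer(charge),
                 spin_multiplicity = as.integer(spin_multiplicity)),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("geometry: %d atoms, charge %d, multiplicity %d\n",
              length(x$atoms), x$charge, x$spin_multiplicity))
  for (i in seq_along(x$atoms)) {
    cat(sprintf("  %-2s %12.6f %12.6f %12.6f\n", x$atoms[i],
                x$coords[i, 1], x$coords[i, 2], x$coords[i, 3]))
  }
  invisible(x)
}

#' Read an XYZ file
#'
#' Standard XYZ: first line atom count, second line free-form comment,
#' then one `element x y z` line per atom (Angstrom).
#'
#' @param path file path.
#' @param charge,spin_multiplicity passed to [geometry()] (XYZ carries
#'   neither).
#' @return a `geometry`.
#' @export
read_xyz <- function(path, charge = 0L, spin_multiplicity = 1L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 2L]
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ: first line must be the atom count")
  body <- lines[seq(3L, length.out = n)]
  toks <- strsplit(trimws(body), "\\s+")
  atoms <- vapply(toks, `[[`, "", 1L)
  coords <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
  geometry(atoms, coords, charge, spin_multiplicity)
}

#' Write an XYZ file
#' @param geom a `geometry`.
#' @param path output path.
#' @param comment comment line.
#' @export
write_xyz <- function(geom, path, comment = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(length(geom$atoms)), con)
  writeLines(comment, con)
  for (i in seq_along(geom$atoms)) {
    writeLines(sprintf("%-2s %18.12f %18.12f %18.12f", geom$atoms[i],
                       geom$coords[i, 1], geom$coords[i, 2],
                       geom$coords[i, 3]), con)
  }
  invisible(path)
}

nuclear_repulsion <- function(geom) {
  z <- .element_numbers[geom$atoms]
  xyz <- geom$coords * BOHR_PER_ANGSTROM
  e <- 0.0
  n <- length(z)
  if (n < 2) return(0.0)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r < 1e-10) stop("overlapping atoms ", i, " and ", j)
      e <- e + z[i] * z[j] / r
    }
  }
  e
}
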