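## Structure container and PDB/mmCIF I/O (bio3d-backed).

#' Atomic structure container
#'
#' A thin data-frame container: one row per atom with columns \code{chain},
#' \code{resno}, \code{resid}, \code{elety} (atom name), \code{element},
#' \code{x}, \code{y}, \code{z}, \code{o}, \code{b}, \code{het}.
#'
#' @param atoms data.frame with the columns above.
#' @return object of class \code{structure3d}.
#' @export
structure3d <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z", "o", "b", "het")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("missing atom columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty structure")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) stop("non-finite coordinates")
  for (ch in unique(atoms$chain)) {
    r <- atoms$resno[atoms$chain == ch]
    if (any(diff(unique(r)) <= 0) && is.unsorted(r))
      stop("residue indices not non-decreasing in chain ", ch)
  }
  structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE)),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat("structure3d:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' Coordinates of a structure as a matrix
#' @param s a \code{structure3d}.
#' @return n x 3 numeric matrix.
#' @export
coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

.guess_element <- function(elety) {
  e <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", trimws(elety))))
  two <- c("ZN", "MG", "FE", "CL", "BR", "NA", "CA", "MN", "CU", "NI", "SE")
  ifelse(e %in% two & nchar(e) >= 2, substr(e, 1, 2), substr(e, 1, 1))
}

#' Load a structure from PDB or mmCIF
#'
#' All ATOM/HETATM records are kept; for alternate locations the first altloc
#' is retained. Coordinates are in Angstrom.
#'
#' @param path file path.
#' @param format "pdb", "mmcif" or "auto" (by extension).
#' @return \code{structure3d}.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("unparseable ", format, " file: ", conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("structure contains no atoms")
  keep <- is.na(a$alt) | a$alt %in% c("", "A", "1")
  a <- a[keep, , drop = FALSE]
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(trimws(elem) == ""))
    elem <- .guess_element(a$elety)
  elem <- ifelse(is.na(elem) | trimws(elem) == "", .guess_element(a$elety), trimws(elem))
  structure3d(data.frame(
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno, resid = a$resid, elety = a$elety,
    element = elem, x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    het = a$type == "HETATM", stringsAsFactors = FALSE))
}

#' Write a structure to PDB
#'
#' Occupancy and B-factor default to 1.00/0.00 when absent; chlorin/metal
#' records are written as HETATM.
#'
#' @param s \code{structure3d}; @param path output file path.
#' @return invisibly, the path.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(coords(s))),
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   o = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
                   elesy = a$element)
  invisible(path)
}
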