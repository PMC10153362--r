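## Idealized chlorin template and the 48-atom tetrapyrrole selection
## convention used for all special-pair structural comparisons.

#' van der Waals radii (Bondi set)
#' @param element character vector of element symbols.
#' @return numeric radii in Angstrom (1.7 for unknown elements).
#' @export
vdw_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           F = 1.47, CL = 1.75, BR = 1.85, ZN = 1.39, MG = 1.73, FE = 1.63)
  r <- tab[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

## element symbol from an atom name ("ND1" -> N, "ZN" -> ZN, "CHA" -> C)
.elem_from_name <- function(nm) {
  up <- toupper(nm)
  ifelse(up %in% c("ZN", "MG", "FE"), up, substr(up, 1, 1))
}

#' Tetrapyrrole ring atom names, in canonical selection order
#'
#' 24 names per chlorin monomer: the 4 pyrrole nitrogens (NA..ND), the 16
#' pyrrole carbons (C1A..C4A, ..., C1D..C4D) and the 4 methine bridge carbons
#' (CHA..CHD). Rings A-D sit at azimuths 0/90/180/270 degrees in the ideal
#' template; CHA bridges rings A and B, and so on around the macrocycle.
#' @return character vector of length 24.
#' @export
tetrapyrrole_atom_names <- function() {
  rings <- c("A", "B", "C", "D")
  c(paste0("N", rings),
    as.vector(sapply(rings, function(r) paste0("C", 1:4, r))),
    paste0("CH", rings))
}

#' Build an idealized metallo-chlorin template
#'
#' Planar, four-fold symmetric macrocycle: pyrrole nitrogens at 90-degree
#' intervals at \code{metal_n_dist} from the central metal, pyrrole rings as
#' outward-pointing pentagons (side 1.40 A), methine bridge carbons on the
#' diagonals at 3.45 A. The Qy transition-dipole axis runs through the
#' NA-NC nitrogen pair by default (configurable to NB-ND).
#'
#' @param metal "Zn" or "Mg".
#' @param qy_convention "NA-NC" (default) or "NB-ND".
#' @param metal_n_dist metal-nitrogen distance, Angstrom (default 2.05).
#' @param peripheral if TRUE, add four peripheral methyl carbons (CMA..CMD)
#'   for clash checking; these are never part of the ring selection.
#' @return object of class \code{chlorin_template}: \code{ring_atoms} (24 x 3,
#'   rownames per \code{\link{tetrapyrrole_atom_names}}), \code{metal}
#'   (element + position), \code{qy_axis}, \code{normal},
#'   \code{substituent_atoms} (matrix or NULL).
#' @export
build_ideal_chlorin <- function(metal = c("Zn", "Mg"),
                                qy_convention = c("NA-NC", "NB-ND"),
                                metal_n_dist = 2.05,
                                peripheral = FALSE) {
  metal <- match.arg(metal)
  qy_convention <- match.arg(qy_convention)
  r_p <- 1.40 / (2 * sin(pi / 5))            # pentagon circumradius, side 1.40
  cen <- metal_n_dist + r_p                  # pyrrole ring center radius
  ## one pyrrole at azimuth 0: N toward metal, C1 at +azimuth side
  pent <- function(theta_deg) {
    th <- deg2rad(theta_deg)
    ca <- cos(th); sa <- sin(th)
    rot <- matrix(c(ca, sa, -sa, ca), 2, 2)  # rotate local +x to azimuth
    loc <- rbind(N  = c(cen - r_p, 0),
                 C1 = c(cen + r_p * cos(deg2rad(108)),  r_p * sin(deg2rad(108))),
                 C2 = c(cen + r_p * cos(deg2rad(36)),   r_p * sin(deg2rad(36))),
                 C3 = c(cen + r_p * cos(deg2rad(36)),  -r_p * sin(deg2rad(36))),
                 C4 = c(cen + r_p * cos(deg2rad(108)), -r_p * sin(deg2rad(108))))
    t(rot %*% t(loc))
  }
  rings <- c(A = 0, B = 90, C = 180, D = 270)
  xy <- matrix(NA_real_, 24, 2,
               dimnames = list(tetrapyrrole_atom_names(), NULL))
  for (k in seq_along(rings)) {
    p <- pent(rings[k])
    nm <- names(rings)[k]
    xy[paste0("N", nm), ] <- p["N", ]
    xy[paste0("C", 1:4, nm), ] <- p[c("C1", "C2", "C3", "C4"), ]
  }
  r_meso <- 3.45
  for (k in seq_along(rings)) {
    th <- deg2rad(rings[k] + 45)
    xy[paste0("CH", names(rings)[k]), ] <- r_meso * c(cos(th), sin(th))
  }
  ring_atoms <- cbind(xy, 0)
  colnames(ring_atoms) <- NULL
  sub <- NULL
  if (peripheral) {
    sub <- matrix(NA_real_, 4, 3,
                  dimnames = list(paste0("CM", names(rings)), NULL))
    for (k in seq_along(rings)) {
      cb <- ring_atoms[paste0("C2", names(rings)[k]), 1:2]
      sub[k, ] <- c(cb * (1 + 1.5 / vnorm(cb)), 0)
    }
  }
  qy <- if (qy_convention == "NA-NC") c(1, 0, 0) else c(0, 1, 0)
  structure(list(ring_atoms = ring_atoms,
                 metal = list(element = metal, position = c(0, 0, 0)),
                 qy_axis = qy, normal = c(0, 0, 1),
                 substituent_atoms = sub),
            class = "chlorin_template")
}

#' Rigidly transform a chlorin template
#' @param tpl \code{chlorin_template}; @param rt \code{rigid_transform}.
#' @return transformed \code{chlorin_template}.
#' @export
transform_chlorin <- function(tpl, rt) {
  tpl$ring_atoms <- apply_transform(rt, tpl$ring_atoms)
  tpl$metal$position <- apply_transform(rt, tpl$metal$position)
  tpl$qy_axis <- as.numeric(rt$rotation %*% tpl$qy_axis)
  tpl$normal <- as.numeric(rt$rotation %*% tpl$normal)
  if (!is.null(tpl$substituent_atoms))
    tpl$substituent_atoms <- apply_transform(rt, tpl$substituent_atoms)
  tpl
}

#' All heavy atoms of a placed chlorin (ring + metal + substituents)
#' @param tpl \code{chlorin_template}.
#' @return n x 3 matrix with rownames.
#' @export
chlorin_atoms <- function(tpl) {
  m <- rbind(tpl$ring_atoms, matrix(tpl$metal$position, 1, 3))
  rownames(m)[nrow(m)] <- toupper(tpl$metal$element)
  if (!is.null(tpl$substituent_atoms)) m <- rbind(m, tpl$substituent_atoms)
  m
}

#' Select tetrapyrrole ring atoms (24 per monomer, 48 per dimer)
#'
#' The selection convention for pairwise special-pair comparisons: for each
#' chlorin the 4 pyrrole N, 16 pyrrole C and 4 methine C, in the fixed order
#' of \code{\link{tetrapyrrole_atom_names}}; metal atoms are excluded.
#' Accepts chlorin templates or (structure, residue reference) input; atom
#' names in a structure may be remapped via \code{name_map}.
#'
#' @param x a \code{chlorin_template}, a list of templates, or a
#'   \code{structure3d}.
#' @param residues for structure input: list of \code{list(chain=, resno=)}
#'   identifying each chlorin residue.
#' @param name_map optional named character vector mapping canonical names to
#'   the names used in the structure (e.g. \code{c(CHA = "CHA", ...)}).
#' @return object of class \code{tetrapyrrole_selection}: \code{positions}
#'   (24*m x 3 matrix), \code{labels}, \code{n_monomers}.
#' @export
select_tetrapyrrole <- function(x, residues = NULL, name_map = NULL) {
  want <- tetrapyrrole_atom_names()
  grab_tpl <- function(tpl) {
    pos <- tpl$ring_atoms[want, , drop = FALSE]
    if (any(is.na(pos))) stop("template missing ring atoms")
    pos
  }
  if (inherits(x, "chlorin_template")) {
    blocks <- list(grab_tpl(x))
  } else if (is.list(x) && all(vapply(x, inherits, TRUE, "chlorin_template"))) {
    blocks <- lapply(x, grab_tpl)
  } else if (inherits(x, "structure3d")) {
    if (is.null(residues)) stop("residues must be given for structure input")
    lookup <- if (is.null(name_map)) stats::setNames(want, want) else {
      full <- stats::setNames(want, want); full[names(name_map)] <- name_map; full
    }
    blocks <- lapply(residues, function(rr) {
      sel <- x$atoms$chain == rr$chain & x$atoms$resno == rr$resno
      res <- x$atoms[sel, , drop = FALSE]
      pos <- matrix(NA_real_, length(want), 3, dimnames = list(want, NULL))
      for (nm in want) {
        hit <- which(trimws(res$elety) == lookup[[nm]])
        if (!length(hit))
          stop("residue ", rr$chain, ":", rr$resno, " is missing ring atom ", nm)
        pos[nm, ] <- as.numeric(res[hit[1], c("x", "y", "z")])
      }
      pos
    })
  } else stop("unsupported input for tetrapyrrole selection")
  structure(list(positions = do.call(rbind, blocks),
                 labels = rep(want, length(blocks)),
                 n_monomers = length(blocks)),
            class = "tetrapyrrole_selection")
}

#' Write a placed chlorin (or several) as a structure3d
#' @param templates list of \code{chlorin_template}s.
#' @param chain chain identifiers (recycled).
#' @return \code{structure3d} with HETATM chlorin records.
#' @export
chlorins_as_structure <- function(templates, chain = LETTERS[seq_along(templates)]) {
  rows <- list()
  for (i in seq_along(templates)) {
    m <- chlorin_atoms(templates[[i]])
    rows[[i]] <- data.frame(
      chain = chain[i], resno = 1L, resid = "CHL", elety = rownames(m),
      element = ifelse(rownames(m) %in% c("ZN", "MG"), rownames(m),
                       substr(rownames(m), 1, 1)),
      x = m[, 1], y = m[, 2], z = m[, 3], o = 1, b = 0, het = TRUE,
      stringsAsFactors = FALSE)
  }
  structure3d(do.call(rbind, rows))
}

#' Beer-Lambert concentration from absorbance
#' @param absorbance absorbance, AU (>= 0).
#' @param epsilon molar extinction coefficient, M^-1 cm^-1 (> 0).
#' @param path path length, cm (> 0).
#' @return molar concentration.
#' @export
concentration_from_absorbance <- function(absorbance, epsilon, path = 1) {
  if (any(absorbance < 0)) stop("negative absorbance")
  stopifnot(epsilon > 0, path > 0)
  absorbance / (epsilon * path)
}
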