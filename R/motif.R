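## C2-symmetric histidine-chlorin dimer motifs, enumerated from
## internal-coordinate grids and filtered for intra-motif clashes.

## idealized histidine internal coordinates (lengths A, angles deg)
.HIS <- list(
  n_ca = 1.458, ca_c = 1.525, c_o = 1.231, ca_cb = 1.530, cb_cg = 1.500,
  cg_nd1 = 1.378, cg_cd2 = 1.354, nd1_ce1 = 1.320, ce1_ne2 = 1.320,
  ang_n_ca_c = 111.0, ang_ca_c_o = 120.5, ang_n_ca_cb = 110.5,
  ang_ca_cb_cg = 113.8, ang_cb_cg_nd1 = 122.7, ang_cb_cg_cd2 = 131.0,
  ang_cg_nd1_ce1 = 109.2, ang_nd1_ce1_ne2 = 111.7,
  improper_c_n_ca_cb = -122.55, dih_n_ca_c_o = 150)

#' Build a histidine residue (heavy atoms) from chi angles
#'
#' NeRF construction outward from an idealized backbone placed in a canonical
#' frame (N at the origin, CA on +x, C in the xy-plane).
#'
#' @param chi1 N-CA-CB-CG dihedral, degrees.
#' @param chi2 CA-CB-CG-ND1 dihedral, degrees.
#' @return 10 x 3 matrix, rownames N, CA, C, O, CB, CG, ND1, CD2, CE1, NE2.
#' @export
build_histidine <- function(chi1, chi2) {
  g <- .HIS
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  th <- deg2rad(180 - g$ang_n_ca_c)
  C <- CA + g$ca_c * c(cos(th), sin(th), 0)
  O <- nerf_place(N, CA, C, c(g$c_o, g$ang_ca_c_o, g$dih_n_ca_c_o))
  CB <- nerf_place(C, N, CA, c(g$ca_cb, g$ang_n_ca_cb, g$improper_c_n_ca_cb))
  CG <- nerf_place(N, CA, CB, c(g$cb_cg, g$ang_ca_cb_cg, chi1))
  ND1 <- nerf_place(CA, CB, CG, c(g$cg_nd1, g$ang_cb_cg_nd1, chi2))
  CD2 <- nerf_place(CA, CB, CG, c(g$cg_cd2, g$ang_cb_cg_cd2, chi2 + 180))
  CE1 <- nerf_place(CB, CG, ND1, c(g$nd1_ce1, g$ang_cg_nd1_ce1, 180))
  NE2 <- nerf_place(CG, ND1, CE1, c(g$ce1_ne2, g$ang_nd1_ce1_ne2, 0))
  m <- rbind(N = N, CA = CA, C = C, O = O, CB = CB, CG = CG,
             ND1 = ND1, CD2 = CD2, CE1 = CE1, NE2 = NE2)
  m
}

#' Chlorin dimer geometry parameters
#'
#' Relative placement of the two chlorins of a C2 pair (axis = global z):
#' \code{stack} is the separation along the shared normal direction (A),
#' \code{slip} the lateral offset (A), \code{tilt} the opening half-angle
#' between ring planes (deg), \code{azimuth} the spin of each chlorin about
#' its own normal (deg). Metal-metal distance is sqrt(stack^2 + slip^2) when
#' tilt = 0. Defaults bracket the native special pair (Mg-Mg ~ 7.6 A).
#'
#' @param stack,slip,tilt,azimuth numeric scalars as above.
#' @return named list of class \code{dimer_geometry}.
#' @export
dimer_geometry <- function(stack = 3.6, slip = 6.7, tilt = 0, azimuth = 0) {
  stopifnot(is.finite(stack), stack > 0, is.finite(slip),
            is.finite(tilt), is.finite(azimuth))
  structure(list(stack = stack, slip = slip, tilt = tilt, azimuth = azimuth),
            class = "dimer_geometry")
}

#' Build one C2-symmetric His-chlorin dimer motif
#'
#' One half is built by NeRF from the histidine backbone outward
#' (\code{\link{build_histidine}}), the chlorin is attached along the ligating
#' nitrogen's lone-pair direction at \code{metal_his_distance} with the ring
#' plane perpendicular to the metal-N bond (metal displaced
#' \code{metal_displacement} out of the ring plane toward the His, i.e.
#' pentacoordinate), spun by \code{ligation_dihedral} about the bond; the
#' whole unit is then posed by the dimer geometry and duplicated by an exact
#' 180-degree rotation about the global z axis.
#'
#' @param chi1,chi2 histidine side-chain dihedrals, degrees.
#' @param ligation_dihedral rotation of the chlorin about the metal-N(His)
#'   bond, degrees.
#' @param geom a \code{\link{dimer_geometry}}.
#' @param ligation_mode "epsilon" (NE2 ligates) or "delta" (ND1).
#' @param metal_his_distance metal to ligating N distance, A (default 2.1).
#' @param metal "Zn" or "Mg".
#' @param metal_displacement out-of-plane metal displacement toward the His, A.
#' @param peripheral include peripheral methyl carbons on the chlorins.
#' @return object of class \code{his_chl_motif} with \code{his1}, \code{chl1},
#'   \code{his2}, \code{chl2} and \code{params}.
#' @export
build_his_chl_motif <- function(chi1 = -60, chi2 = 90, ligation_dihedral = 0,
                                geom = dimer_geometry(),
                                ligation_mode = c("epsilon", "delta"),
                                metal_his_distance = 2.1, metal = "Zn",
                                metal_displacement = 0.3, peripheral = FALSE) {
  ligation_mode <- match.arg(ligation_mode)
  his <- build_histidine(chi1, chi2)
  nlig <- if (ligation_mode == "epsilon") "NE2" else "ND1"
  nbs <- if (ligation_mode == "epsilon") c("CE1", "CD2") else c("CE1", "CG")
  nl <- his[nlig, ]
  dir <- -(unitv(his[nbs[1], ] - nl) + unitv(his[nbs[2], ] - nl))
  dir <- unitv(dir)
  mpos <- nl + metal_his_distance * dir
  ## chlorin frame at the metal: z along N(His)->metal, x referenced to the
  ## imidazole plane then spun by the ligation dihedral
  zc <- dir
  v <- his["CE1", ] - nl
  xc <- unitv(v - sum(v * zc) * zc)
  xc <- as.numeric(rotation_about_axis(zc, ligation_dihedral) %*% xc)
  yc <- cross3(zc, xc)
  Ac <- cbind(xc, yc, zc, deparse.level = 0)
  tpl <- build_ideal_chlorin(metal = metal, peripheral = peripheral)
  tpl$ring_atoms[, 3] <- tpl$ring_atoms[, 3] + metal_displacement
  if (!is.null(tpl$substituent_atoms))
    tpl$substituent_atoms[, 3] <- tpl$substituent_atoms[, 3] + metal_displacement
  chl <- transform_chlorin(tpl, rigid_transform(Ac, mpos))
  ## pose the unit: chlorin normal -> -x (partner side is -x), metal on +x
  At <- rotation_about_axis(c(0, 1, 0), geom$tilt) %*%
        rotation_about_axis(c(1, 0, 0), geom$azimuth) %*%
        rotation_about_axis(c(0, 1, 0), -90)
  mt <- c(geom$stack / 2, geom$slip / 2, 0)
  Rg <- At %*% t(Ac)
  pose <- rigid_transform(Rg, as.numeric(mt - Rg %*% mpos))
  his1 <- apply_transform(pose, his)
  chl1 <- transform_chlorin(chl, pose)
  c2 <- rigid_transform(diag(c(-1, -1, 1)), c(0, 0, 0))
  structure(list(his1 = his1, chl1 = chl1,
                 his2 = apply_transform(c2, his1),
                 chl2 = transform_chlorin(chl1, c2),
                 params = list(chi1 = chi1, chi2 = chi2,
                               ligation_dihedral = ligation_dihedral,
                               geom = geom, ligation_mode = ligation_mode,
                               metal_his_distance = metal_his_distance,
                               metal = metal,
                               metal_displacement = metal_displacement,
                               peripheral = peripheral)),
            class = "his_chl_motif")
}

#' Heavy atoms of one motif half
#' @param motif \code{his_chl_motif}; @param half 1 or 2.
#' @return n x 3 matrix with rownames.
#' @export
motif_half_atoms <- function(motif, half = 1) {
  if (half == 1) rbind(motif$his1, chlorin_atoms(motif$chl1))
  else rbind(motif$his2, chlorin_atoms(motif$chl2))
}

#' Backbone N-CA-C frames of the two ligating histidines
#' @param motif \code{his_chl_motif}.
#' @return list of two \code{frame}s.
#' @export
motif_frames <- function(motif) {
  list(frame_from_residue(motif$his1["N", ], motif$his1["CA", ], motif$his1["C", ]),
       frame_from_residue(motif$his2["N", ], motif$his2["CA", ], motif$his2["C", ]))
}

#' 6-D transform between the two ligating histidine frames
#' @param motif \code{his_chl_motif}.
#' @return \code{rigid_transform}.
#' @export
motif_transform <- function(motif) {
  f <- motif_frames(motif)
  transform_between(f[[1]], f[[2]])
}

#' Motif conformer grid
#'
#' @param chi1_values,chi2_values,ligation_dihedral_values degree vectors.
#' @param dimer_geometries list of \code{\link{dimer_geometry}}.
#' @param ligation_modes subset of c("epsilon", "delta").
#' @param metal_his_distance A.
#' @return object of class \code{motif_grid}; its size is the product of the
#'   list lengths times the number of ligation modes.
#' @export
motif_grid <- function(chi1_values = c(-60, 60, 180),
                       chi2_values = seq(-180, 150, by = 30),
                       ligation_dihedral_values = c(0, 90, 180, 270),
                       dimer_geometries = list(dimer_geometry()),
                       ligation_modes = c("epsilon", "delta"),
                       metal_his_distance = 2.1) {
  stopifnot(length(chi1_values) > 0, length(chi2_values) > 0,
            length(ligation_dihedral_values) > 0, length(dimer_geometries) > 0,
            length(ligation_modes) > 0,
            all(ligation_modes %in% c("epsilon", "delta")))
  structure(list(chi1_values = chi1_values, chi2_values = chi2_values,
                 ligation_dihedral_values = ligation_dihedral_values,
                 dimer_geometries = dimer_geometries,
                 ligation_modes = ligation_modes,
                 metal_his_distance = metal_his_distance),
            class = "motif_grid")
}

#' Size of a motif grid
#' @param grid \code{motif_grid}.
#' @export
motif_grid_size <- function(grid) {
  length(grid$chi1_values) * length(grid$chi2_values) *
    length(grid$ligation_dihedral_values) * length(grid$dimer_geometries) *
    length(grid$ligation_modes)
}

#' Enumerate all motif conformers of a grid
#' @param grid \code{motif_grid}.
#' @return list of \code{his_chl_motif}, length = grid size (pre-filter).
#' @export
enumerate_conformers <- function(grid) {
  if (!inherits(grid, "motif_grid")) stop("not a motif_grid")
  idx <- expand.grid(mode = seq_along(grid$ligation_modes),
                     g = seq_along(grid$dimer_geometries),
                     d = seq_along(grid$ligation_dihedral_values),
                     c2 = seq_along(grid$chi2_values),
                     c1 = seq_along(grid$chi1_values))
  lapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, ]
    m <- build_his_chl_motif(
      chi1 = grid$chi1_values[i$c1], chi2 = grid$chi2_values[i$c2],
      ligation_dihedral = grid$ligation_dihedral_values[i$d],
      geom = grid$dimer_geometries[[i$g]],
      ligation_mode = grid$ligation_modes[i$mode],
      metal_his_distance = grid$metal_his_distance)
    m$params$geom_index <- i$g
    m
  })
}

#' Minimum heavy-atom distance between the two motif halves
#' @param motif \code{his_chl_motif}.
#' @export
motif_min_interhalf_distance <- function(motif) {
  a <- motif_half_atoms(motif, 1); b <- motif_half_atoms(motif, 2)
  min(sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)))
}

#' Filter motifs on inter-half clashes
#'
#' Retains motifs whose minimum heavy-atom distance between the two halves is
#' at least \code{cutoff}. The designed metal-N(His) contact is within a half
#' and never enters the inter-half distance.
#'
#' @param motifs list of \code{his_chl_motif}.
#' @param cutoff minimum allowed distance, A (default 2.8).
#' @return filtered list (subset of the input, order preserved).
#' @export
clash_filter <- function(motifs, cutoff = 2.8) {
  stopifnot(cutoff > 0)
  keep <- vapply(motifs, function(m) motif_min_interhalf_distance(m) >= cutoff,
                 logical(1))
  motifs[keep]
}

#' Compact rebuild record of a motif
#' @param motif \code{his_chl_motif}.
#' @return named list sufficient to rebuild the motif exactly.
#' @export
motif_record <- function(motif) {
  p <- motif$params
  list(ligation_mode = p$ligation_mode, chi1 = p$chi1, chi2 = p$chi2,
       ligation_dihedral = p$ligation_dihedral,
       stack = p$geom$stack, slip = p$geom$slip, tilt = p$geom$tilt,
       azimuth = p$geom$azimuth, metal_his_distance = p$metal_his_distance,
       geom_index = if (is.null(p$geom_index)) NA_integer_ else p$geom_index)
}

#' Rebuild a motif from its record
#' @param record as from \code{\link{motif_record}}.
#' @return \code{his_chl_motif}.
#' @export
rebuild_motif <- function(record) {
  m <- build_his_chl_motif(
    chi1 = record$chi1, chi2 = record$chi2,
    ligation_dihedral = record$ligation_dihedral,
    geom = dimer_geometry(record$stack, record$slip, record$tilt, record$azimuth),
    ligation_mode = record$ligation_mode,
    metal_his_distance = record$metal_his_distance)
  m$params$geom_index <- record$geom_index
  m
}

#' Write a motif library as a structured text table
#' @param motifs list of \code{his_chl_motif}; @param path output TSV path.
#' @export
write_motif_library <- function(motifs, path) {
  df <- do.call(rbind, lapply(motifs, function(m)
    as.data.frame(motif_record(m), stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motif library written by \code{\link{write_motif_library}}
#' @param path TSV path.
#' @return list of \code{his_chl_motif}.
#' @export
read_motif_library <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) rebuild_motif(as.list(df[i, ])))
}

#' One motif as a structure3d (His chains A/B, chlorins C/D)
#' @param motif \code{his_chl_motif}.
#' @return \code{structure3d}.
#' @export
motif_as_structure <- function(motif) {
  his_df <- function(m, ch) data.frame(
    chain = ch, resno = 1L, resid = "HIS", elety = rownames(m),
    element = substr(rownames(m), 1, 1),
    x = m[, 1], y = m[, 2], z = m[, 3], o = 1, b = 0, het = FALSE,
    stringsAsFactors = FALSE)
  chl <- chlorins_as_structure(list(motif$chl1, motif$chl2), chain = c("C", "D"))
  structure3d(rbind(his_df(motif$his1, "A"), his_df(motif$his2, "B"),
                    chl$atoms))
}

#' Write a motif library as a multi-model PDB for visualization
#' @param motifs list of \code{his_chl_motif}; @param path output PDB path.
#' @export
write_motif_pdb <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tmp <- tempfile(fileext = ".pdb")
  for (i in seq_along(motifs)) {
    write_structure(motif_as_structure(motifs[[i]]), tmp)
    lines <- readLines(tmp)
    lines <- lines[grepl("^(ATOM|HETATM|TER)", lines)]
    writeLines(sprintf("MODEL %8d", i), con)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  unlink(tmp)
  invisible(path)
}
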