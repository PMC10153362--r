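## Simplified two-component octahedral (and tetrahedral) nanocage assembly:
## C2 components on 2-fold axes, C3 components on 3-fold axes, axial
## rotation/translation sampling with clash / contact / interface-area scores.

.rotation_group <- function(group) {
  gens <- list(rotation_about_axis(c(0, 0, 1), 90),
               rotation_about_axis(c(1, 0, 0), 90))
  if (group == "T")
    gens <- list(rotation_about_axis(c(0, 0, 1), 180),
                 rotation_about_axis(c(1, 1, 1), 120))
  keyof <- function(R) paste(as.integer(round(R * 1e6)), collapse = ",")
  elems <- list(diag(3))
  keys <- keyof(diag(3))
  repeat {
    added <- FALSE
    for (e in elems) for (g in gens) {
      R <- g %*% e
      k <- keyof(R)
      if (!(k %in% keys)) {
        elems[[length(elems) + 1L]] <- R
        keys <- c(keys, k)
        added <- TRUE
      }
    }
    if (!added) break
  }
  elems
}

#' Two-component cage symmetry architecture
#'
#' For the octahedral group O: 24 rotations, 12 C2 slots (axis through an
#' edge midpoint) and 8 C3 slots (axis through a vertex of the inscribed
#' cube); for T: 12 rotations, 6 C2 and 4 C3 slots.
#'
#' @param group "O" or "T".
#' @return object of class \code{symmetry_architecture}: \code{rotations}
#'   (list of 3x3 matrices), \code{c2_axis}, \code{c3_axis},
#'   \code{n_c2}, \code{n_c3}.
#' @export
architecture <- function(group = c("O", "T")) {
  group <- match.arg(group)
  rots <- .rotation_group(group)
  ord <- length(rots)
  structure(list(group = group, rotations = rots,
                 c2_axis = if (group == "O") unitv(c(1, 1, 0)) else unitv(c(0, 0, 1)),
                 c3_axis = unitv(c(1, 1, 1)),
                 n_c2 = ord / 2, n_c3 = ord / 3),
            class = "symmetry_architecture")
}

#' Coset representatives of a cyclic stabilizer in the cage group
#' @param arch \code{symmetry_architecture}; @param axis slot axis;
#' @param order component symmetry order (2 or 3).
#' @return list of rotation matrices, length group order / order.
#' @export
coset_representatives <- function(arch, axis, order) {
  stab <- lapply(seq_len(order) - 1, function(k)
    rotation_about_axis(axis, 360 * k / order))
  keyof <- function(R) paste(as.integer(round(R * 1e6)), collapse = ",")
  reps <- list()
  seen <- character(0)
  for (R in arch$rotations) {
    ks <- vapply(stab, function(s) keyof(R %*% s), character(1))
    if (any(ks %in% seen)) next
    seen <- c(seen, ks)
    reps[[length(reps) + 1L]] <- R
  }
  reps
}

#' Cyclic-symmetric cage component
#'
#' @param structure \code{structure3d} whose chains are related by rotations
#'   of \code{360/order} degrees about the z axis.
#' @param order internal symmetry order (2 or 3).
#' @param chromophores_per_protomer chromophore count carried by each chain.
#' @param tol maximum allowed deviation of the internal symmetry, A.
#' @return object of class \code{cage_component}.
#' @export
cage_component <- function(structure, order, chromophores_per_protomer = 0,
                           tol = 1e-3) {
  ch <- unique(structure$atoms$chain)
  if (length(ch) != order) stop("component must have exactly ", order, " chains")
  x1 <- as.matrix(structure$atoms[structure$atoms$chain == ch[1], c("x", "y", "z")])
  for (k in 2:order) {
    xk <- as.matrix(structure$atoms[structure$atoms$chain == ch[k], c("x", "y", "z")])
    if (nrow(xk) != nrow(x1)) stop("chains differ in atom count")
    R <- rotation_about_axis(c(0, 0, 1), 360 * (k - 1) / order)
    if (max(abs(x1 %*% t(R) - xk)) > tol)
      stop("component is not C", order, "-symmetric about z within tolerance")
  }
  structure(list(structure = structure, order = order, axis = c(0, 0, 1),
                 chromophores_per_protomer = chromophores_per_protomer),
            class = "cage_component")
}

#' Axial pose of a component
#' @param rotation_deg spin about the component's own symmetry axis, degrees.
#' @param translation_a radial placement along the slot axis, A.
#' @export
component_pose <- function(rotation_deg = 0, translation_a = 0) {
  stopifnot(is.finite(rotation_deg), is.finite(translation_a))
  structure(list(rotation_deg = rotation_deg, translation_a = translation_a),
            class = "component_pose")
}

.pose_component <- function(comp, slot_axis, pose) {
  ## spin about own axis, then align own axis (z) onto the slot axis, then
  ## translate outward along the slot axis
  Rspin <- rotation_about_axis(c(0, 0, 1), pose$rotation_deg)
  v <- cross3(c(0, 0, 1), slot_axis)
  Ralign <- if (vnorm(v) < 1e-12) {
    if (slot_axis[3] > 0) diag(3) else rotation_about_axis(c(1, 0, 0), 180)
  } else rotation_about_axis(v, rad2deg(acos(max(-1, min(1, slot_axis[3])))))
  R <- Ralign %*% Rspin
  rigid_transform(R, pose$translation_a * slot_axis)
}

#' Place both components and expand the full cage
#'
#' Components are posed on their slot axes and expanded by coset
#' representatives of their internal cyclic symmetry in the cage group.
#' Chain identifiers are cycled A-Z then a-z then 0-9 with numeric suffixes.
#'
#' @param arch \code{symmetry_architecture}.
#' @param c2_component,c3_component \code{cage_component}s of order 2 and 3.
#' @param pose2,pose3 \code{component_pose}s.
#' @return object of class \code{cage_model}: \code{structure},
#'   \code{chain_count}, \code{chromophore_count}, \code{copies} (chain ids
#'   per placed copy), \code{arch}.
#' @export
place_and_expand <- function(arch, c2_component, c3_component,
                             pose2 = component_pose(), pose3 = component_pose()) {
  stopifnot(c2_component$order == 2, c3_component$order == 3)
  ids <- c(LETTERS, letters, as.character(0:9))
  ids <- c(ids, as.vector(outer(ids, 1:9, paste0)))
  expand_one <- function(comp, axis, pose) {
    posed <- apply_transform(.pose_component(comp, axis, pose),
                             coords(comp$structure))
    reps <- coset_representatives(arch, axis, comp$order)
    list(posed = posed, reps = reps)
  }
  e2 <- expand_one(c2_component, arch$c2_axis, pose2)
  e3 <- expand_one(c3_component, arch$c3_axis, pose3)
  rows <- list(); next_id <- 1L; copies <- list()
  add_copy <- function(comp, xyz, tag) {
    a <- comp$structure$atoms
    old <- unique(a$chain)
    new <- ids[next_id:(next_id + length(old) - 1)]
    next_id <<- next_id + length(old)
    a$chain <- new[match(a$chain, old)]
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    rows[[length(rows) + 1L]] <<- a
    copies[[length(copies) + 1L]] <<- list(component = tag, chains = new)
  }
  for (R in e2$reps) add_copy(c2_component, e2$posed %*% t(R), "C2")
  for (R in e3$reps) add_copy(c3_component, e3$posed %*% t(R), "C3")
  st <- structure3d(do.call(rbind, rows))
  n_chrom <- length(e2$reps) * 2 * c2_component$chromophores_per_protomer +
    length(e3$reps) * 3 * c3_component$chromophores_per_protomer
  structure(list(structure = st,
                 chain_count = length(unique(st$atoms$chain)),
                 chromophore_count = n_chrom,
                 copies = copies, arch = arch,
                 pose2 = pose2, pose3 = pose3),
            class = "cage_model")
}

#' Score the unique C2-C3 interface of a cage
#'
#' Reports backbone clash count, contact count and buried interface area
#' (by \code{\link{compute_sasa}}) between the first C2 copy and its nearest
#' C3 copy; symmetry copies of the interface are equivalent by group action.
#'
#' @param cage \code{cage_model}.
#' @param clash_cutoff atom-pair clash distance, A (default 3.0).
#' @param contact_cutoff atom-pair contact distance, A (default 8.0).
#' @param area_bounds acceptable buried-area window, A^2 (default
#'   c(1000, 1600)); max allowed clashes default < 3.
#' @param max_clash maximum clash count for the pass flag (default 2).
#' @param sasa_points Shrake-Rupley point count.
#' @return list: \code{clash_count}, \code{contact_count},
#'   \code{interface_area}, \code{pass}.
#' @export
score_dock <- function(cage, clash_cutoff = 3.0, contact_cutoff = 8.0,
                       area_bounds = c(1000, 1600), max_clash = 2,
                       sasa_points = 120) {
  stopifnot(clash_cutoff > 0, contact_cutoff > 0)
  a <- cage$structure$atoms
  grab <- function(copy) {
    sel <- a$chain %in% copy$chains
    list(xyz = as.matrix(a[sel, c("x", "y", "z")]),
         rad = vdw_radius(a$element[sel]))
  }
  i2 <- which(vapply(cage$copies, function(cp) cp$component == "C2", TRUE))[1]
  i3s <- which(vapply(cage$copies, function(cp) cp$component == "C3", TRUE))
  g2 <- grab(cage$copies[[i2]])
  ## nearest C3 copy by centroid
  cent2 <- colMeans(g2$xyz)
  d3 <- vapply(i3s, function(i) {
    vnorm(colMeans(grab(cage$copies[[i]])$xyz) - cent2)
  }, numeric(1))
  g3 <- grab(cage$copies[[i3s[which.min(d3)]]])
  d2m <- outer(rowSums(g2$xyz^2), rowSums(g3$xyz^2), "+") -
    2 * g2$xyz %*% t(g3$xyz)
  clash <- sum(d2m < clash_cutoff^2)
  contact <- sum(d2m < contact_cutoff^2)
  area <- 0
  if (contact > 0) {
    s2 <- sum(compute_sasa(g2$xyz, g2$rad, n_points = sasa_points))
    s3 <- sum(compute_sasa(g3$xyz, g3$rad, n_points = sasa_points))
    s23 <- sum(compute_sasa(rbind(g2$xyz, g3$xyz), c(g2$rad, g3$rad),
                            n_points = sasa_points))
    area <- max(0, s2 + s3 - s23)
  }
  list(clash_count = clash, contact_count = contact, interface_area = area,
       pass = clash <= max_clash && area > area_bounds[1] && area < area_bounds[2])
}

#' Exhaustive axial dock sampling
#'
#' Grid over (C2 spin x C2 radius x C3 spin x C3 radius), deterministic
#' ordering; every pose is scored and the filter-passing subset flagged.
#'
#' @param arch \code{symmetry_architecture};
#' @param c2_component,c3_component \code{cage_component}s.
#' @param rot2,trans2,rot3,trans3 non-empty grids (degrees / A).
#' @param ... passed to \code{\link{score_dock}}.
#' @return data.frame with pose parameters and scores.
#' @export
sample_docks <- function(arch, c2_component, c3_component,
                         rot2 = c(0), trans2 = c(20), rot3 = c(0),
                         trans3 = c(20), ...) {
  stopifnot(length(rot2) > 0, length(trans2) > 0,
            length(rot3) > 0, length(trans3) > 0)
  grid <- expand.grid(rot2 = rot2, trans2 = trans2, rot3 = rot3,
                      trans3 = trans3, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cage <- place_and_expand(arch, c2_component, c3_component,
                             component_pose(g$rot2, g$trans2),
                             component_pose(g$rot3, g$trans3))
    sc <- score_dock(cage, ...)
    data.frame(g, clash_count = sc$clash_count, contact_count = sc$contact_count,
               interface_area = sc$interface_area, pass = sc$pass)
  })
  do.call(rbind, res)
}

#' Build a small synthetic cyclic helical component
#'
#' A toy component for tests and examples: \code{order} ideal helices
#' arranged with exact cyclic symmetry about z at radius \code{radius}.
#'
#' @param order 2 or 3; @param n_residues per chain; @param radius A.
#' @param chromophores_per_protomer forwarded to \code{\link{cage_component}}.
#' @return \code{cage_component}.
#' @export
make_cyclic_component <- function(order, n_residues = 12, radius = 8,
                                  chromophores_per_protomer = 0) {
  helix <- build_helix_backbone(n_residues)
  ## orient the helix along z, offset by radius in x
  ax <- unitv(helix[[n_residues]]["CA", ] - helix[[1]]["CA", ])
  v <- cross3(ax, c(0, 0, 1))
  R <- if (vnorm(v) < 1e-12) diag(3) else
    rotation_about_axis(v, rad2deg(acos(max(-1, min(1, ax[3])))))
  g <- rigid_transform(R, c(radius, 0, 0) - as.numeric(R %*% helix[[1]]["CA", ]))
  base <- lapply(helix, function(m) apply_transform(g, m))
  rows <- list()
  for (k in seq_len(order)) {
    Rk <- rotation_about_axis(c(0, 0, 1), 360 * (k - 1) / order)
    res <- lapply(base, function(m) m %*% t(Rk))
    rows[[k]] <- .residues_to_df(res, LETTERS[k])
  }
  cage_component(structure3d(do.call(rbind, rows)), order,
                 chromophores_per_protomer = chromophores_per_protomer)
}
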