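## Scan C2-homodimeric scaffolds for cross-chain residue pairs whose frame
## transform hits the motif hash table; rebuild and clash-check placements.

## ideal alpha-helix internal coordinates
.HELIX <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
               ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
               phi = -57, psi = -47, omega = 180, ang_ca_c_o = 120.5)

#' Build an ideal alpha-helical backbone
#'
#' NeRF chain of N, CA, C (plus carbonyl O) with phi = -57, psi = -47,
#' omega = 180.
#'
#' @param n_residues number of residues (>= 2).
#' @return list of per-residue 4 x 3 matrices (rownames N, CA, C, O).
#' @export
build_helix_backbone <- function(n_residues) {
  stopifnot(n_residues >= 2)
  g <- .HELIX
  ## seed residue 1 backbone in a canonical pose
  N <- c(0, 0, 0); CA <- c(g$n_ca, 0, 0)
  th <- deg2rad(180 - g$ang_n_ca_c)
  C <- CA + g$ca_c * c(cos(th), sin(th), 0)
  res <- vector("list", n_residues)
  res[[1]] <- rbind(N = N, CA = CA, C = C, O = NA)
  for (i in 2:n_residues) {
    p <- res[[i - 1]]
    Nn <- nerf_place(p["N", ], p["CA", ], p["C", ], c(g$c_n, g$ang_ca_c_n, g$psi))
    CAn <- nerf_place(p["CA", ], p["C", ], Nn, c(g$n_ca, g$ang_c_n_ca, g$omega))
    Cn <- nerf_place(p["C", ], Nn, CAn, c(g$ca_c, g$ang_n_ca_c, g$phi))
    res[[i]] <- rbind(N = Nn, CA = CAn, C = Cn, O = NA)
    ## carbonyl O of the previous residue, anti to the new N
    res[[i - 1]]["O", ] <- nerf_place(Nn, p["CA", ], p["C", ],
                                      c(g$c_o, g$ang_ca_c_o, 180))
  }
  p <- res[[n_residues]]
  res[[n_residues]]["O", ] <- nerf_place(p["N", ], p["CA", ], p["C", ],
                                         c(g$c_o, g$ang_ca_c_o, g$psi + 180))
  res
}

.residues_to_df <- function(res, chain) {
  do.call(rbind, lapply(seq_along(res), function(i) {
    m <- res[[i]]
    data.frame(chain = chain, resno = i, resid = "ALA", elety = rownames(m),
               element = substr(rownames(m), 1, 1),
               x = m[, 1], y = m[, 2], z = m[, 3], o = 1, b = 0, het = FALSE,
               stringsAsFactors = FALSE)
  }))
}

#' C2-homodimeric scaffold
#'
#' @param structure \code{structure3d} with exactly the two chains of the C2
#'   pair (equal residue counts).
#' @param chains length-2 chain identifiers (default: the two chains present).
#' @param mask optional integer residue indices excluded from matching.
#' @return object of class \code{scaffold}.
#' @export
scaffold <- function(structure, chains = NULL, mask = integer(0)) {
  a <- structure$atoms
  if (is.null(chains)) chains <- unique(a$chain)
  if (length(chains) != 2) stop("scaffold needs exactly two chains")
  n1 <- length(unique(a$resno[a$chain == chains[1]]))
  n2 <- length(unique(a$resno[a$chain == chains[2]]))
  if (n1 != n2) stop("the two chains have different lengths")
  structure(list(structure = structure, chains = chains,
                 n_residues = n1, mask = as.integer(mask)),
            class = "scaffold")
}

.backbone_frame <- function(a, chain, resno) {
  r <- a[a$chain == chain & a$resno == resno, , drop = FALSE]
  get <- function(nm) {
    i <- which(trimws(r$elety) == nm)
    if (!length(i)) return(NULL)
    as.numeric(r[i[1], c("x", "y", "z")])
  }
  n <- get("N"); ca <- get("CA"); c <- get("C")
  if (is.null(n) || is.null(ca) || is.null(c)) return(NULL)
  frame_from_residue(n, ca, c)
}

#' Cross-chain frame transforms of all symmetric residue pairs
#'
#' For each unmasked residue index i, the 6-D transform between the N-CA-C
#' frame of chain A residue i and chain B residue i. Positions with missing
#' backbone atoms are skipped with a warning.
#'
#' @param s \code{scaffold}.
#' @return named list of \code{rigid_transform} (names = residue indices).
#' @export
enumerate_symmetric_pairs <- function(s) {
  a <- s$structure$atoms
  idx <- setdiff(sort(unique(a$resno[a$chain == s$chains[1]])), s$mask)
  out <- list()
  for (i in idx) {
    f1 <- .backbone_frame(a, s$chains[1], i)
    f2 <- .backbone_frame(a, s$chains[2], i)
    if (is.null(f1) || is.null(f2)) {
      warning("skipping residue ", i, ": missing backbone atoms")
      next
    }
    out[[as.character(i)]] <- transform_between(f1, f2)
  }
  out
}

#' Count motif atoms clashing with scaffold backbone
#'
#' @param motif_xyz motif heavy-atom positions (n x 3).
#' @param s \code{scaffold}.
#' @param cutoff clash distance, A (default 2.8).
#' @param exempt residue indices whose backbone is exempt (the host His pair).
#' @return integer clash count.
#' @export
backbone_clash_check <- function(motif_xyz, s, cutoff = 2.8, exempt = integer(0)) {
  stopifnot(cutoff > 0)
  a <- s$structure$atoms
  bb <- a[a$elety %in% c("N", "CA", "C", "O") & !(a$resno %in% exempt), ,
          drop = FALSE]
  if (!nrow(bb)) return(0L)
  B <- as.matrix(bb[, c("x", "y", "z")])
  M <- as.matrix(motif_xyz)
  d2 <- outer(rowSums(M^2), rowSums(B^2), "+") - 2 * M %*% t(B)
  sum(apply(d2, 1, min) < cutoff^2)
}

#' Match a scaffold against a motif hash table
#'
#' Every symmetric residue-pair transform is hashed and looked up; for each
#' hit the motif is rebuilt from its record and anchored on the chain-A
#' residue's N-CA-C frame. Placements carry backbone clash counts and
#' (optionally) chlorin-dimer burial.
#'
#' @param s \code{scaffold}; @param table \code{transform_hash_table}.
#' @param clash_cutoff backbone clash distance, A.
#' @param compute_burial if TRUE, compute ligand burial (DSasa) per placement.
#' @param sasa_points Shrake-Rupley point count used for burial.
#' @return list of placements: \code{residue}, \code{record}, \code{motif}
#'   (in scaffold coordinates), \code{backbone_clash_count}, \code{burial},
#'   \code{accepted}.
#' @export
match_scaffold <- function(s, table, clash_cutoff = 2.8,
                           compute_burial = TRUE, sasa_points = 120) {
  pairs <- enumerate_symmetric_pairs(s)
  a <- s$structure$atoms
  placements <- list()
  for (nm in names(pairs)) {
    hits <- hash_query(table, pairs[[nm]])
    if (!length(hits)) next
    i <- as.integer(nm)
    fA <- .backbone_frame(a, s$chains[1], i)
    for (rec in hits) {
      m <- rebuild_motif(rec)
      g <- motion_between_frames(motif_frames(m)[[1]], fA)
      m$his1 <- apply_transform(g, m$his1)
      m$his2 <- apply_transform(g, m$his2)
      m$chl1 <- transform_chlorin(m$chl1, g)
      m$chl2 <- transform_chlorin(m$chl2, g)
      lig <- rbind(chlorin_atoms(m$chl1), chlorin_atoms(m$chl2))
      lig_rad <- vdw_radius(.elem_from_name(rownames(lig)))
      cl <- backbone_clash_check(lig, s, clash_cutoff, exempt = i)
      bur <- NA_real_
      if (compute_burial) {
        bbsel <- a$elety %in% c("N", "CA", "C", "O")
        cplx <- rbind(lig, as.matrix(a[bbsel, c("x", "y", "z")]))
        rad <- c(lig_rad, vdw_radius(a$element[bbsel]))
        bur <- ligand_burial(lig, lig_rad, cplx, rad, n_points = sasa_points)
      }
      placements[[length(placements) + 1L]] <- list(
        residue = i, record = rec, motif = m,
        backbone_clash_count = cl, burial = bur, accepted = (cl == 0L))
    }
  }
  placements
}

#' Filter and order placements
#'
#' Removes placements failing the filters, then orders by clash count
#' (ascending) and burial (descending); the order is stable.
#'
#' @param placements as from \code{\link{match_scaffold}}.
#' @param max_clash maximum allowed backbone clash count (default 0).
#' @param min_burial minimum ligand burial (default 0; NA burial passes).
#' @return ordered, filtered placement list.
#' @export
rank_placements <- function(placements, max_clash = 0, min_burial = 0) {
  if (!length(placements)) return(placements)
  keep <- vapply(placements, function(p)
    p$backbone_clash_count <= max_clash &&
      (is.na(p$burial) || p$burial >= min_burial), logical(1))
  kept <- placements[keep]
  if (!length(kept)) return(kept)
  cl <- vapply(kept, function(p) p$backbone_clash_count, numeric(1))
  bu <- vapply(kept, function(p) ifelse(is.na(p$burial), 0, p$burial), numeric(1))
  kept[order(cl, -bu)]
}

#' Placement report as a data frame
#' @param placements placement list.
#' @return data.frame (one row per placement).
#' @export
placement_report <- function(placements) {
  if (!length(placements))
    return(data.frame(residue = integer(0), ligation_mode = character(0),
                      backbone_clash_count = integer(0), burial = numeric(0),
                      accepted = logical(0)))
  do.call(rbind, lapply(placements, function(p)
    data.frame(residue = p$residue, ligation_mode = p$record$ligation_mode,
               backbone_clash_count = p$backbone_clash_count,
               burial = p$burial, accepted = p$accepted,
               stringsAsFactors = FALSE)))
}

#' Build a two-chain scaffold with one motif-compatible residue pair planted
#'
#' Chain A consists of a short ideal helical segment placed so that the
#' backbone frame of the plant residue coincides exactly with the motif's
#' first histidine frame, plus a distal decoy helix (seeded placement) that
#' supplies the remaining residues; chain B is the image of chain A under the
#' rigid motion realizing the motif's His-pair transform (an exact C2 copy).
#' The helical flanks around the plant residue are trimmed (down to one
#' residue each side) until the backbone clears the chlorin footprint; decoy
#' residues additionally get a small seeded coordinate jitter, so different
#' seeds change decoy geometry without touching the planted pair.
#'
#' @param motif \code{his_chl_motif}; @param n_residues per-chain length
#'   (>= 20); @param seed integer seed.
#' @param jitter decoy jitter amplitude, A (default 0.05).
#' @param clash_cutoff backbone/chlorin clearance required, A.
#' @return \code{scaffold} with attribute \code{planted} = plant residue index.
#' @export
make_planted_scaffold <- function(motif, n_residues = 50, seed = 1,
                                  jitter = 0.05, clash_cutoff = 2.8) {
  stopifnot(n_residues >= 20)
  p <- floor(n_residues / 2)
  fm <- motif_frames(motif)
  lig <- rbind(chlorin_atoms(motif$chl1), chlorin_atoms(motif$chl2))
  lig_center <- colMeans(lig)
  tAB <- motif_transform(motif)
  fB <- frame_apply_local(fm[[1]], tAB)
  gAB <- motion_between_frames(fm[[1]], fB)
  seg_clear <- function(flank) {
    seg <- build_helix_backbone(2 * flank + 1)
    mid <- flank + 1
    fh <- frame_from_residue(seg[[mid]]["N", ], seg[[mid]]["CA", ], seg[[mid]]["C", ])
    g <- motion_between_frames(fh, fm[[1]])
    seg <- lapply(seg, function(m) apply_transform(g, m))
    bbA <- do.call(rbind, seg[-mid])
    bb <- rbind(bbA, apply_transform(gAB, bbA))
    d2 <- outer(rowSums(bb^2), rowSums(lig^2), "+") - 2 * bb %*% t(lig)
    if (min(d2) >= clash_cutoff^2) seg else NULL
  }
  seg <- NULL
  for (flank in c(4, 3, 2, 1)) {
    seg <- seg_clear(flank)
    if (!is.null(seg)) break
  }
  if (is.null(seg))
    stop("impossible graft: backbone cannot clear the chlorin footprint")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  ## distal decoy helix, seeded placement, kept far from the motif
  n_decoy <- n_residues - length(seg)
  decoy <- build_helix_backbone(max(n_decoy, 2))
  u <- unitv(stats::rnorm(3))
  ## orient the decoy helix to extend radially away from the motif
  ax <- unitv(decoy[[length(decoy)]]["CA", ] - decoy[[1]]["CA", ])
  rotax <- cross3(ax, u)
  Rr <- if (vnorm(rotax) < 1e-9) diag(3) else
    rotation_about_axis(rotax, rad2deg(acos(max(-1, min(1, sum(ax * u))))))
  Rr <- rotation_about_axis(u, stats::runif(1, 0, 360)) %*% Rr
  org <- lig_center + (50 + 10 * stats::runif(1)) * u
  gd <- rigid_transform(Rr, as.numeric(org - Rr %*% decoy[[1]]["CA", ]))
  decoy <- lapply(decoy[seq_len(n_decoy)], function(m) apply_transform(gd, m))
  ## assemble chain A: decoys fill indices outside the planted segment
  flank <- (length(seg) - 1) / 2
  chainA <- vector("list", n_residues)
  chainA[(p - flank):(p + flank)] <- seg
  chainA[setdiff(seq_len(n_residues), (p - flank):(p + flank))] <- decoy
  for (i in seq_len(n_residues)) {
    if (abs(i - p) > 2)
      chainA[[i]] <- chainA[[i]] + matrix(stats::rnorm(12, sd = jitter), 4, 3)
  }
  chainB <- lapply(chainA, function(m) apply_transform(gAB, m))
  st <- structure3d(rbind(.residues_to_df(chainA, "A"),
                          .residues_to_df(chainB, "B")))
  sc <- scaffold(st)
  ## frame(A, p) coincides with the motif His1 frame, so the motif's chlorins
  ## are already in scaffold coordinates
  ncl <- backbone_clash_check(lig, sc, clash_cutoff, exempt = p)
  if (ncl > 0)
    stop("impossible graft: ", ncl,
         " backbone atoms inside the chlorin footprint")
  attr(sc, "planted") <- p
  sc
}
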