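# Bilayer trajectory geometry: insertion depth, ring orientation, hydrogen
# bonding and water penetration, all referenced to the bilayer center plane.
#
# Depths are z-projections (distance from the bilayer center plane along the
# normal), not 3D distances to a center point: the analyzed bilayers are
# planar and every reported observable is a depth. Leaflets are not
# distinguished (absolute distance).

#' Construct a frame ensemble
#'
#' A minimal container for a multi-frame coordinate ensemble: a fixed atom
#' table, a coordinate array, and the periodic box.
#'
#' @param atoms data frame with columns \code{name}, \code{resname},
#'   \code{resid}, one row per atom (identical across frames).
#' @param coords numeric array \code{[n_atoms, 3, n_frames]}, nm.
#' @param box box dimensions (nm), length 3; the bilayer normal is z.
#' @return a \code{frame_ensemble} list.
#' @export
frame_ensemble <- function(atoms, coords, box) {
  atoms <- as.data.frame(atoms)
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  stopifnot(dim(coords)[1] == nrow(atoms), dim(coords)[2] == 3)
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  structure(list(atoms = atoms, coords = coords, box = rep_len(box, 3),
                 n_frames = dim(coords)[3]),
            class = "frame_ensemble")
}

#' Select atom indices by name / residue patterns
#'
#' @param ensemble a \code{\link{frame_ensemble}}.
#' @param name,resname,resid optional exact values (vectors allowed) that an
#'   atom must match; omitted criteria match everything.
#' @param heavy_only drop atoms whose name starts with "H".
#' @return integer atom indices.
#' @export
select_atoms <- function(ensemble, name = NULL, resname = NULL, resid = NULL,
                         heavy_only = FALSE) {
  a <- ensemble$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (heavy_only) keep <- keep & !grepl("^H", a$name)
  which(keep)
}

# z coordinates wrapped into the primary box [0, box_z)
wrap_z <- function(z, box_z) z - floor(z / box_z) * box_z

#' Bilayer center z per frame
#'
#' Mean z coordinate of the lipid selection in each frame, after wrapping z
#' into the primary box.
#'
#' @param ensemble a \code{\link{frame_ensemble}}.
#' @param lipid_sel atom indices of the lipid reference atoms.
#' @return numeric vector, one center (nm) per frame.
#' @export
bilayer_center_z <- function(ensemble, lipid_sel) {
  if (length(lipid_sel) < 2) stop("need at least 2 lipid atoms")
  vapply(seq_len(ensemble$n_frames), function(fr) {
    mean(wrap_z(ensemble$coords[lipid_sel, 3, fr], ensemble$box[3]))
  }, numeric(1))
}

#' Minimum-distance-to-bilayer-center distribution of a ligand
#'
#' For every frame and every ligand copy, computes the minimum over the
#' ligand's heavy atoms of the absolute z-distance to the bilayer center
#' plane, accumulates a histogram over frames and copies, and normalizes by
#' the most populated bin (so the peak has height 1).
#'
#' @param ensemble a \code{\link{frame_ensemble}}.
#' @param ligand_resname residue name of the ligand copies.
#' @param lipid_sel lipid reference atom indices (default: resname "LIP").
#' @param bin_width histogram bin width in nm (default 0.05).
#' @param frames optional integer frame range to analyze (e.g. the
#'   equilibrated part of a trajectory); default all.
#' @return a \code{min_distance_distribution} list: \code{bin_edges},
#'   \code{bin_mid}, \code{counts}, \code{normalized}, \code{peak_bin} (nm,
#'   midpoint of the most populated bin), \code{dist_min} (raw per
#'   frame-and-copy values).
#' @export
min_distance_distribution <- function(ensemble, ligand_resname = "LIG",
                                      lipid_sel = NULL, bin_width = 0.05,
                                      frames = NULL) {
  if (is.null(lipid_sel)) lipid_sel <- select_atoms(ensemble, resname = "LIP")
  if (is.null(frames)) frames <- seq_len(ensemble$n_frames)
  zc <- bilayer_center_z(ensemble, lipid_sel)
  lig <- ensemble$atoms$resname == ligand_resname &
    !grepl("^H", ensemble$atoms$name)
  if (!any(lig)) stop(sprintf("no heavy atoms with resname '%s'", ligand_resname))
  copies <- split(which(lig), ensemble$atoms$resid[lig])
  dmin <- unlist(lapply(frames, function(fr) {
    z <- wrap_z(ensemble$coords[, 3, fr], ensemble$box[3])
    vapply(copies, function(idx) min(abs(z[idx] - zc[fr])), numeric(1))
  }), use.names = FALSE)
  edges <- seq(0, ceiling(max(dmin) / bin_width) * bin_width + bin_width,
               by = bin_width)
  counts <- graphics::hist(dmin, breaks = edges, plot = FALSE)$counts
  normalized <- if (max(counts) > 0) counts / max(counts) else counts
  mid <- edges[-length(edges)] + bin_width / 2
  structure(list(bin_edges = edges, bin_mid = mid, counts = counts,
                 normalized = normalized, peak_bin = mid[which.max(counts)],
                 dist_min = dmin),
            class = "min_distance_distribution")
}

#' Indole-ring orientation distribution
#'
#' For every frame and ligand copy, takes the vector from atom C2 to the
#' midpoint of atoms C5 and C6 (the long axis of the nearly rigid indole
#' ring) and computes its angle to the z axis (the bilayer normal) as
#' \eqn{\arccos(v_z/|v|)}, in \eqn{[0, 180]} degrees. The alternative
#' definitions C2->C5 or C2->C6 are available via \code{axis}.
#'
#' @param ensemble a \code{\link{frame_ensemble}}.
#' @param ligand_resname residue name of the ligand copies.
#' @param bin_width angle bin width in degrees.
#' @param axis one of \code{"midpoint"} (C2 to midpoint of C5--C6),
#'   \code{"C5"}, \code{"C6"}.
#' @param frames optional frame range; default all.
#' @return an \code{orientation_distribution} list: \code{bin_mid}
#'   (degrees), \code{density} (sums to 1), \code{angles} (raw values),
#'   \code{mean_angle}.
#' @export
ring_orientation_distribution <- function(ensemble, ligand_resname = "LIG",
                                          bin_width = 2, axis = "midpoint",
                                          frames = NULL) {
  if (is.null(frames)) frames <- seq_len(ensemble$n_frames)
  a <- ensemble$atoms
  lig_resids <- unique(a$resid[a$resname == ligand_resname])
  idx_of <- function(rid, nm) {
    i <- which(a$resid == rid & a$name == nm)
    if (length(i) != 1) {
      stop(sprintf("ligand %s: ring atom %s missing", rid, nm))
    }
    i
  }
  trip <- lapply(lig_resids, function(rid) {
    c(C2 = idx_of(rid, "C2"), C5 = idx_of(rid, "C5"), C6 = idx_of(rid, "C6"))
  })
  angles <- unlist(lapply(frames, function(fr) {
    xyz <- ensemble$coords[, , fr]
    vapply(trip, function(ii) {
      tip <- switch(axis,
                    midpoint = (xyz[ii["C5"], ] + xyz[ii["C6"], ]) / 2,
                    C5 = xyz[ii["C5"], ],
                    C6 = xyz[ii["C6"], ],
                    stop("axis must be 'midpoint', 'C5' or 'C6'"))
      v <- tip - xyz[ii["C2"], ]
      acos(max(min(v[3] / sqrt(sum(v^2)), 1), -1)) * 180 / pi
    }, numeric(1))
  }), use.names = FALSE)
  edges <- seq(0, 180, by = bin_width)
  counts <- graphics::hist(angles, breaks = edges, plot = FALSE)$counts
  structure(list(bin_mid = edges[-length(edges)] + bin_width / 2,
                 density = counts / sum(counts), angles = angles,
                 mean_angle = mean(angles)),
            class = "orientation_distribution")
}

#' Count hydrogen bonds by distance and angle criteria
#'
#' A bond is counted when the donor--acceptor heavy-atom distance is at most
#' \code{d_cut} and the donor--H...acceptor angle is at least
#' \code{angle_cut}. The default cutoffs (0.35 nm, 135 degrees) are common
#' trajectory-analysis defaults; both are reported in the result. The mean
#' is per ligand molecule per frame, so donor/acceptor roles of specific
#' ligand atoms (e.g. the ring N1 versus the side-chain amine) can be probed
#' by passing the corresponding selections separately.
#'
#' @param ensemble a \code{\link{frame_ensemble}}.
#' @param donors data frame (or 2-column matrix) with columns \code{d}
#'   (donor heavy atom index) and \code{h} (its hydrogen index).
#' @param acceptors acceptor heavy-atom indices.
#' @param d_cut donor--acceptor distance cutoff (nm).
#' @param angle_cut donor--H...acceptor angle cutoff (degrees).
#' @param n_molecules number of ligand molecules for the per-molecule mean;
#'   default: number of distinct donor residues.
#' @param frames optional frame range; default all.
#' @return an \code{hbond_stats} list: \code{mean_per_molecule},
#'   \code{n_bonds}, \code{n_frames}, \code{d_cut}, \code{angle_cut}.
#' @export
hbond_count <- function(ensemble, donors, acceptors, d_cut = 0.35,
                        angle_cut = 135, n_molecules = NULL, frames = NULL) {
  donors <- as.data.frame(donors)
  names(donors)[1:2] <- c("d", "h")
  if (nrow(donors) == 0 || length(acceptors) == 0) {
    stop("donor and acceptor sets must be non-empty")
  }
  if (is.null(frames)) frames <- seq_len(ensemble$n_frames)
  if (is.null(n_molecules)) {
    n_molecules <- length(unique(ensemble$atoms$resid[donors$d]))
  }
  total <- 0L
  for (fr in frames) {
    xyz <- ensemble$coords[, , fr]
    for (i in seq_len(nrow(donors))) {
      dpos <- xyz[donors$d[i], ]
      hpos <- xyz[donors$h[i], ]
      for (aidx in acceptors) {
        if (aidx == donors$d[i]) next
        apos <- xyz[aidx, ]
        if (sqrt(sum((apos - dpos)^2)) > d_cut) next
        v1 <- dpos - hpos
        v2 <- apos - hpos
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(max(min(cosang, 1), -1)) * 180 / pi
        if (ang >= angle_cut) total <- total + 1L
      }
    }
  }
  structure(list(mean_per_molecule = total / (length(frames) * n_molecules),
                 n_bonds = total, n_frames = length(frames),
                 d_cut = d_cut, angle_cut = angle_cut),
            class = "hbond_stats")
}

#' Water penetration profile
#'
#' Histogram of the absolute z-distance of water oxygens from the bilayer
#' center, averaged over frames (counts per frame in each bin).
#'
#' @param ensemble a \code{\link{frame_ensemble}}.
#' @param water_sel water oxygen indices (default: atoms named "OW").
#' @param lipid_sel lipid reference atom indices (default: resname "LIP").
#' @param bin_width bin width in nm.
#' @param frames optional frame range; default all.
#' @return a \code{water_profile} list: \code{bin_mid} (nm),
#'   \code{mean_counts} (waters per frame per bin).
#' @export
water_penetration_profile <- function(ensemble, water_sel = NULL,
                                      lipid_sel = NULL, bin_width = 0.1,
                                      frames = NULL) {
  if (is.null(water_sel)) water_sel <- select_atoms(ensemble, name = "OW")
  if (length(water_sel) == 0) stop("water selection is empty")
  if (is.null(lipid_sel)) lipid_sel <- select_atoms(ensemble, resname = "LIP")
  if (is.null(frames)) frames <- seq_len(ensemble$n_frames)
  zc <- bilayer_center_z(ensemble, lipid_sel)
  zmax <- ensemble$box[3] / 2
  edges <- seq(0, ceiling(zmax / bin_width) * bin_width, by = bin_width)
  acc <- numeric(length(edges) - 1)
  for (fr in frames) {
    z <- wrap_z(ensemble$coords[water_sel, 3, fr], ensemble$box[3])
    d <- pmin(abs(z - zc[fr]), max(edges) - 1e-12)
    acc <- acc + graphics::hist(d, breaks = edges, plot = FALSE)$counts
  }
  structure(list(bin_mid = edges[-length(edges)] + bin_width / 2,
                 mean_counts = acc / length(frames), bin_edges = edges),
            class = "water_profile")
}
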