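# Per-frame geometric statistics: contact fractions, coordination numbers,
# distance series, membrane thickness, helix assignment, Kabsch RMSD.

# all-pairs Euclidean distance matrix between two coordinate sets (A: m x 3,
# B: k x 3). Minimum-image wrapping is deliberately not applied: deposited
# frames are whole-molecule.
cross_distances <- function(a, b) {
  a <- matrix(a, ncol = 3)
  b <- matrix(b, ncol = 3)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

resolve_residues <- function(traj, residues) {
  if (is.character(residues)) {
    parts <- strsplit(residues, ":", fixed = TRUE)
    residues <- data.frame(
      chain = vapply(parts, `[`, "", 1),
      resnum = as.integer(vapply(parts, `[`, "", 2)),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(residues), all(c("chain", "resnum") %in% names(residues)))
  residues
}

#' Per-residue probe contact fractions over a trajectory
#'
#' For each residue, the fraction of frames in which any non-hydrogen atom of
#' the residue lies within `cutoff` of any probe atom (a Na+ ion, or the set
#' of water oxygens). The default 3.5 Angstrom cutoff is the interaction
#' definition used for ion/water contact maps.
#'
#' @param traj a [trajectory()] (pass a [select_frames()] view to control the
#'   analysed window, e.g. the last 375 of 400 per-ns frames).
#' @param residues data.frame with columns `chain`, `resnum` (or strings
#'   `"B:24"`).
#' @param probe_atoms integer atom indices of the probe species.
#' @param cutoff contact cutoff, Angstrom.
#' @param roles result of [classify_atoms()]; computed if `NULL`.
#' @param probe label stored on the result (`"ion"` or `"water"`).
#' @return data.frame (`chain`, `resnum`, `resname`, `fraction`) with
#'   attributes `cutoff`, `n_frames`, `probe`.
#' @export
contact_fraction <- function(traj, residues, probe_atoms, cutoff = 3.5,
                             roles = NULL, probe = "ion") {
  residues <- resolve_residues(traj, residues)
  if (nrow(residues) == 0) stop("residue set must be non-empty")
  if (length(probe_atoms) == 0) stop("probe atom set must be non-empty")
  if (is.null(roles)) roles <- classify_atoms(traj)
  topo <- traj$topology
  nf <- n_frames(traj)
  res_atoms <- vector("list", nrow(residues))
  resname <- character(nrow(residues))
  for (i in seq_len(nrow(residues))) {
    idx <- which(topo$chain == residues$chain[i] &
                   topo$resnum == residues$resnum[i] &
                   !roles$is_hydrogen)
    if (length(idx) == 0) {
      stop(sprintf("residue %s:%d has no non-hydrogen atoms",
                   residues$chain[i], residues$resnum[i]))
    }
    res_atoms[[i]] <- idx
    resname[i] <- topo$resname[idx[1]]
  }
  hits <- matrix(FALSE, nrow = nrow(residues), ncol = nf)
  for (k in seq_len(nf)) {
    m <- frame_coords(traj, k)
    probe_xyz <- m[probe_atoms, , drop = FALSE]
    for (i in seq_len(nrow(residues))) {
      d <- cross_distances(m[res_atoms[[i]], , drop = FALSE], probe_xyz)
      hits[i, k] <- min(d) <= cutoff
    }
  }
  out <- data.frame(
    chain = residues$chain, resnum = residues$resnum, resname = resname,
    fraction = rowMeans(hits), stringsAsFactors = FALSE
  )
  attr(out, "cutoff") <- cutoff
  attr(out, "n_frames") <- nf
  attr(out, "probe") <- probe
  out
}

#' Na+ coordination number in one frame
#'
#' Counts polar atoms (O, N, S) of protein and water within `cutoff`
#' (default 2.5 Angstrom) of the ion. Hydrogens and the ion itself never
#' count.
#'
#' @param coords n_atoms x 3 coordinate matrix of one frame (see
#'   [frame_coords()]).
#' @param ion_index atom index of the ion.
#' @param roles result of [classify_atoms()].
#' @param cutoff coordination cutoff, Angstrom.
#' @param species count `"both"` (default), `"protein"` only, or `"water"`
#'   only.
#' @return integer coordination number.
#' @export
coordination_number <- function(coords, ion_index, roles, cutoff = 2.5,
                                species = c("both", "protein", "water")) {
  species <- match.arg(species)
  coords <- matrix(coords, ncol = 3)
  stopifnot(ion_index >= 1, ion_index <= nrow(coords))
  want_role <- switch(species,
                      both = c("protein", "water"),
                      protein = "protein",
                      water = "water")
  eligible <- roles$is_polar & roles$role %in% want_role &
    !roles$is_hydrogen
  eligible[ion_index] <- FALSE
  if (!any(eligible)) return(0L)
  d <- cross_distances(coords[which(eligible), , drop = FALSE],
                       coords[ion_index, , drop = FALSE])
  sum(d <= cutoff)
}

#' Distance from one atom to the nearest of a set of ions, per frame
#'
#' @param traj a [trajectory()].
#' @param atom atom index of the reference atom (e.g. Od1 of PomB-D24).
#' @param ion_indices non-empty set of ion atom indices.
#' @param label series label.
#' @return data.frame (`time_ns`, `value_A`) with attribute `label`.
#' @export
nearest_ion_distance <- function(traj, atom, ion_indices,
                                 label = "nearest ion distance") {
  if (length(ion_indices) == 0) stop("ion index set must be non-empty")
  nf <- n_frames(traj)
  vals <- numeric(nf)
  for (k in seq_len(nf)) {
    m <- frame_coords(traj, k)
    vals[k] <- min(cross_distances(m[atom, , drop = FALSE],
                                   m[ion_indices, , drop = FALSE]))
  }
  out <- data.frame(time_ns = traj$times, value_A = vals)
  attr(out, "label") <- label
  out
}

#' Per-frame distance between two atoms
#'
#' Used for chain-sliding diagnostics (e.g. D24 Od1 to T158 Og1) and for
#' inter-helix QC distances (Q54 Ca to V149 Ca).
#'
#' @inheritParams nearest_ion_distance
#' @param atom_a,atom_b distinct atom indices.
#' @return data.frame (`time_ns`, `value_A`) with attribute `label`.
#' @export
residue_pair_distance <- function(traj, atom_a, atom_b,
                                  label = "pair distance") {
  if (atom_a == atom_b) stop("atom indices must be distinct")
  dif <- traj$coords[atom_a, , , drop = FALSE] -
    traj$coords[atom_b, , , drop = FALSE]
  dim(dif) <- dim(dif)[2:3]           # 3 x n_frames, robust to 1 frame
  out <- data.frame(time_ns = traj$times,
                    value_A = sqrt(colSums(dif^2)))
  attr(out, "label") <- label
  out
}

#' Membrane hydrophobic thickness from leaflet marker atoms
#'
#' Per frame, the difference between the mean z of the top-leaflet markers
#' and the mean z of the bottom-leaflet markers (phosphorus atoms, or ester
#' carbons for the tighter definition). If leaflets are not supplied, markers
#' are split per frame by the sign of z about the median marker z.
#'
#' @param traj a [trajectory()].
#' @param marker_atoms indices of all marker atoms (used when `top`/`bottom`
#'   are `NULL`).
#' @param top,bottom optional explicit leaflet index sets.
#' @param definition `"phosphorus"` or `"ester_carbon"` (recorded only).
#' @return list (`mean`, `sd`, `definition`, `per_frame`, `n_frames`).
#' @export
hydrophobic_thickness <- function(traj, marker_atoms = NULL, top = NULL,
                                  bottom = NULL,
                                  definition = c("phosphorus",
                                                 "ester_carbon")) {
  definition <- match.arg(definition)
  explicit <- !is.null(top) && !is.null(bottom)
  if (!explicit && (is.null(marker_atoms) || length(marker_atoms) == 0)) {
    stop("supply marker_atoms or explicit top/bottom leaflet sets")
  }
  if (explicit && (length(top) == 0 || length(bottom) == 0)) {
    stop("both leaflet marker sets must be non-empty")
  }
  nf <- n_frames(traj)
  per_frame <- numeric(nf)
  for (k in seq_len(nf)) {
    z <- frame_coords(traj, k, apply_flip = TRUE)[, 3]
    if (explicit) {
      zt <- z[top]
      zb <- z[bottom]
    } else {
      zm <- z[marker_atoms]
      mid <- stats::median(zm)
      zt <- zm[zm > mid]
      zb <- zm[zm < mid]
      if (length(zt) == 0 || length(zb) == 0) {
        stop("leaflet assignment produced an empty leaflet in frame ", k)
      }
    }
    per_frame[k] <- mean(zt) - mean(zb)
  }
  list(mean = mean(per_frame),
       sd = if (nf > 1) stats::sd(per_frame) else 0,
       definition = definition, per_frame = per_frame, n_frames = nf)
}

# torsion angle (degrees) for points p1-p2-p3-p4, standard atan2 form
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  c1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  c2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  x <- sum(c1 * c2)
  y <- sum(b2 / sqrt(sum(b2^2)) * c(c1[2] * c2[3] - c1[3] * c2[2],
                                    c1[3] * c2[1] - c1[1] * c2[3],
                                    c1[1] * c2[2] - c1[2] * c2[1]))
  atan2(y, x) * 180 / pi
}

#' Helix assignment from backbone dihedrals
#'
#' A residue is helical when phi lies in `[-100, -30]` degrees, psi in
#' `[-80, 5]` degrees, and the residue belongs to a run of at least
#' `min_run` consecutive such residues (same chain, consecutive residue
#' numbers). Residues with missing backbone neighbours (chain termini,
#' gaps, missing N/CA/C) are unassessed and break runs.
#'
#' @param traj a [trajectory()].
#' @param frame frame index to assess.
#' @param phi_range,psi_range dihedral windows, degrees.
#' @param min_run minimal helical run length.
#' @return list: `residues` (data.frame `chain`, `resnum`, `phi`, `psi`,
#'   `in_window`, `helical`) and `runs` (data.frame `chain`, `start`, `end`).
#' @export
helix_assignment <- function(traj, frame = 1,
                             phi_range = c(-100, -30),
                             psi_range = c(-80, 5), min_run = 4) {
  topo <- traj$topology
  m <- frame_coords(traj, frame)
  key <- paste(topo$chain, topo$resnum, topo$name, sep = "|")
  lookup <- function(chain, resnum, name) {
    i <- match(paste(chain, resnum, name, sep = "|"), key)
    if (is.na(i)) NULL else m[i, ]
  }
  prot <- unique(topo[topo$resname %in% STANDARD_AA, c("chain", "resnum")])
  prot <- prot[order(prot$chain, prot$resnum), , drop = FALSE]
  n <- nrow(prot)
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ch <- prot$chain[i]
    rn <- prot$resnum[i]
    Np <- lookup(ch, rn, "N"); CAp <- lookup(ch, rn, "CA")
    Cp <- lookup(ch, rn, "C")
    Cprev <- lookup(ch, rn - 1, "C")
    Nnext <- lookup(ch, rn + 1, "N")
    if (!is.null(Np) && !is.null(CAp) && !is.null(Cp)) {
      if (!is.null(Cprev)) phi[i] <- dihedral_angle(Cprev, Np, CAp, Cp)
      if (!is.null(Nnext)) psi[i] <- dihedral_angle(Np, CAp, Cp, Nnext)
    }
  }
  in_window <- !is.na(phi) & !is.na(psi) &
    phi >= phi_range[1] & phi <= phi_range[2] &
    psi >= psi_range[1] & psi <= psi_range[2]
  helical <- rep(FALSE, n)
  runs <- list()
  for (ch in unique(prot$chain)) {
    idx <- which(prot$chain == ch)
    # break runs at residue-number gaps
    grp <- cumsum(c(1, diff(prot$resnum[idx]) != 1))
    for (g in unique(grp)) {
      sub <- idx[grp == g]
      r <- rle(in_window[sub])
      pos <- cumsum(c(1, r$lengths))
      for (j in seq_along(r$lengths)) {
        if (r$values[j] && r$lengths[j] >= min_run) {
          span <- sub[pos[j]:(pos[j + 1] - 1)]
          helical[span] <- TRUE
          runs[[length(runs) + 1]] <- data.frame(
            chain = ch, start = prot$resnum[span[1]],
            end = prot$resnum[span[length(span)]],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  runs <- if (length(runs) > 0) do.call(rbind, runs) else
    data.frame(chain = character(), start = integer(), end = integer())
  list(
    residues = data.frame(chain = prot$chain, resnum = prot$resnum,
                          phi = phi, psi = psi, in_window = in_window,
                          helical = helical, stringsAsFactors = FALSE),
    runs = runs
  )
}

#' Minimal RMSD after optimal rigid superposition (Kabsch)
#'
#' Translates both point sets to their centroids and rotates `b` onto `a`
#' with the SVD-based optimal proper rotation, then reports the RMSD.
#'
#' @param coords_a,coords_b N x 3 matrices, equal N.
#' @return RMSD in the coordinate units (Angstrom).
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  a <- matrix(coords_a, ncol = 3)
  b <- matrix(coords_b, ncol = 3)
  if (nrow(a) != nrow(b)) stop("point sets must have equal size")
  if (nrow(a) < 1) stop("need at least one point")
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  h <- crossprod(bc, ac)            # 3x3 covariance
  s <- svd(h)
  d <- sign(det(tcrossprod(s$v, s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  br <- bc %*% t(r)
  sqrt(mean(rowSums((ac - br)^2)))
}
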