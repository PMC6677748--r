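# Fixtures and independent brute-force oracles, built in code at test time.

# Hand-format a PDB ATOM line (independent of write_pdb).
pdb_line <- function(serial, name, resname, chain, resnum, x, y, z,
                     record = "ATOM", element = "") {
  sprintf("%-6s%5d %-4s %-4s%s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, name, resname, chain, resnum, x, y, z, element)
}

# Two-atom, possibly multi-model PDB text.
two_atom_pdb <- function(n_models = 1, drop_atom_in_model = NA) {
  lines <- character(0)
  for (m in seq_len(n_models)) {
    if (n_models > 1) lines <- c(lines, sprintf("MODEL     %4d", m))
    lines <- c(lines, pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, element = "C"))
    if (!identical(m, drop_atom_in_model)) {
      lines <- c(lines, pdb_line(2, "O", "HOH", "W", 100, 3, 0, 0,
                                 record = "HETATM", element = "O"))
    }
    if (n_models > 1) lines <- c(lines, "ENDMDL")
  }
  c(lines, "END")
}

# A small trajectory built directly (bypasses the PDB reader): one GLY
# residue (N, CA, C), one THR OG1, three waters, one Na ion.
toy_trajectory <- function(n_frames = 3) {
  topo <- data.frame(
    serial = 1:8,
    name = c("N", "CA", "C", "OG1", "O", "O", "O", "NA"),
    resname = c("GLY", "GLY", "GLY", "THR", "HOH", "HOH", "HOH", "NA"),
    resnum = c(24L, 24L, 24L, 158L, 301L, 302L, 303L, 900L),
    chain = c("B", "B", "B", "A", "W", "W", "W", "X"),
    element = c("N", "C", "C", "O", "O", "O", "O", "NA"),
    record = c(rep("ATOM", 4), rep("HETATM", 4)),
    stringsAsFactors = FALSE
  )
  base <- rbind(
    c(0, 0, 0), c(1.4, 0, 0), c(2.8, 0.4, 0),   # GLY backbone
    c(10, 0, 0),                                  # THR OG1
    c(0, 5, 0), c(5, 5, 0), c(10, 5, 0),          # waters
    c(20, 20, 20)                                 # ion
  )
  coords <- array(0, dim = c(8, 3, n_frames))
  for (k in seq_len(n_frames)) coords[, , k] <- base + (k - 1) * 0.1
  trajectory(topo, coords)
}

# Brute-force contact-fraction oracle: explicit per-frame double loop.
oracle_contact_fraction <- function(traj, res_chain, res_resnum, probe_idx,
                                    cutoff, roles) {
  topo <- traj$topology
  ridx <- which(topo$chain == res_chain & topo$resnum == res_resnum &
                  !roles$is_hydrogen)
  hit <- logical(n_frames(traj))
  for (k in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, k)
    found <- FALSE
    for (i in ridx) for (j in probe_idx) {
      if (sqrt(sum((m[i, ] - m[j, ])^2)) <= cutoff) found <- TRUE
    }
    hit[k] <- found
  }
  mean(hit)
}

# Brute-force coordination-number oracle.
oracle_coordination <- function(coords, ion, roles, cutoff) {
  count <- 0L
  for (i in seq_len(nrow(coords))) {
    if (i == ion) next
    if (!roles$is_polar[i]) next
    if (!(roles$role[i] %in% c("protein", "water"))) next
    if (sqrt(sum((coords[i, ] - coords[ion, ])^2)) <= cutoff) {
      count <- count + 1L
    }
  }
  count
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}
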