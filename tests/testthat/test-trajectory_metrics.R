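test_that("contact_fraction matches scripted and brute-force values", {
  # always bound: ion 2 A from a residue atom in all frames
  tr <- toy_trajectory(10)
  tr$coords[8, , ] <- tr$coords[2, , ] + c(2, 0, 0)  # ion next to CA
  cm <- contact_fraction(tr, data.frame(chain = "B", resnum = 24), 8)
  expect_equal(cm$fraction, 1.0)

  # never bound: >= 10 A away everywhere
  tr2 <- toy_trajectory(10)
  tr2$coords[8, , ] <- c(100, 100, 100)
  cm2 <- contact_fraction(tr2, data.frame(chain = "B", resnum = 24), 8)
  expect_equal(cm2$fraction, 0.0)

  # contact in 4 of 10 frames -> 0.4, and equality with the explicit oracle
  tr3 <- toy_trajectory(10)
  tr3$coords[8, , ] <- c(100, 100, 100)
  for (k in 1:4) tr3$coords[8, , k] <- tr3$coords[1, , k] + c(0, 3.2, 0)
  roles <- classify_atoms(tr3)
  cm3 <- contact_fraction(tr3, data.frame(chain = "B", resnum = 24), 8,
                          roles = roles)
  expect_equal(cm3$fraction, 0.4)
  expect_equal(cm3$fraction,
               oracle_contact_fraction(tr3, "B", 24, 8, 3.5, roles))
})

test_that("contact_fraction equals the oracle on randomized fixtures and is
           monotone in cutoff", {
  set.seed(7)
  for (rep in 1:5) {
    tr <- toy_trajectory(8)
    tr$coords <- tr$coords + array(stats::rnorm(length(tr$coords), 0, 4),
                                   dim = dim(tr$coords))
    roles <- classify_atoms(tr)
    res <- data.frame(chain = c("B", "A"), resnum = c(24, 158))
    for (cut in c(2, 3.5, 6)) {
      cm <- contact_fraction(tr, res, 8, cutoff = cut, roles = roles)
      expect_equal(cm$fraction[1],
                   oracle_contact_fraction(tr, "B", 24, 8, cut, roles))
      expect_equal(cm$fraction[2],
                   oracle_contact_fraction(tr, "A", 158, 8, cut, roles))
    }
    f1 <- contact_fraction(tr, res, 8, cutoff = 2.5, roles = roles)$fraction
    f2 <- contact_fraction(tr, res, 8, cutoff = 4.5, roles = roles)$fraction
    expect_true(all(f2 >= f1))
  }
})

test_that("coordination_number counts the five-ligand shell and matches the
           oracle", {
  # constructed shell: Od1/Od2 of D24, Og1 of T158, two water O at 2.2-2.4 A
  topo <- data.frame(
    serial = 1:7,
    name = c("OD1", "OD2", "OG1", "O", "O", "O", "NA"),
    resname = c("ASP", "ASP", "THR", "HOH", "HOH", "HOH", "NA"),
    resnum = c(24L, 24L, 158L, 301L, 302L, 303L, 900L),
    chain = c("B", "B", "A", "W", "W", "W", "X"),
    element = c("O", "O", "O", "O", "O", "O", "NA"),
    record = "ATOM", stringsAsFactors = FALSE)
  ion <- c(0, 0, 0)
  shell <- rbind(c(2.2, 0, 0), c(-2.3, 0, 0), c(0, 2.4, 0),
                 c(0, -2.2, 0), c(0, 0, 2.3),
                 c(0, 0, 9))   # third water outside the shell
  coords <- array(rbind(shell, ion), dim = c(7, 3, 1))
  tr <- trajectory(topo, coords)
  roles <- classify_atoms(tr)
  expect_equal(coordination_number(frame_coords(tr, 1), 7, roles), 5)

  # isolated ion
  lone <- frame_coords(tr, 1)
  lone[1:6, ] <- lone[1:6, ] + 100
  expect_equal(coordination_number(lone, 7, roles), 0)

  # randomized radii vs brute-force oracle
  set.seed(13)
  for (rep in 1:10) {
    m <- frame_coords(tr, 1)
    m[1:6, ] <- m[1:6, ] / sqrt(rowSums(m[1:6, ]^2)) * stats::runif(6, 1.5, 4)
    expect_equal(coordination_number(m, 7, roles),
                 oracle_coordination(m, 7, roles, 2.5))
  }
})

test_that("coordination_number is invariant under rigid motion", {
  tr <- toy_trajectory(1)
  tr$coords[8, , 1] <- c(1, 5, 0)  # near two waters
  roles <- classify_atoms(tr)
  m <- frame_coords(tr, 1)
  base <- coordination_number(m, 8, roles, cutoff = 5)
  expect_gt(base, 0)
  for (seed in 1:4) {
    r <- random_rotation(seed)
    moved <- m %*% r + matrix(rep(c(3, -7, 11), each = nrow(m)), ncol = 3)
    expect_equal(coordination_number(moved, 8, roles, cutoff = 5), base)
  }
})

test_that("nearest_ion_distance takes the per-frame minimum", {
  tr <- toy_trajectory(5)
  # constant 7 A offset from THR OG1 analogue
  tr$coords[8, , ] <- tr$coords[4, , ] + c(7, 0, 0)
  ds <- nearest_ion_distance(tr, 4, 8)
  expect_equal(ds$value_A, rep(7, 5))

  # two ions: nearer one wins
  topo <- rbind(tr$topology,
                data.frame(serial = 9, name = "NA", resname = "NA",
                           resnum = 901L, chain = "X", element = "NA",
                           record = "HETATM"))
  coords <- array(0, dim = c(9, 3, 5))
  coords[1:8, , ] <- tr$coords
  for (k in 1:5) coords[9, , k] <- tr$coords[4, , k] + c(0, 2.9, 0)
  tr2 <- trajectory(topo, coords)
  expect_equal(nearest_ion_distance(tr2, 4, c(8, 9))$value_A, rep(2.9, 5))

  # random-walk fixture vs elementwise brute-force min
  set.seed(3)
  tr3 <- tr2
  tr3$coords <- tr3$coords + array(stats::rnorm(length(tr3$coords), 0, 3),
                                   dim = dim(tr3$coords))
  got <- nearest_ion_distance(tr3, 4, c(8, 9))$value_A
  want <- sapply(1:5, function(k) {
    m <- frame_coords(tr3, k)
    min(sqrt(sum((m[4, ] - m[8, ])^2)), sqrt(sum((m[4, ] - m[9, ])^2)))
  })
  expect_equal(got, want)
})

test_that("residue_pair_distance is the per-frame Euclidean norm", {
  tr <- toy_trajectory(3)
  tr$coords[4, , ] <- tr$coords[1, , ]  # identical -> 0
  expect_equal(residue_pair_distance(tr, 1, 4)$value_A, rep(0, 3))
  tr$coords[4, , ] <- tr$coords[1, , ] + c(3, 4, 0)
  expect_equal(residue_pair_distance(tr, 1, 4)$value_A, rep(5, 3))
  set.seed(5)
  tr$coords <- tr$coords + array(stats::rnorm(length(tr$coords)),
                                 dim = dim(tr$coords))
  want <- sapply(1:3, function(k) {
    m <- frame_coords(tr, k)
    sqrt(sum((m[1, ] - m[4, ])^2))
  })
  expect_equal(residue_pair_distance(tr, 1, 4)$value_A, want)
  expect_error(residue_pair_distance(tr, 4, 4), "distinct")
})

test_that("hydrophobic_thickness averages leaflet z and handles flips", {
  mk_markers <- function(z_top, z_bot, n_frames = 1) {
    n <- length(z_top) + length(z_bot)
    topo <- data.frame(serial = 1:n, name = "P", resname = "POPE",
                       resnum = 1:n, chain = "M", element = "P",
                       record = "HETATM", stringsAsFactors = FALSE)
    coords <- array(0, dim = c(n, 3, n_frames))
    for (k in seq_len(n_frames)) coords[, 3, k] <- c(z_top, z_bot)
    trajectory(topo, coords)
  }
  tr <- mk_markers(rep(19.1, 4), rep(-19.1, 4))
  expect_equal(hydrophobic_thickness(tr, 1:8)$mean, 38.2)
  tr2 <- mk_markers(20, -18)
  expect_equal(hydrophobic_thickness(tr2, 1:2)$mean, 38.0)

  # noisy leaflets over 5 frames vs plain arithmetic
  set.seed(9)
  tr3 <- mk_markers(rep(19, 6), rep(-19, 6), n_frames = 5)
  tr3$coords[, 3, ] <- tr3$coords[, 3, ] + stats::rnorm(60, 0, 0.5)
  got <- hydrophobic_thickness(tr3, 1:12)
  per <- sapply(1:5, function(k) {
    z <- tr3$coords[, 3, k]
    mean(z[z > stats::median(z)]) - mean(z[z < stats::median(z)])
  })
  expect_equal(got$per_frame, per)
  expect_equal(got$mean, mean(per))
  expect_equal(got$sd, stats::sd(per))

  # invariant under lateral translation and under the z-convention flip
  tr4 <- tr3
  tr4$coords[, 1, ] <- tr4$coords[, 1, ] + 100
  tr4$coords[, 2, ] <- tr4$coords[, 2, ] - 50
  expect_equal(hydrophobic_thickness(tr4, 1:12)$mean, got$mean)
  tr5 <- tr3
  tr5$z_flip <- TRUE
  expect_equal(hydrophobic_thickness(tr5, 1:12)$mean, got$mean)

  one_side <- mk_markers(rep(10, 4), rep(10, 4))
  expect_error(hydrophobic_thickness(one_side, 1:8), "empty leaflet")
})

test_that("helix_assignment applies the dihedral window and run-length rule", {
  helix <- build_peptide(10, phi = -57, psi = -47)
  h <- helix_assignment(helix)
  assessed <- !is.na(h$residues$phi) & !is.na(h$residues$psi)
  expect_true(all(h$residues$helical[assessed]))
  expect_equal(nrow(h$runs), 1)
  expect_gte(h$runs$end - h$runs$start + 1, 8)

  ext <- helix_assignment(build_peptide(10, phi = 180, psi = 180))
  expect_false(any(ext$residues$helical))
  expect_equal(nrow(ext$runs), 0)

  # 3-residue helical island inside coil: below the run-length threshold
  phis <- rep(180, 12); psis <- rep(180, 12)
  phis[5:7] <- -57; psis[5:7] <- -47
  island <- helix_assignment(build_peptide(12, phi = phis, psi = psis))
  expect_false(any(island$residues$helical))
})

test_that("kabsch_rmsd is rigid-invariant, symmetric and matches the
           two-point closed form", {
  set.seed(21)
  x <- matrix(stats::rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(x, x), 0)
  for (seed in 1:3) {
    r <- random_rotation(seed)
    y <- x %*% r + matrix(rep(c(5, -2, 8), each = 10), ncol = 3)
    expect_lt(kabsch_rmsd(x, y), 1e-6)
  }
  a <- rbind(c(0, 0, 0), c(1, 0, 0))
  b <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(kabsch_rmsd(a, b), 0.5)
  y <- x + matrix(stats::rnorm(30, 0, 0.3), 10, 3)
  expect_equal(kabsch_rmsd(x, y), kabsch_rmsd(y, x))
  expect_error(kabsch_rmsd(x, x[1:5, ]), "equal size")
})
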