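# Synthetic-data generators with known ground truth: pseudo-lipid membranes,
# scripted ion-binding trajectories, a 1D overdamped-Langevin steered-MD
# surrogate, Gaussian-band FTIR spectra with Hill-responsive amplitudes, and
# an ideal-geometry peptide builder. Every generator returns a
# (data, truth) pair and draws all randomness from one explicit seed.

KB_KCAL <- 0.0019872041  # Boltzmann constant, kcal/mol/K

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

#' Build a pseudo-lipid membrane system
#'
#' Places POPE and POPG pseudo-lipids (3:1 by default, 324:108) on a square
#' lattice, balanced across two leaflets. Each lipid carries one phosphorus
#' marker at z = +/- thickness/2 (plus seeded Gaussian jitter) and two
#' ester-carbon markers (`C21`, `C31`) 4 Angstrom inward. The phosphorus
#' hydrophobic thickness of the jitter-free system is exactly `thickness`.
#'
#' @param n_pope,n_popg lipid counts (POPE:POPG defaults to the 3:1 bilayer
#'   composition). Totals must be even so leaflets balance.
#' @param thickness phosphorus-to-phosphorus thickness, Angstrom. Default is
#'   the measured initial-model value, 38.2 A.
#' @param area_per_lipid lateral area per lipid, Angstrom^2 (POPE/POPG
#'   bilayers run near 60 A^2).
#' @param n_frames frames to emit (jitter redrawn per frame).
#' @param jitter_sd Gaussian jitter on marker z, Angstrom.
#' @param seed RNG seed.
#' @return list with `trajectory` and `truth` (thickness, counts, marker
#'   names).
#' @export
build_membrane_system <- function(n_pope = 324, n_popg = 108,
                                  thickness = 38.2, area_per_lipid = 60,
                                  n_frames = 1, jitter_sd = 0.5,
                                  seed = NULL) {
  stopifnot(n_pope > 0, n_popg > 0, thickness > 0)
  n_lip <- n_pope + n_popg
  if (n_lip %% 2 != 0) stop("total lipid count must be even for balanced leaflets")
  per_leaflet <- n_lip / 2
  # interleave POPG every 4th lipid so each leaflet holds half of each species
  resname_leaflet <- rep("POPE", per_leaflet)
  resname_leaflet[seq_len(n_popg / 2) * (per_leaflet %/% (n_popg / 2))] <- "POPG"
  if (sum(resname_leaflet == "POPG") != n_popg / 2) {
    resname_leaflet <- c(rep("POPG", n_popg / 2),
                         rep("POPE", per_leaflet - n_popg / 2))
  }
  side <- ceiling(sqrt(per_leaflet))
  spacing <- sqrt(area_per_lipid)
  gx <- ((seq_len(per_leaflet) - 1) %% side) * spacing
  gy <- ((seq_len(per_leaflet) - 1) %/% side) * spacing

  atom_names <- c("P", "C21", "C31")
  z_off <- c(0, -4, -4)  # ester carbons sit 4 A inward of the phosphorus
  n_atoms_total <- n_lip * length(atom_names)
  topo <- data.frame(
    serial = seq_len(n_atoms_total),
    name = rep(atom_names, n_lip),
    resname = rep(c(resname_leaflet, resname_leaflet), each = length(atom_names)),
    resnum = rep(seq_len(n_lip), each = length(atom_names)),
    chain = rep(c(rep("U", per_leaflet), rep("L", per_leaflet)),
                each = length(atom_names)),
    element = rep(c("P", "C", "C"), n_lip),
    record = "HETATM",
    stringsAsFactors = FALSE
  )
  leaf_sign <- rep(c(rep(1, per_leaflet), rep(-1, per_leaflet)),
                   each = length(atom_names))
  base_x <- rep(rep(gx, 2), each = length(atom_names))
  base_y <- rep(rep(gy, 2), each = length(atom_names))
  # "inward" means toward z = 0 for both leaflets
  base_z <- leaf_sign * (thickness / 2 + rep(z_off, n_lip))

  coords <- with_seed(seed, {
    arr <- array(0, dim = c(n_atoms_total, 3, n_frames))
    for (k in seq_len(n_frames)) {
      jit <- if (jitter_sd > 0) stats::rnorm(n_atoms_total, 0, jitter_sd) else 0
      arr[, , k] <- cbind(base_x, base_y, base_z + jit)
    }
    arr
  })
  traj <- trajectory(topo, coords)
  list(
    trajectory = traj,
    truth = list(thickness = thickness, ester_offset = 4,
                 n_pope = n_pope, n_popg = n_popg, jitter_sd = jitter_sd,
                 phosphorus_atoms = which(topo$name == "P"),
                 ester_atoms = which(topo$name %in% c("C21", "C31")))
  )
}

#' Generate a trajectory with scripted probe-residue contacts
#'
#' Builds a toy protein (one three-atom residue per scripted entry, residues
#' spaced far apart) plus a single probe atom (a Na+ ion, or a water oxygen).
#' During each scripted frame interval the probe sits 2.0 Angstrom from the
#' target residue's CA; in all other frames it is parked >= 10 Angstrom from
#' every residue. [contact_fraction()] on the output therefore equals the
#' scripted fraction exactly.
#'
#' Intervals are 1-based inclusive frame ranges and must not overlap across
#' the whole script (one probe cannot contact two well-separated residues in
#' the same frame).
#'
#' @param script list of entries `list(chain=, resnum=, intervals=list(c(first,last), ...))`.
#' @param n_frames total frame count.
#' @param probe `"ion"` (residue name NA) or `"water"` (water oxygen).
#' @param seed RNG seed (jitters probe placement direction only, never
#'   distances).
#' @return list with `trajectory`, and `truth` containing the per-residue
#'   scripted fractions and the probe atom index.
#' @export
generate_binding_trajectory <- function(script, n_frames, probe = c("ion", "water"),
                                        seed = NULL) {
  probe <- match.arg(probe)
  stopifnot(n_frames >= 1, length(script) >= 1)
  occupied <- integer(0)
  frames_of <- vector("list", length(script))
  for (i in seq_along(script)) {
    entry <- script[[i]]
    fr <- integer(0)
    for (iv in entry$intervals) {
      if (length(iv) != 2 || iv[1] < 1 || iv[2] > n_frames || iv[1] > iv[2]) {
        stop("interval must be 1-based inclusive within [1, n_frames]")
      }
      fr <- c(fr, seq(iv[1], iv[2]))
    }
    if (anyDuplicated(fr)) stop("overlapping intervals for residue ", i)
    if (length(intersect(fr, occupied)) > 0) {
      stop("intervals overlap across residues; one probe cannot serve two sites")
    }
    occupied <- c(occupied, fr)
    frames_of[[i]] <- fr
  }

  n_res <- length(script)
  spacing <- 30
  res_names <- c("N", "CA", "C")
  res_offsets <- rbind(c(-1.4, 0, 0), c(0, 0, 0), c(1.4, 0.4, 0))
  topo_rows <- list()
  for (i in seq_len(n_res)) {
    topo_rows[[i]] <- data.frame(
      serial = (i - 1) * 3 + 1:3, name = res_names, resname = "GLY",
      resnum = script[[i]]$resnum, chain = script[[i]]$chain,
      element = c("N", "C", "C"), record = "ATOM",
      stringsAsFactors = FALSE)
  }
  probe_row <- data.frame(
    serial = n_res * 3 + 1,
    name = if (probe == "ion") "NA" else "O",
    resname = if (probe == "ion") "NA" else "HOH",
    resnum = 9000L, chain = "X",
    element = if (probe == "ion") "NA" else "O",
    record = "HETATM", stringsAsFactors = FALSE)
  topo <- rbind(do.call(rbind, topo_rows), probe_row)

  ca_pos <- cbind((seq_len(n_res) - 1) * spacing, 0, 0)
  park <- c(-spacing, 50, 50)  # far from every residue
  probe_idx <- n_res * 3 + 1

  coords <- with_seed(seed, {
    arr <- array(0, dim = c(nrow(topo), 3, n_frames))
    for (i in seq_len(n_res)) {
      rows <- (i - 1) * 3 + 1:3
      block <- sweep(res_offsets, 2, ca_pos[i, ], `+`)
      for (k in seq_len(n_frames)) arr[rows, , k] <- block
    }
    for (k in seq_len(n_frames)) {
      bound_to <- which(vapply(frames_of, function(f) k %in% f, logical(1)))
      if (length(bound_to) == 1) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        arr[probe_idx, , k] <- ca_pos[bound_to, ] + 2.0 * u
      } else {
        arr[probe_idx, , k] <- park
      }
    }
    arr
  })
  fractions <- vapply(frames_of, length, integer(1)) / n_frames
  list(
    trajectory = trajectory(topo, coords),
    truth = list(
      fractions = data.frame(
        chain = vapply(script, function(e) e$chain, ""),
        resnum = vapply(script, function(e) as.integer(e$resnum), 1L),
        fraction = fractions, stringsAsFactors = FALSE),
      probe_index = probe_idx, contact_distance = 2.0)
  )
}

#' Specify a 1D channel potential as a sum of Gaussians
#'
#' `U(z) = sum_i h_i exp(-(z - c_i)^2 / (2 w_i^2))`, the surrogate for the
#' channel energetics the pulling simulations probe. Positive heights are
#' barriers, negative are wells.
#'
#' @param centers,heights,widths equal-length numeric vectors (A, kcal/mol,
#'   A); widths must be positive.
#' @param z_range domain `c(z_start, z_end)`.
#' @return object of class `potential_spec`.
#' @export
potential_spec <- function(centers, heights, widths, z_range = c(0, 50)) {
  stopifnot(length(centers) == length(heights),
            length(centers) == length(widths), all(widths > 0),
            z_range[2] > z_range[1])
  structure(list(centers = centers, heights = heights, widths = widths,
                 z_range = z_range),
            class = "potential_spec")
}

#' Evaluate a potential and its gradient
#' @param pot a [potential_spec()].
#' @param z positions, Angstrom.
#' @return `potential_energy`: U(z) in kcal/mol; `potential_gradient`:
#'   dU/dz in kcal/mol/A.
#' @export
potential_energy <- function(pot, z) {
  out <- numeric(length(z))
  for (i in seq_along(pot$centers)) {
    out <- out + pot$heights[i] *
      exp(-(z - pot$centers[i])^2 / (2 * pot$widths[i]^2))
  }
  out
}

#' @rdname potential_energy
#' @export
potential_gradient <- function(pot, z) {
  out <- numeric(length(z))
  for (i in seq_along(pot$centers)) {
    out <- out - pot$heights[i] * (z - pot$centers[i]) / pot$widths[i]^2 *
      exp(-(z - pot$centers[i])^2 / (2 * pot$widths[i]^2))
  }
  out
}

#' Location of the maximal uphill slope of a potential
#'
#' Fine-grid argmax of dU/dz; the quasi-static force peak of a pulling run
#' should land within ~1 Angstrom of this position.
#'
#' @param pot a [potential_spec()].
#' @param n grid points.
#' @return z position, Angstrom.
#' @export
argmax_gradient <- function(pot, n = 20001) {
  z <- seq(pot$z_range[1], pot$z_range[2], length.out = n)
  z[which.max(potential_gradient(pot, z))]
}

#' 1D overdamped-Langevin constant-velocity pulling surrogate
#'
#' The ion position follows `dz = (F_pot + F_spring)/gamma dt +
#' sqrt(2 kB T dt / gamma) xi` with the spring anchored at
#' `z0 + velocity * t`; the recorded force is the spring force
#' `k (z_anchor - z_ion)`, the observable of a constant-velocity pulling
#' run. Inertia and the lateral restraint are intentionally absent from the
#' 1D surrogate.
#'
#' @param potential a [potential_spec()].
#' @param schedule an [smd_schedule()]; the anchor travels exactly
#'   `pull_distance` over `duration`.
#' @param friction gamma, kcal ps / (mol A^2). The default 20 makes the
#'   flat-potential drag force `gamma * velocity = 1` kcal/mol/A at the
#'   default velocity.
#' @param temperature K.
#' @param dt integration step, ps. Stability requires
#'   `dt < friction / (spring_k + max |U''|)`.
#' @param trial_id integer label.
#' @param seed RNG seed.
#' @param record_stride record every `record_stride`-th step.
#' @return a [force_log()] with attribute `truth` (potential, friction,
#'   temperature, schedule).
#' @export
simulate_smd_1d <- function(potential, schedule = smd_schedule(),
                            friction = 20, temperature = 310, dt = 0.05,
                            trial_id = 1L, seed = NULL, record_stride = 1L) {
  stopifnot(friction > 0, temperature >= 0, dt > 0)
  zg <- seq(potential$z_range[1], potential$z_range[2], length.out = 4001)
  g <- potential_gradient(potential, zg)
  max_u2 <- max(abs(diff(g) / diff(zg)))
  dt_max <- friction / (schedule$spring_k + max_u2)
  if (dt >= dt_max) {
    stop(sprintf(
      "dt = %g unstable; require dt < friction/(spring_k + max|U''|) = %g ps",
      dt, dt_max))
  }
  n_steps <- ceiling(schedule$duration / dt)
  z0 <- potential$z_range[1]
  noise_sd <- sqrt(2 * KB_KCAL * temperature * dt / friction)
  rec_idx <- seq(1L, n_steps, by = as.integer(record_stride))

  res <- with_seed(seed, {
    z <- z0
    t_out <- numeric(length(rec_idx))
    z_out <- numeric(length(rec_idx))
    f_out <- numeric(length(rec_idx))
    xi <- if (temperature > 0) stats::rnorm(n_steps, 0, noise_sd) else
      numeric(n_steps)
    j <- 1L
    for (s in seq_len(n_steps)) {
      t_now <- (s - 1) * dt
      anchor <- z0 + schedule$velocity * t_now
      f_spring <- schedule$spring_k * (anchor - z)
      if (s == rec_idx[j]) {
        t_out[j] <- t_now
        z_out[j] <- z
        f_out[j] <- f_spring
        if (j < length(rec_idx)) j <- j + 1L
      }
      f_tot <- -potential_gradient(potential, z) + f_spring
      z <- z + f_tot / friction * dt + (if (temperature > 0) xi[s] else 0)
      if (!is.finite(z) || abs(anchor - z) > schedule$pull_distance) {
        stop("trajectory diverged; reduce dt or increase friction")
      }
    }
    list(t = t_out, z = z_out, f = f_out)
  })
  log <- force_log(trial_id, res$t, res$z, res$f)
  attr(log, "truth") <- list(potential = potential, friction = friction,
                             temperature = temperature, schedule = schedule)
  log
}

#' Ensemble of surrogate pulling trials
#'
#' Runs `n_trials` independent [simulate_smd_1d()] trials (trial ids
#' 1..n_trials) from a single seed.
#'
#' @inheritParams simulate_smd_1d
#' @param n_trials number of trials (the production protocol used 10 per
#'   set).
#' @return list of [force_log()] objects.
#' @export
simulate_smd_ensemble <- function(potential, n_trials = 10,
                                  schedule = smd_schedule(), friction = 20,
                                  temperature = 310, dt = 0.05,
                                  seed = NULL, record_stride = 1L) {
  with_seed(seed, {
    lapply(seq_len(n_trials), function(i) {
      simulate_smd_1d(potential, schedule = schedule, friction = friction,
                      temperature = temperature, dt = dt, trial_id = i,
                      seed = NULL, record_stride = record_stride)
    })
  })
}

#' Default synthetic FTIR band model
#'
#' Gaussian bands at the positions observed in the Na+-induced difference
#' spectra. Na+-selective amide/carboxylate bands share one Hill response
#' (Kd 3.5 mM, n 0.9); the Thr C-O bands at 1115/1086/1061 cm-1 share the
#' second (Kd 6.5 mM, n 0.7); non-selective bands (any cation) sit away from
#' the fitted pairs. A `mutant` model zeroes the selective amplitudes, which
#' makes the Na-K double difference essentially flat.
#'
#' @param noise_sd per-point absorbance noise sd.
#' @param drift_sd scale of the random per-spectrum linear baseline drift.
#' @param width Gaussian band sd, cm-1.
#' @param mutant if `TRUE`, selective band amplitudes are zero.
#' @return object of class `ftir_model` (band table plus noise/drift spec).
#' @export
default_ftir_model <- function(noise_sd = 0.005, drift_sd = 0.01,
                               width = 6, mutant = FALSE) {
  bands <- rbind(
    data.frame(center = c(1662, 1648, 1631, 1545, 1525, 1554, 1537,
                          1425, 1406, 1417),
               amplitude = c(1.0, -1.2, 0.6, 0.4, 0.3, -0.4, -0.3,
                             0.3, 0.3, -0.4),
               response = "hill_amide", stringsAsFactors = FALSE),
    data.frame(center = c(1115, 1086, 1061),
               amplitude = c(0.5, -0.3, -0.4),
               response = "hill_thr", stringsAsFactors = FALSE),
    data.frame(center = c(1700, 1580),
               amplitude = c(-0.3, 0.2),
               response = "nonselective", stringsAsFactors = FALSE)
  )
  if (mutant) {
    bands$amplitude[bands$response != "nonselective"] <- 0
  }
  structure(list(
    bands = bands, width = width,
    hill = list(hill_amide = list(kd = 3.5, n = 0.9),
                hill_thr = list(kd = 6.5, n = 0.7),
                nonselective = list(kd = 8, n = 1.0)),
    noise_sd = noise_sd, drift_sd = drift_sd, mutant = mutant
  ), class = "ftir_model")
}

band_response <- function(model, response, conc, cation) {
  if (response == "nonselective") {
    p <- model$hill$nonselective
    hill_model(conc, 1, p$kd, p$n)
  } else if (cation == "Na") {
    p <- model$hill[[response]]
    hill_model(conc, 1, p$kd, p$n)
  } else {
    0
  }
}

#' Generate a synthetic FTIR spectrum set
#'
#' For each cation and each concentration (plus the 0 mM reference) the
#' absolute spectrum is the signed Gaussian band sum with Hill-responsive
#' amplitudes, plus a random linear baseline drift and white noise.
#'
#' @param model a [default_ftir_model()].
#' @param concentrations mM; default is the measured NaCl series
#'   0.5, 2, 10, 20, 50, 100.
#' @param cations condition labels; non-Na cations drive only the
#'   non-selective bands.
#' @param grid wavenumber grid.
#' @param seed RNG seed.
#' @return list with `spectra` (named `<cation>_<conc>`; includes
#'   `<cation>_0`) and `truth` (the model).
#' @export
generate_ftir_dataset <- function(model = default_ftir_model(),
                                  concentrations = c(0.5, 2, 10, 20, 50, 100),
                                  cations = c("Na", "K"),
                                  grid = ftir_grid(), seed = NULL) {
  stopifnot(all(concentrations > 0))
  spectra <- list()
  with_seed(seed, {
    for (cat_ in cations) {
      for (conc in c(0, concentrations)) {
        ab <- numeric(length(grid))
        for (b in seq_len(nrow(model$bands))) {
          amp <- model$bands$amplitude[b] *
            band_response(model, model$bands$response[b], conc, cat_)
          if (amp != 0) {
            ab <- ab + amp *
              exp(-(grid - model$bands$center[b])^2 / (2 * model$width^2))
          }
        }
        if (model$drift_sd > 0) {
          x <- (grid - mean(grid)) / (max(grid) - min(grid))
          ab <- ab + stats::rnorm(1, 0, model$drift_sd) +
            stats::rnorm(1, 0, model$drift_sd) * x
        }
        if (model$noise_sd > 0) {
          ab <- ab + stats::rnorm(length(grid), 0, model$noise_sd)
        }
        spectra[[paste0(cat_, "_", conc)]] <-
          ftir_spectrum(grid, ab, condition = list(cation = cat_,
                                                   conc_mM = conc,
                                                   solvent = "H2O"))
      }
    }
  })
  list(spectra = spectra, truth = model)
}

#' Band-pair binding curve from a synthetic (or measured) spectrum set
#'
#' Builds the `C minus 0` difference spectrum for each concentration,
#' optionally subtracts a linear baseline, and extracts the peak-minus-trough
#' intensity of the band pair.
#'
#' @param spectra named list as produced by [generate_ftir_dataset()].
#' @param pair `c(peak, trough)` wavenumbers.
#' @param cation condition to trace.
#' @param baseline passed to [subtract_baseline()] (`"none"` for clean
#'   synthetic data).
#' @return data.frame (`conc_mM`, `intensity`), concentration ascending.
#' @export
ftir_binding_curve <- function(spectra, pair, cation = "Na",
                               baseline = c("none", "linear")) {
  baseline <- match.arg(baseline)
  names_all <- names(spectra)
  prefix <- paste0(cation, "_")
  concs <- sort(as.numeric(sub(prefix, "", names_all[startsWith(names_all, prefix)])))
  concs <- concs[concs > 0]
  if (length(concs) == 0) stop("no spectra for cation ", cation)
  off <- spectra[[paste0(cation, "_0")]]
  if (is.null(off)) stop("missing 0 mM reference for cation ", cation)
  intensity <- vapply(concs, function(cc) {
    d <- difference_spectrum(spectra[[paste0(cation, "_", cc)]], off)
    if (baseline == "linear") d <- subtract_baseline(d, "linear")
    band_intensity(d, pair)
  }, numeric(1))
  data.frame(conc_mM = concs, intensity = intensity)
}

# -- ideal-geometry peptide builder (NeRF internal-to-Cartesian) ------------

place_atom <- function(a, b, c_, bond, angle_deg, torsion_deg) {
  theta <- angle_deg * pi / 180
  chi <- torsion_deg * pi / 180
  bc <- c_ - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(theta),
          bond * sin(theta) * cos(chi),
          bond * sin(theta) * sin(chi))
  c_ + d2[1] * bc + d2[2] * m2 + d2[3] * n
}

#' Build a poly-alanine-like backbone with prescribed dihedrals
#'
#' Generates N/CA/C backbone coordinates with ideal bond lengths and angles
#' and the requested phi/psi at every residue (omega fixed at 180). An ideal
#' alpha helix is `phi = -57, psi = -47`; a fully extended chain is
#' `phi = psi = 180`.
#'
#' @param n_res residue count.
#' @param phi,psi backbone dihedrals, degrees (recycled).
#' @param chain chain id.
#' @param resname residue name for all residues.
#' @return single-frame [trajectory()].
#' @export
build_peptide <- function(n_res, phi = -57, psi = -47, chain = "A",
                          resname = "ALA") {
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7
  coords <- matrix(NA_real_, nrow = n_res * 3, ncol = 3)
  # seed the first residue
  coords[1, ] <- c(0, 0, 0)                        # N1
  coords[2, ] <- c(b_nca, 0, 0)                    # CA1
  th <- a_ncac * pi / 180
  coords[3, ] <- coords[2, ] + b_cac * c(-cos(th), sin(th), 0)  # C1
  for (i in seq_len(n_res)) {
    nN <- (i - 1) * 3 + 1; nCA <- nN + 1; nC <- nN + 2
    if (i > 1) {
      pN <- (i - 2) * 3 + 1; pCA <- pN + 1; pC <- pN + 2
      coords[nN, ] <- place_atom(coords[pN, ], coords[pCA, ], coords[pC, ],
                                 b_cn, a_cacn, psi[i - 1])
      coords[nCA, ] <- place_atom(coords[pCA, ], coords[pC, ], coords[nN, ],
                                  b_nca, a_cnca, 180)
      coords[nC, ] <- place_atom(coords[pC, ], coords[nN, ], coords[nCA, ],
                                 b_cac, a_ncac, phi[i])
    }
  }
  topo <- data.frame(
    serial = seq_len(n_res * 3),
    name = rep(c("N", "CA", "C"), n_res),
    resname = resname,
    resnum = rep(seq_len(n_res), each = 3),
    chain = chain,
    element = rep(c("N", "C", "C"), n_res),
    record = "ATOM", stringsAsFactors = FALSE
  )
  trajectory(topo, array(coords, dim = c(n_res * 3, 3, 1)))
}
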