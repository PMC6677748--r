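# Structure and trajectory I/O: fixed-column multi-model PDB, atom role
# classification, atom/frame selection, tabular output.

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP", "MSE"
)

# Monoatomic species whose PDB atom name is the element symbol; used to
# resolve two-letter elements when the element column is absent.
TWO_LETTER_IONS <- c("NA", "CL", "MG", "FE", "ZN", "MN", "BR", "CS", "RB",
                     "LI", "CA", "K", "SOD", "CLA", "POT")

#' Construct a trajectory object
#'
#' A trajectory couples a fixed topology (one row per atom) with an ordered
#' stack of coordinate frames. Coordinates are in Angstrom; the membrane
#' normal is the z axis with the periplasmic side at positive z unless
#' `z_flip` is set.
#'
#' @param topology data.frame with columns `serial`, `name`, `resname`,
#'   `resnum`, `chain`, `element` (one row per atom).
#' @param coords numeric array of dimension `c(n_atoms, 3, n_frames)`, Angstrom.
#' @param times numeric vector of frame times in ns, strictly increasing.
#'   Defaults to `0, 1, 2, ...` (one frame per ns).
#' @param z_flip logical; if `TRUE` the stored +z direction points toward the
#'   cytoplasm and z values are negated by accessors that care about sign.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, times = NULL, z_flip = FALSE) {
  stopifnot(is.data.frame(topology))
  req <- c("serial", "name", "resname", "resnum", "chain", "element")
  missing_cols <- setdiff(req, names(topology))
  if (length(missing_cols) > 0) {
    stop("topology lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (length(dim(coords)) == 2) {
    coords <- array(coords, dim = c(dim(coords), 1L))
  }
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[1] != nrow(topology)) {
    stop("coordinate rows (", dim(coords)[1], ") do not match topology atoms (",
         nrow(topology), ")")
  }
  n_frames <- dim(coords)[3]
  if (n_frames < 1) stop("a trajectory needs at least one frame")
  if (is.null(times)) times <- seq_len(n_frames) - 1
  if (length(times) != n_frames) stop("times length must equal frame count")
  if (n_frames > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (any(times < 0)) stop("frame times must be non-negative")
  if (anyDuplicated(topology$serial)) {
    stop("atom serials must be unique within a model")
  }
  if (any(!nzchar(topology$element))) stop("element must be non-empty")
  structure(
    list(topology = topology, coords = coords, times = as.numeric(times),
         z_flip = isTRUE(z_flip)),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d atoms, %d frames, t = %g..%g ns%s>\n",
              n_atoms(x), n_frames(x), x$times[1], x$times[n_frames(x)],
              if (x$z_flip) ", z flipped" else ""))
  invisible(x)
}

#' Number of atoms / frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer count.
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' @rdname n_atoms
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one frame
#'
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @param apply_flip if `TRUE` and the trajectory carries `z_flip`, negate z.
#' @return n_atoms x 3 matrix, Angstrom.
#' @export
frame_coords <- function(traj, i, apply_flip = FALSE) {
  stopifnot(i >= 1, i <= n_frames(traj))
  m <- traj$coords[, , i, drop = FALSE]
  dim(m) <- dim(traj$coords)[1:2]
  colnames(m) <- c("x", "y", "z")
  if (apply_flip && traj$z_flip) m[, 3] <- -m[, 3]
  m
}

parse_pdb_atom_lines <- function(lines, line_numbers) {
  num <- function(s) suppressWarnings(as.numeric(s))
  x <- num(substr(lines, 31, 38))
  y <- num(substr(lines, 39, 46))
  z <- num(substr(lines, 47, 54))
  serial <- num(substr(lines, 7, 11))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z) |
                 !is.finite(serial))
  if (length(bad) > 0) {
    stop("unparseable fixed-width PDB record at line ", line_numbers[bad[1]],
         ": ", trimws(lines[bad[1]]))
  }
  list(
    record = trimws(substr(lines, 1, 6)),
    serial = as.integer(serial),
    name = trimws(substr(lines, 13, 16)),
    # 18-21: 3-char standard names plus CHARMM-style 4-char lipid names
    resname = trimws(substr(lines, 18, 21)),
    chain = substr(lines, 22, 22),
    resnum = as.integer(num(substr(lines, 23, 26))),
    x = x, y = y, z = z,
    element = trimws(substr(lines, 77, 78))
  )
}

#' Infer element symbols from PDB atom names
#'
#' Used when the PDB element column (77-78) is blank. Leading digits are
#' stripped (e.g. `1HG1` is hydrogen); names matching a fixed monoatomic-ion
#' lookup where the residue name equals the atom name resolve to two-letter
#' elements; otherwise the first alphabetic character is the element.
#'
#' @param name atom name(s).
#' @param resname residue name(s), same length.
#' @return character vector of element symbols.
#' @export
infer_element <- function(name, resname) {
  stripped <- toupper(gsub("^[0-9]+", "", name))
  out <- substr(gsub("[^A-Z]", "", stripped), 1, 1)
  # monoatomic ions: atom name == residue name and in the fixed lookup
  ion_like <- stripped %in% TWO_LETTER_IONS & toupper(resname) == stripped
  if (any(ion_like)) {
    canon <- c(SOD = "NA", CLA = "CL", POT = "K")
    sym <- stripped[ion_like]
    hit <- sym %in% names(canon)
    sym[hit] <- canon[sym[hit]]
    out[ion_like] <- sym
  }
  out[!nzchar(out)] <- "X"
  out
}

#' Read a (multi-model) PDB file into a trajectory
#'
#' One frame per `MODEL` record; a file without `MODEL` records yields a
#' single frame. Topology (names, residues, chains, serials, elements) is
#' taken from the first model. Both `ATOM` and `HETATM` records are read,
#' since waters and ions are usually deposited as `HETATM`.
#'
#' @param path PDB file path.
#' @param times optional frame times (ns); default `0, 1, 2, ...`.
#' @param z_flip see [trajectory()].
#' @return a [trajectory()].
#' @export
read_pdb <- function(path, times = NULL, z_flip = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") |
    trimws(rec) %in% c("ATOM", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  if (any(is_model)) {
    model_id <- cumsum(is_model)
    model_no <- suppressWarnings(as.integer(substr(lines[is_model], 11, 14)))
    if (any(is.na(model_no))) model_no <- seq_len(sum(is_model))
    keep <- is_atom & model_id > 0
    groups <- split(which(keep), model_id[keep])
  } else {
    groups <- list(`1` = which(is_atom))
    model_no <- 1L
  }

  first_idx <- groups[[1]]
  first <- parse_pdb_atom_lines(lines[first_idx], first_idx)
  n <- length(first_idx)
  element <- first$element
  blank <- !nzchar(element)
  if (any(blank)) {
    element[blank] <- infer_element(first$name[blank], first$resname[blank])
  }
  topo <- data.frame(
    serial = first$serial, name = first$name, resname = first$resname,
    resnum = first$resnum, chain = first$chain, element = element,
    record = first$record, stringsAsFactors = FALSE
  )

  coords <- array(NA_real_, dim = c(n, 3, length(groups)))
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    if (length(idx) != n) {
      stop(sprintf(
        "atom-count mismatch in MODEL %d: %d atoms, expected %d",
        model_no[k], length(idx), n))
    }
    p <- if (k == 1) first else parse_pdb_atom_lines(lines[idx], idx)
    coords[, , k] <- cbind(p$x, p$y, p$z)
  }
  trajectory(topo, coords, times = times, z_flip = z_flip)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Fixed-column PDB with `MODEL`/`ENDMDL` per frame and three-decimal
#' coordinates (round-trips through [read_pdb()] to 1e-3 Angstrom).
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(traj, path) {
  topo <- traj$topology
  record <- if ("record" %in% names(topo)) topo$record else
    rep("ATOM", nrow(topo))
  record <- ifelse(record == "HETATM", "HETATM", "ATOM  ")
  # PDB name column convention: 1-3 char names start in column 14
  name_fmt <- ifelse(nchar(topo$name) >= 4, sprintf("%-4s", topo$name),
                     sprintf(" %-3s", topo$name))
  con <- file(path, "w")
  on.exit(close(con))
  multi <- n_frames(traj) > 1
  for (k in seq_len(n_frames(traj))) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    m <- frame_coords(traj, k)
    # cols: 13-16 name, 17 altLoc, 18-21 resname (4 chars for lipids),
    # 22 chain, 23-26 resnum, 31-54 xyz, 77-78 element
    writeLines(sprintf(
      "%s%5d %s %-4s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      record, topo$serial %% 100000L, name_fmt, topo$resname, topo$chain,
      topo$resnum %% 10000L, m[, 1], m[, 2], m[, 3], 1, 0,
      sprintf("%2s", topo$element)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Classify atoms by role and polarity
#'
#' Assigns each atom a role (`protein`, `lipid`, `water`, `ion`, `other`),
#' a polar flag (element O, N or S and not hydrogen) and a hydrogen flag.
#' Polar O/N/S atoms of protein and water are what the coordination-number
#' statistic counts.
#'
#' @param traj a [trajectory()].
#' @param lipid_names,ion_names,water_names residue-name sets (disjoint).
#' @return data.frame with columns `role`, `is_polar`, `is_hydrogen`,
#'   one row per atom.
#' @export
classify_atoms <- function(traj,
                           lipid_names = c("POPE", "POPG"),
                           ion_names = c("NA", "SOD", "CL", "CLA", "K",
                                         "POT"),
                           water_names = c("HOH", "TIP3", "WAT", "SPC")) {
  sets <- list(lipid_names, ion_names, water_names)
  pooled <- unlist(sets)
  if (anyDuplicated(pooled)) stop("lipid/ion/water name sets must be disjoint")
  topo <- traj$topology
  role <- rep("other", nrow(topo))
  role[topo$resname %in% STANDARD_AA] <- "protein"
  role[topo$resname %in% lipid_names] <- "lipid"
  role[topo$resname %in% water_names] <- "water"
  role[topo$resname %in% ion_names] <- "ion"
  is_hydrogen <- topo$element %in% c("H", "D")
  is_polar <- topo$element %in% c("O", "N", "S") & !is_hydrogen
  data.frame(role = role, is_polar = is_polar, is_hydrogen = is_hydrogen,
             stringsAsFactors = FALSE)
}

#' Select atom indices by topology fields
#'
#' Conjunction of membership tests over topology columns (`serial`, `name`,
#' `resname`, `resnum`, `chain`, `element`). Returns 0 or more indices,
#' sorted ascending; referencing an unknown field is an error.
#'
#' @param traj a [trajectory()].
#' @param ... named filters, e.g. `chain = "B", resnum = 24,
#'   name = c("OD1","OD2")`. Vector values mean set membership.
#' @return integer vector of atom indices (1-based), ascending.
#' @export
select_atoms <- function(traj, ...) {
  query <- list(...)
  if (length(query) == 0) return(seq_len(n_atoms(traj)))
  if (is.null(names(query)) || any(!nzchar(names(query)))) {
    stop("all selection terms must be named")
  }
  topo <- traj$topology
  unknown <- setdiff(names(query), names(topo))
  if (length(unknown) > 0) {
    stop("unknown selection field(s): ", paste(unknown, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(topo))
  for (field in names(query)) {
    keep <- keep & (topo[[field]] %in% query[[field]])
  }
  which(keep)
}

#' Subset trajectory frames by start time and stride
#'
#' Keeps frames with `time >= start_time` lying on the stride grid anchored
#' at `start_time`. With per-ns frames, `start_time = 25` on a 400-frame
#' (0..399 ns) trajectory keeps the last 375 frames.
#'
#' @param traj a [trajectory()].
#' @param start_time first time (ns) to keep.
#' @param stride time step (ns) between kept frames; must be > 0.
#' @return a new [trajectory()] view.
#' @export
select_frames <- function(traj, start_time = 0, stride = 1) {
  if (stride <= 0) stop("stride must be > 0")
  tmax <- traj$times[n_frames(traj)]
  if (start_time < 0 || start_time > tmax) {
    stop("start_time must lie within [0, ", tmax, "]")
  }
  rel <- (traj$times - start_time) / stride
  keep <- traj$times >= start_time - 1e-9 & abs(rel - round(rel)) < 1e-6
  if (!any(keep)) stop("frame selection is empty; analysis over zero frames is undefined")
  trajectory(traj$topology, traj$coords[, , keep, drop = FALSE],
             times = traj$times[keep], z_flip = traj$z_flip)
}

#' Write a data.frame as a TSV analysis table
#'
#' UTF-8, header row, tab-delimited, no quoting or row names; the common
#' output format of every analysis stage.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a list as a JSON summary
#' @param x list of scalars/vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
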