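# Steered-MD force-profile analysis: force-log parsing, trial pooling,
# moving-average smoothing, peak statistics, mutant/WT peak ratios, and
# coordination-vs-position profiles.

#' Construct a constant-velocity pulling schedule
#'
#' Defaults are the production protocol: spring constant 6.16 kcal/mol/A^2
#' along z, pulling velocity 0.05 A/ps, lateral x/y restraint 1 kcal/mol/A^2,
#' 50 A travelled in 1000 ps. `pull_distance` must equal
#' `velocity * duration`.
#'
#' @param spring_k pulling spring constant, kcal/mol/A^2.
#' @param velocity pulling velocity, A/ps.
#' @param lateral_k lateral restraint constant, kcal/mol/A^2 (metadata in the
#'   1D surrogate).
#' @param duration pull duration, ps.
#' @param pull_distance total anchor travel, A.
#' @return object of class `smd_schedule`.
#' @export
smd_schedule <- function(spring_k = 6.16, velocity = 0.05, lateral_k = 1.0,
                         duration = 1000, pull_distance = velocity * duration) {
  vals <- c(spring_k, velocity, lateral_k, duration, pull_distance)
  if (any(vals <= 0)) stop("all schedule parameters must be positive")
  if (abs(pull_distance - velocity * duration) > 1e-9 * pull_distance) {
    stop("pull_distance must equal velocity * duration")
  }
  structure(list(spring_k = spring_k, velocity = velocity,
                 lateral_k = lateral_k, duration = duration,
                 pull_distance = pull_distance),
            class = "smd_schedule")
}

#' Construct a force log
#'
#' @param trial_id integer trial identifier.
#' @param time_ps,z_A,force equal-length numeric vectors: time (ps), ion z
#'   (A), applied spring force (kcal/mol/A). Times must be strictly
#'   increasing and at least two records are required.
#' @return object of class `force_log`.
#' @export
force_log <- function(trial_id, time_ps, z_A, force) {
  n <- length(time_ps)
  stopifnot(length(z_A) == n, length(force) == n)
  if (n < 2) stop("a force log needs at least 2 records")
  bad <- which(diff(time_ps) <= 0)
  if (length(bad) > 0) {
    stop("non-monotone time in force log at record ", bad[1] + 1)
  }
  structure(list(trial_id = as.integer(trial_id),
                 records = data.frame(time_ps = time_ps, z_A = z_A,
                                      force = force)),
            class = "force_log")
}

#' Parse a plain-text SMD force log
#'
#' Whitespace- or tab-separated columns `time_ps`, `z_A`,
#' `force_kcal_mol_A`; `#` lines are comments. The trial id is taken from a
#' `# trial: N` comment, else from digits in the file name, else 1.
#'
#' @param path file path.
#' @param trial_id override the trial id.
#' @return a [force_log()].
#' @export
parse_force_log <- function(path, trial_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (is.null(trial_id)) {
    tl <- grep("^\\s*#\\s*trial\\s*:", lines, value = TRUE)
    if (length(tl) > 0) {
      trial_id <- as.integer(sub(".*:\\s*", "", tl[1]))
    } else {
      digits <- regmatches(basename(path),
                           regexpr("[0-9]+", basename(path)))
      trial_id <- if (length(digits) > 0) as.integer(digits) else 1L
    }
  }
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  if (length(body) == 0) stop("no data records in ", path)
  has_header <- grepl("[A-Za-z]", body[1])
  df <- utils::read.table(text = body, header = has_header)
  if (ncol(df) < 3) stop("expected 3 columns (time_ps, z_A, force) in ", path)
  force_log(trial_id, df[[1]], df[[2]], df[[3]])
}

#' Write a force log in the plain-text exchange format
#' @param log a [force_log()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_force_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# trial: %d", log$trial_id), con)
  writeLines("time_ps\tz_A\tforce_kcal_mol_A", con)
  r <- log$records
  writeLines(sprintf("%.6g\t%.6g\t%.6g", r$time_ps, r$z_A, r$force), con)
  invisible(path)
}

#' Pool SMD trials into one z-sorted record sequence
#'
#' Concatenates all records of all trials and sorts by ion z ascending with
#' a stable `(trial_id, time)` tie-break; this is the pooled sequence the
#' smoothed profile is computed on.
#'
#' @param logs list of [force_log()] objects (at least one).
#' @param value_col column to carry as the profile value (default `force`).
#' @return data.frame (`z`, `value`, `trial_id`, `time_ps`), z ascending.
#' @export
aggregate_trials <- function(logs, value_col = "force") {
  if (inherits(logs, "force_log")) logs <- list(logs)
  if (length(logs) == 0) stop("need at least one force log")
  pieces <- lapply(logs, function(l) {
    data.frame(z = l$records$z_A, value = l$records[[value_col]],
               trial_id = l$trial_id, time_ps = l$records$time_ps)
  })
  pooled <- do.call(rbind, pieces)
  pooled[order(pooled$z, pooled$trial_id, pooled$time_ps), , drop = FALSE]
}

#' Centered moving average with edge truncation
#'
#' `window` is the total centered window width (the point itself plus its
#' surrounding points); an even window is widened by one to stay symmetric.
#' Near the edges the mean is taken over the available in-window points, so
#' the output has the input's length and stays within its range.
#'
#' @param values numeric vector.
#' @param window total window width in points (>= 1).
#' @return numeric vector, same length as `values`.
#' @export
moving_average <- function(values, window) {
  if (window < 1) stop("window must be >= 1")
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  n <- length(values)
  if (n == 0) return(numeric(0))
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, values))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

new_profile <- function(z, raw, window, n_trials, kind) {
  structure(list(z = z, value = moving_average(raw, window), raw = raw,
                 smoothing_window = as.integer(window) +
                   (as.integer(window) %% 2L == 0L),
                 source_trials = n_trials, kind = kind),
            class = "smd_aggregated_profile")
}

#' Pooled, smoothed profile over SMD trials
#'
#' Pools all trials with [aggregate_trials()] and smooths the z-sorted value
#' sequence with a centered [moving_average()]. Default windows are 501
#' points for force and 101 for coordination (a point averaged with its ~500
#' or ~100 surrounding points).
#'
#' @param logs list of [force_log()] objects.
#' @param kind `"force"` or `"coordination"`.
#' @param window centered window width; defaults by `kind`.
#' @return object of class `smd_aggregated_profile`: `z`, smoothed `value`,
#'   `raw`, `smoothing_window`, `source_trials`, `kind`.
#' @export
smd_profile <- function(logs, kind = c("force", "coordination"),
                        window = NULL) {
  kind <- match.arg(kind)
  if (is.null(window)) window <- if (kind == "force") 501L else 101L
  if (inherits(logs, "force_log")) logs <- list(logs)
  pooled <- aggregate_trials(logs)
  new_profile(pooled$z, pooled$value, window, length(logs), kind)
}

#' @export
print.smd_aggregated_profile <- function(x, ...) {
  cat(sprintf(
    "<smd profile: %s, %d points from %d trial(s), window %d, max %.3g at z=%.2f>\n",
    x$kind, length(x$z), x$source_trials, x$smoothing_window,
    max(x$value), x$z[which.max(x$value)]))
  invisible(x)
}

#' Peak statistics of a smoothed profile
#'
#' Reports the global maximum of the smoothed curve and all local maxima
#' whose height exceeds `min + prominence_frac * range`.
#'
#' @param profile an [smd_profile()] result (>= 3 points).
#' @param prominence_frac height threshold for secondary maxima as a
#'   fraction of the profile range.
#' @return list (`max_value`, `z_at_max`, `peaks` data.frame).
#' @export
peak_stats <- function(profile, prominence_frac = 0.05) {
  v <- profile$value
  z <- profile$z
  if (length(v) < 3) stop("need at least 3 profile points")
  imax <- which.max(v)
  dv <- diff(v)
  s <- sign(dv)
  s[s == 0] <- 1  # plateaus count with the rising side
  local <- which(diff(s) < 0) + 1L
  local <- union(local, imax)
  thr <- min(v) + prominence_frac * (max(v) - min(v))
  local <- sort(local[v[local] >= thr])
  list(max_value = v[imax], z_at_max = z[imax],
       peaks = data.frame(z = z[local], value = v[local]))
}

#' Ratio of mutant to wild-type maximal force
#'
#' @param profile_mut,profile_wt profiles of the same `kind`.
#' @return `max(mut) / max(wt)`; the wild-type maximum must be positive.
#' @export
peak_ratio <- function(profile_mut, profile_wt) {
  if (length(profile_mut$value) == 0 || length(profile_wt$value) == 0) {
    stop("profiles must be non-empty")
  }
  if (!identical(profile_mut$kind, profile_wt$kind)) {
    stop("profiles must be of the same kind")
  }
  mwt <- max(profile_wt$value)
  if (mwt <= 0) stop("wild-type profile maximum must be positive")
  max(profile_mut$value) / mwt
}

#' Na+ coordination number versus ion z over a trajectory
#'
#' Computes the per-frame coordination number of the ion with
#' [coordination_number()] paired with the ion's z coordinate, sorts by z
#' and smooths (default 101-point window). `species` restricts the count to
#' protein-only or water-only ligands; the two restricted counts sum to the
#' total in every frame.
#'
#' @param traj a [trajectory()].
#' @param ion_index atom index of the ion.
#' @param roles result of [classify_atoms()]; computed if `NULL`.
#' @param cutoff coordination cutoff, Angstrom.
#' @param window smoothing window (points).
#' @param species `"both"`, `"protein"` or `"water"`.
#' @return an `smd_aggregated_profile` of kind `"coordination"`.
#' @export
coordination_vs_z <- function(traj, ion_index, roles = NULL, cutoff = 2.5,
                              window = 101L,
                              species = c("both", "protein", "water")) {
  species <- match.arg(species)
  if (is.null(roles)) roles <- classify_atoms(traj)
  nf <- n_frames(traj)
  z <- numeric(nf)
  cn <- numeric(nf)
  for (k in seq_len(nf)) {
    m <- frame_coords(traj, k)
    z[k] <- m[ion_index, 3]
    cn[k] <- coordination_number(m, ion_index, roles, cutoff = cutoff,
                                 species = species)
  }
  o <- order(z)
  new_profile(z[o], cn[o], window, 1L, "coordination")
}

#' Write a profile as a TSV table
#' @param profile an `smd_aggregated_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  write_tsv_table(
    data.frame(z_A = profile$z, value = profile$value, raw = profile$raw),
    path)
}
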