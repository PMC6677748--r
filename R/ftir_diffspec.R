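# ATR-FTIR difference-spectroscopy chain: difference and double-difference
# spectra, cycle averaging, baseline-drift subtraction, band-pair
# intensities, Hill binding fits, and carboxylate nu_as - nu_s
# coordination-mode classification.

#' Default FTIR wavenumber grid
#'
#' Descending uniform grid, 1800 to 1000 cm-1 at the spectrometer's 2 cm-1
#' resolution.
#'
#' @param from,to,by grid limits and step, cm-1.
#' @return numeric vector, strictly descending.
#' @export
ftir_grid <- function(from = 1800, to = 1000, by = 2) {
  seq(from, to, by = -abs(by))
}

#' Construct an absorbance spectrum
#'
#' @param wavenumbers strictly descending uniform grid, cm-1.
#' @param absorbance finite numeric vector, same length.
#' @param condition metadata list (e.g. `cation`, `conc_mM`, `solvent`).
#' @return object of class `ftir_spectrum`.
#' @export
ftir_spectrum <- function(wavenumbers, absorbance, condition = list()) {
  n <- length(wavenumbers)
  stopifnot(length(absorbance) == n, n >= 2)
  d <- diff(wavenumbers)
  if (any(d >= 0)) stop("wavenumber grid must be strictly descending")
  if (max(abs(d - d[1])) > 1e-6 * abs(d[1])) {
    stop("wavenumber grid must be uniform")
  }
  if (any(!is.finite(absorbance))) stop("absorbance must be finite")
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 condition = condition),
            class = "ftir_spectrum")
}

check_same_grid <- function(a, b) {
  if (length(a$wavenumbers) != length(b$wavenumbers) ||
      max(abs(a$wavenumbers - b$wavenumbers)) > 1e-9) {
    stop("wavenumber grids do not match")
  }
  invisible(TRUE)
}

new_diffspec <- function(wavenumbers, values, on_condition, off_condition,
                         n_cycles = 1L) {
  structure(list(wavenumbers = wavenumbers, absorbance = values,
                 on_condition = on_condition, off_condition = off_condition,
                 n_cycles = as.integer(n_cycles)),
            class = c("ftir_difference", "ftir_spectrum"))
}

#' Ligand-on minus ligand-off difference spectrum
#'
#' Pointwise `on - off` (e.g. "20 mM minus 0 mM" NaCl) on a shared grid.
#'
#' @param on,off [ftir_spectrum()] objects with identical grids.
#' @return object of class `ftir_difference`.
#' @export
difference_spectrum <- function(on, off) {
  check_same_grid(on, off)
  new_diffspec(on$wavenumbers, on$absorbance - off$absorbance,
               on$condition, off$condition)
}

#' Average repeated binding/unbinding difference cycles
#'
#' Pointwise mean of forward/backward measurement cycles (typically 6-30);
#' noise amplitude shrinks roughly as 1/sqrt(cycles).
#'
#' @param diffs non-empty list of `ftir_difference` objects, same grid.
#' @return `ftir_difference` with `n_cycles` recorded.
#' @export
average_cycles <- function(diffs) {
  if (inherits(diffs, "ftir_difference")) diffs <- list(diffs)
  if (length(diffs) == 0) stop("need at least one cycle")
  for (d in diffs[-1]) check_same_grid(diffs[[1]], d)
  vals <- rowMeans(vapply(diffs, function(d) d$absorbance,
                          numeric(length(diffs[[1]]$absorbance))))
  new_diffspec(diffs[[1]]$wavenumbers, vals, diffs[[1]]$on_condition,
               diffs[[1]]$off_condition, n_cycles = length(diffs))
}

#' Subtract a slowly varying baseline drift
#'
#' Fits the chosen baseline model by least squares over band-free anchor
#' windows only (default 1780-1750 and 1010-1000 cm-1) and subtracts it from
#' the whole spectrum. Drift arises from protein swelling/shrinkage and free
#' salt/buffer ions.
#'
#' @param diff an `ftir_difference` (or `ftir_spectrum`).
#' @param model `"none"`, `"linear"`, or `"polynomial"`.
#' @param degree polynomial degree when `model = "polynomial"`.
#' @param anchor_regions list of `c(high, low)` wavenumber windows assumed
#'   band-free.
#' @return spectrum of the same class with the baseline removed.
#' @export
subtract_baseline <- function(diff, model = c("linear", "none", "polynomial"),
                              degree = 2,
                              anchor_regions = list(c(1780, 1750),
                                                    c(1010, 1000))) {
  model <- match.arg(model)
  if (model == "none") return(diff)
  wn <- diff$wavenumbers
  in_anchor <- rep(FALSE, length(wn))
  for (w in anchor_regions) {
    hi <- max(w); lo <- min(w)
    if (hi > max(wn) + 1e-9 || lo < min(wn) - 1e-9) {
      stop("anchor region [", lo, ", ", hi, "] outside the grid")
    }
    in_anchor <- in_anchor | (wn >= lo & wn <= hi)
  }
  deg <- if (model == "linear") 1L else as.integer(degree)
  if (sum(in_anchor) <= deg) {
    stop("polynomial order must be below the anchor point count")
  }
  x <- (wn - mean(wn)) / (max(wn) - min(wn))
  basis <- outer(x, 0:deg, `^`)
  fit <- stats::lm.fit(basis[in_anchor, , drop = FALSE],
                       diff$absorbance[in_anchor])
  baseline <- as.numeric(basis %*% fit$coefficients)
  out <- diff
  out$absorbance <- diff$absorbance - baseline
  out
}

#' Cation double difference (Na+ minus K+)
#'
#' Pointwise subtraction of the K+ difference spectrum from the Na+
#' difference spectrum; non-selective cation responses cancel, isolating the
#' Na+-selective structural changes. Mutants lacking the selective site give
#' essentially flat lines.
#'
#' @param na_diff,k_diff `ftir_difference` objects on one grid.
#' @return `ftir_difference`.
#' @export
double_difference <- function(na_diff, k_diff) {
  check_same_grid(na_diff, k_diff)
  new_diffspec(na_diff$wavenumbers, na_diff$absorbance - k_diff$absorbance,
               list(na = na_diff$on_condition, k = k_diff$on_condition),
               list(na = na_diff$off_condition, k = k_diff$off_condition),
               n_cycles = min(na_diff$n_cycles, k_diff$n_cycles))
}

#' Peak-minus-trough intensity of a band pair
#'
#' Value at the positive-lobe wavenumber minus value at the negative-lobe
#' wavenumber, each snapped to the nearest gridpoint (the convention for the
#' 1662(+)/1648(-) and 1115(+)/1061(-) pairs).
#'
#' @param diff an `ftir_difference`.
#' @param pair numeric `c(peak, trough)` wavenumbers, cm-1.
#' @return numeric intensity.
#' @export
band_intensity <- function(diff, pair) {
  stopifnot(length(pair) == 2)
  wn <- diff$wavenumbers
  step <- abs(wn[2] - wn[1])
  idx <- vapply(pair, function(p) {
    if (p > max(wn) + step / 2 || p < min(wn) - step / 2) {
      stop("wavenumber ", p, " outside the grid")
    }
    which.min(abs(wn - p))
  }, integer(1))
  diff$absorbance[idx[1]] - diff$absorbance[idx[2]]
}

#' Hill model intensity
#'
#' `I(C) = A * C^n / (Kd^n + C^n)`.
#'
#' @param conc concentrations, mM.
#' @param amplitude saturation amplitude `A`.
#' @param kd dissociation constant, mM.
#' @param n Hill coefficient.
#' @return numeric intensities.
#' @export
hill_model <- function(conc, amplitude, kd, n) {
  cn <- conc^n
  amplitude * cn / (kd^n + cn)
}

#' Fit the Hill equation to a binding curve
#'
#' Least-squares fit of `I(C) = A C^n / (Kd^n + C^n)` in log-parameter space
#' (so A, Kd, n stay positive), with a deterministic multistart: the
#' data-driven initialisation (A0 = max intensity, Kd0 = concentration
#' nearest half-max, n0 = 1) plus jittered restarts.
#'
#' @param concentrations distinct non-negative concentrations, mM (>= 3).
#' @param intensities band intensities, same length.
#' @return list (`amplitude`, `kd`, `n_hill`, `residual_rms`, `converged`).
#' @export
fit_hill <- function(concentrations, intensities) {
  stopifnot(length(concentrations) == length(intensities))
  if (length(unique(concentrations)) < 3) {
    stop("need at least 3 distinct concentrations")
  }
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  a0 <- max(intensities)
  if (a0 <= 0) stop("intensities must contain positive values to fit")
  pos <- concentrations > 0
  kd0 <- concentrations[pos][which.min(abs(intensities[pos] - a0 / 2))]
  sse <- function(p) {
    r <- intensities - hill_model(concentrations, exp(p[1]), exp(p[2]),
                                  exp(p[3]))
    sum(r * r)
  }
  starts <- list(c(log(a0), log(kd0), 0),
                 c(log(a0 * 1.5), log(kd0 * 0.4), log(0.7)),
                 c(log(a0 * 0.8), log(kd0 * 2.5), log(1.5)))
  best <- NULL
  for (p0 in starts) {
    fit <- try(stats::optim(p0, sse, method = "BFGS",
                            control = list(maxit = 2000, reltol = 1e-14)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    # polish with Nelder-Mead from the BFGS solution
    fit2 <- stats::optim(fit$par, sse,
                         control = list(maxit = 5000, reltol = 1e-15))
    if (fit2$value < fit$value) fit <- fit2
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("Hill fit failed to converge from all starts")
  kd <- exp(best$par[2])
  n <- exp(best$par[3])
  if (!is.finite(kd) || !is.finite(n)) {
    stop("Hill fit diverged (best-so-far SSE ", best$value, ")")
  }
  list(amplitude = exp(best$par[1]), kd = kd, n_hill = n,
       residual_rms = sqrt(best$value / length(intensities)),
       converged = TRUE)
}

#' Carboxylate nu_as - nu_s separations over candidate assignments
#'
#' All cross pairs of candidate antisymmetric-stretch and symmetric-stretch
#' wavenumbers; pairs with negative separation are rejected.
#'
#' @param nu_as_candidates,nu_s_candidates positive wavenumbers, cm-1.
#' @return data.frame (`nu_as`, `nu_s`, `delta`), `delta >= 0`.
#' @export
nu_separations <- function(nu_as_candidates, nu_s_candidates) {
  if (length(nu_as_candidates) == 0 || length(nu_s_candidates) == 0) {
    stop("candidate sets must be non-empty")
  }
  stopifnot(all(nu_as_candidates > 0), all(nu_s_candidates > 0))
  g <- expand.grid(nu_as = nu_as_candidates, nu_s = nu_s_candidates,
                   KEEP.OUT.ATTRS = FALSE)
  g$delta <- g$nu_as - g$nu_s
  g[g$delta >= 0, , drop = FALSE]
}

#' Classify a metal-carboxylate coordination mode from nu_as - nu_s
#'
#' Small separations indicate a bidentate or pseudobridged mode (the
#' Na+-selective site, 100-139 cm-1); larger separations (>= 150 cm-1, the
#' non-selective sites at 159-164 cm-1) indicate less bidentate character.
#' The default thresholds leave a buffer zone classified as indeterminate.
#'
#' @param delta nu_as - nu_s separation(s), cm-1, >= 0.
#' @param bidentate_max upper bound for the bidentate/pseudobridged call.
#' @param less_bidentate_min lower bound for the less-bidentate call.
#' @return data.frame (`delta`, `call`).
#' @export
classify_coordination <- function(delta, bidentate_max = 140,
                                  less_bidentate_min = 150) {
  if (any(delta < 0)) stop("delta must be >= 0")
  call <- ifelse(delta <= bidentate_max, "bidentate_or_pseudobridged",
                 ifelse(delta >= less_bidentate_min, "less_bidentate",
                        "indeterminate"))
  data.frame(delta = delta, call = call, stringsAsFactors = FALSE)
}
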