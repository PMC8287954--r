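#' Multi-angle light-scattering chromatogram
#'
#' Per-slice light-scattering excess Rayleigh ratios at a set of detector
#' angles together with the concentration trace from the in-line
#' refractometer and the optical constant `K` (which houses the laser
#' wavelength, dn/dc and the solvent refractive index in the usual
#' `K = 4 pi^2 n0^2 (dn/dc)^2 / (NA lambda^4)` combination).
#'
#' @param time per-slice time (s or any monotone coordinate).
#' @param conc concentration trace (g/mL), >= 0.
#' @param rtheta slices x angles matrix of excess Rayleigh ratios.
#' @param angles detector angles (degrees), >= 3 of them.
#' @param K optical constant (mol cm^2 g^-2 scale consistent with `rtheta`).
#' @param wavelength laser wavelength in Angstrom (default 6580, i.e.
#'   658 nm), used only for the Rg estimate.
#' @param n0 solvent refractive index (default 1.331).
#' @param buffer_slices optional indices of buffer-only slices used to
#'   estimate baseline noise for the validity threshold.
#' @return object of class `chromatogram`.
#' @export
chromatogram <- function(time, conc, rtheta, angles, K,
                         wavelength = 6580, n0 = 1.331,
                         buffer_slices = NULL) {
  rtheta <- as.matrix(rtheta)
  stopifnot(length(time) == length(conc),
            nrow(rtheta) == length(time),
            ncol(rtheta) == length(angles))
  if (length(angles) < 3L) stop("need >= 3 detector angles")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  structure(list(time = time, conc = conc, rtheta = rtheta,
                 angles = angles, K = K, wavelength = wavelength, n0 = n0,
                 buffer_slices = buffer_slices),
            class = "chromatogram")
}

#' Read a chromatogram from CSV
#'
#' Expected columns: `time`, `conc`, then one column per detector angle with
#' the angle in the header (e.g. `R_34.8`).
#'
#' @param path CSV file.
#' @param K,wavelength,n0,buffer_slices passed to [chromatogram()].
#' @return a [chromatogram()].
#' @export
read_chromatogram_csv <- function(path, K, wavelength = 6580, n0 = 1.331,
                                  buffer_slices = NULL) {
  tab <- read.csv(path, check.names = FALSE)
  ang_cols <- grep("^R_?", names(tab))
  angles <- as.numeric(sub("^R_?", "", names(tab)[ang_cols]))
  chromatogram(tab$time, tab$conc, as.matrix(tab[, ang_cols]), angles, K,
               wavelength = wavelength, n0 = n0,
               buffer_slices = buffer_slices)
}

# baseline concentration noise (sigma) from annotated buffer slices, or a
# small fraction of the peak when no annotation is available
baseline_sigma <- function(chrom) {
  if (!is.null(chrom$buffer_slices) && length(chrom$buffer_slices) >= 2L)
    return(max(sd(chrom$conc[chrom$buffer_slices]), 1e-12))
  max(max(chrom$conc) * 1e-3, 1e-12)
}

#' Debye-plot molar mass of one chromatographic slice
#'
#' Regresses `K c / R(theta)` on `sin^2(theta / 2)` (the Debye plot); the
#' reciprocal intercept is the weight-average molar mass of the slice and
#' the low-angle slope yields an Rg estimate through
#' `slope/intercept = (16 pi^2 n0^2 / (3 lambda^2)) Rg^2`.  The second
#' virial coefficient is neglected (dilute column eluant).
#'
#' @param chrom a [chromatogram()].
#' @param slice slice index.
#' @param conc_threshold minimum concentration for a valid slice; default
#'   3x the baseline noise estimated from the annotated buffer region.
#' @return list: `mw` (Da), `rg` (Angstrom or `NA`), `valid`,
#'   `rg_reliable`, `intercept`, `slope`.
#' @export
debye_slice_mass <- function(chrom, slice, conc_threshold = NULL) {
  stopifnot(inherits(chrom, "chromatogram"))
  conc_threshold <- conc_threshold %||% (3 * baseline_sigma(chrom))
  c_s <- chrom$conc[slice]
  if (is.na(c_s) || c_s < conc_threshold)
    return(list(mw = NA_real_, rg = NA_real_, valid = FALSE,
                rg_reliable = FALSE, intercept = NA_real_,
                slope = NA_real_))
  x <- sin(deg2rad(chrom$angles) / 2)^2
  y <- chrom$K * c_s / chrom$rtheta[slice, ]
  ok <- is.finite(y)
  if (sum(ok) < 3L)
    return(list(mw = NA_real_, rg = NA_real_, valid = FALSE,
                rg_reliable = FALSE, intercept = NA_real_,
                slope = NA_real_))
  fit <- lm(y[ok] ~ x[ok])
  icpt <- coef(fit)[[1L]]
  slope <- coef(fit)[[2L]]
  if (!is.finite(icpt) || icpt <= 0)
    return(list(mw = NA_real_, rg = NA_real_, valid = FALSE,
                rg_reliable = FALSE, intercept = icpt, slope = slope))
  mw <- 1 / icpt
  rg <- NA_real_
  reliable <- FALSE
  if (slope > 0) {
    rg2 <- (slope / icpt) * 3 * chrom$wavelength^2 /
      (16 * pi^2 * chrom$n0^2)
    rg <- sqrt(rg2)
    reliable <- rg > 100  # MALS is blind below ~10 nm
  }
  list(mw = mw, rg = rg, valid = TRUE, rg_reliable = reliable,
       intercept = icpt, slope = slope)
}

#' Per-slice mass profile of a chromatogram
#'
#' Applies [debye_slice_mass()] to every slice.
#'
#' @inheritParams debye_slice_mass
#' @return data.frame of class `mass_profile`: `time`, `conc`, `mw`,
#'   `valid`.
#' @export
slice_masses <- function(chrom, conc_threshold = NULL) {
  conc_threshold <- conc_threshold %||% (3 * baseline_sigma(chrom))
  rows <- lapply(seq_along(chrom$time), function(i)
    debye_slice_mass(chrom, i, conc_threshold))
  out <- data.frame(time = chrom$time, conc = chrom$conc,
                    mw = vapply(rows, `[[`, 0, "mw"),
                    valid = vapply(rows, `[[`, TRUE, "valid"))
  class(out) <- c("mass_profile", "data.frame")
  out
}

#' Peak-averaged molar mass
#'
#' Concentration-weighted average of the valid slice masses inside a peak
#' window, plus the min-max mass range observed across the peak (the range
#' quoted alongside peak-average masses in oligomer tables).
#'
#' @param mass_profile a [slice_masses()] result.
#' @param peak_window length-2 time window (inclusive).
#' @return list: `mw` (weighted average), `mw_min`, `mw_max`, `n_slices`.
#' @export
peak_average_mass <- function(mass_profile, peak_window) {
  stopifnot(inherits(mass_profile, "mass_profile"),
            length(peak_window) == 2L)
  sel <- mass_profile$time >= peak_window[1L] &
    mass_profile$time <= peak_window[2L] & mass_profile$valid
  if (!any(sel)) stop("peak window contains no valid slice")
  mw <- mass_profile$mw[sel]
  w <- mass_profile$conc[sel]
  list(mw = sum(w * mw) / sum(w), mw_min = min(mw), mw_max = max(mw),
       n_slices = sum(sel))
}

#' Assign an oligomer-range label from a mass range
#'
#' Rounds the min and max observed masses to the nearest allowed oligomeric
#' state (geometrically, so 2.2 protomer units round to a dimer and 4.4 to a
#' tetramer) and composes the conventional label, e.g. `"Di-Tet"`.  A `"+"`
#' is appended when the maximum mass exceeds the largest allowed state by
#' more than 10%.
#'
#' @param mw_min,mw_max observed mass range (Da), positive.
#' @param protomer_mass mass of the protomer unit (Da); for an SMN-Gemin2
#'   system this is the mass of one SMN-G2 heterodimer, computed by the user
#'   from the construct sequences.
#' @param allowed_states allowed stoichiometries (default the
#'   dimer-of-dimers ladder `c(1, 2, 4, 8)`).
#' @return list of class `oligomer_assignment`: `n_low`, `n_high`, `label`,
#'   `plus`.
#' @export
assign_oligomer_range <- function(mw_min, mw_max, protomer_mass,
                                  allowed_states = c(1L, 2L, 4L, 8L)) {
  if (protomer_mass <= 0) stop("protomer_mass must be positive")
  if (mw_min <= 0 || mw_max <= 0) stop("masses must be positive")
  if (mw_max < mw_min) stop("mw_max must be >= mw_min")
  allowed_states <- sort(allowed_states)
  round_to_allowed <- function(x) {
    n <- x / protomer_mass
    allowed_states[which.min(abs(log(pmax(n, 1e-12) / allowed_states)))]
  }
  n_low <- round_to_allowed(mw_min)
  n_high <- round_to_allowed(mw_max)
  state_names <- c(`1` = "Monomer", `2` = "Di", `4` = "Tet", `8` = "Oct")
  nm <- function(n) {
    lbl <- unname(state_names[as.character(n)])
    if (is.na(lbl)) as.character(n) else lbl
  }
  plus <- mw_max > 1.1 * max(allowed_states) * protomer_mass
  label <- if (n_low == n_high) nm(n_low) else
    paste0(nm(n_low), "-", nm(n_high))
  if (plus) label <- paste0(label, "+")
  structure(list(n_low = n_low, n_high = n_high, label = label,
                 plus = plus),
            class = "oligomer_assignment")
}

#' @export
print.oligomer_assignment <- function(x, ...) {
  cat(sprintf("<oligomer_assignment> %s (n %d-%d)\n", x$label, x$n_low,
              x$n_high))
  invisible(x)
}
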