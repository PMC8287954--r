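R_GAS <- 8.314462618  # J / (mol K)

#' Mass-action model of the dimer-of-dimers oligomer ladder
#'
#' Stepwise association over the allowed species sizes n = 1, 2, 4, 8
#' protomer units (one protomer = one SMN-Gemin2 heterodimer): two monomers
#' form a dimer, two dimers a tetramer, two tetramers an octamer.  Each
#' step's standard free energy is parameterized by its enthalpy and entropy
#' at a reference temperature plus a heat-capacity change,
#' `dG(T) = dH0 + dCp (T - T0) - T (dS0 + dCp ln(T / T0))`,
#' and the step dissociation constant is `Kd = exp(dG / RT)` (association
#' dG < 0 gives small Kd).  The hydrophobic defaults use `dCp < 0` with
#' entropy-driven association at 25 C, so the higher-order steps weaken on
#' cooling between 0 and 40 C — the cold shift toward smaller species seen
#' for metazoan SMN complexes.
#'
#' @param dh0 named numeric, step association enthalpies at `t_ref`
#'   (J/mol) for steps `dimer`, `tetramer`, `octamer`.
#' @param ds0 step association entropies at `t_ref` (J/mol/K).
#' @param dcp step heat-capacity changes (J/mol/K), negative for
#'   hydrophobically driven steps.
#' @param t_ref reference temperature (K, default 298.15).
#' @param sizes allowed species sizes (default `c(1, 2, 4, 8)`); each size
#'   after the first must be double its predecessor.
#' @return object of class `equilibrium_model`.
#' @export
equilibrium_model <- function(dh0 = c(dimer = 20e3, tetramer = 10e3,
                                      octamer = 10e3),
                              ds0 = c(dimer = 239.3, tetramer = 148.4,
                                      octamer = 142.7),
                              dcp = c(dimer = -3000, tetramer = -4000,
                                      octamer = -4000),
                              t_ref = 298.15,
                              sizes = c(1L, 2L, 4L, 8L)) {
  sizes <- sort(as.integer(sizes))
  if (sizes[1L] != 1L || any(sizes[-1L] != 2L * sizes[-length(sizes)]))
    stop("sizes must start at 1 and double at each step")
  n_steps <- length(sizes) - 1L
  fix <- function(x) {
    if (length(x) == 1L) x <- rep(x, n_steps)
    stopifnot(length(x) == n_steps)
    x
  }
  structure(list(dh0 = fix(dh0), ds0 = fix(ds0), dcp = fix(dcp),
                 t_ref = t_ref, sizes = sizes),
            class = "equilibrium_model")
}

#' Convenience: equilibrium model from step Kd values
#'
#' Builds a temperature-independent ladder (dCp = 0, dH0 = 0) whose step
#' dissociation constants at `t_ref` equal the supplied values; handy for
#' fitting Kd values to titration data.
#'
#' @param kd numeric vector of step dissociation constants (M), one per
#'   association step.
#' @param t_ref reference temperature (K).
#' @param sizes allowed species sizes.
#' @return an [equilibrium_model()].
#' @export
equilibrium_model_from_kd <- function(kd, t_ref = 298.15,
                                      sizes = c(1L, 2L, 4L, 8L)) {
  dg <- R_GAS * t_ref * log(kd)  # association dG (negative for small Kd)
  equilibrium_model(dh0 = rep(0, length(kd)), ds0 = -dg / t_ref,
                    dcp = rep(0, length(kd)), t_ref = t_ref, sizes = sizes)
}

#' Step dissociation constants at a temperature
#'
#' @param model an [equilibrium_model()].
#' @param temperature temperature in K.
#' @return numeric vector of Kd (M), one per association step.
#' @export
step_kd <- function(model, temperature) {
  stopifnot(inherits(model, "equilibrium_model"))
  T0 <- model$t_ref
  dg <- model$dh0 + model$dcp * (temperature - T0) -
    temperature * (model$ds0 + model$dcp * log(temperature / T0))
  exp(dg / (R_GAS * temperature))
}

#' Solve the oligomer ladder at a total protomer concentration
#'
#' Finds the free-protomer concentration by bisection on the strictly
#' monotone conservation function, then fills species by stepwise mass
#' action (`[X2] = [X1]^2 / Kd2`, `[X4] = [X2]^2 / Kd4`, ...).
#'
#' @param model an [equilibrium_model()].
#' @param total total protomer concentration (M, > 0).
#' @param temperature temperature (K, default 298.15).
#' @param tol relative bisection tolerance on the conservation residual
#'   (default 1e-12).
#' @param max_iter maximum bisection iterations.
#' @return data.frame of class `species_distribution` with one row per
#'   species: `n`, `conc` (molar), `mol_fraction`, `mass_fraction`; plus
#'   attributes `mw_avg_units` (weight-average size in protomer units),
#'   `residual` (relative conservation residual), `temperature`.
#' @export
solve_equilibrium <- function(model, total, temperature = 298.15,
                              tol = 1e-12, max_iter = 400L) {
  stopifnot(inherits(model, "equilibrium_model"))
  if (total <= 0) stop("total protomer concentration must be positive")
  kd <- step_kd(model, temperature)
  sizes <- model$sizes
  species_conc <- function(x1) {
    conc <- numeric(length(sizes))
    conc[1L] <- x1
    for (k in seq_along(kd))
      conc[k + 1L] <- if (kd[k] == 0) Inf else conc[k]^2 / kd[k]
    conc
  }
  conserved <- function(x1) sum(sizes * species_conc(x1))
  lo <- 0; hi <- total
  f_hi <- conserved(hi) - total
  if (!is.finite(f_hi)) {  # extremely tight ladders: shrink the bracket
    hi <- total
    while (!is.finite(conserved(hi) - total)) hi <- hi / 2
  }
  x <- hi
  for (it in seq_len(max_iter)) {
    x <- (lo + hi) / 2
    f <- conserved(x) - total
    if (abs(f) <= tol * total) break
    if (f > 0) hi <- x else lo <- x
  }
  resid <- abs(conserved(x) - total) / total
  if (resid > 1e-6)
    stop(sprintf(paste0("bisection failed to converge: residual %.3g with ",
                        "bracket [%.3g, %.3g]"), resid, lo, hi))
  conc <- species_conc(x)
  prot <- sizes * conc
  out <- data.frame(n = sizes, conc = conc,
                    mol_fraction = conc / sum(conc),
                    mass_fraction = prot / sum(prot))
  attr(out, "mw_avg_units") <- sum(prot * sizes) / sum(prot)
  attr(out, "residual") <- resid
  attr(out, "temperature") <- temperature
  class(out) <- c("species_distribution", "data.frame")
  out
}

#' Weight-average mass (protomer units) versus temperature
#'
#' @param model an [equilibrium_model()].
#' @param total total protomer concentration (M).
#' @param temperatures temperatures in K (or degrees C if `celsius = TRUE`).
#' @param celsius interpret `temperatures` as degrees C.
#' @return data.frame: `temperature`, `mw_avg_units`.
#' @export
temperature_profile <- function(model, total, temperatures,
                                celsius = FALSE) {
  tk <- if (celsius) temperatures + 273.15 else temperatures
  mw <- vapply(tk, function(tt)
    attr(solve_equilibrium(model, total, tt), "mw_avg_units"), 0)
  data.frame(temperature = temperatures, mw_avg_units = mw)
}

#' Hydrodynamic scaling parameters for sedimentation trends
#'
#' @param s1 protomer sedimentation coefficient (Svedberg), > 0.
#' @param exponent size-scaling exponent in `s_n = s1 n^exponent`
#'   (default 2/3, compact scaling), in (0, 1].
#' @param f_f0 frictional ratio carried as metadata.
#' @return list of class `hydro_params`.
#' @export
hydro_params <- function(s1 = 4, exponent = 2 / 3, f_f0 = 1.5) {
  if (s1 <= 0) stop("s1 must be positive")
  if (exponent <= 0 || exponent > 1) stop("exponent must be in (0, 1]")
  structure(list(s1 = s1, exponent = exponent, f_f0 = f_f0),
            class = "hydro_params")
}

#' Signal-weighted average sedimentation coefficient of a distribution
#'
#' Trend-level predictor: `s_n = s1 n^exponent`, averaged over species with
#' protomer-mass weights (proportional to the absorbance signal each species
#' contributes).
#'
#' @param distribution a [solve_equilibrium()] result.
#' @param hydro a [hydro_params()].
#' @return weight-average s (Svedberg).
#' @export
predict_sbar <- function(distribution, hydro = hydro_params()) {
  stopifnot(inherits(distribution, "species_distribution"),
            inherits(hydro, "hydro_params"))
  s_n <- hydro$s1 * distribution$n^hydro$exponent
  sum(distribution$mass_fraction * s_n)
}

#' Probability that an untagged protomer co-purifies with a tagged one
#'
#' Under independent random assortment of tagged (fraction `p`) and untagged
#' protomers into n-mers, an untagged protomer is captured on a tag-affinity
#' resin whenever at least one of its n-1 partners is tagged:
#' `P = 1 - (1 - p)^(n - 1)`.  A monomeric mutant (n = 1) can never
#' co-purify, reproducing the behaviour of oligomerization-dead variants in
#' mixed pulldowns.
#'
#' @param n oligomer size (>= 1).
#' @param p tagged fraction in `[0, 1]`.
#' @return capture probability.
#' @export
predict_capture <- function(n, p) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  1 - (1 - p)^(n - 1)
}

#' Fit step Kd values to weight-average mass titration data
#'
#' Least-squares fit of the log10 step dissociation constants of a
#' temperature-independent ladder to observed weight-average mass (protomer
#' units) versus total concentration data, as produced by SEC-MALS
#' titrations.
#'
#' @param total total protomer concentrations (M).
#' @param mw_avg_units observed weight-average sizes (protomer units).
#' @param start_log10_kd starting values (default `c(-8, -6, -6)`).
#' @param temperature temperature (K).
#' @param sizes allowed species sizes.
#' @return list: `log10_kd` (fitted), `model`, `fitted`, `sse`,
#'   `convergence`.
#' @export
fit_equilibrium <- function(total, mw_avg_units,
                            start_log10_kd = c(-8, -6, -6),
                            temperature = 298.15,
                            sizes = c(1L, 2L, 4L, 8L)) {
  stopifnot(length(total) == length(mw_avg_units))
  obj <- function(lk) {
    mdl <- equilibrium_model_from_kd(10^lk, t_ref = temperature,
                                     sizes = sizes)
    pred <- vapply(total, function(ct)
      attr(solve_equilibrium(mdl, ct, temperature), "mw_avg_units"), 0)
    # relative residuals: titration noise is multiplicative
    sum(((pred - mw_avg_units) / mw_avg_units)^2)
  }
  fit <- optim(start_log10_kd, obj, method = "Nelder-Mead",
               control = list(maxit = 2000L, reltol = 1e-12))
  # restart from the solution: Nelder-Mead simplices collapse prematurely
  fit <- optim(fit$par, obj, method = "Nelder-Mead",
               control = list(maxit = 2000L, reltol = 1e-12))
  mdl <- equilibrium_model_from_kd(10^fit$par, t_ref = temperature,
                                   sizes = sizes)
  list(log10_kd = fit$par, model = mdl,
       fitted = vapply(total, function(ct)
         attr(solve_equilibrium(mdl, ct, temperature), "mw_avg_units"), 0),
       sse = fit$value, convergence = fit$convergence)
}
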