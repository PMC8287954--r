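#' Developmental viability and locomotion arithmetic
#'
#' Small, exactly reproducible assay calculations: pupation and eclosion
#' percentages from larval census counts, and crawling speed normalized to
#' body length.
#'
#' @param n_initial_larvae,n_pupae,n_adults non-negative integer counts.
#'   Count orderings violated by censusing gaps (e.g. more adults than
#'   pupae) produce a warning, not an error.
#' @return percentage (0-100).
#' @name viability
NULL

check_counts <- function(...) {
  cts <- c(...)
  if (any(cts < 0) || any(cts != round(cts)))
    stop("counts must be non-negative integers")
  invisible(cts)
}

#' @rdname viability
#' @export
percent_pupation <- function(n_initial_larvae, n_pupae) {
  check_counts(n_initial_larvae, n_pupae)
  if (n_initial_larvae == 0) stop("zero initial larvae")
  if (n_pupae > n_initial_larvae)
    warning("more pupae than initial larvae (censusing gap?)")
  100 * n_pupae / n_initial_larvae
}

#' @rdname viability
#' @export
percent_eclosion <- function(n_initial_larvae, n_adults) {
  check_counts(n_initial_larvae, n_adults)
  if (n_initial_larvae == 0) stop("zero initial larvae")
  if (n_adults > n_initial_larvae)
    warning("more adults than initial larvae (censusing gap?)")
  100 * n_adults / n_initial_larvae
}

#' Body lengths per second
#'
#' Average crawling speed normalized to larval size.
#'
#' @param avg_speed average speed (same length unit as `body_length`, per
#'   second).
#' @param body_length larval body length (> 0).
#' @return speed in body lengths per second (BLPS).
#' @export
blps <- function(avg_speed, body_length) {
  if (any(body_length <= 0)) stop("body_length must be positive")
  avg_speed / body_length
}

#' Fraction of dimer from crosslinking gel quantitation
#'
#' `dimer / (monomer + dimer)` from band intensities of a non-reducing gel;
#' with vectors of replicate pairs, also returns the replicate mean and
#' standard deviation of the fractions.
#'
#' @param monomer,dimer band intensities (arbitrary units, >= 0); vectors
#'   are treated as replicates pairwise.
#' @return for a single pair, the fraction in `[0, 1]`; for replicates, a
#'   list with `fractions`, `mean`, `sd`.
#' @export
fraction_dimer <- function(monomer, dimer) {
  stopifnot(length(monomer) == length(dimer))
  if (any(monomer < 0) || any(dimer < 0))
    stop("band intensities must be >= 0")
  if (any(monomer + dimer <= 0))
    stop("at least one band must be > 0 in each replicate")
  f <- dimer / (monomer + dimer)
  if (length(f) == 1L) return(f)
  list(fractions = f, mean = mean(f), sd = sd(f))
}

#' Summarise replicate dimer fractions
#'
#' @param fractions numeric vector of per-replicate dimer fractions.
#' @return list with `mean` and `sd`.
#' @export
summarise_fractions <- function(fractions) {
  stopifnot(all(fractions >= 0 & fractions <= 1))
  list(mean = mean(fractions), sd = sd(fractions))
}
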