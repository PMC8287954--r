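#' Small-angle scattering profile
#'
#' @param q momentum transfer grid (1/Angstrom), strictly increasing, >= 0.
#' @param intensity I(q), finite.
#' @param sigma optional positive uncertainties.
#' @return object of class `saxs_profile` (a data.frame).
#' @export
saxs_profile <- function(q, intensity, sigma = NULL) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  stopifnot(length(q) == length(intensity))
  if (any(q < 0) || any(diff(q) <= 0))
    stop("q must be non-negative and strictly increasing")
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(q))
    if (any(sigma <= 0)) stop("sigma must be positive where present")
  }
  out <- data.frame(q = q, intensity = intensity)
  if (!is.null(sigma)) out$sigma <- sigma
  class(out) <- c("saxs_profile", "data.frame")
  out
}

#' Read / write three-column scattering files
#'
#' Plain whitespace- or comma-delimited `(q, I, sigma)` text, the common
#' `.dat` exchange format; comment lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return a [saxs_profile()].
#' @export
read_saxs_dat <- function(path) {
  tab <- read.table(path, comment.char = "#",
                    sep = if (grepl(",", readLines(path, n = 5L)[1L]))
                      "," else "")
  saxs_profile(tab[[1L]], tab[[2L]],
               sigma = if (ncol(tab) >= 3L) tab[[3L]])
}

#' @rdname read_saxs_dat
#' @param profile a [saxs_profile()].
#' @export
write_saxs_dat <- function(profile, path) {
  stopifnot(inherits(profile, "saxs_profile"))
  write.table(profile, path, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

# sin(x)/x with the x -> 0 limit evaluated analytically
sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > 1e-12
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

#' Theoretical scattering profile of a bead model (Debye sum)
#'
#' `I(q) = sum_i sum_j w_i w_j sin(q r_ij) / (q r_ij)` over all bead pairs;
#' the `i = j` and `q -> 0` limits are evaluated analytically (sinc -> 1),
#' never by division.  Beads are point scatterers: no atomic form factors or
#' hydration layer.
#'
#' @param bead_coords n x 3 matrix (Angstrom).
#' @param q_grid momentum-transfer grid (1/Angstrom).
#' @param bead_weights optional scattering weights (default 1 per bead).
#' @return a [saxs_profile()].
#' @export
debye_profile <- function(bead_coords, q_grid, bead_weights = NULL) {
  bead_coords <- as.matrix(bead_coords)
  n <- nrow(bead_coords)
  if (n < 1L) stop("need at least one bead")
  w <- bead_weights %||% rep(1, n)
  stopifnot(length(w) == n)
  if (n == 1L)
    return(saxs_profile(q_grid, rep(w^2, length(q_grid))))
  d <- as.vector(dist(bead_coords))
  ww <- as.vector(crossprod_pairs(w))
  diag_term <- sum(w^2)
  I <- vapply(q_grid, function(q) diag_term + 2 * sum(ww * sinc(q * d)),
              0)
  saxs_profile(q_grid, I)
}

# pairwise products w_i w_j for i < j, in the order of stats::dist
crossprod_pairs <- function(w) {
  n <- length(w)
  out <- numeric(n * (n - 1L) / 2L)
  k <- 1L
  for (i in seq_len(n - 1L)) {
    m <- n - i
    out[k:(k + m - 1L)] <- w[i] * w[(i + 1L):n]
    k <- k + m
  }
  out
}

#' Guinier fit of the low-angle region
#'
#' Linear regression of `ln I` on `q^2` over a self-consistently chosen
#' window with `q * Rg <= qRg_limit`: starting from the lowest angles, the
#' window is re-selected with the fitted Rg until it stabilises.
#'
#' @param profile a [saxs_profile()].
#' @param qRg_limit Guinier validity limit (default 1.3, the usual globular
#'   cutoff).
#' @param min_points smallest admissible window (default 5).
#' @return list: `rg`, `i0`, `window` (index range used), `r_squared`,
#'   `qrg_max`.
#' @export
guinier_fit <- function(profile, qRg_limit = 1.3, min_points = 5L) {
  stopifnot(inherits(profile, "saxs_profile"))
  pos <- profile$intensity > 0 & profile$q > 0
  prof <- profile[pos, ]
  if (nrow(prof) < min_points) stop("too few positive-intensity points")
  x <- prof$q^2
  y <- log(prof$intensity)
  n_win <- min(max(min_points, 10L), nrow(prof))
  rg <- NA_real_
  for (iter in 1:50) {
    fit <- lm(y[1:n_win] ~ x[1:n_win])
    slope <- coef(fit)[[2L]]
    if (slope >= 0)
      stop("Guinier fit error: non-negative slope (flat or rising profile)")
    rg_new <- sqrt(-3 * slope)
    n_new <- max(min_points, sum(prof$q * rg_new <= qRg_limit))
    n_new <- min(n_new, nrow(prof))
    if (n_new < min_points)
      stop("Guinier fit error: no window satisfies the qRg limit")
    if (n_new == n_win && !is.na(rg) && abs(rg_new - rg) < 1e-10) break
    rg <- rg_new
    n_win <- n_new
  }
  fit <- lm(y[1:n_win] ~ x[1:n_win])
  slope <- coef(fit)[[2L]]
  if (slope >= 0) stop("Guinier fit error: non-negative slope")
  rg <- sqrt(-3 * slope)
  list(rg = rg, i0 = exp(coef(fit)[[1L]]),
       window = c(1L, n_win),
       # noiseless profiles fit exactly; summary() warns about that
       r_squared = suppressWarnings(summary(fit)$r.squared),
       qrg_max = prof$q[n_win] * rg)
}

# forward transform matrix mapping p(r) on grid r (piecewise linear,
# trapezoid quadrature) to I(q):  I(q) = 4 pi int p(r) sinc(qr) dr
pr_design <- function(q, r) {
  dr <- r[2L] - r[1L]
  wq <- rep(dr, length(r)); wq[c(1L, length(r))] <- dr / 2
  A <- outer(q, r, function(qq, rr) sinc(qq * rr))
  4 * pi * sweep(A, 2L, wq, `*`)
}

#' Indirect transform of a scattering profile to P(r)
#'
#' Solves the regularized linear inversion `I(q) = 4 pi int_0^Dmax p(r)
#' sinc(q r) dr` for `p(r)` on a uniform grid with endpoint-zero constraints
#' (`p(0) = p(Dmax) = 0`) and a second-difference smoothness penalty, the
#' explicit counterpart of classical perceptual-criteria fitting.
#'
#' @param profile a [saxs_profile()]; `sigma` is used for weighting when
#'   present.
#' @param dmax assumed maximum particle dimension (Angstrom, > 0).
#' @param lambda smoothness weight; `NULL` (default) selects it by an
#'   L-curve corner heuristic.
#' @param n_r number of r-grid points (default 101).
#' @return object of class `pofr`: data.frame `r`, `p`, plus attributes
#'   `dmax`, `rg`, `i0`, `chi2` (reduced), `lambda`.
#' @export
pr_invert <- function(profile, dmax, lambda = NULL, n_r = 101L) {
  stopifnot(inherits(profile, "saxs_profile"))
  if (dmax <= 0) stop("dmax must be positive")
  q <- profile$q; I <- profile$intensity
  sig <- profile$sigma %||% rep(max(mean(abs(I)) * 1e-3, 1e-12), length(q))
  r <- seq(0, dmax, length.out = n_r)
  A <- pr_design(q, r)
  # endpoint-zero: solve only for interior nodes
  Ai <- A[, 2:(n_r - 1L), drop = FALSE] / sig
  b <- I / sig
  m <- ncol(Ai)
  D2 <- diff(diag(m + 2L), differences = 2L)[, 2:(m + 1L), drop = FALSE]
  AtA <- crossprod(Ai); Atb <- crossprod(Ai, b); DtD <- crossprod(D2)
  solve_for <- function(lam) {
    M <- AtA + lam * DtD
    p <- try(solve(M, Atb), silent = TRUE)
    if (inherits(p, "try-error"))
      stop("singular inversion system: regularization too small")
    as.numeric(p)
  }
  if (is.null(lambda)) {
    # L-curve corner: maximum distance from the chord in log-log space
    scale0 <- mean(diag(AtA)) / max(mean(diag(DtD)), 1e-12)
    lams <- scale0 * 10^seq(-8, 2, length.out = 25L)
    pts <- t(vapply(lams, function(l) {
      p <- solve_for(l)
      c(log(sum((Ai %*% p - b)^2) + 1e-300),
        log(sum((D2 %*% p)^2) + 1e-300))
    }, c(0, 0)))
    v <- pts[nrow(pts), ] - pts[1L, ]
    v <- v / sqrt(sum(v^2))
    rel <- sweep(pts, 2L, pts[1L, ])
    dist_chord <- abs(rel[, 1L] * v[2L] - rel[, 2L] * v[1L])
    lambda <- lams[which.max(dist_chord)]
  }
  p_int <- solve_for(lambda)
  p <- c(0, p_int, 0)
  fit <- as.numeric(A %*% p)
  chi2 <- sum(((I - fit) / sig)^2) / max(length(q) - m, 1L)
  dr <- r[2L] - r[1L]
  m0 <- sum(p) * dr
  rg <- if (m0 > 0) sqrt(sum(p * r^2) * dr / (2 * m0)) else NA_real_
  out <- data.frame(r = r, p = p)
  attr(out, "dmax") <- dmax
  attr(out, "rg") <- rg
  attr(out, "i0") <- 4 * pi * m0
  attr(out, "chi2") <- chi2
  attr(out, "lambda") <- lambda
  attr(out, "fit") <- fit
  class(out) <- c("pofr", "data.frame")
  out
}

#' Scan Dmax for the best-supported P(r)
#'
#' Re-inverts the profile over a range of trial Dmax values and scores each
#' solution by a combined criterion: reduced chi-square of the fit (weight
#' 1), a non-negativity penalty on p(r) (weight 10) and a tail-oscillation
#' penalty (weight 1).  The incremental-adjustment analogue of interactive
#' Dmax selection.
#'
#' @param profile a [saxs_profile()].
#' @param dmax_range length-2 numeric, scan bounds (Angstrom).
#' @param step scan increment (Angstrom, > 0).
#' @param lambda,n_r passed to [pr_invert()].
#' @param weights named numeric: criterion weights `chi2`, `negativity`,
#'   `tail`.
#' @return list: `dmax` (best), `pofr` (its P(r)), and `trace` (data.frame of
#'   dmax, chi2, negativity, tail, score).
#' @export
scan_dmax <- function(profile, dmax_range, step = 2,
                      lambda = NULL, n_r = 101L,
                      weights = c(chi2 = 1, negativity = 10, tail = 1)) {
  if (length(dmax_range) != 2L || diff(dmax_range) <= 0 || step <= 0 ||
      dmax_range[1L] <= 0)
    stop("dmax_range must be a positive increasing pair and step > 0")
  dms <- seq(dmax_range[1L], dmax_range[2L], by = step)
  rows <- lapply(dms, function(dm) {
    pr <- pr_invert(profile, dm, lambda = lambda, n_r = n_r)
    p <- pr$p
    tot <- sum(abs(p)) + 1e-300
    negativity <- sum(pmax(-p, 0)) / tot
    tail_idx <- p[seq.int(ceiling(0.8 * length(p)), length(p))]
    tail_osc <- sum(abs(diff(sign(tail_idx[tail_idx != 0])))) / 2 /
      max(length(tail_idx), 1L)
    c(chi2 = attr(pr, "chi2"), negativity = negativity, tail = tail_osc)
  })
  tr <- as.data.frame(do.call(rbind, rows))
  tr$dmax <- dms
  tr$score <- -(weights[["chi2"]] * tr$chi2 +
                  weights[["negativity"]] * tr$negativity +
                  weights[["tail"]] * tr$tail)
  best <- which.max(tr$score)
  list(dmax = dms[best],
       pofr = pr_invert(profile, dms[best], lambda = lambda, n_r = n_r),
       trace = tr[, c("dmax", "chi2", "negativity", "tail", "score")])
}

#' Inter-body distance from the parallel-axis theorem
#'
#' For a two-body complex the radii of gyration obey
#' `Rg^2 = f1 R1g^2 + f2 R2g^2 + f1 f2 L^2`, where `f_i` are the relative
#' scattering weights (mass fractions under uniform contrast) and `L` the
#' distance between the body centers.  Solves for `L`.
#'
#' @param rg overall Rg of the complex (Angstrom).
#' @param r1g,r2g component radii of gyration (Angstrom).
#' @param f1 scattering-weight fraction of body 1 (0 < f1 < 1); body 2 gets
#'   `1 - f1`.  Two identical dimers associating into a tetramer have
#'   `f1 = 0.5`.
#' @return L in Angstrom.
#' @export
parallel_axis_distance <- function(rg, r1g, r2g, f1 = 0.5) {
  if (!(f1 > 0 && f1 < 1)) stop("f1 must lie strictly between 0 and 1")
  if (any(c(rg, r1g, r2g) < 0)) stop("radii of gyration must be >= 0")
  f2 <- 1 - f1
  rad <- (rg^2 - f1 * r1g^2 - f2 * r2g^2) / (f1 * f2)
  if (rad < 0)
    stop("inconsistent inputs: complex Rg smaller than the weighted body ",
         "Rg values (negative squared distance)")
  sqrt(rad)
}

#' SEC-SAXS frame stack
#'
#' @param intensities frames x q matrix of buffer-subtracted intensities.
#' @param q momentum-transfer grid matching the columns.
#' @param frame optional frame indices (default `1:nrow`).
#' @param sigma optional frames x q matrix of per-point uncertainties
#'   (> 0); when present, EFA detection runs on the error-weighted
#'   (whitened) matrix.
#' @param buffer_frames optional indices of buffer-only frames (must be
#'   disjoint from sample frames; used for noise-floor estimates).
#' @return object of class `frame_matrix`.
#' @export
frame_matrix <- function(intensities, q, frame = NULL, sigma = NULL,
                         buffer_frames = NULL) {
  intensities <- as.matrix(intensities)
  stopifnot(length(q) == ncol(intensities))
  frame <- frame %||% seq_len(nrow(intensities))
  stopifnot(length(frame) == nrow(intensities))
  if (!is.null(sigma)) {
    sigma <- as.matrix(sigma)
    stopifnot(identical(dim(sigma), dim(intensities)))
    if (any(sigma <= 0)) stop("sigma must be positive where present")
  }
  structure(list(intensities = intensities, q = as.numeric(q),
                 frame = frame, sigma = sigma,
                 buffer_frames = buffer_frames),
            class = "frame_matrix")
}

#' Read a frames-by-q CSV into a frame matrix
#'
#' Column 1 is the frame index; remaining columns are intensities with the q
#' value in the header (e.g. `q_0.0125`).
#'
#' @param path CSV path.
#' @return a [frame_matrix()].
#' @export
read_frame_matrix <- function(path) {
  tab <- read.csv(path, check.names = FALSE)
  q <- as.numeric(sub("^q_?", "", names(tab)[-1L]))
  frame_matrix(as.matrix(tab[, -1L]), q, frame = tab[[1L]])
}

#' SVD / evolving-factor-analysis deconvolution of a SEC-SAXS peak
#'
#' Singular value decomposition locates the number of scattering components
#' in a frame stack; forward and backward evolving factor analysis locate
#' each component's entry and exit frames; the abstract SVD basis is then
#' rotated into non-negative concentration profiles and component scattering
#' profiles by windowed alternating least squares under the sequential
#' (first-in / first-out) elution constraint.
#'
#' @param frames a [frame_matrix()] of buffer-subtracted intensities.
#' @param n_components number of species to extract; must not exceed the
#'   detectable rank.
#' @param sv_threshold entry/exit detection threshold as a multiple of the
#'   expected largest noise singular value of the growing frame window
#'   (`sigma (sqrt(frames) + sqrt(n_q))`, the random-matrix noise edge, with
#'   `sigma` estimated from the trailing singular values); default 3.
#' @param max_iter,tol alternating-least-squares controls.
#' @return object of class `efa_result`: `profiles` (q x n matrix),
#'   `concentrations` (frames x n, non-negative), `windows` (n x 2 entry and
#'   exit frames), `singular_values`, `residual` (relative reconstruction
#'   error).
#' @export
svd_efa <- function(frames, n_components, sv_threshold = 3,
                    max_iter = 500L, tol = 1e-10) {
  stopifnot(inherits(frames, "frame_matrix"))
  M <- frames$intensities           # frames x q
  nf <- nrow(M)
  nq <- ncol(M)
  # detection runs on the error-weighted matrix when uncertainties are
  # known (unit-variance noise, exact random-matrix edge); otherwise the
  # noise scale is estimated from the trailing singular values
  W <- if (!is.null(frames$sigma)) M / frames$sigma else M
  sv <- svd(W, nu = 0, nv = 0)$d
  sigma <- if (!is.null(frames$sigma)) 1 else noise_sigma(sv, nf, nq)
  rank_det <- sum(sv > sv_threshold * sigma * (sqrt(nf) + sqrt(nq)) +
                    .Machine$double.eps)
  if (n_components > rank_det)
    stop(sprintf("requested %d components but only %d detectable (rank)",
                 n_components, rank_det))
  # forward EFA: when does the k-th singular value rise above the noise
  # edge of the growing window?
  fwd <- efa_trace(W, n_components, forward = TRUE)
  bwd <- efa_trace(W, n_components, forward = FALSE)
  edge <- function(i) sigma * (sqrt(i) + sqrt(nq)) + .Machine$double.eps
  entry <- vapply(seq_len(n_components), function(k)
    first_exceed(fwd[, k], k, sv_threshold * edge(seq_len(nf))), 0L)
  exit <- vapply(seq_len(n_components), function(k)
    nf + 1L - first_exceed(bwd[, k], k, sv_threshold * edge(seq_len(nf))),
    0L)
  # sequential elution: component 1 enters first and exits first
  entry <- sort(entry); exit <- sort(exit)
  windows <- cbind(entry = entry, exit = exit)
  # initial concentrations: top-hat windows scaled by total signal
  tot <- rowSums(M)
  C <- sapply(seq_len(n_components), function(k) {
    ck <- rep(0, nf)
    ck[entry[k]:exit[k]] <- pmax(tot[entry[k]:exit[k]], 0)
    ck
  })
  S <- NULL
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    S <- t(M) %*% C %*% solve(crossprod(C) + 1e-12 * diag(n_components))
    C <- M %*% S %*% solve(crossprod(S) + 1e-12 * diag(n_components))
    C[C < 0] <- 0
    for (k in seq_len(n_components)) {
      ck <- rep(0, nf)
      ck[entry[k]:exit[k]] <- C[entry[k]:exit[k], k]
      C[, k] <- ck
    }
    obj <- sum((M - C %*% t(S))^2)
    if (is.finite(obj_old) && abs(obj_old - obj) <= tol * (obj + 1e-300))
      break
    obj_old <- obj
  }
  # normalise: concentration peaks at 1, intensity scale lives in S
  for (k in seq_len(n_components)) {
    pk <- max(C[, k])
    if (pk > 0) {
      C[, k] <- C[, k] / pk
      S[, k] <- S[, k] * pk
    }
  }
  resid <- sqrt(sum((M - C %*% t(S))^2) / sum(M^2))
  structure(list(profiles = S, concentrations = C, windows = windows,
                 n_components = n_components, singular_values = sv,
                 residual = resid, q = frames$q, frame = frames$frame),
            class = "efa_result")
}

# per-element noise standard deviation estimated from the trailing half of
# the singular spectrum: the total noise energy of an nf x nq Gaussian
# matrix is ~ nf * nq * sigma^2, spread over all singular values
noise_sigma <- function(sv, nf, nq) {
  p <- length(sv)
  j0 <- max(2L, ceiling(p / 2))
  tail_sv <- sv[j0:p]
  energy <- sum(tail_sv^2) * p / length(tail_sv)
  sqrt(energy / (nf * nq))
}

# singular values of growing frame windows; column k = k-th singular value
efa_trace <- function(M, n_components, forward = TRUE) {
  nf <- nrow(M)
  out <- matrix(0, nf, n_components)
  for (i in seq_len(nf)) {
    rows <- if (forward) 1:i else (nf - i + 1L):nf
    sub <- M[rows, , drop = FALSE]
    d <- svd(sub, nu = 0, nv = 0)$d
    k <- min(length(d), n_components)
    out[i, seq_len(k)] <- d[seq_len(k)]
  }
  out
}

first_exceed <- function(trace, k, threshold) {
  idx <- which(trace > threshold)  # threshold may be a per-frame vector
  idx <- idx[idx >= k]  # need at least k frames for a k-th singular value
  if (!length(idx)) stop("EFA: component never rises above the noise floor")
  idx[1L]
}

#' Forward Debye transform of a P(r)
#'
#' Utility to reproject an inverted P(r) back to I(q), e.g. for residual
#' inspection.
#'
#' @param pofr a `pofr` object from [pr_invert()].
#' @param q evaluation grid.
#' @return a [saxs_profile()].
#' @export
pr_forward <- function(pofr, q) {
  stopifnot(inherits(pofr, "pofr"))
  A <- pr_design(q, pofr$r)
  saxs_profile(q, as.numeric(A %*% pofr$p))
}
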