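# run expr with a local RNG seeded by `seed`, restoring the caller's state
with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is mandatory for stochastic generators")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Generate a synthetic ortholog family around a motif template
#'
#' Produces `n_species` sequences that keep the template's motif positions
#' fixed while substituting non-motif residues at the given divergence, then
#' injects the listed point mutations — emulating a family of YG-box
#' orthologs with regularly spaced Y/G/s residues plus engineered or
#' disease-derived substitutions.
#'
#' @param template an [ortholog_sequence()] whose Y/G/s motifs define the
#'   conserved scaffold.
#' @param n_species number of sequences to generate.
#' @param divergence per-position substitution probability at non-motif
#'   positions (0-1).
#' @param mutations optional data.frame with columns `species` (index or
#'   generated id), `position` (residue number) and `to` (one-letter code);
#'   a position outside the template is an error.
#' @param motif_positions residue numbers to hold fixed; default the union
#'   of all Y-, G- and s-motif hits of the template.
#' @param seed mandatory RNG seed.
#' @return named list of [ortholog_sequence()] objects (`sp01`, `sp02`, ...).
#' @export
gen_ortholog_family <- function(template, n_species = 8L, divergence = 0.2,
                                mutations = NULL, motif_positions = NULL,
                                seed) {
  stopifnot(inherits(template, "ortholog_sequence"))
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  if (is.null(motif_positions)) {
    hits <- lapply(c("Y", "G", "s"), function(cl)
      scan_motifs(template, cl))
    motif_positions <- sort(unique(unlist(lapply(hits, function(h)
      unlist(h$positions)))))
    if (!length(motif_positions))
      stop("template defines no Y/G/s motif positions")
  }
  chars <- seq_chars(template)
  first <- template$first_residue_number
  resno <- first + seq_along(chars) - 1L
  fixed <- resno %in% motif_positions
  ids <- sprintf("sp%02d", seq_len(n_species))
  seqs <- with_seed(seed, {
    lapply(seq_len(n_species), function(k) {
      ch <- chars
      swap <- !fixed & runif(length(ch)) < divergence
      if (any(swap))
        ch[swap] <- sample(Biostrings::AA_STANDARD, sum(swap),
                           replace = TRUE)
      ortholog_sequence(ids[k], paste(ch, collapse = ""), first)
    })
  })
  names(seqs) <- ids
  if (!is.null(mutations)) {
    stopifnot(all(c("species", "position", "to") %in% names(mutations)))
    for (i in seq_len(nrow(mutations))) {
      sp <- mutations$species[i]
      key <- if (is.numeric(sp)) ids[sp] else as.character(sp)
      if (is.na(key) || !key %in% names(seqs)) stop("unknown species: ", sp)
      pos <- mutations$position[i]
      idx <- pos - first + 1L
      if (idx < 1L || idx > length(chars))
        stop(sprintf("mutation position %d undefined in the template", pos))
      ch <- seq_chars(seqs[[key]])
      ch[idx] <- toupper(mutations$to[i])
      seqs[[key]] <- ortholog_sequence(key, paste(ch, collapse = ""), first)
    }
  }
  seqs
}

#' Generate a synthetic SEC-MALS chromatogram of an oligomer mixture
#'
#' Concentration trace as a sum of Gaussian elution peaks (one per species);
#' light scattering at every detector angle `R_theta(t) = K c_s(t) M_s`
#' summed over species (form factor ~1 at light-scattering angles for
#' particles this small), plus fractional Gaussian noise on both channels.
#' The first `n_buffer` slices carry only baseline noise and are annotated
#' as the buffer region.
#'
#' @param species data.frame with columns `mass` (Da), `peak_center` (s),
#'   `peak_width` (s, Gaussian sigma) and `peak_conc` (g/mL at peak).
#' @param times slice times (default `seq(0, 1200, by = 2)`).
#' @param K optical constant (default 1e-7, typical magnitude for
#'   `cm^2 mol g^-2` units at 658 nm).
#' @param angles detector angles (default 16 angles, 20-150 degrees).
#' @param noise fractional (1-sigma) noise on both channels (default 0.01).
#' @param n_buffer number of leading buffer-only slices annotated for
#'   baseline estimation (default 50).
#' @param seed mandatory RNG seed.
#' @return a [chromatogram()].
#' @export
gen_chromatogram <- function(species, times = seq(0, 1200, by = 2),
                             K = 1e-7,
                             angles = seq(20, 150, length.out = 16L),
                             noise = 0.01, n_buffer = 50L, seed) {
  stopifnot(is.data.frame(species),
            all(c("mass", "peak_center", "peak_width", "peak_conc") %in%
                  names(species)))
  if (noise < 0) stop("noise must be >= 0")
  nt <- length(times)
  conc_s <- sapply(seq_len(nrow(species)), function(s)
    species$peak_conc[s] *
      exp(-(times - species$peak_center[s])^2 /
            (2 * species$peak_width[s]^2)))
  conc_s <- matrix(conc_s, nrow = nt)
  conc <- rowSums(conc_s)
  ls_clean <- K * as.numeric(conc_s %*% species$mass)
  rtheta <- matrix(rep(ls_clean, length(angles)), nt)
  cpeak <- max(conc)
  with_seed(seed, {
    if (noise > 0) {
      rtheta <- rtheta +
        matrix(rnorm(nt * length(angles),
                     sd = noise * max(ls_clean)), nt)
      conc <- pmax(conc + rnorm(nt, sd = noise * cpeak), 0)
    }
    chromatogram(times, conc, rtheta, angles, K,
                 buffer_slices = seq_len(min(n_buffer, nt)))
  })
}

#' Generate a synthetic SEC-SAXS frame stack
#'
#' Each frame is the concentration-weighted sum of the component Debye
#' profiles, `I_f(q) = sum_s c_s(f) I_s(q)`, with variance-scaled Gaussian
#' (Poisson-like) noise: the per-point standard deviation is
#' `noise * sqrt((I + buffer_level * I_peak) * I_peak)`, mimicking counting
#' statistics of buffer-subtracted exposures (the buffer term keeps a
#' residual noise floor where the sample signal vanishes, as in real
#' subtracted data).
#'
#' @param components list of components; each has `coords` (bead matrix) or
#'   a precomputed `profile` ([saxs_profile()]), plus `peak_center`,
#'   `peak_width` (frames) and `scale` (peak concentration weight).
#' @param q momentum-transfer grid (default `seq(0.008, 0.5, length.out =
#'   120)`).
#' @param n_frames number of frames (default 120).
#' @param noise noise scale (fraction of the geometric-mean intensity;
#'   default 0.01).
#' @param buffer_level residual buffer intensity as a fraction of the peak
#'   intensity (default 0.01).
#' @param seed mandatory RNG seed.
#' @return list: `frames` (a [frame_matrix()]), `profiles` (q x n matrix of
#'   the true component profiles), `concentrations` (frames x n true elution
#'   profiles), `noise_sd` (the per-point noise standard deviations).
#' @export
gen_secsaxs_frames <- function(components,
                               q = seq(0.008, 0.5, length.out = 120L),
                               n_frames = 120L, noise = 0.01,
                               buffer_level = 0.01, seed) {
  stopifnot(length(components) >= 1L)
  profs <- sapply(components, function(cp) {
    if (!is.null(cp$profile)) {
      stopifnot(isTRUE(all.equal(cp$profile$q, q)))
      cp$profile$intensity
    } else debye_profile(cp$coords, q)$intensity
  })
  profs <- matrix(profs, ncol = length(components))
  fr <- seq_len(n_frames)
  concs <- sapply(components, function(cp)
    (cp$scale %||% 1) *
      exp(-(fr - cp$peak_center)^2 / (2 * cp$peak_width^2)))
  concs <- matrix(concs, nrow = n_frames)
  clean <- concs %*% t(profs)
  with_seed(seed, {
    M <- clean
    sdev <- matrix(0, n_frames, length(q))
    if (noise > 0) {
      ipeak <- max(clean)
      sdev <- noise * sqrt((pmax(clean, 0) + buffer_level * ipeak) * ipeak)
      M <- clean + matrix(rnorm(length(clean), sd = as.numeric(sdev)),
                          nrow = n_frames)
    }
    list(frames = frame_matrix(M, q, frame = fr,
                               sigma = if (noise > 0) sdev),
         profiles = profs, concentrations = concs, noise_sd = sdev)
  })
}

# deterministic quasi-uniform points on a sphere (Fibonacci lattice)
sphere_points <- function(n, radius, center = c(0, 0, 0)) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  sweep(radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta),
                       cos(phi)), 2L, center, `+`)
}

#' Generate a coarse bead model of a dimer or tetramer
#'
#' Delegates to the helix-bundle builders and returns the C-alpha bead
#' cloud, optionally decorated with one partner-protein-sized sphere of
#' beads per protomer (emulating the Gemin2 moiety that enlarges the
#' envelope of the full SMN-Gemin2 complex).
#'
#' @param level `"dimer"` or `"tetramer"`.
#' @param mode tetramer docking mode, `"parallel"` or `"antiparallel"`.
#' @param sequence helix sequence (default the 43-residue synthetic human
#'   YG-box fragment shipped with the package).
#' @param first_residue_number numbering of the first residue (default 252).
#' @param decorate add one Gemin2-sized bead sphere per protomer.
#' @param gemin2_radius sphere radius (Angstrom, default 20).
#' @param gemin2_beads beads per sphere (default 24).
#' @param ... further arguments to [assemble_dimer()] /
#'   [assemble_tetramer()].
#' @return list: `coords` (bead matrix), `bundle` (the underlying
#'   `bundle_model`), `dimer_index` (1/2 ownership of each bead for
#'   tetramers).
#' @export
gen_bead_model <- function(level = c("dimer", "tetramer"),
                           mode = c("parallel", "antiparallel"),
                           sequence = NULL, first_residue_number = 252L,
                           decorate = FALSE, gemin2_radius = 20,
                           gemin2_beads = 24L, ...) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  if (is.null(sequence)) {
    aln <- read_ortholog_fasta(system.file("extdata",
                                           "yg_alignment_synthetic.fasta",
                                           package = "oligostate"),
                               aligned = TRUE)
    sequence <- gsub("-", "", aln$hs$residues, fixed = TRUE)
    first_residue_number <- aln$hs$first_residue_number
  }
  dimer <- assemble_dimer(sequence,
                          first_residue_number = first_residue_number, ...)
  bundle <- if (level == "dimer") dimer else
    assemble_tetramer(dimer, mode = mode)
  helices <- bundle$helices
  nh <- length(helices)
  coords <- NULL
  owner <- NULL
  for (k in seq_len(nh)) {
    h <- helices[[k]]
    pts <- h$ca
    if (decorate) {
      nterm <- h$ca[1L, ]
      ctr <- nterm - h$axis_dir * (gemin2_radius + 4)
      pts <- rbind(pts, sphere_points(gemin2_beads, gemin2_radius, ctr))
    }
    coords <- rbind(coords, pts)
    owner <- c(owner, rep(if (k <= nh / 2) 1L else 2L, nrow(pts)))
  }
  list(coords = coords, bundle = bundle,
       dimer_index = if (level == "tetramer") owner else rep(1L,
                                                             nrow(coords)))
}
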