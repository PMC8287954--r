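# shared fixtures and independent oracles used across the suite

fixture_alignment <- function() {
  read_ortholog_fasta(system.file("extdata", "yg_alignment_synthetic.fasta",
                                  package = "oligostate"),
                      aligned = TRUE)
}

hs_yg_sequence <- function() {
  aln <- fixture_alignment()
  ortholog_sequence("hs", gsub("-", "", aln$hs$residues, fixed = TRUE),
                    aln$hs$first_residue_number)
}

hs_dimer <- function(...) {
  hs <- hs_yg_sequence()
  assemble_dimer(hs$residues, first_residue_number = hs$first_residue_number,
                 ...)
}

# brute-force motif oracle: enumerate all (i, i+4, i+8) in-class triples and
# merge same-phase overlapping triples into maximal runs
brute_force_motifs <- function(chars, alphabet) {
  n <- length(chars)
  in_class <- chars %in% alphabet
  triples <- list()
  if (n >= 9L)
    for (i in seq_len(n - 8L))
      if (in_class[i] && in_class[i + 4L] && in_class[i + 8L])
        triples[[length(triples) + 1L]] <- c(i, i + 4L, i + 8L)
  runs <- list()
  for (tr in triples) {
    merged <- FALSE
    for (k in seq_along(runs)) {
      r <- runs[[k]]
      if (tr[1L] %% 4L == r[1L] %% 4L && tr[1L] <= max(r) + 4L &&
          max(tr) >= min(r) - 4L && any(tr %in% r)) {
        runs[[k]] <- sort(unique(c(r, tr)))
        merged <- TRUE
        break
      }
    }
    if (!merged) runs[[length(runs) + 1L]] <- tr
  }
  runs[order(vapply(runs, min, 0L))]
}

random_aa_string <- function(n, pool = c("G", "A", "S", "Y", "L", "V", "T",
                                         "E", "K", "W")) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

cosine_sim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# deterministic bead model of a solid sphere: cubic lattice points inside R
sphere_beads <- function(R, spacing) {
  g <- seq(-R, R, by = spacing)
  pts <- as.matrix(expand.grid(g, g, g))
  pts[rowSums(pts^2) <= R^2, , drop = FALSE]
}

# closed-form scattering of a homogeneous sphere of radius R
sphere_profile <- function(R, q, i0 = 1) {
  ff <- 3 * (sin(q * R) - q * R * cos(q * R)) / (q * R)^3
  saxs_profile(q, i0 * ff^2)
}

# standard crosslinking positions and the measured efficiency tiers
# (high / intermediate / low) used for model discrimination
xlink_positions <- c(262, 266, 270, 274, 277, 281)
xlink_measured_tiers <- c(`274` = 3, `277` = 3, `262` = 2, `281` = 2,
                          `266` = 1, `270` = 1)
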