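#' Ortholog sequence with residue numbering
#'
#' Lightweight container for a (fragment of a) protein sequence together with
#' the residue number of its first position in the full-length protein, so
#' that motif hits and mapped positions are reported in each species' native
#' numbering (e.g. the human SMN YG-box construct starts at residue 252).
#'
#' @param species_id short species/construct label, e.g. `"hs"`.
#' @param residues one-letter amino-acid string; `-` is allowed only when
#'   `aligned = TRUE`.
#' @param first_residue_number residue number of the first position (>= 1).
#' @param aligned logical; if `TRUE`, gap characters are permitted.
#' @return an object of class `ortholog_sequence`.
#' @export
ortholog_sequence <- function(species_id, residues, first_residue_number = 1L,
                              aligned = FALSE) {
  stopifnot(is.character(species_id), length(species_id) == 1L,
            is.character(residues), length(residues) == 1L)
  first_residue_number <- as.integer(first_residue_number)
  if (is.na(first_residue_number) || first_residue_number < 1L)
    stop("first_residue_number must be an integer >= 1")
  residues <- toupper(residues)
  ok <- c(Biostrings::AA_STANDARD, if (aligned) "-")
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L)
    stop("empty sequence")
  bad <- setdiff(unique(chars), ok)
  if (length(bad))
    stop("invalid residue letters: ", paste(bad, collapse = ", "))
  structure(list(species_id = species_id, residues = residues,
                 first_residue_number = first_residue_number,
                 aligned = aligned),
            class = "ortholog_sequence")
}

#' @export
print.ortholog_sequence <- function(x, ...) {
  n <- nchar(x$residues)
  cat(sprintf("<ortholog_sequence> %s %d-%d\n  %s\n", x$species_id,
              x$first_residue_number,
              x$first_residue_number + n - 1L, x$residues))
  invisible(x)
}

seq_chars <- function(seq) strsplit(seq$residues, "", fixed = TRUE)[[1L]]

#' Read ortholog sequences from a FASTA file
#'
#' Headers of the form `id/start-end` (e.g. `hs/252-294`) carry the residue
#' numbering of the fragment; headers without a `/start-end` suffix get
#' `first_residue_number = 1`.
#'
#' @param path FASTA file (plain or aligned).
#' @param aligned logical; set `TRUE` for an alignment (gaps allowed).
#' @return named list of [ortholog_sequence()] objects.
#' @export
read_ortholog_fasta <- function(path, aligned = FALSE) {
  aa <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(aa), function(i) {
    hdr <- names(aa)[i]
    id <- sub("/.*$", "", hdr)
    id <- sub("\\s.*$", "", id)
    start <- 1L
    m <- regmatches(hdr, regexec("/(\\d+)-(\\d+)", hdr))[[1L]]
    if (length(m) == 3L) start <- as.integer(m[2L])
    ortholog_sequence(id, as.character(aa[[i]]), start, aligned = aligned)
  })
  names(out) <- vapply(out, `[[`, "", "species_id")
  out
}

#' Write ortholog sequences to FASTA
#'
#' @param seqs list of [ortholog_sequence()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ortholog_fasta <- function(seqs, path) {
  aa <- Biostrings::AAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(aa) <- vapply(seqs, function(s) {
    n <- nchar(gsub("-", "", s$residues, fixed = TRUE))
    sprintf("%s/%d-%d", s$species_id, s$first_residue_number,
            s$first_residue_number + n - 1L)
  }, "")
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Scan a sequence for Y-, G- or s-motif progressions
#'
#' A motif hit is a maximal run of >= 3 class residues spaced exactly four
#' apart (the `XxxxXxxxX` pattern of glycine zippers and the YG box).  Runs
#' in different phases may overlap and are reported separately; a run of
#' four class residues is a single hit of length four.
#'
#' @param seq an [ortholog_sequence()] (ungapped).
#' @param motif_class `"Y"`, `"G"` or `"s"`; the class alphabets are
#'   Y = \{Y\}, G = \{G\}, s = \{G,A,S,T,C\}.
#' @param alphabet optional character vector overriding the class alphabet.
#' @param min_len minimum run length (default 3).
#' @return a data.frame of class `motif_hits` with one row per hit:
#'   `motif_class`, `start` (residue number), `length`, and list-columns
#'   `positions` (residue numbers) and `matched_residues`.
#' @export
scan_motifs <- function(seq, motif_class = c("G", "Y", "s"), alphabet = NULL,
                        min_len = 3L) {
  motif_class <- match.arg(motif_class)
  if (inherits(seq, "ortholog_sequence") && isTRUE(seq$aligned))
    stop("scan_motifs expects an ungapped sequence")
  if (!inherits(seq, "ortholog_sequence"))
    stop("seq must be an ortholog_sequence")
  chars <- seq_chars(seq)
  n <- length(chars)
  if (n < 9L) stop("sequence length must be >= 9")
  ab <- alphabet %||% motif_alphabets[[motif_class]]
  in_class <- chars %in% ab
  step <- 4L
  hits <- list()
  for (i in seq_len(n)) {
    if (!in_class[i]) next
    # only start a run where it cannot be extended backwards (maximality)
    if (i > step && in_class[i - step]) next
    idx <- i
    j <- i + step
    while (j <= n && in_class[j]) {
      idx <- c(idx, j)
      j <- j + step
    }
    if (length(idx) >= min_len) hits[[length(hits) + 1L]] <- idx
  }
  starts <- vapply(hits, `[`, 0L, 1L)
  ord <- order(starts)
  res <- data.frame(
    motif_class = rep(motif_class, length(hits)),
    start = starts[ord] + seq$first_residue_number - 1L,
    length = vapply(hits, length, 0L)[ord]
  )
  res$positions <- lapply(hits[ord], function(ix) ix + seq$first_residue_number - 1L)
  res$matched_residues <- lapply(hits[ord], function(ix) chars[ix])
  class(res) <- c("motif_hits", "data.frame")
  res
}

#' Cross-species residue position map from an ungapped-core alignment
#'
#' Builds the column-to-residue-number correspondence for every sequence of
#' an alignment.  Within each column the mapping is bijective over the
#' species that have a residue (non-gap) in that column.
#'
#' @param aligned_seqs list of aligned [ortholog_sequence()] objects (all the
#'   same aligned length), e.g. from `read_ortholog_fasta(..., aligned=TRUE)`.
#' @return an object of class `position_map` holding, per species, the
#'   residue number in each alignment column (`NA` at gaps).
#' @export
position_map <- function(aligned_seqs) {
  stopifnot(length(aligned_seqs) >= 2L)
  widths <- vapply(aligned_seqs, function(s) nchar(s$residues), 0L)
  if (length(unique(widths)) != 1L)
    stop("aligned sequences must all have the same length")
  cols <- lapply(aligned_seqs, function(s) {
    ch <- seq_chars(s)
    num <- rep(NA_integer_, length(ch))
    nongap <- ch != "-"
    num[nongap] <- seq_len(sum(nongap)) + s$first_residue_number - 1L
    num
  })
  names(cols) <- vapply(aligned_seqs, `[[`, "", "species_id")
  structure(list(columns = as.data.frame(cols), n_col = widths[[1L]]),
            class = "position_map")
}

#' Map a residue number between species
#'
#' Returns the residue number in `to_species` that occupies the same
#' alignment column as `residue_number` in `from_species`.  If the target
#' species has a gap in that column there is no equivalent residue and
#' `NA_integer_` is returned (never a number).
#'
#' @param map a [position_map()].
#' @param from_species,to_species species labels present in the map.
#' @param residue_number residue number in `from_species`.
#' @return the equivalent residue number, or `NA_integer_` when the column
#'   is gapped in `to_species`.
#' @export
map_position <- function(map, from_species, residue_number, to_species) {
  stopifnot(inherits(map, "position_map"))
  cols <- map$columns
  if (!from_species %in% names(cols) || !to_species %in% names(cols))
    stop("unknown species id")
  col <- which(cols[[from_species]] == residue_number)
  if (length(col) != 1L)
    stop(sprintf("residue %d not present in the aligned region of '%s'",
                 residue_number, from_species))
  cols[[to_species]][col]
}

#' Angular offset of two residues around an ideal helix
#'
#' Accumulated helical twist between two positions on the same helix,
#' wrapped to (-180, 180].  With the ideal 100 degrees/residue twist, the
#' step-4 spacing of the Y/G/s motifs advances only 40 degrees per motif
#' residue, which is why all members of one motif lie on a single helix
#' face.
#'
#' @param pos_a,pos_b residue numbers on the same helix.
#' @param twist_per_residue helical twist in degrees per residue
#'   (default 100, the ideal 3.6-residue-per-turn alpha helix).
#' @param face_half_width classification half-width in degrees (default 50):
#'   `|angle| <= face_half_width` counts as the same helix face.
#' @return list with `angle` (degrees in (-180, 180]) and `same_face`.
#' @export
helix_face_angle <- function(pos_a, pos_b, twist_per_residue = 100,
                             face_half_width = 50) {
  ang <- wrap_angle((pos_b - pos_a) * twist_per_residue)
  list(angle = ang, same_face = abs(ang) <= face_half_width)
}

# wrap degrees into (-180, 180]
wrap_angle <- function(deg) {
  w <- deg %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Per-column residue-class conservation of an alignment
#'
#' For each alignment column, the frequency of the residue classes
#' \{glycine, small, hydrophobic, polar\} among non-gap residues.  Residues
#' belonging to several classes are assigned one class by the priority
#' glycine > small > hydrophobic > polar, so the four frequencies sum to 1.
#'
#' @param aligned_seqs list of aligned [ortholog_sequence()] objects of equal
#'   length.
#' @param classes named list of class alphabets, in priority order
#'   (default [aa_classes] of the package).
#' @return data.frame of class `conservation_profile`: `column`, `n` (non-gap
#'   count) and one frequency column per class.
#' @export
conservation_profile <- function(aligned_seqs, classes = aa_classes) {
  widths <- vapply(aligned_seqs, function(s) nchar(s$residues), 0L)
  if (length(unique(widths)) != 1L)
    stop("aligned sequences must all have the same length")
  mat <- do.call(rbind, lapply(aligned_seqs, seq_chars))
  ncol_aln <- ncol(mat)
  assign_class <- function(ch) {
    for (cl in names(classes)) if (ch %in% classes[[cl]]) return(cl)
    "polar"
  }
  out <- data.frame(column = seq_len(ncol_aln),
                    n = colSums(mat != "-"))
  freqs <- matrix(0, ncol_aln, length(classes),
                  dimnames = list(NULL, names(classes)))
  for (j in seq_len(ncol_aln)) {
    res <- mat[mat[, j] != "-", j]
    if (!length(res)) next
    cl <- vapply(res, assign_class, "")
    tab <- table(factor(cl, levels = names(classes)))
    freqs[j, ] <- as.numeric(tab) / length(res)
  }
  out <- cbind(out, as.data.frame(freqs))
  class(out) <- c("conservation_profile", "data.frame")
  out
}
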