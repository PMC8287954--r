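test_that("scan_motifs finds literal step-4 patterns and rejects bad input", {
  s <- ortholog_sequence("x", "GAAAGAAAG", 1)
  hits <- scan_motifs(s, "G")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$positions[[1L]], c(1L, 5L, 9L))
  expect_equal(hits$matched_residues[[1L]], c("G", "G", "G"))

  expect_equal(nrow(scan_motifs(ortholog_sequence("x", "AAAAAAAAA", 1),
                                "Y")), 0L)
  # residue numbering offsets propagate into reported positions
  hits252 <- scan_motifs(ortholog_sequence("x", "GAAAGAAAG", 252), "G")
  expect_equal(hits252$positions[[1L]], c(252L, 256L, 260L))

  expect_error(scan_motifs(ortholog_sequence("x", "GAAAG", 1), "G"),
               ">= 9")
  expect_error(ortholog_sequence("x", "GAAA#AAAG", 1), "invalid")
  expect_error(ortholog_sequence("x", "", 1))
})

test_that("scan_motifs equals exhaustive triple enumeration on random
           sequences", {
  set.seed(101)
  for (cl in c("G", "Y", "s")) {
    ab <- switch(cl, G = "G", Y = "Y", s = c("G", "A", "S", "T", "C"))
    for (rep in 1:333) {
      str <- random_aa_string(40)
      seq <- ortholog_sequence("x", str, 1)
      got <- scan_motifs(seq, cl)$positions
      want <- brute_force_motifs(strsplit(str, "")[[1L]], ab)
      want <- want[vapply(want, length, 0L) >= 3L]
      expect_equal(lapply(got, as.integer), lapply(want, as.integer),
                   info = paste(cl, str))
    }
  }
})

test_that("maximal runs longer than three are one hit, overlapping phases
           are separate hits", {
  # run of four in one phase
  s <- ortholog_sequence("x", "GAAAGAAAGAAAG", 1)
  hits <- scan_motifs(s, "G")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$length, 4L)
  # two phases overlapping: positions 1,5,9 and 3,7,11
  s2 <- ortholog_sequence("x", "GAGAGAGAGAG", 1)
  hits2 <- scan_motifs(s2, "G")
  expect_equal(nrow(hits2), 2L)
  expect_equal(sort(vapply(hits2$positions, min, 0L)), c(1L, 3L))
})

test_that("map_position reproduces the cross-species residue triples", {
  pm <- position_map(fixture_alignment())
  expect_identical(map_position(pm, "hs", 273L, "dm"), 204L)
  expect_identical(map_position(pm, "hs", 277L, "sp"), 141L)
  expect_identical(map_position(pm, "hs", 275L, "dm"), 206L)
  expect_identical(map_position(pm, "hs", 272L, "sp"), 136L)
})

test_that("map_position round-trips every aligned column and flags gaps", {
  aln <- fixture_alignment()
  pm <- position_map(aln)
  cols <- pm$columns
  for (a in names(cols)) for (b in names(cols)) {
    both <- which(!is.na(cols[[a]]) & !is.na(cols[[b]]))
    for (col in both) {
      fwd <- map_position(pm, a, cols[[a]][col], b)
      expect_identical(fwd, cols[[b]][col])
      expect_identical(map_position(pm, b, fwd, a), cols[[a]][col])
    }
  }
  # hs 289 sits in a column gapped in sp: no equivalent, never a number
  expect_true(is.na(map_position(pm, "hs", 289L, "sp")))
  expect_error(map_position(pm, "hs", 500L, "dm"), "not present")
})

test_that("helix_face_angle wraps correctly and matches a twist-accumulation
           loop", {
  expect_equal(helix_face_angle(10, 10)$angle, 0)
  r <- helix_face_angle(1, 5)  # step 4 at 100 deg/residue
  expect_equal(r$angle, 40)
  expect_true(r$same_face)
  for (d in 1:18) {
    acc <- 0
    for (i in seq_len(d)) acc <- acc + 100
    acc <- acc %% 360
    if (acc > 180) acc <- acc - 360
    expect_equal(helix_face_angle(0, d)$angle, acc, info = paste("d =", d))
  }
})

test_that("members of one motif hit share a 90-degree helical sector", {
  hs <- hs_yg_sequence()
  for (cl in c("G", "Y", "s")) {
    hits <- scan_motifs(hs, cl)
    for (pos in hits$positions) {
      # any three consecutive members span at most 80 degrees
      for (i in seq_len(length(pos) - 2L)) {
        ang <- abs(helix_face_angle(pos[i], pos[i + 2L])$angle)
        expect_lte(ang, 90)
      }
    }
  }
})

test_that("conservation_profile matches direct counting and sums to one", {
  single <- list(ortholog_sequence("a", "GAYRL", 1, aligned = TRUE))
  cp1 <- conservation_profile(single)
  freqs <- as.matrix(cp1[, c("glycine", "small", "hydrophobic", "polar")])
  expect_true(all(freqs %in% c(0, 1)))
  expect_equal(unname(rowSums(freqs)), rep(1, 5))

  gcol <- lapply(1:4, function(i)
    ortholog_sequence(letters[i], "G", 1, aligned = TRUE))
  expect_equal(conservation_profile(gcol)$glycine, 1)

  # random alignment against a counting oracle
  set.seed(77)
  alnseqs <- lapply(1:6, function(i)
    ortholog_sequence(letters[i], random_aa_string(30), 1, aligned = TRUE))
  cp <- conservation_profile(alnseqs)
  mat <- do.call(rbind, lapply(alnseqs, function(s)
    strsplit(s$residues, "")[[1L]]))
  classify <- function(ch) {
    if (ch == "G") "glycine"
    else if (ch %in% c("A", "S", "T", "C")) "small"
    else if (ch %in% c("V", "L", "I", "M", "F", "W", "Y")) "hydrophobic"
    else "polar"
  }
  for (j in seq_len(ncol(mat))) {
    tab <- table(factor(vapply(mat[, j], classify, ""),
                        levels = c("glycine", "small", "hydrophobic",
                                   "polar"))) / nrow(mat)
    expect_equal(as.numeric(cp[j, c("glycine", "small", "hydrophobic",
                                    "polar")]),
                 as.numeric(tab))
  }

  bad <- list(ortholog_sequence("a", "GAY", 1, aligned = TRUE),
              ortholog_sequence("b", "GA", 1, aligned = TRUE))
  expect_error(conservation_profile(bad), "same length")
})

test_that("FASTA round trip preserves sequences and numbering", {
  hs <- hs_yg_sequence()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_ortholog_fasta(list(hs), path)
  back <- read_ortholog_fasta(path)
  expect_equal(back$hs$residues, hs$residues)
  expect_equal(back$hs$first_residue_number, hs$first_residue_number)
})
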