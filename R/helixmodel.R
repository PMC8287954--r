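#' Ideal alpha-helix parameters
#'
#' Defaults describe the ideal alpha helix: 1.5 Angstrom rise and 100 degree
#' twist per residue (3.6 residues/turn), C-alpha at 2.3 Angstrom from the
#' axis; the C-beta pseudo-atom sits 1.5 Angstrom further out along the same
#' radial direction (no side-chain rotamers are modelled).
#'
#' @param rise axial rise per residue (Angstrom).
#' @param twist twist per residue (degrees).
#' @param radius C-alpha helical radius (Angstrom).
#' @param cb_offset radial C-beta offset beyond C-alpha (Angstrom).
#' @return list of parameters.
#' @export
helix_params <- function(rise = 1.5, twist = 100, radius = 2.3,
                         cb_offset = 1.5) {
  if (rise <= 0 || radius <= 0)
    stop("rise and radius must be positive")
  list(rise = rise, twist = twist, radius = radius, cb_offset = cb_offset)
}

deg2rad <- function(x) x * pi / 180

# orthonormal frame whose third column is the unit vector `d`
axis_frame <- function(d) {
  d <- d / sqrt(sum(d^2))
  ref <- if (abs(d[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2L] * u[3L] - d[3L] * u[2L],
         d[3L] * u[1L] - d[1L] * u[3L],
         d[1L] * u[2L] - d[2L] * u[1L])
  cbind(u, -v, d)  # right-handed with z = d
}

#' Build a coarse-grained ideal helix
#'
#' Places one C-alpha and one radial C-beta pseudo-atom per residue on an
#' ideal helical path.  Residue `i` (0-based offset) sits at cylindrical
#' coordinates (radius, phase + i*twist, i*rise) in the frame defined by
#' `origin` and `direction`.
#'
#' @param sequence one-letter amino-acid string.
#' @param params a [helix_params()] list.
#' @param origin 3-vector; position of the axis at residue 1.
#' @param direction 3-vector; helix axis direction (N- to C-terminal).
#' @param phase azimuthal phase of residue 1 (degrees).
#' @param first_residue_number residue number of the first position.
#' @return object of class `helix_model`: `sequence`, `resno`, matrices `ca`
#'   and `cb` (n x 3, Angstrom), `axis_point`, `axis_dir`, `params`, `phase`.
#' @export
build_ideal_helix <- function(sequence, params = helix_params(),
                              origin = c(0, 0, 0), direction = c(0, 0, 1),
                              phase = 0, first_residue_number = 1L) {
  stopifnot(nchar(sequence) >= 1L)
  if (params$rise <= 0 || params$radius <= 0)
    stop("rise and radius must be positive")
  n <- nchar(sequence)
  i <- seq_len(n) - 1L
  ang <- deg2rad(phase + i * params$twist)
  frame <- axis_frame(direction)
  local_ca <- cbind(params$radius * cos(ang), params$radius * sin(ang),
                    i * params$rise)
  rcb <- params$radius + params$cb_offset
  local_cb <- cbind(rcb * cos(ang), rcb * sin(ang), i * params$rise)
  ca <- sweep(local_ca %*% t(frame), 2L, origin, `+`)
  cb <- sweep(local_cb %*% t(frame), 2L, origin, `+`)
  structure(list(sequence = sequence,
                 resno = first_residue_number + i,
                 ca = ca, cb = cb,
                 axis_point = origin,
                 axis_dir = frame[, 3L],
                 params = params, phase = phase),
            class = "helix_model")
}

# apply a rigid transform x -> x %*% t(R) + tr to a helix_model
transform_helix <- function(h, R = diag(3), tr = c(0, 0, 0)) {
  h$ca <- sweep(h$ca %*% t(R), 2L, tr, `+`)
  h$cb <- sweep(h$cb %*% t(R), 2L, tr, `+`)
  h$axis_point <- as.numeric(R %*% h$axis_point + tr)
  h$axis_dir <- as.numeric(R %*% h$axis_dir)
  h
}

rot_x <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3L)
}
rot_y <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3L)
}
rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L)
}

#' All atom coordinates of a bundle or helix
#'
#' @param model a `helix_model` or `bundle_model`.
#' @param atoms `"ca"`, `"cb"` or `"both"`.
#' @return numeric matrix (n x 3).
#' @export
bundle_coords <- function(model, atoms = c("ca", "cb", "both")) {
  atoms <- match.arg(atoms)
  hs <- if (inherits(model, "bundle_model")) model$helices else list(model)
  out <- lapply(hs, function(h) switch(atoms,
                                       ca = h$ca, cb = h$cb,
                                       both = rbind(h$ca, h$cb)))
  do.call(rbind, out)
}

min_cross_distance <- function(ca_a, ca_b) {
  d2 <- outer(rowSums(ca_a^2), rowSums(ca_b^2), `+`) -
    2 * ca_a %*% t(ca_b)
  sqrt(max(min(d2), 0))
}

check_clashes <- function(helices, clash_floor) {
  nh <- length(helices)
  for (i in seq_len(nh - 1L)) for (j in seq((i + 1L), nh)) {
    ca_a <- helices[[i]]$ca
    ca_b <- helices[[j]]$ca
    d2 <- outer(rowSums(ca_a^2), rowSums(ca_b^2), `+`) - 2 * ca_a %*% t(ca_b)
    mind <- sqrt(max(min(d2), 0))
    if (mind < clash_floor) {
      idx <- which(d2 == min(d2), arr.ind = TRUE)[1L, ]
      stop(sprintf(paste0("steric clash: C-alpha %d of helix %d and C-alpha ",
                          "%d of helix %d are %.2f A apart (< clash floor ",
                          "%.2f A)"),
                   idx[1L], i, idx[2L], j, mind, clash_floor))
    }
  }
  invisible(TRUE)
}

new_bundle <- function(helices, level, mode, handedness = NA_character_,
                       crossing_angle = NA_real_, inter_axis = NA_real_,
                       register = 0, symmetry = NULL, clash_floor = 3.0) {
  check_clashes(helices, clash_floor)
  structure(list(helices = helices, level = level, mode = mode,
                 handedness = handedness, crossing_angle = crossing_angle,
                 inter_axis = inter_axis, register = register,
                 symmetry = symmetry, clash_floor = clash_floor),
            class = "bundle_model")
}

#' @export
print.bundle_model <- function(x, ...) {
  cat(sprintf("<bundle_model> %s (%s), %d helices x %d residues\n",
              x$level, x$mode, length(x$helices),
              length(x$helices[[1L]]$resno)))
  cat(sprintf("  Rg %.1f A, Dmax %.1f A\n",
              compute_rg(bundle_coords(x)), compute_dmax(bundle_coords(x))))
  invisible(x)
}

#' Assemble a two-helix zipper dimer
#'
#' Builds a glycine/YG-zipper dimer: two identical ideal helices with axes
#' `inter_axis_distance` apart, azimuthal phases set so that the configured
#' G-motif residues face the partner helix, and an exact two-fold relating
#' the helices (about the bundle axis for a parallel dimer, about the
#' perpendicular for an antiparallel one).
#'
#' The G-motif face is rotated `interface_phase` degrees off the inter-axis
#' line.  With the ideal 100-degree twist the residue azimuths fall on a
#' 20-degree grid, so the default 10-degree offset is the rotation that
#' keeps the intimate Gly-Gly backbone contact just above the clash floor
#' while a G-motif residue still attains the closest cross-helix approach.
#'
#' @param sequence one-letter string shared by both helices.
#' @param g_positions residue numbers of the G-motif glycines (used to phase
#'   the interface); default: glycines of the best G-motif hit.
#' @param inter_axis_distance axis separation (Angstrom, default 7.5).
#' @param polarity `"parallel"` (glycine-zipper convention) or
#'   `"antiparallel"`.
#' @param interface_phase azimuthal offset of the G face from the inter-axis
#'   line (degrees); default 10 for a parallel dimer and 0 for an
#'   antiparallel one (whose facing residues are azimuth-mirrored, moving
#'   the tight contact off the G face).
#' @param params [helix_params()].
#' @param first_residue_number numbering of the first residue.
#' @param clash_floor minimum allowed cross-helix C-alpha distance
#'   (Angstrom); violation is an error, never silently relaxed.
#' @return a `bundle_model` of level `"dimer"`.
#' @export
assemble_dimer <- function(sequence, g_positions = NULL,
                           inter_axis_distance = 7.5,
                           polarity = c("parallel", "antiparallel"),
                           interface_phase = NULL,
                           params = helix_params(),
                           first_residue_number = 1L,
                           clash_floor = 3.0) {
  polarity <- match.arg(polarity)
  interface_phase <- interface_phase %||%
    if (polarity == "parallel") 10 else 0
  n <- nchar(sequence)
  if (is.null(g_positions)) {
    hits <- scan_motifs(ortholog_sequence("x", sequence,
                                          first_residue_number), "G")
    if (!nrow(hits)) stop("no G-motif found; supply g_positions")
    g_positions <- hits$positions[[which.max(hits$length)]]
  }
  g_idx <- g_positions - first_residue_number + 1L
  if (any(g_idx < 1L | g_idx > n)) stop("g_positions outside the sequence")
  i_mid <- g_idx[ceiling(length(g_idx) / 2)] - 1L  # 0-based offset
  # helix A at x = -d/2, G-motif face toward +x (partner), offset by
  # interface_phase to avoid dead-on backbone overlap
  phase_a <- interface_phase - i_mid * params$twist
  org <- c(-inter_axis_distance / 2, 0, -(n - 1L) * params$rise / 2)
  ha <- build_ideal_helix(sequence, params, origin = org,
                          direction = c(0, 0, 1), phase = phase_a,
                          first_residue_number = first_residue_number)
  sym <- if (polarity == "parallel") rot_z(180) else rot_y(180)
  hb <- transform_helix(ha, sym)
  new_bundle(list(ha, hb), "dimer", polarity,
             inter_axis = inter_axis_distance,
             symmetry = list(R = sym, t = c(0, 0, 0)),
             clash_floor = clash_floor)
}

#' Assemble a dimer-of-dimers tetramer
#'
#' Docks two copies of a zipper dimer through a second interface that uses
#' one helix from each dimer, mimicking constraint-based tetramer model
#' building.  The two interface helices are related by an exact two-fold;
#' the full tetramer inherits that two-fold because each dimer is carried
#' rigidly by its interface helix.
#'
#' * `mode = "parallel"`: the dimers point the same way and the interface
#'   helices form a right-handed cross.  The default geometry (steep
#'   crossing, dyad grazing the outward T274/Y277 edge in human numbering)
#'   is the package's constraint-built model of the tetramer interface: it
#'   places the small-residue (s-motif) face plus H273/Y277 at the contact
#'   and puts the homotypic C-beta pairs of T274/Y277 nearest the dyad.
#' * `mode = "antiparallel"`: head-to-tail stacked dimers with a left-handed
#'   shallow crossing and an axial register offset, patterned on stacked
#'   crystal-lattice dimers.
#'
#' @param dimer a `bundle_model` of level `"dimer"` (from
#'   [assemble_dimer()]).
#' @param mode `"parallel"` or `"antiparallel"`.
#' @param crossing_angle magnitude of the interface-helix crossing angle in
#'   degrees; default 80 (parallel) / 20 (antiparallel).
#' @param inter_helix_distance axis separation of the two interface helices
#'   at their crossing point (Angstrom; default 9.0 parallel / 10.5
#'   antiparallel).
#' @param register residue number (native numbering) at which the interface
#'   helices cross; defaults to three residues C-terminal of the helix
#'   midpoint for the parallel mode (placing the dyad on the late-motif
#'   face) and to the helix midpoint for the antiparallel mode.
#' @param interface_phase azimuth (degrees) of the residue `register`
#'   C-beta relative to the direction toward the partner dimer; default 130
#'   (parallel) / 30 (antiparallel).
#' @param clash_floor minimum cross-helix C-alpha distance (Angstrom).
#' @return a `bundle_model` of level `"tetramer"`; helices 1-2 are dimer A,
#'   helices 3-4 dimer B, helices 2 and 3 form the dimer-dimer interface.
#' @export
assemble_tetramer <- function(dimer, mode = c("parallel", "antiparallel"),
                              crossing_angle = NULL,
                              inter_helix_distance = NULL,
                              register = NULL,
                              interface_phase = NULL,
                              clash_floor = 3.0) {
  mode <- match.arg(mode)
  stopifnot(inherits(dimer, "bundle_model"), dimer$level == "dimer")
  h1 <- dimer$helices[[1L]]
  h2 <- dimer$helices[[2L]]
  n <- length(h2$resno)
  rise <- h2$params$rise
  crossing_angle <- crossing_angle %||% if (mode == "parallel") 80 else 20
  inter_helix_distance <- inter_helix_distance %||%
    if (mode == "parallel") 9.0 else 10.5
  register <- register %||% (h2$resno[1L] + round((n - 1L) / 2) +
                               if (mode == "parallel") 3L else 0L)
  interface_phase <- interface_phase %||% if (mode == "parallel") 130 else 30
  handed <- if (mode == "parallel") "right" else "left"

  # --- express dimer A in the interface frame of helix 2 ---------------
  # target frame: helix-2 axis along z with the crossing residue at z = 0,
  # C-beta of the crossing residue pointing along -x (toward the partner)
  t_reg <- (register - h2$resno[1L]) * rise
  # current helix 2: axis +z/-z through axis_point (dimer builder geometry)
  # rebuild dimer A by rigid transform: rotate so h2 axis -> +z
  Rflip <- if (sum(h2$axis_dir * c(0, 0, 1)) < 0) rot_x(180) else diag(3)
  A1 <- transform_helix(h1, Rflip)
  A2 <- transform_helix(h2, Rflip)
  # translate so the h2 axis passes through the origin and register at z=0
  reg_idx <- which.min(abs(A2$resno - register))
  axis_xy <- A2$axis_point[1:2]
  tr <- c(-axis_xy, -A2$ca[reg_idx, 3L])
  A1 <- transform_helix(A1, diag(3), tr)
  A2 <- transform_helix(A2, diag(3), tr)
  # rotate about z so the register C-beta azimuth is interface_phase from -x
  cb_dir <- A2$cb[reg_idx, 1:2] - c(0, 0)
  cur <- atan2(cb_dir[2L], cb_dir[1L]) * 180 / pi
  A1 <- transform_helix(A1, rot_z(180 + interface_phase - cur))
  A2 <- transform_helix(A2, rot_z(180 + interface_phase - cur))

  half <- crossing_angle / 2
  if (mode == "parallel") {
    # tilt helix 2 axis away from the dyad (z stays the dyad axis), shift
    # the interface helix to x = +a/2; dimer B = C2 about z
    Rt <- rot_x(if (handed == "right") -half else half)
    sh <- c(inter_helix_distance / 2, 0, 0)
    A1 <- transform_helix(A1, Rt, sh)
    A2 <- transform_helix(A2, Rt, sh)
    C2 <- rot_z(180)
  } else {
    # antiparallel: dyad along y; helix 3 = C2y(helix 2) runs head-to-tail;
    # axial register offset staggers the stack
    Rt <- rot_y(if (handed == "left") half else -half)
    stagger <- c(0, 0, 0.35 * (n - 1L) * rise)
    sh <- c(inter_helix_distance / 2, 0, 0) + stagger / 2
    A1 <- transform_helix(A1, Rt, sh)
    A2 <- transform_helix(A2, Rt, sh)
    C2 <- rot_y(180)
  }
  B1 <- transform_helix(A1, C2)
  B2 <- transform_helix(A2, C2)
  new_bundle(list(A1, A2, B2, B1), "tetramer", mode,
             handedness = handed, crossing_angle = crossing_angle,
             inter_axis = inter_helix_distance, register = register,
             symmetry = list(R = C2, t = c(0, 0, 0)),
             clash_floor = clash_floor)
}

#' Place a tetramer at a requested dimer-dimer separation
#'
#' Rigidly translates the two dimer halves of a tetramer apart along the
#' line joining their centers of mass until the center-of-mass separation
#' equals `distance`.  Used for parallel-axis-theorem constructions.
#'
#' @param tetramer a `bundle_model` of level `"tetramer"`.
#' @param distance requested center-of-mass separation (Angstrom).
#' @return a `bundle_model` with the same assembly metadata.
#' @export
set_dimer_separation <- function(tetramer, distance) {
  stopifnot(inherits(tetramer, "bundle_model"), tetramer$level == "tetramer")
  a <- rbind(tetramer$helices[[1L]]$ca, tetramer$helices[[2L]]$ca)
  b <- rbind(tetramer$helices[[3L]]$ca, tetramer$helices[[4L]]$ca)
  ca <- colMeans(a); cb <- colMeans(b)
  u <- cb - ca
  d0 <- sqrt(sum(u^2))
  if (d0 < 1e-9) stop("dimer centers coincide; cannot define a direction")
  u <- u / d0
  shift <- (distance - d0) / 2
  out <- tetramer
  for (i in 1:2) out$helices[[i]] <-
    transform_helix(out$helices[[i]], diag(3), -shift * u)
  for (i in 3:4) out$helices[[i]] <-
    transform_helix(out$helices[[i]], diag(3), shift * u)
  out$symmetry <- NULL  # translation along u preserves C2 only if u is axial
  check_clashes(out$helices, out$clash_floor)
  out
}

#' Radius of gyration of a point set
#'
#' `Rg = sqrt( sum w_i |r_i - rbar|^2 / sum w_i )` with `rbar` the weighted
#' centroid.
#'
#' @param coords n x 3 matrix (Angstrom).
#' @param weights optional non-negative weights (default uniform).
#' @return Rg in Angstrom.
#' @export
compute_rg <- function(coords, weights = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least 2 points")
  w <- weights %||% rep(1, nrow(coords))
  stopifnot(length(w) == nrow(coords), all(w >= 0), sum(w) > 0)
  ctr <- colSums(coords * w) / sum(w)
  d2 <- rowSums(sweep(coords, 2L, ctr)^2)
  sqrt(sum(w * d2) / sum(w))
}

#' Maximum intramolecular distance of a point set
#'
#' @param coords n x 3 matrix (Angstrom).
#' @return largest pairwise distance (Angstrom).
#' @export
compute_dmax <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least 2 points")
  max(dist(coords))
}

#' Disulfide-crosslink propensity across the dimer-dimer interface
#'
#' For each residue position (shared by the two dimers of a tetramer,
#' modelling a single homotypic cysteine substitution) the minimum C-beta to
#' C-beta distance between the two dimer halves is converted to a propensity
#' with a decreasing logistic: `score = 1 / (1 + exp((d - d0)/w))`.  Rigid
#' pre-formed disulfides need a C-beta separation of roughly 3.5-4.6
#' Angstrom, but helical interfaces breathe, so the default midpoint is a
#' softer 6 Angstrom.
#'
#' @param tetramer a `bundle_model` of level `"tetramer"` (helices 1-2 =
#'   dimer A, 3-4 = dimer B).
#' @param positions residue numbers to score.
#' @param d0 logistic midpoint (Angstrom, default 6).
#' @param w logistic width (Angstrom, default 1).
#' @return data.frame of class `crosslink_prediction`, ranked by descending
#'   score: `position`, `distance` (min cross-dimer C-beta distance), and
#'   `score`; positions absent from the model get `NA` distance/score and an
#'   `error` message.
#' @export
predict_crosslinks <- function(tetramer, positions, d0 = 6.0, w = 1.0) {
  stopifnot(inherits(tetramer, "bundle_model"), tetramer$level == "tetramer")
  dimA <- tetramer$helices[1:2]
  dimB <- tetramer$helices[3:4]
  resno <- tetramer$helices[[1L]]$resno
  one <- function(p) {
    if (!p %in% resno)
      return(c(distance = NA_real_, score = NA_real_))
    cbA <- do.call(rbind, lapply(dimA, function(h) h$cb[h$resno == p, ,
                                                        drop = FALSE]))
    cbB <- do.call(rbind, lapply(dimB, function(h) h$cb[h$resno == p, ,
                                                        drop = FALSE]))
    d <- min_cross_distance(cbA, cbB)
    c(distance = d, score = 1 / (1 + exp((d - d0) / w)))
  }
  m <- t(vapply(positions, one, c(distance = 0, score = 0)))
  out <- data.frame(position = positions, distance = m[, "distance"],
                    score = m[, "score"])
  out$error <- ifelse(is.na(out$distance),
                      "position not present in the model", NA_character_)
  out <- out[order(-out$score, out$position, na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("crosslink_prediction", "data.frame")
  out
}

#' RMSD of a bundle under its declared two-fold
#'
#' Applies the bundle's stored symmetry operation and computes the RMSD
#' between mapped and partner atoms; an exactly symmetric assembly returns
#' ~0.
#'
#' @param bundle a `bundle_model` with a `symmetry` entry.
#' @return RMSD in Angstrom.
#' @export
symmetry_rmsd <- function(bundle) {
  stopifnot(inherits(bundle, "bundle_model"))
  if (is.null(bundle$symmetry)) stop("bundle carries no declared symmetry")
  R <- bundle$symmetry$R
  hs <- bundle$helices
  nh <- length(hs)
  # symmetry maps helix i to helix nh+1-i
  sq <- 0; cnt <- 0
  for (i in seq_len(nh)) {
    mapped <- hs[[i]]$ca %*% t(R)
    target <- hs[[nh + 1L - i]]$ca
    sq <- sq + sum((mapped - target)^2)
    cnt <- cnt + nrow(mapped)
  }
  sqrt(sq / cnt)
}

#' Write a bundle as a PDB file
#'
#' One chain per helix, CA and CB records only.
#'
#' @param bundle a `bundle_model` or `helix_model`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_bundle_pdb <- function(bundle, path) {
  hs <- if (inherits(bundle, "bundle_model")) bundle$helices else list(bundle)
  aa3 <- setNames(
    c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU",
      "LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL"),
    c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T",
      "W","Y","V"))
  xyz <- NULL; resno <- NULL; resid <- NULL; elety <- NULL; chain <- NULL
  for (k in seq_along(hs)) {
    h <- hs[[k]]
    chars <- strsplit(h$sequence, "")[[1L]]
    keep_cb <- chars != "G"
    xyz <- rbind(xyz, h$ca, h$cb[keep_cb, , drop = FALSE])
    resno <- c(resno, h$resno, h$resno[keep_cb])
    resid <- c(resid, aa3[chars], aa3[chars][keep_cb])
    elety <- c(elety, rep("CA", length(h$resno)),
               rep("CB", sum(keep_cb)))
    chain <- c(chain, rep(LETTERS[k], length(h$resno) + sum(keep_cb)))
  }
  ord <- order(chain, resno, elety)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz[ord, ])),
                   resno = resno[ord], resid = resid[ord],
                   elety = elety[ord], chain = chain[ord])
  invisible(path)
}

#' Read coordinates from a PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] returning the C-alpha (or all
#' atom) coordinate matrix, e.g. for template superposition or Rg/Dmax
#' computations on deposited structures.
#'
#' @param path PDB file.
#' @param atoms `"ca"` or `"all"`.
#' @return n x 3 coordinate matrix with `resno`/`chain` attributes.
#' @export
read_pdb_coords <- function(path, atoms = c("ca", "all")) {
  atoms <- match.arg(atoms)
  pdb <- bio3d::read.pdb(path)
  sel <- if (atoms == "ca") bio3d::atom.select(pdb, elety = "CA") else
    bio3d::atom.select(pdb, "all")
  m <- matrix(pdb$xyz[sel$xyz], ncol = 3L, byrow = TRUE)
  attr(m, "resno") <- pdb$atom$resno[sel$atom]
  attr(m, "chain") <- pdb$atom$chain[sel$atom]
  m
}
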