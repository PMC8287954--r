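test_that("ideal helix geometry matches its defining parameters", {
  h <- build_ideal_helix(strrep("A", 10))
  # axial extent of 10 residues at 1.5 A rise
  z <- h$ca %*% h$axis_dir
  expect_equal(max(z) - min(z), 13.5)
  # all C-alpha exactly at the helical radius from the axis
  radial <- sqrt(rowSums((h$ca - outer(as.numeric(z), h$axis_dir))^2))
  expect_equal(radial, rep(2.3, 10), tolerance = 1e-12)
  # consecutive C-alpha spacing ~3.8 A and constant rise
  d <- sqrt(rowSums(diff(h$ca)^2))
  expect_true(all(abs(d - 3.8) < 0.2))
  expect_equal(diff(as.numeric(z)), rep(1.5, 9))
  # C-beta 1.5 A radially outside C-alpha
  expect_equal(sqrt(rowSums((h$cb - h$ca)^2)), rep(1.5, 10))

  expect_error(build_ideal_helix("AAAA", helix_params(rise = -1)),
               "positive")
  expect_error(helix_params(radius = 0), "positive")
})

test_that("helix builder respects arbitrary frames and phases", {
  h <- build_ideal_helix(strrep("G", 12), origin = c(5, -3, 2),
                         direction = c(1, 1, 0), phase = 37)
  u <- c(1, 1, 0) / sqrt(2)
  z <- (h$ca - matrix(c(5, -3, 2), 12, 3, byrow = TRUE)) %*% u
  expect_equal(as.numeric(diff(z)), rep(1.5, 11))
  # Rg from coordinates equals the definition
  ctr <- colMeans(h$ca)
  rg_direct <- sqrt(mean(rowSums(sweep(h$ca, 2, ctr)^2)))
  expect_equal(compute_rg(h$ca), rg_direct)
})

test_that("compute_rg and compute_dmax agree with brute-force definitions", {
  two <- rbind(c(0, 0, 0), c(0, 0, 10))
  expect_equal(compute_dmax(two), 10)
  expect_equal(compute_rg(two), 5)
  expect_error(compute_rg(two[1, , drop = FALSE]), "2 points")
  expect_error(compute_dmax(two[1, , drop = FALSE]), "2 points")

  # surface of a sphere: Rg -> R
  pts <- oligostate:::sphere_points(4000, 17)
  expect_equal(compute_rg(pts), 17, tolerance = 1e-3)

  set.seed(5)
  for (rep in 1:5) {
    cloud <- matrix(rnorm(3 * 60, sd = 12), ncol = 3)
    w <- runif(60, 0.2, 2)
    dm <- 0
    for (i in 1:59) for (j in (i + 1):60)
      dm <- max(dm, sqrt(sum((cloud[i, ] - cloud[j, ])^2)))
    expect_equal(compute_dmax(cloud), dm)
    ctr <- colSums(cloud * w) / sum(w)
    rg <- sqrt(sum(w * rowSums(sweep(cloud, 2, ctr)^2)) / sum(w))
    expect_equal(compute_rg(cloud, w), rg)
  }
})

test_that("zipper dimer puts the G motif at the interface under an exact
           two-fold", {
  d <- hs_dimer()
  expect_lt(symmetry_rmsd(d), 1e-6)
  ca1 <- d$helices[[1]]$ca
  ca2 <- d$helices[[2]]$ca
  d2 <- outer(rowSums(ca1^2), rowSums(ca2^2), `+`) - 2 * ca1 %*% t(ca2)
  resno <- d$helices[[1]]$resno
  overall_min <- sqrt(min(d2))
  g_min <- sqrt(min(d2[resno %in% c(271, 275, 279),
                       resno %in% c(271, 275, 279)]))
  expect_gte(overall_min, 3.0)       # clash floor respected
  expect_lte(g_min, overall_min + 1e-6)  # G motif attains the closest contact

  # widely separated helices cannot touch
  far <- hs_dimer(inter_axis_distance = 40)
  cafar1 <- far$helices[[1]]$ca
  cafar2 <- far$helices[[2]]$ca
  d2far <- outer(rowSums(cafar1^2), rowSums(cafar2^2), `+`) -
    2 * cafar1 %*% t(cafar2)
  expect_gt(sqrt(min(d2far)), 20)

  # both polarities assemble with exact symmetry
  expect_lt(symmetry_rmsd(hs_dimer(polarity = "antiparallel")), 1e-6)
})

test_that("dimer assembly fails loudly on clashes instead of relaxing", {
  expect_error(hs_dimer(inter_axis_distance = 4), "clash")
})

test_that("tetramer assembly respects symmetry, separation control and the
           parallel-axis theorem", {
  d <- hs_dimer()
  tp <- assemble_tetramer(d, "parallel")
  ta <- assemble_tetramer(d, "antiparallel")
  expect_lt(symmetry_rmsd(tp), 1e-6)
  expect_lt(symmetry_rmsd(ta), 1e-6)

  # the compact parallel stack is only slightly larger than one dimer
  expect_lt(compute_dmax(bundle_coords(tp)),
            1.25 * compute_dmax(bundle_coords(d)))
  # head-to-tail stacking extends the particle
  expect_gt(compute_dmax(bundle_coords(ta)),
            compute_dmax(bundle_coords(tp)))

  # requested center-of-mass separation is honoured exactly
  tps <- set_dimer_separation(tp, 48)
  a <- rbind(tps$helices[[1]]$ca, tps$helices[[2]]$ca)
  b <- rbind(tps$helices[[3]]$ca, tps$helices[[4]]$ca)
  expect_equal(sqrt(sum((colMeans(a) - colMeans(b))^2)), 48,
               tolerance = 1e-9)

  # Rg of the union obeys the parallel-axis theorem against the halves
  a <- rbind(tp$helices[[1]]$ca, tp$helices[[2]]$ca)
  b <- rbind(tp$helices[[3]]$ca, tp$helices[[4]]$ca)
  L <- parallel_axis_distance(compute_rg(rbind(a, b)), compute_rg(a),
                              compute_rg(b), 0.5)
  expect_equal(L, sqrt(sum((colMeans(a) - colMeans(b))^2)),
               tolerance = 1e-9)
})

test_that("crosslink propensities follow the logistic distance band and are
           monotone in distance", {
  tp <- assemble_tetramer(hs_dimer(), "parallel")
  xl <- predict_crosslinks(tp, xlink_positions)
  expect_equal(xl$score, 1 / (1 + exp((xl$distance - 6) / 1)))
  ord <- order(xl$distance)
  expect_equal(xl$score[ord], sort(xl$score, decreasing = TRUE))
  # d = d0 sits exactly at score 0.5 by the same functional form
  xl2 <- predict_crosslinks(tp, xlink_positions, d0 = xl$distance[1])
  expect_equal(xl2$score[xl2$position == xl$position[1]], 0.5)

  # missing positions give per-position error records, not exceptions
  xl3 <- predict_crosslinks(tp, c(274, 9999))
  expect_true(is.na(xl3$score[xl3$position == 9999]))
  expect_match(xl3$error[xl3$position == 9999], "not present")

  # distant dimers cannot crosslink anywhere
  tpd <- set_dimer_separation(tp, 100)
  expect_true(all(predict_crosslinks(tpd, xlink_positions)$score < 0.01))
})

test_that("the parallel model reproduces the measured crosslink ordering
           better than the antiparallel model", {
  d <- hs_dimer()
  score_of <- function(bundle) {
    xl <- predict_crosslinks(bundle, xlink_positions)
    setNames(xl$score, xl$position)[names(xlink_measured_tiers)]
  }
  sc_par <- score_of(assemble_tetramer(d, "parallel"))
  sc_anti <- score_of(assemble_tetramer(d, "antiparallel"))
  # T274C / Y277C rank above S266C / S270C on the parallel model
  expect_gt(min(sc_par[c("274", "277")]), max(sc_par[c("266", "270")]))
  rho_par <- cor(sc_par, xlink_measured_tiers, method = "spearman")
  rho_anti <- cor(sc_anti, xlink_measured_tiers, method = "spearman")
  expect_gt(rho_par, rho_anti)
})

test_that("PDB round trip preserves coordinates to format precision", {
  d <- hs_dimer()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_bundle_pdb(d, path)
  ca <- read_pdb_coords(path, "ca")
  expect_equal(nrow(ca), 86)
  expect_lt(max(abs(ca - bundle_coords(d, "ca"))), 1e-3)
})
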