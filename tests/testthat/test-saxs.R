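test_that("debye_profile matches closed forms and is rigid-motion
           invariant", {
  q <- seq(0.01, 0.5, length.out = 60)
  one <- debye_profile(matrix(c(1, 2, 3), 1), q, bead_weights = 2.5)
  expect_equal(one$intensity, rep(2.5^2, 60))

  two <- debye_profile(rbind(c(0, 0, 0), c(0, 0, 20)), q,
                       bead_weights = c(1.5, 1.5))
  closed <- 2 * 1.5^2 * (1 + sin(q * 20) / (q * 20))
  expect_equal(two$intensity, closed, tolerance = 1e-12)

  # q -> 0 limit handled analytically
  withq0 <- debye_profile(rbind(c(0, 0, 0), c(0, 0, 20)),
                          c(0, 0.01), bead_weights = c(1, 1))
  expect_equal(withq0$intensity[1], 4)

  set.seed(8)
  cloud <- matrix(rnorm(3 * 40, sd = 15), ncol = 3)
  base <- debye_profile(cloud, q)$intensity
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  moved <- sweep(cloud %*% R, 2, c(12, -4, 7), `+`)
  expect_equal(debye_profile(moved, q)$intensity, base,
               tolerance = 1e-9)
})

test_that("Guinier fits recover exact and simulated radii of gyration", {
  q <- seq(0.004, 0.2, length.out = 120)
  exact <- saxs_profile(q, 7.3 * exp(-q^2 * 28^2 / 3))
  fit <- guinier_fit(exact)
  expect_equal(fit$rg, 28, tolerance = 1e-6)
  expect_equal(fit$i0, 7.3, tolerance = 1e-6)

  # Debye-sum of any bead cloud has a Guinier Rg matching the coordinates
  set.seed(9)
  cloud <- matrix(rnorm(3 * 80, sd = 14), ncol = 3)
  prof <- debye_profile(cloud, seq(0.003, 0.15, length.out = 120))
  expect_equal(guinier_fit(prof)$rg, compute_rg(cloud), tolerance = 0.01)

  # sphere closed form: Rg = sqrt(3/5) R within 2%
  R <- 30
  profs <- sphere_profile(R, seq(0.005, 0.12, length.out = 80))
  expect_equal(guinier_fit(profs)$rg, sqrt(3 / 5) * R, tolerance = 0.02)

  flat <- saxs_profile(seq(0.01, 0.2, length.out = 50), rep(4, 50))
  expect_error(guinier_fit(flat), "slope")
})

test_that("pr_invert concentrates off-origin mass at the bead separation and
           fits its source profile", {
  q <- seq(0.01, 0.5, length.out = 200)
  prof <- debye_profile(rbind(c(0, 0, 0), c(0, 0, 25)), q)
  pr <- pr_invert(prof, 40)
  expect_equal(pr$p[1], 0)
  expect_equal(pr$p[length(pr$p)], 0)
  away <- pr$r > 10
  expect_lt(abs(pr$r[away][which.max(pr$p[away])] - 25), 2)

  # forward transform reproduces the input within the regularized residual
  beads <- sphere_beads(24, 5)
  qs <- seq(0.008, 0.3, length.out = 150)
  sp <- debye_profile(beads, qs)
  prs <- pr_invert(sp, 1.05 * compute_dmax(beads))
  back <- pr_forward(prs, qs)
  rel <- sqrt(mean((back$intensity - sp$intensity)^2)) /
    sqrt(mean(sp$intensity^2))
  expect_lt(rel, 0.02)
  # derived Rg consistent with the Guinier region within 3%
  expect_equal(attr(prs, "rg"), guinier_fit(sp)$rg, tolerance = 0.03)

  expect_error(pr_invert(prof, -5), "positive")
})

test_that("scan_dmax finds the particle dimension and is deterministic", {
  beads <- sphere_beads(30, 5)
  qs <- seq(0.008, 0.3, length.out = 150)
  prof <- debye_profile(beads, qs)
  sc <- scan_dmax(prof, c(30, 90), step = 2.5)
  expect_lt(abs(sc$dmax - compute_dmax(beads)) / compute_dmax(beads), 0.05)
  # misfit grows away from the optimum on the too-small side
  tr <- sc$trace
  expect_gt(tr$chi2[tr$dmax == 30], tr$chi2[tr$dmax == sc$dmax])
  expect_lt(tr$score[tr$dmax == 30], tr$score[tr$dmax == sc$dmax])
  # determinism
  sc2 <- scan_dmax(prof, c(30, 90), step = 2.5)
  expect_identical(sc$dmax, sc2$dmax)
  expect_identical(sc$trace, sc2$trace)

  # bead-model tetramer: scan optimum within 5% of the true Dmax
  tet <- gen_bead_model("tetramer", "parallel")
  pt <- debye_profile(tet$coords, seq(0.008, 0.35, length.out = 150))
  sct <- scan_dmax(pt, c(0.5, 1.5) * compute_dmax(tet$coords), step = 2.5)
  expect_lt(abs(sct$dmax - compute_dmax(tet$coords)) /
              compute_dmax(tet$coords), 0.05)

  expect_error(scan_dmax(prof, c(50, 40), 2), "increasing")
})

test_that("parallel_axis_distance inverts the printed relation and matches
           bead clouds", {
  expect_equal(parallel_axis_distance(20, 20, 20, 0.5), 0)
  expect_equal(parallel_axis_distance(20, 0, 0, 0.5), 40)
  expect_error(parallel_axis_distance(10, 30, 30, 0.5), "inconsistent")
  expect_error(parallel_axis_distance(10, 5, 5, 1), "between 0 and 1")

  set.seed(11)
  for (rep in 1:20) {
    r1 <- runif(1, 5, 40); r2 <- runif(1, 5, 40)
    f1 <- runif(1, 0.1, 0.9); L <- runif(1, 0, 80)
    rg <- sqrt(f1 * r1^2 + (1 - f1) * r2^2 + f1 * (1 - f1) * L^2)
    expect_equal(parallel_axis_distance(rg, r1, r2, f1), L,
                 tolerance = 1e-9)
  }

  # two bead clouds: theorem distance equals the center-of-mass distance
  set.seed(12)
  a <- matrix(rnorm(3 * 50, sd = 10), ncol = 3)
  b <- sweep(matrix(rnorm(3 * 50, sd = 7), ncol = 3), 2, c(35, 10, -8), `+`)
  L <- parallel_axis_distance(compute_rg(rbind(a, b)), compute_rg(a),
                              compute_rg(b), 0.5)
  expect_equal(L, sqrt(sum((colMeans(a) - colMeans(b))^2)),
               tolerance = 1e-9)
})

test_that("svd_efa deconvolves one- and two-component stacks and counts
           rank honestly", {
  tet <- gen_bead_model("tetramer", "parallel", decorate = TRUE)$coords
  q <- seq(0.008, 0.35, length.out = 100)

  g1 <- gen_secsaxs_frames(list(list(coords = tet, peak_center = 60,
                                     peak_width = 10)),
                           q = q, n_frames = 120, noise = 0.005, seed = 3)
  e1 <- svd_efa(g1$frames, 1)
  expect_gte(cosine_sim(e1$profiles[, 1], g1$profiles[, 1]), 0.999)
  expect_true(all(e1$concentrations >= 0))

  oct <- rbind(tet, sweep(tet, 2, c(95, 0, 0), `+`))
  g2 <- gen_secsaxs_frames(list(
    list(coords = oct, peak_center = 45, peak_width = 9, scale = 1),
    list(coords = tet, peak_center = 65, peak_width = 9, scale = 1.3)),
    q = q, n_frames = 120, noise = 0.01, seed = 7)
  e2 <- svd_efa(g2$frames, 2)
  sims <- vapply(1:2, function(k)
    max(cosine_sim(e2$profiles[, k], g2$profiles[, 1]),
        cosine_sim(e2$profiles[, k], g2$profiles[, 2])), 0)
  expect_true(all(sims >= 0.99))
  expect_true(all(e2$concentrations >= 0))
  expect_true(all(diff(e2$windows[, "entry"]) > 0))

  # requesting more components than the detectable rank errors with the rank
  expect_error(svd_efa(g1$frames, 4), "detectable")
  zero <- frame_matrix(matrix(0, 50, 40), seq_len(40) / 100)
  expect_error(svd_efa(zero, 1), "only 0 detectable")
})

test_that("scattering profile I/O round-trips and validates", {
  q <- seq(0.01, 0.3, length.out = 40)
  prof <- saxs_profile(q, exp(-q^2 * 100), sigma = rep(0.01, 40))
  path <- withr::local_tempfile(fileext = ".dat")
  write_saxs_dat(prof, path)
  back <- read_saxs_dat(path)
  expect_equal(back$q, prof$q)
  expect_equal(back$intensity, prof$intensity)
  expect_equal(back$sigma, prof$sigma)

  expect_error(saxs_profile(c(0.2, 0.1), c(1, 1)), "increasing")
  expect_error(saxs_profile(q, exp(-q), sigma = rep(0, 40)), "positive")
  expect_error(saxs_profile(q, rep(Inf, 40)), "finite")
})
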