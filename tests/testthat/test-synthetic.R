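test_that("CSR generator has Poisson counts, uniform positions, reproducibility", {
  w <- make_window(10)
  expect_equal(n_points(simulate_csr(0, w, seed = 1)), 0)
  expect_error(simulate_csr(-1, w), "non-negative")

  p1 <- simulate_csr(50, w, seed = 42)
  p2 <- simulate_csr(50, w, seed = 42)
  expect_identical(p1$x, p2$x)
  expect_true(all(in_window(p1$x, p1$y, w)))

  counts <- vapply(1:200, function(s) n_points(simulate_csr(100, w, seed = s)),
                   numeric(1))
  se <- sqrt(10000 / 200) # Poisson variance = mean
  expect_lt(abs(mean(counts) - 10000), 3 * se)
})

test_that("Thomas generator matches its closed-form K and count expectation", {
  w <- make_window(10)
  expect_equal(n_points(simulate_thomas(1, 0, 40, w, seed = 1)), 0)
  expect_error(simulate_thomas(0, 20, 40, w), "> 0")

  counts <- vapply(1:200, function(s)
    n_points(simulate_thomas(1, 20, 40, w, seed = s)), numeric(1))
  # mean = kappa * area * mu = 2000; var(N) for Thomas = mu^2*kappa*A + mean
  se <- sqrt((20^2 * 100 + 2000) / 200)
  expect_lt(abs(mean(counts) - 2000), 3 * se)

  radii <- seq(20, 400, by = 20)
  Ks <- vapply(1:40, function(s) {
    ripley_k(simulate_thomas(1, 20, 40, w, seed = 100 + s), radii,
             correction = "toroidal")$K
  }, numeric(length(radii)))
  expected <- thomas_K(radii, 1e-6, 40)
  # Monte-Carlo tolerance: 15% of the clustering excess + CSR baseline noise
  excess <- expected - pi * radii^2
  expect_true(all(abs(rowMeans(Ks) - expected) < 0.15 * excess + 3000))
})

test_that("two-colour modes produce the advertised cross-channel structure", {
  w <- make_window(5)
  tc <- simulate_two_color("colocalized", 50, 0, w, seed = 1)
  expect_identical(tc$ch1$x, tc$ch2$x)

  ts <- simulate_two_color("segregated", 50, 0, w, seed = 2)
  mid <- 2500
  expect_true(all(ts$ch1$x < mid))
  expect_true(all(ts$ch2$x >= mid))
  expect_error(simulate_two_color("weird", 50, 0, w), "arg")

  # cross-channel NND of independent CSR follows 1 - exp(-lambda pi r^2)
  ti <- simulate_two_color("independent", 50, 0, w, seed = 3)
  interior <- ti$ch1$x > 400 & ti$ch1$x < 4600 & ti$ch1$y > 400 & ti$ch1$y < 4600
  qa <- point_pattern(ti$ch1$x[interior], ti$ch1$y[interior], w)
  d <- nn_distances(qa, ti$ch2)
  lam <- 50 / 1e6 # nm^-2
  ks <- max(abs(stats::ecdf(d)(d) - (1 - exp(-lam * pi * d^2))))
  expect_lt(ks, 0.05)

  # jittered copies concentrate the cross NND near the Rayleigh mean
  tj <- simulate_two_color("colocalized", 50, 20, w, seed = 4)
  dj <- nn_distances(tj$ch1, tj$ch2)
  expect_lt(abs(mean(dj) - 20 * sqrt(pi / 2)) / (20 * sqrt(pi / 2)), 0.15)
})

test_that("adhesion scenes carry consistent ground-truth labels", {
  w <- obs_window(0, 0, 20000, 20000)
  cell <- cbind(c(2000, 18000, 18000, 2000), c(2000, 2000, 18000, 18000))
  adh <- list(cbind(c(4000, 7000, 7000, 4000), c(4000, 4000, 6000, 6000)))
  sc <- simulate_adhesion_scene(cell, adh, 500, 0, 5, w, seed = 1)
  expect_true(all(sc$paxillin_in_adhesion))
  lab <- assign_points_to_rois(sc$paxillin, sc$rois)
  expect_true(all(lab == "in_adhesion"))

  bad <- list(cbind(c(1000, 3000, 3000, 1000), c(4000, 4000, 6000, 6000)))
  expect_error(simulate_adhesion_scene(cell, bad, 500, 0, 5, w), "escapes")

  sc2 <- simulate_adhesion_scene(cell, adh, 1000, 10, 5, w, seed = 2)
  expect_identical(as.logical(assign_points_to_rois(sc2$paxillin, sc2$rois) ==
                                "in_adhesion"),
                   sc2$paxillin_in_adhesion)
})

test_that("blinking renderer conserves photons and reports true emissions", {
  w <- obs_window(0, 0, 3200, 3200)
  pp <- photophysics_params(mean_photons_per_frame = 2000, on_time_mean = 1,
                            n_blinks_mean = 1, off_gap_mean = 10,
                            background_rate = 2)
  # pure background
  empty <- point_pattern(numeric(0), numeric(0), w)
  st0 <- render_blinking_stack(empty, pp, 150, 100, 5, seed = 1)
  expect_lt(abs(mean(st0$frames) - 2), 3 * sqrt(2 / length(st0$frames)))
  expect_equal(nrow(st0$truth), 0)

  # deterministic photophysics (mean 1 => degenerate geometric): one
  # emission row per molecule
  mols <- point_pattern(c(800, 1600, 2400), c(800, 1600, 2400), w)
  st1 <- render_blinking_stack(mols, pp, 150, 100, 50, seed = 2)
  expect_equal(nrow(st1$truth), 3)
  expect_setequal(st1$truth$molecule, 1:3)

  # noiseless photon conservation to < 0.1 %
  one <- point_pattern(1630, 1580, w)
  stn <- render_blinking_stack(one, pp, 150, 100, 1, seed = 3, noise = FALSE)
  signal <- sum(stn$frames) - 2 * prod(dim(stn$frames)[1:2])
  expect_lt(abs(signal - 2000) / 2000, 0.001)

  expect_warning(render_blinking_stack(one, pp, 10, 100, 1, seed = 4),
                 "undersampled")
})

test_that("drift trajectories validate and interpolate linearly", {
  expect_error(drift_trajectory(c(0, 10, 10), c(0, 1, 2), c(0, 0, 0)),
               "strictly increasing")
  expect_error(drift_trajectory(c(0, 10), c(5, 1), c(0, 0)), "frame 0")
  tr <- drift_trajectory(c(0, 100, 200), c(0, 10, -10), c(0, 5, 5))
  d <- drift_at(tr, c(0, 50, 150))
  expect_equal(unname(d[, "dx"]), c(0, 5, 0))
  expect_equal(unname(d[, "dy"]), c(0, 2.5, 5))
  expect_error(drift_at(tr, 500), "domain")
})
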