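test_that("event detection finds rendered emitters and nothing on flat frames", {
  w <- obs_window(0, 0, 3200, 3200)
  # perfectly uniform frame: I - M = 0 everywhere
  flat <- frame_stack(array(100, c(32, 32, 1)), 100)
  expect_equal(nrow(detect_events(flat)), 0)
  # zero-frame stack
  empty <- frame_stack(array(0, c(32, 32, 0)), 100)
  expect_equal(nrow(detect_events(empty)), 0)

  pp <- photophysics_params(mean_photons_per_frame = 5000, on_time_mean = 1,
                            n_blinks_mean = 1, background_rate = 2)
  mol <- point_pattern(1650, 1450, w)
  st <- render_blinking_stack(mol, pp, 150, 100, 1, seed = 1, noise = FALSE)
  cand <- detect_events(st)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$px, 16)
  expect_equal(cand$py, 14)
})

test_that("PSF fits recover position, photons and width on noiseless emitters", {
  w <- obs_window(0, 0, 3200, 3200)
  cam <- camera_model(100, 1)
  cfg <- detection_config()
  pp <- photophysics_params(mean_photons_per_frame = 2000, on_time_mean = 1,
                            n_blinks_mean = 1, background_rate = 1)
  cases <- list(c(1650, 1550), # pixel centre
                c(1680, 1530)) # sub-pixel offset (+0.3, -0.2) px
  for (pos in cases) {
    mol <- point_pattern(pos[1], pos[2], w)
    st <- render_blinking_stack(mol, pp, 150, 100, 1, seed = 1, noise = FALSE)
    cand <- detect_events(st, cfg)
    fit <- fit_psf(st$frames[, , 1], cand, cam, cfg, window = st$window)
    expect_lt(abs(fit$x_nm - pos[1]), 1)   # < 0.01 px
    expect_lt(abs(fit$y_nm - pos[2]), 1)
    expect_lt(abs(fit$photons - 2000) / 2000, 0.01)
    expect_lt(abs(fit$sigma_nm - 150), 2)
    expect_true(fit$converged)
  }
})

test_that("overlapping emitters are fitted jointly", {
  w <- obs_window(0, 0, 3200, 3200)
  pp <- photophysics_params(mean_photons_per_frame = 3000, on_time_mean = 1,
                            n_blinks_mean = 1, background_rate = 2)
  mols <- point_pattern(c(1450, 1950), c(1500, 1700), w)
  st <- render_blinking_stack(mols, pp, 150, 100, 1, seed = 2, noise = FALSE)
  tab <- localize_stack(st)
  expect_equal(nrow(tab), 2)
  err <- vapply(seq_len(2), function(i)
    min(sqrt((tab$x_nm - mols$x[i])^2 + (tab$y_nm - mols$y[i])^2)), numeric(1))
  expect_true(all(err < 5))
})

test_that("the precision formula matches its closed form and scaling laws", {
  expect_equal(localization_precision(400, sqrt(120^2 - 100^2 / 12), 0, 100), 8)
  p1 <- localization_precision(500, 150, 0, 100)
  p2 <- localization_precision(1000, 150, 0, 100)
  expect_equal(p1 / p2, sqrt(2))
  expect_equal(localization_precision(1000, 150, 3, 100),
               oracle_mortensen(1000, 150, 3, 100))
  expect_error(localization_precision(0, 150), "> 0")
  # monotone: decreasing in N, increasing in b
  Ns <- c(200, 500, 1000, 5000)
  expect_true(all(diff(localization_precision(Ns, 150, 2, 100)) < 0))
  bs <- c(0, 1, 3, 10)
  expect_true(all(diff(localization_precision(1000, 150, bs, 100)) > 0))
})

test_that("grouping follows the on-time and off-gap chaining rules", {
  base <- function(frames, x, y) {
    data.frame(frame = frames, x_nm = x, y_nm = y, photons = 100,
               precision_nm = 10, channel = "ch1")
  }
  g1 <- group_localizations(base(10, 500, 500))
  expect_equal(nrow(g1$merged), 1)
  expect_equal(g1$merged$n_events, 1)

  # 50 nm apart in consecutive frames: one molecule
  g2 <- group_localizations(base(c(10, 11), c(500, 550), c(500, 500)))
  expect_equal(nrow(g2$merged), 1)

  # same position, frames 10 and 70: dark gap 59 > 50 -> two molecules
  g3 <- group_localizations(base(c(10, 70), c(500, 500), c(500, 500)))
  expect_equal(nrow(g3$merged), 2)
  # gap exactly 50 (frames 10 and 61) still chains
  g4 <- group_localizations(base(c(10, 61), c(500, 500), c(500, 500)))
  expect_equal(nrow(g4$merged), 1)

  # a run longer than max_on splits conservatively
  g5 <- group_localizations(base(0:6, rep(500, 7), rep(500, 7)))
  expect_equal(nrow(g5$merged), 2)

  # never merges beyond the radius
  g6 <- group_localizations(base(c(10, 11), c(500, 650), c(500, 500)))
  expect_equal(nrow(g6$merged), 2)
})

test_that("grouping conserves photons and is order-insensitive", {
  set.seed(51)
  n <- 60
  tab <- data.frame(frame = sort(sample(0:80, n, replace = TRUE)),
                    x_nm = runif(n, 0, 4000), y_nm = runif(n, 0, 4000),
                    photons = rpois(n, 800), precision_nm = 10,
                    channel = "ch1")
  g <- group_localizations(tab)
  expect_equal(sum(g$merged$photons), sum(tab$photons))
  expect_equal(sum(g$merged$n_events), n)
  # permute rows within frames: group count unchanged
  perm <- order(tab$frame, runif(n))
  g2 <- group_localizations(tab[perm, ])
  expect_equal(nrow(g2$merged), nrow(g$merged))
  # no two members of one group farther apart in time than allowed
  for (id in g$merged$group_id) {
    fr <- sort(tab$frame[g$labels == id])
    if (length(fr) > 1) expect_true(all(diff(fr) <= 51))
  }
})

test_that("fiducial drift estimation recovers injected trajectories", {
  w <- obs_window(0, 0, 3200, 3200)
  pp <- photophysics_params(background_rate = 10)
  fid <- point_pattern(c(800, 2300), c(900, 2200), w)
  empty <- point_pattern(numeric(0), numeric(0), w)
  n_fr <- 400
  truth <- drift_trajectory(c(0, n_fr - 1),
                            c(0, 0.5 * (n_fr - 1)), c(0, -0.3 * (n_fr - 1)))
  st <- render_blinking_stack(empty, pp, 150, 100, n_fr, drift = truth,
                              fiducials = fid, seed = 6)
  tab <- localize_stack(st)
  # stationary fiducial control
  st0 <- render_blinking_stack(empty, pp, 150, 100, 50, fiducials = fid,
                               seed = 7)
  est0 <- estimate_drift(localize_stack(st0), cbind(fid$x, fid$y), 50)
  expect_lt(max(abs(drift_at(est0, 0:49))), 1.5)

  est1 <- estimate_drift(tab, cbind(fid$x[1], fid$y[1]), n_fr)
  est2 <- estimate_drift(tab, cbind(fid$x, fid$y), n_fr)
  tr <- drift_at(truth, 0:(n_fr - 1))
  for (est in list(est1, est2)) {
    er <- drift_at(est, 0:(n_fr - 1))
    slope <- (er[n_fr, "dx"] - er[1, "dx"]) / (n_fr - 1)
    expect_lt(abs(slope - 0.5) / 0.5, 0.05)
    expect_lt(sqrt(mean((er - tr)^2)), 5)
  }
  # equal-drift fiducials average to (almost) the single-fiducial answer
  expect_lt(max(abs(drift_at(est1, 0:(n_fr - 1)) -
                      drift_at(est2, 0:(n_fr - 1)))), 2)
  expect_error(estimate_drift(tab, cbind(10000, 10000), n_fr), "fiducial")

  # correction inverts injection
  corr <- apply_drift_correction(tab, truth)
  recon <- apply_drift_correction(corr,
    drift_trajectory(truth$frames, -truth$dx, -truth$dy))
  expect_equal(recon$x_nm, tab$x_nm, tolerance = 1e-12)
  zero <- drift_trajectory(c(0, n_fr - 1), c(0, 0), c(0, 0))
  expect_equal(apply_drift_correction(tab, zero)$x_nm, tab$x_nm)
})
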