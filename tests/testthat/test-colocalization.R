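test_that("density gradients equal brute-force circle counts", {
  w <- make_window(1)
  a <- point_pattern(c(500, 520, 560, 700, 900), c(500, 500, 500, 500, 500), w)
  b <- point_pattern(c(510, 540, 800), c(500, 500, 500), w, "ch2")
  radii <- c(25, 50, 100, 250, 450)
  g <- density_gradients(500, 500, a, b, radii, self_index = 1)
  same_counts <- c(1, 1, 2, 3, 4) # 520; then 560; then 700; then 900
  other_counts <- c(1, 2, 2, 2, 3)
  expect_equal(g$same, (same_counts / (pi * radii^2)) /
                 (same_counts[5] / (pi * 450^2)))
  expect_equal(g$other, (other_counts / (pi * radii^2)) /
                 (other_counts[5] / (pi * 450^2)))
  expect_true(all(g$same >= 0) && all(g$other >= 0))
  expect_error(density_gradients(0, 0, a, point_pattern(numeric(0), numeric(0), w),
                                 radii), "empty")
})

test_that("identical channels score DoC = 1 exactly; scores stay within bounds", {
  w <- make_window(3)
  a <- simulate_csr(100, w, seed = 41)
  b <- point_pattern(a$x, a$y, w, "ch2")
  res <- doc_scores(a, b)
  inc <- res[res$defined & res$edge_ok, ]
  expect_true(all(inc$rho_s == 1))
  expect_true(all(inc$doc == 1))
  expect_true(all(inc$nnd_nm == 0))
  # attenuation never amplifies: |doc| <= |rho_s|
  tc <- simulate_two_color("independent", 100, 0, w, seed = 42)
  r2 <- doc_scores(tc$ch1, tc$ch2)
  ok <- r2$defined
  expect_true(all(abs(r2$doc[ok]) <= abs(r2$rho_s[ok]) + 1e-12))
  expect_true(all(r2$doc >= -1 & r2$doc <= 1))
  # channel-swap symmetry of the identity case
  res_ba <- doc_scores(b, a)
  expect_equal(sort(res$doc[res$defined]), sort(res_ba$doc[res_ba$defined]))
})

test_that("DoC is invariant to a joint rigid motion of both channels", {
  w <- make_window(2)
  tc <- simulate_two_color("colocalized", 100, 20, w, seed = 43,
                           base = "clustered")
  res <- doc_scores(tc$ch1, tc$ch2)
  # rotate both channels by 90 degrees about the window centre
  rot <- function(p, ch) {
    cx <- 1000; cy <- 1000
    point_pattern(cx - (p$y - cy), cy + (p$x - cx), w, ch)
  }
  res_r <- doc_scores(rot(tc$ch1, "ch1"), rot(tc$ch2, "ch2"))
  expect_equal(res_r$doc, res$doc, tolerance = 1e-12)
  # translate jointly (enlarged window so shifted points stay inside)
  w2 <- obs_window(-100, -100, 2100, 2100)
  shift <- function(p, ch) point_pattern(p$x + 5, p$y - 7, w2, ch)
  res_t <- doc_scores(shift(tc$ch1, "ch1"), shift(tc$ch2, "ch2"))
  # edge-exclusion flags can flip for points within 5-7 nm of the guard,
  # so compare per-molecule scores, which are geometry-invariant
  expect_equal(res_t$rho_s, res$rho_s, tolerance = 1e-12)
  expect_equal(res_t$nnd_nm, res$nnd_nm, tolerance = 1e-9)
})

test_that("constant gradients are flagged undefined and excluded from summaries", {
  w <- make_window(2)
  # two far-apart lone molecules: no neighbours within 500 nm
  a <- point_pattern(c(300, 1700), c(300, 1700), w)
  b <- point_pattern(c(320, 1680), c(300, 1700), w, "ch2")
  res <- doc_scores(a, b, edge_handling = "none")
  expect_true(all(!res$defined))
  expect_true(all(res$doc == 0))
  expect_error(doc_summary(res), "no scored molecules")
})

test_that("colocalised fraction counts thresholded scores", {
  fake <- structure(
    data.frame(channel = "a", doc = c(0.5, 0.3, 0.9, -0.2),
               rho_s = 1, nnd_nm = 0, defined = TRUE, edge_ok = TRUE),
    class = c("doc_result", "data.frame"))
  expect_equal(fraction_colocalized(fake, 0.4), 0.5)
  fake$doc <- rep(1, 4)
  expect_equal(fraction_colocalized(fake, 0.4), 1)
  fake$doc <- rep(0, 4)
  expect_equal(fraction_colocalized(fake, 0.4), 0)
})
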