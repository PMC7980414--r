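test_that("grid-aligned single-pixel subfoci give exact distances", {
  focus <- fake_set(list(rbind(c(10, 10))), dims = c(20L, 20L))$clusters[[1]]
  a <- fake_set(list(rbind(c(8, 10))), dims = c(20L, 20L))
  b <- fake_set(list(rbind(c(13, 10))), dims = c(20L, 20L))  # 5 px = 100 nm
  s <- subfoci_distance(focus, a, b, capture_radius = 300)
  expect_equal(s$d, 100)
  s0 <- subfoci_distance(focus, a, a, capture_radius = 300)
  expect_equal(s0$d, 0)
})

test_that("a channel without intensity in the window is skipped with a reason", {
  focus <- fake_set(list(rbind(c(5, 5))), dims = c(40L, 40L))$clusters[[1]]
  a <- fake_set(list(rbind(c(5, 6))), dims = c(40L, 40L))
  b <- fake_set(list(rbind(c(39, 39))), dims = c(40L, 40L))  # far away
  s <- subfoci_distance(focus, a, b, capture_radius = 100)
  expect_true(is.na(s$d))
  expect_match(s$skip_reason, "no_B_intensity")
})

test_that("rendered blobs planted 180 nm apart measure within half a pixel diagonal", {
  roi <- unit_square_roi(3000)
  cfg <- run_config()
  withr::local_seed(55)
  mk <- function(cx) loc_table(rnorm(60, cx, 8), rnorm(60, 1500, 8))
  na <- loc_table(rnorm(300, 1500, 80), rnorm(300, 1500, 80))
  seg <- function(tb) segment_clusters(
    render(tb, roi, pixel_size = 20, smoothing_sigma = cfg$smoothing_sigma),
    pct_threshold(90), min_area = 3)
  sN <- seg(na); sA <- seg(mk(1500 - 90)); sB <- seg(mk(1500 + 90))
  d <- measure_pair_distances(sN, sA, sB, capture_radius = 300)
  expect_equal(nrow(d), length(sN$clusters))
  expect_lt(abs(mean(d$d_nm) - 180), sqrt(2) * 20 / 2)
})

test_that("fewer than 20 samples refuse to fit", {
  expect_error(fit_distance_distribution(runif(10, 0, 100)),
               "need >= 20")
})

test_that("a single Gaussian sample selects k = 1 and recovers its mean", {
  withr::local_seed(56)
  d <- pmax(0.1, rnorm(500, 60, 25))
  f <- fit_distance_distribution(d)
  expect_equal(f$k, 1)
  expect_lt(abs(f$components$mean - 60), 3 * 25 / sqrt(500))
  expect_equal(sum(f$components$weight), 1)
})

test_that("a bimodal sample selects k = 2 and recovers both means", {
  withr::local_seed(57)
  d <- c(pmax(0.1, rnorm(300, 60, 25)), rnorm(300, 220, 40))
  f <- fit_distance_distribution(d)
  expect_equal(f$k, 2)
  expect_lt(abs(f$components$mean[1] - 60), 3 * 25 / sqrt(300))
  expect_lt(abs(f$components$mean[2] - 220), 3 * 40 / sqrt(300))
  expect_true(all(diff(f$components$mean) > 0))
  expect_equal(nrow(f$candidates), 2)
})

test_that("fitting is scale-consistent", {
  withr::local_seed(58)
  d <- pmax(0.1, rnorm(400, 80, 20))
  f1 <- fit_distance_distribution(d, bin_width = 20)
  f2 <- fit_distance_distribution(3 * d, bin_width = 60)
  expect_equal(f2$components$mean, 3 * f1$components$mean,
               tolerance = 1e-6)
  expect_equal(f2$components$sd, 3 * f1$components$sd, tolerance = 1e-6)
})

test_that("model methods are mutually consistent", {
  withr::local_seed(59)
  d <- c(pmax(0.1, rnorm(250, 50, 20)), rnorm(250, 230, 35))
  f <- fit_distance_distribution(d)
  expect_equal(unname(coef(f)[, "weight"]), f$components$weight)
  dens <- predict(f, c(50, 230))
  expect_true(all(dens > 0))
  expect_length(residuals(f), length(f$histogram$mids))
  sims <- simulate(f, nsim = 200, seed = 1)
  expect_length(sims, 200)
  expect_identical(sims, simulate(f, nsim = 200, seed = 1))
})

test_that("proximal/distal/mixed calls follow the component rule", {
  mk_fit <- function(w, mu, sd) {
    structure(list(k = length(w),
                   components = data.frame(weight = w, mean = mu, sd = sd),
                   samples = rnorm(50, mu[1], 5),
                   proximal_cutoff = 135), class = "distance_fit")
  }
  expect_equal(classify_proximal_distal(mk_fit(1, 70, 20))$call, "proximal")
  expect_equal(classify_proximal_distal(mk_fit(1, 260, 30))$call, "distal")
  expect_equal(classify_proximal_distal(
    mk_fit(c(0.5, 0.5), c(70, 260), c(20, 30)))$call, "mixed")
  expect_equal(classify_proximal_distal(
    mk_fit(c(0.9, 0.1), c(70, 260), c(20, 30)))$call, "proximal")
  bl <- structure(list(proximal_cutoff = 100), class = "distance_fit")
  expect_equal(classify_proximal_distal(mk_fit(1, 120, 20),
                                        baseline = bl)$call, "distal")
})

test_that("association maps integrate to one and are y-symmetric", {
  withr::local_seed(60)
  d <- c(pmax(0.1, rnorm(250, 60, 25)), rnorm(250, 220, 40))
  f <- fit_distance_distribution(d)
  m <- association_map(f, grid_step = 5)
  expect_equal(sum(m$grid) * m$grid_step^2, 1, tolerance = 1e-6)
  expect_equal(m$grid, m$grid[, rev(seq_along(m$y))], tolerance = 1e-12)
  marg <- rowSums(m$grid) * m$grid_step
  mix <- predict(f, m$x)
  mix <- mix / (sum(mix) * m$grid_step)
  expect_equal(marg, mix, tolerance = 1e-4)
})

test_that("a zero-mean single component is maximal at the origin", {
  f <- structure(list(k = 1,
                      components = data.frame(weight = 1, mean = 0,
                                              sd = 30),
                      samples = abs(rnorm(50, 0, 30)),
                      proximal_cutoff = 135), class = "distance_fit")
  m <- association_map(f, grid_step = 5)
  peak <- which(m$grid == max(m$grid), arr.ind = TRUE)
  expect_equal(m$x[peak[1]], 0, tolerance = 5)
  expect_equal(m$y[peak[2]], 0, tolerance = 5)
})

test_that("undersampled or truncated association grids are rejected", {
  f <- structure(list(k = 1,
                      components = data.frame(weight = 1, mean = 100,
                                              sd = 20),
                      samples = rnorm(50, 100, 20),
                      proximal_cutoff = 135), class = "distance_fit")
  expect_error(association_map(f, grid_step = 25), "undersampled")
  expect_error(association_map(f, extent = 120), "does not cover")
})

test_that("distances are invariant under global rotation and translation", {
  withr::local_seed(61)
  roi <- unit_square_roi(3000)
  cfg <- run_config()
  base_na <- cbind(rnorm(300, 1200, 80), rnorm(300, 1200, 80))
  base_a <- cbind(rnorm(60, 1120, 8), rnorm(60, 1200, 8))
  base_b <- cbind(rnorm(60, 1290, 8), rnorm(60, 1200, 8))
  th <- pi / 7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xf <- function(m) sweep(sweep(m, 2, c(1200, 1200)) %*% t(R), 2,
                          c(1500, 1400), "+")
  seg <- function(m) segment_clusters(
    render(loc_table(m[, 1], m[, 2]), roi, pixel_size = 20,
           smoothing_sigma = cfg$smoothing_sigma),
    pct_threshold(90), 3)
  d1 <- measure_pair_distances(seg(base_na), seg(base_a), seg(base_b), 300)
  d2 <- measure_pair_distances(seg(xf(base_na)), seg(xf(base_a)),
                               seg(xf(base_b)), 300)
  expect_equal(nrow(d1), 1)
  expect_equal(nrow(d2), 1)
  # pixelation moves centroids by at most ~half a pixel diagonal each
  expect_lt(abs(d1$d_nm - d2$d_nm), 2 * sqrt(2) * 20 / 2)
})
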