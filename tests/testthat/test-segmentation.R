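test_that("a single bright pixel yields one cluster with exact geometry", {
  g <- matrix(0, 10, 10); g[4, 6] <- 5
  s <- segment_clusters(fake_image(g), threshold = 1, min_area = 1)
  expect_length(s$clusters, 1)
  cl <- s$clusters[[1]]
  expect_equal(cl$centroid, c(3.5 * 20, 5.5 * 20))
  expect_equal(cl$area_nm2, 400)
  expect_equal(cl$total_intensity, 5)
})

test_that("two blobs separated by sub-threshold pixels are two clusters", {
  # centers 100 nm apart on a 20 nm grid (5 px), 3x3 blobs with a gap
  g <- matrix(0, 20, 20)
  g[4:6, 9:11] <- 4
  g[9:11, 9:11] <- 4
  g[7:8, 10] <- 1  # bridge below threshold
  s <- segment_clusters(fake_image(g), threshold = 2, min_area = 1)
  expect_length(s$clusters, 2)
  cents <- t(sapply(s$clusters, `[[`, "centroid"))
  expect_equal(abs(diff(cents[, 1])), 100)
})

test_that("segmentation equals a brute-force flood-fill oracle on random images", {
  withr::local_seed(20)
  for (rep in 1:10) {
    g <- matrix(rpois(900, 0.8), 30, 30)
    thr <- 2
    s <- segment_clusters(fake_image(g), threshold = thr, min_area = 1)
    lab <- flood_components(g >= thr & g > 0)
    nx <- 30L
    got <- lapply(s$clusters, function(cl)
      sort((cl$pixels[, 2] - 1L) * nx + cl$pixels[, 1]))
    got <- got[order(vapply(got, min, 1L))]
    expect_equal(got, component_sets(lab))
  }
})

test_that("min_area filters small components and ties at threshold are kept", {
  g <- matrix(0, 10, 10)
  g[2, 2] <- 3              # 1 px
  g[5:7, 5] <- 3            # 3 px
  s <- segment_clusters(fake_image(g), threshold = 3, min_area = 3)
  expect_length(s$clusters, 1)
  expect_equal(nrow(s$clusters[[1]]$pixels), 3)
})

test_that("percentile threshold on an all-zero image gives an empty set", {
  s <- segment_clusters(fake_image(matrix(0, 5, 5)), pct_threshold(90))
  expect_length(s$clusters, 0)
})

test_that("raising the threshold never increases total segmented area", {
  withr::local_seed(21)
  g <- matrix(rpois(900, 1.5), 30, 30)
  areas <- vapply(1:5, function(thr) {
    s <- segment_clusters(fake_image(g), threshold = thr, min_area = 1)
    sum(vapply(s$clusters, `[[`, 1, "area_nm2"))
  }, 1)
  expect_true(all(diff(areas) <= 0))
})

test_that("centroids match a direct weighted sum on an asymmetric cluster", {
  g <- matrix(0, 10, 10)
  px <- rbind(c(3, 3), c(4, 3), c(5, 3), c(4, 4), c(4, 5))
  vals <- c(1, 5, 2, 3, 4)
  g[px] <- vals
  s <- segment_clusters(fake_image(g), threshold = 1, min_area = 1)
  expect_length(s$clusters, 1)
  cx <- sum((px[, 1] - 0.5) * 20 * vals) / sum(vals)
  cy <- sum((px[, 2] - 0.5) * 20 * vals) / sum(vals)
  expect_equal(s$clusters[[1]]$centroid, c(cx, cy), tolerance = 1e-9)
  expect_equal(centroid_of(s$clusters[[1]], fake_image(g)), c(cx, cy),
               tolerance = 1e-9)
})

test_that("centroid_of demands positive intensity and in-range pixels", {
  g <- matrix(0, 5, 5)
  cl <- list(cluster_id = 1, pixels = rbind(c(2, 2)))
  expect_error(centroid_of(cl, fake_image(g)), "zero total intensity")
  cl2 <- list(cluster_id = 1, pixels = rbind(c(9, 9)))
  expect_error(centroid_of(cl2, fake_image(g)), "outside image extent")
})

test_that("segmentation is equivariant to whole-pixel translations", {
  withr::local_seed(22)
  roi <- unit_square_roi(2000)
  n <- 150
  x <- runif(n, 400, 1200); y <- runif(n, 400, 1200)
  cfg_thr <- 1
  img1 <- render(loc_table(x, y), roi, pixel_size = 20)
  img2 <- render(loc_table(x + 5 * 20, y + 3 * 20), roi, pixel_size = 20)
  s1 <- segment_clusters(fake_image(img1$grid), cfg_thr, min_area = 1)
  s2 <- segment_clusters(fake_image(img2$grid), cfg_thr, min_area = 1)
  c1 <- t(sapply(s1$clusters, `[[`, "centroid"))
  c2 <- t(sapply(s2$clusters, `[[`, "centroid"))
  ord1 <- order(c1[, 1], c1[, 2]); ord2 <- order(c2[, 1], c2[, 2])
  expect_equal(c2[ord2, , drop = FALSE],
               c1[ord1, , drop = FALSE] +
                 matrix(rep(c(100, 60), each = nrow(c1)), ncol = 2),
               tolerance = 1e-9)
})

test_that("two point sources are resolved at 100 nm but merged at 40 nm", {
  # the ~80 nm resolvability budget: default pipeline settings must call
  # two emitters two clusters at >= 100 nm and one cluster at <= 40 nm
  roi <- unit_square_roi(2000)
  cfg <- run_config()
  emit <- function(cx, sep) {
    withr::with_seed(33, {
      x <- c(rnorm(40, cx - sep / 2, 7), rnorm(40, cx + sep / 2, 7))
      y <- rnorm(80, 1000, 7)
      loc_table(x, y)
    })
  }
  seg <- function(sep) {
    img <- render(emit(1000, sep), roi, pixel_size = cfg$pixel_size,
                  smoothing_sigma = cfg$smoothing_sigma)
    length(segment_clusters(img, pct_threshold(cfg$threshold_percentile),
                            min_area = cfg$min_area)$clusters)
  }
  expect_equal(seg(140), 2)
  expect_equal(seg(100), 2)
  expect_equal(seg(40), 1)
})
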