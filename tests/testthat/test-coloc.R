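test_that("count_overlaps handles empty sets and the two-pixel textbook case", {
  empty <- fake_set(list(), dims = c(10L, 10L))
  a <- fake_set(list(rbind(c(1, 1), c(1, 2))), dims = c(10L, 10L))
  b <- fake_set(list(rbind(c(1, 2), c(1, 3))), dims = c(10L, 10L))
  expect_equal(count_overlaps(empty, b)$n_overlapping_pairs, 0)
  expect_equal(count_overlaps(a, empty)$overlap_area_nm2, 0)
  ov <- count_overlaps(a, b)
  expect_equal(ov$n_overlapping_pairs, 1)
  expect_equal(ov$overlap_area_nm2, 400)
  expect_equal(ov$n_clusters_A_with_overlap, 1)
})

test_that("count_overlaps refuses mismatched rendering grids", {
  a <- fake_set(list(rbind(c(1, 1))), dims = c(10L, 10L), pixel_size = 20)
  b <- fake_set(list(rbind(c(1, 1))), dims = c(10L, 10L), pixel_size = 10)
  expect_error(count_overlaps(a, b), "different rendering grids")
})

test_that("overlap pairs match the all-pairs intersection oracle", {
  withr::local_seed(30)
  for (rep in 1:10) {
    a <- random_set(20, dims = c(30L, 30L))
    b <- random_set(20, dims = c(30L, 30L))
    got <- count_overlaps(a, b)$pairs
    got <- got[order(got$idA, got$idB), c("idA", "idB", "shared_px")]
    rownames(got) <- NULL
    want <- overlap_oracle(a, b)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("randomization preserves shape, area and intensity for any seed", {
  withr::local_seed(31)
  set <- random_set(10, dims = c(40L, 40L))
  roi <- unit_square_roi(40 * 20)
  for (seed in c(1L, 99L)) {
    out <- randomize_channel(set, roi, rng_seed = seed)
    expect_length(out$clusters, length(set$clusters))
    for (k in seq_along(set$clusters)) {
      expect_equal(out$clusters[[k]]$area_nm2, set$clusters[[k]]$area_nm2)
      expect_equal(out$clusters[[k]]$total_intensity,
                   set$clusters[[k]]$total_intensity)
      rel <- function(cl) {
        ij <- cl$pixels
        m <- cbind(ij[, 1] - min(ij[, 1]), ij[, 2] - min(ij[, 2]))
        m[order(m[, 1], m[, 2]), , drop = FALSE]
      }
      expect_equal(rel(out$clusters[[k]]), rel(set$clusters[[k]]))
    }
  }
})

test_that("randomization is deterministic under a seed and varies across seeds", {
  withr::local_seed(32)
  set <- random_set(8, dims = c(40L, 40L))
  roi <- unit_square_roi(40 * 20)
  r1 <- randomize_channel(set, roi, rng_seed = 7L)
  r2 <- randomize_channel(set, roi, rng_seed = 7L)
  r3 <- randomize_channel(set, roi, rng_seed = 8L)
  pix <- function(s) lapply(s$clusters, `[[`, "pixels")
  expect_identical(pix(r1), pix(r2))
  expect_false(identical(pix(r1), pix(r3)))
})

test_that("an ROI equal to the cluster bounding box forces the placement", {
  set <- fake_set(list(rbind(c(1, 1), c(2, 1), c(2, 2))), dims = c(2L, 2L))
  roi <- unit_square_roi(2 * 20)
  out <- randomize_channel(set, roi, rng_seed = 3L)
  expect_equal(out$clusters[[1]]$pixels, set$clusters[[1]]$pixels)
})

test_that("an oversized cluster triggers an informative placement error", {
  set <- fake_set(list(cbind(1:5, rep(1L, 5))), dims = c(5L, 3L))
  roi <- roi_polygon(cbind(c(0, 40, 40, 0), c(0, 0, 60, 60)))
  expect_error(randomize_channel(set, roi, rng_seed = 1L),
               "larger than the ROI|no in-ROI placement")
})

test_that("zero real overlaps with nonzero random mean gives ratio 0", {
  a <- fake_set(list(rbind(c(2, 2))), dims = c(6L, 6L))
  b <- fake_set(list(rbind(c(5, 5))), dims = c(6L, 6L))
  roi <- unit_square_roi(6 * 20)
  res <- coloc_ratio(a, b, roi, n_iterations = 200, rng_seed = 1L)
  expect_gt(res$random_mean[["n_pairs"]], 0)
  expect_equal(res$ratio_count, 0)
})

test_that("self-colocalized single cluster matches the analytic placement odds", {
  # A = B = one pixel in a 10x10-px square ROI: real overlap 1; a random
  # 1-px placement hits A with probability 1/100, so the ratio estimates
  # the number of valid anchor positions (100)
  a <- fake_set(list(rbind(c(5, 5))), dims = c(10L, 10L))
  roi <- unit_square_roi(10 * 20)
  res <- coloc_ratio(a, a, roi, n_iterations = 3000, rng_seed = 11L)
  expect_equal(res$real$n_overlapping_pairs, 1)
  p_hat <- res$random_mean[["n_pairs"]]
  se <- sqrt(0.01 * 0.99 / 3000)
  expect_lt(abs(p_hat - 0.01), 3 * se)
  expect_gt(res$ratio_count, 1)
})

test_that("the ratio is invariant under whole-scene rigid translation", {
  withr::local_seed(33)
  base <- random_set(6, dims = c(20L, 20L))
  shift_set <- function(s, di, dj, dims) {
    s$dim <- dims
    s$clusters <- lapply(s$clusters, function(cl) {
      cl$pixels <- cbind(cl$pixels[, 1] + di, cl$pixels[, 2] + dj)
      cl
    })
    s
  }
  a2 <- shift_set(base, 5L, 5L, c(30L, 30L))
  b <- random_set(6, dims = c(20L, 20L))
  b2 <- shift_set(b, 5L, 5L, c(30L, 30L))
  base$dim <- c(30L, 30L); b$dim <- c(30L, 30L)
  roi1 <- unit_square_roi(20 * 20)
  roi2 <- roi_polygon(cbind(c(100, 500, 500, 100), c(100, 100, 500, 500)))
  r1 <- coloc_ratio(base, b, roi1, n_iterations = 50, rng_seed = 5L)
  r2 <- coloc_ratio(a2, b2, roi2, n_iterations = 50, rng_seed = 5L)
  expect_equal(r1$real$n_overlapping_pairs, r2$real$n_overlapping_pairs)
  expect_equal(r1$ratio_count, r2$ratio_count)
})

test_that("more Monte Carlo iterations tighten the random-mean estimate", {
  withr::local_seed(34)
  a <- random_set(5, dims = c(15L, 15L))
  b <- random_set(5, dims = c(15L, 15L))
  roi <- unit_square_roi(15 * 20)
  m10 <- vapply(1:25, function(s)
    coloc_ratio(a, b, roi, n_iterations = 10,
                rng_seed = s)$random_mean[["n_pairs"]], 1)
  m200 <- vapply(1:25, function(s)
    coloc_ratio(a, b, roi, n_iterations = 200,
                rng_seed = 100 + s)$random_mean[["n_pairs"]], 1)
  expect_lt(var(m200), var(m10))
})

test_that("group comparison handles identical, degenerate and normal cases", {
  same <- compare_to_control(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$test$p, 1)

  deg <- compare_to_control(c(2, 2, 2, 2), c(1, 1, 1, 1))
  expect_equal(deg$mean_difference, 1)
  expect_true(deg$test$degenerate)
  expect_true(is.infinite(deg$test$t))

  withr::local_seed(35)
  g1 <- rnorm(30, 1.0, 0.2); g2 <- rnorm(30, 1.6, 0.2)
  cmp <- compare_to_control(g2, g1)
  expect_equal(cmp$test$p, t_oracle(g2, g1)$p, tolerance = 1e-10)
  expect_error(compare_to_control(numeric(0), 1:3), "nonempty")
  small <- compare_to_control(c(1), c(1, 2, 3))
  expect_true(is.na(small$test$p))
})
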