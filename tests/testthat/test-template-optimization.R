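# A 3-row stripe label: every class-1 pixel touches background, so the
# boundary set is the whole stripe and bin counts can be dialed exactly.
stripe_atlas <- function(intensities) {
  n <- length(intensities)
  img <- matrix(0, 3, n); img[2, ] <- intensities
  lab <- matrix(0L, 3, n); lab[2, ] <- 1L
  atlas(gray_image(img), label_image(lab), "stripe")
}

test_that("the toy 3-bin prior reproduces the worked frequencies and weights", {
  a <- stripe_atlas(c(rep(0.1, 10), rep(0.4, 30), rep(0.9, 60)))
  pr <- build_intensity_prior(list(a), target_class = 1L, n_bins = 3L)
  expect_equal(pr$bin_counts, c(10L, 30L, 60L))
  expect_equal(pr$pr, c(0.1, 0.3, 0.6))
  expect_equal(pr$P, c(0, 0.4, 1))
  expect_equal(prior_weight(pr, c(0.1, 0.4, 0.9)), c(0, 0.4, 1))
})

test_that("degenerate priors are handled: equal bins give an uninformative prior", {
  a <- stripe_atlas(c(rep(0.1, 10), rep(0.5, 10), rep(0.9, 10)))
  pr <- build_intensity_prior(list(a), 1L, n_bins = 3L)
  expect_equal(pr$P, c(1, 1, 1))
  expect_error(build_intensity_prior(list(a), target_class = 7L), "no contour")
})

test_that("modal bins weight 1 and empty bins weight 0", {
  a <- stripe_atlas(c(rep(0.2, 5), rep(0.9, 20)))
  pr <- build_intensity_prior(list(a), 1L, n_bins = 4L)
  expect_equal(pr$P[4], 1)   # modal bin
  expect_equal(pr$P[2], 0)   # empty bin
})

test_that("template contours match exhaustive adjacency counting", {
  m3 <- matrix(0L, 5, 5); m3[2:4, 2:4] <- 1L
  c3 <- extract_template_contour(label_image(m3))
  expect_equal(nrow(c3), 8L)              # 3x3 square: all but the center
  expect_false(any(c3[, 1] == 3 & c3[, 2] == 3))
  one <- matrix(0L, 4, 4); one[2, 3] <- 1L
  expect_equal(unname(extract_template_contour(label_image(one))[1, ]), c(2L, 3L))
  m5 <- matrix(0L, 9, 9); m5[3:7, 3:7] <- 1L
  expect_equal(nrow(extract_template_contour(label_image(m5))), 16L)  # perimeter
  expect_error(extract_template_contour(matrix(0L, 3, 3)), "empty")
})

test_that("search areas start full and clip to the midpoint of facing outlines", {
  shape <- c(40L, 40L)
  lone <- matrix(c(20L, 20L), 1, 2)
  a <- set_search_areas(lone, shape, 8L)[[1]]
  expect_true(all(a$extents == 8L))
  # second contour line 6 px away in +x: right extent floor(6/2) = 3
  two <- rbind(c(20L, 20L), c(20L, 26L))
  a2 <- set_search_areas(two, shape, 8L)
  expect_equal(unname(a2[[1]]$extents["right"]), 3L)
  expect_equal(unname(a2[[1]]$extents["left"]), 8L)
  expect_equal(unname(a2[[2]]$extents["left"]), 3L)
  # an 8-adjacent contour pixel never clips
  adj <- rbind(c(20L, 20L), c(21L, 20L))
  a3 <- set_search_areas(adj, shape, 8L)
  expect_true(all(a3[[1]]$extents == 8L))
  # clipping is monotone: clipped extents never exceed the initial half-width
  set.seed(41)
  pts <- cbind(sample(10:30, 12), sample(10:30, 12))
  for (a in set_search_areas(pts, shape, 8L))
    expect_true(all(a$extents >= 0 & a$extents <= 8))
})

# Piecewise-linear ramp with three exact slope levels. Gaussian smoothing
# leaves a linear ramp unchanged away from region junctions, so the Roberts
# magnitudes in the three probe areas are a*sqrt(2), 2a*sqrt(2), 3a*sqrt(2)
# exactly and min-max normalize to 0, 0.5, 1.
ramp_scene <- function() {
  n <- 48; a <- 0.009
  I <- matrix(0, n, n)
  for (c in 1:n) {
    v <- if (c <= 16) a * c
         else if (c <= 32) a * 16 + 2 * a * (c - 16)
         else a * 16 + 2 * a * 16 + 3 * a * (c - 32)
    I[, c] <- v
  }
  list(img = gray_image(I), probes = rbind(c(24L, 8L), c(24L, 24L), c(24L, 40L)))
}

test_that("the decision score is the stated convex combination of prior and gradient", {
  sc <- ramp_scene()
  areas <- set_search_areas(sc$probes, dim(sc$img), 2L)
  # probe intensities fall in bins 1, 2, 3 of a 4-bin prior
  mids <- unclass(sc$img)[sc$probes]
  expect_equal(findInterval(mids, c(0, 0.25, 0.5, 0.75)), 1:3)
  # counts 10/25/50/0 -> pr has min 0 (empty bin), so P = c(0.2, 0.5, 1, 0)
  vals <- c(rep(mids[1], 10), rep(mids[2], 25), rep(mids[3], 50))
  pr <- atlascontour:::prior_from_values(vals, 4L)
  expect_equal(pr$P, c(0.2, 0.5, 1, 0))
  pts <- score_candidates(sc$img, areas, pr, w_p = 0.6, w_g = 0.4,
                          threshold = 0, sigma = 0.5)
  ymat <- matrix(NA_real_, 48, 48); ymat[pts$points] <- pts$scores
  expect_equal(ymat[24, 8], 0.6 * 0.2 + 0.4 * 0, tolerance = 1e-9)
  expect_equal(ymat[24, 24], 0.6 * 0.5 + 0.4 * 0.5, tolerance = 1e-9)  # Y = 0.5
  expect_equal(ymat[24, 40], 0.6 * 1 + 0.4 * 1, tolerance = 1e-9)      # Y = 1
  expect_true(all(pts$scores >= 0 & pts$scores <= 1))
  # a pixel with Y = 0.5 is rejected at threshold 0.6 but kept just below
  at06 <- score_candidates(sc$img, areas, pr, 0.6, 0.4, threshold = 0.6)
  expect_false(any(at06$points[, 1] == 24 & at06$points[, 2] == 24))
  at05 <- score_candidates(sc$img, areas, pr, 0.6, 0.4, threshold = 0.5 - 1e-9)
  expect_true(any(at05$points[, 1] == 24 & at05$points[, 2] == 24))
  expect_true(any(abs(at05$scores - 0.5) < 1e-9))
  expect_error(score_candidates(sc$img, list(), pr), "empty")
  expect_error(score_candidates(sc$img, areas, pr, w_p = 0.7, w_g = 0.4),
               "equal 1")
})

test_that("a flat modal region is accepted on prior evidence alone", {
  # constant patch: gradient 0 everywhere, P = 1 at the modal intensity
  img <- gray_image(matrix(0.52, 20, 20))
  pr <- atlascontour:::prior_from_values(c(rep(0.52, 30), rep(0.1, 10)), 20L)
  areas <- set_search_areas(matrix(c(10L, 10L), 1, 2), c(20L, 20L), 3L)
  pts <- score_candidates(img, areas, pr, w_p = 0.7, w_g = 0.3, threshold = 0.6)
  ymat <- matrix(NA_real_, 20, 20); ymat[pts$points] <- pts$scores
  expect_equal(ymat[10, 10], 0.7, tolerance = 1e-9)   # Y = w_p, accepted at 0.6
  # acceptance is inclusive: the same pixel is kept at threshold exactly 0.7
  at07 <- score_candidates(img, areas, pr, w_p = 0.7, w_g = 0.3, threshold = 0.7)
  expect_true(any(at07$points[, 1] == 10 & at07$points[, 2] == 10))
})

test_that("free chaining traces the 5x5 perimeter as one ordered closed loop", {
  m <- matrix(0L, 9, 9); m[3:7, 3:7] <- 1L
  per <- extract_template_contour(label_image(m))
  iac <- chain_contour(per, c(9L, 9L))
  expect_length(unclass(iac), 1)
  loop <- unclass(iac)[[1]]
  expect_equal(nrow(loop), 16L)
  # every perimeter pixel visited, consecutive points adjacent (distance 1)
  expect_setequal(paste(round(loop[, 1]), round(loop[, 2])),
                  paste(per[, 1], per[, 2]))
  steps <- sqrt(rowSums((loop[c(2:16, 1), ] - loop)^2))
  expect_true(all(abs(steps - 1) < 1e-9))
})

test_that("free chaining separates disjoint rings and closes 1-px gaps", {
  ring <- function(cy, cx, r, shape) {
    th <- seq(0, 2 * pi, length.out = 100)
    unique(cbind(round(cy + r * sin(th)), round(cx + r * cos(th))))
  }
  pts <- rbind(ring(12, 12, 6), ring(12, 34, 6))
  iac <- chain_contour(pts, c(24L, 48L))
  expect_length(unclass(iac), 2)
  # ring with one missing pixel still closes
  r1 <- ring(12, 12, 6)
  gap <- r1[-5, ]
  iac2 <- chain_contour(gap, c(24L, 24L))
  expect_length(unclass(iac2), 1)
  loop <- unclass(iac2)[[1]]
  expect_gt(abs(atlascontour:::polygon_area(loop)), 50)
  expect_error(chain_contour(matrix(c(5L, 5L), 1, 2), c(9L, 9L)), "fewer")
})

test_that("loops are resampled to near-uniform spacing and stay simple", {
  m <- matrix(0L, 30, 30); m[8:24, 6:26] <- 1L
  iac <- chain_contour(extract_template_contour(label_image(m)), c(30L, 30L))
  loop <- unclass(iac)[[1]]
  seg <- sqrt(rowSums((loop[c(seq_len(nrow(loop))[-1], 1), ] - loop)^2))
  expect_lt(max(seg) / min(seg), 2.5)
  # no consecutive-segment self-intersection: cheap check via signed area sign
  expect_gt(abs(atlascontour:::polygon_area(loop)),
            0.8 * (17 * 21))  # close to the rectangle area
})
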