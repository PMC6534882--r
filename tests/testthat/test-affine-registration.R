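test_that("identity transform is an exact no-op and translations move pixels", {
  img <- gray_image(matrix(runif(25), 5, 5))
  expect_identical(unclass(apply_affine(img, affine_params(), "nearest")),
                   unclass(img))
  expect_equal(unclass(apply_affine(img, affine_params(), "bilinear")),
               unclass(img))
  one <- matrix(0, 7, 7); one[3, 2] <- 1
  moved <- apply_affine(gray_image(one), affine_params(dx = 2), "nearest")
  expect_equal(which(unclass(moved) == 1, arr.ind = TRUE)[1, ],
               c(row = 3L, col = 4L))
})

test_that("90-degree rotation matches an explicit grid-rotation oracle", {
  set.seed(3)
  m <- matrix(runif(25), 5, 5)
  out <- apply_affine(gray_image(m), affine_params(theta = pi / 2), "nearest")
  # forward map about the center (c = 3): (x,y) -> (cx - (y-cy), cy + (x-cx))
  oracle <- matrix(0, 5, 5)
  for (r in 1:5) for (c in 1:5) {
    xo <- 3 - (r - 3); yo <- 3 + (c - 3)
    if (xo >= 1 && xo <= 5 && yo >= 1 && yo <= 5) oracle[yo, xo] <- m[r, c]
  }
  expect_equal(unclass(out), oracle, ignore_attr = TRUE)
})

test_that("labels require nearest-neighbour warping", {
  lab <- label_image(matrix(0:1, 4, 4))
  expect_error(apply_affine(lab, affine_params(dx = 1), "bilinear"), "nearest")
  ok <- apply_affine(lab, affine_params(dx = 1), "nearest")
  expect_s3_class(ok, "label_image")
})

test_that("NCC matches hand evaluations and handles degenerate input", {
  A <- gray_image(matrix(runif(64), 8, 8))
  expect_equal(ncc(A, A), 1)
  expect_equal(ncc(A, gray_image(1 - unclass(A))), -1)
  expect_equal(ncc(matrix(c(0, 1, 1, 0), 2, 2), matrix(c(0, 1, 0, 1), 2, 2)), 0)
  expect_equal(ncc(matrix(1, 3, 3), matrix(runif(9), 3, 3)), 0)
})

test_that("NCC is invariant to affine intensity rescaling up to sign", {
  set.seed(9)
  T0 <- matrix(runif(100), 10, 10); F0 <- matrix(runif(100), 10, 10)
  base <- ncc(T0, F0)
  expect_equal(ncc(T0, 2.7 * F0 + 0.3), base, tolerance = 1e-12)
  expect_equal(ncc(T0, -1.1 * F0 + 5), -base, tolerance = 1e-12)
})

test_that("affine inversion and composition are consistent", {
  q <- affine_params(K = 1.07, theta = 0.2, dx = 3, dy = -2)
  id <- compose_affine(invert_affine(q), q)
  expect_equal(c(id$K, id$theta, id$dx, id$dy), c(1, 0, 0, 0), tolerance = 1e-12)
})

test_that("registration recovers a pure integer shift against the exhaustive oracle", {
  set.seed(21)
  suite <- generate_phantom(tiny_config(21, noise_sd = 0.02, bias_amplitude = 0,
                                        perturb_theta_max = 0, perturb_scale_max = 0,
                                        perturb_shift_max = 0, shape_jitter_axes = 0,
                                        shape_jitter_phase = 0, satellite_jitter = 0,
                                        n_atlases = 1))
  tgt <- normalize_intensity(suite$target)
  shifted <- apply_affine(suite$atlases[[1]]$intensity, affine_params(dx = -3, dy = 2),
                          "bilinear")
  atl <- atlas(normalize_intensity(shifted),
               apply_affine(suite$atlases[[1]]$label, affine_params(dx = -3, dy = 2),
                            "nearest"), "shifted")
  # exhaustive integer-shift oracle
  best <- c(NA, NA); best_v <- -Inf
  for (dx in -6:6) for (dy in -6:6) {
    v <- ncc(tgt, apply_affine(atl$intensity, affine_params(dx = dx, dy = dy),
                               "bilinear"))
    if (v > best_v) { best_v <- v; best <- c(dx, dy) }
  }
  expect_equal(best, c(3, -2))
  r <- register(tgt, atl)
  expect_lt(abs(r$params$dx - 3), 0.5)
  expect_lt(abs(r$params$dy + 2), 0.5)
  expect_gt(r$ncc, 0.97)
})

test_that("registration recovers rotation and scaling", {
  suite <- generate_phantom(tiny_config(22, noise_sd = 0.02,
                                        perturb_theta_max = 10 * pi / 180,
                                        perturb_scale_max = 0.05,
                                        perturb_shift_max = 4,
                                        shape_jitter_axes = 0,
                                        shape_jitter_phase = 0,
                                        satellite_jitter = 0, n_atlases = 2))
  tgt <- normalize_intensity(suite$target)
  for (a in suite$atlases) {
    q <- attr(a, "true_params")
    r <- register(tgt, atlas(normalize_intensity(a$intensity), a$label, a$id))
    expect_lt(abs(r$params$theta - q$theta), pi / 180)
    expect_lt(abs(r$params$K - q$K), 0.02)
    expect_lt(abs(r$params$dx - q$dx), 1)
    expect_lt(abs(r$params$dy - q$dy), 1)
  }
})

test_that("registering an exact copy of the target yields near-identity", {
  suite <- generate_phantom(tiny_config(23, noise_sd = 0, bias_amplitude = 0,
                                        perturb_theta_max = 0, perturb_scale_max = 0,
                                        perturb_shift_max = 0, shape_jitter_axes = 0,
                                        shape_jitter_phase = 0, satellite_jitter = 0,
                                        n_atlases = 1))
  tgt <- normalize_intensity(suite$target)
  r <- register(tgt, atlas(tgt, suite$truth, "self"))
  expect_gte(r$ncc, 0.999)
})

test_that("register is deterministic", {
  suite <- generate_phantom(tiny_config(24, n_atlases = 1))
  tgt <- normalize_intensity(suite$target)
  a <- suite$atlases[[1]]
  an <- atlas(normalize_intensity(a$intensity), a$label, a$id)
  r1 <- register(tgt, an); r2 <- register(tgt, an)
  expect_identical(r1$params, r2$params)
  expect_identical(unclass(r1$warped_intensity), unclass(r2$warped_intensity))
})

test_that("atlas selection filters by the NCC threshold with top-k fallback", {
  suite <- generate_phantom(tiny_config(25, n_atlases = 4))
  tgt <- normalize_intensity(suite$target)
  atln <- lapply(suite$atlases, function(a)
    atlas(normalize_intensity(a$intensity), a$label, a$id))
  res <- register_all(tgt, atln, ncc_threshold = 0.87)
  nccs_all <- vapply(atln, function(a) {
    register(tgt, a)$ncc
  }, numeric(1))
  expect_equal(length(res), sum(nccs_all > 0.87))
  expect_true(all(vapply(res, `[[`, numeric(1), "ncc") > 0.87))
  # impossible threshold triggers flagged top-k fallback
  res2 <- register_all(tgt, atln, ncc_threshold = 0.99999, fallback_k = 2)
  expect_length(res2, 2)
  expect_true(isTRUE(attr(res2, "fallback")))
  expect_error(register_all(tgt, list()), "empty")
})
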