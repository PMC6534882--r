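# Synthetic brain-like phantom suites with known ground truth.
#
# A phantom emulates a single axial slice: a bright inner structure (the
# white-matter / thalamus stand-in) with a wavy boundary inside a darker
# elliptical surround on near-black background, plus a few small satellite
# structures of the target class that sit close enough to the main boundary
# for the template-optimization search areas to reach, but are small enough
# for naive consensus fusion to lose under atlas misalignment. Each atlas
# is a known random affine warp of its own anatomical variant of the
# geometry — per-atlas anisotropic axis jitter, boundary-phase jitter and
# satellite position jitter emulate inter-subject variability that an
# isotropic affine registration cannot remove, so the fused template
# carries the residual boundary error and satellite loss the template
# optimization step exists to correct. Atlases additionally carry their own
# smooth multiplicative intensity bias and additive Gaussian noise; the
# target gets independent noise. Edges are softened with a small Gaussian
# so that boundary-pixel intensities fall between the two region means —
# which makes the contour-intensity histogram unimodal and roughly normal,
# the structure the intensity prior assumes.

#' Phantom suite configuration
#'
#' @param size image dimensions, default `c(128, 128)`.
#' @param n_atlases number of atlases, default 10.
#' @param inner_mean,outer_mean,background_mean region intensities in \[0,1\].
#' @param noise_sd additive Gaussian noise sd.
#' @param bias_amplitude amplitude of the smooth multiplicative bias applied
#'   to each atlas.
#' @param perturb_theta_max max |rotation| of the atlas-to-target transform
#'   (radians).
#' @param perturb_scale_max max |K - 1| scaling perturbation.
#' @param perturb_shift_max max |translation| per axis (px).
#' @param n_satellites number of small target-class satellites.
#' @param satellite_radius satellite radius (px).
#' @param boundary_waviness radial sinusoid amplitude of the inner boundary,
#'   as a fraction of the inner radius.
#' @param edge_softness Gaussian sd (px) applied to the noise-free scene.
#' @param shape_jitter_axes per-atlas relative jitter of each ellipse
#'   semi-axis, uniform in +/- this value; anisotropic, so an isotropic
#'   affine cannot recover it.
#' @param shape_jitter_phase per-atlas jitter of the boundary-waviness phase
#'   (radians, uniform +/-).
#' @param satellite_jitter per-atlas jitter of each satellite center
#'   (px, uniform +/- per coordinate); larger than the satellite diameter so
#'   consensus fusion loses the satellites.
#' @param seed RNG seed; the same seed reproduces the suite bit-exactly.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(size = c(128L, 128L), n_atlases = 10L,
                           inner_mean = 0.75, outer_mean = 0.45,
                           background_mean = 0.05, noise_sd = 0.03,
                           bias_amplitude = 0.1,
                           perturb_theta_max = 5 * pi / 180,
                           perturb_scale_max = 0.05,
                           perturb_shift_max = 5,
                           n_satellites = 2L, satellite_radius = 2.5,
                           boundary_waviness = 0.05, edge_softness = 0.8,
                           shape_jitter_axes = 0.06,
                           shape_jitter_phase = 0.4,
                           satellite_jitter = 4,
                           seed = 1L) {
  stopifnot(all(size >= 32L), n_atlases >= 1L,
            all(c(inner_mean, outer_mean, background_mean) >= 0),
            all(c(inner_mean, outer_mean, background_mean) <= 1),
            noise_sd >= 0, bias_amplitude >= 0, perturb_theta_max >= 0,
            perturb_scale_max >= 0, perturb_shift_max >= 0,
            boundary_waviness >= 0, shape_jitter_axes >= 0,
            shape_jitter_phase >= 0, satellite_jitter >= 0)
  as.list(environment())
}

# Rasterize one anatomical variant: geom holds the ellipse semi-axes, the
# waviness phase and the satellite centers. Returns the label matrix and
# the blurred noise-free scene.
render_geometry <- function(geom, config, nr, nc) {
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  xs <- matrix(rep(seq_len(nc), each = nr) - cx, nr, nc)
  ys <- matrix(rep(seq_len(nr), times = nc) - cy, nr, nc)
  phi <- atan2(ys, xs)
  rho_out <- sqrt((xs / geom$a_out)^2 + (ys / geom$b_out)^2)
  rho_in <- sqrt((xs / geom$a_in)^2 + (ys / geom$b_in)^2)
  wav <- 1 + config$boundary_waviness * sin(5 * phi + geom$phase)
  outer_mask <- rho_out <= 1
  labels <- matrix(0L, nr, nc)
  labels[outer_mask] <- 2L
  labels[rho_in <= wav] <- 1L
  if (nrow(geom$satellites) > 0L) {
    for (k in seq_len(nrow(geom$satellites))) {
      sat <- (xs + cx - geom$satellites[k, 1L])^2 +
             (ys + cy - geom$satellites[k, 2L])^2 <= config$satellite_radius^2
      labels[sat & outer_mask] <- 1L
    }
  }
  scene <- matrix(config$background_mean, nr, nc)
  scene[labels == 2L] <- config$outer_mean
  scene[labels == 1L] <- config$inner_mean
  list(labels = labels, scene = gaussian_smooth(scene, config$edge_softness))
}

#' Generate a phantom suite
#'
#' @param config a [phantom_config()].
#' @return a `phantom_suite`: list with `target` ([gray_image()]), `truth`
#'   ([label_image()]; 1 = target structure incl. satellites, 2 = surround),
#'   `atlases` (list of [atlas()] objects, each carrying its true
#'   atlas-to-target [affine_params()] as attribute `true_params`),
#'   `scene` (noise-free target intensity) and `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  set.seed(config$seed)
  nr <- config$size[1L]; nc <- config$size[2L]
  S <- min(nr, nc)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  base <- list(a_out = 0.35 * S, b_out = 0.28 * S,
               a_in = 0.175 * S, b_in = 0.14 * S,
               phase = runif(1, 0, 2 * pi))
  if (base$a_out + config$perturb_shift_max + 4 > S / 2)
    stop("generate_phantom: structure does not fit in the frame")
  # satellite centers just outside the wavy inner boundary (x, y)
  sat_ang <- if (config$n_satellites > 0L) runif(config$n_satellites, 0, 2 * pi)
             else numeric(0)
  sat_centers <- function(geom) {
    if (length(sat_ang) == 0L)
      return(matrix(numeric(0), 0L, 2L))
    t(vapply(sat_ang, function(a) {
      dirx <- cos(a); diry <- sin(a)
      rb <- (1 + config$boundary_waviness * sin(5 * a + geom$phase)) /
        sqrt((dirx / geom$a_in)^2 + (diry / geom$b_in)^2)
      c(cx + dirx * (rb + 6), cy + diry * (rb + 6))
    }, numeric(2)))
  }
  base$satellites <- sat_centers(base)
  tgt <- render_geometry(base, config, nr, nc)
  target <- clamp(tgt$scene + rnorm(nr * nc, 0, config$noise_sd), 0, 1)
  xs <- matrix(rep(seq_len(nc), each = nr) - cx, nr, nc)
  ys <- matrix(rep(seq_len(nr), times = nc) - cy, nr, nc)
  atlases <- lapply(seq_len(config$n_atlases), function(k) {
    # anatomical variant of this "subject"
    geom <- base
    geom$a_out <- base$a_out * (1 + runif(1, -1, 1) * config$shape_jitter_axes / 2)
    geom$b_out <- base$b_out * (1 + runif(1, -1, 1) * config$shape_jitter_axes / 2)
    geom$a_in <- base$a_in * (1 + runif(1, -1, 1) * config$shape_jitter_axes)
    geom$b_in <- base$b_in * (1 + runif(1, -1, 1) * config$shape_jitter_axes)
    geom$phase <- base$phase + runif(1, -1, 1) * config$shape_jitter_phase
    geom$satellites <- sat_centers(geom) +
      matrix(runif(2L * length(sat_ang), -1, 1) * config$satellite_jitter,
             ncol = 2L)
    anat <- render_geometry(geom, config, nr, nc)
    q <- affine_params(
      K = 1 + runif(1, -config$perturb_scale_max, config$perturb_scale_max),
      theta = runif(1, -config$perturb_theta_max, config$perturb_theta_max),
      dx = runif(1, -config$perturb_shift_max, config$perturb_shift_max),
      dy = runif(1, -config$perturb_shift_max, config$perturb_shift_max))
    p <- invert_affine(q)  # atlas = variant warped away from target space
    inten <- apply_affine(gray_image(anat$scene), p, "bilinear")
    lab <- apply_affine(label_image(anat$labels), p, "nearest")
    # smooth multiplicative bias: one low-frequency plane wave
    kx <- runif(1, 0.3, 1); ky <- runif(1, 0.3, 1); ph <- runif(1, 0, 2 * pi)
    bias <- 1 + config$bias_amplitude *
      sin(2 * pi * (kx * xs / S + ky * ys / S) + ph)
    inten <- clamp(unclass(inten) * bias + rnorm(nr * nc, 0, config$noise_sd), 0, 1)
    a <- atlas(gray_image(inten), lab, id = sprintf("atlas_%02d", k))
    attr(a, "true_params") <- q
    a
  })
  structure(list(target = gray_image(matrix(target, nr, nc)),
                 truth = label_image(tgt$labels),
                 scene = gray_image(tgt$scene),
                 atlases = atlases,
                 config = config),
            class = "phantom_suite")
}

#' Summary statistics of the target intensities on the truth contour
#'
#' Returns mean, sd and skewness of the target intensities at the boundary
#' pixels of the true target structure. For default configurations the
#' distribution is unimodal and roughly normal (|skewness| < 0.5).
#'
#' @param suite a [generate_phantom()] result.
#' @return list `mean`, `sd`, `skewness`, `n`.
#' @export
contour_intensity_check <- function(suite) {
  mask <- unclass(suite$truth) == 1L
  b <- boundary_pixels(mask)
  v <- unclass(suite$target)[b]
  m <- mean(v); s <- sd(v)
  skew <- if (s < .EPS) 0 else mean((v - m)^3) / (mean((v - m)^2))^1.5
  list(mean = m, sd = s, skewness = skew, n = length(v))
}

#' Write a phantom suite to a directory (fixture rasters + JSON config)
#' @param suite a [generate_phantom()] result.
#' @param dir output directory (created if missing).
#' @export
write_phantom <- function(suite, dir) {
  dir.create(file.path(dir, "atlases"), recursive = TRUE, showWarnings = FALSE)
  write_fixture_image(suite$target, file.path(dir, "target.fgm"))
  write_fixture_label(suite$truth, file.path(dir, "truth.pgm"))
  for (a in suite$atlases) {
    write_fixture_image(a$intensity, file.path(dir, "atlases", paste0(a$id, ".fgm")))
    write_fixture_label(a$label, file.path(dir, "atlases", paste0(a$id, ".pgm")))
  }
  jsonlite::write_json(suite$config[names(suite$config) != "size"],
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a phantom suite directory written by [write_phantom()]
#' @param dir suite directory.
#' @return list with `target`, `truth`, `atlases`.
#' @export
read_phantom <- function(dir) {
  ids <- sub("\\.fgm$", "", list.files(file.path(dir, "atlases"), pattern = "\\.fgm$"))
  list(target = read_fixture_image(file.path(dir, "target.fgm")),
       truth = read_fixture_label(file.path(dir, "truth.pgm")),
       atlases = lapply(ids, function(id)
         atlas(read_fixture_image(file.path(dir, "atlases", paste0(id, ".fgm"))),
               read_fixture_label(file.path(dir, "atlases", paste0(id, ".pgm"))),
               id = id)))
}
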