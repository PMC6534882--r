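# Global 2D affine registration maximizing normalized cross-correlation.
#
# The transform is f'(p) = K R(theta) (p - c) + c + t, with p = (x, y) =
# (col, row), c the image center and t = (dx, dy). The rotation/scaling
# center is the image center: the transform as written in terms of raw
# coordinates has no center, but any fixed center choice is absorbed by the
# translation, and centering minimizes coupling between parameters during
# optimization. Warping is output-driven (inverse mapping) so no holes
# appear.

#' Affine transform parameters
#'
#' @param K isotropic scaling (> 0).
#' @param theta rotation angle in radians, in (-pi, pi].
#' @param dx,dy translation in pixels along columns (x) and rows (y).
#' @param K_range admissible scaling range.
#' @return an `affine_params` object.
#' @export
affine_params <- function(K = 1, theta = 0, dx = 0, dy = 0, K_range = c(0.5, 2)) {
  if (K <= 0) stop("affine_params: K must be positive")
  if (K < K_range[1] || K > K_range[2])
    stop("affine_params: K outside admissible range [", K_range[1], ", ", K_range[2], "]")
  theta <- atan2(sin(theta), cos(theta))  # wrap into (-pi, pi]
  structure(list(K = K, theta = theta, dx = dx, dy = dy), class = "affine_params")
}

#' Invert an affine transform
#' @param params an [affine_params()].
#' @return the inverse transform as `affine_params`.
#' @export
invert_affine <- function(params) {
  K <- 1 / params$K
  th <- -params$theta
  # t' = -R(-theta) t / K_fwd
  ct <- cos(th); st <- sin(th)
  tx <- -(ct * params$dx - st * params$dy) / params$K
  ty <- -(st * params$dx + ct * params$dy) / params$K
  affine_params(K, th, tx, ty)
}

#' Compose two affine transforms (apply `a` first, then `b`)
#' @param a,b [affine_params()] objects.
#' @return the composed transform.
#' @export
compose_affine <- function(a, b) {
  K <- a$K * b$K
  th <- a$theta + b$theta
  cb <- cos(b$theta); sb <- sin(b$theta)
  tx <- b$K * (cb * a$dx - sb * a$dy) + b$dx
  ty <- b$K * (sb * a$dx + cb * a$dy) + b$dy
  affine_params(K, th, tx, ty)
}

#' Warp an image by an affine transform
#'
#' Each output pixel is sampled from the inverse-mapped source location;
#' samples falling outside the source grid take 0 (intensity) or background 0
#' (labels). Label images must use nearest-neighbour interpolation.
#'
#' @param img a [gray_image()] / matrix, or a [label_image()].
#' @param params an [affine_params()].
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return warped image of the same type as the input.
#' @export
apply_affine <- function(img, params, interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  is_label <- inherits(img, "label_image")
  if (is_label && interpolation == "bilinear")
    stop("apply_affine: label images require nearest-neighbour interpolation")
  m <- unclass(as.matrix(img))
  nr <- nrow(m); nc <- ncol(m)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  if (identical(interpolation, "nearest") && params$K == 1 &&
      params$theta == 0 && params$dx == 0 && params$dy == 0)
    return(img)  # identity is bit-exact
  # inverse map: p_src = c + R(-theta) (p_out - c - t) / K
  grid_c <- rep(seq_len(nc), each = nr)
  grid_r <- rep(seq_len(nr), times = nc)
  ux <- grid_c - cx - params$dx
  uy <- grid_r - cy - params$dy
  ct <- cos(params$theta); st <- sin(params$theta)
  sx <- cx + ( ct * ux + st * uy) / params$K
  sy <- cy + (-st * ux + ct * uy) / params$K
  vals <- if (interpolation == "bilinear") bilinear_sample(m, sy, sx, fill = 0)
          else nearest_sample(m, sy, sx, fill = 0)
  out <- matrix(vals, nr, nc)
  if (is_label) label_image(round(out)) else gray_image(out, spacing = attr(img, "spacing") %||% 1)
}

#' Normalized cross-correlation between two images
#'
#' NCC of the (optionally ROI-restricted) pixel sets: the centred
#' cross-product over the geometric mean of the centred sums of squares.
#' By convention a zero-variance argument yields 0 (no evidence of a linear
#' relation) rather than an error, so blank slices do not abort multi-atlas
#' runs.
#'
#' @param target,warped same-shape [gray_image()]s / matrices.
#' @param roi optional [roi_box()] restricting the support.
#' @return NCC value in \[-1, 1\].
#' @export
ncc <- function(target, warped, roi = NULL) {
  a <- unclass(as.matrix(target)); b <- unclass(as.matrix(warped))
  if (!identical(dim(a), dim(b))) stop("ncc: images must have the same shape")
  if (!is.null(roi)) {
    ix <- roi_indices(roi)
    a <- a[ix$rows, ix$cols]; b <- b[ix$rows, ix$cols]
  }
  a <- a - mean(a); b <- b - mean(b)
  va <- sum(a * a); vb <- sum(b * b)
  if (va < .EPS || vb < .EPS) return(0)
  sum(a * b) / sqrt(va * vb)
}

#' Registration search configuration
#'
#' @param n_levels pyramid levels (coarsest is `2^(n_levels-1)` downsampling).
#' @param theta_starts rotation multi-start values (radians) at the coarsest level.
#' @param shift_scan half-range (coarsest-level pixels) of the integer-shift
#'   pre-scan seeding each start.
#' @param maxit_coarse,maxit_fine Nelder-Mead iteration budgets.
#' @param K_range admissible scaling range.
#' @return a `register_control` list.
#' @export
register_control <- function(n_levels = 3L,
                             theta_starts = seq(-pi / 6, pi / 6, length.out = 5L),
                             shift_scan = 6L,
                             maxit_coarse = 120L, maxit_fine = 60L,
                             K_range = c(0.5, 2)) {
  list(n_levels = n_levels, theta_starts = theta_starts, shift_scan = shift_scan,
       maxit_coarse = maxit_coarse, maxit_fine = maxit_fine, K_range = K_range)
}

# 2x2 block-mean downsampling after light smoothing.
downsample2 <- function(m) {
  m <- gaussian_smooth(m, 0.7)
  nr <- floor(nrow(m) / 2) * 2L; nc <- floor(ncol(m) / 2) * 2L
  m <- m[seq_len(nr), seq_len(nc)]
  (m[seq(1L, nr, 2L), seq(1L, nc, 2L)] + m[seq(2L, nr, 2L), seq(1L, nc, 2L)] +
   m[seq(1L, nr, 2L), seq(2L, nc, 2L)] + m[seq(2L, nr, 2L), seq(2L, nc, 2L)]) / 4
}

scale_roi <- function(roi, f, nr, nc) {
  rmin <- max(0L, floor(roi$row_min / f)); rmax <- min(nr, ceiling(roi$row_max / f))
  cmin <- max(0L, floor(roi$col_min / f)); cmax <- min(nc, ceiling(roi$col_max / f))
  if (rmax - rmin < 2L || cmax - cmin < 2L) return(NULL)
  roi_box(rmin, rmax, cmin, cmax)
}

#' Register one atlas to a target slice
#'
#' Estimates the affine transform (scaling, rotation, translation) maximizing
#' NCC between the target and the warped atlas intensity, using a Gaussian
#' image pyramid with an integer-shift pre-scan and rotation multi-starts at
#' the coarsest level, refined by Nelder-Mead at every level. NCC is
#' evaluated over the target ROI to reduce the influence of background
#' pixels. The search is fully deterministic.
#'
#' @param target a [gray_image()] (normalized).
#' @param atl an [atlas()] (intensity normalized).
#' @param control a [register_control()].
#' @param roi optional [roi_box()] over which NCC is evaluated.
#' @return a `registration_result`: list with `params` ([affine_params()]),
#'   `ncc`, `warped_intensity`, `warped_label`, `improved` flag and `id`.
#' @export
register <- function(target, atl, control = register_control(), roi = NULL) {
  tgt <- unclass(as.matrix(target))
  flt <- unclass(as.matrix(atl$intensity))
  if (!identical(dim(tgt), dim(flt)))
    stop("register: target and atlas shapes differ (resample first)")
  n_levels <- control$n_levels
  pyr_t <- list(tgt); pyr_f <- list(flt)
  for (l in seq_len(n_levels - 1L)) {
    pyr_t[[l + 1L]] <- downsample2(pyr_t[[l]])
    pyr_f[[l + 1L]] <- downsample2(pyr_f[[l]])
  }
  objective <- function(par, t_l, f_l, roi_l) {
    K <- clamp(par[1L], control$K_range[1L], control$K_range[2L])
    p <- affine_params(K, par[2L], par[3L], par[4L], K_range = control$K_range)
    w <- apply_affine(gray_image(f_l), p, "bilinear")
    -ncc(t_l, w, roi_l)
  }
  # coarsest level: shift pre-scan per rotation start, then simplex refinement
  lev <- n_levels
  t_l <- pyr_t[[lev]]; f_l <- pyr_f[[lev]]
  roi_l <- if (is.null(roi)) NULL else
    scale_roi(roi, 2^(lev - 1L), nrow(t_l), ncol(t_l))
  cands <- list()
  for (th0 in control$theta_starts) {
    best <- c(0, 0); best_v <- Inf
    sc <- control$shift_scan
    for (dx0 in seq(-sc, sc, by = 3)) for (dy0 in seq(-sc, sc, by = 3)) {
      v <- objective(c(1, th0, dx0, dy0), t_l, f_l, roi_l)
      if (v < best_v) { best_v <- v; best <- c(dx0, dy0) }
    }
    o <- stats::optim(c(1, th0, best[1L], best[2L]), objective,
                      t_l = t_l, f_l = f_l, roi_l = roi_l,
                      method = "Nelder-Mead",
                      control = list(maxit = control$maxit_coarse,
                                     parscale = c(0.05, 0.1, 1, 1)))
    cands[[length(cands) + 1L]] <- o
  }
  ord <- order(vapply(cands, `[[`, numeric(1), "value"))
  keep <- cands[ord[seq_len(min(2L, length(cands)))]]
  # refine the surviving candidates down the pyramid
  for (lev in seq(n_levels - 1L, 1L)) {
    t_l <- pyr_t[[lev]]; f_l <- pyr_f[[lev]]
    roi_l <- if (is.null(roi)) NULL else
      scale_roi(roi, 2^(lev - 1L), nrow(t_l), ncol(t_l))
    keep <- lapply(keep, function(o) {
      par <- o$par; par[3:4] <- par[3:4] * 2  # translations double per level
      stats::optim(par, objective, t_l = t_l, f_l = f_l, roi_l = roi_l,
                   method = "Nelder-Mead",
                   control = list(maxit = control$maxit_fine,
                                  parscale = c(0.02, 0.05, 0.5, 0.5)))
    })
    keep <- keep[order(vapply(keep, `[[`, numeric(1), "value"))]
    if (lev > 1L) keep <- keep[1L]
  }
  best <- keep[[1L]]
  par <- best$par
  params <- affine_params(clamp(par[1L], control$K_range[1L], control$K_range[2L]),
                          par[2L], par[3L], par[4L], K_range = control$K_range)
  warped <- apply_affine(atl$intensity, params, "bilinear")
  final_ncc <- ncc(target, warped, roi)
  identity_ncc <- ncc(target, atl$intensity, roi)
  improved <- final_ncc >= identity_ncc - 1e-9
  if (!improved) {
    params <- affine_params(1, 0, 0, 0)
    warped <- atl$intensity
    final_ncc <- identity_ncc
    warning("register: optimizer failed to improve on identity for atlas '",
            atl$id, "'; returning identity parameters")
  }
  structure(list(params = params, ncc = final_ncc,
                 warped_intensity = warped,
                 warped_label = apply_affine(atl$label, params, "nearest"),
                 improved = improved, id = atl$id),
            class = "registration_result")
}

#' Register an atlas set and select by NCC threshold
#'
#' Registers every atlas and keeps results whose NCC exceeds the selection
#' threshold (default 0.87). If no atlas passes, the top-`fallback_k` results
#' by NCC are returned and the result is flagged with attribute
#' `fallback = TRUE`.
#'
#' @param target a [gray_image()].
#' @param atlases list of [atlas()] objects.
#' @param ncc_threshold atlas-selection NCC cut, default 0.87.
#' @param fallback_k how many best atlases to keep when none pass.
#' @param control a [register_control()].
#' @param roi optional [roi_box()].
#' @return list of `registration_result`s, possibly with attribute `fallback`.
#' @export
register_all <- function(target, atlases, ncc_threshold = 0.87, fallback_k = 3L,
                         control = register_control(), roi = NULL) {
  if (length(atlases) == 0L) stop("register_all: empty atlas list")
  results <- lapply(atlases, function(a) register(target, a, control, roi))
  nccs <- vapply(results, `[[`, numeric(1), "ncc")
  pass <- nccs > ncc_threshold
  if (any(pass)) return(results[pass])
  keep <- order(nccs, decreasing = TRUE)[seq_len(min(fallback_k, length(results)))]
  out <- results[keep]
  attr(out, "fallback") <- TRUE
  out
}
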