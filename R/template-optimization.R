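# Template optimization: correct residual registration error in the fused
# initial template.
#
# Three steps: (1) per-contour-pixel rectangular search areas, clipped where
# a second, non-adjacent stretch of contour enters the initial square (the
# boundary moves to the midpoint between the two contour lines); (2) scoring
# of every pixel inside the actual search areas by a convex combination of
# an intensity prior (20-bin histogram of contour intensities, min-max
# normalized) and the min-max-normalized Roberts gradient magnitude;
# (3) chaining of the accepted points into ordered, closed loops — the
# initial active contour (IAC).

#' Contour-intensity prior
#'
#' Collects the intensities of pixels on the boundary of `target_class`
#' across all atlas label images, bins them into `n_bins` uniform intervals
#' on \[0, 1\], and converts the bin frequencies `pr` into weights
#' `P = (pr - min pr) / (max pr - min pr)`. If all bins are equally
#' populated the min-max map is undefined and the prior is set to 1
#' everywhere (uninformative: scoring then defers to the gradient term).
#'
#' @param atlases list of [atlas()] objects with normalized intensities.
#' @param target_class label whose boundary intensities are collected.
#' @param n_bins number of uniform bins on \[0, 1\], default 20.
#' @return an `intensity_prior`: list with `bin_edges`, `bin_counts`, `pr`,
#'   `P` and `n_bins`.
#' @export
build_intensity_prior <- function(atlases, target_class = 1L, n_bins = 20L) {
  vals <- unlist(lapply(atlases, function(a) {
    mask <- unclass(a$label) == target_class
    if (!any(mask)) return(numeric(0))
    b <- boundary_pixels(mask)
    unclass(a$intensity)[b]
  }))
  if (length(vals) == 0L)
    stop("build_intensity_prior: no contour pixels found for class ", target_class)
  prior_from_values(vals, n_bins)
}

# Build the prior object from raw contour intensities.
prior_from_values <- function(vals, n_bins) {
  vals <- clamp(vals, 0, 1)
  idx <- pmin(n_bins, floor(vals * n_bins) + 1L)
  counts <- tabulate(idx, nbins = n_bins)
  pr <- counts / sum(counts)
  P <- if (max(pr) - min(pr) < .EPS) rep(1, n_bins) else
    (pr - min(pr)) / (max(pr) - min(pr))
  structure(list(bin_edges = seq(0, 1, length.out = n_bins + 1L),
                 bin_counts = counts, pr = pr, P = P, n_bins = n_bins),
            class = "intensity_prior")
}

#' Look up the prior weight P for intensities
#' @param prior an [build_intensity_prior()] result.
#' @param values numeric vector of intensities (clamped into \[0, 1\]).
#' @return numeric vector of prior weights in \[0, 1\].
#' @export
prior_weight <- function(prior, values) {
  idx <- pmin(prior$n_bins, floor(clamp(values, 0, 1) * prior$n_bins) + 1L)
  prior$P[idx]
}

# Logical matrix of foreground pixels 8-adjacent to background (or to the
# image border).
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(FALSE, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask
  all_nb <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    all_nb <- all_nb & padded[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  mask & !all_nb
}

#' Extract the 1-px contour of the initial template
#'
#' Foreground pixels that are 8-adjacent to background (pixels on the image
#' border count as adjacent to background).
#'
#' @param template an [fuse()] result, a [label_image()] mask, or a matrix.
#' @return integer matrix of contour pixel coordinates, columns `row`, `col`.
#' @export
extract_template_contour <- function(template) {
  mask <- if (inherits(template, "initial_template")) unclass(template$binary) != 0
          else unclass(as.matrix(template)) != 0
  if (!any(mask)) stop("extract_template_contour: empty template mask")
  b <- boundary_pixels(mask)
  which(b, arr.ind = TRUE) |> unname() -> ij
  colnames(ij) <- c("row", "col")
  ij
}

#' Set per-contour-pixel search areas
#'
#' Each contour pixel starts from the full square of half-width
#' `initial_half_width`. Scanning outward from the center along +x, -x, +y
#' and -y, the first contour pixel met that is not 8-adjacent to the center
#' clips that direction's extent to half the distance (the search-area
#' boundary moves to the midpoint between the two contour lines), so
#' adjacent outlines do not claim each other's pixels.
#'
#' @param contour coordinate matrix from [extract_template_contour()].
#' @param shape image dimensions `c(nrow, ncol)`.
#' @param initial_half_width half-width of the initial square, default 8.
#' @return list of `search_area` objects: `center` (row, col) and `extents`
#'   (left, right, up, down).
#' @export
set_search_areas <- function(contour, shape, initial_half_width = 8L) {
  h <- as.integer(initial_half_width)
  if (h < 1L) stop("set_search_areas: initial_half_width must be >= 1")
  cmask <- matrix(FALSE, shape[1L], shape[2L])
  cmask[contour] <- TRUE
  scan_dir <- function(r, c, dr, dc) {
    for (d in seq_len(h)) {
      rr <- r + dr * d; cc <- c + dc * d
      if (rr < 1L || rr > shape[1L] || cc < 1L || cc > shape[2L]) break
      if (cmask[rr, cc] && d > 1L)  # d == 1 is 8-adjacent to the center
        return(max(0L, d %/% 2L))
    }
    h
  }
  lapply(seq_len(nrow(contour)), function(i) {
    r <- contour[i, 1L]; c <- contour[i, 2L]
    structure(list(center = c(row = r, col = c),
                   extents = c(left  = scan_dir(r, c, 0L, -1L),
                               right = scan_dir(r, c, 0L, 1L),
                               up    = scan_dir(r, c, -1L, 0L),
                               down  = scan_dir(r, c, 1L, 0L))),
              class = "search_area")
  })
}

# Logical mask of the union of all actual search areas (clipped to image).
search_area_mask <- function(areas, shape) {
  m <- matrix(FALSE, shape[1L], shape[2L])
  for (a in areas) {
    r <- a$center[1L]; c <- a$center[2L]; e <- a$extents
    rows <- max(1L, r - e["up"]):min(shape[1L], r + e["down"])
    cols <- max(1L, c - e["left"]):min(shape[2L], c + e["right"])
    m[rows, cols] <- TRUE
  }
  m
}

#' Score candidate contour points inside the search areas
#'
#' The target is first smoothed with a Gaussian of standard deviation
#' `sigma` (default 0.5). For every pixel in the union of the actual search
#' areas the decision score is
#' `Y = w_p * P(x) + w_g * grad_norm(x)`,
#' where `P(x)` is the intensity-prior weight of the pixel's intensity bin
#' and `grad_norm` is the Roberts gradient magnitude min-max normalized over
#' the union of search-area pixels (normalizing over the whole image would
#' let the bright brain/background edge dominate the scale). Pixels with
#' `Y >= threshold` are accepted as contour points.
#'
#' @param target normalized [gray_image()].
#' @param areas list from [set_search_areas()].
#' @param prior an [build_intensity_prior()] result.
#' @param w_p,w_g prior and gradient weights; must sum to 1
#'   (profiles: 0.7/0.3 and 0.6/0.4).
#' @param threshold acceptance threshold on Y, default 0.6 (inclusive).
#' @param sigma Gaussian smoothing sd in pixels, default 0.5.
#' @return a `contour_point_set`: list with `points` (coordinate matrix),
#'   `scores` (Y per accepted point), and `candidate_mask`.
#' @export
score_candidates <- function(target, areas, prior, w_p = 0.7, w_g = 0.3,
                             threshold = 0.6, sigma = 0.5) {
  if (abs(w_p + w_g - 1) > 1e-9) stop("score_candidates: w_p + w_g must equal 1")
  tgt <- unclass(as.matrix(target))
  mask <- search_area_mask(areas, dim(tgt))
  if (!any(mask)) stop("score_candidates: empty union of search areas")
  sm <- gaussian_smooth(tgt, sigma)
  grad <- roberts_magnitude(sm)
  g <- grad[mask]
  gn <- minmax01(g, flat = 0)
  P <- prior_weight(prior, sm[mask])
  Y <- w_p * P + w_g * gn
  ij <- which(mask, arr.ind = TRUE)
  acc <- Y >= threshold
  pts <- ij[acc, , drop = FALSE]
  colnames(pts) <- c("row", "col")
  structure(list(points = pts, scores = Y[acc], grads = gn[acc],
                 gradient = grad, candidate_mask = mask,
                 threshold = threshold),
            class = "contour_point_set")
}

#' Chain accepted contour points into closed loops (the IAC)
#'
#' Two chaining modes are available.
#'
#' Template-guided (the pipeline default, used when `template` and `areas`
#' are supplied): the accepted points are first clustered (3x3 closing +
#' connected components). Compact small clusters — span at most
#' `2.2 * sqrt(pixel count)`, at most 80 px and 16 px across, the scale of
#' structures a fusion consensus loses — are traced directly into their own
#' small loops (satellite tissues); each such loop is then snapped to the
#' local Roberts-gradient ridge along its inward normals, because the
#' acceptance band around a small blurred structure is a halo wider than
#' the structure while the gradient peaks on its edge. The remaining
#' points form the boundary band; the closed topology for them is taken
#' from the initial template: each boundary loop of the template mask is
#' traced in order, and every template contour pixel is moved to the best
#' band point inside its own search area (highest score, with a mild
#' distance penalty of 0.02/px so that among near-equal candidates the
#' nearest wins); a contour pixel whose search area holds no band point
#' keeps its template position — with no local evidence the prior boundary
#' stands, which also prevents long unsupported chords across the
#' structure. Template loops enclosing less than 50 px^2 are kept at their
#' template positions verbatim: the contour-intensity statistics driving
#' the correction are collected on large-structure boundaries and do not
#' transfer to blob-scale structures.
#'
#' Free chaining (no `template`): the accepted points are rasterized into a
#' contour image, gaps are bridged with one pass of disc closing
#' (`gap_close`), and every connected component is traced into an ordered
#' closed boundary loop.
#'
#' In both modes, components with fewer than `min_points` pixels or
#' enclosing less than `min_area` px^2 are dropped, and every loop is
#' resampled to uniform arc-length spacing
#' (`max(16, round(perimeter / 1.5))` points — snake stability requires
#' roughly uniform spacing).
#'
#' @param points a [score_candidates()] result or a coordinate matrix.
#' @param shape image dimensions `c(nrow, ncol)`.
#' @param min_points minimum component size, default 4.
#' @param min_area minimum enclosed loop area in px^2, default 4.
#' @param spacing target arc-length spacing for resampling, default 1.5 px.
#' @param gap_close odd diameter of the free-chaining disc closing brush,
#'   default 3.
#' @param template optional binary template mask (or [fuse()] result)
#'   providing loop topology for template-guided chaining.
#' @param areas the [set_search_areas()] list matching the template contour
#'   (required with `template`).
#' @return an `initial_active_contour`: list of loops, each an `n x 2`
#'   matrix of (row, col) positions, closed implicitly (first follows last).
#' @export
chain_contour <- function(points, shape, min_points = 4L, min_area = 4,
                          spacing = 1.5, gap_close = 3L,
                          template = NULL, areas = NULL) {
  pts <- if (inherits(points, "contour_point_set")) points$points else points
  scores <- if (inherits(points, "contour_point_set")) points$scores
            else rep(1, nrow(pts))
  gradient <- if (inherits(points, "contour_point_set")) points$gradient
  if (nrow(pts) < min_points)
    stop("chain_contour: fewer than ", min_points,
         " accepted points; consider relaxing the Y threshold")
  loops <- if (is.null(template)) {
    chain_free(pts, shape, min_points, min_area, spacing, gap_close,
               compact_only = FALSE)
  } else {
    if (is.null(areas)) stop("chain_contour: template-guided mode needs `areas`")
    chain_guided(pts, scores, gradient, shape, min_points, min_area, spacing,
                 template, areas)
  }
  if (length(loops) == 0L)
    stop("chain_contour: no component with >= ", min_points,
         " points; consider relaxing the Y threshold")
  structure(loops, class = "initial_active_contour")
}

# 8-connected component labeling. bwlabel uses 4-connectivity, which
# fragments thin diagonal chains; merge its labels across diagonal
# adjacencies with a small union-find.
label8 <- function(mask) {
  l4 <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  n <- max(l4)
  if (n <= 1L) return(l4)
  nr <- nrow(l4); nc <- ncol(l4)
  pairs <- rbind(
    cbind(as.vector(l4[-nr, -nc]), as.vector(l4[-1L, -1L])),   # down-right
    cbind(as.vector(l4[-1L, -nc]), as.vector(l4[-nr, -1L])))   # up-right
  pairs <- pairs[pairs[, 1L] > 0 & pairs[, 2L] > 0 &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  parent <- seq_len(n)
  find_root <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nrow(pairs) > 0L) for (i in seq_len(nrow(pairs))) {
    a <- find_root(pairs[i, 1L]); b <- find_root(pairs[i, 2L])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find_root, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- l4
  out[l4 > 0] <- relab[l4[l4 > 0]]
  out
}

# Ordered outer-boundary trace (Moore-style following) of one component.
trace_component <- function(lbl, k) {
  oc <- EBImage::ocontour(EBImage::Image((lbl == k) * 1))
  oc[[which.max(vapply(oc, nrow, integer(1)))]] + 1
}

# Free chaining: closing + component tracing.
chain_free <- function(pts, shape, min_points, min_area, spacing, gap_close,
                       compact_only = FALSE) {
  img <- matrix(0, shape[1L], shape[2L])
  img[pts] <- 1
  cl <- EBImage::closing(EBImage::Image(img),
                         EBImage::makeBrush(as.integer(gap_close), "disc"))
  lbl <- label8(EBImage::imageData(cl) > 0)
  sizes <- tabulate(lbl[lbl > 0])
  loops <- list()
  for (k in seq_along(sizes)) {
    if (sizes[k] < min_points) next
    tr <- trace_component(lbl, k)
    if (nrow(tr) < 3L) next
    if (compact_only) {
      span <- max(diff(range(tr[, 1L])), diff(range(tr[, 2L]))) + 1
      if (span > 2.2 * sqrt(sizes[k]) || sizes[k] > 80L || span > 16) next
    }
    loop <- resample_loop(tr, spacing)
    if (nrow(loop) >= min_points && abs(polygon_area(loop)) >= min_area)
      loops[[length(loops) + 1L]] <- loop
  }
  loops
}

# Template-guided chaining: compact small clusters of accepted points
# become their own loops (gradient-ridge snapped); template boundary loops
# provide the ordering for the rest, with each contour pixel corrected to
# the best-scoring band point inside its search area.
chain_guided <- function(pts, scores, gradient, shape, min_points, min_area,
                         spacing, template, areas) {
  mask <- if (inherits(template, "initial_template")) unclass(template$binary) != 0
          else unclass(as.matrix(template)) != 0
  # cluster accepted points; split off compact small structures
  img <- matrix(0, shape[1L], shape[2L])
  img[pts] <- 1
  cl <- EBImage::closing(EBImage::Image(img), EBImage::makeBrush(3L, "disc"))
  clab <- label8(EBImage::imageData(cl) > 0)
  csizes <- tabulate(clab[clab > 0])
  ctraces <- lapply(seq_along(csizes), function(k) trace_component(clab, k))
  compact <- vapply(seq_along(ctraces), function(k) {
    tr <- ctraces[[k]]
    span <- max(diff(range(tr[, 1L])), diff(range(tr[, 2L]))) + 1
    csizes[k] <= 80L && span <= 16 && span <= 2.2 * sqrt(csizes[k])
  }, logical(1))
  loops <- list()
  for (k in which(compact)) {
    if (csizes[k] < min_points) next
    tr <- snap_to_ridge(ctraces[[k]], gradient, t_min = 0, t_max = 3)
    loop <- resample_loop(tr, spacing)
    if (nrow(loop) >= min_points && abs(polygon_area(loop)) >= min_area)
      loops[[length(loops) + 1L]] <- loop
  }
  in_band <- !compact[clab[pts]]
  band <- pts[in_band, , drop = FALSE]
  Ymat <- matrix(NA_real_, shape[1L], shape[2L])
  Ymat[band] <- scores[in_band]
  area_idx <- matrix(NA_integer_, shape[1L], shape[2L])
  for (i in seq_along(areas))
    area_idx[areas[[i]]$center[1L], areas[[i]]$center[2L]] <- i
  tlab <- label8(mask)
  tsizes <- tabulate(tlab[tlab > 0])
  for (tk in seq_along(tsizes)) {
    if (tsizes[tk] == 0L) next
    tr <- trace_component(tlab, tk)
    if (nrow(tr) >= 3L && abs(polygon_area(tr)) < 50) {
      # blob-scale template loop: the contour-intensity statistics behind
      # the correction do not transfer; keep the consensus boundary
      loop <- resample_loop(tr, spacing)
      if (nrow(loop) >= min_points && abs(polygon_area(loop)) >= min_area)
        loops[[length(loops) + 1L]] <- loop
      next
    }
    sel <- matrix(numeric(0), 0L, 2L)
    for (j in seq_len(nrow(tr))) {
      r <- tr[j, 1L]; c <- tr[j, 2L]
      ai <- area_idx[r, c]
      best <- c(r, c)   # no evidence: the prior boundary stands
      if (!is.na(ai)) {
        e <- areas[[ai]]$extents
        rows <- max(1L, r - e[["up"]]):min(shape[1L], r + e[["down"]])
        cols <- max(1L, c - e[["left"]]):min(shape[2L], c + e[["right"]])
        Ysub <- Ymat[rows, cols, drop = FALSE]
        if (!all(is.na(Ysub))) {
          ij <- which(!is.na(Ysub), arr.ind = TRUE)
          rr <- rows[ij[, 1L]]; cc <- cols[ij[, 2L]]
          val <- Ysub[ij] - 0.02 * sqrt((rr - r)^2 + (cc - c)^2)
          b <- which.max(val)
          best <- c(rr[b], cc[b])
        }
      }
      if (nrow(sel) == 0L || sel[nrow(sel), 1L] != best[1L] ||
          sel[nrow(sel), 2L] != best[2L])
        sel <- rbind(sel, best)
    }
    if (nrow(sel) < min_points) next
    loop <- resample_loop(sel, spacing)
    if (nrow(loop) >= min_points && abs(polygon_area(loop)) >= min_area)
      loops[[length(loops) + 1L]] <- loop
  }
  loops
}

# Debias a loop against the gradient ridge: sample the gradient magnitude
# along the normal of every vertex over [t_min, t_max] (positive t points
# inward), take the per-vertex ridge distance, and apply the loop-wide
# median as one uniform normal offset. Robust to per-vertex gradient
# noise; corrects the systematic offset of a loop traced around an
# acceptance halo (search inward only) or of a prior-dominated corrected
# boundary (symmetric search).
snap_to_ridge <- function(loop, gradient, t_min = 0, t_max = 3) {
  if (is.null(gradient) || nrow(loop) < 4L) return(loop)
  n <- nrow(loop)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  tang <- loop[nxt, , drop = FALSE] - loop[prv, , drop = FALSE]
  len <- sqrt(rowSums(tang^2)); len[len < .EPS] <- 1
  nrm <- cbind(-tang[, 2L], tang[, 1L]) / len
  if (polygon_area(loop) < 0) nrm <- -nrm   # make normals point outward
  ts <- seq(t_min, t_max, by = 0.25)
  best <- vapply(seq_len(n), function(i) {
    g <- bilinear_sample(gradient,
                         loop[i, 1L] - ts * nrm[i, 1L],
                         loop[i, 2L] - ts * nrm[i, 2L])
    ts[which.max(g)]
  }, numeric(1))
  offset_loop(loop, -stats::median(best))
}

# Uniform arc-length resampling of a closed polyline (n x 2, (row, col)).
resample_loop <- function(loop, spacing, n_points = NULL) {
  p <- rbind(loop, loop[1L, ])
  seg <- sqrt(rowSums(diff(p)^2))
  keep <- seg > .EPS
  if (!any(keep)) return(loop[1L, , drop = FALSE])
  p <- rbind(loop[keep, , drop = FALSE], loop[keep, , drop = FALSE][1L, ])
  seg <- sqrt(rowSums(diff(p)^2))
  per <- sum(seg)
  if (is.null(n_points)) n_points <- max(16L, round(per / spacing))
  s <- cumsum(c(0, seg))
  ss <- seq(0, per, length.out = n_points + 1L)[seq_len(n_points)]
  ri <- stats::approx(s, p[, 1L], xout = ss, rule = 2)$y
  ci <- stats::approx(s, p[, 2L], xout = ss, rule = 2)$y
  cbind(row = ri, col = ci)
}
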