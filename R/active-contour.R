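# Parametric active contour (snake) evolution.
#
# The curve v(s) minimizes E_snake = E_int + E_ext with
# E_int = 1/2 * integral( alpha |v'|^2 + beta |v''|^2 ) ds and an external
# term built from the image. The hybrid potential combines the squared
# gradient of the Gaussian-smoothed image with the contour-intensity prior:
# E_img(x) = | grad(G_sigma * I)(x)^2 + P(x) |.
#
# Sign convention: E_img is large AT edges, so the external energy
# contribution is -gamma * E_img (the curve is attracted toward high E_img;
# the force on the points is +gamma * grad E_img). Minimizing +E_img would
# push the contour away from edges, contradicting its purpose of pulling
# the IAC toward target image edges.
#
# Numerics: semi-implicit Euler — the internal (elastic + bending) terms are
# treated implicitly through a cyclic pentadiagonal system, the external
# force explicitly; the step size is halved automatically whenever a step
# would increase the discrete energy, which makes the energy non-increasing
# between resampling events.

#' Snake evolution parameters
#'
#' Profile defaults (IBSR): alpha 30, beta 70, gamma 70.
#'
#' @param alpha elasticity weight (continuity of the contour).
#' @param beta bending weight (smoothness of the contour).
#' @param gamma external (image force) weight.
#' @param step_size evolution time step, default 0.01.
#' @param max_iters iteration cap, default 500.
#' @param tol convergence threshold: mean point displacement (px) that must
#'   be undershot for 10 consecutive iterations, default 0.05.
#' @param resample_every arc-length resampling period (iterations).
#' @param spacing target point spacing for resampling, default 1.5 px.
#' @param min_evolve_area loops enclosing less than this area (px^2) are
#'   kept fixed instead of evolved, default 50. At that scale the boundary
#'   curvature exceeds the stability envelope of the elasticity/bending
#'   weights and a parametric snake collapses small structures into local
#'   extrema (the known small-thickness failure mode of ACMs), destroying
#'   structure the contour-point scoring already localized.
#' @return a `snake_params` list.
#' @export
snake_params <- function(alpha = 30, beta = 70, gamma = 70,
                         step_size = 0.01, max_iters = 500L, tol = 0.05,
                         resample_every = 25L, spacing = 1.5,
                         min_evolve_area = 50) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, step_size > 0,
            min_evolve_area >= 0)
  list(alpha = alpha, beta = beta, gamma = gamma, step_size = step_size,
       max_iters = as.integer(max_iters), tol = tol,
       resample_every = as.integer(resample_every), spacing = spacing,
       min_evolve_area = min_evolve_area)
}

#' Build the hybrid external potential field
#'
#' Smooths the image with a Gaussian of sd `sigma`, squares its gradient
#' magnitude and min-max normalizes it over the image (for a \[0,1\] image
#' the raw squared gradient is two orders of magnitude smaller than the
#' prior weight; normalizing puts the grayscale and gradient information on
#' a common scale, the same practice applied to the gradient in the
#' contour-point score), adds the per-pixel intensity-prior weight `P(x)`
#' (the same prior used during template optimization, looked up on the
#' smoothed intensity), and takes the absolute value. The attraction force
#' is the spatial gradient of the potential. A constant image has zero
#' normalized gradient everywhere.
#'
#' @param target normalized [gray_image()].
#' @param prior an [build_intensity_prior()] result, or `NULL` for a purely
#'   gradient-based potential.
#' @param sigma Gaussian smoothing sd, default 0.5.
#' @return a `potential_field`: list with `E_img`, `fr`, `fc` (force
#'   components along rows and columns).
#' @export
build_potential <- function(target, prior = NULL, sigma = 0.5) {
  stopifnot(sigma > 0)
  sm <- gaussian_smooth(unclass(as.matrix(target)), sigma)
  g <- central_gradient(sm)
  g2 <- g$dr^2 + g$dc^2
  E <- matrix(minmax01(g2, flat = 0), nrow(sm), ncol(sm))
  if (!is.null(prior))
    E <- E + matrix(prior_weight(prior, sm), nrow(sm), ncol(sm))
  E <- abs(E)
  f <- central_gradient(E)
  structure(list(E_img = E, fr = f$dr, fc = f$dc), class = "potential_field")
}

#' Discrete internal energy of a closed contour
#'
#' Cyclic finite differences with arc-length element `ds = perimeter / n`:
#' `E_int = 1/2 * sum( alpha |v'|^2 + beta |v''|^2 ) * ds` with
#' `v' = forward difference / ds` and `v'' = second central difference /
#' ds^2`. For a circle of radius r this converges to
#' `pi * alpha * r + pi * beta / r` as n grows.
#'
#' @param points `n x 2` matrix of (row, col) positions, closed implicitly.
#' @param params a [snake_params()].
#' @return internal energy value.
#' @export
internal_energy <- function(points, params) {
  n <- nrow(points)
  if (n < 4L) stop("internal_energy: need >= 4 points")
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  d1 <- points[nxt, ] - points
  ds <- sum(sqrt(rowSums(d1^2))) / n
  if (ds < .EPS) return(0)
  v1 <- d1 / ds
  v2 <- (points[nxt, ] - 2 * points + points[prv, ]) / ds^2
  0.5 * sum(params$alpha * rowSums(v1^2) + params$beta * rowSums(v2^2)) * ds
}

# Discrete total energy minimized by the evolution scheme: the classic
# per-point discretization (unit parameter spacing; the physical spacing is
# kept near-constant by periodic arc-length resampling, so the spacing
# factors are absorbed into alpha/beta/gamma):
#   E = 1/2 sum( alpha |x_{i+1}-x_i|^2 + beta |x_{i+1}-2x_i+x_{i-1}|^2 )
#       - gamma sum E_img(x_i).
# The external sum is per point, not a ds-weighted line integral: weighting
# by ds would reward perimeter growth anywhere E_img > 0 and make the
# functional unbounded below along ridges.
snake_total_energy <- function(points, field, params) {
  n <- nrow(points)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  d1 <- points[nxt, , drop = FALSE] - points
  d2 <- points[nxt, , drop = FALSE] - 2 * points + points[prv, , drop = FALSE]
  e_int <- 0.5 * sum(params$alpha * rowSums(d1^2) + params$beta * rowSums(d2^2))
  e_ext <- -params$gamma * sum(bilinear_sample(field$E_img,
                                               points[, 1L], points[, 2L]))
  e_int + e_ext
}

# Cyclic pentadiagonal internal-force matrix: A = alpha L2 + beta L4, the
# gradient of the discrete internal energy with respect to the points.
snake_stiffness <- function(n, alpha, beta) {
  a <- alpha; b <- beta
  A <- matrix(0, n, n)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n)) {
    A[i, i] <- 2 * a + 6 * b
    A[i, idx(i + 1L)] <- A[i, idx(i + 1L)] - a - 4 * b
    A[i, idx(i - 1L)] <- A[i, idx(i - 1L)] - a - 4 * b
    A[i, idx(i + 2L)] <- A[i, idx(i + 2L)] + b
    A[i, idx(i - 2L)] <- A[i, idx(i - 2L)] + b
  }
  A
}

#' Evolve the initial active contour under the snake energy
#'
#' Each loop evolves independently by semi-implicit Euler steps
#' `(I + tau A) x+ = x + tau * gamma * F(x)` with the internal stiffness
#' `A` solved implicitly and the external force `F = grad E_img` sampled
#' bilinearly. Steps that would raise the discrete total energy trigger
#' automatic step halving; loops are resampled to uniform arc length every
#' `resample_every` iterations; evolution stops at `max_iters` or when the
#' mean displacement stays below `tol` for 10 consecutive iterations.
#' Points leaving the image domain are clamped to it and flagged.
#'
#' @param iac an [chain_contour()] result (or list of loop matrices).
#' @param field a [build_potential()] result.
#' @param params a [snake_params()].
#' @return a `snake_state`: list with `loops` (evolved point matrices),
#'   `iterations`, `energy` (per loop), `converged`, `clamped` flags and the
#'   per-iteration `energy_trace` of the first loop.
#' @export
evolve <- function(iac, field, params = snake_params()) {
  shape <- dim(field$E_img)
  clamped_any <- FALSE
  trace1 <- NULL
  ev_loop <- function(P, record_trace = FALSE) {
    tau <- params$step_size
    n <- nrow(P)
    Minv <- solve(diag(n) + tau * snake_stiffness(n, params$alpha, params$beta))
    E_cur <- snake_total_energy(P, field, params)
    tr <- if (record_trace) E_cur else NULL
    calm <- 0L; it <- 0L; converged <- FALSE
    while (it < params$max_iters) {
      it <- it + 1L
      fr <- bilinear_sample(field$fr, P[, 1L], P[, 2L])
      fc <- bilinear_sample(field$fc, P[, 1L], P[, 2L])
      stepped <- FALSE
      for (try in 1:30) {
        Pn <- Minv %*% (P + tau * params$gamma * cbind(fr, fc))
        ri <- clamp(Pn[, 1L], 1, shape[1L]); ci <- clamp(Pn[, 2L], 1, shape[2L])
        if (any(ri != Pn[, 1L]) || any(ci != Pn[, 2L])) clamped_any <<- TRUE
        Pn <- cbind(ri, ci)
        E_new <- snake_total_energy(Pn, field, params)
        if (E_new <= E_cur + 1e-9) { stepped <- TRUE; break }
        tau <- tau / 2
        Minv <- solve(diag(n) + tau * snake_stiffness(n, params$alpha, params$beta))
      }
      if (!stepped) { converged <- TRUE; break }
      disp <- mean(sqrt(rowSums((Pn - P)^2)))
      P <- Pn; E_cur <- E_new
      if (record_trace) tr <- c(tr, E_cur)
      calm <- if (disp < params$tol) calm + 1L else 0L
      if (calm >= 10L) { converged <- TRUE; break }
      if (it %% params$resample_every == 0L && it < params$max_iters) {
        P <- resample_loop(P, params$spacing)
        n <- nrow(P)
        Minv <- solve(diag(n) + tau * snake_stiffness(n, params$alpha, params$beta))
        E_cur <- snake_total_energy(P, field, params)
        if (record_trace) tr <- c(tr, E_cur)
      }
    }
    list(P = P, it = it, E = E_cur, conv = converged, trace = tr)
  }
  loops <- unclass(iac)
  areas <- vapply(loops, function(l) abs(polygon_area(as.matrix(l))), numeric(1))
  trace_k <- which.max(areas)   # energy trace follows the largest loop
  res <- lapply(seq_along(loops), function(k) {
    P <- as.matrix(loops[[k]])
    if (nrow(P) < 4L) stop("evolve: loop ", k, " has fewer than 4 points")
    if (areas[k] < (params$min_evolve_area %||% 0))
      return(list(P = P, it = 0L, E = snake_total_energy(P, field, params),
                  conv = TRUE, trace = snake_total_energy(P, field, params)))
    ev_loop(P, record_trace = (k == trace_k))
  })
  structure(list(loops = lapply(res, `[[`, "P"),
                 iterations = vapply(res, `[[`, integer(1), "it"),
                 energy = vapply(res, `[[`, numeric(1), "E"),
                 converged = vapply(res, `[[`, logical(1), "conv"),
                 clamped = clamped_any,
                 energy_trace = res[[trace_k]]$trace),
            class = "snake_state")
}

#' Rasterize closed contour loops into a binary mask
#'
#' Even-odd scanline polygon fill at pixel centers; pixel centers lying
#' exactly on an edge count as foreground. The union of all loops is the
#' foreground. Degenerate loops (enclosed area below one pixel) contribute
#' nothing and set the `degenerate` attribute.
#'
#' A loop through pixel centers represents a boundary chain whose pixels
#' belong to the region, so the continuous region boundary runs half a pixel
#' outside the chain: each loop is therefore inflated by `inflate` px along
#' its outward vertex normals before filling. Set `inflate = 0` for a strict
#' geometric fill of the polygon as given.
#'
#' @param state a [evolve()] result, [chain_contour()] result, or a single
#'   loop matrix.
#' @param shape image dimensions `c(nrow, ncol)`.
#' @param inflate outward normal offset in px applied before filling,
#'   default 0.5.
#' @return a [label_image()] mask (1 = inside).
#' @export
contour_to_mask <- function(state, shape, inflate = 0.5) {
  loops <- if (inherits(state, "snake_state")) state$loops
           else if (inherits(state, "initial_active_contour")) unclass(state)
           else if (is.matrix(state)) list(state)
           else as.list(state)
  mask <- matrix(FALSE, shape[1L], shape[2L])
  degenerate <- FALSE
  for (loop in loops) {
    loop <- as.matrix(loop)
    area <- abs(polygon_area(loop))
    if (area < 1) { degenerate <- TRUE; next }
    if (inflate > 0) loop <- offset_loop(loop, inflate)
    mask <- mask | fill_polygon(loop, shape)
  }
  out <- label_image(mask * 1L)
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

# Offset a closed loop outward along its vertex normals by `d` px.
# The outward side is determined from the loop's signed area.
offset_loop <- function(loop, d) {
  n <- nrow(loop)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  tang <- loop[nxt, , drop = FALSE] - loop[prv, , drop = FALSE]
  len <- sqrt(rowSums(tang^2)); len[len < .EPS] <- 1
  # rotate tangent (dr, dc) by 90 degrees -> normal candidate (-dc, dr)
  nrm <- cbind(-tang[, 2L], tang[, 1L]) / len
  if (polygon_area(loop) < 0) nrm <- -nrm
  loop + d * nrm
}

# Signed area (shoelace) of a closed polygon given as (row, col).
polygon_area <- function(loop) {
  y <- loop[, 1L]; x <- loop[, 2L]
  n <- length(x); nxt <- c(2:n, 1L)
  sum(x * y[nxt] - x[nxt] * y) / 2
}

# Even-odd scanline fill; boundary pixel centers included.
fill_polygon <- function(loop, shape) {
  m <- matrix(FALSE, shape[1L], shape[2L])
  y <- loop[, 1L]; x <- loop[, 2L]
  n <- length(x); nxt <- c(2:n, 1L)
  eps <- 1e-9
  for (r in max(1L, floor(min(y))):min(shape[1L], ceiling(max(y)))) {
    y1 <- y; y2 <- y[nxt]
    cross <- (pmin(y1, y2) <= r) & (r < pmax(y1, y2))
    if (any(cross)) {
      xc <- x[cross] + (r - y1[cross]) * (x[nxt][cross] - x[cross]) /
        (y2[cross] - y1[cross])
      xc <- sort(xc)
      for (k in seq(1L, length(xc) - 1L, by = 2L)) {
        c1 <- max(1L, ceiling(xc[k] - eps)); c2 <- min(shape[2L], floor(xc[k + 1L] + eps))
        if (c1 <= c2) m[r, c1:c2] <- TRUE
      }
    }
  }
  # include pixel centers lying exactly on an edge
  for (i in seq_len(n)) {
    p1 <- loop[i, ]; p2 <- loop[nxt[i], ]
    len <- sqrt(sum((p2 - p1)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len / 0.5) + 1L))
    pr <- p1[1L] + ts * (p2[1L] - p1[1L])
    pc <- p1[2L] + ts * (p2[2L] - p1[2L])
    cand <- unique(cbind(round(pr), round(pc)))
    for (j in seq_len(nrow(cand))) {
      rr <- cand[j, 1L]; cc <- cand[j, 2L]
      if (rr < 1 || rr > shape[1L] || cc < 1 || cc > shape[2L]) next
      if (point_segment_distance(c(rr, cc), p1, p2) < 1e-7) m[rr, cc] <- TRUE
    }
  }
  m
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  t <- if (L2 < .EPS) 0 else clamp(sum((p - a) * ab) / L2, 0, 1)
  sqrt(sum((a + t * ab - p)^2))
}
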