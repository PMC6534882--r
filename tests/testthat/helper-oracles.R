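# Independent brute-force oracles used across tests. These deliberately use
# naive per-element loops so they share no code path with the package
# implementations they check.

# Per-pixel weighted-vote fusion by explicit loops over atlases and classes.
oracle_fuse <- function(labels, weights, classes, target_class, threshold = 0.5) {
  nr <- nrow(labels[[1]]); nc <- ncol(labels[[1]])
  fp <- matrix(0, nr, nc); lab <- matrix(classes[1], nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    best_s <- -Inf; best_c <- classes[1]
    for (cl in classes) {
      s <- 0
      for (i in seq_along(labels))
        s <- s + weights[[i]][r, c] * (labels[[i]][r, c] == cl)
      if (cl == target_class) fp[r, c] <- min(1, max(0, s))
      if (s > best_s) { best_s <- s; best_c <- cl }
    }
    lab[r, c] <- best_c
  }
  list(fused_prob = fp, label = lab, binary = (fp >= threshold) * 1L)
}

# All-pairs directed Hausdorff on boundary (or full) pixel sets.
oracle_hausdorff <- function(A, B, boundary = TRUE) {
  bnd <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(FALSE, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (!m[r, c]) next
      edge <- FALSE
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc || !m[rr, cc]) edge <- TRUE
      }
      out[r, c] <- edge
    }
    out
  }
  if (boundary) { A <- bnd(A); B <- bnd(B) }
  pa <- which(A, arr.ind = TRUE); pb <- which(B, arr.ind = TRUE)
  dir_h <- function(P, Q) {
    worst <- 0
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q)))
        best <- min(best, sqrt(sum((P[i, ] - Q[j, ])^2)))
      worst <- max(worst, best)
    }
    worst
  }
  max(dir_h(pa, pb), dir_h(pb, pa))
}

# Inclusive point-in-polygon (even-odd crossing test; points on an edge
# count as inside).
oracle_point_in_polygon <- function(py, px, loop) {
  n <- nrow(loop)
  y <- loop[, 1]; x <- loop[, 2]
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ab <- c(y[j], x[j]) - c(y[i], x[i])
    L2 <- sum(ab^2)
    t <- if (L2 == 0) 0 else max(0, min(1, ((py - y[i]) * ab[1] + (px - x[i]) * ab[2]) / L2))
    if (sqrt((y[i] + t * ab[1] - py)^2 + (x[i] + t * ab[2] - px)^2) < 1e-9)
      return(TRUE)
  }
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if ((y[i] <= py) != (y[j] <= py)) {
      xc <- x[i] + (py - y[i]) * (x[j] - x[i]) / (y[j] - y[i])
      if (px < xc) inside <- !inside
    }
  }
  inside
}

# Small phantom configuration for fast unit tests.
tiny_config <- function(seed, ...) {
  args <- utils::modifyList(list(size = c(96L, 96L), n_atlases = 3L, seed = seed),
                            list(...))
  do.call(phantom_config, args)
}
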