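# Local weighted-voting label fusion.
#
# Each warped atlas votes for its label at every pixel; the vote weight is
# the NCC between the small patches of the target and the warped atlas
# intensity centred at that pixel (local area 3x3 by default). The fused
# class is the argmax of the weighted votes; the binary template for the
# class of interest thresholds its normalized score at 0.5.

#' Per-pixel local patch-NCC fusion weights
#'
#' For every atlas and pixel, computes the NCC between the
#' `patch_size` x `patch_size` patches of the target and the warped atlas
#' intensity centred at the pixel (patches are clipped at the image border).
#' Negative patch NCCs are clamped to zero — votes must be nonnegative, and a
#' negatively correlated patch carries no supporting evidence. Weights are
#' then normalized across atlases to sum to one; pixels where every raw
#' weight is zero fall back to uniform weights so they can still be labeled.
#'
#' @param target a [gray_image()].
#' @param warped_intensities list of warped atlas [gray_image()]s.
#' @param patch_size odd integer >= 3, default 3.
#' @return a `fusion_weights` object: list with `w` (list of weight
#'   matrices summing to 1 across atlases) and `patch_size`.
#' @export
local_weights <- function(target, warped_intensities, patch_size = 3L) {
  if (patch_size < 3L || patch_size %% 2L == 0L)
    stop("local_weights: patch_size must be an odd integer >= 3")
  tgt <- unclass(as.matrix(target))
  nr <- nrow(tgt); nc <- ncol(tgt)
  h <- (patch_size - 1L) %/% 2L
  n <- box_count(nr, nc, h)
  St <- box_sum(tgt, h); Stt <- box_sum(tgt * tgt, h)
  vt <- Stt - St * St / n
  raw <- lapply(warped_intensities, function(w) {
    w <- unclass(as.matrix(w))
    if (!identical(dim(w), dim(tgt))) stop("local_weights: shape mismatch")
    Sw <- box_sum(w, h); Sww <- box_sum(w * w, h); Stw <- box_sum(tgt * w, h)
    vw <- Sww - Sw * Sw / n
    cov <- Stw - St * Sw / n
    r <- matrix(0, nr, nc)
    ok <- vt > 1e-10 & vw > 1e-10
    r[ok] <- cov[ok] / sqrt(vt[ok] * vw[ok])
    pmax(r, 0)  # clamp negative correlations
  })
  total <- Reduce(`+`, raw)
  L <- length(raw)
  w <- lapply(raw, function(r) {
    out <- matrix(1 / L, nr, nc)        # uniform fallback where all raw are 0
    nz <- total > 0
    out[nz] <- r[nz] / total[nz]
    out
  })
  structure(list(w = w, patch_size = patch_size), class = "fusion_weights")
}

#' Fuse warped atlas labels by local weighted voting
#'
#' Per pixel, the score of class `c` is the sum of the weights of the atlases
#' voting `c`; the fused label is the argmax over classes, and the binary
#' template for `target_class` thresholds that class's score at
#' `threshold` (default 0.5), with exact ties assigned to foreground.
#'
#' @param warped_labels list of warped [label_image()]s.
#' @param weights a [local_weights()] result (or `NULL` for uniform weights,
#'   i.e. majority voting).
#' @param target_class the class of interest for the binary template.
#' @param classes optional integer vector of classes to score (default: all
#'   classes present).
#' @param threshold binarization threshold on the target-class score.
#' @return an `initial_template`: list with `fused_prob` (target-class score
#'   in \[0,1\]), `label` (argmax [label_image()]), `binary`
#'   ([label_image()] mask) and `threshold`.
#' @export
fuse <- function(warped_labels, weights = NULL, target_class = 1L,
                 classes = NULL, threshold = 0.5) {
  if (length(warped_labels) == 0L) stop("fuse: no warped labels")
  dims <- dim(warped_labels[[1L]])
  L <- length(warped_labels)
  if (is.null(weights)) {
    w <- rep(list(matrix(1 / L, dims[1L], dims[2L])), L)
  } else w <- weights$w
  if (length(w) != L) stop("fuse: weights/labels length mismatch")
  if (is.null(classes))
    classes <- sort(unique(unlist(lapply(warped_labels, function(m) unique(as.vector(m))))))
  if (length(classes) == 0L) stop("fuse: empty class set")
  if (!target_class %in% classes) classes <- sort(c(classes, target_class))
  scores <- lapply(classes, function(cl) {
    s <- matrix(0, dims[1L], dims[2L])
    for (i in seq_len(L)) s <- s + w[[i]] * (unclass(warped_labels[[i]]) == cl)
    s
  })
  names(scores) <- as.character(classes)
  # argmax label; earlier class wins ties (background first in sorted order)
  lab <- matrix(classes[1L], dims[1L], dims[2L])
  best <- scores[[1L]]
  for (k in seq_along(classes)[-1L]) {
    better <- scores[[k]] > best
    lab[better] <- classes[k]
    best[better] <- scores[[k]][better]
  }
  fp <- clamp(scores[[as.character(target_class)]], 0, 1)
  structure(list(fused_prob = fp,
                 label = label_image(lab),
                 binary = label_image((fp >= threshold) * 1L),
                 threshold = threshold,
                 target_class = target_class),
            class = "initial_template")
}
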