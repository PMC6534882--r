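# Segmentation evaluation: Dice, Recall, Precision and Hausdorff distance.

#' Volumetric overlap metrics
#'
#' With T the reference pixel set of `target_class` and F the segmented set:
#' `Dice = 2|T∩F| / (|T|+|F|)`, `Recall = |T∩F| / |T|`,
#' `Precision = |T∩F| / |F|` (defined as 0 when F is empty).
#'
#' @param reference,segmented same-shape [label_image()]s.
#' @param target_class label of interest.
#' @return named list `dice`, `recall`, `precision`.
#' @export
overlap_metrics <- function(reference, segmented, target_class = 1L) {
  R <- unclass(as.matrix(reference)) == target_class
  S <- unclass(as.matrix(segmented)) == target_class
  if (!identical(dim(R), dim(S))) stop("overlap_metrics: shape mismatch")
  nT <- sum(R)
  if (nT == 0L) stop("overlap_metrics: reference does not contain class ", target_class)
  nF <- sum(S); nI <- sum(R & S)
  list(dice = 2 * nI / (nT + nF),
       recall = nI / nT,
       precision = if (nF == 0L) 0 else nI / nF)
}

#' Hausdorff distance between two segmentations
#'
#' `HD(T, F) = max(H1(T, F), H2(F, T))` with `H1` the directed
#' farthest-nearest-point distance. By default the distance is computed
#' between the boundary pixel sets of the two masks (the usual surface
#' distance); `boundary = FALSE` uses the full pixel sets. Distances are
#' Euclidean between pixel centers, scaled by `spacing`.
#'
#' @param reference,segmented same-shape [label_image()]s.
#' @param target_class label of interest.
#' @param boundary compare boundary pixel sets (default) or full sets.
#' @param spacing physical pixel size, default 1.
#' @return Hausdorff distance (>= 0).
#' @export
hausdorff_distance <- function(reference, segmented, target_class = 1L,
                               boundary = TRUE, spacing = 1) {
  R <- unclass(as.matrix(reference)) == target_class
  S <- unclass(as.matrix(segmented)) == target_class
  if (!identical(dim(R), dim(S))) stop("hausdorff_distance: shape mismatch")
  if (!any(R) || !any(S)) stop("hausdorff_distance: empty mask for class ", target_class)
  if (boundary) { R <- boundary_pixels(R); S <- boundary_pixels(S) }
  A <- which(R, arr.ind = TRUE); B <- which(S, arr.ind = TRUE)
  d2 <- outer(A[, 1L], B[, 1L], `-`)^2 + outer(A[, 2L], B[, 2L], `-`)^2
  h1 <- sqrt(max(apply(d2, 1L, min)))
  h2 <- sqrt(max(apply(d2, 2L, min)))
  max(h1, h2) * spacing
}

#' Full metrics report for one segmentation
#'
#' @inheritParams hausdorff_distance
#' @return a `metrics_report` list: `dice`, `recall`, `precision`,
#'   `hausdorff`.
#' @export
metrics_report <- function(reference, segmented, target_class = 1L,
                           boundary = TRUE, spacing = 1) {
  ov <- overlap_metrics(reference, segmented, target_class)
  structure(c(ov, list(hausdorff = hausdorff_distance(reference, segmented,
                                                      target_class, boundary,
                                                      spacing))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Dice %.4f  Recall %.4f  Precision %.4f  HD %.3f px\n",
              x$dice, x$recall, x$precision, x$hausdorff))
  invisible(x)
}
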