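# End-to-end pipeline: registration -> fusion -> template optimization ->
# active contour, with per-stage artifacts and an optional run manifest.

#' Pipeline configuration profiles
#'
#' `"ibsr"` and `"mrbrains"` select the published parameter sets
#' (search-area half-width 8, prior/gradient weights 0.7/0.3 or 0.6/0.4,
#' Y threshold 0.6, snake weights 30/70/70 or 60/100/100); `"custom"` starts
#' from the IBSR profile and applies the overrides in `...`.
#'
#' @param profile one of `"ibsr"`, `"mrbrains"`, `"custom"`.
#' @param target_class class of interest, default 1.
#' @param seed integer seed for any stochastic stage (the pipeline itself is
#'   deterministic; the seed is recorded in the manifest).
#' @param ... overrides for `custom` (any of the fields below).
#' @return a `pipeline_config` list with fields `ncc_threshold`,
#'   `fallback_k`, `half_width`, `w_p`, `w_g`, `y_threshold`, `sigma`,
#'   `patch_size`, `n_bins`, `snake` ([snake_params()]), `target_class`,
#'   `seed`.
#' @export
pipeline_config <- function(profile = c("ibsr", "mrbrains", "custom"),
                            target_class = 1L, seed = 1L, ...) {
  profile <- match.arg(profile)
  cfg <- list(profile = profile,
              ncc_threshold = 0.87, fallback_k = 3L,
              patch_size = 3L, fusion_threshold = 0.5,
              half_width = 8L, w_p = 0.7, w_g = 0.3, y_threshold = 0.6,
              sigma = 0.5, n_bins = 20L,
              snake = snake_params(alpha = 30, beta = 70, gamma = 70),
              target_class = as.integer(target_class), seed = as.integer(seed))
  if (profile == "mrbrains") {
    cfg$w_p <- 0.6; cfg$w_g <- 0.4
    cfg$snake <- snake_params(alpha = 60, beta = 100, gamma = 100)
  }
  if (profile == "custom") {
    dots <- list(...)
    for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Segment a target slice with the full multi-atlas active-contour pipeline
#'
#' Runs, in order: ROI estimation and intensity normalization; affine/NCC
#' registration of every atlas with the 0.87 NCC selection cut; local
#' weighted-voting label fusion into the initial template; template
#' optimization (search areas, prior + Roberts-gradient scoring, chaining
#' into the IAC); snake evolution under the hybrid potential; rasterization
#' of the final contour. Every intermediate is returned and, when
#' `output_dir` is given, persisted together with a JSON run manifest.
#'
#' @param target a [gray_image()] (raw intensities are fine; normalization is
#'   applied internally).
#' @param atlases list of [atlas()] objects.
#' @param config a [pipeline_config()].
#' @param reference optional [label_image()] ground truth; when given,
#'   metrics are computed for the final mask and the initial template.
#' @param output_dir optional directory for stage artifacts.
#' @return a `segmentation_result`: list with `mask` (final
#'   [label_image()]), `metrics` and `template_metrics` (when `reference`
#'   given), and `artifacts` (registrations, template, prior, iac, snake,
#'   roi, normalized target).
#' @export
segment_target <- function(target, atlases, config = pipeline_config(),
                           reference = NULL, output_dir = NULL) {
  if (length(atlases) == 0L) stop("segment_target: at least one atlas required")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  # --- ROI + normalization -------------------------------------------------
  norm <- stage("normalize", {
    g <- unclass(normalize_intensity(target))     # global [0,1] for thresholding
    tissue <- g > EBImage::otsu(EBImage::Image(g))
    roi <- compute_roi(tissue)
    list(target = normalize_intensity(target, roi), roi = roi)
  })
  atl_norm <- stage("normalize_atlases", lapply(atlases, function(a)
    atlas(normalize_intensity(a$intensity), a$label, a$id)))
  # --- registration + selection -------------------------------------------
  regs <- stage("register", register_all(norm$target, atl_norm,
                                         ncc_threshold = config$ncc_threshold,
                                         fallback_k = config$fallback_k,
                                         roi = norm$roi))
  # --- label fusion --------------------------------------------------------
  template <- stage("fuse", {
    w <- local_weights(norm$target, lapply(regs, `[[`, "warped_intensity"),
                       config$patch_size)
    fuse(lapply(regs, `[[`, "warped_label"), w,
         target_class = config$target_class, threshold = config$fusion_threshold)
  })
  # --- template optimization ----------------------------------------------
  prior <- stage("prior", build_intensity_prior(atl_norm, config$target_class,
                                                config$n_bins))
  iac <- stage("template_optimization", {
    contour <- extract_template_contour(template)
    areas <- set_search_areas(contour, dim(norm$target), config$half_width)
    pts <- score_candidates(norm$target, areas, prior,
                            w_p = config$w_p, w_g = config$w_g,
                            threshold = config$y_threshold, sigma = config$sigma)
    chain_contour(pts, dim(norm$target), template = template, areas = areas)
  })
  optimized_mask <- stage("optimized_mask", contour_to_mask(iac, dim(norm$target)))
  # --- active contour ------------------------------------------------------
  snake <- stage("snake", {
    field <- build_potential(norm$target, prior, config$sigma)
    evolve(iac, field, config$snake)
  })
  mask <- stage("rasterize", contour_to_mask(snake, dim(norm$target)))
  metrics <- template_metrics <- optimized_metrics <- NULL
  if (!is.null(reference)) {
    metrics <- metrics_report(reference, mask, config$target_class)
    template_metrics <- metrics_report(reference, template$binary, config$target_class)
    optimized_metrics <- metrics_report(reference, optimized_mask, config$target_class)
  }
  res <- structure(list(mask = mask, metrics = metrics,
                        template_metrics = template_metrics,
                        optimized_metrics = optimized_metrics,
                        artifacts = list(roi = norm$roi,
                                         target_norm = norm$target,
                                         registrations = regs,
                                         template = template,
                                         optimized_mask = optimized_mask,
                                         prior = prior, iac = iac,
                                         snake = snake),
                        config = config),
                   class = "segmentation_result")
  if (!is.null(output_dir)) persist_run(res, output_dir)
  res
}

# Persist stage artifacts and a JSON manifest.
persist_run <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  a <- res$artifacts
  write_fixture_image(a$target_norm, file.path(dir, "target_norm.fgm"))
  write_fixture_label(a$template$binary, file.path(dir, "initial_template.pgm"))
  write_fixture_label(res$mask, file.path(dir, "final_mask.pgm"))
  write_fixture_label(a$optimized_mask, file.path(dir, "optimized_mask.pgm"))
  for (r in a$registrations)
    write_fixture_label(r$warped_label, file.path(dir, paste0("warped_", r$id, ".pgm")))
  jsonlite::write_json(
    list(roi = unclass(a$roi),
         prior = list(bin_edges = a$prior$bin_edges, counts = a$prior$bin_counts,
                      pr = a$prior$pr, P = a$prior$P),
         iac = lapply(unclass(a$iac), function(l) unname(as.matrix(l))),
         final_contour = lapply(a$snake$loops, unname),
         registrations = lapply(a$registrations, function(r)
           list(id = r$id, K = r$params$K, theta_rad = r$params$theta,
                dx = r$params$dx, dy = r$params$dy, ncc = r$ncc)),
         config = unclass(res$config),
         metrics = if (!is.null(res$metrics)) unclass(res$metrics)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Leave-one-out evaluation over a set of labeled images
#'
#' Each labeled image serves once as the target (its label as the
#' reference) while the remaining images form the atlas set.
#'
#' @param images list of [gray_image()]s.
#' @param labels list of matching [label_image()]s.
#' @param config a [pipeline_config()].
#' @return data.frame with one row per held-out subject: `subject`, `dice`,
#'   `recall`, `precision`, `hausdorff`.
#' @export
leave_one_out <- function(images, labels, config = pipeline_config()) {
  stopifnot(length(images) == length(labels), length(images) >= 2L)
  rows <- lapply(seq_along(images), function(i) {
    atl <- lapply(setdiff(seq_along(images), i), function(j)
      atlas(images[[j]], labels[[j]], id = paste0("subj_", j)))
    r <- segment_target(images[[i]], atl, config, reference = labels[[i]])
    data.frame(subject = i, dice = r$metrics$dice, recall = r$metrics$recall,
               precision = r$metrics$precision, hausdorff = r$metrics$hausdorff)
  })
  do.call(rbind, rows)
}
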