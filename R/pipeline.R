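# End-to-end convenience pipeline on a phantom: generate, stitch,
# downscale, detect, classify, evaluate. This is the surrogate benchmark
# for joint detection-plus-classification accuracy.

#' Run the full phantom benchmark pipeline
#'
#' Generates a seeded phantom tile set, stitches it from its manifest by
#' recorded coordinates, downscales for detection (the phantom's cells,
#' soma plus processes, span about 100 native px, under the 200 px display
#' target, so the scale clamps to 1 and no resampling occurs at the default
#' settings), detects somata, classifies each detection by process count,
#' assigns the predicted class to its detection, and evaluates against the
#' phantom ground truth with IoU >= 0.5 matching, ghosts excluded.
#'
#' @param spec an [phantom_spec()]; default is the 200-cell benchmark.
#' @param geom an [acquisition_geometry()].
#' @param det_cfg an [detector_config()].
#' @param cls_cfg an [classifier_config()].
#' @param target_cell_px display target passed to
#'   [downscale_for_detection()].
#' @return list with `truth`, `manifest`, `panorama` (detection-scale),
#'   `scale`, `detections`, `cells`, `metrics` (from
#'   [evaluate_detections()]).
#' @export
run_phantom_pipeline <- function(spec = phantom_spec(seed = 42L),
                                 geom = default_phantom_geometry(),
                                 det_cfg = detector_config(
                                   soma_axes_px = spec$soma_axes_px),
                                 cls_cfg = classifier_config(),
                                 target_cell_px = 200) {
  ph <- generate_phantom(spec, geom)
  pano <- stitch(ph$manifest)
  native_cell_px <- max(spec$soma_axes_px) + 2 * spec$process_length_px
  ds <- downscale_for_detection(pano, native_cell_px, target_cell_px)
  dets <- detect_cells(ds$panorama, det_cfg)
  cells <- classify_cells(ds$panorama, dets, cls_cfg)
  dets$class <- cells$status
  truth <- ph$truth
  if (ds$scale != 1) {
    truth$X <- truth$X * ds$scale; truth$Y <- truth$Y * ds$scale
    truth$W <- truth$W * ds$scale; truth$H <- truth$H * ds$scale
  }
  metrics <- evaluate_detections(dets, truth)
  list(truth = ph$truth, manifest = ph$manifest, panorama = ds$panorama,
       scale = ds$scale, detections = dets, cells = cells,
       metrics = metrics)
}
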