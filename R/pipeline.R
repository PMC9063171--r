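#' Process a synthetic scene (or any image plus weight) into a sample
#'
#' Measures all grains (optionally after bicubic enhancement) and
#' aggregates them into one `sample_measurement`, with MGW from the scene's
#' ground-truth total weight.
#'
#' @param scene a scene from [generate_scene()] / [generate_dataset()].
#' @param enhance bicubic upscale factor used before segmentation.
#' @param ... passed to [measure_image()].
#' @return a `sample_measurement` (see [aggregate_sample()]).
#' @export
process_scene <- function(scene, enhance = 1, ...) {
  meas <- measure_image(scene$image, enhance = enhance, ...)
  id <- if (!is.null(scene$sample_id)) scene$sample_id else "sample"
  aggregate_sample(meas, sample_weight = scene$truth$total_weight,
                   sample_id = id)
}

#' Run the full pipeline over a synthetic dataset
#'
#' Segments and measures every scene, aggregates to samples, and returns
#' the per-sample analysis table (mean descriptors, index catalogue, MGW,
#' grouping columns).
#'
#' @param scenes list of scenes from [generate_dataset()].
#' @param enhance bicubic upscale factor.
#' @param unit_system passed to [sample_table()].
#' @param ... passed to [measure_image()].
#' @return per-sample data.frame (see [sample_table()]).
#' @export
process_dataset <- function(scenes, enhance = 1, unit_system = "mm", ...) {
  sms <- lapply(scenes, process_scene, enhance = enhance, ...)
  extra <- NULL
  if (!is.null(scenes[[1]]$year)) {
    extra <- data.frame(year = vapply(scenes, `[[`, numeric(1), "year"),
                        irrigation = vapply(scenes, `[[`, character(1), "irrigation"),
                        stringsAsFactors = FALSE)
  }
  sample_table(sms, unit_system = unit_system, extra = extra)
}
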