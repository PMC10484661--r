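#' Detection configuration for in vitro droplet fields
#'
#' Parameters of the threshold recipe: objects are pixels at or above
#' `background mean + sd_multiplier * background sd`, labeled at the chosen
#' connectivity, and kept only when their equivalent circular diameter
#' `2 * sqrt(area / pi)` reaches `min_diameter_um`. Densities are reported
#' per `view_area_um2` of field (default 4430 um^2, a standard 100x
#' confocal field of view).
#'
#' @param sd_multiplier Threshold multiplier k in `bg + k * sd` (default 3).
#' @param min_diameter_um Minimum equivalent diameter (um, default 0.5).
#' @param connectivity Pixel connectivity, 4 or 8 (default 8).
#' @param exclude_border Drop components touching the field border, whose
#'   area and diameter are censored (default TRUE).
#' @param view_area_um2 Imaging-view area used to normalize densities.
#' @return A `detection_config` list.
#' @export
detection_config <- function(sd_multiplier = 3, min_diameter_um = 0.5,
                             connectivity = 8, exclude_border = TRUE,
                             view_area_um2 = 4430) {
  if (sd_multiplier <= 0) abort("`sd_multiplier` must be positive.")
  if (min_diameter_um < 0) abort("`min_diameter_um` must be >= 0.")
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  structure(
    list(sd_multiplier = sd_multiplier, min_diameter_um = min_diameter_um,
         connectivity = connectivity, exclude_border = exclude_border,
         view_area_um2 = view_area_um2),
    class = "detection_config"
  )
}

#' Detect condensates by intensity threshold and diameter filter
#'
#' Implements the in vitro recipe: threshold the raw image at
#' `bg$mean + sd_multiplier * bg$sd`, label connected components, discard
#' components whose equivalent circular diameter falls below
#' `min_diameter_um` (and, by default, components touching the border), and
#' measure area, diameter, mean intensity, centroid and partition ratio for
#' each survivor.
#'
#' @param image A [field_image] (raw intensities).
#' @param bg A `background_estimate` from [estimate_background()] on the
#'   same image; computed automatically when NULL.
#' @param config A [detection_config()].
#' @return A tibble with one row per condensate (columns `label`,
#'   `area_um2`, `equivalent_diameter_um`, `mean_intensity`,
#'   `partition_ratio`, `centroid_x_um`, `centroid_y_um`, `n_px`), carrying
#'   the label matrix (`attr(, "labels")`), `bg` and `config` as attributes.
#' @export
detect_condensates <- function(image, bg = NULL, config = detection_config()) {
  assert_field_image(image)
  if (is.null(bg)) bg <- estimate_background(image, sd_multiplier = config$sd_multiplier)
  stopifnot(inherits(bg, "background_estimate"))
  mask <- image$data >= bg$mean + config$sd_multiplier * bg$sd
  labels <- label_components(mask, config$connectivity)
  stats <- component_stats(labels, image)
  if (nrow(stats) > 0) {
    keep <- stats$equivalent_diameter_um >= config$min_diameter_um
    if (config$exclude_border) keep <- keep & !stats$touches_border
    dropped <- stats$label[!keep]
    stats <- stats[keep, ]
    if (length(dropped)) labels[labels %in% dropped] <- 0L
  }
  records <- stats %>%
    mutate(partition_ratio = partition_ratio(.data$mean_intensity, bg)) %>%
    dplyr::select(dplyr::all_of(c(
      "label", "n_px", "area_um2", "equivalent_diameter_um",
      "mean_intensity", "partition_ratio",
      "centroid_x_um", "centroid_y_um")))
  attr(records, "labels") <- labels
  attr(records, "bg") <- bg
  attr(records, "config") <- config
  records
}

#' Partition ratio of condensate mean intensity over background
#'
#' The partition ratio is the mean fluorescence intensity within a
#' condensate divided by the mean intensity of the condensate-free
#' background (solution, or cytoplasm for cellular foci).
#'
#' @param mean_intensity Numeric vector of object mean intensities (ADU).
#' @param bg A `background_estimate`, or a positive background mean.
#' @return Numeric vector of partition ratios.
#' @export
#' @examples
#' partition_ratio(890, 100)  # 8.9
partition_ratio <- function(mean_intensity, bg) {
  m <- if (inherits(bg, "background_estimate")) bg$mean else bg
  if (!is.numeric(m) || length(m) != 1 || m <= 0) {
    abort("Background mean must be a single positive number.")
  }
  mean_intensity / m
}

#' Condensate density per imaging view
#'
#' Normalizes the detected object count to the configured view area:
#' `count * view_area_um2 / field area`.
#'
#' @param records Detection tibble from [detect_condensates()].
#' @param image The analyzed [field_image].
#' @param config A [detection_config()] (for `view_area_um2`).
#' @return Scalar density (objects per view area).
#' @export
droplet_density <- function(records, image, config = detection_config()) {
  assert_field_image(image)
  nrow(records) * config$view_area_um2 / field_area_um2(image)
}

#' Summarize per-droplet records as box-plot statistics
#'
#' Pools records and reports, for each measured quantity (partition ratio,
#' area, equivalent diameter, mean intensity), the median, quartiles, mean,
#' and whisker bounds (minimum and maximum after excluding points beyond
#' 1.5 x IQR from the quartiles).
#'
#' @param records Tibble of condensate or focus records.
#' @return Tibble with one row per metric; empty input yields an empty
#'   tibble rather than an error.
#' @export
summarize_droplets <- function(records) {
  metrics <- intersect(
    c("partition_ratio", "area_um2", "equivalent_diameter_um", "mean_intensity"),
    names(records))
  if (is.null(records) || nrow(records) == 0) {
    return(tibble(metric = character(), n = integer(), mean = double(),
                  median = double(), q25 = double(), q75 = double(),
                  whisker_low = double(), whisker_high = double()))
  }
  purrr::map_dfr(metrics, function(mt) {
    x <- records[[mt]]
    qs <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- qs[3] - qs[1]
    inlier <- x >= qs[1] - 1.5 * iqr & x <= qs[3] + 1.5 * iqr
    tibble(metric = mt, n = length(x), mean = mean(x), median = qs[2],
           q25 = qs[1], q75 = qs[3],
           whisker_low = min(x[inlier]), whisker_high = max(x[inlier]))
  })
}
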