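#' Classify condensates as ring-shaped or filled
#'
#' For each detected condensate, compares the mean intensity of a central
#' core disk (radius `core_fraction * R`, with R the equivalent radius) to
#' the mean over the surrounding annulus out to R. A condensate whose
#' core-to-shell ratio falls below `ring_threshold` is called a ring;
#' condensates whose equivalent radius spans fewer than 2 pixels are
#' flagged indeterminate.
#'
#' @param image The [field_image] the condensates were detected on.
#' @param records Detection tibble from [detect_condensates()] (columns
#'   `label`, `equivalent_diameter_um`, `centroid_x_um`, `centroid_y_um`).
#' @param core_fraction Core radius as a fraction of R (default 0.5).
#' @param ring_threshold Core/shell ratio below which the call is "ring"
#'   (default 0.7).
#' @return `records` with added columns `core_mean`, `shell_mean`,
#'   `core_to_shell`, `call` (`"ring"`/`"filled"`/NA), `determinate`.
#' @export
classify_rings <- function(image, records, core_fraction = 0.5,
                           ring_threshold = 0.7) {
  assert_field_image(image)
  if (core_fraction <= 0 || core_fraction >= 1) {
    abort("`core_fraction` must lie in (0, 1).")
  }
  px <- image$pixel_size_um
  co <- pixel_coords(image)
  res <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    R <- rec$equivalent_diameter_um / 2
    if (R < 2 * px) {
      return(tibble(core_mean = NA_real_, shell_mean = NA_real_,
                    core_to_shell = NA_real_, call = NA_character_,
                    determinate = FALSE))
    }
    d2 <- (co$x - rec$centroid_x_um)^2 + (co$y - rec$centroid_y_um)^2
    core <- d2 <= (core_fraction * R)^2
    shell <- d2 <= R^2 & !core
    cm <- mean(image$data[core]); sm <- mean(image$data[shell])
    ratio <- cm / sm
    tibble(core_mean = cm, shell_mean = sm, core_to_shell = ratio,
           call = if (ratio < ring_threshold) "ring" else "filled",
           determinate = TRUE)
  })
  dplyr::bind_cols(records, res)
}

#' Percentage of ring-shaped condensates
#'
#' @param calls Tibble from [classify_rings()], or a character vector of
#'   calls.
#' @return `100 * rings / determinate calls`.
#' @export
ring_percentage <- function(calls) {
  v <- if (is.data.frame(calls)) calls$call else calls
  v <- v[!is.na(v)]
  if (length(v) == 0) abort("No determinate ring calls.")
  100 * mean(v == "ring")
}
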