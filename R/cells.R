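#' Detection configuration for bacterial cell images
#'
#' Parameters of the cellular recipe: the image is smoothed, cells are
#' detected at `whole-image background + cell_sd_multiplier * sd`, bright
#' spots (foci) inside each cell at
#' `cellular background + foci_sd_multiplier * sd`, foci are grown by a
#' constrained dilation and kept only when their peak-to-cellular-background
#' contrast and equivalent diameter pass the configured minima. The
#' single-rod filter bounds aspect ratio, solidity and area; cells failing
#' it are flagged, never silently removed.
#'
#' @param smooth_sigma_um Gaussian smoothing scale for cell segmentation
#'   (um; default 0.065, i.e. one pixel at default sampling). Foci are
#'   measured on the unsmoothed channel.
#' @param cell_sd_multiplier,foci_sd_multiplier Threshold multipliers
#'   (default 3).
#' @param foci_min_diameter_um Minimum focus equivalent diameter (um).
#' @param min_cell_area_um2,max_cell_area_um2 Area bounds for a single cell.
#' @param rod_aspect_min Minimum aspect ratio of a rod (default 2).
#' @param solidity_min Minimum solidity of a single cell (default 0.9).
#' @param grow_radius_px Maximum constrained-dilation radius for foci
#'   (default 0). Growing is useful when optics smear a focus into a dim
#'   skirt that the threshold misses; with crisp spot boundaries it only
#'   mixes cytoplasm pixels into the focus mean and biases partition
#'   ratios low, so it is off unless requested.
#' @param contrast_min Minimum focus peak / cellular background ratio.
#' @param interior_erode_px Pixels eroded from the cell boundary before any
#'   cellular intensity statistic is computed (default 2). Segmenting on a
#'   smoothed channel leaves a halo of boundary pixels that interpolate
#'   between background and cytoplasm; eroding removes the halo so the
#'   cellular background reflects the cytoplasm. Geometry, containment and
#'   foci search still use the full mask.
#' @param connectivity Pixel connectivity for labeling (default 8).
#' @return A `cell_detection_config` list.
#' @export
cell_detection_config <- function(smooth_sigma_um = 0.065,
                                  cell_sd_multiplier = 3,
                                  foci_sd_multiplier = 3,
                                  foci_min_diameter_um = 0.5,
                                  min_cell_area_um2 = 0.5,
                                  max_cell_area_um2 = 10,
                                  rod_aspect_min = 2,
                                  solidity_min = 0.9,
                                  grow_radius_px = 0,
                                  contrast_min = 1.5,
                                  interior_erode_px = 2,
                                  connectivity = 8) {
  if (cell_sd_multiplier <= 0 || foci_sd_multiplier <= 0) {
    abort("Threshold multipliers must be positive.")
  }
  structure(
    list(smooth_sigma_um = smooth_sigma_um,
         cell_sd_multiplier = cell_sd_multiplier,
         foci_sd_multiplier = foci_sd_multiplier,
         foci_min_diameter_um = foci_min_diameter_um,
         min_cell_area_um2 = min_cell_area_um2,
         max_cell_area_um2 = max_cell_area_um2,
         rod_aspect_min = rod_aspect_min, solidity_min = solidity_min,
         grow_radius_px = as.integer(grow_radius_px),
         contrast_min = contrast_min,
         interior_erode_px = as.integer(interior_erode_px),
         connectivity = connectivity),
    class = "cell_detection_config"
  )
}

#' Gaussian smoothing of a field image
#'
#' @param image A [field_image].
#' @param sigma_um Smoothing scale in um; 0 returns the input unchanged.
#' @return A smoothed [field_image].
#' @export
smooth_field <- function(image, sigma_um) {
  assert_field_image(image)
  if (sigma_um < 0) abort("`sigma_um` must be >= 0.")
  if (sigma_um == 0) return(image)
  field_image(gaussian_blur(image$data, sigma_um / image$pixel_size_um),
              image$pixel_size_um, image$channel)
}

#' Segment individual cells by whole-image threshold
#'
#' Thresholds the (typically smoothed) image at
#' `whole-image background mean + cell_sd_multiplier * sd`, labels connected
#' components, keeps those above `min_cell_area_um2`, and measures
#' morphometrics: area, pole-to-pole length and width (extents along the
#' principal axes), aspect ratio, solidity, mean intensity and centroid.
#'
#' @param image A [field_image]; smoothing per the recipe is the caller's
#'   (or [quant_cells()]'s) responsibility.
#' @param bg Optional `background_estimate`; computed iteratively when NULL.
#' @param config A [cell_detection_config()].
#' @return Tibble with one row per cell, carrying the label matrix and
#'   background as attributes.
#' @export
segment_cells <- function(image, bg = NULL, config = cell_detection_config()) {
  assert_field_image(image)
  if (is.null(bg)) bg <- estimate_background(image, sd_multiplier = config$cell_sd_multiplier)
  mask <- image$data >= bg$mean + config$cell_sd_multiplier * bg$sd
  labels <- label_components(mask, config$connectivity)
  stats <- component_stats(labels, image)
  if (nrow(stats) > 0) {
    keep <- stats$area_um2 >= config$min_cell_area_um2
    dropped <- stats$label[!keep]
    stats <- stats[keep, ]
    if (length(dropped)) labels[labels %in% dropped] <- 0L
  }
  cells <- stats %>%
    dplyr::select(dplyr::all_of(c(
      "label", "n_px", "area_um2", "length_um", "width_um", "aspect_ratio",
      "solidity", "mean_intensity", "centroid_x_um", "centroid_y_um",
      "touches_border")))
  attr(cells, "labels") <- labels
  attr(cells, "bg") <- bg
  attr(cells, "config") <- config
  cells
}

#' Flag rod-shaped, singly detected cells
#'
#' Applies the single-rod criteria (aspect ratio, solidity, area bounds,
#' not touching the border) and records the verdict in `is_single_rod`.
#' Rejected cells are retained with the flag FALSE as an audit trail; this
#' replaces the manual verification step of interactive analysis.
#'
#' @param cells Segmentation tibble from [segment_cells()].
#' @param config A [cell_detection_config()].
#' @return The same tibble with an `is_single_rod` column (attributes
#'   preserved).
#' @export
filter_single_rod_cells <- function(cells, config = cell_detection_config()) {
  flag <- cells$aspect_ratio >= config$rod_aspect_min &
    cells$solidity >= config$solidity_min &
    cells$area_um2 >= config$min_cell_area_um2 &
    cells$area_um2 <= config$max_cell_area_um2 &
    !cells$touches_border
  out <- mutate(cells, is_single_rod = flag)
  for (a in c("labels", "bg", "config")) attr(out, a) <- attr(cells, a)
  out
}

# iterative background estimate on an intensity vector (cellular version of
# estimate_background, restricted to one cell's pixels)
iterative_background_vec <- function(v, sd_multiplier = 3, max_iter = 10) {
  iterative_exclusion(v, sd_multiplier, max_iter)
}

erode_mask <- function(mask, r) {
  out <- mask
  for (i in seq_len(r)) out <- !dilate3x3(!out)
  if (!any(out)) mask else out  # never erode a small cell away entirely
}

dilate3x3 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  out[-1, ] <- out[-1, ] | mask[-nr, ]
  out[-nr, ] <- out[-nr, ] | mask[-1, ]
  out[, -1] <- out[, -1] | out[, -nc]
  out[, -nc] <- out[, -nc] | out[, -1]
  out
}

#' Detect bright-spot foci inside segmented cells
#'
#' For every cell (by default only single rods when the flag is present),
#' the cellular background is estimated by iterative exclusion within the
#' cell mask; pixels at or above
#' `cellular background + foci_sd_multiplier * sd` are labeled as candidate
#' foci. Each focus is grown by up to `grow_radius_px` rounds of constrained
#' dilation over cell pixels that remain above the cellular background mean,
#' then filtered on peak contrast (`max / cellular background >=
#' contrast_min`) and equivalent diameter. Foci are measured on the raw
#' (unsmoothed) image and clipped to their parent cell.
#'
#' @param image Raw [field_image] (the channel foci are measured on).
#' @param cells Segmentation tibble (with its label-matrix attribute).
#' @param config A [cell_detection_config()].
#' @param only_single_rods Restrict to cells flagged `is_single_rod`.
#' @return Tibble with one row per focus: `label`, `parent_cell`, `n_px`,
#'   `area_um2`, `equivalent_diameter_um`, `mean_intensity`,
#'   `max_intensity`, `centroid_x_um`, `centroid_y_um`,
#'   `cellular_bg_mean` (iterative estimate used for detection). Carries a
#'   global focus label matrix as `attr(, "labels")`.
#' @export
detect_foci <- function(image, cells, config = cell_detection_config(),
                        only_single_rods = TRUE) {
  assert_field_image(image)
  cell_labels <- attr(cells, "labels")
  if (is.null(cell_labels)) abort("`cells` must carry its label matrix (from segment_cells).")
  px <- image$pixel_size_um
  todo <- cells
  if (only_single_rods && "is_single_rod" %in% names(cells)) {
    todo <- cells[cells$is_single_rod, ]
  }
  foci_labels <- matrix(0L, nrow(cell_labels), ncol(cell_labels))
  out <- list()
  next_label <- 0L

  for (i in seq_len(nrow(todo))) {
    cl <- todo[i, ]
    idx <- which(cell_labels == cl$label)
    if (length(idx) == 0) abort(sprintf("Cell %d has no interior pixels.", cl$label))
    nr <- nrow(cell_labels)
    ri <- ((idx - 1L) %% nr) + 1L
    ci <- ((idx - 1L) %/% nr) + 1L
    # pad the bounding box so boundary erosion sees the true cell outline
    r0 <- max(min(ri) - 2L, 1L); r1 <- min(max(ri) + 2L, nr)
    c0 <- max(min(ci) - 2L, 1L); c1 <- min(max(ci) + 2L, ncol(cell_labels))
    sub <- image$data[r0:r1, c0:c1, drop = FALSE]
    cmask <- cell_labels[r0:r1, c0:c1, drop = FALSE] == cl$label
    cmask_int <- erode_mask(cmask, config$interior_erode_px)

    cbg <- iterative_background_vec(sub[cmask_int], config$foci_sd_multiplier)
    thr <- cbg$mean + config$foci_sd_multiplier * cbg$sd
    fmask <- cmask & sub >= thr
    if (!any(fmask)) next
    lab <- label_components(fmask, config$connectivity)

    # grow: constrained dilation over cell pixels above the cellular mean
    allowed <- cmask & sub > cbg$mean
    if (config$grow_radius_px > 0) {
      for (it in seq_len(config$grow_radius_px)) {
        for (l in sort(unique(lab[lab > 0]))) {
          cand <- dilate3x3(lab == l) & allowed & lab == 0
          lab[cand] <- l
        }
      }
    }

    stats <- component_stats(lab, field_image(sub, px))
    if (nrow(stats) == 0) next
    keep <- stats$max_intensity / cbg$mean >= config$contrast_min &
      stats$equivalent_diameter_um >= config$foci_min_diameter_um
    stats <- stats[keep, ]
    if (nrow(stats) == 0) next

    for (j in seq_len(nrow(stats))) {
      next_label <- next_label + 1L
      sel <- lab == stats$label[j]
      glob <- foci_labels[r0:r1, c0:c1, drop = FALSE]
      glob[sel] <- next_label
      foci_labels[r0:r1, c0:c1] <- glob
      out[[length(out) + 1]] <- tibble(
        label = next_label, parent_cell = cl$label,
        n_px = stats$n_px[j], area_um2 = stats$area_um2[j],
        equivalent_diameter_um = stats$equivalent_diameter_um[j],
        mean_intensity = stats$mean_intensity[j],
        max_intensity = stats$max_intensity[j],
        centroid_x_um = stats$centroid_x_um[j] + (c0 - 1) * px,
        centroid_y_um = stats$centroid_y_um[j] + (r0 - 1) * px,
        cellular_bg_mean = cbg$mean
      )
    }
  }
  foci <- if (length(out)) bind_rows(out) else tibble(
    label = integer(), parent_cell = integer(), n_px = integer(),
    area_um2 = double(), equivalent_diameter_um = double(),
    mean_intensity = double(), max_intensity = double(),
    centroid_x_um = double(), centroid_y_um = double(),
    cellular_bg_mean = double())
  attr(foci, "labels") <- foci_labels
  foci
}

#' Assign foci to their parent cells (child-in-parent)
#'
#' Each focus is attributed to the cell whose mask contains its centroid
#' pixel. Foci whose centroid falls in no cell are dropped with a warning.
#'
#' @param foci Focus tibble with `centroid_x_um`/`centroid_y_um` columns.
#' @param cells Segmentation tibble carrying its label matrix.
#' @return `foci` with `parent_cell` set, dropped rows removed.
#' @export
assign_foci_to_cells <- function(foci, cells) {
  cell_labels <- attr(cells, "labels")
  if (is.null(cell_labels)) abort("`cells` must carry its label matrix.")
  if (nrow(foci) == 0) return(mutate(foci, parent_cell = integer(0)))
  if (nrow(cells) == 0) {
    warn("No cells: all foci dropped.")
    return(foci[0, ])
  }
  # pixel size recovered exactly from any cell's area / pixel count
  px_um <- sqrt(cells$area_um2[1] / cells$n_px[1])
  ri <- pmin(pmax(ceiling(foci$centroid_y_um / px_um), 1), nrow(cell_labels))
  ci <- pmin(pmax(ceiling(foci$centroid_x_um / px_um), 1), ncol(cell_labels))
  parent <- cell_labels[cbind(ri, ci)]
  if (any(parent == 0)) {
    warn(sprintf("%d focus/foci outside all cells were dropped.", sum(parent == 0)))
  }
  out <- foci
  out$parent_cell <- parent
  out[out$parent_cell > 0, ]
}

#' Foci-subtracted cellular background
#'
#' Mean intensity over the cell mask minus the union of detected foci masks
#' (the "subtract" step of the cellular recipe).
#'
#' @param image Raw [field_image].
#' @param cell_mask Logical matrix of the cell's pixels.
#' @param foci_mask Logical matrix of all focus pixels (may be NULL).
#' @return Scalar mean background intensity within the cell.
#' @export
cellular_background <- function(image, cell_mask, foci_mask = NULL) {
  assert_field_image(image)
  keep <- cell_mask
  if (!is.null(foci_mask)) keep <- keep & !foci_mask
  if (!any(keep)) abort("Foci cover the whole cell; no background pixels remain.")
  mean(image$data[keep])
}

#' Partition ratio of a cellular focus
#'
#' @param focus_mean Focus mean intensity (ADU), vectorized.
#' @param cellular_bg_mean Foci-subtracted cellular background mean (> 0).
#' @return `focus_mean / cellular_bg_mean`.
#' @export
focus_partition_ratio <- function(focus_mean, cellular_bg_mean) {
  if (any(cellular_bg_mean <= 0)) abort("`cellular_bg_mean` must be positive.")
  focus_mean / cellular_bg_mean
}

#' Distribution of foci counts per cell
#'
#' @param foci_count Integer vector of per-cell focus counts (cells passing
#'   the single-rod filter).
#' @return A list: `histogram` (tibble of count, n, fraction),
#'   `fraction_1_2` (fraction of cells with one or two foci), `median`,
#'   `iqr`, `mean`. Empty input yields an empty histogram.
#' @export
foci_count_distribution <- function(foci_count) {
  if (length(foci_count) == 0) {
    return(list(histogram = tibble(foci = integer(), n = integer(),
                                   fraction = double()),
                fraction_1_2 = NA_real_, median = NA_real_,
                iqr = NA_real_, mean = NA_real_))
  }
  tab <- table(factor(foci_count, levels = 0:max(foci_count)))
  list(
    histogram = tibble(foci = as.integer(names(tab)), n = as.integer(tab),
                       fraction = as.integer(tab) / length(foci_count)),
    fraction_1_2 = mean(foci_count %in% c(1, 2)),
    median = median(foci_count),
    iqr = unname(diff(quantile(foci_count, c(0.25, 0.75)))),
    mean = mean(foci_count)
  )
}

#' Cell length of segmented rods
#'
#' Pole-to-pole length via the extent of the component along its principal
#' axis (already computed at segmentation). Warns when a cell failed the
#' rod filter but still returns its major-axis length.
#'
#' @param cells Segmentation tibble (after [filter_single_rod_cells()]).
#' @return Tibble of `label`, `length_um`, `is_single_rod`.
#' @export
measure_cell_length <- function(cells) {
  flag <- if ("is_single_rod" %in% names(cells)) cells$is_single_rod else rep(TRUE, nrow(cells))
  if (any(!flag)) {
    warn("Some cells are not single rods; their major-axis length is reported anyway.")
  }
  tibble(label = cells$label, length_um = cells$length_um, is_single_rod = flag)
}
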