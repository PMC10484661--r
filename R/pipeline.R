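#' Quantify an in vitro droplet field
#'
#' Runs the full in vitro recipe on one image: iterative background
#' estimation, threshold detection with the diameter filter, per-droplet
#' partition ratios, density per imaging view, and pooled summaries.
#'
#' @param image A [field_image].
#' @param config A [detection_config()].
#' @return A `droplet_quant` object: `records` (per-droplet tibble),
#'   `background`, `density`, `summary`, `config`, `image`.
#' @export
quant_droplets <- function(image, config = detection_config()) {
  assert_field_image(image)
  bg <- estimate_background(image, sd_multiplier = config$sd_multiplier)
  records <- detect_condensates(image, bg, config)
  structure(
    list(records = records, background = bg,
         density = droplet_density(records, image, config),
         summary = summarize_droplets(records),
         config = config, image = image),
    class = "droplet_quant"
  )
}

#' @export
print.droplet_quant <- function(x, ...) {
  cat(sprintf(
    "<droplet_quant> %d condensates, density %.1f per %.0f um2 view, bg %.1f +/- %.1f ADU\n",
    nrow(x$records), x$density, x$config$view_area_um2,
    x$background$mean, x$background$sd))
  invisible(x)
}

#' @describeIn quant_droplets Per-droplet records.
#' @param x,object A `droplet_quant`.
#' @param ... Unused.
#' @method tidy droplet_quant
#' @export
tidy.droplet_quant <- function(x, ...) as_tibble(as.data.frame(x$records))

#' @describeIn quant_droplets One-row field summary.
#' @method glance droplet_quant
#' @export
glance.droplet_quant <- function(x, ...) {
  tibble(
    n_condensates = nrow(x$records),
    density_per_view = x$density,
    bg_mean = x$background$mean, bg_sd = x$background$sd,
    median_partition_ratio = if (nrow(x$records)) median(x$records$partition_ratio) else NA_real_,
    median_diameter_um = if (nrow(x$records)) median(x$records$equivalent_diameter_um) else NA_real_
  )
}

#' Quantify a bacterial cell field
#'
#' Runs the cellular recipe in order: smooth, segment cells on the smoothed
#' channel against the whole-image background, flag single rods, detect
#' bright-spot foci per rod on the raw channel, form the foci-subtracted
#' cellular background, and compute per-focus partition ratios and per-cell
#' foci counts.
#'
#' @param image Raw [field_image].
#' @param config A [cell_detection_config()].
#' @return A `cell_quant` object: `cells` (with `foci_count`,
#'   `cellular_bg_mean`), `foci` (with `partition_ratio`), `background`,
#'   `foci_distribution`, `config`.
#' @export
quant_cells <- function(image, config = cell_detection_config()) {
  assert_field_image(image)
  smoothed <- smooth_field(image, config$smooth_sigma_um)
  bg <- estimate_background(smoothed, sd_multiplier = config$cell_sd_multiplier)
  cells <- segment_cells(smoothed, bg, config)
  cells <- filter_single_rod_cells(cells, config)
  foci <- detect_foci(image, cells, config, only_single_rods = TRUE)

  cell_labels <- attr(cells, "labels")
  foci_labels <- attr(foci, "labels")
  cbg <- vapply(cells$label, function(l) {
    cmask <- erode_mask(cell_labels == l, config$interior_erode_px)
    fmask <- if (!is.null(foci_labels)) foci_labels > 0 else NULL
    cellular_background(image, cmask, fmask)
  }, numeric(1))
  cells$cellular_bg_mean <- cbg
  counts <- table(factor(foci$parent_cell, levels = cells$label))
  cells$foci_count <- as.integer(counts)

  if (nrow(foci) > 0) {
    foci$cellular_bg_mean <- cbg[match(foci$parent_cell, cells$label)]
    foci$partition_ratio <- focus_partition_ratio(foci$mean_intensity,
                                                  foci$cellular_bg_mean)
  } else {
    foci$partition_ratio <- double(0)
  }
  attr(foci, "labels") <- foci_labels

  structure(
    list(cells = cells, foci = foci, background = bg,
         foci_distribution = foci_count_distribution(
           cells$foci_count[cells$is_single_rod]),
         config = config, image = image),
    class = "cell_quant"
  )
}

#' @export
print.cell_quant <- function(x, ...) {
  cat(sprintf(
    "<cell_quant> %d cells (%d single rods), %d foci; fraction with 1-2 foci %.2f\n",
    nrow(x$cells), sum(x$cells$is_single_rod), nrow(x$foci),
    x$foci_distribution$fraction_1_2))
  invisible(x)
}

#' @describeIn quant_cells Per-cell records (use `tidy(x)$foci` via the
#'   `which` argument for foci).
#' @param x,object A `cell_quant`.
#' @param which `"cells"` or `"foci"`.
#' @param ... Unused.
#' @method tidy cell_quant
#' @export
tidy.cell_quant <- function(x, which = c("cells", "foci"), ...) {
  which <- match.arg(which)
  as_tibble(as.data.frame(if (which == "cells") x$cells else x$foci))
}

#' @describeIn quant_cells One-row field summary.
#' @method glance cell_quant
#' @export
glance.cell_quant <- function(x, ...) {
  rods <- x$cells[x$cells$is_single_rod, ]
  tibble(
    n_cells = nrow(x$cells), n_single_rods = nrow(rods),
    n_foci = nrow(x$foci),
    fraction_cells_1_2_foci = x$foci_distribution$fraction_1_2,
    median_focus_partition_ratio = if (nrow(x$foci)) median(x$foci$partition_ratio) else NA_real_,
    median_cell_length_um = if (nrow(rods)) median(rods$length_um) else NA_real_,
    bg_mean = x$background$mean, bg_sd = x$background$sd
  )
}

#' Run a reproducible quantification pipeline from a configuration
#'
#' Drives either the in vitro (`mode = "droplets"`) or the cellular
#' (`mode = "cells"`) recipe over one or more TIFF inputs and writes a run
#' directory containing per-object CSVs, a JSON summary, the resolved
#' configuration (YAML) and a log. Reruns with the same configuration are
#' bit-identical for the deterministic stages (all of them: the analysis
#' path draws no random numbers).
#'
#' @param config A list (or path to a YAML file) with elements `mode`
#'   ("droplets" or "cells"), `inputs` (TIFF paths), `pixel_size_um`,
#'   `out_dir`, and optionally `detection` / `cell_detection` parameter
#'   lists passed to the respective config constructors.
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("mode", "inputs", "pixel_size_um", "out_dir")) {
    if (is.null(config[[f]])) abort(sprintf("Config field `%s` is required. [config error]", f))
  }
  missing_in <- config$inputs[!file.exists(config$inputs)]
  if (length(missing_in)) {
    abort(sprintf("Input file(s) not found: %s [config error]",
                  paste(missing_in, collapse = ", ")))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("condensatr run, mode=%s, %d input(s)", config$mode, length(config$inputs))

  dcfg <- do.call(detection_config, config$detection %||% list())
  ccfg <- do.call(cell_detection_config, config$cell_detection %||% list())

  results <- purrr::map(config$inputs, function(path) {
    logf("stage read_image: %s", path)
    img <- read_field_tiff(path, pixel_size_um = config$pixel_size_um)
    if (!is_field_image(img)) img <- img[[1]]
    res <- tryCatch({
      if (config$mode == "droplets") quant_droplets(img, dcfg) else quant_cells(img, ccfg)
    }, error = function(e) {
      abort(sprintf("Stage quantification failed on %s: %s [stage failure]",
                    path, conditionMessage(e)))
    })
    logf("stage quantify done: %s", path)
    res
  })

  input_ids <- basename(config$inputs)
  if (config$mode == "droplets") {
    recs <- purrr::map2_dfr(results, input_ids, ~ mutate(as_tibble(as.data.frame(.x$records)), input = .y))
    readr::write_csv(recs, file.path(config$out_dir, "droplets.csv"))
    summ <- purrr::map2_dfr(results, input_ids, ~ mutate(glance(.x), input = .y))
  } else {
    cells <- purrr::map2_dfr(results, input_ids, ~ mutate(tidy(.x, "cells"), input = .y))
    foci <- purrr::map2_dfr(results, input_ids, ~ mutate(tidy(.x, "foci"), input = .y))
    readr::write_csv(cells, file.path(config$out_dir, "cells.csv"))
    readr::write_csv(foci, file.path(config$out_dir, "foci.csv"))
    summ <- purrr::map2_dfr(results, input_ids, ~ mutate(glance(.x), input = .y))
  }
  jsonlite::write_json(summ, file.path(config$out_dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  resolved <- config
  resolved$detection <- unclass(dcfg)
  resolved$cell_detection <- unclass(ccfg)
  yaml::write_yaml(resolved, file.path(config$out_dir, "config.yaml"))
  logf("run complete")
  invisible(config$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
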