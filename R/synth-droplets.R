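#' Specification of a synthetic imaging field
#'
#' Describes the camera frame and background statistics used by all the
#' synthetic renderers. Defaults emulate a 100x oil-immersion objective on a
#' modern sCMOS camera: 0.065 um/pixel sampling with a near-uniform
#' background. `psf_sigma_um` applies a Gaussian softening to object edges;
#' its default is deliberately sub-pixel (see the methods vignette) so that
#' threshold masks remain faithful to the ground-truth geometry.
#'
#' @param width_px,height_px Field size in pixels (>= 32).
#' @param pixel_size_um Pixel size, um/pixel.
#' @param bg_mean,bg_sd Background mean and standard deviation (ADU).
#' @param psf_sigma_um Gaussian blur scale (um); 0 disables blur.
#' @param noise_model `"gaussian"` (additive, sd = `bg_sd`) or
#'   `"poisson_gaussian"` (shot noise on the signal plus Gaussian read noise).
#' @param seed Integer seed used by renderers unless overridden.
#' @return A `field_spec` list.
#' @export
field_spec <- function(width_px = 256, height_px = 256,
                       pixel_size_um = 0.065,
                       bg_mean = 100, bg_sd = 10,
                       psf_sigma_um = 0.02,
                       noise_model = c("gaussian", "poisson_gaussian"),
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (width_px < 32 || height_px < 32) abort("Field must be at least 32 x 32 px.")
  if (pixel_size_um <= 0) abort("`pixel_size_um` must be positive.")
  if (bg_sd < 0 || psf_sigma_um < 0) abort("`bg_sd` and `psf_sigma_um` must be >= 0.")
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         pixel_size_um = pixel_size_um, bg_mean = bg_mean, bg_sd = bg_sd,
         psf_sigma_um = psf_sigma_um, noise_model = noise_model,
         seed = as.integer(seed)),
    class = "field_spec"
  )
}

field_extent_um <- function(field) {
  c(x = field$width_px * field$pixel_size_um,
    y = field$height_px * field$pixel_size_um)
}

#' Draw random non-overlapping droplet specifications
#'
#' Places `n` droplets uniformly in the field, keeping every droplet fully
#' inside the frame and at least `min_gap_um` away from previously placed
#' droplets (surface-to-surface).
#'
#' @param field A [field_spec()].
#' @param n Number of droplets.
#' @param diameter_um Length-1 or length-2 numeric: fixed diameter or a
#'   uniform range (um). Default spans the sizes typical of annealed
#'   CAG-repeat condensates (~1.4-1.8 um).
#' @param partition_ratio Length-1 or length-2 numeric: fixed value or
#'   uniform range of the true partition ratio (droplet mean / background).
#' @param shape `"filled"` or `"ring"`, recycled to `n`.
#' @param ring_core_fraction Core/shell intensity ratio for ring droplets.
#' @param min_gap_um Minimum surface separation between droplets.
#' @param seed Integer seed for placement.
#' @return Tibble with one row per droplet.
#' @export
random_droplets <- function(field, n, diameter_um = c(1.4, 1.8),
                            partition_ratio = 7.7, shape = "filled",
                            ring_core_fraction = 0.2,
                            min_gap_um = 0.3, seed = field$seed) {
  ext <- field_extent_um(field)
  withr::with_seed(seed, {
    d <- if (length(diameter_um) == 2) {
      stats::runif(n, diameter_um[1], diameter_um[2])
    } else rep(diameter_um, n)
    pr <- if (length(partition_ratio) == 2) {
      stats::runif(n, partition_ratio[1], partition_ratio[2])
    } else rep(partition_ratio, n)
    shp <- rep(shape, length.out = n)
    xs <- ys <- numeric(n)
    placed <- 0L; tries <- 0L
    while (placed < n) {
      tries <- tries + 1L
      if (tries > 200L * n) {
        abort("Could not place droplets without overlap; field too crowded.")
      }
      i <- placed + 1L
      r <- d[i] / 2
      x <- stats::runif(1, r + 2 * field$pixel_size_um, ext["x"] - r - 2 * field$pixel_size_um)
      y <- stats::runif(1, r + 2 * field$pixel_size_um, ext["y"] - r - 2 * field$pixel_size_um)
      ok <- placed == 0L ||
        all(sqrt((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) >=
              r + d[seq_len(placed)] / 2 + min_gap_um)
      if (ok) {
        xs[i] <- x; ys[i] <- y; placed <- i
      }
    }
    tibble(
      droplet_id = seq_len(n), x_um = xs, y_um = ys, diameter_um = d,
      partition_ratio = pr, shape = shp,
      ring_core_fraction = ifelse(shp == "ring", ring_core_fraction, NA_real_)
    )
  })
}

#' Render a synthetic droplet field with a ground-truth manifest
#'
#' Each droplet is rasterized as a disk (or, for ring droplets, a bright
#' shell over a dim core) whose pre-noise intensity is
#' `bg_mean * partition_ratio`, so the mean over the true mask equals the
#' specified level exactly when blur is off. The ideal image is then blurred
#' at `psf_sigma_um` and noise is added per the field's noise model. Pixels
#' driven negative by noise are clipped at zero and counted in the manifest.
#'
#' @param field A [field_spec()].
#' @param droplets Tibble as produced by [random_droplets()] (columns
#'   `droplet_id`, `x_um`, `y_um`, `diameter_um`, `partition_ratio`,
#'   `shape`, `ring_core_fraction`).
#' @param seed Seed for the noise draw; defaults to the field's seed.
#' @param allow_overlap Permit overlapping droplets (default FALSE: overlap
#'   is an error so manifests stay unambiguous).
#' @return A `synthetic_field` list: `image` ([field_image]), `manifest`
#'   (ground truth, serializable via [write_manifest()]), and `truth_labels`
#'   (integer matrix of true per-droplet masks).
#' @export
render_droplet_field <- function(field, droplets, seed = field$seed,
                                 allow_overlap = FALSE) {
  stopifnot(inherits(field, "field_spec"))
  required <- c("droplet_id", "x_um", "y_um", "diameter_um", "partition_ratio", "shape")
  if (!all(required %in% names(droplets))) {
    abort("`droplets` is missing required columns.")
  }
  nr <- field$height_px; nc <- field$width_px
  px <- field$pixel_size_um
  ext <- field_extent_um(field)
  ideal <- matrix(field$bg_mean, nr, nc)
  truth <- matrix(0L, nr, nc)
  xc <- (seq_len(nc) - 0.5) * px
  yc <- (seq_len(nr) - 0.5) * px

  for (i in seq_len(nrow(droplets))) {
    dr <- droplets[i, ]
    r <- dr$diameter_um / 2
    if (dr$x_um - r < 0 || dr$x_um + r > ext["x"] ||
        dr$y_um - r < 0 || dr$y_um + r > ext["y"]) {
      abort(sprintf("Droplet %d extends outside the field.", dr$droplet_id))
    }
    cols <- which(abs(xc - dr$x_um) <= r + px)
    rows <- which(abs(yc - dr$y_um) <= r + px)
    d2 <- outer((yc[rows] - dr$y_um)^2, (xc[cols] - dr$x_um)^2, `+`)
    inside <- d2 <= r^2
    if (!any(inside)) next
    sub_t <- truth[rows, cols, drop = FALSE]
    if (!allow_overlap && any(sub_t[inside] > 0)) {
      abort(sprintf("Droplet %d overlaps a previously placed droplet.", dr$droplet_id))
    }
    level <- field$bg_mean * dr$partition_ratio
    sub_i <- ideal[rows, cols, drop = FALSE]
    if (identical(dr$shape, "ring")) {
      core <- d2 <= (0.5 * r)^2
      sub_i[inside & !core] <- level
      sub_i[core] <- dr$ring_core_fraction * level
    } else {
      sub_i[inside] <- level
    }
    ideal[rows, cols] <- sub_i
    sub_t[inside] <- dr$droplet_id
    truth[rows, cols] <- sub_t
  }

  img <- apply_psf_and_noise(ideal, field, seed)
  manifest <- new_manifest(field, droplets = droplets, seed = seed,
                           clipped_px = attr(img, "clipped_px"))
  structure(
    list(image = field_image(unclass_mat(img), px, channel = "green"),
         manifest = manifest, truth_labels = truth),
    class = "synthetic_field"
  )
}

# blur + noise + clipping shared by all renderers
apply_psf_and_noise <- function(ideal, field, seed) {
  if (field$psf_sigma_um > 0) {
    sigma_px <- field$psf_sigma_um / field$pixel_size_um
    ideal <- gaussian_blur(ideal, sigma_px)
  }
  noisy <- withr::with_seed(seed, {
    switch(field$noise_model,
      gaussian = ideal + rnorm(length(ideal), 0, field$bg_sd),
      poisson_gaussian = {
        shot <- matrix(rpois(length(ideal), pmax(ideal, 0)), nrow(ideal))
        shot + rnorm(length(ideal), 0, field$bg_sd)
      })
  })
  clipped <- sum(noisy < 0)
  noisy[noisy < 0] <- 0
  attr(noisy, "clipped_px") <- clipped
  noisy
}

gaussian_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  out <- EBImage::imageData(EBImage::gblur(EBImage::Image(mat), sigma = sigma_px))
  matrix(as.numeric(out), nrow(mat))
}

unclass_mat <- function(m) {
  attr(m, "clipped_px") <- NULL
  matrix(as.numeric(m), nrow(m))
}

new_manifest <- function(field, droplets = NULL, cells = NULL, foci = NULL,
                         coloc_target_pcc = NULL, seed = field$seed,
                         clipped_px = 0L, extra = NULL) {
  structure(
    list(field = unclass(field),
         droplets = droplets, cells = cells, foci = foci,
         coloc_target_pcc = coloc_target_pcc,
         seed = as.integer(seed), clipped_px = as.integer(clipped_px),
         generator_version = "condensatr-synth-1",
         extra = extra),
    class = "gt_manifest"
  )
}

#' Write / read a ground-truth manifest (JSON)
#'
#' Manifests serialize losslessly: `read_manifest(write_manifest(m, p))`
#' reproduces the object, with object tables as tibbles.
#'
#' @param manifest A `gt_manifest`.
#' @param path Output JSON path.
#' @return `path` invisibly; `read_manifest()` returns the manifest.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "gt_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("droplets", "cells", "foci")) {
    if (!is.null(raw[[nm]])) {
      tb <- as_tibble(as.data.frame(raw[[nm]]))
      # all-NA numeric columns deserialize as logical; restore their type
      for (cn in c("ring_core_fraction")) {
        if (cn %in% names(tb)) tb[[cn]] <- as.numeric(tb[[cn]])
      }
      raw[[nm]] <- tb
    }
  }
  raw$seed <- as.integer(raw$seed)
  raw$clipped_px <- as.integer(raw$clipped_px)
  structure(raw, class = "gt_manifest")
}
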