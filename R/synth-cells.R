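#' Draw random non-overlapping rod-shaped cell specifications
#'
#' Cells are spherocylinders (a rectangle capped by half-disks) placed on a
#' jittered grid so they never touch, with random orientations. Defaults
#' emulate exponential-phase E. coli: ~3 um long, ~1 um wide, cytoplasmic
#' reporter signal well above the extracellular background.
#'
#' @param field A [field_spec()].
#' @param n Number of cells.
#' @param length_um Length-1 or length-2 numeric, pole-to-pole length (um).
#' @param width_um Cell width (um); must not exceed the length.
#' @param cyto_intensity Cytoplasm intensity above background (ADU).
#' @param seed Placement seed.
#' @return Tibble with one row per cell.
#' @export
random_cells <- function(field, n, length_um = c(2.8, 3.4), width_um = 1.0,
                         cyto_intensity = 150, seed = field$seed) {
  ext <- field_extent_um(field)
  lmax <- max(length_um)
  pitch <- lmax + 1.0  # grid pitch leaves >= 1 um between any two cells
  nx <- floor((ext["x"] - 1) / pitch)
  ny <- floor((ext["y"] - 1) / pitch)
  if (nx * ny < n) {
    abort(sprintf("Field holds at most %d non-overlapping cells; %d requested.",
                  nx * ny, n))
  }
  withr::with_seed(seed, {
    slots <- sample(nx * ny, n)
    gx <- ((slots - 1) %% nx)
    gy <- ((slots - 1) %/% nx)
    len <- if (length(length_um) == 2) stats::runif(n, length_um[1], length_um[2]) else rep(length_um, n)
    jit <- (pitch - len - 0.6) / 2
    tibble(
      cell_id = seq_len(n),
      x_um = 0.5 + gx * pitch + pitch / 2 + stats::runif(n, -1, 1) * pmax(jit, 0) * 0.5,
      y_um = 0.5 + gy * pitch + pitch / 2 + stats::runif(n, -1, 1) * pmax(jit, 0) * 0.5,
      length_um = len,
      width_um = rep(width_um, n),
      orientation_deg = stats::runif(n, 0, 180),
      cyto_intensity = rep(cyto_intensity, n)
    )
  })
}

#' Place foci inside cells, polar by default
#'
#' Gives each cell `n_foci[i]` condensate foci. Polar placement puts the
#' first two foci at the two pole-cap centres (within 15% of the pole-to-pole
#' axis from each end, matching the polar localization typical of cellular
#' RNA condensates); a third and fourth focus go to mid-cell positions.
#' With `polar = FALSE` foci are placed uniformly along the axis.
#'
#' @param cells Tibble from [random_cells()].
#' @param n_foci Integer vector (recycled) of per-cell focus counts, 0-4.
#' @param diameter_um Length-1 or -2 numeric focus diameter (um); must fit
#'   inside the cell width.
#' @param partition_ratio True focus partition ratio over the cytoplasm.
#' @param polar Polar placement (default) or uniform along the axis.
#' @param seed Seed for diameters/ratios/jitter.
#' @return Tibble with one row per focus.
#' @export
place_foci <- function(cells, n_foci = 2, diameter_um = c(0.55, 0.75),
                       partition_ratio = 4, polar = TRUE, seed = 1L) {
  n_foci <- rep(n_foci, length.out = nrow(cells))
  if (any(n_foci < 0 | n_foci > 4)) abort("`n_foci` must be between 0 and 4.")
  withr::with_seed(seed, {
    out <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
      k <- n_foci[i]
      if (k == 0) return(NULL)
      cl <- cells[i, ]
      th <- cl$orientation_deg * pi / 180
      u <- c(cos(th), sin(th))
      d <- if (length(diameter_um) == 2) stats::runif(k, diameter_um[1], diameter_um[2]) else rep(diameter_um, k)
      pr <- if (length(partition_ratio) == 2) stats::runif(k, partition_ratio[1], partition_ratio[2]) else rep(partition_ratio, k)
      if (any(d / 2 > cl$width_um / 2)) {
        abort("Focus diameter exceeds the cell width; it cannot fit inside the cell.")
      }
      cap <- cl$length_um / 2 - cl$width_um / 2  # pole-cap centre offset
      offs <- if (polar) {
        # polar foci sit within 15% of the axis length from the tip, as far
        # out as the focus still fits inside the cap
        pole <- pmin(pmax(cap, 0.355 * cl$length_um),
                     cl$length_um / 2 - d / 2 - 0.02)
        o <- numeric(k)
        o[1] <- pole[1]
        if (k >= 2) o[2] <- -pole[2]
        if (k >= 3) o[3] <- 0
        if (k >= 4) o[4] <- cap / 2
        o
      } else {
        stats::runif(k, -cap, cap)
      }
      tibble(
        cell_id = cl$cell_id,
        x_um = cl$x_um + offs * u[1],
        y_um = cl$y_um + offs * u[2],
        diameter_um = d,
        partition_ratio = pr
      )
    })
    if (is.null(out) || nrow(out) == 0) return(empty_foci_spec())
    out$focus_id <- seq_len(nrow(out))
    out[, c("focus_id", "cell_id", "x_um", "y_um", "diameter_um", "partition_ratio")]
  })
}

empty_foci_spec <- function() {
  tibble(focus_id = integer(), cell_id = integer(), x_um = double(),
         y_um = double(), diameter_um = double(), partition_ratio = double())
}

# logical spherocylinder test for point sets (vectorized over x, y)
in_spherocylinder <- function(x, y, cell) {
  th <- cell$orientation_deg * pi / 180
  ux <- cos(th); uy <- sin(th)
  dx <- x - cell$x_um; dy <- y - cell$y_um
  proj <- dx * ux + dy * uy
  perp <- -dx * uy + dy * ux
  half <- cell$length_um / 2 - cell$width_um / 2
  r <- cell$width_um / 2
  (abs(proj) <= half & abs(perp) <= r) |
    ((abs(proj) - half)^2 + perp^2 <= r^2 & abs(proj) > half)
}

#' Render a synthetic field of cells (one or two channels)
#'
#' Cells are rasterized as spherocylinders at `bg_mean + cyto_intensity`;
#' each focus is a disk clipped to its parent cell, rendered at
#' `cytoplasm level x partition_ratio`. For two channels, channel 2 is a
#' mixture of the standardized channel 1 and independent Gaussian noise with
#' a closed-form weight chosen so the expected Pearson correlation over cell
#' pixels equals `coloc_target_pcc`; with a target of 1 channel 2 is an
#' exact affine transform of channel 1.
#'
#' @param field A [field_spec()].
#' @param cells Tibble from [random_cells()].
#' @param foci Optional tibble from [place_foci()].
#' @param channels 1 or 2.
#' @param coloc_target_pcc Target Pearson correlation for channel 2
#'   (required when `channels = 2`).
#' @param second_channel_scale Affine intensity scale of channel 2.
#' @param seed Noise seed; defaults to the field's seed.
#' @param allow_overlap Permit overlapping cells (used to exercise the
#'   single-cell filter on merged components).
#' @return A `synthetic_field` list: `image` (channel 1), `image2` (channel
#'   2 or NULL), `manifest`, `truth_cells` and `truth_foci` label matrices.
#' @export
render_cell_field <- function(field, cells, foci = NULL, channels = 1,
                              coloc_target_pcc = NULL,
                              second_channel_scale = 1,
                              seed = field$seed, allow_overlap = FALSE) {
  stopifnot(inherits(field, "field_spec"), channels %in% c(1, 2))
  if (channels == 2 && is.null(coloc_target_pcc)) {
    abort("`coloc_target_pcc` must be given when rendering two channels.")
  }
  if (any(cells$length_um < cells$width_um)) {
    abort("Cell length must be >= width.")
  }
  nr <- field$height_px; nc <- field$width_px
  px <- field$pixel_size_um
  ideal <- matrix(field$bg_mean, nr, nc)
  truth_cells <- matrix(0L, nr, nc)
  truth_foci <- matrix(0L, nr, nc)
  xc <- (seq_len(nc) - 0.5) * px
  yc <- (seq_len(nr) - 0.5) * px

  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    reach <- cl$length_um / 2 + px
    cols <- which(abs(xc - cl$x_um) <= reach)
    rows <- which(abs(yc - cl$y_um) <= reach)
    if (length(rows) == 0 || length(cols) == 0) {
      abort(sprintf("Cell %d lies outside the field.", cl$cell_id))
    }
    gx <- matrix(rep(xc[cols], each = length(rows)), length(rows))
    gy <- matrix(rep(yc[rows], times = length(cols)), length(rows))
    inside <- in_spherocylinder(gx, gy, cl)
    sub_t <- truth_cells[rows, cols, drop = FALSE]
    if (!allow_overlap && any(sub_t[inside] > 0)) {
      abort(sprintf("Cell %d overlaps a previously placed cell.", cl$cell_id))
    }
    sub_i <- ideal[rows, cols, drop = FALSE]
    sub_i[inside] <- field$bg_mean + cl$cyto_intensity
    ideal[rows, cols] <- sub_i
    sub_t[inside] <- cl$cell_id
    truth_cells[rows, cols] <- sub_t
  }

  if (!is.null(foci) && nrow(foci) > 0) {
    for (i in seq_len(nrow(foci))) {
      fc <- foci[i, ]
      cl <- cells[cells$cell_id == fc$cell_id, ]
      if (nrow(cl) != 1 || !in_spherocylinder(fc$x_um, fc$y_um, cl)) {
        abort(sprintf("Focus %d lies outside its parent cell.", fc$focus_id))
      }
      r <- fc$diameter_um / 2
      cols <- which(abs(xc - fc$x_um) <= r + px)
      rows <- which(abs(yc - fc$y_um) <= r + px)
      d2 <- outer((yc[rows] - fc$y_um)^2, (xc[cols] - fc$x_um)^2, `+`)
      inside <- d2 <= r^2 & truth_cells[rows, cols, drop = FALSE] == fc$cell_id
      sub_i <- ideal[rows, cols, drop = FALSE]
      sub_i[inside] <- (field$bg_mean + cl$cyto_intensity) * fc$partition_ratio
      ideal[rows, cols] <- sub_i
      sub_t <- truth_foci[rows, cols, drop = FALSE]
      sub_t[inside] <- fc$focus_id
      truth_foci[rows, cols] <- sub_t
    }
  }

  img1 <- apply_psf_and_noise(ideal, field, seed)
  image2 <- NULL
  if (channels == 2) {
    rho <- coloc_target_pcc
    if (rho < -1 || rho > 1) abort("`coloc_target_pcc` must lie in [-1, 1].")
    cellmask <- truth_cells > 0
    m <- mean(img1[cellmask]); s <- sd(img1[cellmask])
    z1 <- (unclass_mat(img1) - m) / s
    e <- withr::with_seed(mix_seed(seed), matrix(rnorm(length(z1)), nrow(z1)))
    raw2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * e
    ch2 <- second_channel_scale * (m + s * raw2)
    ch2[ch2 < 0] <- 0
    image2 <- field_image(ch2, px, channel = "red")
  }

  manifest <- new_manifest(field, cells = cells, foci = foci,
                           coloc_target_pcc = coloc_target_pcc, seed = seed,
                           clipped_px = attr(img1, "clipped_px"))
  structure(
    list(image = field_image(unclass_mat(img1), px, channel = "green"),
         image2 = image2, manifest = manifest,
         truth_cells = truth_cells, truth_foci = truth_foci),
    class = "synthetic_field"
  )
}

# derived stream for auxiliary noise draws; stays a valid 32-bit seed
mix_seed <- function(seed) (as.integer(seed) %% 1000000007L) + 7919L
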