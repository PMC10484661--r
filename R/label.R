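# Connected-component labeling and per-component morphometrics.
#
# Labeling is done in-package because the detection recipe requires a
# configurable 4- or 8-neighbourhood, which the installed image toolkits fix.
# Foreground pixels become graph vertices, neighbour pairs become edges, and
# igraph's union-find supplies the components; this is vectorized and fast at
# the densities typical of condensate fields.

#' Label connected components of a binary mask
#'
#' @param mask Logical matrix (TRUE = foreground).
#' @param connectivity 4 or 8 (pixel neighbourhood).
#' @return Integer matrix of the same shape; 0 = background, components
#'   numbered 1..n in scan order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix.")
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  mask <- mask & !is.na(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  labels <- matrix(0L, nr, nc)
  if (length(fg) == 0) return(labels)
  id <- integer(nr * nc)
  id[fg] <- seq_along(fg)

  ri <- ((fg - 1L) %% nr) + 1L
  ci <- ((fg - 1L) %/% nr) + 1L
  edge_to <- function(dr, dc) {
    ok <- ri + dr >= 1L & ri + dr <= nr & ci + dc >= 1L & ci + dc <= nc
    from <- fg[ok]
    to <- from + dr + dc * nr
    keep <- mask[to]
    cbind(id[from[keep]], id[to[keep]])
  }
  edges <- rbind(edge_to(1L, 0L), edge_to(0L, 1L))
  if (connectivity == 8) {
    edges <- rbind(edges, edge_to(1L, 1L), edge_to(-1L, 1L))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  # renumber in first-pixel scan order for determinism
  first <- !duplicated(memb)
  remap <- integer(max(memb))
  remap[memb[first]] <- seq_len(sum(first))
  labels[fg] <- remap[memb]
  labels
}

# Per-component morphometrics on a label matrix.
# Returns one row per label with area, equivalent circular diameter,
# intensity statistics, centroid, principal-axis extents (pole-to-pole
# length and width), aspect ratio, solidity, and a border flag.
component_stats <- function(labels, image) {
  px <- image$pixel_size_um
  nr <- nrow(labels); nc <- ncol(labels)
  idx <- which(labels > 0)
  if (length(idx) == 0) return(empty_component_stats())
  lab <- labels[idx]
  val <- image$data[idx]
  ri <- ((idx - 1L) %% nr) + 1L
  ci <- ((idx - 1L) %/% nr) + 1L
  x <- (ci - 0.5) * px
  y <- (ri - 0.5) * px

  ord <- order(lab)
  lab <- lab[ord]; val <- val[ord]; x <- x[ord]; y <- y[ord]
  ri <- ri[ord]; ci <- ci[ord]
  groups <- split(seq_along(lab), lab)

  purrr::map_dfr(groups, function(g) {
    n_px <- length(g)
    area <- n_px * px^2
    xm <- mean(x[g]); ym <- mean(y[g])
    axes <- principal_extents(x[g], y[g], px)
    hull <- convex_hull_area(x[g], y[g], px)
    tibble(
      label = lab[g[1]],
      n_px = n_px,
      area_um2 = area,
      equivalent_diameter_um = 2 * sqrt(area / pi),
      mean_intensity = mean(val[g]),
      max_intensity = max(val[g]),
      centroid_x_um = xm,
      centroid_y_um = ym,
      length_um = axes$major,
      width_um = axes$minor,
      aspect_ratio = axes$major / max(axes$minor, px),
      solidity = min(1, area / hull),
      touches_border = any(ri[g] == 1L | ri[g] == nr | ci[g] == 1L | ci[g] == nc)
    )
  })
}

empty_component_stats <- function() {
  tibble(
    label = integer(), n_px = integer(), area_um2 = double(),
    equivalent_diameter_um = double(), mean_intensity = double(),
    max_intensity = double(), centroid_x_um = double(),
    centroid_y_um = double(), length_um = double(), width_um = double(),
    aspect_ratio = double(), solidity = double(), touches_border = logical()
  )
}

# Extent of the pixel set along its principal axes (covariance
# eigenvectors). The plain centre-to-centre range is used (floored at one
# pixel): threshold masks of blurred objects already over-cover the true
# boundary, so padding the range by a pixel would double-count it.
principal_extents <- function(x, y, px) {
  if (length(x) == 1) return(list(major = px, minor = px))
  cx <- x - mean(x); cy <- y - mean(y)
  cv <- cbind(cx, cy)
  ev <- eigen(crossprod(cv) / length(x), symmetric = TRUE)$vectors
  p1 <- cv %*% ev[, 1]
  p2 <- cv %*% ev[, 2]
  list(
    major = max(diff(range(p1)), px),
    minor = max(diff(range(p2)), px)
  )
}

# Convex hull area of pixel centres, padded by one pixel area to avoid
# zero-area degenerate hulls (collinear components).
convex_hull_area <- function(x, y, px) {
  if (length(x) < 3) return(length(x) * px^2)
  h <- grDevices::chull(x, y)
  xs <- x[h]; ys <- y[h]
  a <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  max(a, px^2)  # guard against degenerate (collinear) hulls
}

# mean intensity of `image` over a logical mask
mask_mean <- function(image, mask) mean(image$data[mask])
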