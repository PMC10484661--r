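# Shared fixtures: everything is generated in code, seeded, and small.

# match detections to ground-truth objects by nearest centroid;
# returns per-detection index into truth (NA when nothing within max_dist)
match_by_centroid <- function(det_x, det_y, truth_x, truth_y, max_dist_um = 0.3) {
  if (length(det_x) == 0) return(integer(0))
  d <- sqrt(outer(det_x, truth_x, "-")^2 + outer(det_y, truth_y, "-")^2)
  idx <- apply(d, 1, which.min)
  idx[apply(d, 1, min) > max_dist_um] <- NA_integer_
  idx
}

# precision / recall of a detection set against a truth table
detection_pr <- function(records, truth, max_dist_um = 0.3) {
  m <- match_by_centroid(records$centroid_x_um, records$centroid_y_um,
                         truth$x_um, truth$y_um, max_dist_um)
  tp <- length(unique(m[!is.na(m)]))
  list(precision = if (nrow(records)) tp / nrow(records) else 1,
       recall = tp / nrow(truth))
}

# one standard synthetic droplet field
demo_droplet_field <- function(seed = 1, n = 15, partition_ratio = 7.7,
                               diameter_um = c(1.4, 1.8), ...) {
  fs <- field_spec(seed = seed, ...)
  dr <- random_droplets(fs, n, diameter_um = diameter_um,
                        partition_ratio = partition_ratio, seed = seed)
  render_droplet_field(fs, dr)
}

# one standard synthetic cell field (30 rods on a 512 px frame)
demo_cell_field <- function(seed = 1, n_cells = 30, n_foci = rep(0:3, length.out = 30),
                            focus_pr = 4, focus_diameter = c(0.55, 0.7), ...) {
  fs <- field_spec(width_px = 512, height_px = 512, seed = seed, ...)
  cells <- random_cells(fs, n_cells, seed = seed)
  foci <- place_foci(cells, n_foci = n_foci, diameter_um = focus_diameter,
                     partition_ratio = focus_pr, seed = seed + 500L)
  sf <- render_cell_field(fs, cells, foci, seed = seed + 900L)
  list(field = fs, cells = cells, foci = foci, sf = sf)
}

# truth foci count per cell id
truth_foci_counts <- function(cells, foci) {
  vapply(cells$cell_id, function(id) sum(foci$cell_id == id), integer(1))
}
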