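#' Simulate a condensation time series with per-frame ground truth
#'
#' Emulates droplet nucleation and growth after a quench: new droplets
#' nucleate as a Poisson process whose cumulative expectation saturates as
#' `1 - exp(-t / nucleation_sat_tau_s)`, and each droplet's diameter and
#' partition ratio relax towards their plateaus as
#' `1 - exp(-(t - t_birth) / growth_tau_s)`. Defaults reproduce the fast
#' assembly regime in which object size and partition ratio reach ~90% of
#' their plateau within ~5 min while the count keeps rising for ~15 min.
#'
#' @param field A [field_spec()].
#' @param nucleation_rate Initial nucleation rate (droplets per second).
#' @param growth_tau_s Growth time constant (s) for diameter and partition
#'   ratio (default 130 s, i.e. 90% of plateau at ~300 s).
#' @param n_frames Number of frames.
#' @param frame_interval_s Time between frames (s).
#' @param nucleation_sat_tau_s Saturation time constant of nucleation (s).
#' @param diameter_plateau_um,partition_plateau Per-droplet plateaus.
#' @param render Also rasterize every frame (slower); if FALSE only the
#'   truth tables are produced.
#' @param seed Integer seed.
#' @return A list: `frames` (list of [field_image] or NULL), `truth`
#'   (per-frame per-droplet tibble), `per_frame` (per-frame summary tibble
#'   with `time_s`, `count`, `mean_diameter_um`, `mean_partition_ratio`),
#'   and `manifest`.
#' @export
render_kinetics_series <- function(field, nucleation_rate = 0.1,
                                   growth_tau_s = 130, n_frames = 30,
                                   frame_interval_s = 30,
                                   nucleation_sat_tau_s = 390,
                                   diameter_plateau_um = 1.6,
                                   partition_plateau = 7.7,
                                   render = FALSE, seed = field$seed) {
  if (nucleation_rate < 0 || growth_tau_s <= 0 || frame_interval_s <= 0) {
    abort("Rates and time constants must be positive.")
  }
  times <- (seq_len(n_frames) - 1) * frame_interval_s
  # expected cumulative nucleations: rate * sat_tau * (1 - exp(-t/sat_tau))
  lam <- nucleation_rate * nucleation_sat_tau_s *
    (1 - exp(-times / nucleation_sat_tau_s))
  out <- withr::with_seed(seed, {
    births <- numeric(0)
    for (k in seq_len(n_frames)) {
      inc <- lam[k] - if (k == 1) 0 else lam[k - 1]
      n_new <- rpois(1, inc)
      if (n_new > 0) births <- c(births, rep(times[k], n_new))
    }
    n_total <- length(births)
    placement <- if (n_total > 0) {
      random_droplets(field, n_total, diameter_um = diameter_plateau_um,
                      partition_ratio = partition_plateau,
                      seed = mix_seed(seed))
    } else NULL
    list(births = births, placement = placement)
  })
  births <- out$births
  placement <- out$placement

  empty_truth <- tibble(
    frame = integer(), time_s = double(), droplet_id = integer(),
    x_um = double(), y_um = double(), diameter_um = double(),
    partition_ratio = double())
  truth <- purrr::map_dfr(seq_len(n_frames), function(k) {
    alive <- which(births <= times[k])
    if (length(alive) == 0) return(NULL)
    age <- times[k] - births[alive]
    g <- 1 - exp(-age / growth_tau_s)
    tibble(
      frame = k, time_s = times[k], droplet_id = alive,
      x_um = placement$x_um[alive], y_um = placement$y_um[alive],
      diameter_um = diameter_plateau_um * g,
      partition_ratio = 1 + (partition_plateau - 1) * g
    )
  })
  if (nrow(truth) == 0) truth <- empty_truth

  per_frame <- purrr::map_dfr(seq_len(n_frames), function(k) {
    fr <- truth[truth$frame == k, ]
    tibble(
      frame = k, time_s = times[k], count = nrow(fr),
      mean_diameter_um = if (nrow(fr)) mean(fr$diameter_um) else NA_real_,
      mean_partition_ratio = if (nrow(fr)) mean(fr$partition_ratio) else NA_real_
    )
  })

  frames <- NULL
  if (render) {
    frames <- purrr::map(seq_len(n_frames), function(k) {
      fr <- truth[truth$frame == k, ]
      fr <- fr[fr$diameter_um > 2 * field$pixel_size_um, ]
      dr <- tibble(droplet_id = fr$droplet_id, x_um = fr$x_um, y_um = fr$y_um,
                   diameter_um = fr$diameter_um,
                   partition_ratio = fr$partition_ratio,
                   shape = "filled", ring_core_fraction = NA_real_)
      render_droplet_field(field, dr, seed = mix_seed(seed) + k)$image
    })
  }

  manifest <- new_manifest(field, droplets = placement, seed = seed,
                           extra = list(growth_tau_s = growth_tau_s,
                                        nucleation_rate = nucleation_rate,
                                        nucleation_sat_tau_s = nucleation_sat_tau_s,
                                        births = births))
  list(frames = frames, truth = truth, per_frame = per_frame,
       manifest = manifest)
}
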