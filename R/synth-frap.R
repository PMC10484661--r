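#' Simulate a FRAP recovery trace
#'
#' Produces a single-ROI fluorescence-recovery trace following a
#' single-exponential model: after the bleach at time zero,
#' `I(t) = post_bleach + mobile_fraction * (pre_bleach - post_bleach) *
#' (1 - exp(-t / tau_s)) + noise`. Pre-bleach frames sit at `pre_bleach`.
#' Defaults mirror a typical confocal FRAP acquisition: one frame every 5 s
#' for several minutes.
#'
#' @param pre_bleach Pre-bleach intensity (normalized units by default).
#' @param post_bleach Intensity immediately after the bleach; must be below
#'   `pre_bleach`.
#' @param mobile_fraction True mobile fraction in `[0, 1]`.
#' @param tau_s Exponential recovery time constant (s).
#' @param frame_interval_s Time between frames (s).
#' @param n_frames Number of post-bleach frames (>= 5).
#' @param pre_bleach_frames Number of pre-bleach frames (>= 1).
#' @param noise_sd Gaussian noise sd added to every frame.
#' @param seed Integer seed.
#' @return Tibble with columns `time_s`, `intensity`, `phase`
#'   (`"pre"`/`"post"`); post-bleach time starts at 0.
#' @export
render_frap_series <- function(pre_bleach = 1.0, post_bleach = 0.1,
                               mobile_fraction = 0.9, tau_s = 13.0,
                               frame_interval_s = 5, n_frames = 60,
                               pre_bleach_frames = 3, noise_sd = 0.02,
                               seed = 1L) {
  if (post_bleach >= pre_bleach) abort("`post_bleach` must be below `pre_bleach`.")
  if (tau_s <= 0 || frame_interval_s <= 0) abort("`tau_s` and `frame_interval_s` must be positive.")
  if (mobile_fraction < 0 || mobile_fraction > 1) abort("`mobile_fraction` must lie in [0, 1].")
  if (n_frames < 5) abort("At least 5 post-bleach frames are required.")
  if (pre_bleach_frames < 1) abort("At least one pre-bleach frame is required.")
  t_pre <- -rev(seq_len(pre_bleach_frames)) * frame_interval_s
  t_post <- (seq_len(n_frames) - 1) * frame_interval_s
  ideal <- c(rep(pre_bleach, pre_bleach_frames),
             post_bleach + mobile_fraction * (pre_bleach - post_bleach) *
               (1 - exp(-t_post / tau_s)))
  noisy <- withr::with_seed(seed, ideal + rnorm(length(ideal), 0, noise_sd))
  tibble(
    time_s = c(t_pre, t_post),
    intensity = noisy,
    phase = c(rep("pre", pre_bleach_frames), rep("post", n_frames))
  )
}
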