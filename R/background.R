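#' Estimate the background intensity of a field
#'
#' Returns the mean and standard deviation of the condensate-free
#' background. With an `object_mask`, the statistics are computed over the
#' remaining pixels directly. Without one, bright objects are excluded
#' iteratively: the threshold `mean + sd_multiplier * sd` is recomputed and
#' above-threshold pixels dropped until the retained pixel set is stable
#' (at most `max_iter` rounds). The iteration is seeded with robust
#' statistics (median and scaled MAD) so that bright objects cannot inflate
#' the starting threshold; it then refines with the plain mean and sd of
#' the retained pixels. This mirrors an inverted-threshold background
#' measurement: the same (mean, sd) pair then drives both the detection
#' threshold and the partition-ratio denominator.
#'
#' @param image A [field_image].
#' @param object_mask Optional logical matrix marking pixels to exclude.
#' @param sd_multiplier Exclusion threshold multiplier (default 3).
#' @param max_iter Maximum refinement iterations.
#' @return A `background_estimate` list with `mean`, `sd`, `n_pixels`,
#'   `method` (`"masked"` or `"inverted_threshold"`), `iterations`.
#' @export
#' @examples
#' img <- field_image(matrix(100, 64, 64), 0.065)
#' estimate_background(img)
estimate_background <- function(image, object_mask = NULL,
                                sd_multiplier = 3, max_iter = 10) {
  assert_field_image(image)
  v <- as.vector(image$data)
  if (!is.null(object_mask)) {
    keep <- !as.vector(object_mask)
    if (!any(keep)) abort("All pixels are excluded by `object_mask`.")
    return(new_background(mean(v[keep]), sd_or_zero(v[keep]), sum(keep),
                          "masked", 0L))
  }
  st <- iterative_exclusion(v, sd_multiplier, max_iter)
  new_background(st$mean, st$sd, st$n, "inverted_threshold", st$iterations)
}

# Shared iterative-exclusion engine: robust (median/MAD) start, then
# mean/sd refinement of the below-threshold pixel set until stable. An
# exclusion step that would empty the set counts as converged (e.g. a
# constant image, where the threshold equals every pixel).
iterative_exclusion <- function(v, sd_multiplier = 3, max_iter = 10) {
  m <- median(v); s <- stats::mad(v)
  keep <- v < m + sd_multiplier * s
  if (!any(keep)) keep <- rep(TRUE, length(v))
  it <- 0L
  repeat {
    m <- mean(v[keep]); s <- sd_or_zero(v[keep])
    new_keep <- v < m + sd_multiplier * s
    it <- it + 1L
    if (!any(new_keep)) new_keep <- keep
    if (identical(new_keep, keep) || it >= max_iter) {
      m <- mean(v[new_keep]); s <- sd_or_zero(v[new_keep])
      return(list(mean = m, sd = s, n = sum(new_keep), iterations = it))
    }
    keep <- new_keep
  }
}

sd_or_zero <- function(x) if (length(x) < 2) 0 else sd(x)

new_background <- function(mean, sd, n_pixels, method, iterations) {
  structure(
    list(mean = mean, sd = sd, n_pixels = as.integer(n_pixels),
         method = method, iterations = iterations),
    class = "background_estimate"
  )
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("<background_estimate> mean %.2f, sd %.2f ADU over %d px (%s)\n",
              x$mean, x$sd, x$n_pixels, x$method))
  invisible(x)
}
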