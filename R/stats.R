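#' Two-sample Student's t-test (pooled variance)
#'
#' The classic two-tailed Student's t-test with pooled variance, the test
#' conventionally reported alongside condensate group comparisons. Welch's
#' unequal-variance form is available via `welch = TRUE`. Implemented
#' directly from the pooled-variance formula so degenerate inputs are
#' handled explicitly: zero pooled variance with equal means yields
#' `t = 0, p = 1`; zero pooled variance with unequal means is an error.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use Welch's approximation instead of pooled variance.
#' @return One-row tibble with `t`, `df`, `p`.
#' @export
#' @examples
#' two_sample_ttest(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, p ~ 0.288
two_sample_ttest <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("Each sample needs n >= 2.")
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  if (welch) {
    se2 <- va / na + vb / nb
    if (se2 == 0) {
      if (mean(a) == mean(b)) return(tibble(t = 0, df = na + nb - 2, p = 1))
      abort("Zero variance with unequal means: t is undefined.")
    }
    t_stat <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    df <- na + nb - 2
    if (sp2 == 0) {
      if (mean(a) == mean(b)) return(tibble(t = 0, df = df, p = 1))
      abort("Zero pooled variance with unequal means: t is undefined.")
    }
    t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  }
  tibble(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

#' Summarize condensation kinetics: plateaus and t90 times
#'
#' For each series in a per-frame summary (`count`, `mean_diameter_um`,
#' `mean_partition_ratio`), takes the plateau as the mean of the final 10%
#' of frames and reports `t90`, the first time the series crosses 90% of
#' the plateau (linear interpolation between frames). Series that never
#' reach 90% of their plateau get `reached = FALSE`.
#'
#' @param per_frame Tibble with a `time_s` column and one or more numeric
#'   series columns (default those produced by [render_kinetics_series()]).
#' @param series Character vector of series column names to summarize.
#' @return Tibble with one row per series: `series`, `plateau`, `t90_s`,
#'   `reached`.
#' @export
kinetics_summary <- function(per_frame,
                             series = intersect(
                               c("count", "mean_diameter_um",
                                 "mean_partition_ratio"),
                               names(per_frame))) {
  if (nrow(per_frame) < 5) abort("At least 5 frames are required.")
  if (!"time_s" %in% names(per_frame)) abort("`per_frame` needs a time_s column.")
  purrr::map_dfr(series, function(s) {
    y <- per_frame[[s]]; t <- per_frame$time_s
    ok <- !is.na(y)
    y <- y[ok]; t <- t[ok]
    n_tail <- max(1, ceiling(0.1 * length(y)))
    plateau <- mean(tail(y, n_tail))
    target <- 0.9 * plateau
    if (y[1] >= target) {
      return(tibble(series = s, plateau = plateau, t90_s = t[1], reached = TRUE))
    }
    cross <- which(y >= target)[1]
    if (is.na(cross)) {
      return(tibble(series = s, plateau = plateau, t90_s = NA_real_,
                    reached = FALSE))
    }
    # linear interpolation between the bracketing frames
    t0 <- t[cross - 1]; t1 <- t[cross]
    y0 <- y[cross - 1]; y1 <- y[cross]
    t90 <- t0 + (target - y0) / (y1 - y0) * (t1 - t0)
    tibble(series = s, plateau = plateau, t90_s = t90, reached = TRUE)
  })
}

#' Construct metadata table for repeat-tagged RNAs
#'
#' Records the number of CAG trinucleotide repeats and the total transcript
#' length of each construct, and derives the repeat-content ratio
#' `N_CAG / N_total` as a percentage. By default the repeat content is
#' counted in nucleotides (`3 * repeats / total_length_nt`); set
#' `repeat_units = "repeats"` to count repeat units instead.
#'
#' @param name Construct names.
#' @param n_cag_repeats Integer repeat counts.
#' @param total_length_nt Total transcript lengths (nt).
#' @param repeat_units `"nt"` (default) or `"repeats"`.
#' @return Tibble with a `ratio_pct` column.
#' @export
construct_metadata <- function(name, n_cag_repeats, total_length_nt,
                               repeat_units = c("nt", "repeats")) {
  repeat_units <- match.arg(repeat_units)
  if (any(total_length_nt < 3 * n_cag_repeats)) {
    abort("Total length must be at least the repeat-tract length.")
  }
  num <- if (repeat_units == "nt") 3 * n_cag_repeats else n_cag_repeats
  tibble(name = name, n_cag_repeats = as.integer(n_cag_repeats),
         total_length_nt = as.integer(total_length_nt),
         ratio_pct = 100 * num / total_length_nt)
}

#' Aggregate condensate records by repeat-content ratio
#'
#' Joins per-condensate records to construct metadata and reports, per
#' construct, the mean radius and mean partition ratio with their SEMs,
#' keyed by the repeat-content ratio (percent). Grouping over condensates
#' is the default; `by_field` groups replicate fields first and computes
#' the SEM over field means instead.
#'
#' @param records Tibble of condensate records with a `construct` column
#'   (and `equivalent_diameter_um`, `partition_ratio`); a `field` column is
#'   required when `by_field = TRUE`.
#' @param meta Tibble from [construct_metadata()].
#' @param by_field SEM over replicate fields instead of over condensates.
#' @return Tibble with one row per construct, ordered by `ratio_pct`.
#' @export
aggregate_by_ratio <- function(records, meta, by_field = FALSE) {
  if (!"construct" %in% names(records)) abort("`records` needs a construct column.")
  sem <- function(x) sd_or_zero(x) / sqrt(length(x))
  if (by_field) {
    if (!"field" %in% names(records)) abort("`by_field` needs a field column.")
    records <- records %>%
      group_by(.data$construct, .data$field) %>%
      summarise(
        equivalent_diameter_um = mean(.data$equivalent_diameter_um),
        partition_ratio = mean(.data$partition_ratio), .groups = "drop")
  }
  records %>%
    group_by(.data$construct) %>%
    summarise(
      n = n(),
      mean_radius_um = mean(.data$equivalent_diameter_um / 2),
      sem_radius_um = sem(.data$equivalent_diameter_um / 2),
      mean_partition_ratio = mean(.data$partition_ratio),
      sem_partition_ratio = sem(.data$partition_ratio),
      .groups = "drop") %>%
    left_join(meta, by = c(construct = "name")) %>%
    arrange(.data$ratio_pct)
}

#' Convert fluorescence intensity to concentration
#'
#' Linear calibration `(intensity - intercept) / slope`, with the slope and
#' intercept supplied by the user from known-concentration standards (for
#' example the bulk condition of the condensate preparation). Negative
#' results are clipped at zero with a warning.
#'
#' @param mean_intensity Numeric intensities (ADU).
#' @param slope ADU per uM; must be positive.
#' @param intercept ADU offset at zero concentration.
#' @return Concentrations in uM.
#' @export
fluorescence_to_concentration <- function(mean_intensity, slope, intercept = 0) {
  if (slope <= 0) abort("`slope` must be positive.")
  conc <- (mean_intensity - intercept) / slope
  if (any(conc < 0)) {
    warn("Negative concentration(s) clipped at 0.")
    conc[conc < 0] <- 0
  }
  conc
}
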