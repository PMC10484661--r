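#' Pearson colocalization of two channels over a mask
#'
#' Computes the Pearson correlation coefficient (PCC) of two fluorescence
#' channels over the pixels of a mask. Restricting to cell (or object)
#' masks avoids the background-driven inflation that whole-image PCC
#' suffers from; pass `mask = NULL` explicitly for a whole-image PCC.
#'
#' @param ch1,ch2 [field_image]s of identical dimensions.
#' @param mask Logical matrix selecting the pixels to correlate, or NULL
#'   for the whole image.
#' @return Scalar PCC in `[-1, 1]`.
#' @export
#' @examples
#' a <- field_image(matrix(rnorm(100, 100, 10), 32), 0.065)
#' b <- field_image(2 * a$data + 5, 0.065)
#' pearson_colocalization(a, b)  # 1
pearson_colocalization <- function(ch1, ch2, mask = NULL) {
  assert_field_image(ch1, "ch1"); assert_field_image(ch2, "ch2")
  if (!identical(dim(ch1$data), dim(ch2$data))) {
    abort("`ch1` and `ch2` must have identical dimensions.")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ch1$data), ncol(ch1$data))
  if (!any(mask)) abort("`mask` is empty.")
  x <- ch1$data[mask]; y <- ch2$data[mask]
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero variance in a channel over the mask; PCC is undefined.")
  }
  stats::cor(x, y)
}
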