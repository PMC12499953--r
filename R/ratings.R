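#' Transform raw VAS clicks into \[0, 1\] ratings
#'
#' Linear map of a click position in pixels onto the rating scale: 0 at the
#' /s/ end of the arrow, 1 at the /sh/ end. Clicks outside the arrow are
#' clamped to the nearer end with a warning. The orientation (0 = /s/) is a
#' fixed convention of the package; every downstream sign interpretation
#' depends on it.
#'
#' @param click_px Click positions in pixels (vector).
#' @param scale_min_px,scale_max_px Pixel positions of the /s/ and /sh/ arrow
#'   tips (scalars or vectors).
#' @return Ratings in \[0, 1\].
#' @export
transform_click <- function(click_px, scale_min_px, scale_max_px) {
  if (any(scale_max_px <= scale_min_px)) {
    stop("transform_click: scale_max_px must exceed scale_min_px",
         call. = FALSE)
  }
  v <- (click_px - scale_min_px) / (scale_max_px - scale_min_px)
  n_out <- sum(v < 0 | v > 1)
  if (n_out > 0) {
    warning(sprintf("transform_click: %d click(s) outside the scale clamped to the nearer end",
                    n_out), call. = FALSE)
    v <- pmin(1, pmax(0, v))
  }
  v
}

#' Compress ratings into the open interval (0, 1)
#'
#' The beta likelihood is undefined at exactly 0 or 1, so ratings are
#' compressed with the standard transformation
#' \deqn{y' = (y (n - 1) + 0.5) / n}
#' applied uniformly to all values, where `n` is the number of ratings in the
#' analysis set. The map is strictly monotone and converges to the identity
#' as `n` grows (`|y' - y| <= 0.5 / n`).
#'
#' @param values Ratings in \[0, 1\].
#' @param n Number of ratings in the analysis set (default `length(values)`).
#' @return Values in the open interval (0, 1).
#' @export
squeeze_boundaries <- function(values, n = length(values)) {
  if (n < 2) {
    stop("squeeze_boundaries: need n >= 2", call. = FALSE)
  }
  (values * (n - 1) + 0.5) / n
}

#' Prepare a raw VAS click table for modeling
#'
#' @param clicks Data frame with columns `listener_id`, `token_id`,
#'   `click_px`, `scale_min_px`, `scale_max_px`.
#' @return Data frame `listener_id`, `token_id`, `value` (closed interval),
#'   `value_open` (after boundary compression over the whole table).
#' @export
prepare_ratings <- function(clicks) {
  required <- c("listener_id", "token_id", "click_px", "scale_min_px",
                "scale_max_px")
  missing <- setdiff(required, names(clicks))
  if (length(missing)) {
    stop(sprintf("prepare_ratings: missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  v <- transform_click(clicks$click_px, clicks$scale_min_px,
                       clicks$scale_max_px)
  data.frame(listener_id = clicks$listener_id,
             token_id = clicks$token_id,
             value = v,
             value_open = squeeze_boundaries(v),
             stringsAsFactors = FALSE)
}
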